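# Seeded synthetic-study generator. Emits a self-consistent miniature
# regulatory-genomics study — genome layout, peaks, sequences with planted
# motif instances, per-group cleavage profiles with planted footprints,
# negative-binomial tag counts with planted group-specific accessibility,
# promoter-capture interactions, and an FPKM table with planted TF->target
# up-regulation — in exactly the formats the readers in this package accept,
# together with the ground truth needed to score recovery.

#' Synthetic study configuration
#'
#' Defaults emulate the study design this package targets: two AML patients
#' of the subtype of interest (`t69`), two NPM1-mutated and two FLT3-ITD
#' patients, three healthy PBSC references; 4-fold planted accessibility and
#' expression effects; digital footprints as 80% cleavage depletion
#' (`footprint_depletion = 0.2`) at occupied 20-bp motif instances under
#' 2 cuts/bp coverage across 2 kb windows.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp, or `NULL` to derive from the
#'   gene grid.
#' @param n_peaks total number of peaks (distal plus proximal).
#' @param peak_width peak width in bp.
#' @param window profile window in bp, centered on the peak midpoint.
#' @param n_tfs number of planted transcription factors.
#' @param n_targets number of planted target genes (>= `n_tfs`).
#' @param sites_per_edge planted regulatory sites per TF->target edge.
#' @param motif_length length of planted motifs / protected footprints (bp).
#' @param groups named integer vector, group label -> number of samples.
#' @param aml_group group carrying the planted regulatory program.
#' @param reference_group healthy reference group.
#' @param n_specific_per_group planted group-specific peaks for each
#'   non-AML, non-reference group.
#' @param n_constitutive background peaks with a constitutively occupied
#'   housekeeping motif (footprinted in every group).
#' @param n_proximal peaks planted within the promoter-exclusion radius.
#' @param decoy_frac fraction of plain background peaks given a decoy
#'   interaction to a random gene.
#' @param accessibility_fold planted tag-count fold for group-specific peaks
#'   (>= 1; 1 plants nothing).
#' @param expression_fold planted expression fold for edge targets (>= 1;
#'   1 plants nothing). Planted on the pseudocounted scale so that a
#'   noise-free study passes a `fold`-threshold filter exactly.
#' @param footprint_depletion cleavage-rate multiplier inside occupied
#'   motifs, in (0, 1].
#' @param mean_cuts_per_bp mean cleavage rate (cuts/bp) across windows.
#' @param nb_dispersion negative-binomial size parameter for tag counts
#'   (larger = closer to Poisson).
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of
#'   per-peak base mean counts.
#' @param tf_fpkm baseline FPKM of planted TFs.
#' @param target_fpkm_meanlog,target_fpkm_sdlog log-normal parameters of
#'   target-gene baseline FPKM.
#' @param n_down_genes genes planted down-regulated in the AML group.
#' @param n_null_genes unplanted genes.
#' @param expression_noise_sd sd of multiplicative log-normal expression
#'   noise (0 = noise-free).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chromosomes = 2, chrom_length = NULL,
                       n_peaks = 2400, peak_width = 400, window = 2000,
                       n_tfs = 10, n_targets = 200, sites_per_edge = 2,
                       motif_length = 20,
                       groups = c(t69 = 2, NPM1 = 2, FLT3_ITD = 2, PBSC = 3),
                       aml_group = "t69", reference_group = "PBSC",
                       n_specific_per_group = 200, n_constitutive = 100,
                       n_proximal = 100, decoy_frac = 0.1,
                       accessibility_fold = 4, expression_fold = 4,
                       footprint_depletion = 0.2, mean_cuts_per_bp = 2,
                       nb_dispersion = 20, base_mean_meanlog = log(100),
                       base_mean_sdlog = 0.5, tf_fpkm = 30,
                       target_fpkm_meanlog = log(10),
                       target_fpkm_sdlog = 0.5, n_down_genes = 50,
                       n_null_genes = 50, expression_noise_sd = 0.25) {
  cfg <- as.list(environment())
  if (n_targets < n_tfs)
    stop("n_targets < n_tfs: each TF needs at least one target")
  if (window < peak_width) stop("window must be >= peak_width")
  if (accessibility_fold < 1 || expression_fold < 1)
    stop("planted folds must be >= 1")
  if (footprint_depletion <= 0 && footprint_depletion != 0)
    stop("footprint_depletion must be in [0, 1]")
  if (footprint_depletion > 1) stop("footprint_depletion must be <= 1")
  if (mean_cuts_per_bp <= 0) stop("mean_cuts_per_bp must be positive")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector")
  if (any(groups < 1)) stop("every group needs >= 1 sample")
  if (!aml_group %in% names(groups) || !reference_group %in% names(groups))
    stop("aml_group and reference_group must be members of groups")
  for (f in c("n_chromosomes", "n_peaks", "peak_width", "window", "n_tfs",
              "n_targets", "sites_per_edge", "motif_length"))
    if (cfg[[f]] < 1) stop(f, " must be positive")
  if (motif_length < 4) stop("motif_length must be >= 4")
  if (peak_width < motif_length + 40)
    stop("peak_width too small for planted motifs")
  class(cfg) <- "sim_config"
  cfg
}

GENE_SPACING <- 20000
TSS_OFFSET <- 10000
SLOT_OFFSETS <- seq(2000, 16000, by = 2000)  # distal slots per gene block

study_genes <- function(cfg) {
  lsc <- read_lsc17_weights(system.file("extdata", "lsc17_weights.tsv",
                                        package = "accessGRN"))
  list(tfs = sprintf("TF%02d", seq_len(cfg$n_tfs)),
       hk = "HKTF",
       targets = sprintf("TG%03d", seq_len(cfg$n_targets)),
       down = if (cfg$n_down_genes) sprintf("DN%02d",
                                            seq_len(cfg$n_down_genes))
              else character(),
       null = if (cfg$n_null_genes) sprintf("NL%02d",
                                            seq_len(cfg$n_null_genes))
              else character(),
       lsc17 = lsc$gene_id, lsc17_weights = lsc)
}

sample_ids <- function(cfg) {
  unlist(lapply(names(cfg$groups), function(g)
    paste0(g, "_", seq_len(cfg$groups[[g]]))), use.names = FALSE)
}

sample_groups <- function(cfg) {
  ids <- sample_ids(cfg)
  setNames(sub("_[0-9]+$", "", ids), ids)
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Lay out genes on a regular grid and peaks in fixed distal slots between
# TSSs, so "nearest TSS" is unambiguous and every distal slot clears the
# promoter-exclusion radius by construction.
plan_study <- function(cfg) {
  g <- study_genes(cfg)
  gene_ids <- c(g$tfs, g$hk, g$targets, g$down, g$null, g$lsc17)
  n_genes <- length(gene_ids)
  per_chrom <- ceiling(n_genes / cfg$n_chromosomes)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_len <- if (is.null(cfg$chrom_length))
    TSS_OFFSET + per_chrom * GENE_SPACING + TSS_OFFSET else cfg$chrom_length
  gi <- seq_len(n_genes)
  tss <- data.frame(
    gene_id = gene_ids,
    chrom = chroms[((gi - 1) %% cfg$n_chromosomes) + 1],
    pos = TSS_OFFSET + ((gi - 1) %/% cfg$n_chromosomes) * GENE_SPACING,
    strand = "+", stringsAsFactors = FALSE)
  class(tss) <- c("tss_annotation", "data.frame")
  if (max(tss$pos) + GENE_SPACING > chrom_len)
    stop("chrom_length too small for the gene grid")

  slot <- expand.grid(gene = gi, off = SLOT_OFFSETS)
  slot_start <- tss$pos[slot$gene] + slot$off
  slot_chrom <- tss$chrom[slot$gene]
  n_edge_sites <- cfg$n_targets * cfg$sites_per_edge
  other_groups <- setdiff(names(cfg$groups),
                          c(cfg$aml_group, cfg$reference_group))
  n_specific <- length(other_groups) * cfg$n_specific_per_group
  n_distal <- cfg$n_peaks - cfg$n_proximal
  n_background <- n_distal - n_edge_sites - n_specific - cfg$n_constitutive
  if (n_background < 0)
    stop("n_peaks too small for the requested planted categories")
  if (n_distal > nrow(slot))
    stop("n_peaks exceeds available distal slots (",
         nrow(slot), "); increase n_targets/genes or reduce n_peaks")
  pick <- sample(nrow(slot), n_distal)
  category <- rep("background", n_distal)
  idx <- 1
  category[idx:(idx + n_edge_sites - 1)] <- "edge_site"
  idx <- idx + n_edge_sites
  for (og in other_groups) {
    if (cfg$n_specific_per_group > 0) {
      category[idx:(idx + cfg$n_specific_per_group - 1)] <-
        paste0("specific_", og)
      idx <- idx + cfg$n_specific_per_group
    }
  }
  if (cfg$n_constitutive > 0)
    category[idx:(idx + cfg$n_constitutive - 1)] <- "constitutive"

  peaks_df <- data.frame(chrom = slot_chrom[pick], start = slot_start[pick],
                         category = category, stringsAsFactors = FALSE)
  if (cfg$n_proximal > 0) {
    pg <- sample(gi, cfg$n_proximal)
    peaks_df <- rbind(peaks_df, data.frame(
      chrom = tss$chrom[pg], start = tss$pos[pg] + 300,
      category = "proximal", stringsAsFactors = FALSE))
  }
  ord <- order(peaks_df$chrom, peaks_df$start)
  peaks_df <- peaks_df[ord, , drop = FALSE]
  peaks_df$id <- sprintf("pk%04d", seq_len(nrow(peaks_df)))
  peaks <- genomic_intervals(peaks_df$chrom, peaks_df$start,
                             peaks_df$start + cfg$peak_width,
                             id = peaks_df$id)
  list(genes = g, gene_ids = gene_ids, tss = tss, chroms = chroms,
       chrom_length = chrom_len, peaks = peaks,
       category = setNames(peaks_df$category, peaks_df$id),
       other_groups = other_groups)
}

#' Generate a complete synthetic study on disk
#'
#' Emits `peaks.bed`, `peaks.fasta`, `tss.bed`, `interactions.bedpe`,
#' `counts.tsv`, `samples.tsv`, `expression.tsv`, `pwms.jaspar`,
#' `tf_motifs.tsv`, one `cuts_<group>.tsv` per sample group, and
#' `truth.json`, all in the formats read by this package. Identical seed and
#' config produce byte-identical outputs. The returned (and serialized)
#' ground truth suffices to predict which peaks pass any fold threshold in
#' expectation and which network edges are recoverable.
#'
#' @param config a [sim_config].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `truth`, `files` (named paths) and
#'   `outdir`.
#' @export
generate_study <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  plan <- plan_study(config)
  g <- plan$genes
  cat_of <- plan$category
  peaks <- plan$peaks

  # --- motifs: near-deterministic consensus PWMs for each TF -------------
  tf_all <- c(g$tfs, g$hk)
  motif_of <- setNames(paste0("M_", tf_all), tf_all)
  consensus <- setNames(vapply(tf_all, function(x)
    random_seq(config$motif_length), ""), motif_of[tf_all])
  pwm_counts <- lapply(consensus, function(cs) {
    m <- matrix(0, 4, nchar(cs), dimnames = list(BASES, NULL))
    m[cbind(match(strsplit(cs, "")[[1]], BASES), seq_len(nchar(cs)))] <- 100
    m
  })

  # --- planted edges and site assignment ---------------------------------
  edge_sites <- names(cat_of)[cat_of == "edge_site"]
  edge_sites <- sample(edge_sites)   # random pairing of sites to targets
  tf_of_target <- setNames(g$tfs[((seq_len(config$n_targets) - 1) %%
                                    config$n_tfs) + 1], g$targets)
  planted_edges <- lapply(seq_len(config$n_targets), function(j) {
    sites <- edge_sites[((j - 1) * config$sites_per_edge + 1):
                          (j * config$sites_per_edge)]
    list(tf = unname(tf_of_target[g$targets[j]]), target = g$targets[j],
         site_ids = sites)
  })

  # --- occupied motif occurrences ----------------------------------------
  const_sites <- names(cat_of)[cat_of == "constitutive"]
  occ_rows <- list()
  plant_occ <- function(peak_id, motif_id, groups_active) {
    L <- nchar(consensus[[motif_id]])
    offset <- sample(seq(20, config$peak_width - L - 20), 1)
    strand <- sample(c("+", "-"), 1)
    data.frame(peak_id = peak_id, offset = offset, width = L,
               strand = strand, motif_id = motif_id,
               groups = paste(groups_active, collapse = ","),
               stringsAsFactors = FALSE)
  }
  for (e in planted_edges)
    for (s in e$site_ids)
      occ_rows[[length(occ_rows) + 1L]] <-
        plant_occ(s, unname(motif_of[e$tf]), config$aml_group)
  for (s in const_sites)
    occ_rows[[length(occ_rows) + 1L]] <-
      plant_occ(s, unname(motif_of[g$hk]), names(config$groups))
  occupied <- data.table::setDF(data.table::rbindlist(occ_rows))

  # --- peak sequences with motif instances written in --------------------
  seqs <- setNames(vapply(seq_len(nrow(peaks)), function(i)
    random_seq(config$peak_width), ""), peaks$id)
  for (i in seq_len(nrow(occupied))) {
    cs <- consensus[[occupied$motif_id[i]]]
    if (occupied$strand[i] == "-") cs <- revcomp(cs)
    s <- seqs[[occupied$peak_id[i]]]
    substr(s, occupied$offset[i] + 1,
           occupied$offset[i] + occupied$width[i]) <- cs
    seqs[[occupied$peak_id[i]]] <- s
  }

  # --- ground truth -------------------------------------------------------
  gsp <- setNames(vector("list", length(names(config$groups))),
                  names(config$groups))
  for (grp in names(config$groups)) gsp[[grp]] <- character()
  if (config$accessibility_fold > 1) {
    gsp[[config$aml_group]] <- sort(names(cat_of)[cat_of == "edge_site"])
    for (og in plan$other_groups)
      gsp[[og]] <- sort(names(cat_of)[cat_of == paste0("specific_", og)])
  }
  de <- list()
  de[[config$aml_group]] <- if (config$expression_fold > 1)
    list(up = g$targets, down = g$down)
  else list(up = character(), down = character())
  truth <- structure(list(
    peak_ids = peaks$id,
    tf_motif_map = as.list(motif_of),
    planted_edges = planted_edges,
    group_specific_peaks = gsp,
    planted_de_genes = de,
    occupied_motif_occurrences = occupied,
    config = list(seed = config$seed, window = config$window,
                  peak_width = config$peak_width,
                  motif_length = config$motif_length,
                  accessibility_fold = config$accessibility_fold,
                  expression_fold = config$expression_fold,
                  footprint_depletion = config$footprint_depletion,
                  mean_cuts_per_bp = config$mean_cuts_per_bp,
                  groups = as.list(config$groups),
                  aml_group = config$aml_group,
                  reference_group = config$reference_group)),
    class = "ground_truth")

  # --- tag counts ---------------------------------------------------------
  counts <- simulate_counts(truth, config)

  # --- cut profiles per group --------------------------------------------
  profiles <- list()
  for (grp in names(config$groups)) {
    active <- vapply(strsplit(occupied$groups, ",", fixed = TRUE),
                     function(gl) grp %in% gl, TRUE)
    oa <- occupied[active, , drop = FALSE]
    profiles[[grp]] <- setNames(lapply(seq_len(nrow(peaks)), function(i) {
      po <- oa[oa$peak_id == peaks$id[i], , drop = FALSE]
      simulate_cut_profile(peaks[i, , drop = FALSE], po, config)
    }), peaks$id)
  }

  # --- expression ---------------------------------------------------------
  expr <- simulate_expression(truth, config, g)

  # --- interactions -------------------------------------------------------
  target_of_site <- list()
  for (e in planted_edges) for (s in e$site_ids) target_of_site[[s]] <- e$target
  tss_pos <- setNames(plan$tss$pos, plan$tss$gene_id)
  tss_chrom <- setNames(plan$tss$chrom, plan$tss$gene_id)
  bg <- names(cat_of)[cat_of == "background"]
  decoys <- sample(bg, round(config$decoy_frac * length(bg)))
  ia_rows <- list()
  pk_idx <- setNames(seq_len(nrow(peaks)), peaks$id)
  add_ia <- function(pid, gene, score) {
    i <- pk_idx[[pid]]
    data.frame(p_chrom = unname(tss_chrom[gene]),
               p_start = max(0, tss_pos[[gene]] - 1000),
               p_end = tss_pos[[gene]] + 1000,
               d_chrom = peaks$chrom[i], d_start = peaks$start[i],
               d_end = peaks$end[i], gene_id = gene, score = score,
               stringsAsFactors = FALSE)
  }
  for (pid in names(target_of_site))
    ia_rows[[length(ia_rows) + 1L]] <-
      add_ia(pid, target_of_site[[pid]], round(runif(1, 5, 10), 3))
  for (pid in decoys)
    ia_rows[[length(ia_rows) + 1L]] <-
      add_ia(pid, sample(plan$gene_ids, 1), round(runif(1, 0.5, 5), 3))
  interactions <- data.table::setDF(data.table::rbindlist(ia_rows))
  class(interactions) <- c("interaction_set", "data.frame")

  # --- write everything ---------------------------------------------------
  fp <- function(name) file.path(outdir, name)
  files <- c(peaks = fp("peaks.bed"), fasta = fp("peaks.fasta"),
             tss = fp("tss.bed"), interactions = fp("interactions.bedpe"),
             counts = fp("counts.tsv"), samples = fp("samples.tsv"),
             expression = fp("expression.tsv"), pwms = fp("pwms.jaspar"),
             tf_motifs = fp("tf_motifs.tsv"), truth = fp("truth.json"))
  write_bed(peaks, files[["peaks"]])
  write_fasta(seqs, files[["fasta"]])
  write_tss(plan$tss, files[["tss"]])
  write_interactions(interactions, files[["interactions"]])
  write_count_matrix(counts, files[["counts"]])
  write_sample_table(sample_groups(config), files[["samples"]])
  write_expression(expr, files[["expression"]])
  write_pwms(pwm_counts, files[["pwms"]])
  data.table::fwrite(data.table::data.table(
    tf = tf_all, motif_id = unname(motif_of[tf_all])),
    files[["tf_motifs"]], sep = "\t", quote = FALSE)
  for (grp in names(config$groups)) {
    f <- fp(paste0("cuts_", grp, ".tsv"))
    write_cut_profiles(profiles[[grp]], f)
    files[[paste0("cuts_", grp)]] <- f
  }
  write_truth(truth, files[["truth"]])
  invisible(list(truth = truth, files = files, outdir = outdir))
}

#' Simulate a tag count matrix from a ground truth
#'
#' Per-peak base means are log-normal and shared across samples; the count
#' of peak p in sample s is negative binomial with mean
#' base_mean(p) * accessibility_fold when p is planted specific to s's
#' group (1 otherwise) and size `nb_dispersion`.
#'
#' @param truth a `ground_truth` (needs `peak_ids` and
#'   `group_specific_peaks`).
#' @param config the [sim_config] the truth was generated under.
#' @return a raw [tag_count_matrix] with group labels.
#' @export
simulate_counts <- function(truth, config) {
  ids <- truth$peak_ids
  base <- rlnorm(length(ids), config$base_mean_meanlog,
                 config$base_mean_sdlog)
  groups <- sample_groups(config)
  m <- matrix(0, length(ids), length(groups),
              dimnames = list(ids, names(groups)))
  for (s in names(groups)) {
    fold <- rep(1, length(ids))
    spec <- truth$group_specific_peaks[[groups[[s]]]]
    if (length(spec)) fold[ids %in% spec] <- config$accessibility_fold
    m[, s] <- rnbinom(length(ids), mu = base * fold,
                      size = config$nb_dispersion)
  }
  tag_count_matrix(m, groups = groups)
}

#' Simulate a per-base cut profile for one peak
#'
#' Per-base cuts are Poisson(`mean_cuts_per_bp`); at bases covered by an
#' occupied motif occurrence the rate is multiplied by
#' `footprint_depletion`. The window is centered on the peak midpoint.
#'
#' @param peak single-row [genomic_intervals].
#' @param occupied data.frame of occupied occurrences in this peak with
#'   columns `offset` (0-based, peak-relative) and `width`; may be empty.
#' @param config a [sim_config].
#' @return a [cut_profile].
#' @export
simulate_cut_profile <- function(peak, occupied, config) {
  mid <- interval_midpoint(peak)
  ws <- mid - config$window / 2
  rate <- rep(config$mean_cuts_per_bp, config$window)
  if (!is.null(occupied) && nrow(occupied)) {
    for (i in seq_len(nrow(occupied))) {
      a <- peak$start + occupied$offset[i] - ws          # window-relative
      b <- a + occupied$width[i]
      if (a < 0 || b > config$window)
        stop("occupied occurrence [", a, ", ", b, ") outside window")
      rate[(a + 1):b] <- rate[(a + 1):b] * config$footprint_depletion
    }
  }
  cut_profile(peak$id, ws, rpois(config$window, rate))
}

# Expression: TFs flat and high; targets up in the AML group on the
# pseudocounted scale (mean = fold*(b+1) - 1); planted down genes have
# baseline >= 3 so (b+1)/fold - 1 stays non-negative; LSC17 genes carry a
# doubled positive-weight component in the AML group (higher stemness).
simulate_expression <- function(truth, config, genes) {
  groups <- sample_groups(config)
  gene_ids <- c(genes$tfs, genes$hk, genes$targets, genes$down, genes$null,
                genes$lsc17)
  n <- length(gene_ids)
  base <- setNames(numeric(n), gene_ids)
  base[c(genes$tfs, genes$hk)] <- config$tf_fpkm
  base[genes$targets] <- rlnorm(length(genes$targets),
                                config$target_fpkm_meanlog,
                                config$target_fpkm_sdlog)
  if (length(genes$down))
    base[genes$down] <- 3 + rlnorm(length(genes$down), log(17), 0.4)
  if (length(genes$null))
    base[genes$null] <- rlnorm(length(genes$null),
                               config$target_fpkm_meanlog,
                               config$target_fpkm_sdlog)
  base[genes$lsc17] <- rlnorm(length(genes$lsc17), log(15), 0.5)
  pos_lsc <- genes$lsc17[genes$lsc17_weights$weight > 0]
  m <- matrix(0, n, length(groups), dimnames = list(gene_ids, names(groups)))
  for (s in names(groups)) {
    mu <- base
    if (groups[[s]] == config$aml_group) {
      if (config$expression_fold > 1) {
        mu[genes$targets] <- config$expression_fold *
          (base[genes$targets] + 1) - 1
        if (length(genes$down))
          mu[genes$down] <- (base[genes$down] + 1) / config$expression_fold - 1
      }
      mu[pos_lsc] <- 2 * base[pos_lsc]
    }
    noise <- exp(rnorm(n, 0, config$expression_noise_sd))
    m[, s] <- mu * noise
  }
  expression_table(m, groups = groups)
}

#' Write / read the ground truth (JSON)
#'
#' The schema mirrors the `ground_truth` fields: `peak_ids`,
#' `tf_motif_map`, `planted_edges` (records with `tf`, `target`,
#' `site_ids`), `group_specific_peaks`, `planted_de_genes` (per group, `up`
#' and `down`), `occupied_motif_occurrences` (records with `peak_id`,
#' `offset`, `width`, `strand`, `motif_id`, `groups`), and a `config` echo.
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  truth <- list(
    peak_ids = as.character(obj$peak_ids),
    tf_motif_map = lapply(obj$tf_motif_map, as.character),
    planted_edges = lapply(seq_len(nrow(obj$planted_edges)), function(i)
      list(tf = obj$planted_edges$tf[[i]][1],
           target = obj$planted_edges$target[[i]][1],
           site_ids = as.character(unlist(obj$planted_edges$site_ids[[i]])))),
    group_specific_peaks = lapply(obj$group_specific_peaks, as.character),
    planted_de_genes = lapply(obj$planted_de_genes, function(x)
      list(up = as.character(unlist(x$up)),
           down = as.character(unlist(x$down)))),
    occupied_motif_occurrences = local({
      oc <- obj$occupied_motif_occurrences
      data.frame(peak_id = unlist(oc$peak_id), offset = unlist(oc$offset),
                 width = unlist(oc$width), strand = unlist(oc$strand),
                 motif_id = unlist(oc$motif_id), groups = unlist(oc$groups),
                 stringsAsFactors = FALSE)
    }),
    config = lapply(obj$config, function(x)
      if (is.list(x)) lapply(x, unlist) else unlist(x)))
  class(truth) <- "ground_truth"
  truth
}
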
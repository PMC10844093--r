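# Enhancer-to-gene assignment and TF -> target network construction.
# Edges require a footprinted motif occurrence of the TF inside an
# AML-specific peak assigned to the target gene, with both TF and target
# expressed: the strict "footprinted motifs" reading.

#' Assign peaks to cognate genes, interaction-first
#'
#' A peak overlapping (>= 1 bp) the distal anchor of any interaction with
#' score >= `min_interaction_score` is assigned to that interaction's gene
#' (highest score wins, ties broken by gene id order) with evidence
#' `"interaction"` and distance 0. Otherwise it is assigned to the nearest
#' TSS (midpoint-to-TSS distance, same chromosome) when within
#' `max_nearest` bp, with evidence `"nearest"`; otherwise it is unmapped.
#'
#' @param peaks a [genomic_intervals] object with ids.
#' @param interactions an `interaction_set` from [read_interactions].
#' @param tss a `tss_annotation` from [read_tss].
#' @param max_nearest maximum nearest-TSS distance in bp (default 50000).
#' @param min_interaction_score minimum interaction score (default 0).
#' @return list with `map` (data.frame `peak_id`, `gene_id`, `evidence`,
#'   `distance`) and `unmapped` (character vector of peak ids).
#' @export
assign_peaks_to_genes <- function(peaks, interactions, tss,
                                  max_nearest = 50000,
                                  min_interaction_score = 0) {
  stopifnot(!anyNA(peaks$id))
  n <- nrow(peaks)
  gene <- rep(NA_character_, n)
  evid <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  ia <- interactions[interactions$score >= min_interaction_score, ,
                     drop = FALSE]
  if (nrow(ia) > 0 && n > 0) {
    for (ch in intersect(unique(peaks$chrom), unique(ia$d_chrom))) {
      pi <- which(peaks$chrom == ch)
      ii <- which(ia$d_chrom == ch)
      # IRanges is 1-based closed; shift half-open [s, e) to [s+1, e]
      q <- IRanges::IRanges(peaks$start[pi] + 1, peaks$end[pi])
      s <- IRanges::IRanges(ia$d_start[ii] + 1, ia$d_end[ii])
      ov <- IRanges::findOverlaps(q, s)
      if (!length(ov)) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      for (k in unique(qh)) {
        cand <- ii[sh[qh == k]]
        best <- cand[order(-ia$score[cand], ia$gene_id[cand])][1]
        gene[pi[k]] <- ia$gene_id[best]
        evid[pi[k]] <- "interaction"
        dist[pi[k]] <- 0
      }
    }
  }
  mid <- interval_midpoint(peaks)
  todo <- which(is.na(gene))
  for (ch in unique(peaks$chrom[todo])) {
    i <- todo[peaks$chrom[todo] == ch]
    tt <- tss[tss$chrom == ch, , drop = FALSE]
    if (!nrow(tt)) next
    ord <- order(tt$pos, tt$gene_id)
    pos <- tt$pos[ord]; gid <- tt$gene_id[ord]
    idx <- findInterval(mid[i], pos)
    lo_d <- ifelse(idx >= 1, abs(mid[i] - pos[pmax(idx, 1)]), Inf)
    hi_d <- ifelse(idx < length(pos),
                   abs(pos[pmin(idx + 1, length(pos))] - mid[i]), Inf)
    # tie at equal distance: keep the lower-position TSS (deterministic)
    use_hi <- hi_d < lo_d
    d <- pmin(lo_d, hi_d)
    g <- ifelse(use_hi, gid[pmin(idx + 1, length(pos))], gid[pmax(idx, 1)])
    ok <- d <= max_nearest
    gene[i[ok]] <- g[ok]
    evid[i[ok]] <- "nearest"
    dist[i[ok]] <- d[ok]
  }
  mapped <- !is.na(gene)
  list(map = data.frame(peak_id = peaks$id[mapped], gene_id = gene[mapped],
                        evidence = evid[mapped], distance = dist[mapped],
                        stringsAsFactors = FALSE),
       unmapped = peaks$id[!mapped])
}

#' AML-specific peaks versus a healthy reference
#'
#' Peaks whose pseudocounted group-mean ratio
#' (mean_aml + 1) / (mean_ref + 1) is at least `fold` on normalized counts.
#'
#' @param x a normalized, grouped [tag_count_matrix].
#' @param aml_group AML group label.
#' @param reference_group healthy reference label (default `"PBSC"`).
#' @param fold minimum fold enrichment (default 2).
#' @return character vector of peak ids.
#' @export
aml_specific_peaks <- function(x, aml_group, reference_group = "PBSC",
                               fold = 2) {
  stopifnot(inherits(x, "tag_count_matrix"))
  if (!x$normalized) stop("aml_specific_peaks requires a normalized matrix")
  require_groups(x, c(aml_group, reference_group))
  mA <- group_means(x$counts, x$groups, aml_group)
  mR <- group_means(x$counts, x$groups, reference_group)
  names(mA)[(mA + 1) / (mR + 1) >= fold]
}

#' Build the TF -> target gene regulatory network
#'
#' Candidate regulatory sites are motif occurrences that overlap (>= 1 bp) a
#' detected footprint and lie inside an AML-specific peak. Each candidate
#' with the motif of TF t (mean AML FPKM >= `min_fpkm`) in a peak assigned
#' to gene g (mean AML FPKM >= `min_fpkm`) contributes one site to the edge
#' t -> g. Node expression is the mean FPKM over the AML samples.
#'
#' @param specific_peaks character vector of AML-specific peak ids.
#' @param footprints a `footprints` data.frame for the AML condition.
#' @param occurrences a `motif_occurrences` data.frame.
#' @param map result of [assign_peaks_to_genes] (the list or its `$map`).
#' @param tf_motifs named list TF gene id -> character vector of motif ids.
#' @param expression an [expression_table] with group labels.
#' @param aml_group group label of the AML samples in `expression`.
#' @param peaks [genomic_intervals]; geometry for footprint/occurrence
#'   overlap.
#' @param profiles named list of [cut_profile] objects (window geometry).
#' @param min_fpkm expression floor for TF and target nodes (default 1).
#' @return object of class `grn`: list with `nodes` (data.frame `gene_id`,
#'   `expression`, `is_tf`) and `edges` (data.frame `source`, `target`,
#'   `site_count`, `site_ids` with `;`-joined site identifiers).
#' @export
build_grn <- function(specific_peaks, footprints, occurrences, map,
                      tf_motifs, expression, aml_group, peaks, profiles,
                      min_fpkm = 1) {
  if (is.list(map) && !is.data.frame(map)) map <- map$map
  stopifnot(inherits(expression, "expression_table"))
  if (is.null(expression$groups)) stop("expression table needs group labels")
  missing_tfs <- setdiff(names(tf_motifs), rownames(expression$fpkm))
  if (length(missing_tfs))
    stop("TF(s) in tf_motifs absent from expression table: ",
         paste(missing_tfs, collapse = ", "))
  aml_samples <- names(expression$groups)[expression$groups == aml_group]
  if (!length(aml_samples)) stop("unknown or empty group: ", aml_group)
  expr_mean <- rowMeans(expression$fpkm[, aml_samples, drop = FALSE])
  motif2tf <- list()
  for (tf in names(tf_motifs))
    for (m in tf_motifs[[tf]])
      motif2tf[[m]] <- c(motif2tf[[m]], tf)
  occ <- occurrences[occurrences$peak_id %in% specific_peaks, , drop = FALSE]
  edges <- list()
  if (nrow(occ) > 0 && nrow(footprints) > 0) {
    occw <- occ_window_relative(occ, peaks, profiles)
    gene_of <- setNames(map$gene_id, map$peak_id)
    fsplit <- split(footprints, footprints$peak_id)
    for (i in seq_len(nrow(occ))) {
      pid <- occ$peak_id[i]
      fp <- fsplit[[pid]]
      if (is.null(fp)) next
      if (!any(occw$start[i] < fp$end & occw$end[i] > fp$start)) next
      g <- gene_of[pid]
      if (is.na(g) || is.na(expr_mean[g]) || expr_mean[g] < min_fpkm) next
      for (tf in motif2tf[[occ$motif_id[i]]]) {
        if (expr_mean[tf] < min_fpkm) next
        key <- paste(tf, g, sep = "\r")
        site <- paste(pid, occ$offset[i], occ$motif_id[i], sep = ":")
        edges[[key]] <- union(edges[[key]], site)
      }
    }
  }
  if (length(edges)) {
    sp <- strsplit(names(edges), "\r", fixed = TRUE)
    edf <- data.frame(
      source = vapply(sp, `[`, "", 1), target = vapply(sp, `[`, "", 2),
      site_count = vapply(edges, length, 0L),
      site_ids = vapply(edges, function(s) paste(sort(s), collapse = ";"), ""),
      stringsAsFactors = FALSE)
    edf <- edf[order(edf$source, edf$target), , drop = FALSE]
    rownames(edf) <- NULL
  } else {
    edf <- data.frame(source = character(), target = character(),
                      site_count = integer(), site_ids = character(),
                      stringsAsFactors = FALSE)
  }
  node_ids <- sort(unique(c(edf$source, edf$target)))
  nodes <- data.frame(
    gene_id = node_ids,
    expression = unname(expr_mean[node_ids]),
    is_tf = node_ids %in% names(tf_motifs),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edf), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn: %d nodes (%d TFs), %d edges, %d sites\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges),
              sum(x$edges$site_count)))
  invisible(x)
}

#' Edge recovery metrics against a planted ground truth
#'
#' Precision, recall and F1 on directed (source, target) edge sets, ignoring
#' site counts. With no predicted edges, precision is reported as `NA`
#' (conventionally 1 for the F1 computation).
#'
#' @param grn a `grn` object.
#' @param truth either a `ground_truth` (from [generate_study]) or a
#'   data.frame/list with planted edges (`tf`, `target`).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
grn_recovery_report <- function(grn, truth) {
  planted <- truth_edge_keys(truth)
  pred <- if (nrow(grn$edges)) paste(grn$edges$source, grn$edges$target,
                                     sep = "->") else character()
  tp <- length(intersect(pred, planted))
  fp <- length(setdiff(pred, planted))
  fn <- length(setdiff(planted, pred))
  prec_eff <- if (length(pred)) tp / length(pred) else 1
  rec <- if (length(planted)) tp / length(planted) else 1
  f1 <- if (prec_eff + rec == 0) 0 else 2 * prec_eff * rec / (prec_eff + rec)
  list(tp = tp, fp = fp, fn = fn,
       precision = if (length(pred)) prec_eff else NA_real_,
       recall = rec, f1 = f1)
}

truth_edge_keys <- function(truth) {
  if (!is.null(truth$planted_edges)) truth <- truth$planted_edges
  if (is.data.frame(truth)) return(paste(truth$tf, truth$target, sep = "->"))
  vapply(truth, function(e) paste(e$tf, e$target, sep = "->"), "")
}

#' Serialize / read a GRN
#'
#' `graph-json` is a faithful round-trip format (nodes with `gene_id`,
#' `expression`, `is_tf`; edges with `source`, `target`, `site_count`,
#' `site_ids`); `dot` is write-only for layout tools. Writing refuses a GRN
#' whose edges reference absent nodes.
#'
#' @param grn a `grn` object.
#' @param path output path.
#' @param format `"graph-json"` or `"dot"`.
#' @export
write_network <- function(grn, path, format = c("graph-json", "dot")) {
  format <- match.arg(format)
  bad <- setdiff(c(grn$edges$source, grn$edges$target), grn$nodes$gene_id)
  if (length(bad))
    stop("edge references absent node(s): ", paste(bad, collapse = ", "))
  if (format == "graph-json") {
    obj <- list(
      nodes = lapply(seq_len(nrow(grn$nodes)), function(i) list(
        gene_id = grn$nodes$gene_id[i],
        expression = grn$nodes$expression[i],
        is_tf = grn$nodes$is_tf[i])),
      edges = lapply(seq_len(nrow(grn$edges)), function(i) list(
        source = grn$edges$source[i], target = grn$edges$target[i],
        site_count = grn$edges$site_count[i],
        site_ids = strsplit(grn$edges$site_ids[i], ";", fixed = TRUE)[[1]])))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- c("digraph grn {")
    for (i in seq_len(nrow(grn$nodes)))
      lines <- c(lines, sprintf("  \"%s\" [expression=%s, is_tf=%s];",
                                grn$nodes$gene_id[i],
                                format_num(grn$nodes$expression[i]),
                                tolower(grn$nodes$is_tf[i])))
    for (i in seq_len(nrow(grn$edges)))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [site_count=%d];",
                                grn$edges$source[i], grn$edges$target[i],
                                grn$edges$site_count[i]))
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path)
  if (length(obj$nodes)) {
    nodes <- data.frame(
      gene_id = vapply(obj$nodes, function(n) n$gene_id, ""),
      expression = vapply(obj$nodes, function(n) as.numeric(n$expression), 0),
      is_tf = vapply(obj$nodes, function(n) isTRUE(n$is_tf), TRUE),
      stringsAsFactors = FALSE)
  } else {
    nodes <- data.frame(gene_id = character(), expression = numeric(),
                        is_tf = logical(), stringsAsFactors = FALSE)
  }
  if (length(obj$edges)) {
    edges <- data.frame(
      source = vapply(obj$edges, function(e) e$source, ""),
      target = vapply(obj$edges, function(e) e$target, ""),
      site_count = vapply(obj$edges, function(e) as.integer(e$site_count), 0L),
      site_ids = vapply(obj$edges, function(e)
        paste(unlist(e$site_ids), collapse = ";"), ""),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        site_count = integer(), site_ids = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

#' Write the GRN edge table as TSV
#' @param grn a `grn` object.
#' @param path output path.
#' @export
write_edge_table <- function(grn, path) {
  data.table::fwrite(grn$edges, path, sep = "\t", quote = FALSE)
  invisible(path)
}
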
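# The synthetic-study generator: seeded determinism, null configurations,
# and the stated count / cleavage noise models.

test_that("same config and seed give byte-identical outputs", {
  cfg <- tiny_sim(seed = 11)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  for (f in c("truth.json", "counts.tsv", "peaks.bed", "peaks.fasta",
              "expression.tsv", "interactions.bedpe", "cuts_t69.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("null configuration plants nothing", {
  cfg <- tiny_sim(seed = 12)
  cfg$accessibility_fold <- 1
  cfg$expression_fold <- 1
  d <- file.path(tempdir(), "nullcfg")
  st <- generate_study(cfg, d)
  expect_true(all(lengths(st$truth$group_specific_peaks) == 0))
  expect_equal(length(st$truth$planted_de_genes$t69$up), 0L)
  expect_equal(length(st$truth$planted_de_genes$t69$down), 0L)
  # and indeed no gene passes a 4-fold filter at noise 0
  cfg2 <- tiny_sim(seed = 12)
  cfg2$expression_fold <- 1
  cfg2$expression_noise_sd <- 0
  d2 <- file.path(tempdir(), "nullcfg2")
  generate_study(cfg2, d2)
  groups <- read_sample_table(file.path(d2, "samples.tsv"))
  expr <- read_expression(file.path(d2, "expression.tsv"), groups)
  de <- fold_change_de(expr, "t69", "PBSC", fold = 4)
  expect_equal(length(de$up), 0L)
  expect_equal(length(de$down), 0L)
  unlink(c(d, d2), recursive = TRUE)
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_tfs = 10, n_targets = 5), "n_targets < n_tfs")
  expect_error(sim_config(window = 300, peak_width = 400), "window")
  expect_error(sim_config(accessibility_fold = 0.5), "folds")
  expect_error(sim_config(footprint_depletion = 1.5), "depletion")
  expect_error(sim_config(mean_cuts_per_bp = 0), "positive")
})

test_that("occupied bases are Poisson-thinned to depletion * rate", {
  # depletion 0.2 at 2 cuts/bp -> 0.4 cuts/bp inside occupied motifs,
  # checked over >= 1000 occupied bases
  cfg <- sim_config(seed = 13, footprint_depletion = 0.2,
                    mean_cuts_per_bp = 2)
  peak <- genomic_intervals("chr1", 10000, 10400, id = "pk1")
  occ <- data.frame(offset = seq(20, 359, by = 20), width = 20)  # 340 bases
  set.seed(13)
  tot <- 0; nb <- 0
  for (i in 1:4) {
    p <- simulate_cut_profile(peak, occ, cfg)
    w <- (peak$start + rep(occ$offset, each = 20) +
            0:19 - p$window_start) + 1
    tot <- tot + sum(p$cuts[w]); nb <- nb + length(w)
  }
  expect_gt(nb, 1000)
  expect_lt(abs(tot / nb - 0.4), 0.04)
})

test_that("depletion 0 zeroes occupied bases; depletion 1 is flat", {
  peak <- genomic_intervals("chr1", 10000, 10400, id = "pk1")
  occ <- data.frame(offset = c(50, 200), width = 20)
  cfg0 <- sim_config(seed = 14, footprint_depletion = 1)
  cfg0$footprint_depletion <- 0
  set.seed(14)
  for (i in 1:10) {
    p <- simulate_cut_profile(peak, occ, cfg0)
    w <- (peak$start + c(outer(0:19, occ$offset, "+")) - p$window_start) + 1
    expect_true(all(p$cuts[w] == 0))
  }
  # depletion 1: chi-square uniformity across positions, aggregated over
  # 100 profiles, not rejected at alpha = 0.01
  cfg1 <- sim_config(seed = 15, footprint_depletion = 1)
  set.seed(15)
  agg <- rep(0, cfg1$window)
  for (i in 1:100) agg <- agg + simulate_cut_profile(peak, occ, cfg1)$cuts
  cs <- sum((agg - mean(agg))^2 / mean(agg))
  expect_gt(pchisq(cs, df = cfg1$window - 1, lower.tail = FALSE), 0.01)
})

test_that("window cut totals match the Poisson mean", {
  cfg <- sim_config(seed = 16, mean_cuts_per_bp = 2)
  peak <- genomic_intervals("chr1", 10000, 10400, id = "pk1")
  set.seed(16)
  tot <- replicate(200, sum(simulate_cut_profile(
    peak, data.frame(offset = numeric(), width = numeric()), cfg)$cuts))
  expect_lt(abs(mean(tot) - 4000), 0.02 * 4000)
})

test_that("simulate_cut_profile rejects occurrences outside the window", {
  cfg <- sim_config(seed = 17)
  peak <- genomic_intervals("chr1", 10000, 10400, id = "pk1")
  expect_error(simulate_cut_profile(
    peak, data.frame(offset = 1500, width = 20), cfg), "outside window")
})

test_that("counts approach Poisson in the large-dispersion limit", {
  cfg <- sim_config(seed = 18, nb_dispersion = 1e9,
                    base_mean_meanlog = log(50), base_mean_sdlog = 0)
  truth <- manual_truth(sprintf("p%04d", 1:250),
                        list(t69 = character(), NPM1 = character(),
                             FLT3_ITD = character(), PBSC = character()))
  set.seed(18)
  x <- simulate_counts(truth, cfg)
  draws <- as.vector(x$counts)[1:2000]
  expect_gt(var(draws) / mean(draws), 0.8)
  expect_lt(var(draws) / mean(draws), 1.3)
})

test_that("planted accessibility fold is recovered in group means", {
  cfg <- sim_config(seed = 19, accessibility_fold = 4)
  ids <- sprintf("p%04d", 1:500)
  truth <- manual_truth(ids, list(t69 = ids, NPM1 = character(),
                                  FLT3_ITD = character(),
                                  PBSC = character()))
  set.seed(19)
  x <- simulate_counts(truth, cfg)
  r <- mean(rowMeans(x$counts[, x$groups == "t69"])) /
    mean(rowMeans(x$counts[, x$groups == "PBSC"]))
  expect_gt(r, 3.5)
  expect_lt(r, 4.5)
})

test_that("fold 1 gives calibrated null p-values on log counts", {
  cfg <- sim_config(seed = 20, accessibility_fold = 1)
  ids <- sprintf("p%04d", 1:200)
  truth <- manual_truth(ids, list(t69 = character(), NPM1 = character(),
                                  FLT3_ITD = character(),
                                  PBSC = character()))
  set.seed(20)
  x <- simulate_counts(truth, cfg)
  a <- log(x$counts[, x$groups == "t69"] + 1)
  b <- log(x$counts[, x$groups == "PBSC"] + 1)
  pv <- vapply(seq_along(ids), function(i)
    stats::t.test(a[i, ], b[i, ])$p.value, 0)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("ground truth serialization round-trips", {
  cfg <- tiny_sim(seed = 21)
  d <- file.path(tempdir(), "truthrt")
  st <- generate_study(cfg, d)
  back <- read_truth(file.path(d, "truth.json"))
  expect_equal(back$peak_ids, st$truth$peak_ids)
  expect_equal(back$group_specific_peaks, st$truth$group_specific_peaks)
  expect_equal(back$planted_edges, st$truth$planted_edges)
  expect_equal(back$planted_de_genes$t69, st$truth$planted_de_genes$t69)
  expect_equal(back$occupied_motif_occurrences$offset,
               st$truth$occupied_motif_occurrences$offset)
  unlink(d, recursive = TRUE)
})

test_that("every emitted file passes its reader", {
  cfg <- tiny_sim(seed = 22)
  d <- file.path(tempdir(), "readall")
  st <- generate_study(cfg, d)
  peaks <- read_bed(file.path(d, "peaks.bed"))
  expect_equal(nrow(peaks), cfg$n_peaks)
  expect_false(anyNA(peaks$id))
  groups <- read_sample_table(file.path(d, "samples.tsv"))
  expect_equal(sort(unique(unname(groups))), sort(names(cfg$groups)))
  counts <- read_count_matrix(file.path(d, "counts.tsv"), groups)
  expect_equal(rownames(counts$counts), peaks$id)
  seqs <- read_fasta(file.path(d, "peaks.fasta"))
  expect_equal(sort(names(seqs)), sort(peaks$id))
  expect_true(all(nchar(seqs) == cfg$peak_width))
  expect_gt(nrow(read_interactions(file.path(d, "interactions.bedpe"))), 0)
  expect_equal(length(read_pwms(file.path(d, "pwms.jaspar"))),
               cfg$n_tfs + 1)
  prof <- read_cut_profiles(file.path(d, "cuts_PBSC.tsv"))
  expect_equal(length(prof), cfg$n_peaks)
  expect_equal(length(prof[[1]]$cuts), cfg$window)
  expr <- read_expression(file.path(d, "expression.tsv"), groups)
  expect_true(all(st$truth$planted_edges[[1]]$site_ids %in% peaks$id))
  unlink(d, recursive = TRUE)
})
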
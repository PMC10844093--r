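# Normalization, distal filtering, correlation clustering, fold-change
# ranking and profile summaries.

mk_tcm <- function(m, groups = NULL, normalized = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  tag_count_matrix(m, groups = groups, normalized = normalized)
}

test_that("normalize_counts scales columns proportionally", {
  x <- mk_tcm(cbind(a = c(2, 3, 5), b = c(1, 1, 2)))
  n <- normalize_counts(x, scale = 100)
  expect_equal(unname(n$counts[, "a"]), c(20, 30, 50))
  expect_true(n$normalized)
  expect_error(normalize_counts(n), "already normalized")

  x0 <- mk_tcm(cbind(a = c(1, 2), b = c(0, 0)))
  expect_error(normalize_counts(x0), "b")

  set.seed(30)
  for (i in 1:5) {
    x <- mk_tcm(matrix(rpois(50, 20) + 1, 10, 5))
    n <- normalize_counts(x, scale = 1e6)
    expect_true(all(abs(colSums(n$counts) - 1e6) < 1e-6))
  }
})

test_that("filter_distal applies the midpoint rule inclusively", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", pos = 10250,
                    strand = "+", stringsAsFactors = FALSE)
  class(tss) <- c("tss_annotation", "data.frame")
  pk <- genomic_intervals("chr1", c(10000, 20000), c(10400, 20400),
                          id = c("near", "far"))
  out <- filter_distal(pk, tss, min_dist = 1500)
  expect_equal(out$id, "far")   # midpoint 10200 is 50 bp from the TSS

  # boundary: midpoint exactly min_dist away is retained
  pk2 <- genomic_intervals("chr1", 11550, 11950, id = "edge")  # mid 11750
  expect_equal(nrow(filter_distal(pk2, tss, min_dist = 1500)), 1L)
  expect_equal(nrow(filter_distal(pk2, tss, min_dist = 1501)), 0L)

  # chromosome without any TSS is retained
  pk3 <- genomic_intervals("chrX", 100, 500, id = "orphan")
  expect_equal(filter_distal(pk3, tss, 1500)$id, "orphan")
})

test_that("filter_distal agrees with a brute-force all-pairs scan", {
  set.seed(31)
  pk <- rand_intervals(200, max_pos = 50000)
  tss <- rand_tss(40, max_pos = 50000)
  for (min_dist in c(500, 1500, 5000)) {
    got <- filter_distal(pk, tss, min_dist)$id
    mid <- interval_midpoint(pk)
    keep <- vapply(seq_len(nrow(pk)), function(i) {
      d <- abs(mid[i] - tss$pos[tss$chrom == pk$chrom[i]])
      !length(d) || min(d) >= min_dist
    }, TRUE)
    expect_equal(got, pk$id[keep])
  }
})

test_that("correlation_matrix matches the Pearson formula", {
  set.seed(32)
  m <- matrix(rpois(15, 50), 5, 3)
  x <- normalize_counts(mk_tcm(m))
  r <- correlation_matrix(x, log_transform = FALSE)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  v <- x$counts
  pearson <- function(a, b)
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  for (i in 1:3) for (j in 1:3)
    expect_lt(abs(r[i, j] - pearson(v[, i], v[, j])), 1e-12)

  # duplicated sample -> r = 1; reflection about the mean -> r = -1
  m2 <- cbind(a = c(1, 5, 9, 4), b = c(1, 5, 9, 4),
              c = 2 * mean(c(1, 5, 9, 4)) - c(1, 5, 9, 4))
  rownames(m2) <- sprintf("p%d", 1:4)
  x2 <- tag_count_matrix(m2, normalized = TRUE)
  r2 <- correlation_matrix(x2, log_transform = FALSE)
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)

  m3 <- cbind(a = c(1, 2), b = c(3, 3))
  rownames(m3) <- c("p1", "p2")
  expect_error(correlation_matrix(tag_count_matrix(m3, normalized = TRUE),
                                  log_transform = FALSE), "b")
})

test_that("hierarchical clustering is deterministic and merges duplicates first", {
  set.seed(33)
  base <- rpois(30, 100)
  m <- cbind(s1 = base, s2 = base, s3 = rpois(30, 100), s4 = rpois(30, 100))
  rownames(m) <- sprintf("p%02d", 1:30)
  x <- normalize_counts(tag_count_matrix(m))
  cl <- hierarchical_cluster(correlation_matrix(x))
  first <- sort(cl$merge[1, ])
  expect_equal(sort(cl$hclust$labels[-first]), c("s1", "s2"))
  expect_equal(cl$height[1], 0)
  cl2 <- hierarchical_cluster(correlation_matrix(x))
  expect_identical(cl$leaf_order, cl2$leaf_order)
})

test_that("clustering recovers planted two-group structure", {
  set.seed(34)
  ids <- sprintf("p%04d", 1:400)
  truth <- manual_truth(ids, list(gA = ids[1:120], gB = ids[121:240]))
  cfg <- sim_config(seed = 34, groups = c(gA = 2, gB = 2, PBSC = 2),
                    aml_group = "gA", reference_group = "PBSC")
  x <- simulate_counts(truth, cfg)
  cl <- hierarchical_cluster(correlation_matrix(normalize_counts(x)))
  cut <- cut_sample_groups(cl, 3)
  expect_equal(length(unique(cut[c("gA_1", "gA_2")])), 1L)
  expect_equal(length(unique(cut[c("gB_1", "gB_2")])), 1L)
  expect_equal(length(unique(cut[c("gA_1", "gB_1", "PBSC_1")])), 3L)
})

test_that("rank_by_fold_change computes and orders log2 fold changes", {
  m <- cbind(a1 = c(40, 10, 5), a2 = c(40, 10, 5),
             b1 = c(10, 10, 40), b2 = c(10, 10, 40))
  rownames(m) <- c("up", "flat", "dn")
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  x <- tag_count_matrix(m, groups = groups, normalized = TRUE)
  r <- rank_by_fold_change(x, "A", "B", pseudocount = 1)
  expect_equal(r$peak_id, c("up", "flat", "dn"))
  expect_equal(r$log2fc[r$peak_id == "up"], log2(41 / 11))
  expect_equal(r$log2fc[r$peak_id == "flat"], 0)
  expect_error(rank_by_fold_change(x, "A", "Z"), "unknown group")

  # antisymmetry: swapping groups negates and reverses
  rswap <- rank_by_fold_change(x, "B", "A", pseudocount = 1)
  expect_equal(rswap$peak_id, rev(r$peak_id))
  expect_equal(rswap$log2fc,
               -r$log2fc[match(rswap$peak_id, r$peak_id)])
})

test_that("specific_sites applies inclusive thresholds and is monotone", {
  r <- data.frame(peak_id = c("a", "b", "c", "d"),
                  log2fc = c(3, 2, 0, -2.5), stringsAsFactors = FALSE)
  attr(r, "groups") <- c("A", "B")
  attr(r, "pseudocount") <- 1
  class(r) <- c("ranked_peaks", "data.frame")
  s <- specific_sites(r, fold = 4)
  expect_equal(s$A, c("a", "b"))   # log2fc == 2 exactly is included
  expect_equal(s$B, "d")
  expect_length(intersect(s$A, s$B), 0)

  set.seed(35)
  r2 <- data.frame(peak_id = sprintf("p%03d", 1:100),
                   log2fc = sort(rnorm(100, 0, 2), decreasing = TRUE))
  attr(r2, "groups") <- c("A", "B")
  class(r2) <- c("ranked_peaks", "data.frame")
  prev <- specific_sites(r2, 1.5)
  for (f in c(2, 3, 5, 9)) {
    cur <- specific_sites(r2, f)
    expect_true(all(cur$A %in% prev$A))
    expect_true(all(cur$B %in% prev$B))
    expect_lte(length(cur$A) + length(cur$B), 100)
    prev <- cur
  }
})

test_that("density_matrix bins conserve totals in ranked order", {
  set.seed(36)
  ids <- c("pA", "pB", "pC")
  profiles <- setNames(lapply(1:3, function(i)
    cut_profile(ids[i], 0, rpois(2000, 2))), ids)
  r <- data.frame(peak_id = c("pC", "pA", "pB"),
                  log2fc = c(2, 0, -1), stringsAsFactors = FALSE)
  attr(r, "groups") <- c("A", "B")
  class(r) <- c("ranked_peaks", "data.frame")
  dm <- density_matrix(profiles, r, window = 2000, bin = 20)
  expect_equal(dim(dm), c(3L, 100L))
  expect_equal(rownames(dm), r$peak_id)
  for (pid in ids)
    expect_equal(sum(dm[pid, ]), sum(profiles[[pid]]$cuts))

  const <- setNames(list(cut_profile("pX", 0, rep(3, 2000))), "pX")
  rX <- r[1, ]; rX$peak_id <- "pX"
  class(rX) <- class(r)
  expect_true(all(density_matrix(const, rX, 2000, 20) == 60))

  r$peak_id[1] <- "missing"
  expect_error(density_matrix(profiles, r), "missing")
})

test_that("average_profile is the positionwise mean", {
  p1 <- cut_profile("a", 0, rep(2, 100))
  p2 <- cut_profile("b", 0, rep(4, 100))
  profiles <- list(a = p1, b = p2)
  expect_equal(average_profile(profiles, "a", window = 100), rep(2, 100))
  avg <- average_profile(profiles, c("a", "b"), window = 100)
  expect_equal(avg, rep(3, 100))
  expect_equal(mean(avg),
               mean(c(mean(p1$cuts), mean(p2$cuts))))
  expect_error(average_profile(profiles, character()), "empty")
})
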
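# Peak-to-gene assignment and network construction.

mk_tss <- function(gene_id, chrom, pos) {
  out <- data.frame(gene_id = gene_id, chrom = chrom, pos = pos,
                    strand = "+", stringsAsFactors = FALSE)
  class(out) <- c("tss_annotation", "data.frame")
  out
}

test_that("interaction evidence takes precedence over a nearer TSS", {
  peaks <- genomic_intervals("chr1", 100000, 100400, id = "pk1")
  tss <- mk_tss(c("H", "G"), "chr1", c(102200, 140200))
  ia <- data.frame(p_chrom = "chr1", p_start = 139000, p_end = 141000,
                   d_chrom = "chr1", d_start = 100000, d_end = 100400,
                   gene_id = "G", score = 5, stringsAsFactors = FALSE)
  res <- assign_peaks_to_genes(peaks, ia, tss)
  expect_equal(res$map$gene_id, "G")
  expect_equal(res$map$evidence, "interaction")
  expect_equal(res$map$distance, 0)

  # without the interaction: nearest TSS within range
  res2 <- assign_peaks_to_genes(peaks, ia[0, ], tss)
  expect_equal(res2$map$gene_id, "H")
  expect_equal(res2$map$evidence, "nearest")
  expect_equal(res2$map$distance, 2000)

  # nearest TSS beyond max_nearest -> unmapped
  res3 <- assign_peaks_to_genes(peaks, ia[0, ], mk_tss("F", "chr1", 160200),
                                max_nearest = 50000)
  expect_equal(nrow(res3$map), 0L)
  expect_equal(res3$unmapped, "pk1")
  # boundary: exactly max_nearest is mapped
  res4 <- assign_peaks_to_genes(peaks, ia[0, ], mk_tss("F", "chr1", 150200),
                                max_nearest = 50000)
  expect_equal(res4$map$gene_id, "F")
})

test_that("highest-score interaction wins, ties by gene id", {
  peaks <- genomic_intervals("chr1", 1000, 1400, id = "pk1")
  tss <- mk_tss(c("A", "B"), "chr1", c(900000, 950000))
  ia <- data.frame(p_chrom = "chr1", p_start = c(1, 1), p_end = c(100, 100),
                   d_chrom = "chr1", d_start = c(1000, 1100),
                   d_end = c(1400, 1500), gene_id = c("A", "B"),
                   score = c(2, 7), stringsAsFactors = FALSE)
  res <- assign_peaks_to_genes(peaks, ia, tss)
  expect_equal(res$map$gene_id, "B")
  ia$score <- c(7, 7)
  expect_equal(assign_peaks_to_genes(peaks, ia, tss)$map$gene_id, "A")
  # min_interaction_score filters; falls back to the nearest TSS
  ia$score <- c(2, 7)
  res5 <- assign_peaks_to_genes(peaks, ia, tss, max_nearest = 1e6,
                                min_interaction_score = 8)
  expect_equal(res5$map$evidence, "nearest")
  expect_equal(res5$map$gene_id, "A")
})

test_that("deleting interactions changes only interaction-evidence peaks", {
  set.seed(60)
  d <- file.path(tempdir(), "iadiff")
  st <- generate_study(tiny_sim(seed = 61), d)
  peaks <- read_bed(file.path(d, "peaks.bed"))
  tss <- read_tss(file.path(d, "tss.bed"))
  ia <- read_interactions(file.path(d, "interactions.bedpe"))
  with_ia <- assign_peaks_to_genes(peaks, ia, tss)
  without <- assign_peaks_to_genes(peaks, ia[0, ], tss)
  expect_equal(sum(without$map$evidence == "interaction"), 0L)
  m1 <- setNames(with_ia$map$gene_id, with_ia$map$peak_id)
  m2 <- setNames(without$map$gene_id, without$map$peak_id)
  had_ia <- with_ia$map$peak_id[with_ia$map$evidence == "interaction"]
  shared <- setdiff(intersect(names(m1), names(m2)), had_ia)
  expect_equal(m1[shared], m2[shared])
  unlink(d, recursive = TRUE)
})

test_that("aml_specific_peaks applies the pseudocounted ratio", {
  m <- cbind(t1 = c(40, 10), t2 = c(40, 10), r1 = c(10, 10), r2 = c(10, 10))
  rownames(m) <- c("hit", "flat")
  x <- tag_count_matrix(m, groups = c(t1 = "t69", t2 = "t69", r1 = "PBSC",
                                      r2 = "PBSC"), normalized = TRUE)
  expect_equal(aml_specific_peaks(x, "t69", "PBSC", 2), "hit")
  expect_length(aml_specific_peaks(x, "t69", "PBSC", 1.001), 1L)
  expect_error(aml_specific_peaks(x, "t69", "NOPE"), "unknown")

  set.seed(62)
  m2 <- matrix(rpois(400, 50), 100, 4, dimnames = list(
    sprintf("p%03d", 1:100), colnames(m)))
  x2 <- tag_count_matrix(m2, groups = x$groups, normalized = TRUE)
  got <- aml_specific_peaks(x2, "t69", "PBSC", 1.2)
  want <- rownames(m2)[(rowMeans(m2[, 1:2]) + 1) /
                         (rowMeans(m2[, 3:4]) + 1) >= 1.2]
  expect_equal(got, want)
})

grn_fixture <- function() {
  peaks <- genomic_intervals("chr1", c(1000, 5000), c(1400, 5400),
                             id = c("pkA", "pkB"))
  profiles <- list(pkA = cut_profile("pkA", 200, rep(1, 2000)),
                   pkB = cut_profile("pkB", 4200, rep(1, 2000)))
  occ <- data.frame(peak_id = c("pkA", "pkB"), offset = c(100L, 50L),
                    width = 10L, strand = "+", motif_id = "M_A",
                    log_odds = 10, stringsAsFactors = FALSE)
  fps <- data.frame(peak_id = c("pkA", "pkB"), start = c(905, 850),
                    end = c(920, 865), window_start = c(200, 4200),
                    score = 8, n_cuts_inside = 0, n_cuts_flanks = 40,
                    stringsAsFactors = FALSE)
  map <- data.frame(peak_id = c("pkA", "pkB"), gene_id = c("B", "B"),
                    evidence = "interaction", distance = 0,
                    stringsAsFactors = FALSE)
  fpkm <- matrix(c(20, 20, 5, 5, 9, 9, 1, 1), 4, 2, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expr <- expression_table(fpkm, groups = c(s1 = "t69", s2 = "t69"))
  list(peaks = peaks, profiles = profiles, occ = occ, fps = fps, map = map,
       expr = expr)
}

test_that("build_grn assembles edges from footprinted occurrences", {
  fx <- grn_fixture()
  # occurrence pkA offset 100 -> window-relative 900..910 overlaps 905..920
  g1 <- build_grn("pkA", fx$fps, fx$occ, fx$map, list(A = "M_A"), fx$expr,
                  "t69", fx$peaks, fx$profiles)
  expect_equal(g1$edges$source, "A")
  expect_equal(g1$edges$target, "B")
  expect_equal(g1$edges$site_count, 1L)
  expect_equal(sort(g1$nodes$gene_id), c("A", "B"))
  expect_equal(g1$nodes$expression[g1$nodes$gene_id == "A"], 20)
  expect_true(g1$nodes$is_tf[g1$nodes$gene_id == "A"])

  # two sites in different peaks, both mapped to B -> site_count 2
  g2 <- build_grn(c("pkA", "pkB"), fx$fps, fx$occ, fx$map, list(A = "M_A"),
                  fx$expr, "t69", fx$peaks, fx$profiles)
  expect_equal(g2$edges$site_count, 2L)
  expect_equal(length(strsplit(g2$edges$site_ids, ";")[[1]]), 2L)

  # TF below the expression floor contributes nothing
  g3 <- build_grn("pkA", fx$fps, fx$occ, fx$map, list(D = "M_A"), fx$expr,
                  "t69", fx$peaks, fx$profiles, min_fpkm = 1.5)
  expect_equal(nrow(g3$edges), 0L)
  expect_false("D" %in% g3$nodes$gene_id)

  expect_error(build_grn("pkA", fx$fps, fx$occ, fx$map, list(ZZ = "M_A"),
                         fx$expr, "t69", fx$peaks, fx$profiles),
               "absent from expression")
})

test_that("edge site counts are invariant to input row order", {
  fx <- grn_fixture()
  g1 <- build_grn(c("pkA", "pkB"), fx$fps, fx$occ, fx$map, list(A = "M_A"),
                  fx$expr, "t69", fx$peaks, fx$profiles)
  g2 <- build_grn(c("pkB", "pkA"), fx$fps[2:1, ], fx$occ[2:1, ],
                  fx$map[2:1, ], list(A = "M_A"), fx$expr, "t69",
                  fx$peaks[2:1, ], fx$profiles[2:1])
  expect_equal(g1$edges, g2$edges)
})

test_that("recovery report computes set-overlap metrics", {
  g <- structure(list(
    nodes = data.frame(gene_id = c("A", "B", "C", "X"),
                       expression = 1, is_tf = c(TRUE, FALSE, FALSE, FALSE)),
    edges = data.frame(source = c("A", "A", "A"),
                       target = c("B", "C", "X"),
                       site_count = 1L, site_ids = "s",
                       stringsAsFactors = FALSE)), class = "grn")
  truth <- list(planted_edges = list(
    list(tf = "A", target = "B", site_ids = "p1"),
    list(tf = "A", target = "C", site_ids = "p2"),
    list(tf = "A", target = "D", site_ids = "p3")))
  rec <- grn_recovery_report(g, truth)
  expect_equal(rec$precision, 2 / 3)
  expect_equal(rec$recall, 2 / 3)
  expect_equal(rec$f1, 2 / 3)

  # identical edge sets -> all 1
  g$edges <- data.frame(source = "A", target = c("B", "C", "D"),
                        site_count = 1L, site_ids = "s",
                        stringsAsFactors = FALSE)
  rec2 <- grn_recovery_report(g, truth)
  expect_equal(c(rec2$precision, rec2$recall, rec2$f1), c(1, 1, 1))

  # empty prediction: recall 0, precision NA by convention
  g$edges <- g$edges[0, ]
  rec3 <- grn_recovery_report(g, truth)
  expect_true(is.na(rec3$precision))
  expect_equal(rec3$recall, 0)
  expect_equal(rec3$f1, 0)
})
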
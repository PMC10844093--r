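# Expression-level statistics: fold-change differential expression,
# hypergeometric set-overlap significance, pooled-variance t-tests, and the
# LSC17 stemness score.

#' Fold-change differential expression between groups
#'
#' up = genes with (meanA + pc) / (meanB + pc) >= fold;
#' down = genes with (meanB + pc) / (meanA + pc) >= fold (on FPKM group
#' means). Swapping the groups swaps the sets.
#'
#' @param expr an [expression_table] with group labels.
#' @param groupA,groupB group labels.
#' @param fold fold threshold (default 4).
#' @param pseudocount added to both means (default 1).
#' @return list of class `gene_set_pair` with `up`, `down`, `contrast`,
#'   `fold`.
#' @export
fold_change_de <- function(expr, groupA, groupB, fold = 4, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_table"))
  if (is.null(expr$groups)) stop("expression table needs group labels")
  for (g in c(groupA, groupB))
    if (!g %in% expr$groups) stop("unknown group label: ", g)
  mA <- group_means(expr$fpkm, expr$groups, groupA)
  mB <- group_means(expr$fpkm, expr$groups, groupB)
  ratio <- (mA + pseudocount) / (mB + pseudocount)
  structure(list(up = names(ratio)[ratio >= fold],
                 down = names(ratio)[1 / ratio >= fold],
                 contrast = c(groupA, groupB), fold = fold),
            class = "gene_set_pair")
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail p-value P(X >= |A intersect B|) for
#' X ~ Hypergeometric(universe, |A|, |B|): the chance of an overlap at least
#' this large when B is drawn uniformly from the universe.
#'
#' @param setA,setB character vectors of gene ids from a shared universe.
#' @param universe_size size of the shared universe.
#' @return p-value in (0, 1].
#' @export
overlap_significance <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(union(setA, setB)) > universe_size)
    stop("universe smaller than |A union B|")
  k <- length(intersect(setA, setB))
  # P(X >= k): phyper's upper tail is strict, so shift by one
  phyper(k - 1, length(setA), universe_size - length(setA), length(setB),
         lower.tail = FALSE)
}

#' Classical Student's t-test for one gene between two groups
#'
#' Pooled-variance (equal-variance) two-sided t-test with nA + nB - 2
#' degrees of freedom. Zero pooled variance with equal means gives t = 0,
#' p = 1.
#'
#' @param expr an [expression_table] with group labels.
#' @param gene gene id.
#' @param groupA,groupB group labels, each with >= 2 samples.
#' @return list with `t`, `p_value`, `df`.
#' @export
group_ttest <- function(expr, gene, groupA, groupB) {
  stopifnot(inherits(expr, "expression_table"))
  if (is.null(expr$groups)) stop("expression table needs group labels")
  if (!gene %in% rownames(expr$fpkm)) stop("unknown gene: ", gene)
  a <- expr$fpkm[gene, names(expr$groups)[expr$groups == groupA]]
  b <- expr$fpkm[gene, names(expr$groups)[expr$groups == groupB]]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 samples per group (got ", length(a), ", ", length(b), ")")
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  if (se == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p_value = 1, df = df))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p_value = 0, df = df))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, p_value = 2 * pt(-abs(t), df), df = df)
}

#' LSC17 leukemia stemness score
#'
#' Per-sample weighted sum score(s) = sum_i w_i * f(FPKM_i,s) over the 17
#' signature genes (16 when `exclude_cd34`), with f the transform
#' (default log2(x + 1)). The canonical published weight table ships with
#' the package (`system.file("extdata", "lsc17_weights.tsv",
#' package = "accessGRN")`).
#'
#' @param expr an [expression_table]; all 17 signature genes must be present
#'   (missing genes are an error listing them).
#' @param weights weight table from [read_lsc17_weights].
#' @param exclude_cd34 drop the CD34 term (default FALSE).
#' @param transform expression transform applied before weighting.
#' @return named numeric vector of per-sample scores.
#' @export
lsc17_score <- function(expr, weights, exclude_cd34 = FALSE,
                        transform = function(x) log2(x + 1)) {
  stopifnot(inherits(expr, "expression_table"))
  missing <- setdiff(weights$gene_id, rownames(expr$fpkm))
  if (length(missing))
    stop("LSC17 gene(s) missing from expression table: ",
         paste(missing, collapse = ", "))
  w <- weights
  if (exclude_cd34) w <- w[!w$is_cd34, , drop = FALSE]
  m <- transform(expr$fpkm[w$gene_id, , drop = FALSE])
  s <- drop(crossprod(m, w$weight))
  setNames(as.numeric(s), colnames(expr$fpkm))
}
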
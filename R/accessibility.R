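# Accessibility-level analysis: depth normalization, distal filtering,
# correlation clustering of samples, fold-change ranking of peaks, and
# profile summaries over fixed windows.

#' Depth-normalize a tag count matrix
#'
#' Scales each sample column so that its total equals `scale` (counts per
#' `scale` tags). Refuses to normalize twice.
#'
#' @param x a [tag_count_matrix] with `normalized = FALSE`.
#' @param scale target column total (default 1e7).
#' @return a normalized [tag_count_matrix].
#' @export
normalize_counts <- function(x, scale = 1e7) {
  stopifnot(inherits(x, "tag_count_matrix"))
  if (x$normalized) stop("matrix is already normalized")
  tot <- colSums(x$counts)
  zero <- colnames(x$counts)[tot == 0]
  if (length(zero))
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  counts <- sweep(x$counts, 2, tot / scale, "/")
  tag_count_matrix(counts, groups = x$groups, normalized = TRUE)
}

#' Filter peaks to distal elements
#'
#' Retains peaks whose midpoint lies at least `min_dist` bp from the nearest
#' TSS on the same chromosome (inclusive boundary). Peaks on chromosomes
#' without any TSS are retained.
#'
#' @param peaks a [genomic_intervals] object.
#' @param tss a `tss_annotation` (see [read_tss]).
#' @param min_dist minimum midpoint-to-TSS distance in bp (default 1500).
#' @return the retained subset of `peaks`.
#' @export
filter_distal <- function(peaks, tss, min_dist = 1500) {
  if (nrow(peaks) == 0L) return(peaks)
  mid <- interval_midpoint(peaks)
  keep <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    i <- which(peaks$chrom == ch)
    pos <- sort(tss$pos[tss$chrom == ch])
    if (!length(pos)) { keep[i] <- TRUE; next }
    # distance to nearest TSS via the sorted position vector
    idx <- findInterval(mid[i], pos)
    lo <- ifelse(idx >= 1, abs(mid[i] - pos[pmax(idx, 1)]), Inf)
    hi <- ifelse(idx < length(pos), abs(pos[pmin(idx + 1, length(pos))] -
                                          mid[i]), Inf)
    keep[i] <- pmin(lo, hi) >= min_dist
  }
  out <- peaks[keep, , drop = FALSE]
  class(out) <- class(peaks)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between samples
#'
#' Sample-by-sample Pearson correlation of (by default) log2(x + 1)
#' transformed normalized tag counts.
#'
#' @param x a normalized [tag_count_matrix] with >= 2 peaks.
#' @param log_transform compute on log2(x + 1) values (default TRUE).
#' @return symmetric samples x samples correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, log_transform = TRUE) {
  stopifnot(inherits(x, "tag_count_matrix"))
  if (!x$normalized) stop("correlation_matrix requires a normalized matrix")
  if (nrow(x$counts) < 2L) stop("need at least 2 peaks")
  m <- if (log_transform) log2(x$counts + 1) else x$counts
  v <- apply(m, 2, sd)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[v == 0], collapse = ", "))
  r <- cor(m, method = "pearson")
  diag(r) <- 1
  r
}

#' Hierarchical clustering of samples from a correlation matrix
#'
#' Average-linkage clustering on the distance 1 - r. Deterministic for a
#' given input.
#'
#' @param corr a correlation matrix as from [correlation_matrix].
#' @return list with the `stats::hclust` object (`hclust`), `merge`,
#'   `height`, and `leaf_order` (sample ids in dendrogram order).
#' @export
hierarchical_cluster <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  hc <- hclust(as.dist(1 - corr), method = "average")
  list(hclust = hc, merge = hc$merge, height = hc$height,
       leaf_order = hc$labels[hc$order])
}

#' Cut a sample dendrogram into k groups
#' @param clustering result of [hierarchical_cluster].
#' @param k number of groups.
#' @return named integer vector of cluster memberships.
#' @export
cut_sample_groups <- function(clustering, k) cutree(clustering$hclust, k = k)

#' Rank peaks by between-group log2 fold change
#'
#' log2FC(p) = log2((meanA(p) + pseudocount) / (meanB(p) + pseudocount)) on
#' normalized counts, sorted non-increasing; ties broken by peak id.
#'
#' @param x a normalized, grouped [tag_count_matrix].
#' @param groupA,groupB group labels (A in the numerator).
#' @param pseudocount added to both group means (default 1).
#' @return data.frame of class `ranked_peaks` with columns `peak_id`,
#'   `log2fc`, carrying `groups` and `pseudocount` attributes.
#' @export
rank_by_fold_change <- function(x, groupA, groupB, pseudocount = 1) {
  stopifnot(inherits(x, "tag_count_matrix"))
  if (!x$normalized) stop("rank_by_fold_change requires a normalized matrix")
  require_groups(x, c(groupA, groupB))
  mA <- group_means(x$counts, x$groups, groupA)
  mB <- group_means(x$counts, x$groups, groupB)
  lfc <- log2((mA + pseudocount) / (mB + pseudocount))
  ord <- order(-lfc, names(lfc))
  out <- data.frame(peak_id = names(lfc)[ord], log2fc = unname(lfc[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- c(groupA, groupB)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("ranked_peaks", "data.frame")
  out
}

#' Group-specific sites at a fold threshold
#'
#' Splits a fold-change ranking into the sites at least `fold`-fold more
#' accessible in each group (inclusive threshold on |log2FC|).
#'
#' @param ranked a `ranked_peaks` object from [rank_by_fold_change].
#' @param fold fold-change threshold > 1 (default 4).
#' @return list with one element per group label, each a character vector of
#'   peak ids; attributes record the threshold.
#' @export
specific_sites <- function(ranked, fold = 4) {
  stopifnot(inherits(ranked, "ranked_peaks"), fold > 1)
  gl <- attr(ranked, "groups")
  thr <- log2(fold)
  out <- list(ranked$peak_id[ranked$log2fc >= thr],
              ranked$peak_id[ranked$log2fc <= -thr])
  names(out) <- gl
  attr(out, "fold") <- fold
  out
}

#' Binned cut-density matrix over ranked peaks
#'
#' One row per ranked peak (in ranking order), one column per `bin`-bp bin of
#' the window; entries are per-bin cut sums, so each row sums to the total
#' cuts in the window.
#'
#' @param profiles named list of [cut_profile] objects keyed by peak id.
#' @param ranked a `ranked_peaks` object.
#' @param window window length in bp (default 2000); every profile must have
#'   this length.
#' @param bin bin width in bp (default 20); must divide `window`.
#' @return numeric matrix, peaks x bins.
#' @export
density_matrix <- function(profiles, ranked, window = 2000, bin = 20) {
  stopifnot(window %% bin == 0)
  miss <- setdiff(ranked$peak_id, names(profiles))
  if (length(miss))
    stop("missing cut profile for peak(s): ",
         paste(head(miss, 5), collapse = ", "))
  nb <- window %/% bin
  grp <- rep(seq_len(nb), each = bin)
  out <- t(vapply(ranked$peak_id, function(pid) {
    p <- profiles[[pid]]
    if (length(p$cuts) != window)
      stop("profile for ", pid, " has length ", length(p$cuts),
           ", expected ", window)
    as.numeric(tapply(p$cuts, grp, sum))
  }, numeric(nb)))
  rownames(out) <- ranked$peak_id
  colnames(out) <- paste0("bin", seq_len(nb))
  out
}

#' Average cut profile over a site set
#'
#' Position-wise mean cleavage across all sites in the set.
#'
#' @param profiles named list of [cut_profile] objects keyed by peak id.
#' @param site_ids non-empty character vector of peak ids.
#' @param window expected window length (default 2000).
#' @return numeric vector of length `window`.
#' @export
average_profile <- function(profiles, site_ids, window = 2000) {
  if (!length(site_ids)) stop("empty site set")
  miss <- setdiff(site_ids, names(profiles))
  if (length(miss))
    stop("missing cut profile for peak(s): ",
         paste(head(miss, 5), collapse = ", "))
  m <- vapply(site_ids, function(pid) {
    p <- profiles[[pid]]
    if (length(p$cuts) != window)
      stop("profile for ", pid, " has length ", length(p$cuts),
           ", expected ", window)
    as.numeric(p$cuts)
  }, numeric(window))
  rowMeans(m)
}
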
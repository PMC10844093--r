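#' @import data.table
#' @importFrom stats cor cutree dist hclust pbinom phyper pt rlnorm rnbinom
#'   rnorm rpois runif sd var setNames as.dist
#' @importFrom utils head tail
NULL

#' Genomic interval set
#'
#' Construct a validated set of genomic intervals. All coordinates in this
#' package are 0-based half-open (BED-native): `start` is the first base of
#' the interval and `end` is one past the last.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `0 <= start < end`.
#' @param id optional character vector of unique interval ids.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `id`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, strand = NULL) {
  n <- length(chrom)
  if (is.null(id)) id <- rep(NA_character_, n)
  if (is.null(strand)) strand <- rep(".", n)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  id = as.character(id), strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

validate_intervals <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
    stop("interval coordinates must be integers")
  ids <- x$id[!is.na(x$id)]
  if (anyDuplicated(ids))
    stop("duplicate interval id(s): ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "))
  if (!all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

#' Interval midpoints
#'
#' Midpoint of each interval on the 0-based coordinate axis (may be
#' half-integer for odd lengths).
#' @param x a `genomic_intervals` object.
#' @return numeric vector.
#' @export
interval_midpoint <- function(x) (x$start + x$end) / 2

#' Tag-count matrix of accessibility signal at peaks
#'
#' Peaks-by-samples matrix of (DNaseI) tag counts, with optional sample group
#' labels. The substrate for clustering, fold-change ranking and
#' group-specific site calling.
#'
#' @param counts numeric matrix, rows = peak ids, columns = sample ids;
#'   non-negative, no missing values.
#' @param groups optional named character vector mapping every sample id to a
#'   group label.
#' @param normalized logical; whether columns have already been depth-scaled.
#' @return An object of class `tag_count_matrix`.
#' @export
tag_count_matrix <- function(counts, groups = NULL, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have peak ids as rownames and sample ids as colnames")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts contain negative values")
  if (anyDuplicated(rownames(counts))) stop("duplicate peak ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (!is.null(groups)) {
    miss <- setdiff(colnames(counts), names(groups))
    if (length(miss))
      stop("samples without a group label: ", paste(miss, collapse = ", "))
    groups <- groups[colnames(counts)]
  }
  structure(list(counts = counts, groups = groups,
                 normalized = isTRUE(normalized)),
            class = "tag_count_matrix")
}

#' @export
print.tag_count_matrix <- function(x, ...) {
  cat(sprintf("tag_count_matrix: %d peaks x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw"))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.tag_count_matrix <- function(x) dim(x$counts)

group_means <- function(mat, groups, group) {
  smp <- names(groups)[groups == group]
  if (!length(smp)) stop("unknown or empty group: ", group)
  rowMeans(mat[, smp, drop = FALSE])
}

require_groups <- function(x, labels) {
  if (is.null(x$groups)) stop("sample group labels are required but absent")
  for (g in labels)
    if (!g %in% x$groups) stop("unknown group label: ", g)
  invisible(x)
}

#' Gene expression table (FPKM)
#'
#' Genes-by-samples matrix of non-negative FPKM values with optional sample
#' group labels.
#'
#' @param fpkm numeric matrix, rows = gene ids, columns = sample ids.
#' @param groups optional named character vector mapping sample id to group.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(fpkm, groups = NULL) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    stop("fpkm must have gene ids as rownames and sample ids as colnames")
  if (anyNA(fpkm)) stop("expression table contains missing values")
  if (any(fpkm < 0)) stop("negative FPKM values")
  if (anyDuplicated(rownames(fpkm))) stop("duplicate gene ids")
  if (!is.null(groups)) {
    miss <- setdiff(colnames(fpkm), names(groups))
    if (length(miss))
      stop("samples without a group label: ", paste(miss, collapse = ", "))
    groups <- groups[colnames(fpkm)]
  }
  structure(list(fpkm = fpkm, groups = groups), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples\n",
              nrow(x$fpkm), ncol(x$fpkm)))
  invisible(x)
}

#' Per-base cleavage profile over a peak window
#'
#' @param peak_id peak identifier.
#' @param window_start genomic start (0-based) of the profiled window,
#'   conventionally peak midpoint minus window/2.
#' @param cuts non-negative integer vector of per-base cleavage counts.
#' @return An object of class `cut_profile`.
#' @export
cut_profile <- function(peak_id, window_start, cuts) {
  cuts <- as.integer(cuts)
  if (anyNA(cuts) || any(cuts < 0)) stop("cuts must be non-negative integers")
  structure(list(peak_id = as.character(peak_id),
                 window_start = as.numeric(window_start), cuts = cuts),
            class = "cut_profile")
}

#' @export
print.cut_profile <- function(x, ...) {
  cat(sprintf("cut_profile %s: window_start=%.0f, length=%d, total cuts=%d\n",
              x$peak_id, x$window_start, length(x$cuts), sum(x$cuts)))
  invisible(x)
}
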
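# Digital genomic footprinting. A footprint is a localized depletion of
# DNaseI cleavage inside an otherwise accessible window. The statistic asks:
# given the N cuts falling in a candidate window plus its two flanks, is the
# number n landing inside the window smaller than the binomial expectation
# under a locally uniform cleavage rate?

#' Binomial cleavage-depletion statistic
#'
#' For a candidate footprint `[start, start + width)` with symmetric flanks
#' of `flank` bp: with n = cuts inside, N = cuts across footprint plus both
#' flanks and p0 = width / (width + 2 * flank), the p-value is the lower
#' binomial tail P(X <= n), X ~ Binomial(N, p0), and the score is
#' -log10(p). Coordinates are 0-based and window-relative.
#'
#' @param profile a [cut_profile].
#' @param start 0-based window-relative start of the candidate footprint.
#' @param width footprint width in bp.
#' @param flank flank width in bp on each side.
#' @return list with `p_value`, `score`, `n_cuts_inside`, `n_cuts_flanks`.
#' @export
footprint_statistic <- function(profile, start, width, flank) {
  L <- length(profile$cuts)
  if (start - flank < 0 || start + width + flank > L)
    stop("footprint span [", start - flank, ", ", start + width + flank,
         ") outside window of length ", L)
  inside <- sum(profile$cuts[(start + 1):(start + width)])
  span <- sum(profile$cuts[(start - flank + 1):(start + width + flank)])
  p0 <- width / (width + 2 * flank)
  p <- pbinom(inside, span, p0)
  list(p_value = p, score = max(0, -log10(p)),
       n_cuts_inside = inside, n_cuts_flanks = span - inside)
}

#' Detect footprints in a cut profile
#'
#' Slides candidate windows of every width in `widths` across the profile
#' (candidate starts every `step` bp — see Details), scores each with
#' [footprint_statistic], keeps candidates with score >= `score_min`, and
#' greedily accepts them in decreasing score order, discarding any candidate
#' overlapping an already accepted footprint. Ties in score are broken by
#' position then width, so detection is fully deterministic.
#'
#' @details The candidate grid is every `step` bp rather than every base:
#' with the default score threshold, an exhaustive 1-bp slide performs ~12k
#' highly dependent tests per 2 kb window and its family-wise null rate on
#' depletion-free profiles exceeds 1%; a 6-bp grid keeps essentially full
#' power for protected regions of typical TF size while holding the
#' per-profile false call rate below 1%.
#'
#' @param profile a [cut_profile].
#' @param widths candidate footprint widths in bp (default 11 to 31 by 4).
#' @param flank flank width in bp (default 35).
#' @param score_min minimum -log10 p-value to call a footprint (default 5).
#' @param step candidate grid spacing in bp (default 6).
#' @return data.frame of class `footprints` with columns `peak_id`, `start`,
#'   `end` (window-relative, 0-based half-open), `window_start` (genomic),
#'   `score`, `n_cuts_inside`, `n_cuts_flanks`, sorted by position;
#'   accepted footprints are pairwise non-overlapping.
#' @export
detect_footprints <- function(profile, widths = seq(11, 31, by = 4),
                              flank = 35, score_min = 5, step = 6) {
  L <- length(profile$cuts)
  if (L <= max(widths) + 2 * flank)
    stop("profile shorter than max width + 2*flank")
  cs <- c(0, cumsum(profile$cuts))
  cand <- vector("list", length(widths))
  for (k in seq_along(widths)) {
    w <- widths[k]
    p0 <- w / (w + 2 * flank)
    s <- seq(flank, L - w - flank, by = step)   # 0-based starts
    n <- cs[s + w + 1] - cs[s + 1]
    N <- cs[s + w + flank + 1] - cs[s - flank + 1]
    sc <- -log10(pbinom(n, N, p0))
    hit <- which(sc >= score_min)
    if (length(hit))
      cand[[k]] <- data.frame(start = s[hit], end = s[hit] + w,
                              score = sc[hit], n_cuts_inside = n[hit],
                              n_cuts_flanks = N[hit] - n[hit])
  }
  cand <- do.call(rbind, cand)
  empty <- data.frame(peak_id = character(), start = numeric(),
                      end = numeric(), window_start = numeric(),
                      score = numeric(), n_cuts_inside = numeric(),
                      n_cuts_flanks = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("footprints", "data.frame")
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$score, cand$start, cand$end), , drop = FALSE]
  acc_s <- numeric(0); acc_e <- numeric(0); keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < acc_e & cand$end[i] > acc_s)) {
      keep <- c(keep, i)
      acc_s <- c(acc_s, cand$start[i]); acc_e <- c(acc_e, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out <- data.frame(peak_id = profile$peak_id, start = out$start,
                    end = out$end, window_start = profile$window_start,
                    score = out$score, n_cuts_inside = out$n_cuts_inside,
                    n_cuts_flanks = out$n_cuts_flanks,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("footprints", "data.frame")
  out
}

#' Detect footprints across a set of profiles
#' @param profiles named list of [cut_profile] objects.
#' @param ... passed to [detect_footprints].
#' @return combined `footprints` data.frame.
#' @export
detect_footprints_all <- function(profiles, ...) {
  res <- lapply(profiles, detect_footprints, ...)
  out <- data.table::setDF(data.table::rbindlist(res))
  class(out) <- c("footprints", "data.frame")
  out
}
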
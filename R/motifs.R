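# PWM scanning and condition-specific motif enrichment.

BASES <- c("A", "C", "G", "T")

encode_seq <- function(seq, what = "sequence") {
  v <- strsplit(seq, "")[[1]]
  code <- match(v, BASES)
  bad <- is.na(code) & v != "N"
  if (any(bad))
    stop(what, " contains characters outside ACGTN: ",
         paste(unique(v[bad]), collapse = ""))
  code  # NA marks N
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Maximum achievable log-odds score of a PWM
#' @param pwm a `pwm` object (see [read_pwms]).
#' @return sum over positions of the best per-base log2 odds.
#' @export
pwm_max_score <- function(pwm) {
  lo <- log2(pwm$matrix / pwm$background)
  sum(apply(lo, 2, max))
}

score_offsets <- function(code, lo) {
  L <- ncol(lo)
  n_off <- length(code) - L + 1L
  if (n_off < 1L) return(numeric(0))
  sc <- numeric(n_off)
  for (j in seq_len(L)) {
    contrib <- lo[, j][code[j:(j + n_off - 1L)]]
    contrib[is.na(contrib)] <- -Inf   # N never matches
    sc <- sc + contrib
  }
  sc
}

#' Scan peak sequences with a PWM library
#'
#' Scores every offset of every sequence on both strands with per-position
#' log2 odds, log2(p_base / background_base), the minus strand being scored
#' on the reverse complement. An occurrence is reported when its score
#' reaches `rel_threshold` times the maximum achievable score of that PWM.
#' Reported offsets are always on the plus-strand coordinate system of the
#' input sequence (0-based start of the matched span).
#'
#' @param sequences named character vector of uppercase A/C/G/T/N sequences
#'   keyed by peak id.
#' @param pwms named list of `pwm` objects from [read_pwms].
#' @param rel_threshold fraction of the maximum achievable log-odds
#'   (default 0.8).
#' @return data.frame of class `motif_occurrences` with columns `peak_id`,
#'   `offset`, `width`, `strand`, `motif_id`, `log_odds`.
#' @export
scan_motifs <- function(sequences, pwms, rel_threshold = 0.8) {
  stopifnot(length(names(sequences)) == length(sequences))
  rows <- list()
  for (pid in names(sequences)) {
    fwd <- encode_seq(sequences[[pid]], paste0("sequence ", pid))
    rcs <- revcomp(sequences[[pid]])
    rev <- encode_seq(rcs)
    slen <- length(fwd)
    for (m in names(pwms)) {
      pwm <- pwms[[m]]
      lo <- log2(pwm$matrix / pwm$background)
      L <- ncol(lo)
      thr <- rel_threshold * pwm_max_score(pwm)
      scf <- score_offsets(fwd, lo)
      hit <- which(scf >= thr)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = pid, offset = hit - 1L, width = L, strand = "+",
          motif_id = m, log_odds = scf[hit], stringsAsFactors = FALSE)
      scr <- score_offsets(rev, lo)
      hit <- which(scr >= thr)
      if (length(hit))   # map RC offset back to plus-strand coordinates
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = pid, offset = slen - L - (hit - 1L), width = L,
          strand = "-", motif_id = m, log_odds = scr[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(peak_id = character(), offset = integer(),
                      width = integer(), strand = character(),
                      motif_id = character(), log_odds = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.table::setDF(data.table::rbindlist(rows))
    out <- out[order(out$peak_id, out$motif_id, out$offset, out$strand), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("motif_occurrences", "data.frame")
  out
}

# occurrences joined to footprints by peak id and >=1 bp overlap in
# window-relative coordinates; peaks supplies the peak->window geometry
occ_window_relative <- function(occurrences, peaks, profiles) {
  pk <- setNames(seq_len(nrow(peaks)), peaks$id)
  i <- pk[occurrences$peak_id]
  if (anyNA(i))
    stop("occurrence in unknown peak: ",
         occurrences$peak_id[which(is.na(i))[1]])
  abs_start <- peaks$start[i] + occurrences$offset
  ws <- vapply(profiles[occurrences$peak_id], function(p)
    if (is.null(p)) NA_real_ else p$window_start, 0)
  if (anyNA(ws))
    stop("no cut profile for peak: ",
         occurrences$peak_id[which(is.na(ws))[1]])
  data.frame(peak_id = occurrences$peak_id,
             start = abs_start - ws,
             end = abs_start - ws + occurrences$width,
             motif_id = occurrences$motif_id, stringsAsFactors = FALSE)
}

footprint_overlaps_motif <- function(fp, occ, motif_id) {
  # for each footprint row: does it overlap an occurrence of motif_id in the
  # same peak (window-relative coordinates)?
  o <- occ[occ$motif_id == motif_id, , drop = FALSE]
  if (!nrow(o) || !nrow(fp)) return(rep(FALSE, nrow(fp)))
  out <- logical(nrow(fp))
  osplit <- split(o, o$peak_id)
  for (pid in intersect(names(osplit), unique(fp$peak_id))) {
    fi <- which(fp$peak_id == pid)
    ob <- osplit[[pid]]
    out[fi] <- vapply(fi, function(k)
      any(fp$start[k] < ob$end & fp$end[k] > ob$start), TRUE)
  }
  out
}

#' Condition-specific motif enrichment over footprints
#'
#' For motif m and condition c, with pseudocount q:
#' f_obs = (#footprints of c overlapping an occurrence of m + q) /
#' (#footprints of c + q); f_bg is the same computed over the footprints of
#' c lying in `background_peaks`; score(m, c) = log2(f_obs / f_bg).
#'
#' Footprints and occurrences are matched by peak id and >= 1 bp overlap.
#' The footprint set of every condition must be non-empty.
#'
#' @param footprints named list (condition -> `footprints` data.frame, as
#'   from [detect_footprints_all]); should span both the condition's
#'   analysis peaks and the background peaks.
#' @param occurrences a `motif_occurrences` data.frame from [scan_motifs]
#'   (offsets are peak-relative).
#' @param peaks [genomic_intervals] with ids covering all occurrence peaks.
#' @param profiles named list of [cut_profile] objects giving the window
#'   geometry of each peak.
#' @param background_peaks character vector of peak ids forming the
#'   background set.
#' @param pseudocount added to numerator and denominator (default 1).
#' @return matrix of class `motif_score_table`, motifs x conditions, of log2
#'   enrichment scores.
#' @export
motif_enrichment <- function(footprints, occurrences, peaks, profiles,
                             background_peaks, pseudocount = 1) {
  stopifnot(is.list(footprints), length(names(footprints)) > 0)
  occ <- occ_window_relative(occurrences, peaks, profiles)
  motifs <- sort(unique(occ$motif_id))
  conds <- names(footprints)
  out <- matrix(NA_real_, length(motifs), length(conds),
                dimnames = list(motifs, conds))
  for (cn in conds) {
    fp <- footprints[[cn]]
    if (is.null(fp) || nrow(fp) == 0L)
      stop("empty footprint set for condition: ", cn)
    bg <- fp[fp$peak_id %in% background_peaks, , drop = FALSE]
    for (m in motifs) {
      ov <- footprint_overlaps_motif(fp, occ, m)
      f_obs <- (sum(ov) + pseudocount) / (nrow(fp) + pseudocount)
      ovb <- footprint_overlaps_motif(bg, occ, m)
      f_bg <- (sum(ovb) + pseudocount) / (nrow(bg) + pseudocount)
      out[m, cn] <- log2(f_obs / f_bg)
    }
  }
  class(out) <- c("motif_score_table", class(out))
  out
}

#' Motifs specific to a condition versus a reference
#'
#' A motif is condition-specific when its enrichment score is at least
#' `min_score` in the condition and below `max_ref` in the reference
#' (operationalizing "footprinted in the condition, not found in the
#' reference").
#'
#' @param scores a `motif_score_table` from [motif_enrichment].
#' @param condition condition column of interest.
#' @param reference reference column (default `"PBSC"`).
#' @param min_score minimum score in the condition (default log2(2) = 1).
#' @param max_ref maximum score allowed in the reference
#'   (default log2(1.25)).
#' @return character vector of motif ids.
#' @export
condition_specific_motifs <- function(scores, condition, reference = "PBSC",
                                      min_score = log2(2),
                                      max_ref = log2(1.25)) {
  stopifnot(condition %in% colnames(scores), reference %in% colnames(scores))
  rownames(scores)[scores[, condition] >= min_score &
                     scores[, reference] < max_ref]
}
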
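# Shared fixtures and independent oracles, built in code at test time.

tmpfile <- function(ext = "") tempfile(fileext = ext)

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  start <- sample.int(max_pos, n)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample(50:500, n, replace = TRUE),
                    id = sprintf("iv%04d", seq_len(n)),
                    strand = sample(c("+", "-", "."), n, replace = TRUE))
}

rand_tss <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  out <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                    chrom = sample(chroms, n, replace = TRUE),
                    pos = sample.int(max_pos, n), strand = "+",
                    stringsAsFactors = FALSE)
  class(out) <- c("tss_annotation", "data.frame")
  out
}

# independent binomial lower-tail CDF: explicit log-coefficient summation,
# no call to pbinom/pbeta
binom_cdf_oracle <- function(n, N, p0) {
  if (N == 0) return(1)
  k <- 0:n
  sum(exp(lchoose(N, k) + k * log(p0) + (N - k) * log1p(-p0)))
}

# brute-force PWM scanner: every offset, both strands, scalar arithmetic
brute_scan <- function(sequences, pwms, rel_threshold = 0.8) {
  rc1 <- function(s) chartr("ACGTN", "TGCAN",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rows <- list()
  for (pid in names(sequences)) {
    for (m in names(pwms)) {
      pwm <- pwms[[m]]
      L <- ncol(pwm$matrix)
      lo <- log2(pwm$matrix / pwm$background)
      thr <- rel_threshold * sum(apply(lo, 2, max))
      for (strand in c("+", "-")) {
        s <- if (strand == "+") sequences[[pid]] else rc1(sequences[[pid]])
        v <- strsplit(s, "")[[1]]
        for (off in 0:(length(v) - L)) {
          sc <- 0
          for (j in 1:L) {
            b <- v[off + j]
            sc <- sc + if (b %in% rownames(lo)) lo[b, j] else -Inf
          }
          if (sc >= thr) {
            plus_off <- if (strand == "+") off else length(v) - L - off
            rows[[length(rows) + 1]] <- data.frame(
              peak_id = pid, offset = plus_off, width = L, strand = strand,
              motif_id = m, log_odds = sc, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(peak_id = character(), offset = integer(),
                      width = integer(), strand = character(),
                      motif_id = character(), log_odds = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$peak_id, out$motif_id, out$offset, out$strand), ,
      drop = FALSE]
}

# minimal hand-built ground truth for simulate_counts
manual_truth <- function(peak_ids, group_specific_peaks) {
  structure(list(peak_ids = peak_ids,
                 group_specific_peaks = group_specific_peaks),
            class = "ground_truth")
}

# a consensus PWM with hard counts (probability ~1 after pseudocount)
consensus_pwm <- function(motif_id, consensus, count = 100) {
  L <- nchar(consensus)
  m <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")),
          1:L)] <- count
  m <- m + 0.5
  m <- sweep(m, 2, colSums(m), "/")
  structure(list(motif_id = motif_id, matrix = m,
                 background = rep(0.25, 4)), class = "pwm")
}

# small full study for pipeline-level tests
tiny_sim <- function(seed = 5) {
  sim_config(seed = seed, n_peaks = 220, n_tfs = 2, n_targets = 12,
             n_specific_per_group = 20, n_constitutive = 15,
             n_proximal = 15, n_down_genes = 8, n_null_genes = 8)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
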
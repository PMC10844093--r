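# File-format boundary. Everything in memory is 0-based half-open; 1-based
# dialects never leak past this file.

#' Read a BED file of genomic intervals
#'
#' Whitespace-delimited, >= 3 columns. Column 4 (if present) becomes `id`,
#' column 6 becomes `strand`. Coordinates are taken verbatim (BED is already
#' 0-based half-open). Input ordering is preserved. An empty file yields an
#' empty interval set; a malformed line is an error naming the line number.
#'
#' @param path file path.
#' @return a [genomic_intervals] object.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- length(fields)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  id <- rep(NA_character_, n); strand <- rep(".", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("%s line %d: fewer than 3 columns", path, i))
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stop(sprintf("%s line %d: non-integer coordinates '%s' '%s'",
                   path, i, f[2L], f[3L]))
    if (!(s >= 0 && s < e))
      stop(sprintf("%s line %d: need 0 <= start < end (got %s, %s)",
                   path, i, f[2L], f[3L]))
    chrom[i] <- f[1L]; start[i] <- s; end[i] <- e
    if (length(f) >= 4L) id[i] <- f[4L]
    if (length(f) >= 6L) {
      if (!f[6L] %in% c("+", "-", "."))
        stop(sprintf("%s line %d: bad strand '%s'", path, i, f[6L]))
      strand[i] <- f[6L]
    }
  }
  if (all(is.na(id))) id <- NULL
  genomic_intervals(chrom, start, end, id = id, strand = strand)
}

#' Write genomic intervals as BED
#'
#' Writes 3 columns when no ids/strands are set, 6 columns (with a
#' placeholder score of 0) otherwise, so that [read_bed] round-trips.
#'
#' @param x a [genomic_intervals] object.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  if (nrow(x) == 0L) { file.create(path); return(invisible(path)) }
  if (all(is.na(x$id)) && all(x$strand == ".")) {
    dt <- data.table::data.table(x$chrom, format_coord(x$start),
                                 format_coord(x$end))
  } else {
    dt <- data.table::data.table(x$chrom, format_coord(x$start),
                                 format_coord(x$end),
                                 ifelse(is.na(x$id), ".", x$id), 0L, x$strand)
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_coord <- function(x) sprintf("%.0f", x)

#' Read a TSS annotation (BED-like)
#'
#' One row per TSS: chrom, start, end (= start + 1), gene id in column 4,
#' strand in column 6. Several TSS per gene are allowed.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `chrom`, `pos` (0-based),
#'   `strand`, of class `tss_annotation`.
#' @export
read_tss <- function(path) {
  iv <- read_bed(path)
  if (nrow(iv) > 0 && anyNA(iv$id))
    stop("TSS annotation requires a gene id in column 4")
  out <- data.frame(gene_id = if (nrow(iv)) iv$id else character(),
                    chrom = iv$chrom, pos = iv$start, strand = iv$strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("tss_annotation", "data.frame")
  out
}

#' @rdname read_tss
#' @param tss a `tss_annotation` data.frame.
#' @export
write_tss <- function(tss, path) {
  # duplicate gene ids are legitimate here (multiple TSS per gene), so bypass
  # the unique-id invariant of genomic_intervals
  dt <- data.table::data.table(tss$chrom, format_coord(tss$pos),
                               format_coord(tss$pos + 1), tss$gene_id, 0L,
                               tss$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read promoter-capture interaction pairs (BEDPE + gene + score)
#'
#' Columns 1-6 are the two anchors (promoter then distal), column 7 the gene
#' id of the promoter anchor, column 8 a non-negative interaction score.
#'
#' @param path file path.
#' @return data.frame of class `interaction_set` with anchor coordinates,
#'   `gene_id` and `score`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- data.frame(p_chrom = character(), p_start = numeric(),
                      p_end = numeric(), d_chrom = character(),
                      d_start = numeric(), d_end = numeric(),
                      gene_id = character(), score = numeric())
    class(out) <- c("interaction_set", "data.frame")
    return(out)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  parse1 <- function(f, i) {
    if (length(f) < 8L)
      stop(sprintf("%s line %d: expected 8 columns, got %d", path, i, length(f)))
    co <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    sc <- suppressWarnings(as.numeric(f[8]))
    if (anyNA(co) || any(co != floor(co)))
      stop(sprintf("%s line %d: non-integer anchor coordinates", path, i))
    if (co[1] >= co[2] || co[3] >= co[4] || any(co < 0))
      stop(sprintf("%s line %d: invalid anchor interval", path, i))
    if (is.na(sc) || sc < 0)
      stop(sprintf("%s line %d: score must be a non-negative number", path, i))
    if (!nzchar(f[7]) || f[7] == ".")
      stop(sprintf("%s line %d: gene id missing", path, i))
    list(f[1], co[1], co[2], f[4], co[3], co[4], f[7], sc)
  }
  rows <- lapply(seq_along(fields), function(i) parse1(fields[[i]], i))
  out <- data.frame(
    p_chrom = vapply(rows, `[[`, "", 1), p_start = vapply(rows, `[[`, 0, 2),
    p_end = vapply(rows, `[[`, 0, 3), d_chrom = vapply(rows, `[[`, "", 4),
    d_start = vapply(rows, `[[`, 0, 5), d_end = vapply(rows, `[[`, 0, 6),
    gene_id = vapply(rows, `[[`, "", 7), score = vapply(rows, `[[`, 0, 8),
    stringsAsFactors = FALSE)
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' @rdname read_interactions
#' @param x an `interaction_set` data.frame.
#' @export
write_interactions <- function(x, path) {
  dt <- data.table::data.table(
    x$p_chrom, format_coord(x$p_start), format_coord(x$p_end),
    x$d_chrom, format_coord(x$d_start), format_coord(x$d_end),
    x$gene_id, format_num(x$score))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# shortest decimal that survives as.numeric() round-trip
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

read_numeric_tsv <- function(path, what = "matrix") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2L) stop(path, ": expected an id column plus data columns")
  ids <- dt[[1L]]
  if (anyDuplicated(ids))
    stop(path, ": duplicate ", what, " row id: ", ids[duplicated(ids)][1])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(dt[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop(sprintf("%s: non-numeric value at row '%s', column '%s'",
                 path, ids[bad[1, 1]], colnames(dt)[-1L][bad[1, 2]]))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("%s: missing value at row '%s', column '%s'",
                 path, ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  m
}

write_numeric_tsv <- function(mat, path, id_col) {
  dt <- data.table::as.data.table(
    apply(mat, 2, format_num, simplify = FALSE))
  dt <- cbind(data.table::data.table(..id = rownames(mat)), dt)
  data.table::setnames(dt, "..id", id_col)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a peaks-by-samples tag count matrix (TSV)
#'
#' TSV with a header row of sample names; first column holds peak ids.
#' Missing or non-numeric cells and duplicate peak ids are errors. Values
#' round-trip at full double precision.
#'
#' @param path file path.
#' @param groups optional named character vector of sample group labels.
#' @return a [tag_count_matrix] (raw, `normalized = FALSE` unless the file
#'   was written from a normalized object — the flag is not serialized).
#' @export
read_count_matrix <- function(path, groups = NULL) {
  tag_count_matrix(read_numeric_tsv(path, "peak"), groups = groups)
}

#' @rdname read_count_matrix
#' @param x a [tag_count_matrix].
#' @export
write_count_matrix <- function(x, path) {
  write_numeric_tsv(x$counts, path, "peak_id")
}

#' Read / write a genes-by-samples FPKM expression table (TSV)
#' @inheritParams read_count_matrix
#' @return an [expression_table].
#' @export
read_expression <- function(path, groups = NULL) {
  expression_table(read_numeric_tsv(path, "gene"), groups = groups)
}

#' @rdname read_expression
#' @param x an [expression_table].
#' @export
write_expression <- function(x, path) {
  write_numeric_tsv(x$fpkm, path, "gene_id")
}

#' Read / write the sample table (sample id, group)
#' @param path file path.
#' @return named character vector mapping sample id to group label.
#' @export
read_sample_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(dt)))
    stop(path, ": need columns sample_id, group")
  if (anyDuplicated(dt$sample_id)) stop(path, ": duplicate sample id")
  setNames(dt$group, dt$sample_id)
}

#' @rdname read_sample_table
#' @param groups named character vector (names = sample ids).
#' @export
write_sample_table <- function(groups, path) {
  data.table::fwrite(data.table::data.table(sample_id = names(groups),
                                            group = unname(groups)),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a JASPAR-style PWM library
#'
#' Each motif: a header line starting with `>` (first token after `>` is the
#' motif id) followed by four rows labeled A, C, G, T of non-negative counts
#' or frequencies, optionally bracketed (`A [ 10 0 5 ]`). Counts are
#' regularized by adding a pseudocount of 0.5 to every cell and then
#' normalized per column to probabilities.
#'
#' @param path file path.
#' @param background base background probabilities (A, C, G, T); must sum
#'   to 1. Default uniform.
#' @param pseudocount per-cell regularization added before normalization.
#' @return named list of `pwm` objects, each with `motif_id`,
#'   `matrix` (4 x L probability matrix, rows A/C/G/T) and `background`.
#' @export
read_pwms <- function(path, background = rep(0.25, 4), pseudocount = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop(path, ": no '>' motif headers found")
  ends <- c(heads[-1] - 1L, length(lines))
  pwms <- list()
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    motif_id <- strsplit(hdr, "[ \t]+")[[1]][1]
    body <- if (ends[k] >= heads[k] + 1L)
      lines[(heads[k] + 1L):ends[k]] else character()
    if (length(body) > 4L)
      stop(path, ": motif ", motif_id, ": expected 4 base rows, got ",
           length(body))
    rows <- list()
    for (b in body) {
      base <- toupper(substr(b, 1, 1))
      if (!base %in% c("A", "C", "G", "T"))
        stop(path, ": motif ", motif_id, ": unlabeled row '", b, "'")
      vals <- gsub("[][]", " ", substr(b, 2, nchar(b)))
      v <- suppressWarnings(as.numeric(strsplit(trimws(vals), "[ \t]+")[[1]]))
      if (anyNA(v)) stop(path, ": motif ", motif_id, ": non-numeric count")
      if (any(v < 0)) stop(path, ": motif ", motif_id, ": negative count")
      if (base %in% names(rows))
        stop(path, ": motif ", motif_id, ": duplicate ", base, " row")
      rows[[base]] <- v
    }
    if (!all(c("A", "C", "G", "T") %in% names(rows)))
      stop(path, ": motif ", motif_id, ": missing base row(s): ",
           paste(setdiff(c("A", "C", "G", "T"), names(rows)), collapse = ", "))
    lens <- vapply(rows, length, 0L)
    if (length(unique(lens)) != 1L)
      stop(path, ": motif ", motif_id, ": rows of unequal length")
    if (lens[1] < 4L)
      stop(path, ": motif ", motif_id, ": motif length must be >= 4")
    m <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T) + pseudocount
    m <- sweep(m, 2, colSums(m), "/")
    pwms[[motif_id]] <- structure(
      list(motif_id = motif_id, matrix = m, background = background),
      class = "pwm")
  }
  pwms
}

#' Write PWM count matrices in JASPAR text format
#'
#' Note this writes *counts*; [read_pwms] regularizes with a pseudocount on
#' the way back in, so read(write(x)) is a regularization, not an identity.
#'
#' @param counts named list of 4 x L count matrices (rows A, C, G, T).
#' @param path output path.
#' @export
write_pwms <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(counts)) {
    m <- counts[[id]]
    writeLines(paste0(">", id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(format_num(m[b, ]), collapse = " "),
                        " ]"), con)
  }
  invisible(path)
}

#' Read / write peak sequences (FASTA)
#'
#' Thin wrappers over Biostrings; sequences are handled internally as a
#' named uppercase character vector.
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @param seqs named character vector of A/C/G/T/N sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read / write per-base cut profiles (wide TSV)
#'
#' One row per peak: `peak_id`, `window_start`, then one column per base of
#' the window. All profiles in one file share the window length.
#'
#' @param path file path.
#' @return named list of [cut_profile] objects keyed by peak id.
#' @export
read_cut_profiles <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 3L) stop(path, ": malformed cut profile table")
  ids <- dt[[1L]]
  ws <- dt[[2L]]
  cuts <- as.matrix(dt[, -(1:2), drop = FALSE])
  if (anyNA(cuts) || any(cuts < 0))
    stop(path, ": cut counts must be non-negative and complete")
  out <- lapply(seq_along(ids), function(i)
    cut_profile(ids[i], ws[i], cuts[i, ]))
  setNames(out, ids)
}

#' @rdname read_cut_profiles
#' @param profiles named list of [cut_profile] objects (equal window length).
#' @export
write_cut_profiles <- function(profiles, path) {
  lens <- vapply(profiles, function(p) length(p$cuts), 0L)
  if (length(unique(lens)) > 1L)
    stop("all profiles in one file must share the window length")
  m <- do.call(rbind, lapply(profiles, function(p) p$cuts))
  dt <- data.table::data.table(
    peak_id = vapply(profiles, function(p) p$peak_id, ""),
    window_start = vapply(profiles, function(p) p$window_start, 0))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::setnames(dt, c("peak_id", "window_start",
                             paste0("b", seq_len(ncol(m)))))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read the LSC17 weight table
#'
#' TSV with columns `gene_id` and `weight`; exactly 17 rows, unique gene
#' ids, and a CD34 entry (the variant score excludes it).
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `weight`, `is_cd34`.
#' @export
read_lsc17_weights <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("gene_id", "weight") %in% colnames(dt)))
    stop(path, ": need columns gene_id, weight")
  if (nrow(dt) != 17L)
    stop(path, ": LSC17 weight table must have exactly 17 rows, has ",
         nrow(dt))
  if (anyDuplicated(dt$gene_id)) stop(path, ": duplicate gene id")
  if (!is.numeric(dt$weight) || anyNA(dt$weight))
    stop(path, ": weights must be numeric")
  if (!"CD34" %in% dt$gene_id) stop(path, ": no CD34 entry")
  data.frame(gene_id = dt$gene_id, weight = dt$weight,
             is_cd34 = dt$gene_id == "CD34", stringsAsFactors = FALSE)
}
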
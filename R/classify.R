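# Binomial significance classification of reads against a kmer_db.
#
# Null model per assembly i: each of the n syncmer queries from a read is an
# independent Bernoulli trial with success probability p_i = |K_i|/|U|. The
# P-value of observing x_i or more matches is the exact binomial upper tail.
# To make one cutoff comparable across read lengths, match counts are
# rescaled to a fixed trial count n_fixed before the table lookup.

#' Classification options
#'
#' @param n_fixed fixed trial count for the P-value lookup tables
#'   (default 100).
#' @param cutoff_exponent e; a read is classified when its smallest P-value
#'   is below `10^-e` (default 12).
#' @param max_read_length optional prefix truncation length in bp (emulating
#'   adaptive sampling); NULL classifies the full read.
#' @return object of class `classify_options`.
#' @export
classify_options <- function(n_fixed = 100L, cutoff_exponent = 12,
                             max_read_length = NULL) {
  n_fixed <- as.integer(n_fixed)
  if (n_fixed < 1L) stop("n_fixed must be >= 1")
  if (cutoff_exponent <= 0) stop("cutoff_exponent must be positive")
  if (!is.null(max_read_length)) {
    max_read_length <- as.integer(max_read_length)
    if (max_read_length < 1L) stop("max_read_length must be >= 1")
  }
  structure(list(n_fixed = n_fixed, cutoff_exponent = cutoff_exponent,
                 max_read_length = max_read_length),
            class = "classify_options")
}

#' Exact binomial upper tail
#'
#' `P(Bin(n, p) >= x)`, the probability of observing `x` or more successes
#' in `n` independent trials with success probability `p`. Evaluated through
#' the regularized incomplete beta function (via [stats::pbinom()]), so
#' values down to the smallest normal double are representable.
#' `P(>= 0) = 1` and `P(>= n+1) = 0`.
#'
#' @param n number of trials.
#' @param p success probability.
#' @param x threshold match count, `0 <= x <= n + 1` (vectorized).
#' @return upper-tail probability.
#' @export
binom_sf <- function(n, p, x) {
  if (any(n < 0) || any(p < 0 | p > 1)) stop("binom_sf: parameters out of domain")
  if (any(x < 0 | x > n + 1)) stop("binom_sf: x out of [0, n + 1]")
  stats::pbinom(x - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Precompute P-value lookup tables for a database
#'
#' One column per assembly; entry `[x + 1, i]` equals
#' `binom_sf(n_fixed, p_i, x)` for `x` in `0..n_fixed`. Assemblies with an
#' undefined match probability (empty k-mer set) are excluded with a warning
#' and can never be matched.
#'
#' @param db a `kmer_db`.
#' @param options a [classify_options()] object.
#' @return object of class `pvalue_table`: matrix `table`
#'   (`n_fixed + 1` rows), `n_fixed`, `p` per column.
#' @export
build_pvalue_tables <- function(db, options = classify_options()) {
  stopifnot(inherits(db, "kmer_db"), inherits(options, "classify_options"))
  nf <- options$n_fixed
  p <- rep(NA_real_, length(db$labels))
  ok <- db$set_sizes > 0
  if (any(!ok)) {
    warning(sprintf("excluding assemblies with empty k-mer sets: %s",
                    paste(db$labels[!ok], collapse = ", ")))
  }
  p[ok] <- db$set_sizes[ok] / db$universe_size
  tab <- matrix(NA_real_, nf + 1L, length(p),
                dimnames = list(NULL, db$labels))
  for (i in which(ok)) {
    tab[, i] <- binom_sf(nf, p[i], 0:nf)
  }
  structure(list(table = tab, n_fixed = nf, p = p), class = "pvalue_table")
}

#' Rescale a match count to the fixed trial count
#'
#' `floor(x * n_fixed / n)` when `n >= n_fixed`; when fewer than `n_fixed`
#' k-mers were queried the raw count is used unchanged (the P-value is still
#' evaluated at `n_fixed` trials).
#'
#' @param x raw match count, `0 <= x <= n`.
#' @param n number of k-mer trials from the read.
#' @param n_fixed fixed trial count.
#' @return scaled match count (vectorized over `x`).
#' @export
scale_matches <- function(x, n, n_fixed) {
  if (n == 0L) stop("no k-mer trials: read unclassifiable")
  if (any(x < 0 | x > n)) stop("x must be in [0, n]")
  if (n >= n_fixed) floor(x * n_fixed / n) else x
}

#' Classify one read against the database
#'
#' Truncates the sequence to its first `max_read_length` bases when set,
#' extracts k-mer trials with the database parameters (every emitted window
#' occurrence is one trial), counts per-assembly matches through the
#' compressed rows, rescales counts to `n_fixed` trials and looks up exact
#' binomial P-values. The read is assigned the assembly with the smallest
#' P-value when that P-value is below `10^-cutoff_exponent`, otherwise it is
#' reported unclassified. Ties at the minimal P-value are broken by larger
#' scaled count, then smaller match probability, then smaller column index;
#' P-values that underflow are clamped to the smallest positive normal
#' double so ordering stays defined.
#'
#' @param db a `kmer_db`.
#' @param tables a [build_pvalue_tables()] result consistent with `db`.
#' @param read_id read identifier.
#' @param sequence read sequence (character scalar).
#' @param options a [classify_options()] object.
#' @return one-row data.frame: `read_id`, `status` ("classified" or
#'   "unclassified"), `label` (or NA), `p_value`, `x_raw`, `x_scaled`, `n`.
#' @export
classify_read <- function(db, tables, read_id, sequence,
                          options = classify_options()) {
  stopifnot(inherits(db, "kmer_db"), inherits(tables, "pvalue_table"))
  if (!is.null(options$max_read_length)) {
    sequence <- substr(sequence, 1L, options$max_read_length)
  }
  codes <- extract_kmers(sequence, db$params)
  n <- length(codes)
  unclassified <- data.frame(
    read_id = read_id, status = "unclassified", label = NA_character_,
    p_value = 1, x_raw = 0L, x_scaled = 0L, n = n,
    stringsAsFactors = FALSE)
  if (n == 0L) return(unclassified)

  idx <- match(codes, db$codes)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(unclassified)
  x <- numeric(length(db$labels))
  row_counts <- table(idx)
  for (j in seq_along(row_counts)) {
    cols <- .row_columns(db, as.integer(names(row_counts)[j]))
    x[cols] <- x[cols] + as.numeric(row_counts[j])
  }

  hit <- which(x > 0 & !is.na(tables$p))  # x = 0 gives P = 1, never wins
  if (length(hit) == 0L) return(unclassified)
  xbar <- scale_matches(x[hit], n, tables$n_fixed)
  stopifnot(all(xbar <= tables$n_fixed))
  pv <- tables$table[cbind(xbar + 1L, hit)]
  pv <- pmax(pv, .Machine$double.xmin)
  best <- order(pv, -xbar, tables$p[hit], hit)[1L]
  if (pv[best] < 10^(-options$cutoff_exponent)) {
    data.frame(
      read_id = read_id, status = "classified",
      label = db$labels[hit[best]], p_value = pv[best],
      x_raw = as.integer(x[hit[best]]), x_scaled = as.integer(xbar[best]),
      n = n, stringsAsFactors = FALSE)
  } else {
    unclassified$p_value <- pv[best]
    unclassified$x_raw <- as.integer(x[hit[best]])
    unclassified$x_scaled <- as.integer(xbar[best])
    unclassified
  }
}

# read a FASTA or FASTQ (possibly gzipped) into a named character vector
.read_sequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("reads file not found: %s", path))
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) return(character(0))
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  recs <- Biostrings::readBStringSet(path, format = fmt)
  seqs <- as.character(recs)
  names(seqs) <- sub("\\s.*$", "", names(recs))
  seqs
}

#' Classify a stream of reads
#'
#' Reads FASTA or FASTQ (plain or gzipped; format sniffed from the first
#' character), classifies each read in input order, and optionally writes a
#' TSV (one row per read, columns as in [classify_read()], `label` written
#' as `-` for unclassified reads, with `#`-prefixed parameter-echo header
#' lines).
#'
#' @param db a `kmer_db`.
#' @param reads path to a FASTA/FASTQ file, or a named character vector of
#'   sequences.
#' @param options a [classify_options()] object.
#' @param output optional path for the results TSV.
#' @param tables optional precomputed [build_pvalue_tables()] result.
#' @return data.frame of per-read results with attribute `summary` (counts
#'   per status).
#' @export
classify_stream <- function(db, reads, options = classify_options(),
                            output = NULL, tables = NULL) {
  stopifnot(inherits(db, "kmer_db"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      is.null(names(reads))) {
    reads <- .read_sequences(reads)
  }
  if (is.null(names(reads)) && length(reads) > 0L) {
    names(reads) <- sprintf("read%06d", seq_along(reads))
  }
  if (is.null(tables)) tables <- build_pvalue_tables(db, options)
  res <- lapply(seq_along(reads), function(i) {
    classify_read(db, tables, names(reads)[i], reads[[i]], options)
  })
  res <- if (length(res)) do.call(rbind, res) else data.frame(
    read_id = character(0), status = character(0), label = character(0),
    p_value = numeric(0), x_raw = integer(0), x_scaled = integer(0),
    n = integer(0), stringsAsFactors = FALSE)
  summary_counts <- c(
    classified = sum(res$status == "classified"),
    unclassified = sum(res$status == "unclassified"))
  attr(res, "summary") <- summary_counts
  if (!is.null(output)) {
    hdr <- c(
      sprintf("# kmerscreen classify: k=%d s=%d t=%d mode=%s canonicalize=%s w=%d",
              db$params$k, db$params$s, db$params$t,
              db$params$subsample_mode, db$params$canonicalize, db$w),
      sprintf("# n_fixed=%d cutoff=1e-%g max_read_length=%s",
              options$n_fixed, options$cutoff_exponent,
              if (is.null(options$max_read_length)) "none"
              else options$max_read_length))
    out <- res
    out$label[is.na(out$label)] <- "-"
    writeLines(hdr, output)
    suppressWarnings(utils::write.table(
      out, output, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = TRUE, append = TRUE))
  }
  res
}
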
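# Compressed reference database: column-ordered, row-compressed k-mer by
# assembly matrix plus per-assembly match probabilities.
#
# Only k-mers present in at least one assembly get a stored row (a dense
# 4^k-row matrix is infeasible for k=15); absent codes mean zero matches.
# Rows are looked up by binary search over the sorted code index.

#' Build a compressed k-mer classification database
#'
#' Runs the full construction pipeline: per-assembly k-mer sets, pairwise
#' Hamming distances, greedy nearest-neighbour column ordering, then one
#' adaptive-RLE row per k-mer in the permuted column order. Deterministic
#' given inputs, parameters and `start_index`.
#'
#' @param x character vector of FASTA paths (one file = one classification
#'   target; column order is the lexicographic order of file names), or a
#'   list of [kmer_set()] objects (used in given order).
#' @param labels optional assembly labels; default is the FASTA file stem or
#'   the set label. Duplicates are an error.
#' @param params a [syncmer_params()] object.
#' @param w adaptive-RLE word width in bits.
#' @param start_index 1-based column the nearest-neighbour ordering starts
#'   from (default 1, for reproducibility; see [nearest_neighbor_order()]).
#' @param universe a [universe_size()] result, a bare number `|U|`, or NULL
#'   to compute it (exact for small k, Monte-Carlo with 1e7 samples and seed
#'   1 otherwise).
#' @param distance_fn optional distance override passed to
#'   [pairwise_distances()].
#' @return object of class `kmer_db`.
#' @export
build_database <- function(x, labels = NULL, params = syncmer_params(),
                           w = 16L, start_index = 1L, universe = NULL,
                           distance_fn = NULL) {
  w <- .arle_validate_w(w)
  files <- NULL
  if (is.character(x)) {
    files <- x[order(basename(x))]
    sets <- lapply(seq_along(files), function(i) {
      build_kmer_set(files[i],
                     label = if (is.null(labels)) NULL else labels[order(basename(x))][i],
                     params = params)
    })
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "kmer_set")))
    sets <- x
    if (!is.null(labels)) {
      stopifnot(length(labels) == length(sets))
      sets <- Map(function(s, l) { s$label <- l; s }, sets, labels)
    }
  }
  labs <- vapply(sets, function(s) s$label, character(1))
  if (anyDuplicated(labs)) {
    stop(sprintf("duplicate assembly labels: %s",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  }
  for (s in sets) {
    if (!identical(unclass(s$params), unclass(params))) {
      stop(sprintf("set '%s' was built with different parameters", s$label))
    }
  }

  dist <- pairwise_distances(sets, distance_fn = distance_fn)
  ord <- nearest_neighbor_order(dist, start_index = start_index)
  sets <- sets[ord$permutation]
  labs <- labs[ord$permutation]

  if (is.null(universe)) universe <- universe_size(params)
  usize <- if (inherits(universe, "kmer_universe")) universe$size else as.numeric(universe)
  umethod <- if (inherits(universe, "kmer_universe")) universe$method else "supplied"
  if (usize <= 0) stop("universe size must be positive")

  codes <- sort(unique(unlist(lapply(sets, function(s) s$codes))))
  n_asm <- length(sets)
  member <- matrix(FALSE, length(codes), n_asm)
  for (j in seq_len(n_asm)) {
    member[match(sets[[j]]$codes, codes), j] <- TRUE
  }
  rows <- lapply(seq_along(codes), function(i) {
    arle_encode(as.integer(member[i, ]), w)
  })

  structure(
    list(params = params, w = w, labels = labs,
         set_sizes = vapply(sets, function(s) length(s$codes), numeric(1)),
         universe_size = usize, universe_method = umethod,
         codes = codes, rows = rows,
         order = list(permutation = ord$permutation,
                      start_index = ord$start_index),
         files = files, cache = new.env(parent = emptyenv())),
    class = "kmer_db"
  )
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf(
    "kmer_db: %d assemblies, %d stored rows, |U| = %.6g (%s)\n  params: k=%d s=%d t=%d mode=%s canonicalize=%s, w=%d\n",
    length(x$labels), length(x$codes), x$universe_size, x$universe_method,
    x$params$k, x$params$s, x$params$t, x$params$subsample_mode,
    x$params$canonicalize, x$w))
  invisible(x)
}

# memoized set-bit decode of one stored row
.row_columns <- function(db, row_index) {
  key <- as.character(row_index)
  cols <- db$cache[[key]]
  if (is.null(cols)) {
    cols <- arle_set_bits(db$rows[[row_index]])
    db$cache[[key]] <- cols
  }
  cols
}

#' Query a k-mer code against the database
#'
#' @param db a `kmer_db`.
#' @param code a k-mer code, canonicalized/filtered consistently with the
#'   database parameters (codes from [extract_kmers()] with `db$params`).
#' @return increasing 1-based column indices (matrix order) of the
#'   assemblies containing the k-mer; empty for absent codes.
#' @export
query_kmer <- function(db, code) {
  stopifnot(inherits(db, "kmer_db"), length(code) == 1L)
  i <- match(code, db$codes)
  if (is.na(i)) return(integer(0))
  .row_columns(db, i)
}

#' Per-assembly match probability
#'
#' The probability that a random universe k-mer lies in assembly `i`'s set:
#' `p_i = |K_i| / |U|`. The binomial null model of [classify_read()] uses
#' these as success probabilities.
#'
#' @param db a `kmer_db`.
#' @param column_index 1-based column index (matrix order).
#' @return probability in (0, 1].
#' @export
match_probability <- function(db, column_index) {
  stopifnot(inherits(db, "kmer_db"))
  sz <- db$set_sizes[column_index]
  if (any(sz == 0)) {
    stop(sprintf("match probability undefined for empty assembly column(s): %s",
                 paste(db$labels[column_index][sz == 0], collapse = ", ")))
  }
  sz / db$universe_size
}

#' Build manifest for a database
#'
#' Diagnostic table with one row per assembly column: label, source file (if
#' known), k-mer set size and match probability.
#'
#' @param db a `kmer_db`.
#' @return data.frame with columns `label`, `file`, `set_size`, `p`.
#' @export
db_manifest <- function(db) {
  stopifnot(inherits(db, "kmer_db"))
  files <- if (is.null(db$files)) NA_character_ else db$files[db$order$permutation]
  data.frame(
    label = db$labels,
    file = files,
    set_size = db$set_sizes,
    p = ifelse(db$set_sizes > 0, db$set_sizes / db$universe_size, NA_real_),
    stringsAsFactors = FALSE
  )
}

## ---- binary serialization -------------------------------------------------

.DB_MAGIC <- c(utf8ToInt("KSCRDB1"), 0L)

.write_u8 <- function(con, x) writeBin(as.integer(x), con, size = 1L)
.write_u16 <- function(con, x) {
  x <- as.numeric(x)
  writeBin(as.integer(ifelse(x >= 2^15, x - 2^16, x)), con, size = 2L,
           endian = "little")
}
.write_u32 <- function(con, x) {
  x <- as.numeric(x)
  writeBin(as.integer(ifelse(x >= 2^31, x - 2^32, x)), con, size = 4L,
           endian = "little")
}
.write_u64 <- function(con, x) {
  x <- as.numeric(x)
  lo <- x %% 2^32
  hi <- x %/% 2^32
  both <- as.numeric(rbind(lo, hi))
  .write_u32(con, both)
}

.read_exact <- function(con, what, n, size, offset_env) {
  v <- readBin(con, what, n = n, size = size, endian = "little")
  if (length(v) != n) {
    stop(sprintf("corrupt database file: truncated at byte offset %d",
                 offset_env$offset + length(v) * size))
  }
  offset_env$offset <- offset_env$offset + n * size
  v
}
.read_u8 <- function(con, n, oe) .read_exact(con, integer(), n, 1L, oe)
.read_u16 <- function(con, n, oe) {
  v <- .read_exact(con, integer(), n, 2L, oe)
  ifelse(v < 0, v + 2^16, v)
}
.read_u32 <- function(con, n, oe) {
  v <- .read_exact(con, integer(), n, 4L, oe)
  ifelse(v < 0, v + 2^32, v)
}
.read_u64 <- function(con, n, oe) {
  v <- .read_u32(con, 2L * n, oe)
  v[seq(1L, 2L * n, by = 2L)] + v[seq(2L, 2L * n, by = 2L)] * 2^32
}

#' Save a database to a binary file
#'
#' Versioned little-endian layout: magic `"KSCRDB1\0"`, version byte,
#' k/s/t/w bytes, flags byte (subsample mode, canonicalization, syncmer test
#' strand), assembly count (u32), `|U|` (float64), universe-method byte,
#' length-prefixed UTF-8 labels in column order, per-column set sizes (u64),
#' row count (u64), a code-sorted row index of (code u64, word offset u64,
#' word count u32), then contiguous u16 word data. [load_database()] is the
#' bit-exact inverse.
#'
#' @param db a `kmer_db` with word width `w <= 16`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "kmer_db"))
  if (db$w > 16L) stop("on-disk format stores u16 words; w must be <= 16")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(.DB_MAGIC), con)
  .write_u8(con, 1L)  # version
  .write_u8(con, c(db$params$k, db$params$s, db$params$t, db$w))
  flags <- (db$params$subsample_mode == "syncmer") +
    2L * db$params$canonicalize +
    4L * (db$params$syncmer_on == "forward")
  .write_u8(con, flags)
  .write_u32(con, length(db$labels))
  writeBin(as.numeric(db$universe_size), con, size = 8L, endian = "little")
  .write_u8(con, match(db$universe_method,
                       c("exact", "montecarlo", "supplied")))
  for (lab in db$labels) {
    raw_lab <- charToRaw(enc2utf8(lab))
    .write_u16(con, length(raw_lab))
    writeBin(raw_lab, con)
  }
  .write_u64(con, db$set_sizes)
  .write_u64(con, length(db$codes))
  counts <- vapply(db$rows, function(r) length(r$words), numeric(1))
  offsets <- cumsum(c(0, counts[-length(counts)]))
  if (length(db$codes)) {
    for (i in seq_along(db$codes)) {
      .write_u64(con, c(db$codes[i], offsets[i]))
      .write_u32(con, counts[i])
    }
    .write_u16(con, unlist(lapply(db$rows, function(r) r$words),
                           use.names = FALSE))
  }
  invisible(path)
}

#' Load a database saved by [save_database()]
#'
#' @param path file produced by [save_database()].
#' @return a `kmer_db` comparing equal to the saved one on all fields.
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop(sprintf("database file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  oe <- new.env(parent = emptyenv())
  oe$offset <- 0
  magic <- readBin(con, raw(), n = 8L)
  if (length(magic) != 8L || !identical(as.integer(magic), .DB_MAGIC)) {
    stop("unsupported format: bad magic bytes (not a kmerscreen database)")
  }
  oe$offset <- 8
  version <- .read_u8(con, 1L, oe)
  if (version != 1L) {
    stop(sprintf("unsupported database format version: %d", version))
  }
  kstw <- .read_u8(con, 4L, oe)
  flags <- .read_u8(con, 1L, oe)
  n_asm <- .read_u32(con, 1L, oe)
  usize <- .read_exact(con, numeric(), 1L, 8L, oe)
  umethod <- c("exact", "montecarlo", "supplied")[.read_u8(con, 1L, oe)]
  labels <- character(n_asm)
  for (i in seq_len(n_asm)) {
    len <- .read_u16(con, 1L, oe)
    raw_lab <- .read_exact(con, raw(), len, 1L, oe)
    labels[i] <- rawToChar(raw_lab)
  }
  set_sizes <- .read_u64(con, n_asm, oe)
  n_rows <- .read_u64(con, 1L, oe)
  codes <- numeric(n_rows)
  offsets <- numeric(n_rows)
  counts <- numeric(n_rows)
  for (i in seq_len(n_rows)) {
    cw <- .read_u64(con, 2L, oe)
    codes[i] <- cw[1L]
    offsets[i] <- cw[2L]
    counts[i] <- .read_u32(con, 1L, oe)
  }
  words <- .read_u16(con, sum(counts), oe)
  w <- kstw[4L]
  params <- syncmer_params(
    k = kstw[1L], s = kstw[2L], t = kstw[3L],
    subsample_mode = if (flags %% 2L == 1L) "syncmer" else "none",
    canonicalize = (flags %/% 2L) %% 2L == 1L,
    syncmer_on = if ((flags %/% 4L) %% 2L == 1L) "forward" else "canonical")
  rows <- lapply(seq_len(n_rows), function(i) {
    structure(
      list(words = as.integer(words[offsets[i] + seq_len(counts[i])]),
           row_length = n_asm, w = w),
      class = "arle_row")
  })
  structure(
    list(params = params, w = w, labels = labels, set_sizes = set_sizes,
         universe_size = usize, universe_method = umethod,
         codes = codes, rows = rows,
         order = list(permutation = seq_len(n_asm), start_index = NA_integer_),
         files = NULL, cache = new.env(parent = emptyenv())),
    class = "kmer_db"
  )
}
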
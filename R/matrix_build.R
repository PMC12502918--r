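# Assembly k-mer sets, pairwise Hamming distances over the implicit bitmap
# matrix, and the greedy nearest-neighbour column ordering that shrinks the
# total run-length-encoding cost.

#' Construct an assembly k-mer set from sequences in memory
#'
#' @param sequences character vector of DNA sequences (e.g. chromosomes and
#'   plasmids of one assembly); all records merge into one set.
#' @param label assembly identifier.
#' @param params a [syncmer_params()] object.
#' @return object of class `kmer_set`: sorted unique codes, label, source
#'   length, params.
#' @export
kmer_set <- function(sequences, label, params = syncmer_params()) {
  stopifnot(inherits(params, "syncmer_params"), length(label) == 1L)
  codes <- unlist(lapply(sequences, extract_kmers, params = params),
                  use.names = FALSE)
  codes <- sort(unique(codes))
  if (length(codes) == 0L) {
    warning(sprintf("assembly '%s' yielded no usable k-mers", label))
  }
  structure(
    list(label = as.character(label), codes = codes,
         source_length = sum(nchar(sequences)), params = params),
    class = "kmer_set"
  )
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set '%s': %d codes from %d bases (k=%d)\n",
              x$label, length(x$codes), x$source_length, x$params$k))
  invisible(x)
}

#' Build an assembly k-mer set from a FASTA file
#'
#' Reads a (possibly gzipped) FASTA file, extracts codes from every record
#' with [extract_kmers()], and returns the deduplicated sorted union. One
#' file is one classification target; multi-record files (chromosomes,
#' plasmids) merge into a single set.
#'
#' @param fasta_path path to a FASTA or FASTA.gz file with at least one
#'   record.
#' @param label assembly identifier; defaults to the file name stem.
#' @param params a [syncmer_params()] object.
#' @return a [kmer_set()] object.
#' @export
build_kmer_set <- function(fasta_path, label = NULL,
                           params = syncmer_params()) {
  if (!file.exists(fasta_path)) {
    stop(sprintf("FASTA file not found: %s", fasta_path))
  }
  recs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) {
      stop(sprintf("failed to read FASTA '%s': %s",
                   fasta_path, conditionMessage(e)))
    })
  if (length(recs) == 0L) stop(sprintf("empty FASTA file: %s", fasta_path))
  if (is.null(label)) {
    label <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(fasta_path),
                 ignore.case = TRUE)
  }
  kmer_set(as.character(recs), label, params)
}

#' Hamming distance between two assembly bitmaps
#'
#' With each k-mer set viewed as a bitmap over the universe, the Hamming
#' distance between two columns is the size of the symmetric difference of
#' the sets: `|x| + |y| - 2 |x intersect y|`.
#'
#' @param x,y [kmer_set()] objects built under identical parameters.
#' @return nonnegative integer distance.
#' @export
hamming_distance <- function(x, y) {
  stopifnot(inherits(x, "kmer_set"), inherits(y, "kmer_set"))
  if (!identical(unclass(x$params), unclass(y$params))) {
    stop("k-mer sets were built with different parameters")
  }
  common <- sum(x$codes %in% y$codes)
  length(x$codes) + length(y$codes) - 2L * common
}

#' Pairwise Hamming distances between assembly k-mer sets
#'
#' @param sets list of [kmer_set()] objects.
#' @param distance_fn optional override taking two `kmer_set`s and returning
#'   a nonnegative number; hook for estimated (e.g. sketch-based) distances.
#' @return symmetric numeric matrix with zero diagonal, labelled by assembly.
#' @export
pairwise_distances <- function(sets, distance_fn = NULL) {
  stopifnot(length(sets) >= 1L)
  if (is.null(distance_fn)) distance_fn <- hamming_distance
  n <- length(sets)
  labels <- vapply(sets, function(s) s$label, character(1))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- tryCatch(distance_fn(sets[[i]], sets[[j]]), error = function(e) {
          stop(sprintf("distance failed for pair (%s, %s): %s",
                       labels[i], labels[j], conditionMessage(e)))
        })
        d[i, j] <- dij
        d[j, i] <- dij
      }
    }
  }
  d
}

#' Greedy nearest-neighbour column ordering
#'
#' Treats each column (assembly bitmap) as a point in Hamming space and
#' builds a travelling-salesperson-style chain: starting from `start_index`,
#' repeatedly append the unvisited column closest to the last appended one.
#' Ties are broken by the smallest column index, so the result is
#' deterministic given the start.
#'
#' @param dist symmetric distance matrix as from [pairwise_distances()].
#' @param start_index 1-based index of the starting column (default 1).
#' @return object of class `column_order`: `permutation` (1-based column
#'   indices) and `start_index`.
#' @export
nearest_neighbor_order <- function(dist, start_index = 1L) {
  n <- nrow(dist)
  stopifnot(is.matrix(dist), n == ncol(dist))
  start_index <- as.integer(start_index)
  if (start_index < 1L || start_index > n) stop("start_index out of range")
  perm <- integer(n)
  perm[1L] <- start_index
  visited <- rep(FALSE, n)
  visited[start_index] <- TRUE
  for (i in seq_len(n - 1L)) {
    last <- perm[i]
    cand <- which(!visited)
    nxt <- cand[which.min(dist[last, cand])]  # which.min takes first = smallest index
    perm[i + 1L] <- nxt
    visited[nxt] <- TRUE
  }
  structure(list(permutation = perm, start_index = start_index),
            class = "column_order")
}

#' @export
print.column_order <- function(x, ...) {
  cat("column_order:", paste(x$permutation, collapse = " "),
      sprintf("(start %d)\n", x$start_index))
  invisible(x)
}

#' Total naive-RLE run count of the ordered bitmap matrix
#'
#' Under naive run-length encoding, each row of the k-mer-by-assembly matrix
#' contributes one baseline run (all-zero rows included) plus one extra run
#' per adjacent bit change along the row. Summed over all rows this equals
#' `universe_rows` plus the sum of Hamming distances between consecutive
#' ordered columns — the objective the nearest-neighbour ordering minimises
#' heuristically.
#'
#' @param sets list of [kmer_set()] objects (the matrix columns).
#' @param order a [nearest_neighbor_order()] result, or NULL for input order.
#' @param universe_rows number of matrix rows (e.g. `4^k` for the full
#'   universe); must be at least the number of distinct codes observed.
#' @return total run count (integer-valued numeric).
#' @export
naive_runs_total <- function(sets, order = NULL, universe_rows) {
  stopifnot(length(sets) >= 1L)
  perm <- if (is.null(order)) seq_along(sets) else order$permutation
  stopifnot(sort(perm) == seq_along(sets))
  distinct <- length(unique(unlist(lapply(sets, function(s) s$codes))))
  if (universe_rows < distinct) {
    stop(sprintf("universe_rows (%d) < distinct codes observed (%d)",
                 universe_rows, distinct))
  }
  total <- universe_rows
  if (length(perm) > 1L) {
    for (i in seq_len(length(perm) - 1L)) {
      total <- total + hamming_distance(sets[[perm[i]]], sets[[perm[i + 1L]]])
    }
  }
  total
}
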
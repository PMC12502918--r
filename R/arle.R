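# Naive and adaptive run-length encoding of bitmap rows.
#
# A w-bit word is either a compressed run (up to 2^(w-2)-1 identical bits:
# one flag bit, one value bit, w-2 length bits) or a raw block storing up to
# w-1 bits verbatim (one flag bit, w-1 payload bits). The encoder scans left
# to right: a run shorter than w is cheaper stored raw, so it emits a raw
# block covering the next min(w-1, remaining) bits; otherwise it emits one
# compressed word. Word layout (for serialization): bit w-1 set = compressed,
# bit w-2 = run bit value, low w-2 bits = run length; raw words carry the
# first covered column in the highest payload bit (bit w-2). Trailing partial
# raw blocks are resolved by the decoder tracking remaining row length.

#' Naive run-length encoding of a bit vector
#'
#' Decomposes a bitmap into maximal runs of identical bits. The run count is
#' `1 +` the number of adjacent bit changes (0 for an empty bitmap).
#'
#' @param bitmap integer/logical vector of 0s and 1s.
#' @return data.frame with columns `bit` and `length`, one row per run.
#' @export
nrle_encode <- function(bitmap) {
  bitmap <- as.integer(bitmap)
  if (length(bitmap) == 0L) {
    return(data.frame(bit = integer(0), length = integer(0)))
  }
  if (any(bitmap != 0L & bitmap != 1L)) stop("bitmap must contain only 0/1")
  r <- rle(bitmap)
  data.frame(bit = r$values, length = r$lengths)
}

.arle_validate_w <- function(w) {
  w <- as.integer(w)
  if (w < 4L || w > 30L) stop("word width w must be in [4, 30]")
  w
}

#' Adaptive run-length encoding of a bit vector
#'
#' Greedy left-to-right encoding: scan the run starting at the current
#' position, capped at `2^(w-2) - 1` bits. If the (capped) run is shorter
#' than `w`, emit a raw word covering the next `min(w - 1, remaining)` bits
#' verbatim; otherwise emit one compressed word for the run. The word count
#' never exceeds the naive run count of the same bitmap (runs beyond the cap
#' counting as separate runs).
#'
#' @param bitmap integer/logical vector of 0s and 1s.
#' @param w word width in bits (default 16).
#' @return object of class `arle_row`: integer vector `words` of w-bit word
#'   values, `row_length`, `w`.
#' @seealso [arle_decode()], [arle_set_bits()]
#' @export
arle_encode <- function(bitmap, w = 16L) {
  w <- .arle_validate_w(w)
  bitmap <- as.integer(bitmap)
  n <- length(bitmap)
  if (n > 0L && any(bitmap != 0L & bitmap != 1L)) {
    stop("bitmap must contain only 0/1")
  }
  cap <- 2L^(w - 2L) - 1L
  words <- integer(0)
  if (n > 0L) {
    r <- rle(bitmap)
    run_end <- cumsum(r$lengths)
    ridx <- 1L
    pos <- 1L
    nw <- 0L
    words <- integer(max(2L, length(r$lengths)))
    while (pos <= n) {
      while (run_end[ridx] < pos) ridx <- ridx + 1L
      run_len <- min(run_end[ridx] - pos + 1L, cap)
      nw <- nw + 1L
      if (nw > length(words)) words <- c(words, integer(length(words)))
      if (run_len >= w) {
        bit <- r$values[ridx]
        words[nw] <- as.integer(2^(w - 1L) + bit * 2^(w - 2L) + run_len)
        pos <- pos + run_len
      } else {
        len <- min(w - 1L, n - pos + 1L)
        payload <- bitmap[pos:(pos + len - 1L)]
        words[nw] <- as.integer(sum(payload * 2^((w - 2L):(w - 1L - len))))
        pos <- pos + len
      }
    }
    words <- words[seq_len(nw)]
  }
  structure(list(words = words, row_length = n, w = w), class = "arle_row")
}

#' @export
print.arle_row <- function(x, ...) {
  cat(sprintf("arle_row: %d bits in %d word(s) of %d bits\n",
              x$row_length, length(x$words), x$w))
  invisible(x)
}

# decode one word; returns list(bits) given bits remaining in the row
.arle_word_bits <- function(word, w, remaining) {
  if (word >= 2L^(w - 1L)) {
    body <- word - 2L^(w - 1L)
    bit <- body %/% 2L^(w - 2L)
    len <- body %% 2L^(w - 2L)
    if (len < 1L || len > remaining) {
      stop("corrupt ARLE stream: run length inconsistent with row length")
    }
    rep(as.integer(bit), len)
  } else {
    len <- min(w - 1L, remaining)
    if (len < 1L) stop("corrupt ARLE stream: raw word beyond row end")
    as.integer((word %/% 2^((w - 2L):(w - 1L - len))) %% 2)
  }
}

#' Decode an adaptive-RLE row back to its bit vector
#'
#' Exact inverse of [arle_encode()]; a malformed word stream whose lengths do
#' not sum to `row_length` raises a corruption error.
#'
#' @param row an `arle_row` object.
#' @return integer vector of 0s and 1s of length `row_length`.
#' @export
arle_decode <- function(row) {
  stopifnot(inherits(row, "arle_row"))
  out <- integer(row$row_length)
  pos <- 1L
  for (word in row$words) {
    bits <- .arle_word_bits(word, row$w, row$row_length - pos + 1L)
    out[pos:(pos + length(bits) - 1L)] <- bits
    pos <- pos + length(bits)
  }
  if (pos != row$row_length + 1L) {
    stop("corrupt ARLE stream: word lengths do not sum to row length")
  }
  out
}

#' Positions of set bits in an adaptive-RLE row
#'
#' Yields the 1-based column indices of set bits in ascending order, doing
#' work proportional to the word count plus the number of set bits: zero
#' runs are skipped in O(1) without inspecting their bits.
#'
#' @param row an `arle_row` object.
#' @return increasing integer vector of set-bit positions.
#' @export
arle_set_bits <- function(row) {
  stopifnot(inherits(row, "arle_row"))
  w <- row$w
  out <- vector("list", length(row$words))
  pos <- 1L
  for (i in seq_along(row$words)) {
    word <- row$words[i]
    if (word >= 2L^(w - 1L)) {
      body <- word - 2L^(w - 1L)
      bit <- body %/% 2L^(w - 2L)
      len <- body %% 2L^(w - 2L)
      if (bit == 1L) out[[i]] <- pos:(pos + len - 1L)
      pos <- pos + len
    } else {
      len <- min(w - 1L, row$row_length - pos + 1L)
      bits <- (word %/% 2L^((w - 2L):(w - 1L - len))) %% 2L
      hit <- which(bits == 1L)
      if (length(hit)) out[[i]] <- pos + hit - 1L
      pos <- pos + len
    }
  }
  if (pos != row$row_length + 1L) {
    stop("corrupt ARLE stream: word lengths do not sum to row length")
  }
  as.integer(unlist(out, use.names = FALSE))
}

#' Total adaptive-RLE word count over a collection of rows
#'
#' Sums [arle_encode()] word counts; by construction never exceeds the total
#' naive run count of the same rows, where runs longer than the
#' `2^(w-2) - 1`-bit cap count as separate runs.
#'
#' @param bitmaps list of bit vectors.
#' @param w word width in bits.
#' @return total word count.
#' @export
adaptive_blocks_count <- function(bitmaps, w = 16L) {
  sum(vapply(bitmaps, function(b) length(arle_encode(b, w)$words), numeric(1)))
}
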
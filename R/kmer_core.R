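# k-mer integer encoding, canonicalization, and open-syncmer extraction.
#
# k-mers are encoded as base-4 integers under A=0, C=1, G=2, T=3 with the
# first base most significant, so integer order coincides with lexicographic
# order. Codes are held in doubles: k is capped at 31, hence codes stay well
# below 2^53 and are exactly representable.

.KS_BASES <- c("A", "C", "G", "T")

.ks_env <- new.env(parent = emptyenv())

.base_lut <- function() {
  lut <- .ks_env$base_lut
  if (is.null(lut)) {
    lut <- rep(NA_real_, 128L)
    lut[utf8ToInt("A")] <- 0; lut[utf8ToInt("a")] <- 0
    lut[utf8ToInt("C")] <- 1; lut[utf8ToInt("c")] <- 1
    lut[utf8ToInt("G")] <- 2; lut[utf8ToInt("g")] <- 2
    lut[utf8ToInt("T")] <- 3; lut[utf8ToInt("t")] <- 3
    .ks_env$base_lut <- lut
  }
  lut
}

# DNA string -> numeric base codes (0..3), NA for anything outside ACGT.
.seq_to_bases <- function(sequence) {
  if (nchar(sequence) == 0L) return(numeric(0))
  ints <- utf8ToInt(sequence)
  ints[ints > 128L | ints < 1L] <- 1L  # out-of-range chars map to NA slot
  .base_lut()[ints]
}

#' Syncmer extraction parameters
#'
#' Bundles the k-mer length `k`, the s-mer length `s`, the required
#' 0-indexed offset `t` of the minimal s-mer, the subsampling mode, and
#' whether windows are canonicalized (collapsed with their reverse
#' complement). The defaults (`k = 15`, `s = 9`, `t = 2`) retain roughly 12%
#' of windows as canonical open syncmers while remaining robust to the
#' substitution errors typical of nanopore reads.
#'
#' @param k k-mer length in bases; `1 <= s < k <= 31` (codes must fit one
#'   64-bit word).
#' @param s s-mer length in bases.
#' @param t required 0-indexed start position of the minimal s-mer,
#'   `0 <= t <= k - s`.
#' @param subsample_mode `"syncmer"` keeps only open-syncmer windows;
#'   `"none"` keeps every window.
#' @param canonicalize collapse each window with its reverse complement
#'   (lexicographic minimum) before any syncmer test.
#' @param syncmer_on which strand form the syncmer test inspects:
#'   `"canonical"` (default) tests the canonical form of the window,
#'   `"forward"` tests the window as read.
#' @return An object of class `syncmer_params`.
#' @export
syncmer_params <- function(k = 15L, s = 9L, t = 2L,
                           subsample_mode = c("syncmer", "none"),
                           canonicalize = TRUE,
                           syncmer_on = c("canonical", "forward")) {
  subsample_mode <- match.arg(subsample_mode)
  syncmer_on <- match.arg(syncmer_on)
  k <- as.integer(k); s <- as.integer(s); t <- as.integer(t)
  if (k < 1L || k > 31L) stop("k must be in [1, 31]")
  if (subsample_mode == "syncmer") {
    if (s < 1L || s >= k) stop("s must satisfy 1 <= s < k")
    if (t < 0L || t > k - s) stop("t must satisfy 0 <= t <= k - s")
  }
  structure(
    list(k = k, s = s, t = t, subsample_mode = subsample_mode,
         canonicalize = isTRUE(canonicalize), syncmer_on = syncmer_on),
    class = "syncmer_params"
  )
}

#' @export
print.syncmer_params <- function(x, ...) {
  cat(sprintf(
    "syncmer_params: k=%d s=%d t=%d mode=%s canonicalize=%s (test on %s)\n",
    x$k, x$s, x$t, x$subsample_mode, x$canonicalize, x$syncmer_on))
  invisible(x)
}

#' Encode a k-mer as an integer code
#'
#' Maps a DNA string of length `k` to its base-4 value under A=0, C=1, G=2,
#' T=3, first base most significant. The mapping is a bijection between
#' k-mers and `[0, 4^k)`; [decode_kmer()] inverts it.
#'
#' @param seq character vector of DNA strings, all the same length
#'   (case-insensitive, ACGT only).
#' @return numeric vector of codes in `[0, 4^k)`.
#' @seealso [decode_kmer()], [canonical_code()]
#' @examples
#' encode_kmer("CT")   # 7
#' decode_kmer(7, 2)   # "CT"
#' @export
encode_kmer <- function(seq) {
  if (length(seq) == 0L) return(numeric(0))
  k <- unique(nchar(seq))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  if (k < 1L || k > 31L) stop("k must be in [1, 31]")
  vapply(seq, function(sq) {
    b <- .seq_to_bases(sq)
    if (anyNA(b)) {
      stop(sprintf("invalid base '%s' at position %d in '%s'",
                   substr(sq, which(is.na(b))[1L], which(is.na(b))[1L]),
                   which(is.na(b))[1L], sq))
    }
    sum(b * 4^((k - 1):0))
  }, numeric(1), USE.NAMES = FALSE)
}

# codes -> n x k base matrix (0..3)
.codes_to_bases <- function(codes, k) {
  B <- matrix(0, length(codes), k)
  rest <- codes
  for (j in k:1) {
    B[, j] <- rest %% 4
    rest <- rest %/% 4
  }
  B
}

#' Decode an integer k-mer code back to a DNA string
#'
#' @param code numeric vector of codes in `[0, 4^k)`.
#' @param k k-mer length.
#' @return character vector of k-mers.
#' @export
decode_kmer <- function(code, k) {
  k <- as.integer(k)
  if (k < 1L || k > 31L) stop("k must be in [1, 31]")
  if (length(code) == 0L) return(character(0))
  if (any(code < 0 | code >= 4^k | code != floor(code))) {
    stop(sprintf("code out of range [0, 4^%d)", k))
  }
  B <- .codes_to_bases(code, k)
  apply(B, 1L, function(row) paste(.KS_BASES[row + 1], collapse = ""))
}

#' Reverse complement of a k-mer code
#'
#' Equals `encode_kmer()` of the reverse-complement string; an involution.
#'
#' @inheritParams decode_kmer
#' @return numeric vector of codes.
#' @export
revcomp_code <- function(code, k) {
  k <- as.integer(k)
  if (any(code < 0 | code >= 4^k)) stop(sprintf("code out of range [0, 4^%d)", k))
  if (length(code) == 0L) return(numeric(0))
  B <- .codes_to_bases(code, k)
  Brc <- 3 - B[, k:1, drop = FALSE]
  as.numeric(Brc %*% 4^((k - 1):0))
}

#' Canonical form of a k-mer code
#'
#' The minimum of a code and its reverse complement. Because integer order
#' equals lexicographic order under the A<C<G<T encoding, this is the usual
#' canonical k-mer. Idempotent.
#'
#' @inheritParams decode_kmer
#' @return numeric vector of canonical codes.
#' @export
canonical_code <- function(code, k) {
  pmin(code, revcomp_code(code, k))
}

# Open-syncmer test on base matrices: TRUE where the minimal s-mer of the
# row, ties broken by leftmost occurrence, first occurs at offset t.
.sync_flags <- function(B, s, t) {
  k <- ncol(B)
  nw <- k - s + 1L
  pw <- 4^((s - 1):0)
  S <- matrix(0, nrow(B), nw)
  for (q in seq_len(nw)) {
    S[, q] <- B[, q:(q + s - 1L), drop = FALSE] %*% pw
  }
  m <- S[, 1L]
  if (nw > 1L) for (q in 2:nw) m <- pmin(m, S[, q])
  first <- max.col(S == m, ties.method = "first") - 1L
  first == t
}

#' Open-syncmer test
#'
#' A k-mer is an open syncmer when, among its `k - s + 1` s-mer windows, the
#' minimal s-mer (ties broken by leftmost occurrence) first occurs exactly at
#' 0-indexed offset `t`. The test is applied to the code as given; see
#' [extract_kmers()] for how canonicalization and the test compose during
#' extraction.
#'
#' @param code numeric vector of k-mer codes.
#' @param params a [syncmer_params()] object.
#' @return logical vector.
#' @export
is_open_syncmer <- function(code, params) {
  stopifnot(inherits(params, "syncmer_params"))
  if (length(code) == 0L) return(logical(0))
  if (any(code < 0 | code >= 4^params$k)) stop("code out of range")
  B <- .codes_to_bases(code, params$k)
  .sync_flags(B, params$s, params$t)
}

# Core window engine: base vector (0..3 / NA) -> emitted window codes, in
# order, with multiplicity. Windows containing NA bases are skipped.
.window_codes <- function(b, params) {
  k <- params$k
  n <- length(b) - k + 1L
  if (n < 1L) return(numeric(0))
  E <- matrix(0, n, k)
  for (j in seq_len(k)) E[, j] <- b[j:(j + n - 1L)]
  keep <- rowSums(is.na(E)) == 0L
  E <- E[keep, , drop = FALSE]
  if (nrow(E) == 0L) return(numeric(0))
  pwk <- 4^((k - 1):0)
  fwd <- as.numeric(E %*% pwk)
  out_codes <- fwd
  Etest <- E
  if (params$canonicalize) {
    Erc <- 3 - E[, k:1, drop = FALSE]
    rc <- as.numeric(Erc %*% pwk)
    use_rc <- rc < fwd
    out_codes <- pmin(fwd, rc)
    if (params$subsample_mode == "syncmer" && params$syncmer_on == "canonical") {
      Etest <- E
      if (any(use_rc)) Etest[use_rc, ] <- Erc[use_rc, , drop = FALSE]
    }
  }
  if (params$subsample_mode == "syncmer") {
    ok <- .sync_flags(Etest, params$s, params$t)
    out_codes <- out_codes[ok]
  }
  out_codes
}

#' Extract (canonical) syncmer codes from a DNA sequence
#'
#' Slides a k-window over the sequence; windows containing non-ACGT
#' characters are skipped. When `canonicalize = TRUE` each window is replaced
#' by its canonical form; when `subsample_mode = "syncmer"` a window is kept
#' only if its form selected by `syncmer_on` passes the open-syncmer test.
#' Output preserves window order and multiplicity; reference-set builders
#' deduplicate downstream.
#'
#' @param sequence a DNA string (character scalar); lowercase and ambiguity
#'   codes are tolerated (ambiguous windows are dropped).
#' @param params a [syncmer_params()] object.
#' @return numeric vector of emitted window codes (possibly empty).
#' @export
extract_kmers <- function(sequence, params = syncmer_params()) {
  stopifnot(inherits(params, "syncmer_params"))
  if (is.na(sequence) || nchar(sequence) < params$k) return(numeric(0))
  L <- nchar(sequence)
  chunk <- 262144L
  if (L <= chunk) return(.window_codes(.seq_to_bases(sequence), params))
  # long sequences: overlap chunks by k-1 so no window is lost
  starts <- seq(1L, L, by = chunk - params$k + 1L)
  starts <- starts[starts + params$k - 1L <= L]
  out <- lapply(starts, function(st) {
    en <- min(st + chunk - 1L, L)
    .window_codes(.seq_to_bases(substr(sequence, st, en)), params)
  })
  unlist(out, use.names = FALSE)
}

# universe membership flags for a base matrix under params
.universe_flags <- function(B, params) {
  k <- params$k
  pwk <- 4^((k - 1):0)
  keep <- rep(TRUE, nrow(B))
  if (params$canonicalize) {
    fwd <- as.numeric(B %*% pwk)
    rc <- as.numeric((3 - B[, k:1, drop = FALSE]) %*% pwk)
    keep <- fwd <= rc  # code is its own canonical form
  }
  if (params$subsample_mode == "syncmer") {
    keep <- keep & .sync_flags(B, params$s, params$t)
  }
  keep
}

#' Size of the queryable k-mer universe
#'
#' The universe U is the set of codes that can ever be stored or queried
#' under the chosen canonicalization and subsampling rules: canonical codes
#' (fixed points of [canonical_code()]) that pass the open-syncmer test,
#' according to `params`. `|U|` is the denominator of the per-assembly match
#' probability `p_i = |K_i| / |U|`.
#'
#' The exact method enumerates all `4^k` codes and is refused above
#' `max_exact_k`; the Monte-Carlo method estimates `|U|` as `4^k` times the
#' fraction of uniformly sampled codes in U, deterministically for a fixed
#' seed. Results are cached per parameter set within the session.
#'
#' @param params a [syncmer_params()] object.
#' @param method `"auto"` picks exact for `k <= max_exact_k`, else
#'   Monte-Carlo.
#' @param samples Monte-Carlo sample count (minimum 1e5).
#' @param seed RNG seed for the Monte-Carlo estimate.
#' @param max_exact_k largest k for which exhaustive enumeration is allowed.
#' @return a list of class `kmer_universe` with fields `params`, `size`,
#'   `method`, and (for Monte-Carlo) `samples` and `seed`.
#' @export
universe_size <- function(params = syncmer_params(),
                          method = c("auto", "exact", "montecarlo"),
                          samples = 1e7, seed = 1L, max_exact_k = 10L) {
  stopifnot(inherits(params, "syncmer_params"))
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (params$k <= max_exact_k) "exact" else "montecarlo"
  }
  key <- paste(params$k, params$s, params$t, params$subsample_mode,
               params$canonicalize, params$syncmer_on, method,
               if (method == "montecarlo") paste(samples, seed) else "",
               sep = "|")
  cache <- .ks_env$universe_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .ks_env$universe_cache <- cache
  }
  if (!is.null(cache[[key]])) return(cache[[key]])

  k <- params$k
  if (method == "exact") {
    if (k > max_exact_k) {
      stop(sprintf(
        "exact enumeration refused for k=%d > %d; use method='montecarlo'",
        k, max_exact_k))
    }
    total <- 0
    all_codes <- 0:(4^k - 1)
    for (chunk in split(all_codes, ceiling(seq_along(all_codes) / 2^20))) {
      B <- .codes_to_bases(chunk, k)
      total <- total + sum(.universe_flags(B, params))
    }
    res <- structure(list(params = params, size = total, method = "exact"),
                     class = "kmer_universe")
  } else {
    if (samples < 1e5) stop("montecarlo requires samples >= 1e5")
    hits <- 0
    done <- 0
    withr::with_seed(seed, {
      while (done < samples) {
        m <- min(1e6, samples - done)
        B <- matrix(sample(0:3, m * k, replace = TRUE), m, k)
        hits <- hits + sum(.universe_flags(B, params))
        done <- done + m
      }
    })
    res <- structure(
      list(params = params, size = 4^k * hits / samples,
           method = "montecarlo", samples = samples, seed = seed),
      class = "kmer_universe")
  }
  cache[[key]] <- res
  res
}

#' @export
print.kmer_universe <- function(x, ...) {
  cat(sprintf("kmer_universe: |U| = %.6g (k=%d, %s)\n",
              x$size, x$params$k, x$method))
  invisible(x)
}
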
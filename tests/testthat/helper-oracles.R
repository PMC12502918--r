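# Shared fixtures and independent oracles used across the test files.

# Six-assembly worked example: 7 bp assemblies, 2-mers, no subsampling,
# no canonicalization.
example_sequences <- function() {
  c(a1 = "AATCTAA", a2 = "TAGACAT", a3 = "GGACGCT",
    a4 = "CATAACT", a5 = "CTCTAGA", a6 = "CCGCTGG")
}

example_params <- function() {
  syncmer_params(k = 2, subsample_mode = "none", canonicalize = FALSE)
}

example_sets <- function() {
  seqs <- example_sequences()
  unname(Map(function(s, l) kmer_set(s, l, example_params()),
             seqs, names(seqs)))
}

# string-level oracle: all k-length windows of a sequence (ACGT only kept)
oracle_windows <- function(sequence, k) {
  if (nchar(sequence) < k) return(character(0))
  wins <- substring(sequence, 1:(nchar(sequence) - k + 1),
                    k:nchar(sequence))
  wins[grepl("^[ACGT]+$", wins)]
}

# string-level reverse complement
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# string-level open-syncmer test: minimal s-mer (leftmost tie) at offset t
oracle_is_syncmer <- function(kmer, s, t) {
  k <- nchar(kmer)
  smers <- substring(kmer, 1:(k - s + 1), s:k)
  (which(smers == min(smers))[1] - 1) == t
}

# positional base-4 value of a DNA string (independent of encode_kmer)
oracle_encode <- function(x) {
  vals <- c(A = 0, C = 1, G = 2, T = 3)
  sum(vals[strsplit(x, "")[[1]]] * 4^((nchar(x) - 1):0))
}

# brute-force naive-run count of the materialized membership matrix
# (an all-zero row is a single run)
oracle_matrix_runs <- function(sets, perm, universe_rows) {
  codes <- 0:(universe_rows - 1)
  M <- vapply(sets[perm], function(s) codes %in% s$codes,
              logical(universe_rows))
  sum(apply(M, 1, function(row) length(rle(as.integer(row))$lengths)))
}

# naive run count with runs longer than the w-bit cap counted as separate
# runs (the bound adaptive encoding is guaranteed not to exceed)
nrle_capped_runs <- function(bitmap, w) {
  cap <- 2^(w - 2) - 1
  r <- nrle_encode(bitmap)
  sum(ceiling(r$length / cap))
}

# random 0/1 vector with given density
random_bitmap <- function(len, density) {
  as.integer(stats::runif(len) < density)
}

# exact rational binomial upper tail, evaluated by Python's Fraction
# arithmetic; returns a data.frame(n, p10, x, value) for the full grid
# n in ns, p in {0.1..0.9}, x in 0..n
python_binom_grid <- function(ns) {
  py <- Sys.which("python")
  script <- paste(
    "from fractions import Fraction",
    "from math import comb",
    sprintf("ns = [%s]", paste(ns, collapse = ",")),
    "for n in ns:",
    "    for a in range(1, 10):",
    "        p = Fraction(a, 10)",
    "        for x in range(0, n + 1):",
    "            v = sum(comb(n, j) * p**j * (1 - p)**(n - j)",
    "                    for j in range(x, n + 1))",
    "            print(n, a, x, repr(float(v)))",
    sep = "\n")
  out <- system2(py, args = "-", input = script, stdout = TRUE)
  con <- textConnection(out)
  on.exit(close(con))
  utils::read.table(con, col.names = c("n", "p10", "x", "value"))
}
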
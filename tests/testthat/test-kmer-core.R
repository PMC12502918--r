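test_that("encode/decode follow the base-4 bijection", {
  expect_equal(encode_kmer("AA"), 0)
  expect_equal(encode_kmer("TT"), 15)
  expect_equal(encode_kmer("CT"), oracle_encode("CT"))
  expect_equal(encode_kmer("CT"), 7)
  expect_equal(decode_kmer(0, 2), "AA")
  expect_equal(decode_kmer(7, 2), "CT")
  expect_equal(decode_kmer(8, 2), "GA")
  expect_equal(encode_kmer("acgt"), encode_kmer("ACGT"))
  expect_error(encode_kmer("ANGT"), "position 2")
  expect_error(decode_kmer(16, 2), "out of range")
})

test_that("encode and decode are mutually inverse over the whole code space", {
  for (k in c(2, 5)) {
    codes <- 0:(4^k - 1)
    strs <- decode_kmer(codes, k)
    expect_equal(encode_kmer(strs), codes)
    expect_equal(length(unique(strs)), 4^k)
  }
})

test_that("reverse complement codes match the string-level oracle", {
  expect_equal(revcomp_code(encode_kmer("AA"), 2), encode_kmer("TT"))
  expect_equal(revcomp_code(encode_kmer("AT"), 2), encode_kmer("AT"))
  expect_equal(revcomp_code(encode_kmer("ACG"), 3), encode_kmer("CGT"))
  for (k in c(3, 4)) {
    codes <- 0:(4^k - 1)
    via_strings <- encode_kmer(vapply(decode_kmer(codes, k),
                                      oracle_revcomp, character(1)))
    expect_equal(revcomp_code(codes, k), via_strings)
    # involution
    expect_equal(revcomp_code(revcomp_code(codes, k), k), codes)
  }
})

test_that("canonical codes are idempotent, strand-invariant, and count correctly", {
  expect_equal(canonical_code(encode_kmer("TT"), 2), encode_kmer("AA"))
  expect_equal(canonical_code(encode_kmer("ACG"), 3), encode_kmer("ACG"))
  # all 16 2-mers collapse to 10 canonical values
  expect_equal(length(unique(canonical_code(0:15, 2))), 10)
  for (k in c(3, 5)) {
    codes <- 0:(4^k - 1)
    canon <- canonical_code(codes, k)
    expect_equal(canonical_code(canon, k), canon)
    expect_equal(canonical_code(revcomp_code(codes, k), k), canon)
    # odd k: no palindromes, exactly half the codes are canonical
    expect_false(any(codes == revcomp_code(codes, k) & k %% 2 == 1))
    expect_equal(sum(canon == codes), 4^k / 2)
  }
})

test_that("open-syncmer test honours the leftmost-minimum tie rule", {
  p531 <- syncmer_params(k = 5, s = 3, t = 1)
  expect_true(is_open_syncmer(encode_kmer("TAAAT"), p531))
  expect_false(is_open_syncmer(encode_kmer("AAATT"), p531))
  # min s-mer AAA occurs at 0 and 1; first occurrence 0 != t
  expect_false(is_open_syncmer(encode_kmer("AAAAT"), p531))
  # exhaustive agreement with the string-level oracle
  codes <- 0:(4^5 - 1)
  expected <- vapply(decode_kmer(codes, 5), oracle_is_syncmer, logical(1),
                     s = 3, t = 1)
  expect_equal(is_open_syncmer(codes, p531), unname(expected))
})

test_that("extract_kmers slides windows, skips ambiguity, preserves multiplicity", {
  p <- example_params()
  expect_equal(extract_kmers("AATCTAA", p),
               encode_kmer(c("AA", "AT", "TC", "CT", "TA", "AA")))
  expect_equal(extract_kmers("", p), numeric(0))
  expect_equal(extract_kmers("A", p), numeric(0))
  expect_equal(extract_kmers("AANCT", p), encode_kmer(c("AA", "CT")))
  # canonicalized windows match per-window canonical_code
  pc <- syncmer_params(k = 3, subsample_mode = "none", canonicalize = TRUE)
  seq <- random_genome(200, seed = 7)
  wins <- oracle_windows(seq, 3)
  expect_equal(extract_kmers(seq, pc),
               canonical_code(encode_kmer(wins), 3))
})

test_that("syncmer extraction equals the per-window scalar test", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
      for (canon in c(TRUE, FALSE)) {
        p <- syncmer_params(k = 7, s = 3, t = 1, canonicalize = canon)
        wins <- encode_kmer(oracle_windows(seq, 7))
        test_codes <- if (canon) canonical_code(wins, 7) else wins
        keep <- is_open_syncmer(test_codes, p)
        expect_equal(extract_kmers(seq, p), test_codes[keep])
      }
    }
  })
})

test_that("forward-strand syncmer testing is available as the non-default switch", {
  p_fwd <- syncmer_params(k = 7, s = 3, t = 1, syncmer_on = "forward")
  seq <- random_genome(500, seed = 3)
  wins <- encode_kmer(oracle_windows(seq, 7))
  keep <- is_open_syncmer(wins, p_fwd)
  expect_equal(extract_kmers(seq, p_fwd), canonical_code(wins[keep], 7))
})

test_that("extraction is reverse-complement invariant as a multiset when canonicalized", {
  p <- syncmer_params(k = 5, subsample_mode = "none", canonicalize = TRUE)
  seq <- random_genome(400, seed = 5)
  fwd <- extract_kmers(seq, p)
  rev <- extract_kmers(oracle_revcomp(seq), p)
  expect_equal(sort(fwd), sort(rev))
})

test_that("syncmer density on random sequence is about 1/(k-s+1) without canonicalization", {
  p <- syncmer_params(k = 15, s = 9, t = 2, canonicalize = FALSE,
                      syncmer_on = "forward")
  seq <- random_genome(2e5, seed = 9)
  n_windows <- nchar(seq) - p$k + 1
  frac <- length(extract_kmers(seq, p)) / n_windows
  expect_lt(abs(frac - 1 / (p$k - p$s + 1)), 0.01)
})

test_that("universe size: exact enumeration and Monte-Carlo agree", {
  u_full <- universe_size(example_params(), method = "exact")
  expect_equal(u_full$size, 16)
  # exact count matches brute-force enumeration of all 5-mers
  p530 <- syncmer_params(k = 5, s = 3, t = 0, canonicalize = FALSE,
                         syncmer_on = "forward")
  brute <- sum(vapply(decode_kmer(0:(4^5 - 1), 5), oracle_is_syncmer,
                      logical(1), s = 3, t = 0))
  expect_equal(universe_size(p530, method = "exact")$size, brute)
  # Monte-Carlo is seeded, reproducible, and near the exact count
  mc1 <- universe_size(p530, method = "montecarlo", samples = 2e5, seed = 4)
  mc2 <- universe_size(p530, method = "montecarlo", samples = 2e5, seed = 4)
  expect_identical(mc1$size, mc2$size)
  expect_lt(abs(mc1$size - brute) / brute, 0.05)
  expect_error(universe_size(syncmer_params(k = 15), method = "exact"),
               "montecarlo")
  expect_error(universe_size(p530, method = "montecarlo", samples = 10),
               ">= 1e5")
})

test_that("canonical universe size for odd k without subsampling is half the code space", {
  p <- syncmer_params(k = 5, subsample_mode = "none", canonicalize = TRUE)
  expect_equal(universe_size(p, method = "exact")$size, 4^5 / 2)
})
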
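test_that("binomial upper tail handles the boundary cases", {
  expect_equal(binom_sf(5, 0.7, 0), 1)
  expect_equal(binom_sf(1, 0.3, 1), 0.3)
  expect_equal(binom_sf(2, 0.5, 1), 0.75)
  expect_equal(binom_sf(10, 0.2, 11), 0)
  expect_error(binom_sf(5, 1.2, 1), "domain")
  expect_error(binom_sf(5, 0.5, 7), "x out of")
  # deep tails stay representable
  expect_gt(binom_sf(100, 1e-4, 70), 0)
  expect_lt(binom_sf(100, 1e-4, 70), 1e-250)
})

test_that("binomial upper tail matches exact rational summation to 12 digits", {
  grid <- python_binom_grid(1:30)
  got <- binom_sf(grid$n, grid$p10 / 10, grid$x)
  rel <- ifelse(grid$value == 0, abs(got),
                abs(got - grid$value) / pmax(abs(grid$value), 1e-300))
  expect_lt(max(rel), 1e-12)
})

test_that("P-value tables equal direct evaluation, with degenerate p handled", {
  db <- build_database(example_sets(), params = example_params(),
                       universe = 16)
  tables <- build_pvalue_tables(db, classify_options(n_fixed = 20))
  for (i in seq_along(db$labels)) {
    expect_equal(tables$table[, i],
                 binom_sf(20, db$set_sizes[i] / 16, 0:20))
  }
  expect_equal(tables$table[1, ], setNames(rep(1, 6), db$labels))
  expect_true(all(diff(tables$table[, 1]) <= 0))  # nonincreasing in x
  expect_equal(binom_sf(20, 0, 0:20), c(1, rep(0, 20)))
  expect_equal(binom_sf(20, 1, 0:20), rep(1, 21))
  # empty column: excluded with warning, never matchable
  db_bad <- db
  db_bad$set_sizes[3] <- 0
  expect_warning(tb <- build_pvalue_tables(db_bad), "empty")
  expect_true(all(is.na(tb$table[, 3])))
})

test_that("match counts rescale to the fixed trial count", {
  expect_equal(scale_matches(50, 200, 100), 25)
  # fewer trials than n_fixed: no scaling
  expect_equal(scale_matches(21, 21, 100), 21)
  expect_equal(scale_matches(0, 150, 100), 0)
  expect_equal(scale_matches(c(10, 99), 150, 100), c(6, 66))
  expect_error(scale_matches(1, 0, 100), "no k-mer trials")
  expect_error(scale_matches(7, 5, 100), "x must be")
})

# a small seeded two-genome database used across classification tests;
# built from FASTA paths so the manifest records genome file locations
small_db <- function() {
  community <- mock_community(2, 20000, seed = 71)
  build_database(community$path, params = syncmer_params(),
                 universe = universe_size(syncmer_params(),
                                          method = "montecarlo",
                                          samples = 1e6, seed = 1))
}

test_that("an exact substring classifies to its source genome", {
  db <- small_db()
  genome <- as.character(Biostrings::readDNAStringSet(
    db_manifest(db)$file[which(db$labels == "g000")]))[[1]]
  tables <- build_pvalue_tables(db)
  read <- substr(genome, 5001, 7000)
  res <- classify_read(db, tables, "r1", read)
  expect_equal(res$status, "classified")
  expect_equal(res$label, "g000")
  expect_lt(res$p_value, 1e-12)
  expect_equal(res$n, length(extract_kmers(read, db$params)))
})

test_that("degenerate reads come back unclassified", {
  db <- small_db()
  tables <- build_pvalue_tables(db)
  short <- classify_read(db, tables, "short", strrep("A", 14))
  expect_equal(short$status, "unclassified")
  expect_equal(short$n, 0)
  nohit <- classify_read(db, tables, "nohit", random_genome(500, seed = 99))
  expect_equal(nohit$status, "unclassified")
})

test_that("raising the cutoff exponent never classifies more reads", {
  db <- small_db()
  genome <- as.character(Biostrings::readDNAStringSet(
    db_manifest(db)$file[1]))[[1]]
  mutate <- function(x, rate) {
    b <- strsplit(x, "")[[1]]
    hit <- stats::runif(length(b)) < rate
    b[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    paste(b, collapse = "")
  }
  withr::with_seed(72, {
    reads <- vapply(1:30, function(i) {
      len <- sample(30:400, 1)
      pos <- sample.int(nchar(genome) - len, 1)
      mutate(substr(genome, pos, pos + len - 1), 0.15)
    }, character(1))
  })
  names(reads) <- sprintf("r%02d", 1:30)
  classified_at <- function(e) {
    res <- classify_stream(db, reads,
                           classify_options(cutoff_exponent = e))
    sum(res$status == "classified")
  }
  counts <- vapply(c(6, 12, 40, 200), classified_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("prefix truncation shortens the trial count consistently", {
  db <- small_db()
  tables <- build_pvalue_tables(db)
  genome <- as.character(Biostrings::readDNAStringSet(
    db_manifest(db)$file[1]))[[1]]
  read <- substr(genome, 1001, 3000)
  full <- classify_read(db, tables, "r", read)
  trunc <- classify_read(db, tables, "r", read,
                         classify_options(max_read_length = 360))
  expect_lte(trunc$n, full$n)
  expect_equal(trunc$n,
               length(extract_kmers(substr(read, 1, 360), db$params)))
  # trial count equals a brute-force window-emission count
  expect_equal(full$n, length(extract_kmers(read, db$params)))
})

test_that("looked-up P-values are monotone in matches and match probability", {
  p_grid <- c(0.001, 0.01, 0.1, 0.5)
  for (p in p_grid) {
    sf <- binom_sf(100, p, 0:100)
    expect_true(all(diff(sf) <= 0))
  }
  for (x in c(1, 5, 50)) {
    sf_p <- vapply(p_grid, function(p) binom_sf(100, p, x), numeric(1))
    expect_true(all(diff(sf_p) >= 0))
  }
})

test_that("classify_stream writes ordered TSV output for FASTA and FASTQ alike", {
  db <- small_db()
  genome <- as.character(Biostrings::readDNAStringSet(
    db_manifest(db)$file[2]))[[1]]
  reads <- c(hit = substr(genome, 101, 1100),
             miss = random_genome(1000, seed = 5))
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">hit", reads[["hit"]], ">miss", reads[["miss"]]), fa)
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@hit", reads[["hit"]], "+", strrep("I", 1000),
               "@miss", reads[["miss"]], "+", strrep("I", 1000)), fq)
  out <- tempfile(fileext = ".tsv")
  res_fa <- classify_stream(db, fa, output = out)
  res_fq <- classify_stream(db, fq)
  expect_equal(res_fa$read_id, c("hit", "miss"))  # input order preserved
  expect_equal(res_fa$status, res_fq$status)
  expect_equal(res_fa$label, res_fq$label)
  expect_equal(res_fa$p_value, res_fq$p_value)
  expect_equal(attr(res_fa, "summary"),
               c(classified = 1L, unclassified = 1L))
  tsv <- read.table(out, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(tsv$read_id, c("hit", "miss"))
  expect_equal(tsv$label[2], "-")
  # empty input gives an empty result with zero counts
  res0 <- classify_stream(db, character(0))
  expect_equal(nrow(res0), 0)
  expect_equal(attr(res0, "summary"),
               c(classified = 0L, unclassified = 0L))
})

test_that("per-read results are identical across stream partitions", {
  db <- small_db()
  genome <- as.character(Biostrings::readDNAStringSet(
    db_manifest(db)$file[1]))[[1]]
  withr::with_seed(73, {
    reads <- vapply(1:20, function(i) {
      pos <- sample.int(nchar(genome) - 500, 1)
      substr(genome, pos, pos + 499)
    }, character(1))
  })
  names(reads) <- sprintf("r%02d", 1:20)
  whole <- classify_stream(db, reads)
  parts <- rbind(classify_stream(db, reads[1:7]),
                 classify_stream(db, reads[8:20]))
  expect_equal(whole$label, parts$label)
  expect_equal(whole$p_value, parts$p_value)
})
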
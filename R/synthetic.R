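# Seeded synthetic mock communities and error-bearing reads with ground
# truth, standing in for real nanopore sequencing data in tests and demos.

#' Uniform error model for simulated reads
#'
#' Per-base substitution, insertion and deletion probabilities. A uniform
#' model is a deliberate simplification of basecaller error profiles; total
#' rates of 5-15% bracket the regimes of early and current nanopore
#' basecallers.
#'
#' @param substitution,insertion,deletion per-base rates, each in `[0, 1)`,
#'   summing to less than 1.
#' @return object of class `error_model`.
#' @export
error_model <- function(substitution = 0, insertion = 0, deletion = 0) {
  rates <- c(substitution, insertion, deletion)
  if (any(rates < 0 | rates >= 1) || sum(rates) >= 1) {
    stop("error rates must lie in [0, 1) and sum to less than 1")
  }
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion), class = "error_model")
}

.rand_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' Generate a uniform random genome
#'
#' @param length genome length in bases.
#' @param seed optional RNG seed; identical seeds give identical strings.
#' @return a DNA string.
#' @export
random_genome <- function(length, seed = NULL) {
  gen <- function() {
    if (length == 0L) return("")
    paste(.rand_bases(length), collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substitute bases at the given rate, never to the same base
.mutate_subs <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(b)) < rate)
  if (length(hit)) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    cur <- match(b[hit], c("A", "C", "G", "T")) - 1L
    b[hit] <- c("A", "C", "G", "T")[(cur + shift) %% 4L + 1L]
  }
  paste(b, collapse = "")
}

#' Generate a labelled mock community of genomes
#'
#' Either independent uniform random genomes, or — when `divergence` is set
#' — one random ancestor plus copies mutated at the given per-base
#' substitution rate (near-identical strain sets that share most k-mers).
#' Genomes are written as one FASTA file per assembly, labelled
#' `g000`, `g001`, ...
#'
#' @param n_genomes number of genomes (>= 1).
#' @param genome_length length of each genome in bases.
#' @param divergence optional per-base substitution rate relative to a
#'   common ancestor; NULL for independent genomes.
#' @param seed optional RNG seed; outputs are byte-identical per seed.
#' @param dir output directory (created if needed).
#' @return data.frame with columns `label`, `path`, `length`.
#' @export
mock_community <- function(n_genomes, genome_length, divergence = NULL,
                           seed = NULL, dir = tempfile("community")) {
  stopifnot(n_genomes >= 1L)
  gen <- function() {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    labels <- sprintf("g%03d", seq_len(n_genomes) - 1L)
    if (is.null(divergence)) {
      genomes <- vapply(labels, function(l)
        paste(.rand_bases(genome_length), collapse = ""), character(1))
    } else {
      ancestor <- paste(.rand_bases(genome_length), collapse = "")
      genomes <- c(ancestor, vapply(labels[-1L], function(l)
        .mutate_subs(ancestor, divergence), character(1)))
      names(genomes) <- labels
    }
    paths <- file.path(dir, paste0(labels, ".fasta"))
    for (i in seq_along(labels)) {
      writeLines(c(paste0(">", labels[i]), genomes[[i]]), paths[i])
    }
    data.frame(label = labels, path = paths, length = genome_length,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# apply the uniform error model to one sequence; each base independently
# substituted (never to itself), preceded by an inserted random base, or
# deleted (mutually exclusive outcomes)
.apply_errors <- function(sequence, model) {
  total <- model$substitution + model$insertion + model$deletion
  if (total <= 0) return(sequence)
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  u <- stats::runif(length(b))
  subs <- u < model$substitution
  ins <- !subs & u < model$substitution + model$insertion
  del <- !subs & !ins & u < total
  if (any(subs)) {
    cur <- match(b[subs], c("A", "C", "G", "T")) - 1L
    b[subs] <- c("A", "C", "G", "T")[
      (cur + sample(1:3, sum(subs), replace = TRUE)) %% 4L + 1L]
  }
  b[del] <- ""
  if (any(ins)) b[ins] <- paste0(.rand_bases(sum(ins)), b[ins])
  paste(b, collapse = "")
}

#' Simulate error-bearing reads from a mock community
#'
#' Reads are drawn from uniformly chosen genomes, positions and strands;
#' minus-strand reads are emitted reverse-complemented (exercising
#' canonicalization end to end). A fixed fraction of reads is drawn from a
#' withheld genome generated alongside the community and labelled
#' `OUT_OF_DB` in the truth table. Errors are applied per [error_model()].
#' Reads requested longer than a genome are capped at the genome length with
#' a warning.
#'
#' @param community data.frame as from [mock_community()] (columns `label`,
#'   `path`).
#' @param n_reads number of reads.
#' @param read_length fixed read length in bp, or a list
#'   `list(dist = "lognormal", meanlog =, sdlog =)`.
#' @param errors an [error_model()].
#' @param out_of_db_fraction fraction of reads drawn from the withheld
#'   genome (exact count `round(n_reads * fraction)` by construction).
#' @param seed optional RNG seed; outputs are byte-identical per seed.
#' @param fastq_path optional path to write reads as FASTQ (dummy qualities).
#' @param truth_path optional path to write the truth TSV
#'   (read_id, label, position, strand).
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read_id, label, position, strand).
#' @export
simulate_reads <- function(community, n_reads, read_length = 1000L,
                           errors = error_model(), out_of_db_fraction = 0,
                           seed = NULL, fastq_path = NULL, truth_path = NULL) {
  stopifnot(nrow(community) >= 1L, n_reads >= 0L,
            out_of_db_fraction >= 0, out_of_db_fraction < 1)
  gen <- function() {
    genomes <- lapply(community$path, function(p)
      as.character(Biostrings::readDNAStringSet(p))[[1L]])
    names(genomes) <- community$label
    withheld_len <- as.integer(round(mean(nchar(unlist(genomes)))))
    withheld <- paste(.rand_bases(withheld_len), collapse = "")

    n_out <- as.integer(round(n_reads * out_of_db_fraction))
    is_out <- rep(FALSE, n_reads)
    if (n_out > 0L) is_out[sample.int(n_reads, n_out)] <- TRUE

    lens <- if (is.list(read_length)) {
      pmax(1L, as.integer(round(stats::rlnorm(
        n_reads, meanlog = read_length$meanlog, sdlog = read_length$sdlog))))
    } else {
      rep(as.integer(read_length), n_reads)
    }

    ids <- sprintf("read%06d", seq_len(n_reads))
    reads <- character(n_reads)
    truth <- data.frame(read_id = ids, label = character(n_reads),
                        position = integer(n_reads),
                        strand = character(n_reads),
                        stringsAsFactors = FALSE)
    warned <- FALSE
    for (i in seq_len(n_reads)) {
      if (is_out[i]) {
        src <- withheld
        truth$label[i] <- OUT_OF_DB
      } else {
        gi <- sample.int(length(genomes), 1L)
        src <- genomes[[gi]]
        truth$label[i] <- names(genomes)[gi]
      }
      rl <- lens[i]
      if (rl > nchar(src)) {
        if (!warned) {
          warning("read length exceeds genome length; capping at genome length")
          warned <- TRUE
        }
        rl <- nchar(src)
      }
      pos <- sample.int(nchar(src) - rl + 1L, 1L)
      frag <- substr(src, pos, pos + rl - 1L)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") frag <- .revcomp_string(frag)
      frag <- .apply_errors(frag, errors)
      reads[i] <- frag
      truth$position[i] <- pos
      truth$strand[i] <- strand
    }
    names(reads) <- ids
    list(reads = reads, truth = truth)
  }
  res <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  if (!is.null(fastq_path)) {
    qual <- vapply(res$reads, function(r)
      strrep("I", nchar(r)), character(1), USE.NAMES = FALSE)
    writeLines(as.vector(rbind(paste0("@", names(res$reads)),
                               unname(res$reads), "+", qual)), fastq_path)
  }
  if (!is.null(truth_path)) {
    utils::write.table(res$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  res
}

#' Truncate reads to a maximum prefix length
#'
#' Emulates the adaptive-sampling evaluation protocol: every read longer
#' than `max_length` is replaced by its first `max_length` bases; shorter
#' reads pass through unchanged. Read ids are preserved.
#'
#' @param reads named character vector of read sequences.
#' @param max_length prefix length in bp (>= 1).
#' @return named character vector of truncated reads.
#' @export
truncate_reads <- function(reads, max_length) {
  max_length <- as.integer(max_length)
  if (max_length < 1L) stop("max_length must be >= 1")
  out <- substr(reads, 1L, max_length)
  names(out) <- names(reads)
  out
}
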
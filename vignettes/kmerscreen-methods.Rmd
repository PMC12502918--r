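---
title: "kmerscreen: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kmerscreen: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kmerscreen` classifies DNA reads against a collection of reference
assemblies using short, subsampled k-mers and an exact binomial significance
test. This vignette explains the statistical model and its assumptions, the
parameters that matter, the numerical and design choices made where more
than one reasonable option existed, and what the bundled synthetic data can
and cannot tell you about behaviour on real sequencing data.

## The classification model

Each assembly `a_i` is represented by the set `K_i` of canonical open
syncmers extracted from its sequence. The *universe* `U` is the set of all
k-mer codes that can ever be stored or queried — canonical codes passing the
open-syncmer test — so a read's extracted syncmers and the reference sets
live in the same space. The model treats a read as a random nucleotide
sequence: each of its `n` extracted syncmers is a Bernoulli trial that hits
assembly `i` with probability

    p_i = |K_i| / |U|,

independently of the other trials. Both parts of that assumption are
deliberate approximations: overlapping k-mers share bases (trials are not
independent), and real reads are not uniform random DNA. The test is
calibrated under the null of an *unrelated* read, which is exactly the case
where false classifications must be controlled — for adaptive sampling, a
wrongly ejected molecule is lost for good, so the model trades recall on
borderline reads for strict false-positive control.

Match counts `x_i` are compared against the binomial upper tail
`P(Bin(n_fixed, p_i) >= x̄_i)`. Reads vary enormously in length, and with
them the trial count `n`; using `n` directly would make one P-value cutoff
mean different things for different reads. Counts are therefore rescaled to
a fixed trial count:

    x̄_i = floor(x_i * n_fixed / n)    when n >= n_fixed,
    x̄_i = x_i                          when n <  n_fixed,

with the table always evaluated at `n_fixed` trials. The read is assigned
the assembly with the smallest P-value when it is below `10^-e`, else it is
unclassified. Because `p_i` also normalises for reference size, ten matches
to a small virus can outrank eleven matches to a large bacterium.

Note there is no multiplicity correction across assemblies: a single fixed
cutoff is applied to the minimum P-value. With `e = 12` the per-read
family-wise error is negligible for any realistic database size, and the
single-cutoff rule keeps the decision identical to the per-assembly test a
streaming implementation makes.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 15 | bases | k-mer length; short enough that a k-mer survives 5–10% error rates with useful probability (`0.95^15 ≈ 0.46`), long enough that `4^k` dwarfs any reference collection |
| `s` | 9 | bases | s-mer length of the open-syncmer rule |
| `t` | 2 | offset (0-indexed) | required first position of the minimal s-mer |
| `subsample_mode` | `"syncmer"` | — | syncmer subsampling or none |
| `canonicalize` | `TRUE` | — | collapse each window with its reverse complement |
| `w` | 16 | bits | ARLE word width |
| `n_fixed` | 100 | trials | fixed trial count for P-value tables |
| `e` | 12 | — | classification cutoff `10^-e` |
| `max_read_length` | unset | bp | prefix truncation emulating adaptive sampling |

`(k, s, t) = (15, 9, 2)` retains roughly 12% of windows. Syncmers (rather
than minimizers) are used because the rule is a property of the k-mer alone,
not of its neighbours in the sequence, so a substitution error destroys only
the windows it touches. `n_fixed = 100` keeps the lookup tables tiny
(101 entries per assembly, recomputed at load time) while being close to the
trial count of a ~1 kb read.

## Order of canonicalization and the syncmer test

Whether a window should be canonicalized before or after the syncmer test is
a genuine fork: the two orders keep different window sets. `kmerscreen`
tests the *canonical* form (canonicalize-then-test). Measured on a million
uniform random 15-mers, canonicalize-then-test keeps 11.8% of windows while
test-then-canonicalize keeps 13.9%; the former matches the ~12% density the
default parameters are advertised to achieve, and it makes the kept set a
deterministic function of the canonical code, which is what the universe
definition requires. The forward-strand variant remains available as
`syncmer_params(syncmer_on = "forward")`.

Ties inside the syncmer test — the minimal s-mer occurring at several
offsets — are resolved by requiring the *first* (leftmost) occurrence to be
exactly `t`. Any fixed rule works; leftmost is the conventional one and is
applied consistently to reads and references.

## The compressed index

The k-mer-by-assembly matrix is stored sparsely: only codes present in at
least one assembly get a row (for `k = 15` a dense matrix would have a
billion rows), indexed by sorted code. Column order matters for row
compressibility, and finding the run-minimising order is NP-hard, so the
package uses the classic greedy nearest-neighbour chain on pairwise Hamming
distances (symmetric-difference sizes between k-mer sets). Two
determinism choices are fixed here: the chain starts at column 1 by default
(a seeded random start is available in the CLI) and distance ties are broken
by the smallest column index. Input columns are taken in lexicographic
file-name order so builds reproduce across file systems. The
`distance_fn` hook in `pairwise_distances()` accepts estimated distances
(e.g. from sketching) for large collections without changing anything
downstream.

Rows are encoded with a two-word-type adaptive RLE. Design details worth
recording:

* **Raw-block width.** A raw word spends one flag bit, so it carries
  `w - 1` payload bits, and the encoder takes `min(w - 1, remaining)` bits
  per raw block. (Writing `w` bits into a flagged word is a specification
  one cannot serialize; the `w - 1` reading is the consistent one.)
* **Run cap.** A compressed word stores lengths up to `2^(w-2) - 1`
  *inclusive*; the cap only matters for runs of exactly that length and is
  count-neutral either way.
* **The word-count bound.** The guarantee "adaptive words ≤ naive runs"
  holds with naive runs counted cap-aware: a run longer than `2^(w-2) - 1`
  bits counts as multiple runs on both sides. Cap-free naive runs can be
  beaten by a genuine counter-example (at `w = 8`, a 70-bit run inside an
  otherwise short-run row costs two words but one unbounded run); the
  property tests use the cap-aware count.
* Zero-length rows encode as zero words; the decoder disambiguates a
  trailing short raw block from the remaining row length, so raw words need
  no explicit length field.

The on-disk format is original to this package (magic `KSCRDB1\0`,
versioned); `|U|` is stored as a float64 because the default Monte-Carlo
estimate is non-integral.

## Numerical choices

* K-mer codes are base-4 integers in doubles; `k <= 31` keeps them below
  `2^53`, so all arithmetic is exact. Integer order equals lexicographic
  order under `A<C<G<T`, which is why canonical selection is a plain `min`.
* `|U|` is enumerated exactly for `k <= 10` (at most ~1M codes) and
  estimated by Monte-Carlo above that (default `1e7` samples, seed 1,
  cached per parameter set). `p_i` enters the model only through binomial
  tails compared against `10^-12`, where three significant digits of `|U|`
  are ample; the estimate's relative error at `1e7` samples is ~0.1%.
  Sampling draws uniform bases rather than `floor(runif * 4^k)` codes,
  avoiding the granularity of a single uniform deviate.
* Binomial tails use the regularized incomplete beta via `stats::pbinom`,
  exact to machine precision down to ~`1e-308`. Tails that underflow are
  clamped to the smallest positive normal double — still far below any
  sensible cutoff — and winners among clamped ties are ordered by larger
  scaled count, then smaller `p_i`, then smaller column index, so results
  stay deterministic.
* Repeated syncmers within one read count as separate trials (`n` is the
  window count, not the distinct-code count). This keeps `n` an observable
  of the read alone; a distinct-code rule would couple `n` to database
  contents. Low-complexity reads overcount evidence slightly under this
  rule, which is conservative for the unclassified outcome only when
  repeats also hit references.
* Columns with `x_i = 0` are skipped — their P-value is 1 and can never win
  or pass the cutoff.

## The synthetic data generator

The generator produces uniform random genomes (optionally as a family of
strains diverged from one ancestor at a given substitution rate), reads from
uniform positions and strands (minus-strand reads are reverse-complemented,
exercising canonicalization end to end), a uniform
substitution/insertion/deletion error model, and an exact fraction of reads
drawn from a withheld genome labelled `OUT_OF_DB`. Everything is
deterministic per seed.

What it emulates: error rates in the 5–15% range typical of nanopore
basecallers; reads shorter or longer than `n_fixed` trials; out-of-database
contamination; strandedness. What it does not: real genomes' repeat
structure and shared gene content (random genomes of this size share almost
no 15-mers, so cross-matching is far rarer than between related bacteria),
homopolymer-biased indel profiles, quality-score information (ignored by
the method anyway), chimeras and abundance skew. Passing the bundled tests
therefore demonstrates correctness of the machinery and the statistical
calibration under the null, not species-level discrimination among close
relatives — for that, the strain-divergence mode gives a harder, though
still synthetic, instance.

The test suite's end-to-end check uses a 5-genome community of 100 kb
genomes, 2,000 reads of 1 kb at 5% substitution error with 10% withheld
reads — small enough to run comfortably on one CPU while leaving the
relevant statistics (per-read trial counts, match fractions, tail
behaviour) in the same regime as full-size data, since all of them are
per-read quantities independent of genome count.

## Known limitations

* Classification reports a single best label; it does not produce abundance
  profiles or lowest-common-ancestor assignments.
* The nearest-neighbour ordering is a heuristic; no optimality gap is
  tracked. Orderings from different start columns give different sizes but
  identical query answers (tested).
* The R implementation favours clarity over throughput: building and
  querying are vectorised but not multithreaded, and the pairwise distance
  step is quadratic in the number of assemblies. The `distance_fn` hook is
  the intended escape hatch for large collections.
* `p_i` assumes reads are drawn independently of the references; for reads
  from a genome that *is* in the database the model is intentionally
  misspecified — that is the alternative hypothesis, and it only makes the
  test more conservative for unrelated reads.
* All column and bit positions in the R API are 1-based; only the syncmer
  offset `t` is 0-indexed, following the field's convention for that
  parameter.
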
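## Self-contained sequence statistics: DUST complexity, GC fraction,
## canonical k-mers, HyperLogLog cardinality sketches, and PMD scores.

#' Reverse complement of nucleotide sequences
#'
#' Vectorised reverse complement over the DNA alphabet; characters outside
#' A/C/G/T/N map to N.
#'
#' @param seqs character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTT"))
revcomp <- function(seqs) {
  .revcomp(as.character(seqs))
}

#' DUST low-complexity score of a read
#'
#' Whole-read triplet-repetition score scaled to 0-100, where higher scores
#' indicate lower complexity and any homopolymer scores exactly 100. With
#' `n = nchar(seq) - 2` overlapping triplets and `c_t` the count of triplet
#' `t`, the score is `100 * sum(c_t * (c_t - 1)) / (n * (n - 1))`. Sequences
#' with fewer than two triplets score 0. The scaling follows the Prinseq
#' convention (no windowing, homopolymer = 100).
#'
#' @param seq a single nucleotide string.
#' @return numeric score in \[0, 100\].
#' @export
#' @examples
#' dust_score("TTTTTTTTTT") # 100
#' dust_score("ACGTACGTACGT")
dust_score <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  len <- nchar(seq)
  n <- len - 2L
  if (is.na(len) || n < 2L) return(0)
  trip <- substring(seq, seq_len(n), seq_len(n) + 2L)
  ct <- tabulate(factor(trip))
  100 * sum(ct * (ct - 1)) / (n * (n - 1))
}

#' GC fraction of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N and other characters are excluded from
#' both numerator and denominator. Empty or all-N sequences return 0.
#'
#' @param seq a single nucleotide string.
#' @return numeric in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  acgt <- sum(b %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(0)
  sum(b %in% c("G", "C")) / acgt
}

#' Canonical k-mers of a sequence
#'
#' For each of the `nchar(seq) - k + 1` windows, returns the lexicographic
#' minimum of the window and its reverse complement. Windows containing
#' non-ACGT characters are skipped; sequences shorter than k yield nothing.
#'
#' @param seq a single nucleotide string.
#' @param k k-mer length (default 29).
#' @return character vector of canonical k-mers, in window order.
#' @export
canonical_kmers <- function(seq, k = 29L) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L)
  .canonical_kmers(seq, as.integer(k))
}

#' Create a HyperLogLog k-mer sketch
#'
#' A probabilistic cardinality sketch with `2^precision` one-byte registers.
#' At the default precision 14 the relative standard error is
#' `1.04 / sqrt(2^14)`, about 0.8%, which keeps mean unique-k-mer counting
#' error within 1%. Hashing is a fixed-constant 64-bit FNV-1a/splitmix64
#' combination, so estimates are reproducible across runs and platforms.
#'
#' @param precision register-count exponent (default 14).
#' @param k k-mer length recorded for bookkeeping (default 29).
#' @return an object of class `kmer_sketch`.
#' @export
kmer_sketch <- function(precision = 14L, k = 29L) {
  structure(
    list(ptr = .hll_create(as.integer(precision)),
         precision = as.integer(precision), k = as.integer(k)),
    class = "kmer_sketch")
}

#' Insert keys into a sketch
#'
#' @param sk a `kmer_sketch`.
#' @param keys character vector of (canonical) k-mers or arbitrary keys.
#' @return the sketch, invisibly (updated in place).
#' @export
sketch_add <- function(sk, keys) {
  stopifnot(inherits(sk, "kmer_sketch"))
  .hll_insert(sk$ptr, as.character(keys))
  invisible(sk)
}

#' Insert all canonical k-mers of a read into a sketch
#'
#' @param sk a `kmer_sketch`.
#' @param seq a single nucleotide string.
#' @param k k-mer length; defaults to the sketch's k.
#' @return integer count of k-mer windows inserted (the read's total-k-mer
#'   contribution).
#' @export
sketch_add_read <- function(sk, seq, k = sk$k) {
  stopifnot(inherits(sk, "kmer_sketch"))
  .hll_insert_kmers(sk$ptr, seq, as.integer(k))
}

#' Estimate the number of distinct inserted keys
#'
#' @param sk a `kmer_sketch`.
#' @return numeric cardinality estimate (>= 0).
#' @export
sketch_estimate <- function(sk) {
  stopifnot(inherits(sk, "kmer_sketch"))
  .hll_estimate(sk$ptr)
}

#' Merge a sketch into another
#'
#' Register-wise maximum; both sketches must share a precision. Merging is
#' commutative and idempotent, so multi-sample unions never double count.
#'
#' @param sk,other `kmer_sketch` objects of equal precision.
#' @return `sk`, invisibly (updated in place).
#' @export
sketch_merge <- function(sk, other) {
  stopifnot(inherits(sk, "kmer_sketch"), inherits(other, "kmer_sketch"))
  .hll_merge_into(sk$ptr, other$ptr)
  invisible(sk)
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("<kmer_sketch p=%d k=%d estimate=%.1f>\n",
              x$precision, x$k, sketch_estimate(x)))
  invisible(x)
}

#' PMD model parameters
#'
#' Parameters of the postmortem-damage likelihood-ratio model: the
#' terminal damage probability decays geometrically with distance z from the
#' read end, `D(z) = p * (1 - p)^(z - 1) + const`, and the null model assumes
#' mismatches arise only from a flat base-error rate. Defaults follow the
#' commonly used PMD scoring convention (p = 0.3, const = 0.01,
#' base error 0.001). These are tunable parameters, not ground truth.
#'
#' @param p damage amplitude at the terminal base.
#' @param const residual damage probability far from the ends.
#' @param base_error flat sequencing-error rate used by both models.
#' @return a list of class `pmd_params`.
#' @export
pmd_params <- function(p = 0.3, const = 0.01, base_error = 0.001) {
  stopifnot(p >= 0, p <= 1, const >= 0, const < 1, base_error > 0, base_error < 1)
  structure(list(p = p, const = const, base_error = base_error),
            class = "pmd_params")
}

#' PMD score of one alignment
#'
#' Log-likelihood ratio of a postmortem-damage model against a null model,
#' summed over aligned columns whose reference base can carry damage: for
#' double-stranded libraries, reference C sites scored by 5' distance and
#' reference G sites scored by 3' distance (expected transition G-to-A); for
#' single-stranded libraries, reference C sites scored by distance to the
#' nearer end. Adding a terminal C-to-T observation never decreases the
#' score.
#'
#' @param profile an `oriented_mismatch_profile` (see
#'   [oriented_substitutions()]) with `all_pairs = TRUE` so every aligned
#'   column is available.
#' @param params a [pmd_params()] object.
#' @param stranded `"ds"` or `"ss"` library chemistry.
#' @return numeric log-likelihood ratio (natural log).
#' @export
pmd_score <- function(profile, params = pmd_params(), stranded = c("ds", "ss")) {
  stranded <- match.arg(stranded)
  stopifnot(inherits(profile, "oriented_mismatch_profile"))
  pr <- profile$pairs
  if (is.null(pr) || nrow(pr) == 0L) return(0)
  dz <- function(z) pmin(1, params$p * (1 - params$p)^(z - 1) + params$const)
  eps <- params$base_error
  ll <- 0
  score_site <- function(z, damaged) {
    d <- dz(z)
    p_dam <- d * (1 - eps) + (1 - d) * eps   # P(transition | damage model)
    p_nul <- eps                             # P(transition | null model)
    ifelse(damaged, log(p_dam / p_nul), log((1 - p_dam) / (1 - p_nul)))
  }
  if (stranded == "ds") {
    c5 <- pr[pr$ref == "C", , drop = FALSE]
    if (nrow(c5)) ll <- ll + sum(score_site(c5$off5, c5$read == "T"))
    g3 <- pr[pr$ref == "G", , drop = FALSE]
    if (nrow(g3)) ll <- ll + sum(score_site(g3$off3, g3$read == "A"))
  } else {
    cc <- pr[pr$ref == "C", , drop = FALSE]
    if (nrow(cc)) ll <- ll + sum(score_site(pmin(cc$off5, cc$off3), cc$read == "T"))
  }
  ll
}
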
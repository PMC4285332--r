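# Diversity summaries: rank abundance, dominance ratios, top-N fractions
# and rarefaction.

#' Rank-abundance table for one sample
#'
#' @param x A [VariantCounts-class] table.
#' @param sample sample id with at least one read.
#' @return A data.frame with `variant_id`, `count`, `fraction`, sorted by
#'   descending count (ties broken by lexicographically smaller sequence).
#' @export
rankAbundance <- function(x, sample) {
  stopifnot(is(x, "VariantCounts"))
  if (!sample %in% sampleIds(x)) stop("unknown sample: ", sample)
  cnt <- countMatrix(x)[, sample]
  pres <- cnt > 0
  if (!any(pres)) stop("sample has no reads: ", sample)
  ids <- variantIds(x)[pres]
  cnt <- cnt[pres]
  sq <- x@sequences[pres]
  ord <- order(-cnt, sq)
  data.frame(variant_id = ids[ord], count = as.integer(cnt[ord]),
             fraction = as.numeric(cnt[ord] / sum(cnt)),
             stringsAsFactors = FALSE)
}

#' Dominance fold ratio (most abundant / second most abundant)
#'
#' @param ra a rank-abundance data.frame from [rankAbundance()].
#' @return `count[1] / count[2]` as a double.
#' @export
dominanceFold <- function(ra) {
  if (nrow(ra) < 2) stop("dominance fold needs at least 2 variants")
  ra$count[1] / ra$count[2]
}

#' Cumulative fraction of the top-n variants
#'
#' @param ra a rank-abundance data.frame from [rankAbundance()].
#' @param n number of top variants (all variants when `n` exceeds the count).
#' @return A fraction in (0, 1\].
#' @export
topNFraction <- function(ra, n) {
  if (n < 1) stop("n must be >= 1")
  sum(ra$fraction[seq_len(min(n, nrow(ra)))])
}

#' Analytic rarefaction curve (expected distinct variants)
#'
#' Exact hypergeometric expectation of the number of distinct variants in a
#' random subsample without replacement:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated in
#' log-gamma arithmetic. This is the exact expectation of the resampling
#' procedure that rarefaction tools estimate by Monte Carlo.
#'
#' @param counts integer vector of variant counts for one sample (zeros are
#'   dropped).
#' @param depths subsampling depths, each between 1 and `sum(counts)`.
#' @return A data.frame with `depth` and `expected_variants`.
#' @export
rarefactionCurve <- function(counts, depths) {
  counts <- as.numeric(counts[counts > 0])
  if (!length(counts)) stop("sample has no reads")
  N <- sum(counts)
  if (any(depths < 1 | depths > N))
    stop("depths must lie in [1, total reads = ", N, "]")
  ev <- vapply(depths, function(n) {
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1))
  data.frame(depth = as.integer(depths), expected_variants = ev)
}

#' Monte-Carlo rarefaction (seeded cross-check)
#'
#' @param counts integer vector of variant counts.
#' @param depth subsampling depth.
#' @param reps number of resampling replicates.
#' @param seed integer seed (RNG state is restored afterwards).
#' @return A list with `mean`, `se` and `reps`.
#' @export
rarefyMonteCarlo <- function(counts, depth, reps = 1000, seed = 1) {
  counts <- as.integer(counts[counts > 0])
  N <- sum(counts)
  if (depth < 1 || depth > N) stop("depth must lie in [1, ", N, "]")
  pool <- rep.int(seq_along(counts), counts)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i)
      length(unique(sample(pool, depth))), numeric(1))
  })
  list(mean = mean(draws), se = stats::sd(draws) / sqrt(reps), reps = reps)
}
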
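#' Probability that a shared haplotype survived since archaic divergence
#'
#' The incomplete-lineage-sorting (ILS) test.  Under the recombination
#' clock, the unbroken ancestral segment around a focal site extends in
#' each direction by an independent Exponential length with rate G per
#' Morgan, where G is the total branch length separating the two lineages
#' (the sum of the modern-human and archaic branches, in generations).  The
#' total length is therefore Gamma(shape 2, rate G) and the probability of
#' observing a shared fragment at least m Morgans long is
#'
#'   P(L >= m) = (1 + G m) exp(-G m)
#'
#' The expected length is 2/G Morgans.  A fragment long enough to make this
#' probability small cannot plausibly be retained ancestral polymorphism
#' and must have entered by admixture.  With `sides = 1` the one-sided
#' survival exp(-G m) is returned instead (sensitivity analysis).
#'
#' @param m_cM genetic length of the shared haplotype, centiMorgans
#' @param branch_human_gens modern-human branch length in generations since
#'   divergence from the archaics (default 21,500)
#' @param branch_archaic_gens archaic branch length in generations
#'   (default 19,500)
#' @param sides 2 (default, segment extends both ways from the focal
#'   variant) or 1
#' @return an object of class `ils_result` with fields `m_cM`, `m_morgans`,
#'   `G` (total branch length, generations), `expected_length_cM`,
#'   `probability`
#' @export
ils_probability <- function(m_cM, branch_human_gens = 21500,
                            branch_archaic_gens = 19500, sides = 2L) {
  if (m_cM < 0) stop("genetic length must be >= 0", call. = FALSE)
  if (branch_human_gens <= 0 || branch_archaic_gens <= 0)
    stop("branch lengths must be positive", call. = FALSE)
  if (!sides %in% c(1L, 2L)) stop("sides must be 1 or 2", call. = FALSE)
  G <- branch_human_gens + branch_archaic_gens
  m <- m_cM / 100                        # centiMorgans -> Morgans
  p <- if (sides == 2L) (1 + G * m) * exp(-G * m) else exp(-G * m)
  structure(list(m_cM = m_cM, m_morgans = m, G = G,
                 branch_human_gens = branch_human_gens,
                 branch_archaic_gens = branch_archaic_gens,
                 sides = as.integer(sides),
                 expected_length_cM = 100 * sides / G,
                 probability = p),
            class = "ils_result")
}

#' @export
print.ils_result <- function(x, ...) {
  cat(sprintf("<ils_result> m = %g cM, G = %d + %d = %d generations\n",
              x$m_cM, x$branch_human_gens, x$branch_archaic_gens, x$G))
  cat(sprintf("  expected shared length %.4g cM; P(L >= m) = %.3g\n",
              x$expected_length_cM, x$probability))
  invisible(x)
}

#' Percentile rank of a fragment among archaic fragment lengths
#'
#' Fraction of fragments strictly shorter than the query (ties count as not
#' shorter).  A query longer than 41% of genome-wide introgressed fragments
#' is typical, not exceptional, for an introgressed haplotype.
#'
#' @param query_cM query genetic length (cM, >= 0)
#' @param fragment_lengths nonempty numeric vector of fragment lengths (cM)
#' @return fraction in \[0, 1\]
#' @export
fragment_percentile <- function(query_cM, fragment_lengths) {
  if (!length(fragment_lengths)) stop("empty fragment list", call. = FALSE)
  if (query_cM < 0) stop("query must be >= 0", call. = FALSE)
  mean(fragment_lengths < query_cM)
}
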
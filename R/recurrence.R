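#' Parameters for recurrent-mutation significance statistics
#'
#' Bundles the three quantities that drive the recurrence calculations: the
#' per-base per-proband de novo mutation probability, the protein-altering
#' target size of the exome, and the assumed population allele frequency of
#' the variant among additional unrelated cases.
#'
#' @param mu_dn Per-base per-proband de novo mutation probability
#'   (default `1.4e-8`).
#' @param target_bp Protein-altering exome target size in base pairs
#'   (default `24.75e6`, i.e. 24.75 Mb).
#' @param allele_freq Assumed population allele frequency for the
#'   additional-carrier statistic (default `1e-5`).
#' @return A list of class `recurrence_params`.
#' @examples
#' recurrence_params()
#' @export
recurrence_params <- function(mu_dn = 1.4e-8, target_bp = 24.75e6,
                              allele_freq = 1e-5) {
  stopifnot(mu_dn > 0, mu_dn < 1, target_bp >= 1,
            allele_freq > 0, allele_freq < 1)
  if (mu_dn * target_bp >= 1)
    warning("mu_dn * target_bp >= 1: expected per-proband de novo count ",
            "exceeds one protein-altering event; results remain valid ",
            "probabilities but the linear target-size correction is crude")
  structure(list(mu_dn = mu_dn, target_bp = target_bp,
                 allele_freq = allele_freq),
            class = "recurrence_params")
}

#' @export
print.recurrence_params <- function(x, ...) {
  cat("Recurrence parameters\n",
      "  de novo rate mu:   ", format(x$mu_dn), " per base per proband\n",
      "  exome target:      ", format(x$target_bp / 1e6), " Mb\n",
      "  allele frequency:  ", format(x$allele_freq), "\n", sep = "")
  invisible(x)
}

#' Probability of a recurrent de novo mutation anywhere in the exome
#'
#' Per-site probability of observing two or more de novo mutations at the
#' same position among `n_cases` independent probands, each with per-base
#' de novo probability `mu_dn`, multiplied by the number of protein-altering
#' target bases to correct for the genome-wide search.  The per-site tail is
#' the exact binomial `P(X >= 2)`, not the `choose(n,2) mu^2` approximation
#' (both agree to well under 1% at human de novo rates; the approximation is
#' exposed for cross-checking).
#'
#' @param n_cases Number of independent cases searched.
#' @param mu_dn Per-base per-proband de novo probability.
#' @param target_bp Target size in base pairs used for the multiple-site
#'   correction.
#' @param strict If `TRUE`, `n_cases < 2` is an error ("recurrence
#'   undefined"); if `FALSE` (default) it returns 0, since two hits are
#'   impossible.
#'
#' @return Numeric probability (clamped to `[0, 1]`), with attributes:
#'   `p_site` — the exact per-site tail; `p_site_approx` — the
#'   `choose(n,2) mu^2` approximation; `p_exact_genomewide` — the
#'   Bonferroni-exact form `1 - (1 - p_site)^target_bp`.
#' @examples
#' # ~4.0e-6 for 41 cases at mu = 1.4e-8 over 24.75 Mb
#' p_recurrent_de_novo(41, 1.4e-8, 24.75e6)
#' @export
p_recurrent_de_novo <- function(n_cases, mu_dn, target_bp,
                                strict = FALSE) {
  stopifnot(n_cases >= 0, target_bp >= 1)
  if (mu_dn <= 0 || mu_dn >= 1) {
    if (strict) stop("recurrence undefined: mu_dn must lie in (0, 1)")
    stopifnot(mu_dn >= 0, mu_dn <= 1)
  }
  if (n_cases < 2) {
    if (strict) stop("recurrence undefined: fewer than two cases")
    p_site <- 0
  } else {
    p_site <- stats::pbinom(1, size = n_cases, prob = mu_dn,
                            lower.tail = FALSE)
  }
  p <- min(1, max(0, p_site * target_bp))
  attr(p, "p_site") <- p_site
  attr(p, "p_site_approx") <- choose(n_cases, 2) * mu_dn^2
  attr(p, "p_exact_genomewide") <- -expm1(target_bp * log1p(-p_site))
  p
}

#' Probability of additional unrelated carriers at an assumed allele frequency
#'
#' Binomial probability of observing exactly `k` carriers of a given variant
#' among `n_subjects` additional unrelated subjects, with the per-subject
#' carrier probability set equal to the allele frequency itself.  Equating
#' carrier probability with allele frequency (rather than the Hardy-Weinberg
#' carrier frequency of about `2q`) understates the chance of carriers and is
#' therefore the conservative convention for arguing that observed recurrence
#' is non-random.  The upper tail `P(X >= k)` is attached for comparison; at
#' rare-variant frequencies the two agree to two significant figures.
#'
#' @param n_subjects Number of additional unrelated subjects.
#' @param k Observed number of carriers.
#' @param allele_freq Assumed population allele frequency, in (0, 1).
#' @return `P(X = k)` for `X ~ Binomial(n_subjects, allele_freq)`, with
#'   attribute `p_tail` giving `P(X >= k)`.
#' @examples
#' # ~8.4e-12 for 3 carriers among 38 subjects at q = 1e-5
#' p_additional_carriers(38, 3, 1e-5)
#' @export
p_additional_carriers <- function(n_subjects, k, allele_freq) {
  stopifnot(n_subjects >= 0, k >= 0, allele_freq > 0, allele_freq < 1)
  if (k > n_subjects)
    stop("k carriers cannot exceed n_subjects")
  p <- stats::dbinom(k, size = n_subjects, prob = allele_freq)
  attr(p, "p_tail") <- stats::pbinom(k - 1, size = n_subjects,
                                     prob = allele_freq, lower.tail = FALSE)
  p
}

#' Combine independent recurrence probabilities
#'
#' The de novo recurrence statistic and the additional-carrier statistic are
#' computed on disjoint sets of subjects, so their joint probability under
#' the chance hypothesis is the product.
#'
#' @param p1,p2 Probabilities in `[0, 1]`.
#' @return `p1 * p2`.
#' @export
combined_recurrence <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  p1 * p2
}

#' Expected biallelic loss-of-function frequency under Hardy-Weinberg
#'
#' Given the cumulative population frequency `q` of loss-of-function alleles
#' in a gene (splice-site, frameshift and nonsense combined), the expected
#' frequency of subjects carrying two such alleles — homozygous or compound
#' heterozygous — is `q^2`, because the cumulative frequency already pools
#' all qualifying alleles.
#'
#' @param cum_lof_freq Cumulative loss-of-function allele frequency, in
#'   (0, 1).
#' @return A list with `freq` (`q^2`) and `one_in` (its reciprocal, the
#'   "1 in N subjects" form).
#' @examples
#' biallelic_lof_frequency(6e-4)  # 3.6e-7, about 1 in 2.8 million
#' @export
biallelic_lof_frequency <- function(cum_lof_freq) {
  stopifnot(cum_lof_freq > 0, cum_lof_freq < 1)
  freq <- cum_lof_freq^2
  list(freq = freq, one_in = 1 / freq)
}

#' Full recurrence significance report
#'
#' Convenience wrapper running all three recurrence statistics with one
#' parameter set, mirroring the analysis for a variant seen de novo in some
#' cases and inherited in additional unrelated cases.
#'
#' @param params A [recurrence_params()] object.
#' @param n_cases_de_novo Cases searched for recurrent de novo mutations.
#' @param n_cases_inherited Additional unrelated subjects searched.
#' @param k_carriers Carriers observed among the additional subjects.
#' @return A list of class `recurrence_result` with elements
#'   `p_de_novo_recurrent`, `p_additional_carriers`, `p_combined` and the
#'   input counts.
#' @examples
#' recurrence_report(recurrence_params(), 41, 38, 3)
#' @export
recurrence_report <- function(params = recurrence_params(),
                              n_cases_de_novo = 41,
                              n_cases_inherited = 38,
                              k_carriers = 3) {
  stopifnot(inherits(params, "recurrence_params"))
  p1 <- p_recurrent_de_novo(n_cases_de_novo, params$mu_dn, params$target_bp)
  p2 <- p_additional_carriers(n_cases_inherited, k_carriers,
                              params$allele_freq)
  structure(list(p_de_novo_recurrent = as.numeric(p1),
                 p_additional_carriers = as.numeric(p2),
                 p_combined = combined_recurrence(p1, p2),
                 n_cases_de_novo = n_cases_de_novo,
                 n_cases_inherited = n_cases_inherited,
                 k_carriers = k_carriers,
                 params = params),
            class = "recurrence_result")
}

#' @export
print.recurrence_result <- function(x, ...) {
  cat("Recurrent-mutation significance\n",
      "  P(recurrent de novo, exome-wide, ", x$n_cases_de_novo, " cases): ",
      format(x$p_de_novo_recurrent, digits = 3), "\n",
      "  P(", x$k_carriers, " carriers among ", x$n_cases_inherited,
      " subjects at q = ", format(x$params$allele_freq), "): ",
      format(x$p_additional_carriers, digits = 3), "\n",
      "  Combined: ", format(x$p_combined, digits = 3), "\n", sep = "")
  invisible(x)
}
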
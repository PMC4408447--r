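Package: aldorecur
Title: Recurrent-Mutation Statistics, Aldosterone Screening, Haplotype
    Dating and T-Type Channel Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational analyses behind the genetic
    dissection of early-onset primary aldosteronism caused by a recurrent
    gain-of-function mutation in a T-type calcium channel gene: exact
    binomial significance statistics for recurrent de novo and inherited
    mutations corrected for exome target size, aldosterone:renin ratio
    screening with censored laboratory values, cohort-level recurrent
    variant and gene-burden searches, identity-by-descent shared-haplotype
    detection with maximum-likelihood mutation-age estimation, and
    whole-cell patch-clamp analysis (peak current-voltage extraction,
    Boltzmann activation fits, exponential inactivation and recovery
    kinetics, window current, non-stationary noise analysis). Synthetic
    data generators (a stochastic Hodgkin-Huxley style channel-gating
    simulator, a descendant-haplotype simulator, and toy cohort tables)
    make every analysis testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    jsonlite
Config/testthat/edition: 3
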
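#' Simulate carrier haplotypes descending from a common ancestor
#'
#' Generates `n_carriers` present-day carrier haplotypes around a focal
#' variant that arose on an ancestral haplotype `g` generations ago.  On
#' each side of the focal variant the retained ancestral segment ends at
#' marker `k` with the survival law `(1 - theta_k)^g` (recombination
#' fraction `theta` from the focal variant, Haldane map); beyond the
#' breakpoint alleles are drawn from the population, matching the
#' ancestral allele by chance with the map's frequencies; and each marker
#' still on the ancestral segment mutates with probability
#' `1 - (1 - mu_m)^g`.  This is exactly the generative model scored by
#' [sharing_likelihood()], so age estimation on simulated data is a
#' like-for-like parameter-recovery exercise.
#'
#' @param ancestral Integer 0/1 vector of ancestral alleles aligned to
#'   `map`.
#' @param map A [marker_map()].
#' @param g True age in generations (>= 1).
#' @param n_carriers Number of carrier haplotypes.
#' @param seed Mandatory integer seed.
#' @return A list with `haplotypes` (matrix, one row per carrier),
#'   `obs` (the [sharing_obs()] of first discordances against
#'   `ancestral`) and `breakpoints` (data frame of the true per-side
#'   breakpoint indices, `NA` when the segment survived past the map).
#' @export
simulate_descendant_haplotypes <- function(ancestral, map, g, n_carriers,
                                           seed) {
  stopifnot(inherits(map, "marker_map"), g >= 1, n_carriers >= 1,
            length(ancestral) == nrow(map), all(ancestral %in% 0:1))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  sides <- map_sides(map)
  haps <- matrix(rep(as.integer(ancestral), each = n_carriers),
                 nrow = n_carriers)
  bp_rows <- list()
  for (s in c("left", "right")) {
    sd <- sides[[s]]
    M <- length(sd$theta)
    surv <- (1 - c(0, sd$theta))^g       # S_0..S_M
    p_break <- c(surv[1:M] - surv[2:(M + 1)], surv[M + 1])
    for (i in seq_len(n_carriers)) {
      k <- sample.int(M + 1, 1, prob = p_break)  # M+1 = survived past map
      if (k <= M) {
        pop_idx <- k:M
        match_anc <- stats::rbinom(length(pop_idx), 1,
                                   sd$freq[pop_idx]) == 1
        new_alleles <- ifelse(match_anc, ancestral[sd$idx[pop_idx]],
                              1L - ancestral[sd$idx[pop_idx]])
        haps[i, sd$idx[pop_idx]] <- new_alleles
        anc_span <- if (k > 1) 1:(k - 1) else integer(0)
      } else {
        anc_span <- 1:M
      }
      # marker mutations on the retained ancestral segment
      if (length(anc_span)) {
        p_mut <- 1 - (1 - attr(map, "mu_m"))^g
        flips <- stats::runif(length(anc_span)) < p_mut
        if (any(flips)) {
          cols <- sd$idx[anc_span[flips]]
          haps[i, cols] <- 1L - haps[i, cols]
        }
      }
      bp_rows[[length(bp_rows) + 1L]] <- data.frame(
        carrier = i, side = s,
        breakpoint = if (k <= M) k else NA_integer_)
    }
  }
  obs <- sharing_obs_from_haplotypes(haps, map,
                                     ancestral = as.integer(ancestral))
  list(haplotypes = haps, obs = obs,
       breakpoints = do.call(rbind, bp_rows))
}

#' Simulate unphased carrier genotypes from haplotypes
#'
#' Pairs each carrier haplotype with an independent population
#' chromosome (alleles drawn from the map frequencies) to produce 0/1/2
#' dosage genotypes, the input of [discordance_bound_unphased()].
#'
#' @param haplotypes Carrier haplotype matrix (rows = carriers).
#' @param map A [marker_map()].
#' @param seed Mandatory integer seed.
#' @return Integer dosage matrix with the same shape as `haplotypes`.
#' @export
simulate_carrier_genotypes <- function(haplotypes, map, seed) {
  stopifnot(is.matrix(haplotypes), ncol(haplotypes) == nrow(map))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  anc <- consensus_ancestral(haplotypes)
  n <- nrow(haplotypes); m <- ncol(haplotypes)
  other <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    match_anc <- stats::rbinom(m, 1, map$freq) == 1
    other[i, ] <- ifelse(match_anc, anc, 1L - anc)
  }
  haplotypes + other
}

#' Simulate a toy cohort variant table with lab panels
#'
#' Builds a cohort of `n_subjects` subjects carrying random singleton
#' background variants plus one planted previously-unreported
#' protein-altering variant shared by `n_planted_carriers` subjects.  Lab
#' panels are drawn so that planted carriers satisfy the aldosterone:renin
#' screening rule and the remaining subjects do not.
#'
#' @param n_subjects Number of subjects (default 40).
#' @param n_variants Number of background singleton variants (default
#'   200).
#' @param n_planted_carriers Subjects carrying the planted recurrent
#'   variant (default 5).
#' @param planted_gene Gene name of the planted variant.
#' @param seed Mandatory integer seed.
#' @return A list with `variants` (a [cohort_variants()] table), `labs`
#'   (data frame with columns `subject`, `aldo`, `pra`, `k`), `planted`
#'   (list describing the planted variant) and `carriers` (subject ids).
#' @export
simulate_cohort <- function(n_subjects = 40, n_variants = 200,
                            n_planted_carriers = 5,
                            planted_gene = "GENE_X", seed) {
  stopifnot(n_subjects >= 1, n_variants >= 1,
            n_planted_carriers <= n_subjects)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  bases <- c("A", "C", "G", "T")
  consequences <- c(protein_altering_classes(), "synonymous", "intronic")
  pos <- sort(sample.int(5e7, n_variants + 1))
  planted_pos <- pos[ceiling(length(pos) / 2)]
  bg_pos <- setdiff(pos, planted_pos)
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  bg <- data.frame(
    chrom = "chr16", pos = bg_pos, ref = ref, alt = alt,
    subject = sample(subjects, n_variants, replace = TRUE),
    gene = sprintf("GENE%03d", sample.int(50, n_variants,
                                          replace = TRUE)),
    consequence = sample(consequences, n_variants, replace = TRUE,
                         prob = c(rep(1, 6), 3, 3)),
    known = stats::runif(n_variants) < 0.7,
    genotype = "het", stringsAsFactors = FALSE)
  carriers <- sample(subjects, n_planted_carriers)
  planted <- data.frame(
    chrom = "chr16", pos = planted_pos, ref = "A", alt = "G",
    subject = carriers, gene = planted_gene, consequence = "missense",
    known = FALSE, genotype = "het", stringsAsFactors = FALSE)
  variants <- cohort_variants(rbind(bg, planted))
  is_carrier <- subjects %in% carriers
  labs <- data.frame(
    subject = subjects,
    aldo = round(ifelse(is_carrier,
                        stats::runif(n_subjects, 25, 90),
                        stats::runif(n_subjects, 2, 12)), 1),
    pra = round(ifelse(is_carrier,
                       stats::runif(n_subjects, 0.1, 0.5),
                       stats::runif(n_subjects, 1.0, 3.0)), 2),
    k = round(ifelse(is_carrier,
                     stats::runif(n_subjects, 3.0, 3.9),
                     stats::runif(n_subjects, 3.6, 4.8)), 1),
    stringsAsFactors = FALSE)
  list(variants = variants, labs = labs,
       planted = list(chrom = "chr16", pos = planted_pos, ref = "A",
                      alt = "G", gene = planted_gene),
       carriers = sort(carriers))
}

#' Evenly spaced synthetic marker map around a focal variant
#'
#' Convenience constructor for simulations: `n_side` markers on each side
#' of the focal variant at fixed spacing, with a common ancestral-allele
#' frequency.
#'
#' @param n_side Markers per side (default 41).
#' @param spacing_bp Marker spacing (bp, default 50000).
#' @param freq Ancestral-allele frequency at every marker (default 0.7).
#' @param focal_pos Focal variant position (bp).
#' @param rate_cM_per_Mb,mu_m Passed to [marker_map()].
#' @return A [marker_map()].
#' @export
synthetic_marker_map <- function(n_side = 41, spacing_bp = 5e4,
                                 freq = 0.7, focal_pos = 5e6,
                                 rate_cM_per_Mb = 2.9, mu_m = 2e-8) {
  offs <- spacing_bp * seq_len(n_side)
  pos <- c(focal_pos - rev(offs), focal_pos + offs)
  marker_map(id = sprintf("rs%05d", seq_along(pos)), pos_bp = pos,
             freq = rep(freq, length(pos)), focal_pos = focal_pos,
             rate_cM_per_Mb = rate_cM_per_Mb, mu_m = mu_m)
}
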
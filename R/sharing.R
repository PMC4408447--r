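#' Maximal haplotype interval shared by phased carriers
#'
#' Scans outward from the focal variant on each side and finds the first
#' marker at which any pair of carrier haplotypes differs.  The shared
#' interval is the open interval between the innermost discordant marker on
#' each side; when no discordance is found on a side the interval extends
#' to the outermost typed marker and that side is flagged censored.
#'
#' @param haplotypes Integer matrix of 0/1 alleles, one row per carrier
#'   haplotype, columns aligned to `map` (all carriers of the focal
#'   variant).
#' @param map A [marker_map()].
#' @return A list of class `shared_interval` with `start`, `end` (bp),
#'   `left_marker`, `right_marker` (ids, `NA` when censored), `length_bp`,
#'   `censored_left`, `censored_right` and `pairwise` (data frame of
#'   pairwise interval lengths).
#' @export
shared_interval_phased <- function(haplotypes, map) {
  stopifnot(is.matrix(haplotypes), ncol(haplotypes) == nrow(map))
  if (nrow(haplotypes) < 2)
    stop("at least two carrier haplotypes are required")
  sides <- map_sides(map)
  discord <- function(rows, side) {
    # first outward index where any pair among `rows` differs; NA if none
    for (k in seq_along(side$idx)) {
      col <- haplotypes[rows, side$idx[k]]
      if (length(unique(col)) > 1L) return(k)
    }
    NA_integer_
  }
  all_rows <- seq_len(nrow(haplotypes))
  build <- function(rows) {
    jl <- discord(rows, sides$left)
    jr <- discord(rows, sides$right)
    start <- if (is.na(jl)) sides$left$pos[length(sides$left$pos)]
             else sides$left$pos[jl]
    end <- if (is.na(jr)) sides$right$pos[length(sides$right$pos)]
           else sides$right$pos[jr]
    list(start = start, end = end,
         left_marker = if (is.na(jl)) NA_character_ else sides$left$id[jl],
         right_marker = if (is.na(jr)) NA_character_ else sides$right$id[jr],
         length_bp = end - start,
         censored_left = is.na(jl), censored_right = is.na(jr))
  }
  main <- build(all_rows)
  pairs <- utils::combn(all_rows, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    b <- build(pairs[, i])
    data.frame(hap1 = pairs[1, i], hap2 = pairs[2, i],
               start = b$start, end = b$end, length_bp = b$length_bp)
  }))
  structure(c(main, list(pairwise = pairwise)), class = "shared_interval")
}

#' @export
print.shared_interval <- function(x, ...) {
  cat("Shared interval: ", format(x$start, big.mark = ","), " - ",
      format(x$end, big.mark = ","), " bp (",
      format(x$length_bp / 1e3), " kb), flanked by ",
      ifelse(is.na(x$left_marker), "[typed region end]", x$left_marker),
      " and ",
      ifelse(is.na(x$right_marker), "[typed region end]", x$right_marker),
      "\n", sep = "")
  invisible(x)
}

#' Unphased sharing bound from homozygous-discordant genotypes
#'
#' Without phase, the only genotype configuration that excludes sharing of
#' a haplotype between two carriers is a marker at which they are
#' homozygous for different alleles.  The bound is the open interval
#' between the nearest such marker on each side of the focal variant; it
#' always contains the phased shared interval.
#'
#' @param genotypes Integer matrix of allele dosages (0/1/2), one row per
#'   carrier, columns aligned to `map`.
#' @param map A [marker_map()].
#' @return A `shared_interval` (no pairwise table); sides with no
#'   homozygous-discordant pair are censored at the typed region end and
#'   flagged.
#' @export
discordance_bound_unphased <- function(genotypes, map) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == nrow(map))
  if (nrow(genotypes) < 2)
    stop("at least two carriers are required")
  sides <- map_sides(map)
  hom_discord <- function(side) {
    for (k in seq_along(side$idx)) {
      g <- genotypes[, side$idx[k]]
      if (any(g == 0) && any(g == 2)) return(k)
    }
    NA_integer_
  }
  jl <- hom_discord(sides$left)
  jr <- hom_discord(sides$right)
  start <- if (is.na(jl)) sides$left$pos[length(sides$left$pos)]
           else sides$left$pos[jl]
  end <- if (is.na(jr)) sides$right$pos[length(sides$right$pos)]
         else sides$right$pos[jr]
  structure(list(start = start, end = end,
                 left_marker = if (is.na(jl)) NA_character_
                               else sides$left$id[jl],
                 right_marker = if (is.na(jr)) NA_character_
                                else sides$right$id[jr],
                 length_bp = end - start,
                 censored_left = is.na(jl), censored_right = is.na(jr),
                 pairwise = NULL),
            class = "shared_interval")
}

#' Consensus ancestral haplotype among carriers
#'
#' Majority allele at each marker; ties resolved toward the first-listed
#' carrier.
#'
#' @param haplotypes 0/1 matrix, one row per carrier haplotype.
#' @return Integer vector of ancestral alleles.
#' @export
consensus_ancestral <- function(haplotypes) {
  stopifnot(is.matrix(haplotypes))
  apply(haplotypes, 2, function(col) {
    n1 <- sum(col == 1)
    if (n1 * 2 > length(col)) 1L
    else if (n1 * 2 < length(col)) 0L
    else col[1]
  })
}

#' First-discordance observations from carrier haplotypes
#'
#' For each carrier and each side of the focal variant, records the
#' outward index of the first marker at which the carrier differs from the
#' ancestral haplotype, or a censored flag when the carrier matches through
#' the last typed marker.  These are the sufficient observations for the
#' mutation-age likelihood.
#'
#' @param haplotypes 0/1 matrix of carrier haplotypes aligned to `map`.
#' @param map A [marker_map()].
#' @param ancestral Optional explicit ancestral haplotype (0/1 vector
#'   aligned to `map`); defaults to the carrier consensus
#'   ([consensus_ancestral()]).
#' @return A data frame of class `sharing_obs` with columns `carrier`,
#'   `side` (`"left"`/`"right"`), `j` (first-discordance index, `NA` when
#'   censored).
#' @export
sharing_obs_from_haplotypes <- function(haplotypes, map, ancestral = NULL) {
  stopifnot(is.matrix(haplotypes), ncol(haplotypes) == nrow(map))
  if (is.null(ancestral)) ancestral <- consensus_ancestral(haplotypes)
  stopifnot(length(ancestral) == nrow(map))
  sides <- map_sides(map)
  rows <- list()
  for (i in seq_len(nrow(haplotypes))) {
    for (s in c("left", "right")) {
      idx <- sides[[s]]$idx
      mismatch <- which(haplotypes[i, idx] != ancestral[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        carrier = i, side = s,
        j = if (length(mismatch)) mismatch[1] else NA_integer_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sharing_obs", class(out))
  out
}

#' Sharing observations from explicit per-side indices
#'
#' @param carrier Carrier identifiers (recycled against `side`/`j`).
#' @param side `"left"` or `"right"` per observation.
#' @param j First-discordance outward marker index, `NA` for censored
#'   (shared through the last typed marker).
#' @return A `sharing_obs` data frame.
#' @export
sharing_obs <- function(carrier, side, j) {
  out <- data.frame(carrier = carrier, side = side, j = as.integer(j))
  stopifnot(all(out$side %in% c("left", "right")))
  class(out) <- c("sharing_obs", class(out))
  out
}

# Per-side likelihood of a first-discordance observation, vectorized over
# a vector of candidate ages g.
#
# theta: recombination fractions focal -> marker (outward order)
# f:     chance-match (ancestral allele) frequencies, same order
# j:     observed first-discordance index, NA = censored at last marker
# mu_m:  per-generation marker mutation rate
side_likelihood <- function(theta, f, j, mu_m, g) {
  M <- length(theta)
  stopifnot(length(f) == M, M >= 1)
  # survival S_k = (1 - theta_k)^g for k = 0..M (theta_0 = 0), G x (M+1)
  S <- exp(outer(g, log1p(-c(0, theta))))
  A <- S[, 1:M, drop = FALSE] - S[, 2:(M + 1), drop = FALSE]  # A_k, k=1..M
  if (is.na(j)) {
    # shared through marker M: no recombination within the map, or
    # recombination at k followed by chance matching at k..M
    cumf_rev <- rev(cumprod(rev(f)))            # prod f_m, m = k..M
    L <- S[, M + 1] + as.vector(A %*% cumf_rev)
  } else {
    stopifnot(j >= 1, j <= M)
    # chance-match products prod_{m=k..j-1} f_m for k = 1..j
    if (j == 1) {
      match_prod <- 1
    } else {
      fp <- f[1:(j - 1)]
      match_prod <- c(rev(cumprod(rev(fp))), 1)
    }
    recomb_term <- as.vector(A[, 1:j, drop = FALSE] %*%
                               (match_prod * (1 - f[j])))
    mut_term <- S[, j + 1] * (1 - (1 - mu_m)^g)
    L <- recomb_term + mut_term
  }
  L
}

#' Log-likelihood of haplotype-sharing observations at a candidate age
#'
#' Likelihood of the observed per-carrier, per-side first discordances
#' from the ancestral haplotype, given `g` generations since the most
#' recent common ancestor.  For each side the ancestral segment survives
#' past marker `k` with probability `(1 - theta_k)^g`; after recombination
#' the carrier can continue to match the ancestral haplotype by chance
#' with the population allele frequencies, and a marker mutation can
#' produce a discordance without recombination.  Carriers and sides are
#' treated as independent.
#'
#' @param obs A [sharing_obs()] data frame.
#' @param map A [marker_map()].
#' @param g Candidate age(s) in generations (vectorized), each >= 1.
#' @return Log-likelihood value(s), one per element of `g`.
#' @export
sharing_likelihood <- function(obs, map, g) {
  stopifnot(inherits(obs, "sharing_obs"), nrow(obs) >= 1, all(g >= 1))
  sides <- map_sides(map)
  ll <- numeric(length(g))
  for (r in seq_len(nrow(obs))) {
    sd <- sides[[obs$side[r]]]
    if (!length(sd$theta))
      stop("no markers on the ", obs$side[r], " side of the focal variant")
    L <- side_likelihood(sd$theta, sd$freq, obs$j[r], sides$mu_m, g)
    ll <- ll + log(L)
  }
  ll
}

#' Maximum-likelihood mutation age from haplotype sharing
#'
#' Grid-search maximum-likelihood estimate of the number of generations
#' since the most recent common ancestor of the focal-variant carriers,
#' from their first-discordance observations, with a profile-likelihood
#' 95% confidence interval (log-likelihood within `qchisq(0.95, 1)/2` of
#' the maximum).  Estimates or interval ends on the grid boundary are
#' flagged rather than treated as errors, since monotone likelihoods are
#' legitimate outcomes for uninformative data.
#'
#' @param obs A [sharing_obs()] data frame.
#' @param map A [marker_map()].
#' @param g_grid Integer grid of candidate ages (default `1:5000`).
#' @param conf_level Confidence level for the profile interval.
#' @return An object of class `age_estimate`: `g_hat`, `ci_low`,
#'   `ci_high`, `boundary` (logical), `loglik` (data frame over the grid).
#' @export
estimate_age <- function(obs, map, g_grid = 1:5000, conf_level = 0.95) {
  stopifnot(length(g_grid) >= 2, all(g_grid >= 1))
  g_grid <- sort(unique(as.integer(g_grid)))
  ll <- sharing_likelihood(obs, map, g_grid)
  imax <- which.max(ll)
  g_hat <- g_grid[imax]
  thresh <- ll[imax] - stats::qchisq(conf_level, df = 1) / 2
  inside <- which(ll >= thresh)
  ci_low <- g_grid[min(inside)]
  ci_high <- g_grid[max(inside)]
  boundary <- imax == 1L || imax == length(g_grid) ||
    ci_low == g_grid[1] || ci_high == g_grid[length(g_grid)]
  structure(list(g_hat = g_hat, ci_low = ci_low, ci_high = ci_high,
                 boundary = boundary, conf_level = conf_level,
                 loglik = data.frame(g = g_grid, loglik = ll)),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat("Mutation age: ", x$g_hat, " generations (",
      round(100 * x$conf_level), "% CI ", x$ci_low, "-", x$ci_high, ")",
      if (x$boundary) " [estimate or interval hits the search boundary]",
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.age_estimate <- function(x, ...) {
  plot(x$loglik$g, x$loglik$loglik, type = "l", log = "x",
       xlab = "generations since common ancestor",
       ylab = "log-likelihood", ...)
  graphics::abline(v = c(x$ci_low, x$g_hat, x$ci_high),
                   lty = c(3, 2, 3))
  invisible(x)
}
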
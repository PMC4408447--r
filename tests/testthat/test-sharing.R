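test_that("Haldane recombination fractions behave", {
  expect_equal(recomb_fraction(0, 2.9), 0)
  d <- 1e6 * 2.9 / 1e8
  expect_equal(recomb_fraction(1e6, 2.9), (1 - exp(-2 * d)) / 2,
               tolerance = 1e-12)
  expect_equal(recomb_fraction(1e6, 2.9), 0.02818, tolerance = 3e-4)
  expect_equal(recomb_fraction(1e9, 2.9), 0.5, tolerance = 1e-6)
  expect_error(recomb_fraction(-1), "non-negative")
  # monotone
  d_grid <- seq(0, 5e6, by = 1e5)
  expect_true(all(diff(recomb_fraction(d_grid)) > 0))
})

test_that("phased shared interval finds the innermost discordant markers", {
  map <- synthetic_marker_map(n_side = 5, spacing_bp = 1e4,
                              focal_pos = 1e6)
  anc <- rep(0L, nrow(map))
  # identical haplotypes: interval spans the whole typed region
  haps <- rbind(anc, anc)
  si <- shared_interval_phased(haps, map)
  expect_true(si$censored_left && si$censored_right)
  expect_equal(si$start, min(map$pos_bp))
  expect_equal(si$end, max(map$pos_bp))
  # constructed discordance: left outward index 3, right outward index 2
  h2 <- anc
  h2[3] <- 1L     # left side outward index 3 (positions 5,4,3 outward)
  h2[7] <- 1L     # right side outward index 2 (positions 6,7,... outward)
  si2 <- shared_interval_phased(rbind(anc, h2), map)
  expect_equal(si2$start, map$pos_bp[3])
  expect_equal(si2$end, map$pos_bp[7])
  expect_equal(si2$length_bp, map$pos_bp[7] - map$pos_bp[3])
  expect_error(shared_interval_phased(haps[1, , drop = FALSE], map),
               "at least two")
})

test_that("shared interval equals a brute-force all-pairs scan on random haplotypes", {
  map <- synthetic_marker_map(n_side = 12, spacing_bp = 2e4,
                              focal_pos = 2e6)
  set.seed(42)
  for (rep in 1:10) {
    # planted shared core of 6 markers per side around the focal variant
    haps <- matrix(rbinom(3 * nrow(map), 1, 0.5), nrow = 3)
    core <- c(7:12, 13:18)   # innermost 6 on each side (map rows)
    for (cc in core) haps[, cc] <- haps[1, cc]
    si <- shared_interval_phased(haps, map)
    # oracle: scan marker rows outward from the focal position
    left_rows <- 12:1; right_rows <- 13:24
    first_disc <- function(rows) {
      for (r in rows)
        if (length(unique(haps[, r])) > 1) return(r)
      NA_integer_
    }
    dl <- first_disc(left_rows); dr <- first_disc(right_rows)
    expect_equal(si$start,
                 if (is.na(dl)) map$pos_bp[1] else map$pos_bp[dl])
    expect_equal(si$end,
                 if (is.na(dr)) map$pos_bp[24] else map$pos_bp[dr])
  }
})

test_that("unphased homozygous-discordant bound contains the phased interval", {
  map <- synthetic_marker_map(n_side = 8, spacing_bp = 1e4,
                              focal_pos = 1e6)
  # hom-discordant markers adjacent to the focal variant on both sides
  g <- matrix(1L, nrow = 2, ncol = nrow(map))
  g[1, 8] <- 0L; g[2, 8] <- 2L
  g[1, 9] <- 2L; g[2, 9] <- 0L
  b <- discordance_bound_unphased(g, map)
  expect_equal(b$start, map$pos_bp[8])
  expect_equal(b$end, map$pos_bp[9])
  # all-het genotypes exclude nothing
  g2 <- matrix(1L, nrow = 3, ncol = nrow(map))
  b2 <- discordance_bound_unphased(g2, map)
  expect_true(b2$censored_left && b2$censored_right)
  expect_equal(b2$length_bp, max(map$pos_bp) - min(map$pos_bp))
})

test_that("phased interval is contained in the unphased bound on simulated data", {
  map <- synthetic_marker_map(n_side = 15, spacing_bp = 5e4)
  anc <- rep(0L, nrow(map))
  for (seed in 1:8) {
    sim <- simulate_descendant_haplotypes(anc, map, g = 150,
                                          n_carriers = 3, seed = seed)
    gt <- simulate_carrier_genotypes(sim$haplotypes, map,
                                     seed = seed + 100)
    si <- shared_interval_phased(sim$haplotypes, map)
    db <- discordance_bound_unphased(gt, map)
    expect_gte(si$start, db$start)
    expect_lte(si$end, db$end)
  }
})

test_that("sharing likelihood matches closed forms and conserves probability", {
  # one marker per side, f ~ 0, no mutation: P(discordant at 1) =
  # 1 - (1 - theta_1)^g, increasing in g
  map1 <- marker_map(id = c("L1", "R1"), pos_bp = c(1, 2000001),
                     freq = c(1e-12, 1e-12), focal_pos = 1000001,
                     mu_m = 0)
  th <- recomb_fraction(1e6, 2.9)
  obs <- sharing_obs("c1", "right", 1L)
  g_grid <- c(10, 100, 500)
  ll <- sharing_likelihood(obs, map1, g_grid)
  expect_equal(ll, log(1 - (1 - th)^g_grid), tolerance = 1e-9)
  expect_true(all(diff(ll) > 0))
  # fully censored with f ~ 0: P = (1 - theta_M)^g on each side,
  # strictly decreasing in g
  obs_c <- sharing_obs(c("c1", "c1"), c("left", "right"),
                       c(NA_integer_, NA_integer_))
  ll_c <- sharing_likelihood(obs_c, map1, g_grid)
  expect_equal(ll_c, 2 * g_grid * log1p(-th), tolerance = 1e-6)
  expect_true(all(diff(ll_c) < 0))
})

test_that("sharing likelihood equals exhaustive enumeration over breakpoints", {
  map <- synthetic_marker_map(n_side = 3, spacing_bp = 3e5, freq = 0.6,
                              mu_m = 0)
  sides <- aldorecur:::map_sides(map)
  for (g in c(5, 60, 400)) {
    total <- 0
    for (j in c(1:3, NA)) {
      lik <- aldorecur:::side_likelihood(sides$right$theta,
                                         sides$right$freq,
                                         if (is.na(j)) NA else j, 0, g)
      oracle <- enum_side_prob(sides$right$theta, sides$right$freq,
                               if (is.na(j)) NA_integer_ else j, g)
      expect_equal(lik, oracle, tolerance = 1e-10,
                   label = sprintf("g=%d j=%s", g, j))
      total <- total + lik
    }
    expect_equal(total, 1, tolerance = 1e-10)  # conservation
  }
})

test_that("age estimation flags boundary solutions for degenerate observations", {
  map <- synthetic_marker_map(n_side = 10, spacing_bp = 5e4)
  # all sides censored: likelihood maximal at the smallest age
  obs_c <- sharing_obs(rep(1:3, each = 2), rep(c("left", "right"), 3),
                       rep(NA_integer_, 6))
  est <- estimate_age(obs_c, map, g_grid = 1:500)
  expect_equal(est$g_hat, 1)
  expect_true(est$boundary)
  # discordance at the first marker with negligible chance matching:
  # likelihood increases with age without bound
  map0 <- synthetic_marker_map(n_side = 4, spacing_bp = 5e4,
                               freq = 1e-9, mu_m = 0)
  est2 <- estimate_age(sharing_obs("c1", "right", 1L), map0,
                       g_grid = 1:500)
  expect_equal(est2$g_hat, 500)
  expect_true(est2$boundary)
})

test_that("age estimation recovers the generating age from simulated carriers", {
  map <- synthetic_marker_map()
  anc <- rep(0L, nrow(map))
  g_true <- 100
  ests <- vapply(1:15, function(seed) {
    sim <- simulate_descendant_haplotypes(anc, map, g = g_true,
                                          n_carriers = 4, seed = seed)
    obs <- sharing_obs_from_haplotypes(sim$haplotypes, map,
                                       ancestral = anc)
    estimate_age(obs, map, g_grid = 1:2000)$g_hat
  }, 0)
  expect_gt(stats::median(ests), 70)
  expect_lt(stats::median(ests), 140)
})

test_that("age estimate is invariant to uninformative map padding", {
  # appending markers whose ancestral allele frequency is ~1 beyond the
  # last informative marker cannot change the likelihood
  base <- synthetic_marker_map(n_side = 6, spacing_bp = 5e4,
                               focal_pos = 1e6)
  obs <- sharing_obs(c(1, 1), c("left", "right"), c(3L, 4L))
  padded <- marker_map(
    id = c(base$id, "pad1", "pad2"),
    pos_bp = c(base$pos_bp, max(base$pos_bp) + c(1e4, 2e4)),
    freq = c(base$freq, 1 - 1e-12, 1 - 1e-12),
    focal_pos = attr(base, "focal_pos"),
    rate_cM_per_Mb = attr(base, "rate_cM_per_Mb"),
    mu_m = attr(base, "mu_m"))
  e1 <- estimate_age(obs, base, g_grid = 1:1000)
  e2 <- estimate_age(obs, padded, g_grid = 1:1000)
  expect_equal(e1$g_hat, e2$g_hat)
  expect_equal(e1$ci_low, e2$ci_low)
  expect_equal(e1$ci_high, e2$ci_high)
})

test_that("plink map, haplotype and frequency files round-trip", {
  mapf <- tempfile(fileext = ".map")
  writeLines(c("16\trs1\t0\t1000", "16\trs2\t0\t2000",
               "16\trs3\t0\t3000"), mapf)
  pm <- read_plink_map(mapf)
  expect_equal(pm$pos_bp, c(1000, 2000, 3000))
  hapf <- tempfile(fileext = ".tsv")
  writeLines(c("subject\talleles\tcarries_focal",
               "K1\t0|1|0\tTRUE", "K2\t0|1|1\tTRUE"), hapf)
  hp <- read_haplotypes_tsv(hapf)
  expect_true(hp$phased)
  expect_equal(dim(hp$alleles), c(2L, 3L))
  fqf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfreq", "rs1\t0.7", "rs2\t0.5", "rs3\t0.9"), fqf)
  expect_equal(read_marker_freqs(fqf)$freq, c(0.7, 0.5, 0.9))
})
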
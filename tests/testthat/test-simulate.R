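test_that("deterministic traces vanish at the reversal potential and show mutant tails", {
  wt <- default_gating_params("WT")
  mut <- default_gating_params("M1549V")
  prot_rev <- voltage_protocol(c(60, 60), c(10, 50), dt = 0.1)
  ens <- simulate_deterministic(wt, prot_rev)
  expect_true(all(ens$current == 0))
  # 400 ms step to -20 mV, then repolarization: tail current only in the
  # mutant
  prot <- voltage_protocol(c(-90, -20, -90), c(50, 400, 50), dt = 0.1)
  tail_peak <- function(p) {
    e <- simulate_deterministic(p, prot)
    sel <- e$time >= 450
    max(abs(e$current[sel, 1]))
  }
  step_peak <- function(p) {
    e <- simulate_deterministic(p, prot)
    sel <- e$time >= 50 & e$time < 450
    max(abs(e$current[sel, 1]))
  }
  wt_ratio <- tail_peak(wt) / step_peak(wt)
  mut_ratio <- tail_peak(mut) / step_peak(mut)
  expect_lt(wt_ratio, 0.06)
  expect_gt(mut_ratio, 0.2)
  expect_gt(mut_ratio / wt_ratio, 5)
})

test_that("deterministic integration is exact in the step size", {
  p <- default_gating_params("WT")
  prot1 <- voltage_protocol(c(-90, -20, -90), c(20, 100, 20), dt = 0.2)
  prot2 <- voltage_protocol(c(-90, -20, -90), c(20, 100, 20), dt = 0.1)
  e1 <- simulate_deterministic(p, prot1)
  e2 <- simulate_deterministic(p, prot2)
  common <- match(e1$time, e2$time)
  expect_false(anyNA(common))
  rel <- max(abs(e1$current[, 1] - e2$current[common, 1])) /
    max(abs(e1$current))
  expect_lt(rel, 1e-3)
})

test_that("stochastic simulation is reproducible and seed-sensitive", {
  p <- default_gating_params("WT")
  p$N <- 500
  prot <- noise_protocol(hold_ms = 10, activate_ms = 20, tail_ms = 10,
                         dt = 0.2)
  a <- simulate_stochastic(p, prot, n_sweeps = 5, seed = 9)
  b <- simulate_stochastic(p, prot, n_sweeps = 5, seed = 9)
  d <- simulate_stochastic(p, prot, n_sweeps = 5, seed = 10)
  expect_identical(a$current, b$current)
  expect_false(identical(a$current, d$current))
  expect_error(simulate_stochastic(p, prot, n_sweeps = 5),
               "seed")
  expect_error(simulate_stochastic(p, prot, n_sweeps = 1e9, seed = 1),
               "guard")
})

test_that("ensemble mean converges to the deterministic trace", {
  p <- default_gating_params("WT")
  p$N <- 2000
  p$noise_sd_pA <- 1
  prot <- noise_protocol(hold_ms = 10, activate_ms = 40, tail_ms = 20,
                         dt = 0.2)
  M <- 500
  sto <- simulate_stochastic(p, prot, n_sweeps = M, seed = 42)
  det <- simulate_deterministic(p, prot)
  mean_t <- rowMeans(sto$current)
  se_t <- apply(sto$current, 1, stats::sd) / sqrt(M)
  dev <- abs(mean_t - det$current[, 1]) / pmax(se_t, 1e-9)
  # pointwise z-scores: allow a small fraction above 3 by chance
  expect_lt(mean(dev > 3), 0.01)
  expect_lt(max(abs(mean_t - det$current[, 1])) /
              max(abs(det$current)), 0.05)
})

test_that("isochronal variance obeys the binomial channel-gating law", {
  p <- default_gating_params("WT")
  p$N <- 2000
  p$noise_sd_pA <- 1
  prot <- noise_protocol(hold_ms = 10, activate_ms = 40, tail_ms = 20,
                         dt = 0.2)
  M <- 600
  sto <- simulate_stochastic(p, prot, n_sweeps = M, seed = 7)
  det <- simulate_deterministic(p, prot)
  i_tail <- p$gamma_pS * (-20 - p$V_rev) / 1000
  # during the activating step: p_open from the deterministic trace
  sel <- which(sto$time >= 12 & sto$time < 50)
  p_open <- det$current[sel, 1] / (p$N * i_tail)
  pred <- p$N * i_tail^2 * p_open * (1 - p_open) + p$noise_sd_pA^2
  obs <- apply(sto$current[sel, ], 1, stats::var)
  # moment-based standard error of a sample variance
  z <- (obs - pred) / (pred * sqrt(2 / (M - 1)))
  expect_lt(mean(abs(z) > 3), 0.02)
})

test_that("descendant haplotypes reduce to full sharing without recombination or mutation", {
  map <- synthetic_marker_map(n_side = 8, spacing_bp = 100,
                              rate_cM_per_Mb = 1e-9, mu_m = 0,
                              focal_pos = 1e6)
  anc <- rep(1L, nrow(map))
  sim <- simulate_descendant_haplotypes(anc, map, g = 5000,
                                        n_carriers = 5, seed = 3)
  expect_true(all(sim$haplotypes == 1L))
  expect_true(all(is.na(sim$obs$j)))
})

test_that("first-marker discordance approaches 1 - f at large age", {
  # distant first marker (theta ~ 0.5) and very old mutation: the
  # ancestral segment never survives, so the first marker matches only
  # by chance
  f1 <- 0.6
  map <- marker_map(id = c("L", "R"), pos_bp = c(1, 6e8 + 7),
                    freq = c(f1, f1), focal_pos = 7, mu_m = 0)
  anc <- c(0L, 0L)
  hits <- vapply(1:400, function(s) {
    sim <- simulate_descendant_haplotypes(anc, map, g = 4000,
                                          n_carriers = 1, seed = s)
    j <- sim$obs$j[sim$obs$side == "right"]
    identical(j, 1L)
  }, TRUE)
  phat <- mean(hits)
  se <- sqrt(phat * (1 - phat) / length(hits))
  expect_lt(abs(phat - (1 - f1)), 3 * se + 0.01)
})

test_that("cohort simulator plants a recoverable recurrent variant", {
  sim <- simulate_cohort(n_subjects = 40, n_variants = 150,
                         n_planted_carriers = 5, seed = 11)
  res <- recurrent_novel_variants(sim$variants)
  expect_equal(nrow(res), 1)
  expect_equal(res$pos, sim$planted$pos)
  expect_equal(strsplit(res$subjects, ",")[[1]], sim$carriers)
  # identical seed reproduces the tables exactly
  sim2 <- simulate_cohort(n_subjects = 40, n_variants = 150,
                          n_planted_carriers = 5, seed = 11)
  expect_identical(as.data.frame(sim$variants),
                   as.data.frame(sim2$variants))
  expect_identical(sim$labs, sim2$labs)
  # planted carriers screen as indicative, others do not
  cls <- vapply(seq_len(nrow(sim$labs)), function(i) {
    classify_pa(lab_panel(sim$labs$aldo[i], pra = sim$labs$pra[i],
                          potassium = sim$labs$k[i],
                          subject = sim$labs$subject[i]))$indicative
  }, TRUE)
  expect_setequal(sim$labs$subject[cls], sim$carriers)
})

test_that("ensemble TSV round-trip preserves traces and protocol", {
  p <- default_gating_params("WT")
  prot <- voltage_protocol(c(-90, -20), c(5, 10), dt = 0.5)
  ens <- simulate_deterministic(p, prot)
  path <- tempfile(fileext = ".tsv")
  write_ensemble_tsv(ens, path)
  back <- read_ensemble_tsv(path)
  expect_equal(back$time, ens$time)
  expect_equal(unname(back$current[, 1]), unname(ens$current[, 1]),
               tolerance = 1e-6)
  expect_equal(back$protocol$durations, prot$durations)
})
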
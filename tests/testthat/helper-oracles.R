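# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (enumeration, grid search) so that they cannot share
# a failure mode with the package implementations they check.

# P(exactly k successes) and P(>= k) in n Bernoulli(p) trials by full
# outcome enumeration (n small)
enum_binom <- function(n, k, p) {
  stopifnot(n <= 20)
  outcomes <- expand.grid(rep(list(0:1), n))
  succ <- rowSums(outcomes)
  prob <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  c(exact = sum(prob[succ == k]), tail = sum(prob[succ >= k]))
}

# two-sided Fisher p-value by hypergeometric enumeration: sum of the
# probabilities of all tables (fixed margins) no more likely than observed
enum_fisher_two_sided <- function(a, case_n, ctrl_carriers, ctrl_n) {
  m <- a + ctrl_carriers            # total carriers
  lo <- max(0, m - ctrl_n)
  hi <- min(m, case_n)
  probs <- stats::dhyper(lo:hi, case_n, ctrl_n, m)
  p_obs <- stats::dhyper(a, case_n, ctrl_n, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-pass brute-force filter for recurrent novel protein-altering
# variants
brute_recurrent <- function(df, min_subjects, classes) {
  keys <- unique(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  hits <- character()
  for (k in keys) {
    sub <- df[paste(df$chrom, df$pos, df$ref, df$alt, sep = ":") == k, ]
    if (any(sub$known)) next
    if (!all(sub$consequence %in% classes)) next
    if (length(unique(sub$subject)) >= min_subjects) hits <- c(hits, k)
  }
  sort(hits)
}

# 1-D grid-search least-squares oracle for a mono-exponential decay with
# offset: profile amplitude/offset analytically at each tau
grid_tau_oracle <- function(t, y, tau_grid) {
  best <- c(tau = NA_real_, sse = Inf)
  for (tau in tau_grid) {
    x <- exp(-(t - t[1]) / tau)
    fit <- stats::lm(y ~ x)
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best["sse"]) best <- c(tau = tau, sse = sse)
  }
  best["tau"]
}

# grid-search oracle for the saturating recovery curve y0 + a(1-exp(-t/tau))
grid_recovery_oracle <- function(t, y, tau_grid) {
  best <- c(tau = NA_real_, sse = Inf)
  for (tau in tau_grid) {
    x <- 1 - exp(-t / tau)
    fit <- stats::lm(y ~ x)
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best["sse"]) best <- c(tau = tau, sse = sse)
  }
  best["tau"]
}

# exhaustive-enumeration oracle for the first-discordance probability on
# one side with M markers: sums over the breakpoint position and every
# post-breakpoint allele pattern (mu_m = 0)
enum_side_prob <- function(theta, f, j_obs, g) {
  M <- length(theta)
  stopifnot(M <= 6)
  S <- (1 - c(0, theta))^g
  p_break <- c(S[1:M] - S[2:(M + 1)], S[M + 1])  # break before k / none
  total <- 0
  for (k in seq_len(M + 1)) {
    if (k > M) {
      # segment survives the whole map: discordance impossible
      if (is.na(j_obs)) total <- total + p_break[k]
      next
    }
    pop <- k:M
    n_pop <- length(pop)
    for (pattern in 0:(2^n_pop - 1)) {
      bits <- as.integer(intToBits(pattern))[seq_len(n_pop)]  # 1 = match
      pr <- prod(ifelse(bits == 1, f[pop], 1 - f[pop]))
      mism <- pop[bits == 0]
      j_sim <- if (length(mism)) min(mism) else NA_integer_
      if (identical(j_sim, j_obs) ||
          (is.na(j_obs) && is.na(j_sim)))
        total <- total + p_break[k] * pr
    }
  }
  total
}

# deterministic m^2 h trace evaluated on an arbitrarily fine grid via the
# closed-form segment solution (re-derived here independently of the
# simulator's bookkeeping)
analytic_trace <- function(params, segments, t_dense) {
  # segments: data.frame(voltage, duration)
  edges <- cumsum(c(0, segments$duration))
  m <- 1 / (1 + exp((params$V_half_act - segments$voltage[1]) /
                      params$k_act))
  h <- 1 / (1 + exp((segments$voltage[1] - params$V_half_inact) /
                      params$k_inact))
  out <- numeric(length(t_dense))
  for (i in seq_len(nrow(segments))) {
    V <- segments$voltage[i]
    mi <- 1 / (1 + exp((params$V_half_act - V) / params$k_act))
    hi <- 1 / (1 + exp((V - params$V_half_inact) / params$k_inact))
    tm <- params$tau_act_min + params$tau_act_amp *
      exp(-((V - params$tau_act_vpeak) / params$tau_act_width)^2)
    depol <- params$tau_inact_ref *
      exp(-(V - params$v_tau_ref) / params$k_tau_inact)
    w <- 1 / (1 + exp((V - params$v_rec_mix) / params$k_rec_mix))
    th <- (1 - w) * depol + w * params$tau_rec
    sel <- t_dense >= edges[i] & t_dense < edges[i + 1]
    tr <- t_dense[sel] - edges[i]
    mt <- mi + (m - mi) * exp(-tr / tm)
    ht <- hi + (h - hi) * exp(-tr / th)
    out[sel] <- params$N * params$gamma_pS * (V - params$V_rev) / 1000 *
      mt^2 * ht
    m <- mi + (m - mi) * exp(-segments$duration[i] / tm)
    h <- hi + (h - hi) * exp(-segments$duration[i] / th)
  }
  out
}

# small random cohort variant data frame; annotation (gene, consequence,
# known) is a property of the variant, not of the carrier row
random_cohort_df <- function(n_rows, seed) {
  set.seed(seed)
  classes <- c(protein_altering_classes(), "synonymous", "intronic")
  n_var <- 40
  var_tab <- data.frame(
    chrom = sample(c("chr1", "chr16"), n_var, replace = TRUE),
    pos = sample.int(1e6, n_var),
    ref = "A", alt = "G",
    gene = sample(sprintf("G%02d", 1:8), n_var, replace = TRUE),
    consequence = sample(classes, n_var, replace = TRUE),
    known = stats::runif(n_var) < 0.5, stringsAsFactors = FALSE)
  rows <- var_tab[sample.int(n_var, n_rows, replace = TRUE), ]
  rows$subject <- sample(sprintf("S%02d", 1:12), n_rows, replace = TRUE)
  rows$genotype <- "het"
  rows[!duplicated(paste(rows$pos, rows$subject)), ]
}
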
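# Shared fixtures and independent oracles, built in code at test time.

# A proportions table lying exactly on a cumulative Gaussian (mu, sigma).
exact_props <- function(mu, sigma, soas, n_per_level) {
  data.frame(soa_ms = soas, n = n_per_level,
             k = round(n_per_level * pnorm((soas - mu) / sigma)))
}

# Long participant x condition outcome table for ANOVA tests:
# participant random intercept + optional group shift + noise.
make_jnd_long <- function(N = 30, group_shift = c(HC = 0, BD = 0, SZ = 0),
                          subj_sd = 30, noise_sd = 20, seed = 1) {
  set.seed(seed)
  stopifnot(N %% 3 == 0)
  ids <- sprintf("P%02d", seq_len(N))
  grp <- rep(c("HC", "BD", "SZ"), each = N / 3)
  base <- 100 + group_shift[grp] + rnorm(N, 0, subj_sd)
  age <- rnorm(N, 45, 12)
  data.frame(
    participant_id = rep(ids, each = 3),
    group = rep(grp, each = 3),
    age = rep(age, each = 3),
    condition = rep(c("AT", "AV", "VT"), N),
    jnd_ms = rep(base, each = 3) + rnorm(3 * N, 0, noise_sd))
}

# Exhaustive pair-count oracle for Kendall tau-b, following the
# (C - D) / sqrt((C + D + Tx)(C + D + Ty)) definition directly.
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  C <- D <- Tx <- Ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

welch_t_oracle <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# Simulated observer truth recast as a psychometric-estimates table
# (used to exercise screening stages without session simulation).
truth_as_estimates <- function(cohort) {
  tt <- observer_truth(cohort$observers)
  do.call(rbind, lapply(c("AT", "AV", "VT"), function(cc)
    data.frame(participant_id = tt$participant_id, condition = cc,
               jnd_ms = tt$true_jnd, group = tt$group)))
}

# Normalized QUEST posterior, recomputed outside the package internals.
quest_posterior_for_test <- function(state) {
  p <- exp(state$log_posterior)
  p / sum(p)
}

# Small complete synthetic study for pipeline tests (cached per session).
small_study_config <- function(seed = 42, n = c(HC = 6, BD = 6, SZ = 6)) {
  cohort_config(n_per_group = n, rng_seed = seed)
}
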
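test_that("kendall_tau_b matches exhaustive pair counting", {
  expect_equal(kendall_tau_b(1:5, 1:5)$tau_b, 1)
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3))$tau_b, 1 / 3)

  set.seed(10)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    x <- sample(1:8, n, replace = TRUE)  # heavy ties
    y <- sample(1:8, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y)$tau_b, tau_b_bruteforce(x, y),
                 tolerance = 1e-12)
  }
})

test_that("kendall_tau_b antisymmetry, ties, and error paths", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  a <- kendall_tau_b(x, y)
  b <- kendall_tau_b(x, -y)
  expect_equal(b$tau_b, -a$tau_b)
  expect_equal(b$z, -a$z)
  expect_equal(b$p, a$p)
  expect_warning(r <- kendall_tau_b(c(1, 1, 1), c(1, 2, 3)), "all-tied")
  expect_true(is.na(r$tau_b))
  expect_error(kendall_tau_b(c(1, 2), c(1, 2)), "at least 3")
})

test_that("clinical screening detects the PANSS-positive coupling", {
  runs <- 60
  hit <- 0
  for (i in seq_len(runs)) {
    cfg <- cohort_config(n_per_group = c(HC = 2, BD = 20, SZ = 21),
                         rng_seed = 1000 + i)
    co <- generate_cohort(cfg)
    cs <- clinical_screen(truth_as_estimates(co), co$participants)
    pp <- cs[cs$scale == "panss_pos", ]
    if (pp$tau_b > 0 && pp$p_bonferroni == min(cs$p_bonferroni))
      hit <- hit + 1
  }
  # coupled scale should dominate the family far above the 1/4 chance rate
  expect_gte(hit / runs, 0.6)
})

test_that("clinical screening is calibrated under the uncoupled null", {
  runs <- 50
  rej <- 0
  for (i in seq_len(runs)) {
    cfg <- cohort_config(n_per_group = c(HC = 2, BD = 20, SZ = 21),
                         glm_beta1 = 0, rng_seed = 5000 + i)
    co <- generate_cohort(cfg)
    cs <- clinical_screen(truth_as_estimates(co), co$participants)
    if (any(cs$p_bonferroni < 0.05)) rej <- rej + 1
  }
  expect_lte(rej / runs, 0.1)  # familywise error near or below alpha
})

test_that("screening uses patients only and applies the family of 4", {
  cfg <- cohort_config(n_per_group = c(HC = 10, BD = 12, SZ = 12),
                       rng_seed = 3)
  co <- generate_cohort(cfg)
  cs <- clinical_screen(truth_as_estimates(co), co$participants)
  expect_setequal(cs$scale, c("panss_pos", "panss_neg", "ymrs", "hamd"))
  expect_true(all(cs$n <= 24))
  expect_equal(cs$p_bonferroni, pmin(1, 4 * cs$p))
  ms <- medication_screen(truth_as_estimates(co), co$participants)
  expect_equal(nrow(ms), 4)
  expect_true(all(ms$n <= 24))  # missing doses dropped pairwise
})

test_that("NB GLM recovers simulated coefficients and flags bad input", {
  set.seed(8)
  jnd <- runif(800, 30, 400)
  y <- rnbinom(800, mu = exp(2.5 + 0.002 * jnd), size = 8)
  f <- nb_glm_fit(y, jnd)
  expect_true(f$converged)
  expect_lt(abs(f$beta1 - 0.002), 2 * f$se_beta1)
  expect_gt(f$dispersion_theta, 2)
  expect_error(nb_glm_fit(c(1.5, 2, 3, 4, 5, 6), 1:6), "integers")
  expect_error(nb_glm_fit(c(1, 2, 3), 1:3), "at least 5")
})

test_that("NB fit approaches the Poisson fit in the equidispersed limit", {
  set.seed(9)
  jnd <- runif(1500, 30, 400)
  y <- rpois(1500, exp(2 + 0.003 * jnd))
  f <- nb_glm_fit(y, jnd)
  pois <- glm(y ~ jnd, family = poisson())
  expect_equal(f$beta0, unname(coef(pois)[1]), tolerance = 1e-3)
  expect_equal(f$beta1, unname(coef(pois)[2]), tolerance = 1e-3)
})

test_that("null slopes give Wald z centered on zero", {
  set.seed(12)
  zs <- replicate(20, {
    jnd <- runif(120, 30, 400)
    y <- rnbinom(120, mu = exp(2.7), size = 8)
    nb_glm_fit(y, jnd)$wald_z
  })
  expect_lt(abs(mean(zs)), 2 / sqrt(20) * 1.5)
  expect_lt(mean(abs(zs) > 1.96), 0.2)
})

test_that("Nagelkerke R2 follows its closed form and bounds", {
  expect_equal(nagelkerke_r2(-50, -50, 30), 0)
  cs <- 1 - exp(2 * (-100 + 80) / 41)
  expect_equal(nagelkerke_r2(-80, -100, 41), cs / (1 - exp(-200 / 41)))
  # monotone increasing in the full-model log-likelihood
  lls <- seq(-99, -60, length.out = 10)
  r2 <- vapply(lls, nagelkerke_r2, numeric(1), loglik_null = -100, n = 41)
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_error(nagelkerke_r2(-120, -100, 41), "loglik_full")
  expect_error(nagelkerke_r2(-80, -100, 0), "positive")
})
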
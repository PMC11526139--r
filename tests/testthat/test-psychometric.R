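test_that("aggregate_proportions counts reference-first reports", {
  tr <- data.frame(participant_id = "p", condition = "AT",
                   trial_index = 1:4, soa_ms = c(-100, -100, 100, 100),
                   response = c("A", "A", "T", "T"),
                   skipped = FALSE)
  agg <- aggregate_proportions(tr, "AT")
  expect_equal(agg$soa_ms, c(-100, 100))
  expect_equal(agg$n, c(2, 2))
  expect_equal(agg$k, c(2, 0))
  expect_true(all(agg$k / agg$n >= 0 & agg$k / agg$n <= 1))

  tr$skipped <- TRUE
  expect_error(aggregate_proportions(tr, "AT"), "zero usable")
})

test_that("ML fit is consistent on exact on-curve data", {
  props <- exact_props(0, 100, c(-400, -150, -50, 50, 150, 400), 1e6)
  f <- fit_cumulative_gaussian(props)
  expect_true(f$converged)
  expect_lt(abs(f$pse_ms - 0), 1)
  expect_lt(abs(f$sigma_ms - 100) / 100, 0.01)
})

test_that("antisymmetric data give a zero PSE", {
  props <- data.frame(soa_ms = c(-200, -80, 80, 200),
                      n = c(20, 20, 20, 20), k = c(2, 7, 13, 18))
  f <- fit_cumulative_gaussian(props)
  expect_lt(abs(f$pse_ms), 0.01)
})

test_that("ML fit matches an exhaustive 1-ms grid search", {
  props <- data.frame(soa_ms = c(-300, -150, -60, 60, 150, 300),
                      n = rep(18, 6), k = c(1, 4, 7, 12, 15, 17))
  f <- fit_cumulative_gaussian(props)
  nll <- function(mu, sigma) {
    psi <- pnorm((props$soa_ms - mu) / sigma)
    psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
    -sum(props$k * log(psi) + (props$n - props$k) * log(1 - psi))
  }
  grid <- expand.grid(mu = seq(-100, 100, 1), sigma = seq(10, 400, 1))
  vals <- mapply(nll, grid$mu, grid$sigma)
  best <- grid[which.min(vals), ]
  expect_lte(abs(f$pse_ms - best$mu), 1)
  expect_lte(abs(f$sigma_ms - best$sigma), 1)
})

test_that("perfect separation is flagged as a non-identifiable floor fit", {
  props <- data.frame(soa_ms = c(-300, -200, 200, 300),
                      n = rep(10, 4), k = c(0, 0, 10, 10))
  f <- fit_cumulative_gaussian(props)
  expect_true(f$sigma_at_floor)
  expect_false(f$converged)
  expect_warning(j <- compute_jnd(f), "non-converged")
  expect_true(is.na(j))
  expect_error(fit_cumulative_gaussian(
    data.frame(soa_ms = 50, n = 20, k = 10)), "distinct SOA")
})

test_that("JND equals half the interquartile span of the fitted curve", {
  for (sigma in c(1, 50, 800)) {
    f <- structure(list(sigma_ms = sigma, converged = TRUE),
                   class = "psychometric_fit")
    # quantile-difference form, located numerically on the curve
    x75 <- uniroot(function(s) pnorm(s / sigma) - 0.75,
                   c(-10 * sigma, 10 * sigma), tol = 1e-12)$root
    x25 <- uniroot(function(s) pnorm(s / sigma) - 0.25,
                   c(-10 * sigma, 10 * sigma), tol = 1e-12)$root
    expect_equal(compute_jnd(f), (x75 - x25) / 2,
                 tolerance = 1e-9)
  }
  expect_equal(100 * qnorm(0.75), 67.449, tolerance = 1e-3)
})

test_that("flipping the SOA sign convention negates PSE, preserves JND", {
  props <- data.frame(soa_ms = c(-300, -150, -60, 60, 150, 300),
                      n = rep(18, 6), k = c(1, 4, 7, 12, 15, 17))
  f1 <- fit_cumulative_gaussian(props)
  flipped <- data.frame(soa_ms = -props$soa_ms, n = props$n,
                        k = props$n - props$k)
  f2 <- fit_cumulative_gaussian(flipped)
  expect_equal(f2$pse_ms, -f1$pse_ms, tolerance = 1e-3)
  expect_equal(f2$jnd_ms, f1$jnd_ms, tolerance = 1e-3)
})

test_that("fitted parameters are local likelihood maxima", {
  set.seed(4)
  for (rep in 1:3) {
    mu <- runif(1, -80, 80); sigma <- runif(1, 60, 250)
    soas <- seq(-400, 400, length.out = 8)
    props <- data.frame(soa_ms = soas, n = 15,
                        k = rbinom(8, 15, pnorm((soas - mu) / sigma)))
    f <- tryCatch(fit_cumulative_gaussian(props), error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    ll <- function(mu, sigma) {
      psi <- pmin(pmax(pnorm((props$soa_ms - mu) / sigma), 1e-12),
                  1 - 1e-12)
      sum(props$k * log(psi) + (props$n - props$k) * log(1 - psi))
    }
    ll_hat <- ll(f$pse_ms, f$sigma_ms)
    for (dm in c(0.95, 1, 1.05)) for (ds in c(0.95, 1, 1.05)) {
      expect_lte(ll(f$pse_ms * dm, f$sigma_ms * ds), ll_hat + 1e-6)
    }
  }
})

test_that("IQR filter excludes Tukey-fence outliers at participant level", {
  est <- data.frame(
    participant_id = sprintf("p%d", 1:5), condition = "AT",
    group = "HC", jnd_ms = c(10, 11, 12, 13, 500))
  # independent Tukey-fence oracle
  q <- quantile(est$jnd_ms, c(0.25, 0.75), type = 7)
  expect_true(500 > q[2] + 1.5 * diff(q))
  filt <- iqr_outlier_filter(est)
  expect_equal(filt$excluded, "p5")
  expect_setequal(filt$kept, sprintf("p%d", 1:4))

  # all-equal cell: fences collapse onto the common value, nobody excluded
  est$jnd_ms <- rep(50, 5)
  expect_equal(length(iqr_outlier_filter(est)$excluded), 0)

  # idempotence on the kept set
  est$jnd_ms <- c(10, 11, 12, 13, 500)
  kept1 <- iqr_outlier_filter(est)$kept
  filt2 <- iqr_outlier_filter(est[est$participant_id %in% kept1, ])
  expect_setequal(filt2$kept, kept1)

  expect_warning(iqr_outlier_filter(est[1:3, ]), "filter skipped")
})
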
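#' Kendall tau-b with tie-corrected normal test
#'
#' Rank correlation with tie correction in both margins:
#' `tau_b = S / sqrt((n0 - n1)(n0 - n2))` where `S = C - D` is the
#' concordant-minus-discordant pair count, `n0 = n(n-1)/2`, and `n1`, `n2`
#' are tied-pair counts in each margin. The z statistic uses the
#' tie-corrected variance of S; the p-value is two-sided normal.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list with `tau_b`, `S`, `z`, `p`, `n`. An all-tied margin makes
#'   tau undefined: returned as `NA` with a warning.
#' @export
kendall_tau_b <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  S <- sum(dx[lower.tri(dx)] * dy[lower.tri(dy)])
  n0 <- n * (n - 1) / 2
  tx <- as.numeric(table(x)); ty <- as.numeric(table(y))
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    warning("all-tied margin: tau-b undefined")
    return(list(tau_b = NA_real_, S = S, z = NA_real_, p = NA_real_, n = n))
  }
  tau <- S / denom
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (varS > 0) S / sqrt(varS) else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  list(tau_b = tau, S = S, z = z, p = p, n = n)
}

# Participant-level mean JND across conditions for the given ids.
mean_jnd_by_participant <- function(estimates, ids = NULL) {
  if (!is.null(ids))
    estimates <- estimates[estimates$participant_id %in% ids, ]
  agg <- aggregate(jnd_ms ~ participant_id, data = estimates, FUN = mean)
  names(agg)[2] <- "mean_jnd"
  agg
}

kendall_screen <- function(estimates, participants, scales, ids = NULL) {
  pat <- participants[participants$group != "HC", ]
  mj <- mean_jnd_by_participant(estimates,
                                ids = if (is.null(ids))
                                  pat$participant_id
                                else intersect(ids, pat$participant_id))
  merged <- merge(mj, pat, by = "participant_id")
  rows <- lapply(scales, function(sc) {
    ok <- !is.na(merged[[sc]]) & !is.na(merged$mean_jnd)
    if (sum(ok) < 3)
      stop("fewer than 3 complete pairs for scale ", sc)
    kt <- kendall_tau_b(merged$mean_jnd[ok], merged[[sc]][ok])
    data.frame(scale = sc, tau_b = kt$tau_b, z = kt$z, p = kt$p,
               n = kt$n)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p, m = length(scales))
  out
}

#' Screen temporal precision against clinical scales
#'
#' Kendall tau-b correlations between each patient's mean JND across the
#' three conditions and the four clinical scales (PANSS positive, PANSS
#' negative, YMRS, HAM-D), Bonferroni-adjusted over the family of 4.
#' Healthy controls carry no scale scores and are excluded.
#'
#' @param estimates data frame from [fit_participants()].
#' @param participants clinical profile table.
#' @param ids optional participant ids to keep (e.g. after
#'   [iqr_outlier_filter()]).
#' @return data frame of correlation results (`scale`, `tau_b`, `z`, `p`,
#'   `p_bonferroni`, `n`).
#' @export
clinical_screen <- function(estimates, participants, ids = NULL) {
  kendall_screen(estimates, participants,
                 c("panss_pos", "panss_neg", "ymrs", "hamd"), ids)
}

#' Screen temporal precision against medication equivalents
#'
#' As [clinical_screen()], for the four daily-dose equivalents
#' (antipsychotic, mood stabilizer, benzodiazepine, antidepressant);
#' missing doses are dropped pairwise.
#'
#' @inheritParams clinical_screen
#' @return data frame of correlation results.
#' @export
medication_screen <- function(estimates, participants, ids = NULL) {
  kendall_screen(estimates, participants,
                 c("med_antipsychotic", "med_mood_stabilizer",
                   "med_benzodiazepine", "med_antidepressant"), ids)
}

#' Negative-binomial regression of symptom counts on temporal precision
#'
#' Fits `count ~ 1 + jnd` with a log link and NB2 variance
#' (`Var = mu + mu^2 / theta`), maximizing the joint likelihood over the
#' coefficients and the dispersion theta (profile ML via [MASS::glm.nb()]).
#' Reports the Wald z for the slope and the Nagelkerke pseudo R-squared
#' against the intercept-only negative-binomial null.
#'
#' @param counts non-negative integer response (e.g. PANSS positive
#'   totals).
#' @param jnd_ms predictor in ms (mean JND across conditions).
#' @param theta_cap upper bound for theta; fits drifting to the Poisson
#'   limit are capped with a warning (default 1e6).
#' @return object of class `nb_glm_result`: `beta0`, `beta1`, `se_beta1`,
#'   `wald_z`, `p_wald`, `dispersion_theta`, `loglik_full`, `loglik_null`,
#'   `nagelkerke_r2`, `n`, `converged`.
#' @export
nb_glm_fit <- function(counts, jnd_ms, theta_cap = 1e6) {
  ok <- !is.na(counts) & !is.na(jnd_ms)
  counts <- counts[ok]; jnd_ms <- jnd_ms[ok]
  if (length(counts) < 5) stop("need at least 5 observations")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("response must be non-negative integers")
  dat <- data.frame(y = counts, x = jnd_ms)
  capped <- FALSE
  fit <- withCallingHandlers(
    MASS::glm.nb(y ~ x, data = dat, control = glm.control(maxit = 100)),
    warning = function(w) {
      capped <<- TRUE
      invokeRestart("muffleWarning")
    })
  null <- withCallingHandlers(
    MASS::glm.nb(y ~ 1, data = dat, control = glm.control(maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  theta <- fit$theta
  if (theta > theta_cap) {
    warning("dispersion diverged; theta capped at Poisson limit")
    theta <- theta_cap
  }
  co <- summary(fit)$coefficients
  ll1 <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(null))
  n <- length(counts)
  structure(list(
    beta0 = unname(co["(Intercept)", "Estimate"]),
    beta1 = unname(co["x", "Estimate"]),
    se_beta1 = unname(co["x", "Std. Error"]),
    wald_z = unname(co["x", "z value"]),
    p_wald = unname(co["x", "Pr(>|z|)"]),
    dispersion_theta = theta,
    loglik_full = ll1, loglik_null = ll0,
    nagelkerke_r2 = nagelkerke_r2(ll1, ll0, n),
    n = n, converged = fit$converged && !capped
  ), class = "nb_glm_result")
}

#' @export
print.nb_glm_result <- function(x, ...) {
  cat(sprintf(
    "NB GLM (log link): beta1 = %.4g +/- %.2g, z = %.2f, p = %.3g\n",
    x$beta1, x$se_beta1, x$wald_z, x$p_wald))
  cat(sprintf("  theta = %.3g, Nagelkerke R2 = %.3f, n = %d\n",
              x$dispersion_theta, x$nagelkerke_r2, x$n))
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `R2_cs = 1 - exp(2 (ll0 - ll1) / n)` rescaled by its maximum
#' `1 - exp(2 ll0 / n)` to lie in `[0, 1]`.
#'
#' @param loglik_full,loglik_null log-likelihoods of the full and null
#'   models (`loglik_full >= loglik_null`).
#' @param n number of observations.
#' @return Nagelkerke R-squared.
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  if (n <= 0) stop("n must be positive")
  if (loglik_full < loglik_null - 1e-8)
    stop("loglik_full must be >= loglik_null")
  cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  max_cs <- 1 - exp(2 * loglik_null / n)
  if (max_cs <= 0) return(0)
  min(max(cs / max_cs, 0), 1)
}
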
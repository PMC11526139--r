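#' Aggregate trial records into response proportions per SOA
#'
#' Tallies, for one participant and condition, how often the condition's
#' reference modality (A for AT; V for AV and VT) was reported first at each
#' distinct signed SOA. Skipped trials are excluded.
#'
#' @param trials data frame of trial records for a single participant.
#' @param condition condition label; if `NULL`, `trials` must contain
#'   exactly one condition.
#' @return data frame with columns `soa_ms`, `n` (trials), `k`
#'   (reference-first reports), sorted by SOA. `sum(n)` equals the number of
#'   usable (non-skipped) trials.
#' @export
aggregate_proportions <- function(trials, condition = NULL) {
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  conds <- unique(trials$condition)
  if (length(conds) != 1) stop("trials must cover exactly one condition")
  trials <- trials[!trials$skipped, ]
  if (nrow(trials) == 0) stop("zero usable trials after excluding skips")
  ref <- condition_modalities(conds)[["ref"]]
  agg <- aggregate(cbind(n = rep(1L, nrow(trials)),
                         k = as.integer(trials$response == ref)) ~ soa_ms,
                   data = data.frame(soa_ms = trials$soa_ms,
                                     response = trials$response),
                   FUN = sum)
  agg <- agg[order(agg$soa_ms), ]
  rownames(agg) <- NULL
  agg
}

# Negative Bernoulli log-likelihood of a cumulative-Gaussian psychometric
# function at (mu, sigma) for a proportions table.
cg_negloglik <- function(par, props, eps = 1e-12) {
  psi <- pnorm((props$soa_ms - par[1]) / par[2])
  psi <- pmin(pmax(psi, eps), 1 - eps)
  -sum(props$k * log(psi) + (props$n - props$k) * log(1 - psi))
}

cg_ssq <- function(par, props) {
  psi <- pnorm((props$soa_ms - par[1]) / par[2])
  sum(props$n * (props$k / props$n - psi)^2)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Estimates the point of subjective equality (PSE, the fitted mean) and
#' the slope sigma of `P(reference first) = Phi((SOA - mu) / sigma)` from a
#' proportions table. The default criterion is the trial-level Bernoulli
#' log-likelihood; `method = "ls"` minimizes the n-weighted squared error
#' of proportions instead. Optimization is bounded quasi-Newton (L-BFGS-B)
#' from a deterministic grid of multistarts (`mu0` in -100/0/100, `sigma0`
#' in 50/200 ms), with bounds `mu` in \[-800, 800\] and `sigma` in
#' \[1, 2000\] ms.
#'
#' Perfect separation (no overlap between all-0 and all-1 SOA regions)
#' drives sigma to its lower bound; the fit is then flagged
#' non-identifiable (`converged = FALSE`, sigma at floor).
#'
#' @param props data frame from [aggregate_proportions()] (`soa_ms`, `n`,
#'   `k`).
#' @param method `"ml"` (default) or `"ls"`.
#' @return object of class `psychometric_fit`: list with `pse_ms`,
#'   `sigma_ms`, `jnd_ms`, `n_trials_used`, `loglik`, `converged`,
#'   `sigma_at_floor`, `method`.
#' @export
fit_cumulative_gaussian <- function(props, method = c("ml", "ls")) {
  method <- match.arg(method)
  stopifnot(all(c("soa_ms", "n", "k") %in% names(props)))
  if (any(props$k < 0 | props$k > props$n)) stop("k must lie in [0, n]")
  if (length(unique(props$soa_ms)) < 2)
    stop("need at least 2 distinct SOA levels to fit")
  obj <- if (method == "ml") cg_negloglik else cg_ssq
  lower <- c(-800, 1); upper <- c(800, 2000)
  starts <- expand.grid(mu = c(-100, 0, 100), sigma = c(50, 200))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[s, ]), obj, props = props,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed from every start")
  sigma_floor <- best$par[2] <= lower[2] + 1e-6
  converged <- best$convergence == 0 && !sigma_floor
  est <- structure(list(
    pse_ms = best$par[1], sigma_ms = best$par[2],
    jnd_ms = best$par[2] * qnorm(0.75),
    n_trials_used = sum(props$n),
    loglik = -cg_negloglik(best$par, props),
    converged = converged, sigma_at_floor = sigma_floor,
    method = method
  ), class = "psychometric_fit")
  est
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Cumulative-Gaussian fit (%s): PSE = %.2f ms, sigma = %.2f ms, JND = %.2f ms\n",
    x$method, x$pse_ms, x$sigma_ms, x$jnd_ms))
  cat(sprintf("  trials used: %d, loglik = %.3f, converged: %s\n",
              x$n_trials_used, x$loglik, x$converged))
  invisible(x)
}

#' Just noticeable difference of a fitted psychometric function
#'
#' The JND is half the interquartile span of the fitted curve,
#' `(x_.75 - x_.25) / 2`, which for the cumulative Gaussian equals
#' `sigma * qnorm(0.75)`.
#'
#' @param estimate a `psychometric_fit`.
#' @return JND in ms; `NA` with a warning for a non-converged fit.
#' @export
compute_jnd <- function(estimate) {
  if (!isTRUE(estimate$converged)) {
    warning("non-converged fit: JND is undefined")
    return(NA_real_)
  }
  estimate$sigma_ms * qnorm(0.75)
}

#' Fit every participant x condition in a trials table
#'
#' @param trials trial-record data frame (multiple participants).
#' @param participants optional participant table supplying `group`.
#' @param method passed to [fit_cumulative_gaussian()].
#' @return data frame of estimates: `participant_id`, `condition`,
#'   `pse_ms`, `sigma_ms`, `jnd_ms`, `n_trials_used`, `converged` (and
#'   `group` when `participants` given).
#' @export
fit_participants <- function(trials, participants = NULL,
                             method = c("ml", "ls")) {
  method <- match.arg(method)
  cells <- unique(trials[, c("participant_id", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$participant_id == cells$participant_id[i] &
                    trials$condition == cells$condition[i], ]
    props <- aggregate_proportions(sub, cells$condition[i])
    f <- fit_cumulative_gaussian(props, method = method)
    data.frame(participant_id = cells$participant_id[i],
               condition = cells$condition[i],
               pse_ms = f$pse_ms, sigma_ms = f$sigma_ms, jnd_ms = f$jnd_ms,
               n_trials_used = f$n_trials_used, loglik = f$loglik,
               converged = f$converged)
  })
  est <- do.call(rbind, rows)
  if (!is.null(participants))
    est$group <- participants$group[match(est$participant_id,
                                          participants$participant_id)]
  est
}

#' Interquartile-range participant exclusion
#'
#' Within each group x condition cell, flags JNDs outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 sample quantiles). A participant
#' flagged in any condition is excluded entirely. Cells with fewer than 4
#' members are skipped with a warning.
#'
#' @param estimates data frame from [fit_participants()], with a `group`
#'   column.
#' @param value column to screen (default `"jnd_ms"`).
#' @param k Tukey multiplier (default 1.5).
#' @return list with `kept` and `excluded` participant ids, and `flags`
#'   (data frame of flagged participant x condition cells).
#' @export
iqr_outlier_filter <- function(estimates, value = "jnd_ms", k = 1.5) {
  stopifnot("group" %in% names(estimates))
  flags <- list()
  for (g in unique(estimates$group)) {
    for (cond in unique(estimates$condition)) {
      cell <- estimates[estimates$group == g & estimates$condition == cond, ]
      if (nrow(cell) == 0) next
      if (nrow(cell) < 4) {
        warning(sprintf("cell %s x %s has < 4 members; filter skipped",
                        g, cond))
        next
      }
      v <- cell[[value]]
      q <- quantile(v, c(0.25, 0.75), type = 7, na.rm = TRUE)
      fence <- c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
      out <- which(v < fence[1] | v > fence[2])
      if (length(out))
        flags[[length(flags) + 1L]] <- data.frame(
          participant_id = cell$participant_id[out], group = g,
          condition = cond, value = v[out],
          fence_low = fence[1], fence_high = fence[2],
          row.names = NULL)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(participant_id = character(0), group = character(0),
               condition = character(0), value = numeric(0),
               fence_low = numeric(0), fence_high = numeric(0))
  all_ids <- unique(estimates$participant_id)
  excluded <- unique(flags$participant_id)
  list(kept = setdiff(all_ids, excluded), excluded = excluded,
       flags = flags)
}
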
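#' QUEST configuration
#'
#' Parameters of the Bayesian adaptive staircase used to place each trial's
#' stimulus onset asynchrony (SOA) magnitude. QUEST maintains a discretized
#' posterior over the observer's temporal threshold and recommends the next
#' SOA from it.
#'
#' The trial-level likelihood kernel is a Weibull psychometric function on
#' linear SOA magnitude `x` given candidate threshold `T`:
#' \deqn{p(\mathrm{correct} \mid x, T) = \delta\gamma +
#'   (1-\delta)\{1 - (1-\gamma)\exp[-(x/T)^\beta]\}}
#' with guess rate `gamma` (0.5 for a two-alternative order judgment), lapse
#' `delta`, and assumed slope `beta`.
#'
#' @param grid_min_ms,grid_max_ms SOA range in ms (defaults 0 and 800). The
#'   threshold grid starts at `max(grid_min_ms, grid_step_ms)` because a
#'   zero threshold is degenerate for the Weibull kernel.
#' @param grid_step_ms grid resolution in ms (default 10).
#' @param assumed_slope_beta Weibull slope assumed by QUEST (default 3.5).
#' @param guess_rate_gamma chance performance level (default 0.5).
#' @param lapse_delta assumed lapse rate (default 0.01).
#' @param prior_mean_ms,prior_sd_ms Gaussian prior over the threshold, in ms.
#'   `prior_sd_ms = Inf` gives a flat prior.
#' @param placement_rule one of `"mean"` (posterior mean, the default),
#'   `"mode"` (posterior mode), or `"quantile"` (posterior quantile
#'   `placement_quantile`).
#' @param placement_quantile quantile used when `placement_rule = "quantile"`.
#' @param target_p nominal target proportion correct (recorded for
#'   reporting; the placement rules above are threshold-based).
#' @return an object of class `quest_config`.
#' @seealso [quest_init()], [quest_next_soa()], [quest_update()]
#' @export
quest_config <- function(grid_min_ms = 0, grid_max_ms = 800,
                         grid_step_ms = 10,
                         assumed_slope_beta = 3.5,
                         guess_rate_gamma = 0.5,
                         lapse_delta = 0.01,
                         prior_mean_ms = 200, prior_sd_ms = 200,
                         placement_rule = c("mean", "mode", "quantile"),
                         placement_quantile = 0.5,
                         target_p = 0.75) {
  placement_rule <- match.arg(placement_rule)
  if (!is.numeric(grid_min_ms) || !is.numeric(grid_max_ms) ||
      grid_min_ms >= grid_max_ms)
    stop("degenerate grid: need grid_min_ms < grid_max_ms")
  if (grid_step_ms <= 0) stop("grid_step_ms must be positive")
  if (guess_rate_gamma < 0 || guess_rate_gamma >= target_p ||
      target_p >= 1 - lapse_delta)
    stop("need 0 <= gamma < target_p < 1 - delta")
  if (prior_sd_ms <= 0) stop("prior_sd_ms must be positive")
  structure(list(
    grid_min_ms = grid_min_ms, grid_max_ms = grid_max_ms,
    grid_step_ms = grid_step_ms,
    assumed_slope_beta = assumed_slope_beta,
    guess_rate_gamma = guess_rate_gamma,
    lapse_delta = lapse_delta,
    prior_mean_ms = prior_mean_ms, prior_sd_ms = prior_sd_ms,
    placement_rule = placement_rule,
    placement_quantile = placement_quantile,
    target_p = target_p
  ), class = "quest_config")
}

quest_grid <- function(config) {
  seq(max(config$grid_min_ms, config$grid_step_ms), config$grid_max_ms,
      by = config$grid_step_ms)
}

#' Weibull likelihood kernel assumed by QUEST
#'
#' Probability of a correct order report at SOA magnitude `x` for an
#' observer with threshold `threshold`, under the staircase's assumed
#' psychometric kernel.
#'
#' @param x SOA magnitude(s), ms (>= 0).
#' @param threshold candidate threshold(s), ms (> 0).
#' @param config a [quest_config()].
#' @return probability/ies of a correct response.
#' @export
quest_p_correct <- function(x, threshold, config) {
  gamma <- config$guess_rate_gamma
  delta <- config$lapse_delta
  beta <- config$assumed_slope_beta
  delta * gamma +
    (1 - delta) * (1 - (1 - gamma) * exp(-(x / threshold)^beta))
}

#' Initialize a QUEST state
#'
#' The posterior over the threshold grid is set to the discretized Gaussian
#' prior (uniform when `prior_sd_ms = Inf`).
#'
#' @param config a [quest_config()].
#' @return an object of class `quest_state` with fields `log_posterior`,
#'   `grid` (threshold grid, ms), `trial_count`, and `history` (a data frame
#'   of `soa_magnitude_ms`, `correct`).
#' @export
quest_init <- function(config) {
  grid <- quest_grid(config)
  if (length(grid) < 2) stop("degenerate grid: fewer than 2 grid points")
  if (is.infinite(config$prior_sd_ms)) {
    lp <- rep(0, length(grid))
  } else {
    lp <- dnorm(grid, config$prior_mean_ms, config$prior_sd_ms, log = TRUE)
  }
  lp <- lp - log_sum_exp(lp)
  structure(list(
    log_posterior = lp,
    grid = grid,
    trial_count = 0L,
    history = data.frame(soa_magnitude_ms = numeric(0), correct = logical(0))
  ), class = "quest_state")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

quest_posterior <- function(state) {
  p <- exp(state$log_posterior - log_sum_exp(state$log_posterior))
  p / sum(p)
}

#' Recommend the next SOA magnitude
#'
#' Applies the configured placement rule to the current posterior and snaps
#' the recommendation to the nearest grid point, clamped to
#' `[grid_min_ms, grid_max_ms]`.
#'
#' @param state a `quest_state`.
#' @param config the [quest_config()] used to create it.
#' @return recommended SOA magnitude in ms (a grid value).
#' @export
quest_next_soa <- function(state, config) {
  p <- quest_posterior(state)
  if (abs(sum(p) - 1) > 1e-8 || anyNA(p))
    stop("unnormalized or invalid posterior state")
  g <- state$grid
  rec <- switch(config$placement_rule,
    mean = sum(p * g),
    mode = g[which.max(p)],
    quantile = g[which(cumsum(p) >= config$placement_quantile)[1]]
  )
  rec <- min(max(rec, config$grid_min_ms), config$grid_max_ms)
  g[which.min(abs(g - rec))]
}

#' Update the QUEST posterior with one trial
#'
#' Adds the log-likelihood of the observed outcome at each candidate
#' threshold to the log posterior. Updates commute: the final posterior
#' depends only on the multiset of `(soa, correct)` pairs.
#'
#' @param state a `quest_state`.
#' @param soa_magnitude_ms tested SOA magnitude, ms.
#' @param correct logical, whether the reported order was correct.
#' @param config the [quest_config()].
#' @return the updated `quest_state`.
#' @export
quest_update <- function(state, soa_magnitude_ms, correct, config) {
  if (is.na(correct)) stop("cannot update QUEST with a skipped trial")
  x <- min(max(soa_magnitude_ms, config$grid_min_ms), config$grid_max_ms)
  p <- quest_p_correct(x, state$grid, config)
  lik <- if (isTRUE(correct)) p else 1 - p
  if (all(lik <= 0))
    stop("impossible likelihood (zero everywhere); posterior unchanged")
  lp <- state$log_posterior + log(lik)
  state$log_posterior <- lp - log_sum_exp(lp)
  state$trial_count <- state$trial_count + 1L
  state$history <- rbind(state$history,
                         data.frame(soa_magnitude_ms = soa_magnitude_ms,
                                    correct = correct))
  state
}

#' Posterior summaries of the QUEST threshold estimate
#'
#' @param state a `quest_state`.
#' @return list with `mean`, `mode`, `sd` of the threshold posterior (ms).
#' @export
quest_estimate <- function(state) {
  p <- quest_posterior(state)
  m <- sum(p * state$grid)
  list(mean = m,
       mode = state$grid[which.max(p)],
       sd = sqrt(sum(p * (state$grid - m)^2)))
}

# Which modality is the condition's reference (the one whose "first" report
# is tallied when fitting), and which is the other member of the pair.
condition_modalities <- function(condition) {
  switch(condition,
    AT = c(ref = "A", other = "T"),
    AV = c(ref = "V", other = "A"),
    VT = c(ref = "V", other = "T"),
    stop("unknown condition label: ", condition)
  )
}

#' Simulate the practice gate preceding a TOJ session
#'
#' Observers receive 3-10 easy trials (SOA 600-800 ms) and proceed once they
#' have answered at least three consecutive trials correctly. Practice
#' trials are excluded from analysis records; this function only consumes
#' RNG and reports whether/when the gate was passed.
#'
#' @param observer an [observer_params()] object.
#' @param condition condition label (`"AT"`, `"AV"`, `"VT"`).
#' @param max_trials maximum number of practice trials (default 10).
#' @return list with `n_trials` used and `passed` (logical).
#' @export
simulate_practice_gate <- function(observer, condition, max_trials = 10) {
  streak <- 0L
  n <- 0L
  while (n < max_trials && streak < 3L) {
    n <- n + 1L
    soa <- runif(1, 600, 800) * sample(c(-1, 1), 1)
    resp <- simulate_toj_response(observer, condition, soa)
    streak <- if (resp$correct) streak + 1L else 0L
  }
  list(n_trials = n, passed = streak >= 3L)
}

# One simulated response at signed SOA `soa_ms` (positive = reference
# modality led). Returns the reported modality and whether it was correct.
simulate_toj_response <- function(observer, condition, soa_ms) {
  mods <- condition_modalities(condition)
  mu <- observer$condition_pse[[condition]]
  p_ref_first <- observer$lapse_rate / 2 +
    (1 - observer$lapse_rate) * pnorm((soa_ms - mu) / observer$sigma)
  ref_reported <- runif(1) < p_ref_first
  response <- unname(if (ref_reported) mods["ref"] else mods["other"])
  truth_ref_first <- if (soa_ms > 0) TRUE
                     else if (soa_ms < 0) FALSE
                     else runif(1) < 0.5
  list(response = response, correct = ref_reported == truth_ref_first)
}

#' Simulate one QUEST-driven TOJ block
#'
#' Runs a block of adaptively placed trials against a simulated observer.
#' Each trial's SOA magnitude comes from [quest_next_soa()]; its sign (which
#' modality leads) is a fair coin; the observer's report is drawn from a
#' lapse-mixed cumulative Gaussian in signed SOA; response correctness
#' (did the reported modality actually lead?) is fed back to
#' [quest_update()]. Skipped trials (rate `observer$skip_rate`) are recorded
#' with no response and do not update the staircase.
#'
#' @param observer an [observer_params()] object.
#' @param condition condition label (`"AT"`, `"AV"`, `"VT"`).
#' @param config a [quest_config()].
#' @param n_trials number of trials in the block (default 52).
#' @param practice run the practice gate first (default `FALSE`).
#' @return a data frame of trial records: `participant_id`, `condition`,
#'   `trial_index`, `soa_ms` (signed; positive = reference modality led),
#'   `response` (reported-first modality, `NA` when skipped), `skipped`,
#'   plus attribute `quest_state` (final state).
#' @export
simulate_toj_session <- function(observer, condition, config = quest_config(),
                                 n_trials = 52, practice = FALSE) {
  stopifnot(inherits(config, "quest_config"))
  if (practice) simulate_practice_gate(observer, condition)
  state <- quest_init(config)
  rec <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    mag <- quest_next_soa(state, config)
    sgn <- sample(c(-1, 1), 1)
    soa <- sgn * mag
    if (runif(1) < observer$skip_rate) {
      rec[[i]] <- data.frame(participant_id = observer$participant_id,
                             condition = condition, trial_index = i,
                             soa_ms = soa, response = NA_character_,
                             skipped = TRUE)
      next
    }
    resp <- simulate_toj_response(observer, condition, soa)
    state <- quest_update(state, mag, resp$correct, config)
    rec[[i]] <- data.frame(participant_id = observer$participant_id,
                           condition = condition, trial_index = i,
                           soa_ms = soa, response = resp$response,
                           skipped = FALSE)
  }
  out <- do.call(rbind, rec)
  attr(out, "quest_state") <- state
  out
}
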
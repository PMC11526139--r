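#' Latent psychometric parameters of a simulated observer
#'
#' @param participant_id character id.
#' @param group `"HC"`, `"BD"`, or `"SZ"`.
#' @param age age in years.
#' @param condition_pse named list/vector of true PSE (ms) per condition
#'   (`AT`, `AV`, `VT`).
#' @param sigma true psychometric slope (SD of the cumulative Gaussian), ms,
#'   shared across conditions.
#' @param lapse_rate probability of a stimulus-independent random report,
#'   in `[0, 0.1]`.
#' @param skip_rate probability of skipping a trial, in `[0, 0.2]`.
#' @return object of class `observer_params`. The observer's true JND is
#'   `sigma * qnorm(0.75)`.
#' @export
observer_params <- function(participant_id, group, age, condition_pse,
                            sigma, lapse_rate = 0, skip_rate = 0) {
  group <- match.arg(group, c("HC", "BD", "SZ"))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (lapse_rate < 0 || lapse_rate > 0.1)
    stop("lapse_rate must be in [0, 0.1]")
  if (skip_rate < 0 || skip_rate > 0.2)
    stop("skip_rate must be in [0, 0.2]")
  condition_pse <- as.list(condition_pse)
  if (!all(c("AT", "AV", "VT") %in% names(condition_pse)))
    stop("condition_pse must name AT, AV and VT")
  obs <- structure(list(
    participant_id = as.character(participant_id), group = group,
    age = age, condition_pse = condition_pse, sigma = sigma,
    lapse_rate = lapse_rate, skip_rate = skip_rate
  ), class = "observer_params")
  if (!is.finite(true_jnd(obs))) stop("true JND must be finite")
  obs
}

#' True JND of a simulated observer
#' @param observer an [observer_params()] object.
#' @return `sigma * qnorm(0.75)` in ms.
#' @export
true_jnd <- function(observer) observer$sigma * qnorm(0.75)

# Demographic and clinical population parameters used as generator
# defaults: per-group means and SDs of age, scale totals, and daily
# medication equivalents, plus sex composition (n male / n female).
default_group_profiles <- function() {
  list(
    HC = list(n = 21, age = c(41, 9.9), male_female = c(8, 13)),
    BD = list(n = 20, age = c(44.9, 15.2), male_female = c(7, 13),
              hamd = c(10.1, 5.5), ymrs = c(13.7, 9.5),
              panss_neg = c(11.1, 8.6), panss_gen = c(35.2, 9.9),
              med_antipsychotic = c(510.3, 951.5),
              med_mood_stabilizer = c(999.4, 571),
              med_benzodiazepine = c(7.6, 9.8),
              med_antidepressant = c(19.7, 47.8)),
    SZ = list(n = 21, age = c(44.9, 14.2), male_female = c(6, 15),
              hamd = c(11.5, 5.8), ymrs = c(9.1, 7.6),
              panss_neg = c(17, 8.4), panss_gen = c(34.8, 9.8),
              med_antipsychotic = c(293.5, 249.6),
              med_mood_stabilizer = c(580.2, 525.9),
              med_benzodiazepine = c(6.1, 8.3),
              med_antidepressant = c(30.4, 92.5))
  )
}

default_pse_means <- function() {
  # group x condition mean PSE, ms
  matrix(c(23.9, -35.07, -25.85,
           -28.08, 49.6, -7.68,
           34.88, 7.98, 66.27),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("HC", "BD", "SZ"), c("AT", "AV", "VT")))
}

#' Configuration of a synthetic TOJ study
#'
#' Defines the cohort composition, the observers' psychometric population,
#' the session layout, and the coupling between temporal precision and
#' positive psychotic symptoms. Patient PANSS-positive totals are drawn from
#' a negative binomial with log-mean `glm_beta0 + glm_beta1 * trueJND_mean`
#' (trueJND_mean in ms); all other clinical scales are drawn independently
#' of precision.
#'
#' @param n_per_group named vector of group sizes (default `c(HC = 21,
#'   BD = 20, SZ = 21)`).
#' @param trials_per_block trials per condition block (default 52).
#' @param soa_min_ms,soa_max_ms SOA magnitude range, ms (defaults 0, 800).
#' @param group_sigma_mean,group_sigma_sd named vectors (per group) of the
#'   mean and SD of the true psychometric slope sigma, ms. Defaults put
#'   healthy controls at 150 ms and patients at twice that (a configurable
#'   precision deficit).
#' @param pse_means group x condition matrix of true mean PSE, ms.
#' @param pse_sd between-participant SD of the true PSE, ms (default 150).
#' @param lapse_rate,skip_rate per-trial lapse and skip probabilities
#'   (defaults 0 and 0.007).
#' @param glm_beta0 log-scale intercept of the symptom model (default 2.4).
#' @param glm_beta1 log-scale slope per ms of mean true JND (default 0.002).
#' @param nb_dispersion negative-binomial size parameter theta (default 8).
#' @param med_missing_rate probability a patient's medication equivalents
#'   are missing (default 0.1).
#' @param rng_seed integer seed; all randomness flows from it.
#' @param quest a [quest_config()] for session simulation.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(HC = 21, BD = 20, SZ = 21),
                          trials_per_block = 52,
                          soa_min_ms = 0, soa_max_ms = 800,
                          group_sigma_mean = c(HC = 150, BD = 300, SZ = 300),
                          group_sigma_sd = c(HC = 40, BD = 90, SZ = 90),
                          pse_means = default_pse_means(),
                          pse_sd = 150,
                          lapse_rate = 0, skip_rate = 0.007,
                          glm_beta0 = 2.4, glm_beta1 = 0.002,
                          nb_dispersion = 8,
                          med_missing_rate = 0.1,
                          rng_seed = NULL,
                          quest = quest_config(grid_min_ms = soa_min_ms,
                                               grid_max_ms = soa_max_ms)) {
  if (is.null(rng_seed) || is.na(rng_seed))
    stop("configuration error: rng_seed is required")
  if (any(n_per_group < 1)) stop("configuration error: empty group")
  if (trials_per_block < 1) stop("configuration error: trials_per_block >= 1")
  if (soa_min_ms < 0 || soa_min_ms >= soa_max_ms)
    stop("configuration error: need 0 <= soa_min_ms < soa_max_ms")
  if (nb_dispersion <= 0)
    stop("configuration error: non-positive dispersion")
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% c("HC", "BD", "SZ")))
    stop("n_per_group must be named with HC/BD/SZ")
  structure(list(
    n_per_group = n_per_group, trials_per_block = trials_per_block,
    soa_min_ms = soa_min_ms, soa_max_ms = soa_max_ms,
    group_sigma_mean = group_sigma_mean, group_sigma_sd = group_sigma_sd,
    pse_means = pse_means, pse_sd = pse_sd,
    lapse_rate = lapse_rate, skip_rate = skip_rate,
    glm_beta0 = glm_beta0, glm_beta1 = glm_beta1,
    nb_dispersion = nb_dispersion,
    med_missing_rate = med_missing_rate,
    rng_seed = as.integer(rng_seed), quest = quest
  ), class = "cohort_config")
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# Negative binomial truncated below at `floor` by resampling.
rnbinom_trunc <- function(n, mu, size, floor) {
  x <- rnbinom(n, mu = mu, size = size)
  bad <- which(x < floor)
  while (length(bad)) {
    x[bad] <- rnbinom(length(bad), mu = mu[bad], size = size)
    bad <- which(x < floor)
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws observers (latent psychometric truth) and matching clinical
#' profiles. Deterministic given `config$rng_seed`. Healthy controls carry
#' no clinical scale scores (they did not undergo the psychopathological
#' assessment); patient PANSS-positive totals are coupled to mean true JND
#' through the configured log-link negative binomial, truncated below at
#' the scale floor of 7 by resampling; HAM-D, YMRS, PANSS-negative/general
#' and medication equivalents are drawn independently of precision.
#'
#' @param config a [cohort_config()].
#' @return list with `observers` (list of [observer_params()]) and
#'   `participants` (clinical profile data frame, one row per participant).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  profiles <- default_group_profiles()
  observers <- list()
  rows <- list()
  idx <- 0L
  for (g in names(config$n_per_group)) {
    n <- config$n_per_group[[g]]
    prof <- profiles[[g]]
    age <- rnorm_trunc(n, prof$age[1], prof$age[2], 18, 75)
    p_male <- prof$male_female[1] / sum(prof$male_female)
    sex <- ifelse(runif(n) < p_male, "M", "F")
    sigma <- rnorm_trunc(n, config$group_sigma_mean[[g]],
                         config$group_sigma_sd[[g]], 20, 1500)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", g, i)
      pse <- as.list(config$pse_means[g, c("AT", "AV", "VT")] +
                       rnorm(3, 0, config$pse_sd))
      names(pse) <- c("AT", "AV", "VT")
      obs <- observer_params(pid, g, age[i], pse, sigma[i],
                             lapse_rate = config$lapse_rate,
                             skip_rate = config$skip_rate)
      observers[[idx]] <- obs
      if (g == "HC") {
        rows[[idx]] <- data.frame(
          participant_id = pid, group = g, age = age[i], sex = sex[i],
          hamd = NA_integer_, ymrs = NA_integer_,
          panss_pos = NA_integer_, panss_neg = NA_integer_,
          panss_gen = NA_integer_,
          med_antipsychotic = NA_real_, med_mood_stabilizer = NA_real_,
          med_benzodiazepine = NA_real_, med_antidepressant = NA_real_)
      } else {
        jnd <- true_jnd(obs)
        mu <- exp(config$glm_beta0 + config$glm_beta1 * jnd)
        panss_pos <- rnbinom_trunc(1, mu, config$nb_dispersion, 7L)
        meds <- vapply(c("med_antipsychotic", "med_mood_stabilizer",
                         "med_benzodiazepine", "med_antidepressant"),
                       function(m) rnorm_trunc(1, prof[[m]][1],
                                               prof[[m]][2], 0, Inf),
                       numeric(1))
        if (runif(1) < config$med_missing_rate) meds[] <- NA_real_
        rows[[idx]] <- data.frame(
          participant_id = pid, group = g, age = age[i], sex = sex[i],
          hamd = round(rnorm_trunc(1, prof$hamd[1], prof$hamd[2], 0, Inf)),
          ymrs = round(rnorm_trunc(1, prof$ymrs[1], prof$ymrs[2], 0, Inf)),
          panss_pos = panss_pos,
          panss_neg = round(rnorm_trunc(1, prof$panss_neg[1],
                                        prof$panss_neg[2], 7, 49)),
          panss_gen = round(rnorm_trunc(1, prof$panss_gen[1],
                                        prof$panss_gen[2], 16, 112)),
          med_antipsychotic = meds[[1]], med_mood_stabilizer = meds[[2]],
          med_benzodiazepine = meds[[3]], med_antidepressant = meds[[4]])
      }
    }
  }
  list(observers = observers, participants = do.call(rbind, rows))
}

#' Simulate all TOJ sessions for one observer
#'
#' Runs one QUEST-driven block per condition (AT, AV, VT) with
#' `config$trials_per_block` trials each. Uses the current RNG stream; seed
#' upstream (e.g. via [simulate_study()]) for reproducibility.
#'
#' @param observer an [observer_params()] object.
#' @param config a [cohort_config()].
#' @return data frame of trial records across the three conditions, with a
#'   `block_order` column recording the (randomized) block position.
#' @export
generate_session_data <- function(observer, config) {
  stopifnot(inherits(observer, "observer_params"),
            inherits(config, "cohort_config"))
  conds <- sample(c("AT", "AV", "VT"))
  out <- lapply(seq_along(conds), function(b) {
    tr <- simulate_toj_session(observer, conds[b], config$quest,
                               n_trials = config$trials_per_block)
    tr$block_order <- b
    tr
  })
  do.call(rbind, out)
}

#' Simulate a complete synthetic study
#'
#' Generates the cohort and all trial data under a single seed.
#' Deterministic: identical seeds give identical datasets.
#'
#' @param config a [cohort_config()].
#' @return list with `participants` (clinical profiles), `trials` (trial
#'   records for all participants), and `observers` (latent truth).
#' @export
simulate_study <- function(config) {
  cohort <- generate_cohort(config)  # seeds the RNG
  trials <- do.call(rbind, lapply(cohort$observers, generate_session_data,
                                  config = config))
  rownames(trials) <- NULL
  list(participants = cohort$participants, trials = trials,
       observers = cohort$observers)
}

#' Latent truth table of a simulated cohort
#'
#' @param observers list of [observer_params()] from [generate_cohort()].
#' @return data frame with one row per participant: group, sigma, true JND,
#'   and true PSE per condition.
#' @export
observer_truth <- function(observers) {
  do.call(rbind, lapply(observers, function(o) {
    data.frame(participant_id = o$participant_id, group = o$group,
               age = o$age, sigma = o$sigma, true_jnd = true_jnd(o),
               pse_AT = o$condition_pse$AT, pse_AV = o$condition_pse$AV,
               pse_VT = o$condition_pse$VT)
  }))
}

#' Write a study to disk as the canonical CSV pair
#'
#' Emits `participants.csv` (one row per participant; empty cells are
#' missing values) and `trials.csv` (one row per trial). Round-trips
#' losslessly through [read_participants()] / [read_trials()].
#'
#' @param study a list with `participants` and `trials` (from
#'   [simulate_study()] or equivalent).
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_dataset <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf <- file.path(dir, "participants.csv")
  tf <- file.path(dir, "trials.csv")
  utils::write.csv(study$participants, pf, row.names = FALSE, na = "")
  tr <- study$trials
  tr$skipped <- as.integer(tr$skipped)
  cols <- c("participant_id", "condition", "block_order", "trial_index",
            "soa_ms", "response", "skipped")
  if (!"block_order" %in% names(tr)) tr$block_order <- NA_integer_
  utils::write.csv(tr[, cols], tf, row.names = FALSE, na = "")
  invisible(c(participants = pf, trials = tf))
}
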
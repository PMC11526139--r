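#' Read a trials table
#'
#' CSV dialect: UTF-8, header row, comma-separated, empty cell = missing.
#' Validates the schema, condition labels, and uniqueness of
#' (participant, condition, trial_index); violations are reported with the
#' offending line numbers.
#'
#' @param path path to `trials.csv`.
#' @return validated trials data frame (`skipped` as logical).
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("participant_id", "condition", "trial_index", "soa_ms",
            "response", "skipped")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!tr$condition %in% c("AT", "AV", "VT"))
  if (length(bad))
    stop(path, ": unknown condition labels at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(tr$participant_id, tr$condition, tr$trial_index)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(path, ": duplicate (participant, condition, trial_index) at ",
         "data line(s) ", paste(utils::head(dup, 5), collapse = ", "))
  tr$skipped <- as.logical(as.integer(tr$skipped))
  if (anyNA(tr$skipped)) stop(path, ": skipped must be 0/1")
  if (any(!tr$skipped & is.na(tr$response)))
    stop(path, ": non-skipped trials must carry a response")
  tr
}

#' Read a participants table
#'
#' @param path path to `participants.csv`.
#' @return validated participant data frame.
#' @export
read_participants <- function(path) {
  pp <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("participant_id", "group", "age")
  miss <- setdiff(need, names(pp))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!pp$group %in% c("HC", "BD", "SZ"))
  if (length(bad))
    stop(path, ": unknown group labels at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  dup <- which(duplicated(pp$participant_id))
  if (length(dup))
    stop(path, ": duplicate participant_id at data line(s) ",
         paste(dup, collapse = ", "))
  pp
}

#' Pipeline configuration
#'
#' @param trials,participants input table paths (both `NULL` when
#'   synthesizing).
#' @param synth a [cohort_config()] to simulate inputs in-process.
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param n_perm permutations for ANOVA and post-hoc tests (default 5000).
#' @param bf_prior_r Cauchy scale for post-hoc Bayes factors (default
#'   0.707).
#' @param n_mc_bf Monte-Carlo draws for [linear_model_bf()] (default 4000).
#' @param fit_method psychometric fit criterion, `"ml"` or `"ls"`.
#' @param out_dir output directory for `estimates.csv` and
#'   `stats_report.json` (`NULL` = no files).
#' @param verbose print stage progress to stderr.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(trials = NULL, participants = NULL,
                            synth = NULL, seed = NULL, n_perm = 5000,
                            bf_prior_r = 0.707, n_mc_bf = 4000,
                            fit_method = c("ml", "ls"), out_dir = NULL,
                            verbose = FALSE) {
  if (is.null(seed)) stop("seed is required")
  if (is.null(synth) && (is.null(trials) || is.null(participants)))
    stop("provide either input paths or a synthesis config")
  structure(list(trials = trials, participants = participants,
                 synth = synth, seed = as.integer(seed), n_perm = n_perm,
                 bf_prior_r = bf_prior_r, n_mc_bf = n_mc_bf,
                 fit_method = match.arg(fit_method), out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

stage_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message(sprintf(...))
}

#' Run the full TOJ analysis pipeline
#'
#' Stages, in order: load (or synthesize) trials and participants; fit a
#' cumulative Gaussian per participant x condition; exclude
#' interquartile-range outliers at the participant level; permutation
#' mixed ANOVA with age covariate on JND and PSE; Bonferroni-corrected
#' permutation post-hoc t-tests between groups on mean JND with JZS Bayes
#' factors; Zellner-Siow model Bayes factors for group/condition structure
#' in PSE; Kendall tau-b screening of mean JND against clinical scales and
#' medication equivalents; negative-binomial GLM of PANSS-positive on mean
#' JND. Deterministic given `config$seed`. Writes `estimates.csv` and
#' `stats_report.json` when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return the report, an object of class `toj_report` (a nested list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$synth)) {
    stage_msg(config, "simulate: seed %d", config$synth$rng_seed)
    study <- simulate_study(config$synth)
    trials <- study$trials; participants <- study$participants
  } else {
    trials <- read_trials(config$trials)
    participants <- read_participants(config$participants)
  }

  usable <- trials[!trials$skipped, ]
  cell_counts <- aggregate(
    trial_index ~ group + condition,
    data = merge(usable,
                 participants[, c("participant_id", "group")],
                 by = "participant_id"),
    FUN = length)
  np <- aggregate(participant_id ~ group,
                  data = participants, FUN = function(x) length(unique(x)))
  cell_counts$mean_trials <- cell_counts$trial_index /
    np$participant_id[match(cell_counts$group, np$group)]

  stage_msg(config, "fit: %d participants",
            length(unique(trials$participant_id)))
  estimates <- fit_participants(trials, participants,
                                method = config$fit_method)

  filt <- iqr_outlier_filter(estimates)
  stage_msg(config, "outlier filter: %d excluded", length(filt$excluded))
  est_kept <- estimates[estimates$participant_id %in% filt$kept, ]

  jnd_long <- merge(est_kept,
                    participants[, c("participant_id", "age")],
                    by = "participant_id")
  shapiro <- do.call(rbind, lapply(split(
    jnd_long, list(jnd_long$group, jnd_long$condition)), function(cell) {
      sw <- shapiro_wilk(cell$jnd_ms)
      data.frame(group = cell$group[1], condition = cell$condition[1],
                 W = sw$W, p = sw$p)
    }))
  rownames(shapiro) <- NULL

  stage_msg(config, "anova: n_perm %d", config$n_perm)
  anova_jnd <- permutation_mixed_anova(jnd_long, "jnd_ms",
                                       n_perm = config$n_perm,
                                       seed = config$seed + 1L)
  anova_pse <- permutation_mixed_anova(jnd_long, "pse_ms",
                                       n_perm = config$n_perm,
                                       seed = config$seed + 2L)

  mj <- mean_jnd_by_participant(est_kept)
  mj$group <- participants$group[match(mj$participant_id,
                                       participants$participant_id)]
  pairs <- list(c("HC", "BD"), c("HC", "SZ"), c("BD", "SZ"))
  posthoc <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    a <- mj$mean_jnd[mj$group == pr[1]]
    b <- mj$mean_jnd[mj$group == pr[2]]
    pt <- permutation_ttest(a, b, n_perm = config$n_perm,
                            seed = config$seed + 10L + i)
    bf <- jzs_ttest_bf(a, b, prior_r = config$bf_prior_r)
    data.frame(pair = paste(pr, collapse = "-"), t = pt$t,
               p_perm = pt$p_perm, bf10 = bf$bf10,
               bf_prior_r = config$bf_prior_r)
  }))
  posthoc$p_bonferroni <- bonferroni_adjust(posthoc$p_perm,
                                            m = length(pairs))

  stage_msg(config, "model BFs: n_mc %d", config$n_mc_bf)
  pse_bf <- linear_model_bf(jnd_long, value = "pse_ms",
                            n_mc = config$n_mc_bf,
                            seed = config$seed + 20L)

  clinical <- clinical_screen(est_kept, participants, ids = filt$kept)
  medication <- medication_screen(est_kept, participants, ids = filt$kept)

  pat <- participants[participants$group != "HC" &
                        participants$participant_id %in% filt$kept, ]
  glm_dat <- merge(pat[, c("participant_id", "panss_pos")], mj,
                   by = "participant_id")
  glm_fit <- nb_glm_fit(glm_dat$panss_pos, glm_dat$mean_jnd)

  report <- structure(list(
    meta = list(seed = config$seed, n_perm = config$n_perm,
                bf_prior_r = config$bf_prior_r, n_mc_bf = config$n_mc_bf,
                fit_method = config$fit_method),
    sample = list(
      n_per_group = setNames(np$participant_id, np$group),
      n_excluded = length(filt$excluded),
      excluded = filt$excluded,
      mean_trials_per_cell = cell_counts[, c("group", "condition",
                                             "mean_trials")]),
    shapiro = shapiro,
    anova_jnd = as.data.frame(anova_jnd),
    anova_pse = as.data.frame(anova_pse),
    posthoc_jnd = posthoc,
    pse_model_bf = pse_bf,
    clinical_screen = clinical,
    medication_screen = medication,
    glm_panss_pos = unclass(glm_fit)
  ), class = "toj_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    est_out <- estimates
    est_out$excluded <- as.integer(!estimates$participant_id %in% filt$kept)
    utils::write.csv(est_out,
                     file.path(config$out_dir, "estimates.csv"),
                     row.names = FALSE, na = "")
    write_report(report, file.path(config$out_dir, "stats_report.json"))
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a `toj_report` from [run_pipeline()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a report against the package's schema
#'
#' Checks that every section named in the report schema
#' (`inst/extdata/stats_report_schema.json`) is present.
#'
#' @param report a `toj_report` or a path to a report JSON file.
#' @return `TRUE` invisibly, or an error listing the missing sections.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(
    system.file("extdata", "stats_report_schema.json",
                package = "tojpsych"))
  miss <- setdiff(unlist(schema$required), names(report))
  if (length(miss))
    stop("report is missing sections: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
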
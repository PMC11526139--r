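test_that("cohort generation is deterministic and respects the config", {
  cfg <- small_study_config(seed = 101)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)

  tab <- table(a$participants$group)
  expect_equal(as.integer(tab[c("HC", "BD", "SZ")]), c(6L, 6L, 6L))
  # 3 conditions x 52 trials per participant
  expect_equal(unname(table(a$trials$participant_id))[1], 156L)
})

test_that("clinical profiles respect scale structure", {
  cfg <- cohort_config(n_per_group = c(HC = 10, BD = 15, SZ = 15),
                       rng_seed = 5)
  co <- generate_cohort(cfg)
  pp <- co$participants
  hc <- pp[pp$group == "HC", ]
  clin <- c("hamd", "ymrs", "panss_pos", "panss_neg", "panss_gen",
            "med_antipsychotic", "med_mood_stabilizer",
            "med_benzodiazepine", "med_antidepressant")
  expect_true(all(is.na(hc[, clin])))
  pat <- pp[pp$group != "HC", ]
  expect_true(all(pat$panss_pos >= 7))
  expect_true(all(pat$panss_neg >= 7))
  expect_true(all(pat$panss_gen >= 16))
  expect_true(all(pat$hamd >= 0 & pat$ymrs >= 0))
  expect_true(all(observer_truth(co$observers)$sigma > 0))
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(rng_seed = NULL), "rng_seed")
  expect_error(cohort_config(nb_dispersion = 0, rng_seed = 1),
               "dispersion")
  expect_error(cohort_config(n_per_group = c(HC = 0, BD = 5, SZ = 5),
                             rng_seed = 1), "empty group")
  expect_error(observer_params("x", "HC", 30, list(AT = 0, AV = 0, VT = 0),
                               sigma = -5), "sigma")
})

test_that("response model hits its analytic operating points", {
  # 75% point of the cumulative Gaussian: SOA = mu + sigma * qnorm(.75)
  obs <- observer_params("o", "HC", 30, list(AT = 0, AV = 0, VT = 0),
                         sigma = 50)
  set.seed(9)
  soa <- 50 * qnorm(0.75)
  hits <- replicate(10000,
    tojpsych:::simulate_toj_response(obs, "AT", soa)$response == "A")
  expect_equal(mean(hits), 0.75, tolerance = 0.015)

  # lapse mixture at asymptote: 0.5 * 1 + 0.5 * 0.5 = 0.75
  obs$lapse_rate <- 0.5
  hits <- replicate(10000,
    tojpsych:::simulate_toj_response(obs, "AT", 800)$response == "A")
  expect_equal(mean(hits), 0.75, tolerance = 0.015)
})

test_that("true JND is calibrated to the configured population mean", {
  cfg <- cohort_config(n_per_group = c(HC = 2000, BD = 2000, SZ = 2000),
                       rng_seed = 77)
  co <- generate_cohort(cfg)
  tt <- observer_truth(co$observers)
  for (g in c("HC", "BD", "SZ")) {
    want <- cfg$group_sigma_mean[[g]] * qnorm(0.75)
    got <- mean(tt$true_jnd[tt$group == g])
    expect_equal(got, want, tolerance = 0.02 * want)
  }
})

test_that("PANSS-positive coupling recovers the configured slope", {
  cfg <- cohort_config(n_per_group = c(HC = 2, BD = 1500, SZ = 2),
                       rng_seed = 11)
  co <- generate_cohort(cfg)
  tt <- observer_truth(co$observers)
  pat <- merge(co$participants, tt[, c("participant_id", "true_jnd")],
               by = "participant_id")
  pat <- pat[pat$group != "HC", ]
  f <- nb_glm_fit(pat$panss_pos, pat$true_jnd)
  expect_lt(abs(f$beta1 - cfg$glm_beta1), 2 * f$se_beta1)

  # uncoupled cohort: tau between true JND and PANSS-pos is near zero
  cfg0 <- cohort_config(n_per_group = c(HC = 2, BD = 1000, SZ = 2),
                        glm_beta1 = 0, rng_seed = 12)
  co0 <- generate_cohort(cfg0)
  tt0 <- observer_truth(co0$observers)
  pat0 <- merge(co0$participants, tt0[, c("participant_id", "true_jnd")],
                by = "participant_id")
  pat0 <- pat0[pat0$group != "HC", ]
  kt <- kendall_tau_b(pat0$true_jnd, pat0$panss_pos)
  expect_lt(abs(kt$tau_b), 0.05)
})

test_that("datasets round-trip through the CSV readers", {
  for (n in list(c(HC = 1, BD = 1, SZ = 1), c(HC = 3, BD = 3, SZ = 3))) {
    cfg <- cohort_config(n_per_group = n, trials_per_block = 8,
                         rng_seed = 21)
    study <- simulate_study(cfg)
    dir <- file.path(tempdir(), paste0("ds", sum(n)))
    write_dataset(study, dir)
    tr <- read_trials(file.path(dir, "trials.csv"))
    pp <- read_participants(file.path(dir, "participants.csv"))
    expect_equal(tr$soa_ms, study$trials$soa_ms)
    expect_equal(tr$response, study$trials$response)
    expect_equal(tr$skipped, study$trials$skipped)
    expect_equal(pp$participant_id, study$participants$participant_id)
    expect_equal(pp$age, study$participants$age)
    expect_equal(pp$panss_pos, study$participants$panss_pos)
  }
})
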
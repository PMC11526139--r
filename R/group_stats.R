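#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the vetted base implementation, used to screen JND
#' distributions per group x condition before group inference.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("Shapiro-Wilk needs at least 3 values")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Bonferroni adjustment
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param m family size; must be at least `length(pvalues)`.
#' @return `pmin(1, m * pvalues)`.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(pvalues))
    stop("family size m smaller than the number of tests")
  pmin(1, m * pvalues)
}

#' Generalized eta squared
#'
#' Effect size for mixed designs: `SS_effect / (SS_effect +
#' sum(SS_error_terms))`, summing the error sums of squares of every
#' stratum (Olejnik-Algina convention with all factors manipulated).
#'
#' @param ss_effect effect sum of squares.
#' @param ss_errors numeric vector of error sums of squares (between- and
#'   within-participant residuals).
#' @return generalized eta squared in `[0, 1]`.
#' @export
generalized_eta_squared <- function(ss_effect, ss_errors) {
  denom <- ss_effect + sum(ss_errors)
  if (denom <= 0) stop("zero total sum of squares")
  ss_effect / denom
}

# Freedman-Lane permutation F-test for one effect within a stratum.
# y: stratum response; Xf/Xr: full and reduced design matrices;
# perm_idx: n x B matrix of row permutations applied to reduced-model
# residuals. Returns observed F, SS_effect, RSS_full and p_perm.
fl_perm_F <- function(y, Xf, Xr, df_eff, df_err, perm_idx) {
  qf <- qr(Xf)
  rf <- function(Y) qr.resid(qf, Y)
  if (is.null(Xr)) {
    fit_r <- rep(0, length(y)); res_r <- y
    rr <- identity
  } else {
    qr_ <- qr(Xr)
    fit_r <- qr.fitted(qr_, y); res_r <- qr.resid(qr_, y)
    rr <- function(Y) qr.resid(qr_, Y)
  }
  rss_f <- sum(rf(y)^2)
  rss_r <- sum(res_r^2)
  ss_eff <- rss_r - rss_f
  f_obs <- if (rss_f <= 0) Inf else (ss_eff / df_eff) / (rss_f / df_err)
  p_perm <- NA_real_
  if (!is.null(perm_idx)) {
    ystar <- fit_r + matrix(res_r[perm_idx], nrow = length(y))
    rssf_s <- colSums(rf(ystar)^2)
    rssr_s <- colSums(rr(ystar)^2)
    fs <- ifelse(rssf_s <= 0, Inf,
                 ((rssr_s - rssf_s) / df_eff) / (rssf_s / df_err))
    p_perm <- (1 + sum(fs >= f_obs)) / (1 + ncol(perm_idx))
  }
  list(F = f_obs, ss_effect = ss_eff, rss_full = rss_f, p_perm = p_perm)
}

# B column-wise free permutations of 1..n
perm_matrix_free <- function(n, B) {
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

# B permutations of 1..(N*k) that shuffle the k condition rows within each
# participant block (rows ordered participant-major).
perm_matrix_within <- function(N, k, B) {
  base <- (rep(seq_len(N), each = k) - 1L) * k
  vapply(seq_len(B), function(b) {
    off <- as.integer(vapply(seq_len(N), function(i) sample.int(k),
                             integer(k)))
    base + off
  }, integer(N * k))
}

#' Permutation-based mixed-design ANOVA with an age covariate
#'
#' Split-plot decomposition of a participant x condition outcome (JND or
#' PSE) with a between-participant group factor, a centered continuous age
#' covariate, and a within-participant condition factor. Between effects
#' (Group, Age, Group x Age) are tested against the between-participant
#' error; within effects (Condition and its interactions) against the
#' within-participant error, reproducing the classic split-plot degrees of
#' freedom. Each effect's permutation p-value uses the Freedman-Lane
#' scheme: residuals of the reduced model in the effect's stratum are
#' permuted (freely across participants for between effects; condition
#' labels within participant for within effects), and the Type-III F is
#' recomputed; `p = (1 + #\{F* >= F\}) / (1 + n_perm)`.
#'
#' @param data long data frame with columns `participant_id`, `group`,
#'   `age`, `condition`, and the outcome column `value`. Every participant
#'   must contribute every condition exactly once.
#' @param value name of the outcome column (default `"jnd_ms"`).
#' @param n_perm number of permutations (default 5000; minimum 99).
#' @param seed integer seed for the permutation draws (required).
#' @return object of class `perm_anova`: a data frame with one row per
#'   effect (`effect`, `df_num`, `df_den`, `F`, `p_perm`, `ges`,
#'   `ss_effect`), with attributes `n_perm`, `seed`, `ss_error_between`,
#'   `ss_error_within`, `ss_total`, `n`.
#' @export
permutation_mixed_anova <- function(data, value = "jnd_ms",
                                    n_perm = 5000, seed = NULL) {
  if (is.null(seed)) stop("seed is required for permutation inference")
  if (!is.null(n_perm) && n_perm < 99) stop("n_perm must be at least 99")
  need <- c("participant_id", "group", "age", "condition", value)
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)),
                                    collapse = ", "))
  conds <- sort(unique(data$condition))
  k <- length(conds)
  tab <- table(data$participant_id, data$condition)
  bad <- rownames(tab)[rowSums(tab == 1) != k]
  if (length(bad))
    stop("incomplete within-participant design for: ",
         paste(bad, collapse = ", "))
  ids <- sort(unique(data$participant_id))
  N <- length(ids)
  # participant-major, condition-minor ordering
  data <- data[order(match(data$participant_id, ids),
                     match(data$condition, conds)), ]
  Y <- matrix(data[[value]], nrow = N, ncol = k, byrow = TRUE)
  pdat <- data[!duplicated(data$participant_id),
               c("participant_id", "group", "age")]
  grp <- factor(pdat$group)
  G <- nlevels(grp)
  if (G < 2) stop("need at least 2 groups")
  age_c <- pdat$age - mean(pdat$age)

  # between stratum: scaled participant means
  u <- sqrt(k) * rowMeans(Y)
  Xg <- contr.sum(G)[as.integer(grp), , drop = FALSE]
  Xb_int <- matrix(1, N, 1)
  Xb_grp <- Xg
  Xb_age <- matrix(age_c, N, 1)
  Xb_ga <- Xg * age_c
  Xb_full <- cbind(Xb_int, Xb_grp, Xb_age, Xb_ga)
  df_err_b <- N - ncol(Xb_full)
  if (df_err_b < 1) stop("no between-participant error degrees of freedom")

  # within stratum: participant-centered values, participant-major stacking
  w <- as.vector(t(Y - rowMeans(Y)))
  Cc <- contr.sum(k)                            # k x (k-1)
  Ccond <- Cc[rep(seq_len(k), times = N), , drop = FALSE]
  age_l <- rep(age_c, each = k)
  Xg_l <- Xg[rep(seq_len(N), each = k), , drop = FALSE]
  Xw_c <- Ccond
  Xw_ca <- Ccond * age_l
  Xw_cg <- do.call(cbind, lapply(seq_len(ncol(Xg_l)), function(j)
    Ccond * Xg_l[, j]))
  Xw_cga <- Xw_cg * age_l
  Xw_full <- cbind(Xw_c, Xw_ca, Xw_cg, Xw_cga)
  df_err_w <- N * (k - 1) - ncol(Xw_full)
  if (df_err_w < 1) stop("no within-participant error degrees of freedom")

  set.seed(seed)
  Pb <- if (is.null(n_perm)) NULL else perm_matrix_free(N, n_perm)
  Pw <- if (is.null(n_perm)) NULL else perm_matrix_within(N, k, n_perm)

  btw_effects <- list(Group = Xb_grp, Age = Xb_age, `Group:Age` = Xb_ga)
  wth_effects <- list(Condition = Xw_c, `Condition:Age` = Xw_ca,
                      `Group:Condition` = Xw_cg,
                      `Group:Condition:Age` = Xw_cga)

  run_stratum <- function(effects, y, Xfull, df_err, P) {
    cols <- lapply(effects, ncol)
    lapply(names(effects), function(nm) {
      keep <- setdiff(names(effects), nm)
      Xr <- do.call(cbind, c(list(if (identical(y, u)) Xb_int else NULL),
                             effects[keep]))
      res <- fl_perm_F(y, Xfull, Xr, cols[[nm]], df_err, P)
      res$effect <- nm; res$df_num <- cols[[nm]]; res$df_den <- df_err
      res
    })
  }
  rb <- run_stratum(btw_effects, u, Xb_full, df_err_b, Pb)
  rw <- run_stratum(wth_effects, w, Xw_full, df_err_w, Pw)

  rss_b <- sum(qr.resid(qr(Xb_full), u)^2)
  rss_w <- sum(qr.resid(qr(Xw_full), w)^2)
  all_res <- c(rb, rw)
  out <- do.call(rbind, lapply(all_res, function(r)
    data.frame(effect = r$effect, df_num = r$df_num, df_den = r$df_den,
               F = r$F, p_perm = r$p_perm,
               ges = generalized_eta_squared(max(r$ss_effect, 0),
                                             c(rss_b, rss_w)),
               ss_effect = r$ss_effect)))
  rownames(out) <- NULL
  structure(out, class = c("perm_anova", "data.frame"),
            n_perm = n_perm, seed = seed,
            ss_error_between = rss_b, ss_error_within = rss_w,
            ss_total = sum((data[[value]] - mean(data[[value]]))^2),
            n = N, k = k)
}

#' Welch permutation t-test
#'
#' Two-sample Welch t statistic (`mean(a) - mean(b)` over the pooled
#' standard error) with a permutation reference distribution from random
#' (or, for small samples, exhaustive) reassignments of the pooled values.
#' The two-sided p-value counts permuted `|t*| >= |t_obs|`; Monte-Carlo
#' p-values include the observed statistic (`(1 + c) / (1 + n_perm)`).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param n_perm number of Monte-Carlo permutations (default 5000).
#' @param seed integer seed (required for Monte-Carlo mode).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default enumerates when there are at most 10000 reassignments.
#' @return list with `t`, `p_perm`, `n_perm` (or `"exact"`), `seed`.
#' @export
permutation_ttest <- function(values_a, values_b, n_perm = 5000,
                              seed = NULL, exact = NULL) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each arm needs at least 2 values")
  welch_t <- function(x, y) {
    se2 <- var(x) / length(x) + var(y) / length(y)
    d <- mean(x) - mean(y)
    if (se2 <= 0) { if (d == 0) 0 else sign(d) * Inf } else d / sqrt(se2)
  }
  if (var(a) + var(b) <= 0 && mean(a) == mean(b))
    stop("degenerate variance with equal means: t undefined")
  t_obs <- welch_t(a, b)
  pool <- c(a, b)
  n <- na + nb
  n_comb <- choose(n, na)
  if (is.null(exact)) exact <- n_comb <= 10000
  if (exact) {
    idx <- utils::combn(n, na)
    ts <- apply(idx, 2, function(ii) welch_t(pool[ii], pool[-ii]))
    p <- mean(abs(ts) >= abs(t_obs) - 1e-12)
    return(list(t = t_obs, p_perm = p, n_perm = "exact", seed = seed))
  }
  if (is.null(seed)) stop("seed is required for Monte-Carlo permutations")
  set.seed(seed)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    ii <- sample.int(n, na)
    if (abs(welch_t(pool[ii], pool[-ii])) >= abs(t_obs) - 1e-12)
      cnt <- cnt + 1L
  }
  list(t = t_obs, p_perm = (1 + cnt) / (1 + n_perm), n_perm = n_perm,
       seed = seed)
}
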
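#' JZS Bayes factor from a t statistic
#'
#' Jeffreys-Zellner-Siow default Bayes factor for a one- or two-sample
#' t design: Cauchy prior with scale `rscale` on the standardized effect,
#' Jeffreys priors on nuisance mean and variance. Computed by adaptive 1-D
#' quadrature of the marginal likelihood over the mixing parameter g
#' (g ~ inverse-gamma(1/2, rscale^2/2)), mapped to the unit interval.
#'
#' @param t observed t statistic.
#' @param n1 first sample size.
#' @param n2 second sample size (`NULL` for a one-sample design).
#' @param rscale Cauchy prior scale (default 0.707).
#' @return `bf10`, the Bayes factor for the effect against the point null.
#' @export
jzs_bf_from_t <- function(t, n1, n2 = NULL, rscale = 0.707) {
  if (rscale <= 0) stop("rscale must be positive")
  if (is.null(n2)) {
    ne <- n1; nu <- n1 - 1
  } else {
    ne <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2
  }
  if (nu < 1) stop("sample too small for a defined t statistic")
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(u) {
    g <- u / (1 - u)
    log_alt <- -0.5 * log1p(ne * g) -
      (nu + 1) / 2 * log1p(t^2 / (nu * (1 + ne * g)))
    log_prior <- 0.5 * log(rscale^2 / 2) - lgamma(0.5) -
      1.5 * log(g) - rscale^2 / (2 * g)
    jac <- -2 * log(1 - u)
    exp(log_alt - log_null + log_prior + jac)
  }
  q <- stats::integrate(integrand, 0, 1, rel.tol = 1e-10,
                        subdivisions = 1000L)
  q$value
}

#' JZS two-sample t Bayes factor
#'
#' Computes the pooled-variance two-sample t statistic and the
#' corresponding [jzs_bf_from_t()] Bayes factor. `bf10 > 1` favors a group
#' difference; `bf10 < 1` favors the null (equal means).
#'
#' @param values_a,values_b numeric vectors.
#' @param prior_r Cauchy prior scale (default 0.707).
#' @return list with `bf10`, `t`, `n1`, `n2`, `prior_r`.
#' @export
jzs_ttest_bf <- function(values_a, values_b, prior_r = 0.707) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("too few observations for a defined t")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(bf10 = jzs_bf_from_t(t, n1, n2, prior_r), t = t,
       n1 = n1, n2 = n2, prior_r = prior_r)
}

# Monte-Carlo Zellner-Siow marginal: blocks is a list of design-matrix
# blocks, rscales the per-block prior scales. Returns log BF vs the
# intercept-only model plus a Monte-Carlo standard error.
zs_log_bf_mc <- function(yc, blocks, rscales, n_mc) {
  X <- do.call(cbind, blocks)
  pb <- vapply(blocks, ncol, integer(1))
  n <- length(yc)
  XtX <- crossprod(X); Xty <- crossprod(X, yc); yty <- sum(yc^2)
  p <- ncol(X)
  logr <- numeric(n_mc)
  for (m in seq_len(n_mc)) {
    g <- 1 / rgamma(length(blocks), shape = 0.5, rate = rscales^2 / 2)
    g_cols <- rep(g, pb)
    A <- XtX + diag(1 / g_cols, p)
    ch <- chol(A)
    logdet <- 2 * sum(log(diag(ch)))
    v <- backsolve(ch, forwardsolve(t(ch), Xty))
    rss <- max(yty - sum(Xty * v), .Machine$double.eps * yty)
    logr[m] <- -0.5 * (sum(log(g_cols)) + logdet) -
      (n - 1) / 2 * (log(rss) - log(yty))
  }
  mx <- max(logr)
  bf <- mx + log(mean(exp(logr - mx)))
  se <- sd(exp(logr - mx)) / sqrt(n_mc) / mean(exp(logr - mx))
  list(log_bf = bf, rel_mc_error = se)
}

#' Bayes factors for group/condition structure in a repeated-measures table
#'
#' Compares linear models of a participant x condition outcome (e.g. PSE)
#' against the participant-intercepts-only null under Zellner-Siow
#' mixture-of-g priors: each tested model adds centered effect-coded blocks
#' for Group, Condition, their sum, or their crossing to an additive
#' participant nuisance block. Each block carries its own g with an
#' inverse-gamma(1/2, r^2/2) mixing prior (`r = rscale_random` for the
#' participant block, `rscale_fixed` for effect blocks); marginal
#' likelihoods are integrated by Monte Carlo over the g's, with the
#' relative integration error reported.
#'
#' @param data long data frame with `participant_id`, `group`, `condition`
#'   and the outcome column `value`; complete and balanced.
#' @param value outcome column name (default `"pse_ms"`).
#' @param effects character vector among `"Group"`, `"Condition"`,
#'   `"Group+Condition"`, `"Group:Condition"` (default all four).
#' @param rscale_fixed,rscale_random prior scales (defaults 0.5 and 1).
#' @param n_mc Monte-Carlo draws per model (default 4000).
#' @param seed integer seed (required).
#' @return data frame with `effect`, `bf10` (model vs participant-only
#'   null), `log_bf10`, and `rel_mc_error`.
#' @export
linear_model_bf <- function(data, value = "pse_ms",
                            effects = c("Group", "Condition",
                                        "Group+Condition",
                                        "Group:Condition"),
                            rscale_fixed = 0.5, rscale_random = 1,
                            n_mc = 4000, seed = NULL) {
  if (is.null(seed)) stop("seed is required for Monte-Carlo integration")
  effects <- match.arg(effects, several.ok = TRUE)
  ids <- sort(unique(data$participant_id))
  conds <- sort(unique(data$condition))
  N <- length(ids); k <- length(conds)
  if (nrow(data) != N * k ||
      any(table(data$participant_id, data$condition) != 1))
    stop("data must be complete and balanced (one row per participant x condition)")
  data <- data[order(match(data$participant_id, ids),
                     match(data$condition, conds)), ]
  y <- data[[value]]
  yc <- y - mean(y)
  center <- function(M) sweep(M, 2, colMeans(M))
  P <- center(contr.sum(N)[rep(seq_len(N), each = k), , drop = FALSE])
  Gc <- contr.sum(nlevels(factor(data$group)))[
    as.integer(factor(data$group)), , drop = FALSE]
  if (qr(cbind(1, Gc))$rank <= 1) stop("rank-deficient design: one group")
  Gm <- center(Gc)
  Cm <- center(contr.sum(k)[match(data$condition, conds), , drop = FALSE])
  GCm <- center(do.call(cbind, lapply(seq_len(ncol(Gc)), function(j)
    Cm * Gc[, j])))
  model_blocks <- list(
    "Group" = list(blocks = list(P, Gm), r = c(rscale_random, rscale_fixed)),
    "Condition" = list(blocks = list(P, Cm),
                       r = c(rscale_random, rscale_fixed)),
    "Group+Condition" = list(blocks = list(P, Gm, Cm),
                             r = c(rscale_random, rscale_fixed,
                                   rscale_fixed)),
    "Group:Condition" = list(blocks = list(P, Gm, Cm, GCm),
                             r = c(rscale_random, rep(rscale_fixed, 3))))
  set.seed(seed)
  null_mc <- zs_log_bf_mc(yc, list(P), rscale_random, n_mc)
  rows <- lapply(effects, function(e) {
    mb <- model_blocks[[e]]
    mc <- zs_log_bf_mc(yc, mb$blocks, mb$r, n_mc)
    data.frame(effect = e, bf10 = exp(mc$log_bf - null_mc$log_bf),
               log_bf10 = mc$log_bf - null_mc$log_bf,
               rel_mc_error = sqrt(mc$rel_mc_error^2 +
                                     null_mc$rel_mc_error^2))
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "n_mc") <- n_mc
  out
}
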
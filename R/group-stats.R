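#' Two-sample t test with Cohen's d
#'
#' Pooled-variance two-sample t test (`df = n_a + n_b - 2`) with Cohen's d
#' computed on the pooled standard deviation. The statistic is positive when
#' group `a` has the larger mean.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a `test_result` list: `statistic`, `df`, `p`, `effect_size`
#'   (Cohen's d), `method`.
#' @export
two_sample_t <- function(a, b) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tval <- (mean(a) - mean(b)) / se
  df <- na + nb - 2
  list(statistic = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       effect_size = (mean(a) - mean(b)) / sqrt(sp2),
       method = "two-sample t (pooled variance), Cohen's d")
}

#' Interaction test in a 2 x 2 ANOVA
#'
#' Two-way ANOVA for two binary factors with type-II sums of squares
#' (appropriate for unbalanced cell sizes): the interaction sum of squares
#' is the drop in residual sum of squares from the additive model
#' `y ~ f1 + f2` to the full model `y ~ f1 * f2`. Reports the interaction F,
#' degrees of freedom, p, and partial eta squared
#' `SS_int / (SS_int + SS_error)`.
#'
#' @param y numeric response.
#' @param factor1,factor2 binary factors (two levels each); all four cells
#'   must be nonempty.
#' @return a `test_result` list: `statistic` (F), `df` (c(1, df_res)), `p`,
#'   `effect_size` (partial eta squared), `method`, `defined` (FALSE when
#'   the response is constant).
#' @export
two_way_anova_interaction <- function(y, factor1, factor2) {
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  f1 <- factor(factor1[keep]); f2 <- factor(factor2[keep])
  stopifnot(nlevels(f1) == 2, nlevels(f2) == 2)
  if (any(table(f1, f2) == 0)) stop("empty design cell", call. = FALSE)
  if (stats::var(y) == 0) {
    return(list(statistic = NA_real_, df = c(1, length(y) - 4), p = NA_real_,
                effect_size = NA_real_, method = "two-way ANOVA interaction",
                defined = FALSE))
  }
  fit_add <- stats::lm(y ~ f1 + f2)
  fit_full <- stats::lm(y ~ f1 * f2)
  ss_int <- sum(stats::residuals(fit_add)^2) - sum(stats::residuals(fit_full)^2)
  ss_err <- sum(stats::residuals(fit_full)^2)
  df_res <- stats::df.residual(fit_full)
  fval <- (ss_int / 1) / (ss_err / df_res)
  list(statistic = fval, df = c(1, df_res),
       p = stats::pf(fval, 1, df_res, lower.tail = FALSE),
       effect_size = ss_int / (ss_int + ss_err),
       method = "two-way ANOVA interaction (type II SS), partial eta^2",
       defined = TRUE)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p`, `df`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  stopifnot(length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in correlation input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter))
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the OLS residuals of `x` and `y` after regressing each on
#' the control variables (plus an intercept); the p value uses
#' `df = n - n_controls - 2`.
#'
#' @param x,y numeric vectors.
#' @param control numeric vector or matrix of control variables.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, control) {
  control <- as.matrix(control)
  keep <- !is.na(x) & !is.na(y) & stats::complete.cases(control)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  control <- control[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(control)
  if (n <= k + 2) stop("too few observations for the controls", call. = FALSE)
  X <- cbind(1, control)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient control matrix", call. = FALSE)
  rx <- stats::.lm.fit(X, x)$residuals
  ry <- stats::.lm.fit(X, y)$residuals
  if (stats::var(rx) < 1e-14 || stats::var(ry) < 1e-14) {
    stop("zero residual variance after controlling", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH adjustment of a p-value vector and the significance mask at
#' level `q`.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  check_pvalues(p_values)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj <= q)
}

#' Bonferroni correction
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p values (`p * m`, capped at 1).
#' @export
bonferroni <- function(p_values) {
  check_pvalues(p_values)
  stats::p.adjust(p_values, method = "bonferroni")
}

check_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Bootstrap mediation analysis
#'
#' Decomposes the effect of `x` on `y` through a mediator `m` with three OLS
#' fits: `m ~ x` gives the path `alpha`; `y ~ x` gives the total effect
#' `gamma`; `y ~ x + m` gives the direct effect `gamma_prime` and the path
#' `beta`. The indirect effect is `alpha * beta`, and the OLS identity
#' `gamma = gamma_prime + alpha * beta` holds exactly. Percentile confidence
#' intervals for every coefficient come from seeded case-resampling
#' bootstrap.
#'
#' @param x,m,y numeric vectors of equal length >= 10.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return a `mediation_result`: list with `alpha`, `beta`, `gamma`,
#'   `gamma_prime`, `indirect`, per-coefficient `ci` matrix, `n`, `n_boot`,
#'   `seed`.
#' @export
mediation_bootstrap <- function(x, m, y, n_boot = 5000, seed = 1L,
                                conf = 0.95) {
  keep <- !is.na(x) & !is.na(m) & !is.na(y)
  x <- as.numeric(x[keep]); m <- as.numeric(m[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  stopifnot(n >= 10, n_boot >= 1)
  if (abs(stats::cor(x, m)) > 1 - 1e-8) {
    stop("x and m are collinear; mediation paths are unidentified",
         call. = FALSE)
  }
  paths <- function(x, m, y) {
    a <- stats::.lm.fit(cbind(1, x), m)$coefficients[2]
    g <- stats::.lm.fit(cbind(1, x), y)$coefficients[2]
    co <- stats::.lm.fit(cbind(1, x, m), y)$coefficients
    c(alpha = a, beta = co[3], gamma = g, gamma_prime = co[2],
      indirect = a * co[3])
  }
  est <- paths(x, m, y)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    t(apply(idx, 2, function(i) paths(x[i], m[i], y[i])))
  })
  alpha2 <- (1 - conf) / 2
  ci <- t(apply(boot, 2, stats::quantile, probs = c(alpha2, 1 - alpha2)))
  colnames(ci) <- c("lower", "upper")
  rownames(ci) <- names(est) <- c("alpha", "beta", "gamma", "gamma_prime",
                                  "indirect")
  structure(list(alpha = est[["alpha"]], beta = est[["beta"]],
                 gamma = est[["gamma"]], gamma_prime = est[["gamma_prime"]],
                 indirect = est[["indirect"]], ci = ci, n = n,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 conf = conf),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n=%d, %d bootstrap replicates\n",
              x$n, x$n_boot))
  est <- c(alpha = x$alpha, beta = x$beta, gamma = x$gamma,
           gamma_prime = x$gamma_prime, indirect = x$indirect)
  out <- cbind(estimate = est, x$ci)
  print(round(out, 4))
  invisible(x)
}
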
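#' Repeated-measures one-way ANOVA with sphericity handling
#'
#' Within-subject one-way decomposition of a participants x levels matrix.
#' For k >= 3 levels, Mauchly's sphericity test is computed on the covariance
#' of k-1 orthonormal contrasts of the level scores; when it rejects at
#' p < 0.05, the Greenhouse-Geisser epsilon rescales both degrees of freedom
#' before the p-value is taken. Effect size is partial eta squared,
#' SS_effect / (SS_effect + SS_error).
#'
#' @param data numeric matrix, rows = participants, columns = levels; no
#'   missing cells.
#' @return A list of class `anova_result` with elements `F`, `df_num`,
#'   `df_den`, `p`, `eta_sq`, `epsilon`, `mauchly_p`, `corrected`,
#'   `p_uncorrected`.
#' @export
rm_anova <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("data: missing or non-finite cells")
  n <- nrow(data); k <- ncol(data)
  if (n < 2) stop("data: need >= 2 participants")
  if (k < 2) stop("data: need >= 2 levels")

  grand <- mean(data)
  subj_means <- rowMeans(data)
  lvl_means <- colMeans(data)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_lvl <- n * sum((lvl_means - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_lvl
  ss_err <- max(ss_err, 0)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  F_stat <- if (ms_err > 0) (ss_lvl / df1) / ms_err else if (ss_lvl > 0) Inf else 0
  eta_sq <- if (ss_lvl + ss_err > 0) ss_lvl / (ss_lvl + ss_err) else 0

  epsilon <- NA_real_
  mauchly_p <- NA_real_
  corrected <- FALSE
  p_unc <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  p <- p_unc
  df_num <- df1; df_den <- df2

  if (k >= 3) {
    C <- orthonormal_contrasts(k)
    V <- stats::cov(data %*% C)          # (k-1) x (k-1) contrast covariance
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    if (sum(ev^2) > 0) {
      epsilon <- sum(ev)^2 / (df1 * sum(ev^2))
      epsilon <- min(max(epsilon, 1 / df1), 1)
    } else epsilon <- 1
    mauchly_p <- mauchly_p_value(V, n, k)
    if (is.finite(mauchly_p) && mauchly_p < 0.05) {
      corrected <- TRUE
      df_num <- epsilon * df1
      df_den <- epsilon * df2
      p <- stats::pf(F_stat, df_num, df_den, lower.tail = FALSE)
    }
  }

  structure(list(F = F_stat, df_num = df_num, df_den = df_den, p = p,
                 p_uncorrected = p_unc, eta_sq = eta_sq, epsilon = epsilon,
                 mauchly_p = mauchly_p, corrected = corrected,
                 n = n, k = k),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("rm-ANOVA: F(%.3g, %.3g) = %.4f, p = %.4g, partial eta^2 = %.3f%s\n",
              x$df_num, x$df_den, x$F, x$p, x$eta_sq,
              if (isTRUE(x$corrected)) sprintf(" [GG eps = %.3f]", x$epsilon) else ""))
  invisible(x)
}

# k x (k-1) matrix of orthonormal contrasts (orthogonal to the unit vector)
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Mauchly's W on an already-formed contrast covariance (dims (k-1) x (k-1))
mauchly_p_value <- function(V, n, k) {
  d <- k - 1
  tr <- sum(diag(V))
  if (tr <= 0) return(NA_real_)
  detV <- det(V)
  if (detV <= 0) return(0)                  # perfectly degenerate: sphericity dead
  W <- detV / (tr / d)^d
  # Mauchly's chi-square approximation with the second-order expansion term
  ndf <- n - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * ndf)
  X2 <- -ndf * rho * log(W)
  f <- d * (d + 1) / 2 - 1
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
    (288 * d^2 * ndf^2 * rho^2)
  p1 <- stats::pchisq(X2, f, lower.tail = FALSE)
  min(1, max(0, p1 + w2 * (stats::pchisq(X2, f + 4, lower.tail = FALSE) - p1)))
}

#' Two-sided paired t test
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop("zero variance of differences")
  res <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and monotone in the raw values.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return Adjusted vector, same order as input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p_values: must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return List of class `correlation_result` with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  res <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(res$estimate), p = res$p.value, n = length(x)),
            class = "correlation_result")
}

#' Ordinary least squares with overall F test
#'
#' Fits `y ~ X` with an intercept prepended (unless `add_intercept = FALSE`,
#' in which case the first column of `X` is taken as given). Reports
#' coefficients, the overall F against the intercept-only model, R squared,
#' and its p-value.
#'
#' @param X numeric matrix of predictors (n x p).
#' @param y numeric response vector.
#' @param add_intercept prepend an intercept column (default `TRUE`).
#' @return List of class `regression_result` with `coefficients`, `F`, `R2`,
#'   `p`, `df_num`, `df_den`, `residuals`.
#' @export
ols <- function(X, y, add_intercept = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y length must match nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  M <- if (add_intercept) cbind(`(Intercept)` = 1, X) else X
  p <- ncol(M)
  if (n <= p) stop("need n > number of coefficients")
  if (qr(M)$rank < p) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(M, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_num <- p - if (add_intercept) 1L else 0L
  df_den <- n - p
  if (df_num == 0) stop("no non-intercept predictors")
  R2 <- if (tss > 0) 1 - rss / tss else NA_real_
  F_stat <- if (rss > 0) ((tss - rss) / df_num) / (rss / df_den) else Inf
  p_val <- stats::pf(F_stat, df_num, df_den, lower.tail = FALSE)
  structure(list(coefficients = coefs, F = F_stat, R2 = R2, p = p_val,
                 df_num = df_num, df_den = df_den, residuals = res),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: F(%d, %d) = %.4f, p = %.4g, R^2 = %.4f\n",
              x$df_num, x$df_den, x$F, x$p, x$R2))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Inverse standard-normal quantile
#'
#' The Z transform used by the d-prime computation, `Z(q) = qnorm(q)`.
#'
#' @param q probability strictly inside (0, 1).
#' @return The standard-normal quantile.
#' @export
z_quantile <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0 | q >= 1)) stop("q: must lie strictly in (0, 1)")
  stats::qnorm(q)
}
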
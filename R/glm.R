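#' Fit a quasi-binomial GLM by iteratively reweighted least squares
#'
#' Logit-link binomial-family fit of a proportion response with prior
#' weights (typically the total junction counts supporting each PSI value).
#' The quasi-binomial dispersion is estimated as Pearson chi-squared over
#' residual degrees of freedom; it inflates the variance without changing
#' the coefficient estimates.
#'
#' @param y proportions in `[0,1]`.
#' @param X design matrix (with intercept column).
#' @param weights prior weights > 0; default 1 (use the retained totals
#'   where counts exist, 1 for imputed cells).
#' @param tol relative deviance-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `coefficients`, `fitted`, `deviance`, `pearson`,
#'   `dispersion` (`NA` when the fit is saturated), `df_residual`,
#'   `converged`.
#' @export
fit_quasibinomial_glm <- function(y, X, weights = NULL, tol = 1e-10,
                                  max_iter = 100L) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (any(y < 0 | y > 1)) stop("response must lie in [0,1]")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be > 0")
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  eps <- 1e-8
  mu <- pmin(pmax((weights * y + 0.5) / (weights + 1), eps), 1 - eps)
  eta <- log(mu / (1 - mu))
  dev_terms <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
    2 * sum(weights * (t1 + t2))
  }
  dev <- dev_terms(mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- weights * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- stats::lm.wfit(X, z, W)
    eta <- drop(X %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    eta <- pmin(pmax(eta, -30), 30)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, eps), 1 - eps)
    dev_new <- dev_terms(mu)
    if (is.finite(dev) && abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new; converged <- TRUE; break
    }
    dev <- dev_new
  }
  pearson <- sum(weights * (y - mu)^2 / (mu * (1 - mu)))
  df_res <- n - p
  structure(list(coefficients = fit$coefficients, fitted = mu, deviance = dev,
                 pearson = pearson,
                 dispersion = if (df_res > 0) pearson / df_res else NA_real_,
                 df_residual = df_res, converged = converged),
            class = "qb_glm")
}

#' Quasi-likelihood ratio F-test between nested quasi-binomial fits
#'
#' `F = ((D0 - D1) / df_num) / phi_full`, compared to an F distribution
#' with `(df_num, df_residual(full))` degrees of freedom — the standard
#' quasi-likelihood analysis-of-deviance test.
#'
#' @param fit_null,fit_full fits from [fit_quasibinomial_glm()] on the same
#'   data; the null design must be nested in the full design.
#' @return list with `f_statistic`, `df_num`, `df_den`, `dispersion`,
#'   `pvalue`.
#' @export
qlrt <- function(fit_null, fit_full) {
  df_num <- fit_null$df_residual - fit_full$df_residual
  df_den <- fit_full$df_residual
  if (df_num < 1L || df_den < 1L) stop("invalid degrees of freedom for QLRT")
  phi <- fit_full$dispersion
  d_drop <- max(fit_null$deviance - fit_full$deviance, 0)
  if (!is.finite(phi) || phi <= 0) {
    return(list(f_statistic = NA_real_, df_num = df_num, df_den = df_den,
                dispersion = phi, pvalue = 1))
  }
  f <- (d_drop / df_num) / phi
  list(f_statistic = f, df_num = df_num, df_den = df_den, dispersion = phi,
       pvalue = stats::pf(f, df_num, df_den, lower.tail = FALSE))
}

#' Precision weights for PSI regression
#'
#' Observed cells are weighted by their junction totals, moderated by the
#' intra-class correlation prior `rho0`: `w = n / (1 + (n - 1) * rho0)`.
#' Under beta-binomial counts the variance of a PSI value is
#' `p(1-p) * (1 + (n-1)rho) / n`, so these are inverse-variance weights and
#' keep the quasi-binomial dispersion homogeneous across unequal totals
#' (raw totals over-weight deep cells, whose precision is capped by the
#' intra-class correlation, and make the QL F-test anti-conservative).
#' `rho0 = 0` recovers plain total-count weights. Imputed cells carry no
#' count evidence and get weight 1.
#'
#' @param psi a `psi_matrix`.
#' @param rho0 intra-class correlation prior (default 0.02).
#' @return weight matrix, events x samples.
#' @export
glm_weights <- function(psi, rho0 = 0.02) {
  if (is.null(psi$L) || is.null(psi$S))
    return(matrix(1, nrow(psi$psi), ncol(psi$psi)))
  tot <- psi$L + psi$S
  tot[is.na(tot) | tot <= 0 | psi$missing_mask] <- 1
  tot / (1 + (tot - 1) * rho0)
}
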
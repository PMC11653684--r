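#' Quasi-likelihood ratio test for developmentally dynamic splicing
#'
#' Per event, fits a quasi-binomial GLM of PSI on a natural cubic spline of
#' developmental stage rank (full model) against an intercept-only null, and
#' reports the quasi-likelihood ratio F-test
#' `F = ((D0 - D1)/df_num) / phi_full` with `phi_full` the Pearson
#' dispersion of the full model. P-values are Benjamini-Hochberg adjusted
#' across events.
#'
#' Stage labels are rank-transformed (embryonic-day / postnatal-day labels
#' need only be ordered, not on a common scale); the spline has `spline_df`
#' degrees of freedom, capped at the number of distinct stages minus one.
#'
#' @param psi an imputed `psi_matrix` whose metadata has a numeric `stage`.
#' @param spline_df spline degrees of freedom (default 3).
#' @param rho0 intra-class correlation prior for the precision weights, see
#'   [glm_weights()].
#' @return data.frame: `event_id`, `f_statistic`, `df_num`, `df_den`,
#'   `dispersion`, `pvalue`, `adjusted_pvalue`, `converged`.
#' @export
qlrt_devtest <- function(psi, spline_df = 3L, rho0 = 0.02) {
  stage <- psi$metadata$stage
  if (any(is.na(stage))) stop("all samples need a stage for the devSE test")
  n_stages <- length(unique(stage))
  if (n_stages < 3L) stop("need at least 3 distinct stages")
  spline_df <- min(spline_df, n_stages - 1L)
  srank <- match(stage, sort(unique(stage)))
  X1 <- cbind(1, splines::ns(srank, df = spline_df))
  X0 <- matrix(1, length(srank), 1L)
  w <- glm_weights(psi, rho0)
  res <- lapply(seq_len(nrow(psi$psi)), function(i) {
    y <- psi$psi[i, ]
    if (stats::sd(y) == 0)
      return(list(f = NA_real_, df_num = ncol(X1) - 1L,
                  df_den = length(y) - ncol(X1), phi = NA_real_, p = 1,
                  converged = TRUE))
    f0 <- fit_quasibinomial_glm(y, X0, w[i, ])
    f1 <- fit_quasibinomial_glm(y, X1, w[i, ])
    if (!f1$converged || !f0$converged)
      return(list(f = NA_real_, df_num = ncol(X1) - 1L,
                  df_den = length(y) - ncol(X1), phi = NA_real_, p = NA_real_,
                  converged = FALSE))
    t <- qlrt(f0, f1)
    list(f = t$f_statistic, df_num = t$df_num, df_den = t$df_den,
         phi = t$dispersion, p = t$pvalue, converged = TRUE)
  })
  out <- data.frame(
    event_id = psi$events$event_id,
    f_statistic = vapply(res, `[[`, numeric(1L), "f"),
    df_num = vapply(res, function(r) as.integer(r$df_num), integer(1L)),
    df_den = vapply(res, function(r) as.integer(r$df_den), integer(1L)),
    dispersion = vapply(res, `[[`, numeric(1L), "phi"),
    pvalue = vapply(res, `[[`, numeric(1L), "p"),
    converged = vapply(res, `[[`, logical(1L), "converged"),
    stringsAsFactors = FALSE
  )
  out$adjusted_pvalue <- NA_real_
  ok <- !is.na(out$pvalue)
  out$adjusted_pvalue[ok] <- benjamini_hochberg(out$pvalue[ok])
  out
}

#' Call developmentally dynamic skipped exons (devSEs)
#'
#' An event is a devSE iff its BH-adjusted p-value is `<= alpha`
#' (inclusive, default 0.05).
#'
#' @param results output of [qlrt_devtest()].
#' @param alpha inclusive adjusted-p threshold.
#' @return the result table with `is_devse`; attribute `fraction` is the
#'   devSE percentage among tested events.
#' @export
call_devses <- function(results, alpha = 0.05) {
  is_devse <- !is.na(results$adjusted_pvalue) &
    results$adjusted_pvalue <= alpha
  results$is_devse <- is_devse
  tested <- sum(!is.na(results$adjusted_pvalue))
  attr(results, "fraction") <-
    if (tested > 0) summarize_overlap(sum(is_devse), tested) else NA_real_
  results
}
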
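#' Two-group differential splicing test per event
#'
#' Compares inclusion between two sample groups (e.g. proliferating GM vs
#' differentiating DM myoblasts) with a quasi-binomial GLM on a single
#' group indicator, tested against the intercept-only model by a
#' quasi-likelihood ratio F-test. The effect size is the plain difference of
#' group mean PSI, `delta_psi = mean(group_b) - mean(group_a)` — with the
#' GM/DM convention, positive values mean more inclusion upon
#' differentiation.
#'
#' @param psi an imputed `psi_matrix`.
#' @param group_a,group_b values of `metadata$group` defining the reference
#'   and contrast groups (defaults `"GM"`, `"DM"`).
#' @param rho0 intra-class correlation prior for the precision weights, see
#'   [glm_weights()].
#' @return data.frame: `event_id`, `delta_psi`, `statistic` (quasi F),
#'   `pvalue`, `fdr` (Benjamini-Hochberg across events), `converged`.
#' @export
test_two_group <- function(psi, group_a = "GM", group_b = "DM", rho0 = 0.02) {
  sel_a <- psi$metadata$group == group_a
  sel_b <- psi$metadata$group == group_b
  if (sum(sel_a) < 2L || sum(sel_b) < 2L)
    stop("each group needs at least 2 samples")
  keep <- sel_a | sel_b
  x <- psi$psi[, keep, drop = FALSE]
  w <- glm_weights(psi, rho0)[, keep, drop = FALSE]
  g <- as.numeric(sel_b[keep])
  X1 <- cbind(1, g)
  X0 <- matrix(1, ncol(x), 1L)
  res <- lapply(seq_len(nrow(x)), function(i) {
    y <- x[i, ]
    dpsi <- mean(y[g == 1]) - mean(y[g == 0])
    if (stats::sd(y) == 0)  # constant event: never called
      return(list(delta_psi = dpsi, statistic = NA_real_, pvalue = 1,
                  converged = TRUE))
    f0 <- fit_quasibinomial_glm(y, X0, w[i, ])
    f1 <- fit_quasibinomial_glm(y, X1, w[i, ])
    if (!f1$converged)
      return(list(delta_psi = dpsi, statistic = NA_real_, pvalue = NA_real_,
                  converged = FALSE))
    t <- qlrt(f0, f1)
    list(delta_psi = dpsi, statistic = t$f_statistic, pvalue = t$pvalue,
         converged = TRUE)
  })
  out <- data.frame(
    event_id = psi$events$event_id,
    delta_psi = vapply(res, `[[`, numeric(1L), "delta_psi"),
    statistic = vapply(res, `[[`, numeric(1L), "statistic"),
    pvalue = vapply(res, `[[`, numeric(1L), "pvalue"),
    converged = vapply(res, `[[`, logical(1L), "converged"),
    stringsAsFactors = FALSE
  )
  out$fdr <- NA_real_
  ok <- !is.na(out$pvalue)
  out$fdr[ok] <- benjamini_hochberg(out$pvalue[ok])
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `p_(i) * m / i`, enforced monotone from the largest rank down and capped
#' at 1; input order is preserved.
#'
#' @param pvalues numeric vector in `[0,1]`.
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0,1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  adj <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Call differentiation-associated splicing events (DASEs)
#'
#' An event is a DASE iff `|delta_psi| > delta_threshold` and
#' `fdr < fdr_threshold` (defaults 0.1 and 0.05). Direction is `"up"`
#' (more included in the contrast group) or `"down"`.
#'
#' @param results output of [test_two_group()].
#' @param delta_threshold,fdr_threshold strict thresholds.
#' @return the result table with `is_dase` and `direction` columns;
#'   attribute `counts` holds up/down/total tallies.
#' @export
call_dases <- function(results, delta_threshold = 0.1, fdr_threshold = 0.05) {
  is_dase <- !is.na(results$fdr) &
    abs(results$delta_psi) > delta_threshold & results$fdr < fdr_threshold
  direction <- ifelse(!is_dase, "none",
                      ifelse(results$delta_psi > 0, "up", "down"))
  results$is_dase <- is_dase
  results$direction <- direction
  attr(results, "counts") <- c(up = sum(direction == "up"),
                               down = sum(direction == "down"),
                               total = sum(is_dase))
  results
}

#' Count splicing events conserved across species
#'
#' Given per-species DASE tables keyed to shared ortholog-exon identifiers,
#' returns the keys called in at least `min_species` species.
#'
#' @param dase_tables named list (one element per species) of data.frames
#'   with columns `ortholog_key` and `is_dase`.
#' @param min_species minimum number of species (default 2).
#' @return list with `conserved_keys`, `n_conserved`, and
#'   `per_key_species` (named integer: species count per called key).
#' @export
count_conserved <- function(dase_tables, min_species = 2L) {
  called <- lapply(names(dase_tables), function(sp) {
    t <- dase_tables[[sp]]
    if (anyDuplicated(t$ortholog_key))
      stop("duplicate ortholog key within species ", sp)
    unique(t$ortholog_key[t$is_dase])
  })
  tab <- table(unlist(called))
  conserved <- names(tab)[tab >= min_species]
  list(conserved_keys = sort(conserved), n_conserved = length(conserved),
       per_key_species = tab)
}
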
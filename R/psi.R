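#' Compute percent-spliced-in (PSI) from junction counts
#'
#' PSI is the inclusion ratio of the long (inclusion) form over the total
#' support: `PSI = L / (L + S)`. Cells with `L + S = 0` or missing counts
#' are marked missing.
#'
#' @param counts a [junction_counts()] object.
#' @return a `psi_matrix`: list with `psi` (events x samples), `missing_mask`
#'   (logical, the pre-imputation missingness), retained `L`, `S`, the
#'   events and the sample metadata.
#' @export
compute_psi <- function(counts) {
  L <- counts$L; S <- counts$S
  if (any(L < 0, na.rm = TRUE) || any(S < 0, na.rm = TRUE))
    stop("negative junction counts")
  tot <- L + S
  psi <- ifelse(!is.na(tot) & tot > 0, L / tot, NA_real_)
  mask <- is.na(psi)
  structure(list(psi = psi, missing_mask = mask, L = L, S = S,
                 events = counts$events, metadata = counts$metadata),
            class = "psi_matrix")
}

#' Impute missing PSI values
#'
#' Observed cells are never changed; imputed cells are clamped to `[0,1]`.
#' `"knn"` (default) imputes each missing cell from the `k` nearest event
#' rows (Euclidean distance over samples observed in both rows), averaging
#' the neighbours' values at that sample. `"iterative"` is a seeded chained
#' linear-regression imputer (each sample regressed on the others,
#' iterated to convergence), a deterministic stand-in for iterative
#' random-forest imputation.
#'
#' @param psi a `psi_matrix` from [compute_psi()].
#' @param method `"knn"` or `"iterative"`.
#' @param k neighbours for `"knn"`.
#' @param seed integer seed (only the iterative method draws random initial
#'   column orderings).
#' @param max_iter,tol iteration control for `"iterative"`.
#' @return the `psi_matrix` with no missing values; `missing_mask` is
#'   preserved so filters can still see pre-imputation missingness.
#' @export
impute_missing <- function(psi, method = c("knn", "iterative"), k = 10L,
                           seed = 1L, max_iter = 10L, tol = 1e-4) {
  method <- match.arg(method)
  x <- psi$psi
  mask <- psi$missing_mask
  all_missing <- rowSums(!mask) == 0L
  if (any(all_missing))
    stop("event(s) with all cells missing: ",
         paste(rownames(x)[all_missing], collapse = ", "))
  if (any(rowSums(!mask) < 2L))
    stop("each event needs >= 2 observed values for imputation")
  if (!any(mask)) return(psi)
  imp <- switch(method,
                knn = impute_knn(x, mask, k),
                iterative = impute_iterative(x, mask, seed, max_iter, tol))
  imp <- pmin(pmax(imp, 0), 1)
  imp[!mask] <- x[!mask]  # observed cells bit-exact
  psi$psi <- imp
  psi
}

impute_knn <- function(x, mask, k) {
  n_ev <- nrow(x)
  out <- x
  need <- which(rowSums(mask) > 0L)
  row_means <- rowMeans(x, na.rm = TRUE)
  for (i in need) {
    # distance to every other event over samples observed in both rows
    d <- vapply(seq_len(n_ev), function(j) {
      if (j == i) return(Inf)
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (sum(ok) < 2L) return(Inf)
      sqrt(mean((x[i, ok] - x[j, ok])^2))
    }, numeric(1L))
    ord <- order(d)
    for (j in which(mask[i, ])) {
      nb <- ord[!is.na(x[ord, j]) & is.finite(d[ord])]
      nb <- nb[seq_len(min(k, length(nb)))]
      out[i, j] <- if (length(nb)) mean(x[nb, j]) else row_means[i]
    }
  }
  out
}

impute_iterative <- function(x, mask, seed, max_iter, tol) {
  withr_seed(seed)
  out <- x
  # initialize with row means
  rm <- rowMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(out))) {
    mis <- is.na(out[, j]); out[mis, j] <- rm[mis]
  }
  cols_with_na <- which(colSums(mask) > 0L)
  for (it in seq_len(max_iter)) {
    prev <- out
    ord <- cols_with_na[sample.int(length(cols_with_na))]
    for (j in ord) {
      obs <- !mask[, j]
      if (sum(obs) < 3L || !any(!obs)) next
      others <- out[, -j, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, others[obs, , drop = FALSE]), out[obs, j])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- cbind(1, others[!obs, , drop = FALSE]) %*% beta
      out[!obs, j] <- pred
    }
    if (max(abs(out - prev)) < tol) break
  }
  out
}

#' Event filter thresholds
#'
#' Defaults are the standard stage-series quality filters: (1) average PSI
#' within `[0.05, 0.95]`; (2) average total read count (inclusion +
#' skipping) >= 10; (3) number of samples with missing PSI < 5 (strict,
#' evaluated on pre-imputation missingness); (4) max(PSI) - min(PSI) > 0.05.
#'
#' @param psi_mean_low,psi_mean_high bounds for rule 1.
#' @param min_mean_total threshold for rule 2.
#' @param max_missing_samples strict upper bound for rule 3.
#' @param min_psi_range strict lower bound for rule 4.
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(psi_mean_low = 0.05, psi_mean_high = 0.95,
                            min_mean_total = 10, max_missing_samples = 5L,
                            min_psi_range = 0.05) {
  stopifnot(psi_mean_low >= 0, psi_mean_low < psi_mean_high, psi_mean_high <= 1)
  structure(list(psi_mean_low = psi_mean_low, psi_mean_high = psi_mean_high,
                 min_mean_total = min_mean_total,
                 max_missing_samples = max_missing_samples,
                 min_psi_range = min_psi_range),
            class = "filter_criteria")
}

#' Apply the four-rule event filter
#'
#' Rules 1 (mean PSI band), 2 (mean total count) and 4 (PSI range) are
#' evaluated on the imputed matrix; rule 3 on the pre-imputation missing
#' mask. Events failing any rule are removed and reported.
#'
#' @param psi an imputed `psi_matrix` (see [impute_missing()]).
#' @param criteria a [filter_criteria()] object.
#' @return list with `psi` (the surviving subset, a `psi_matrix`) and
#'   `report` (data.frame: `event_id`, logical `pass_*` per rule, `pass`,
#'   and `failed_rules` naming the violated rules for removed events).
#' @export
filter_events <- function(psi, criteria = filter_criteria()) {
  x <- psi$psi
  if (any(is.na(x)))
    stop("filter_events expects an imputed matrix; run impute_missing() first")
  if (is.null(psi$L) || is.null(psi$S))
    stop("retained counts (L, S) are required for the mean-total rule")
  mean_psi <- rowMeans(x)
  tot <- psi$L + psi$S
  mean_tot <- rowMeans(tot, na.rm = TRUE)
  n_missing <- rowSums(psi$missing_mask)
  rng <- apply(x, 1L, max) - apply(x, 1L, min)
  pass1 <- mean_psi >= criteria$psi_mean_low & mean_psi <= criteria$psi_mean_high
  pass2 <- mean_tot >= criteria$min_mean_total
  pass3 <- n_missing < criteria$max_missing_samples
  pass4 <- rng > criteria$min_psi_range
  pass <- pass1 & pass2 & pass3 & pass4
  rule_names <- c("mean_psi_band", "mean_total_count", "missing_samples",
                  "psi_range")
  failed <- apply(cbind(pass1, pass2, pass3, pass4), 1L, function(p)
    paste(rule_names[!p], collapse = ";"))
  report <- data.frame(event_id = psi$events$event_id,
                       pass_mean_psi_band = pass1,
                       pass_mean_total_count = pass2,
                       pass_missing_samples = pass3,
                       pass_psi_range = pass4,
                       pass = pass, failed_rules = failed,
                       stringsAsFactors = FALSE)
  list(psi = subset_psi(psi, pass), report = report)
}

# subset a psi_matrix by a logical/integer event index
subset_psi <- function(psi, idx) {
  psi$psi <- psi$psi[idx, , drop = FALSE]
  psi$missing_mask <- psi$missing_mask[idx, , drop = FALSE]
  if (!is.null(psi$L)) psi$L <- psi$L[idx, , drop = FALSE]
  if (!is.null(psi$S)) psi$S <- psi$S[idx, , drop = FALSE]
  psi$events <- psi$events[idx, , drop = FALSE]
  class(psi$events) <- c("splice_events", "data.frame")
  psi
}
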
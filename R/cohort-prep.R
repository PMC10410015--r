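#' Inclusion filtering of variables and individuals
#'
#' Applies the two inclusion rules in a fixed order: biomarker variables with
#' a non-missing fraction below `min_coverage` are removed first, then
#' individuals whose missing fraction over the *retained* variables strictly
#' exceeds `max_individual_missing` (more than 10% by default) are dropped.
#' The order matters and is part of the contract: dropping sparse variables
#' first can rescue individuals whose missingness was concentrated in them.
#' Filtering is idempotent.
#'
#' @param cohort A cohort table.
#' @param min_coverage Minimum non-missing fraction per variable (default 0.8).
#' @param max_individual_missing Maximum missing fraction per individual over
#'   the retained variables; strictly greater is dropped (default 0.10).
#' @return A list with `cohort` (the filtered table) and `report` (dropped
#'   variable names with their coverage, dropped individual ids, and
#'   before/after counts).
#' @examples
#' ch <- as_cohort(data.frame(id = 1:10, age = 20:29,
#'                            a = c(rep(NA, 7), 1, 2, 3), b = rnorm(10)))
#' filter_cohort(ch, min_coverage = 0.5)$report$dropped_variables
#' @export
filter_cohort <- function(cohort, min_coverage = 0.8, max_individual_missing = 0.10) {
  if (nrow(cohort) == 0L) stopf("cohort is empty")
  vars <- biomarker_names(cohort)
  if (!length(vars)) stopf("cohort has no biomarker variables")
  coverage <- vapply(vars, function(v) mean(!is.na(cohort[[v]])), numeric(1))
  keep_vars <- vars[coverage >= min_coverage]
  if (!length(keep_vars)) stopf("all variables fall below min_coverage = %g", min_coverage)
  frac_missing <- rowMeans(is.na(as.data.frame(cohort)[, keep_vars, drop = FALSE]))
  keep_ind <- frac_missing <= max_individual_missing
  if (!any(keep_ind)) stopf("no individuals left after the %g missingness rule",
                            max_individual_missing)
  out <- as.data.frame(cohort)[keep_ind,
                               c(intersect(names(cohort), .reserved_cols), keep_vars),
                               drop = FALSE]
  list(cohort = as_cohort(out, keep_vars),
       report = list(
         dropped_variables = coverage[coverage < min_coverage],
         dropped_individuals = cohort$id[!keep_ind],
         n_variables = c(before = length(vars), after = length(keep_vars)),
         n_individuals = c(before = nrow(cohort), after = sum(keep_ind))))
}

#' Iterative multivariate imputation
#'
#' Round-robin regression imputation: missing cells are initialised at the
#' column mean, then each incomplete variable in turn is regressed on all the
#' others (ridge-regularised linear model fitted on the rows where it is
#' observed) and its missing cells replaced by the predictions, sweeping the
#' variables repeatedly until the largest change falls below `tol` or
#' `max_iter` sweeps. Observed cells are never modified. The ridge penalty is
#' a numerical stabiliser only (`lambda` is relative to the mean predictor
#' variance), so exact linear relationships are recovered to machine-level
#' accuracy.
#'
#' The tree-ensemble age model does not need this step (it routes missing
#' values natively); imputation is for the comparator metrics (KDM, HD) and
#' any model that requires complete data.
#'
#' @param cohort A cohort table.
#' @param max_iter Maximum number of round-robin sweeps.
#' @param tol Convergence tolerance on the largest absolute change of an
#'   imputed cell, in units of the variable's SD.
#' @param lambda Relative ridge penalty.
#' @return The cohort with all biomarker `NA`s filled.
#' @export
impute_cohort <- function(cohort, max_iter = 10, tol = 1e-6, lambda = 1e-8) {
  vars <- biomarker_names(cohort)
  if (length(vars) < 2L) stopf("imputation needs at least 2 biomarker variables")
  X <- biomarker_matrix(cohort)
  miss <- is.na(X)
  if (!any(miss)) return(cohort)
  if (any(colSums(!miss) == 0L)) {
    stopf("variable(s) fully missing: %s", paste(vars[colSums(!miss) == 0], collapse = ", "))
  }
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_along(vars)) X[miss[, j], j] <- mu[j]
  sds <- pmax(apply(X, 2, sd), 1e-12)
  order_j <- order(colSums(miss), decreasing = TRUE)
  order_j <- order_j[colSums(miss)[order_j] > 0]
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in order_j) {
      obs <- !miss[, j]
      Z <- cbind(1, X[, -j, drop = FALSE])
      ZtZ <- crossprod(Z[obs, , drop = FALSE])
      pen <- lambda * mean(diag(ZtZ)[-1])
      diag(ZtZ)[-1] <- diag(ZtZ)[-1] + pen
      beta <- tryCatch(solve(ZtZ, crossprod(Z[obs, , drop = FALSE], X[obs, j])),
                       error = function(e) qr.solve(ZtZ, crossprod(Z[obs, , drop = FALSE], X[obs, j])))
      pred <- drop(Z[miss[, j], , drop = FALSE] %*% beta)
      delta <- max(delta, if (length(pred)) max(abs(pred - X[miss[, j], j]) / sds[j]) else 0)
      X[miss[, j], j] <- pred
    }
    if (delta < tol) break
  }
  for (v in vars) cohort[[v]] <- X[, v]
  rewrap_cohort(cohort, cohort)
}

#' Stratified train/test split
#'
#' Splits the cohort into disjoint, exhaustive train and test sets in an
#' 80:20 proportion by default, stratifying the draw by integer age and sex so
#' that every age-sex cell is represented in the test set in proportion to its
#' share of the cohort (largest-remainder allocation, then a uniform draw
#' within each cell). Deterministic under `seed`.
#'
#' @param cohort A cohort table with `n >= 5`.
#' @param test_fraction Fraction held out, in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return A list with cohort tables `train` and `test`.
#' @export
split_cohort <- function(cohort, test_fraction = 0.2, seed = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1) stopf("`test_fraction` must be in (0, 1)")
  n <- nrow(cohort)
  if (n < 5L) stopf("need at least 5 individuals to split")
  cell <- interaction(cohort$age, cohort$sex %||% rep(1L, n), drop = TRUE)
  n_test <- round(n * test_fraction)
  cells <- split(seq_len(n), cell)
  ideal <- vapply(cells, length, integer(1)) * test_fraction
  base <- floor(ideal)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    takeable <- which(base > 0)
    cut <- takeable[order((ideal - base)[takeable])][seq_len(-rem)]
    base[cut] <- base[cut] - 1L
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(cells), function(k) {
      idx <- cells[[k]]
      if (base[k] == 0L) return(integer(0))
      idx[sample.int(length(idx), base[k])]
    }), use.names = FALSE)
  })
  list(train = rewrap_cohort(as.data.frame(cohort)[-test_idx, , drop = FALSE], cohort),
       test = rewrap_cohort(as.data.frame(cohort)[test_idx, , drop = FALSE], cohort))
}
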
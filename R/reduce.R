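#' SHAP-importance recursive feature elimination
#'
#' Repeatedly fits the age model, ranks the variables by mean absolute
#' contribution on the training set, drops the least important one, and
#' records test-set performance, until a single variable remains. The
#' minimal model is the smallest retained set whose test R-squared is within
#' 1% (relative) of the full model's. Ties in minimal importance are broken
#' by dropping the lexicographically last variable, so the trace is
#' reproducible.
#'
#' Importance is taken from the fast path-dependent explanation by default;
#' `retune = TRUE` re-runs the reduced hyperparameter search at every step
#' (substantially slower).
#'
#' @param train,test Cohort tables.
#' @param hyperparameters,objective,seed As in [fit_age_model()].
#' @param retune Re-tune hyperparameters at every elimination step.
#' @param importance_method Passed to [explain_global()].
#' @param r2_tolerance Relative R-squared loss defining the minimal set
#'   (default 0.01, i.e. R2 >= 0.99 x full-model R2).
#' @return A list of class `rfe_trace`: `trace` (step, n_variables, dropped,
#'   r2, mae), `retained` (variable set per step), `minimal_set`, `full_r2`.
#' @export
recursive_eliminate <- function(train, test, hyperparameters = list(),
                                objective = "age_normalized", retune = FALSE,
                                importance_method = "tree_path",
                                r2_tolerance = 0.01, seed = 1L) {
  vars <- biomarker_names(train)
  if (length(vars) < 2L) stopf("recursive elimination needs at least 2 variables")
  steps <- list(); retained <- list()
  current <- sort(vars)
  step <- 0L
  hp <- hyperparameters
  repeat {
    if (retune) {
      hp <- tune_age_model(train, n_candidates = 4, k = 3,
                           objective = objective, seed = seed)$best
    }
    model <- fit_age_model(train, hp, objective, variables = current, seed = seed)
    met <- evaluate_age_model(model, test)
    if (!is.finite(met$r2) || !is.finite(met$mae)) {
      warning("non-finite metric; aborting with partial trace")
      break
    }
    retained[[step + 1L]] <- current
    imp <- rank_importance(explain_global(model, train, method = importance_method))
    steps[[step + 1L]] <- data.frame(step = step, n_variables = length(current),
                                     r2 = met$r2, mae = met$mae,
                                     dropped = NA_character_)
    if (length(current) == 1L) break
    worst <- min(imp$mean_abs_phi)
    candidates <- sort(imp$variable[imp$mean_abs_phi == worst])
    drop_var <- candidates[length(candidates)]
    steps[[step + 1L]]$dropped <- drop_var
    current <- setdiff(current, drop_var)
    step <- step + 1L
  }
  trace <- do.call(rbind, steps)
  full_r2 <- trace$r2[1]
  ok <- trace$r2 >= (1 - r2_tolerance) * full_r2
  minimal_set <- retained[[max(which(ok))]]
  structure(list(trace = trace, retained = retained,
                 minimal_set = sort(minimal_set), full_r2 = full_r2),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf("RFE over %d variables: full R2 = %.3f, minimal set = %d variables\n",
              x$trace$n_variables[1], x$full_r2, length(x$minimal_set)))
  cat(paste(x$minimal_set, collapse = ", "), "\n")
  invisible(x)
}
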
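# Parse an xgboost booster into flat per-tree arrays for the C++ kernels.
# Leaf values live in `split_conditions` at leaf positions; children are
# 0-based with -1 marking a leaf; `default_left` gives the missing route.
parse_booster <- function(model) {
  booster <- if (inherits(model, "age_model")) model$booster else model
  raw <- xgboost::xgb.save.raw(booster, raw_format = "json")
  mj <- jsonlite::fromJSON(rawToChar(raw), simplifyVector = TRUE)
  trees <- mj$learner$gradient_booster$model$trees
  if (is.null(trees)) stopf("unsupported booster serialization (no tree array)")
  list(split_index = lapply(trees$split_indices, as.integer),
       split_cond = lapply(trees$split_conditions, as.numeric),
       left = lapply(trees$left_children, as.integer),
       right = lapply(trees$right_children, as.integer),
       default_left = lapply(trees$default_left, as.integer),
       base_score = as.numeric(mj$learner$learner_model_param$base_score))
}

# Margin predictions through the parsed trees; used to keep explanation base
# values exactly additive with the phi matrices.
margin_predict <- function(parsed, X) {
  cpp_predict_trees(parsed$split_index, parsed$split_cond, parsed$left,
                    parsed$right, parsed$default_left, X) + parsed$base_score
}

new_explanation_matrix <- function(phi, base, flavor, groups = NULL,
                                   background_description = "") {
  structure(list(phi = phi, base = base, flavor = flavor, groups = groups,
                 background_description = background_description),
            class = "explanation_matrix")
}

#' @export
print.explanation_matrix <- function(x, ...) {
  cat(sprintf("%s explanation matrix: %d individuals x %d variables\n",
              x$flavor, nrow(x$phi), ncol(x$phi)))
  if (x$flavor == "global") cat(sprintf("base value: %.2f years\n", x$base))
  else cat(sprintf("%d age-group base values (%.1f to %.1f years)\n",
                   length(x$base), min(x$base), max(x$base)))
  cat(x$background_description, "\n")
  invisible(x)
}

#' Global additive explanations of the age model
#'
#' Computes per-individual, per-variable additive (Shapley) contributions of
#' the model prediction, in years of age. The default `"interventional"`
#' method attributes each prediction against a background reference
#' population drawn from `data` (capped at `background_size` rows), so that
#' `base + rowSums(phi) = prediction` with `base` the mean model prediction
#' over the background. The `"tree_path"` method is xgboost's fast
#' path-dependent TreeSHAP (no explicit background; base is the model's
#' learned expectation); it is used where only an importance ranking is
#' needed.
#'
#' @param model A fitted `age_model`.
#' @param data Cohort table to explain.
#' @param method `"interventional"` (reference-population Shapley) or
#'   `"tree_path"` (path-dependent).
#' @param background_size Maximum background rows (interventional method).
#' @param seed Seed for the background subsample.
#' @return An `explanation_matrix` with `flavor = "global"`: `phi`
#'   (individuals x variables, years), scalar `base`.
#' @export
explain_global <- function(model, data, method = c("interventional", "tree_path"),
                           background_size = 200, seed = 1L) {
  method <- match.arg(method)
  if (!inherits(model, "age_model")) stopf("`model` must be a fitted age_model")
  check_model_columns(model, data)
  X <- biomarker_matrix(data, model$variables)
  if (method == "tree_path") {
    contrib <- predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1, missing = NA),
                       predcontrib = TRUE)
    p <- length(model$variables)
    phi <- contrib[, seq_len(p), drop = FALSE]
    colnames(phi) <- model$variables
    rownames(phi) <- as.character(data$id)
    return(new_explanation_matrix(phi, base = contrib[1, p + 1L], flavor = "global",
                                  background_description = "path-dependent TreeSHAP (training cover)"))
  }
  parsed <- parse_booster(model)
  bidx <- if (nrow(X) <= background_size) seq_len(nrow(X)) else {
    with_seed(seed, sort(sample.int(nrow(X), background_size)))
  }
  B <- X[bidx, , drop = FALSE]
  phi <- cpp_ind_treeshap(parsed$split_index, parsed$split_cond, parsed$left,
                          parsed$right, parsed$default_left, X, B)
  dimnames(phi) <- list(as.character(data$id), model$variables)
  base <- mean(margin_predict(parsed, B))
  new_explanation_matrix(phi, base = base, flavor = "global",
                         background_description = sprintf(
                           "interventional TreeSHAP, background = %d rows of the explained data", nrow(B)))
}

# Partition integer ages into contiguous groups of at least `min_size`
# members: each year starts as its own group and undersized groups are merged
# with their nearest (by age, then smaller) neighbour until all are large
# enough. Returns a factor over individuals, levelled in age order.
age_grouping <- function(ages, min_size = 50) {
  tab <- table(ages)
  grp_ages <- lapply(as.numeric(names(tab)), function(a) a)
  grp_n <- as.integer(tab)
  while (length(grp_n) > 1L && min(grp_n) < min_size) {
    i <- which.min(grp_n)
    nb <- c(if (i > 1) i - 1L, if (i < length(grp_n)) i + 1L)
    j <- nb[which.min(grp_n[nb])]
    lo <- min(i, j); hi <- max(i, j)
    grp_ages[[lo]] <- c(grp_ages[[lo]], grp_ages[[hi]])
    grp_n[lo] <- grp_n[lo] + grp_n[hi]
    grp_ages[[hi]] <- NULL
    grp_n <- grp_n[-hi]
  }
  labels <- vapply(grp_ages, function(a) {
    if (length(a) == 1L) as.character(a) else paste0(min(a), "-", max(a))
  }, character(1))
  key <- unlist(lapply(seq_along(grp_ages), function(g) {
    setNames(rep(labels[g], length(grp_ages[[g]])), grp_ages[[g]])
  }))
  factor(key[as.character(ages)], levels = labels)
}

#' Age-contextualized additive explanations
#'
#' Re-bases the additive explanation of every individual on the population
#' that shares their chronological age: contributions are interventional
#' tree-Shapley values computed with the background restricted to the
#' individual's age group, and the per-group base value is the mean model
#' prediction within that group. Summing a row therefore gives the
#' individual's deviation from same-aged peers rather than from the whole
#' cohort. Integer-age groups are merged with their nearest neighbours until
#' each holds at least `min_group_size` individuals.
#'
#' @param model A fitted `age_model`.
#' @param data Cohort table to explain.
#' @param min_group_size Minimum individuals per age group before merging.
#' @param background_size Cap on background rows per group (default 150).
#'   Groups at or below the cap use every member as background, which keeps
#'   the within-group mean of the deviations at exactly zero; larger groups
#'   are represented by a random subsample, trading a little centering
#'   accuracy for compute.
#' @param seed Seed for background subsampling when capped.
#' @return An `explanation_matrix` with `flavor = "contextualized"`: `phi`,
#'   per-group `base` (named numeric), and `groups` (factor per individual).
#' @export
explain_contextualized <- function(model, data, min_group_size = 50,
                                   background_size = 150, seed = 1L) {
  if (!inherits(model, "age_model")) stopf("`model` must be a fitted age_model")
  check_model_columns(model, data)
  X <- biomarker_matrix(data, model$variables)
  groups <- age_grouping(data$age, min_group_size)
  sizes <- table(groups)
  if (any(sizes < 2L)) stopf("age group(s) with < 2 members after merging: %s",
                             paste(names(sizes)[sizes < 2], collapse = ", "))
  parsed <- parse_booster(model)
  phi <- matrix(NA_real_, nrow(X), ncol(X),
                dimnames = list(as.character(data$id), model$variables))
  base <- setNames(numeric(nlevels(groups)), levels(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    bidx <- if (length(idx) <= background_size) idx else {
      with_seed(seed, sort(sample(idx, background_size)))
    }
    B <- X[bidx, , drop = FALSE]
    phi[idx, ] <- cpp_ind_treeshap(parsed$split_index, parsed$split_cond,
                                   parsed$left, parsed$right, parsed$default_left,
                                   X[idx, , drop = FALSE], B)
    base[g] <- mean(margin_predict(parsed, B))
  }
  new_explanation_matrix(phi, base = base, flavor = "contextualized", groups = groups,
                         background_description = sprintf(
                           "interventional TreeSHAP, background = individual's age group (%d groups, min size %d)",
                           nlevels(groups), min(sizes)))
}

#' Personalized physiological age and its deviation
#'
#' The PPA of an individual is the global base value plus the sum of their
#' global contributions (equal to the model's predicted age); the PPA
#' deviation is the sum of their contextualized contributions — the predicted
#' age minus the mean prediction of same-aged individuals. Positive deviation
#' reads as accelerated physiological aging.
#'
#' @param global A global `explanation_matrix`.
#' @param contextualized A contextualized `explanation_matrix` over the same
#'   individuals.
#' @param data The cohort table explained (supplies `id` and `age`).
#' @return A data frame of class `ppa_records`: `id`, `age`, `ppa` (years),
#'   `ppa_deviation` (years).
#' @export
compute_ppa <- function(global, contextualized, data) {
  if (!identical(rownames(global$phi), rownames(contextualized$phi))) {
    stopf("global and contextualized explanations cover different individuals")
  }
  if (!identical(rownames(global$phi), as.character(data$id))) {
    stopf("explanations and cohort ids do not match")
  }
  out <- data.frame(id = data$id, age = data$age,
                    ppa = unname(global$base + rowSums(global$phi)),
                    ppa_deviation = unname(rowSums(contextualized$phi)))
  class(out) <- c("ppa_records", class(out))
  out
}

#' Rank variables by mean absolute contribution
#'
#' Orders variables by the mean absolute value of their contributions and
#' reports each variable's share of the total mean-|phi| sum plus the
#' cumulative share. Ties are broken lexicographically. If every contribution
#' is zero the shares are uniform.
#'
#' @param expl An `explanation_matrix`.
#' @param top_k Number of variables to keep (clamped with a warning).
#' @return A data frame of class `importance_ranking`: `variable`,
#'   `mean_abs_phi`, `share`, `cumulative_share`.
#' @export
rank_importance <- function(expl, top_k = ncol(expl$phi)) {
  if (!ncol(expl$phi)) stopf("empty explanation matrix")
  m <- colMeans(abs(expl$phi))
  if (top_k > length(m)) {
    warning(sprintf("top_k = %d clamped to %d variables", top_k, length(m)))
    top_k <- length(m)
  }
  ord <- order(-m, names(m))
  total <- sum(m)
  share <- if (total > 0) m / total else rep(1 / length(m), length(m))
  out <- data.frame(variable = names(m)[ord], mean_abs_phi = unname(m[ord]),
                    share = unname(share[ord]))
  out$cumulative_share <- cumsum(out$share)
  out <- out[seq_len(top_k), ]
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Dependence profile and age-specific thresholds of one variable
#'
#' Partial-dependence view of a contextualized explanation: the contribution
#' of a variable plotted against its raw value, binned by age. The per-age
#' zero crossing — the raw-value range where the mean contribution changes
#' sign — is the age-specific threshold separating values that read younger
#' from values that read older than same-aged peers. Value bins are
#' equal-frequency; per-bin means are smoothed with a 3-bin moving average
#' before the sign change is located. In the clean monotone case the interval
#' runs from the last negative bin to the first positive bin; otherwise the
#' widest sign-change bracket is reported; with no crossing the interval is
#' empty (`NA` bounds). Interval endpoints are the outer edges of the two
#' bracketing bins — the sign change is only localized to within them — so a
#' clean crossing spans at most two value bins.
#'
#' @param expl A contextualized `explanation_matrix`.
#' @param data The explained cohort table.
#' @param variable Variable name.
#' @param age_breaks Break points of the age bins (default decades 12-79).
#' @param value_bins Number of equal-frequency raw-value bins (default 40).
#' @param min_amplitude Noise floor in years: a crossing is only declared when
#'   the smoothed profile reaches beyond `min_amplitude` on both sides of
#'   zero, so sign flips of a flat (uninformative) profile are not reported
#'   as thresholds.
#' @return An object of class `dependence_profile`: `points` (raw value,
#'   phi, age per individual), `grid` (age bin x value bin mean phi),
#'   `crossings` (age bin, lo, hi; plus a pooled all-ages row) and bin
#'   descriptors.
#' @export
dependence_profile <- function(expl, data, variable,
                               age_breaks = c(12, 20, 30, 40, 50, 60, 70, 80),
                               value_bins = 40, min_amplitude = 0.1) {
  if (!variable %in% colnames(expl$phi)) stopf("unknown variable '%s'", variable)
  if (value_bins < 2) stopf("need at least 2 value bins")
  x <- data[[variable]]
  phi <- expl$phi[, variable]
  ok <- !is.na(x)
  x <- x[ok]; phi <- phi[ok]; age <- data$age[ok]
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = value_bins + 1), names = FALSE))
  if (length(qs) < 3) stopf("variable '%s' has too few distinct values", variable)
  vbin <- cut(x, qs, include.lowest = TRUE)
  vmid <- vapply(split(x, vbin), function(v) if (length(v)) median(v) else NA_real_, numeric(1))
  vlo <- qs[-length(qs)]
  vhi <- qs[-1]
  abin <- cut(age, age_breaks, include.lowest = TRUE, right = FALSE)
  grid <- tapply(phi, list(abin, vbin), mean)
  crossing_of <- function(means) {
    s <- smooth_3bin(means)
    nonempty <- which(!is.na(s))
    if (length(nonempty) < 2) return(c(NA_real_, NA_real_))
    sv <- s[nonempty]
    neg <- which(sv < 0); pos <- which(sv > 0)
    if (!length(neg) || !length(pos)) return(c(NA_real_, NA_real_))
    if (min(sv) > -min_amplitude || max(sv) < min_amplitude) {
      return(c(NA_real_, NA_real_))
    }
    if (max(neg) < min(pos)) {
      return(c(vlo[nonempty[max(neg)]], vhi[nonempty[min(pos)]]))
    }
    # non-monotone: widest bracket among adjacent opposite-sign bins
    br <- NULL; best <- -Inf
    for (i in seq_len(length(sv) - 1)) {
      if (sv[i] < 0 && sv[i + 1] > 0) {
        w <- vhi[nonempty[i + 1]] - vlo[nonempty[i]]
        if (w > best) { best <- w; br <- c(vlo[nonempty[i]], vhi[nonempty[i + 1]]) }
      }
    }
    br %||% c(NA_real_, NA_real_)
  }
  crossings <- do.call(rbind, lapply(levels(abin), function(a) {
    ci <- crossing_of(grid[a, ])
    data.frame(age_bin = a, lo = ci[1], hi = ci[2])
  }))
  pooled <- crossing_of(tapply(phi, vbin, mean))
  crossings <- rbind(crossings, data.frame(age_bin = "all", lo = pooled[1], hi = pooled[2]))
  structure(list(variable = variable,
                 points = data.frame(value = x, phi = phi, age = age),
                 grid = grid, value_breaks = qs, value_mids = vmid,
                 age_breaks = age_breaks, crossings = crossings),
            class = "dependence_profile")
}

# 3-bin moving average, NA-tolerant at the edges.
smooth_3bin <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  for (i in seq_len(n)) {
    w <- v[max(1, i - 1):min(n, i + 1)]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out[is.na(v)] <- NA_real_
  out
}

#' @export
print.dependence_profile <- function(x, ...) {
  cat(sprintf("Dependence profile of '%s' (%d individuals)\n", x$variable, nrow(x$points)))
  print(x$crossings, row.names = FALSE)
  invisible(x)
}

#' Extract threshold table from several variables
#'
#' Tidy table of per-age zero-crossing intervals for a set of variables.
#'
#' @param expl Contextualized `explanation_matrix`.
#' @param data Explained cohort.
#' @param variables Variables to profile (default: all).
#' @param ... Passed to [dependence_profile()].
#' @return A data frame `variable`, `age_bin`, `lo`, `hi`.
#' @export
threshold_table <- function(expl, data, variables = colnames(expl$phi), ...) {
  do.call(rbind, lapply(variables, function(v) {
    cr <- dependence_profile(expl, data, v, ...)$crossings
    cbind(variable = v, cr)
  }))
}
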
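#' Klemera-Doubal biological age
#'
#' Fits the Klemera-Doubal estimator in its corrected form: each biomarker is
#' regressed on chronological age (`x_j = q_j + k_j * age`), biomarkers whose
#' absolute age correlation falls below `screen_r` are excluded, and
#' biological age combines the inverse regressions weighted by their residual
#' variances, with the chronological-age term weighted by the age-correction
#' variance `s_BA^2`:
#'
#' \deqn{BA_i = \frac{\sum_j (x_{ij} - q_j) k_j / s_j^2 + CA_i / s_{BA}^2}
#'                  {\sum_j k_j^2 / s_j^2 + 1 / s_{BA}^2}}
#'
#' `s_BA^2` is estimated from the spread of the uncorrected estimator around
#' chronological age minus its expected sampling noise, using the
#' characteristic correlation of the biomarker set. On noise-free linear
#' biomarkers the estimator returns chronological age exactly.
#'
#' @param cohort An imputed cohort table (no missing biomarkers).
#' @param biomarkers Biomarker subset (default: all).
#' @param screen_r Minimum absolute age correlation for inclusion.
#' @return An object of class `kdm_model`: per-biomarker `q`, `k`, `s`, `r`,
#'   `excluded` (with reasons), `s_ba2`.
#' @export
fit_kdm <- function(cohort, biomarkers = NULL, screen_r = 0.1) {
  biomarkers <- biomarkers %||% biomarker_names(cohort)
  X <- biomarker_matrix(cohort, biomarkers)
  if (anyNA(X)) stopf("KDM needs imputed (complete) data; run impute_cohort() first")
  age <- cohort$age
  r <- apply(X, 2, cor, y = age)
  excluded <- setNames(rep("", 0), character(0))
  low <- abs(r) < screen_r | !is.finite(r)
  if (any(low)) {
    excluded <- setNames(sprintf("|age correlation| = %.3f < %g", r[low], screen_r),
                         biomarkers[low])
  }
  keep <- biomarkers[!low]
  if (length(keep) < 2L && length(biomarkers) >= 2L) {
    if (length(keep) == 0L) stopf("no biomarker passes the age-correlation screen")
  }
  if (!length(keep)) stopf("no biomarker passes the age-correlation screen")
  fits <- lapply(keep, function(v) lm(X[, v] ~ age))
  q <- vapply(fits, function(f) coef(f)[1], numeric(1))
  k <- vapply(fits, function(f) coef(f)[2], numeric(1))
  s <- vapply(fits, function(f) sqrt(max(mean(f$residuals^2), 0)), numeric(1))
  s <- pmax(s, 1e-8)
  names(q) <- names(k) <- names(s) <- keep
  rk <- pmin(abs(r[keep]), 1 - 1e-9)
  # uncorrected estimator on the training data
  num <- sweep(X[, keep, drop = FALSE], 2, q) %*% (k / s^2)
  den <- sum(k^2 / s^2)
  ba_e <- as.numeric(num) / den
  m <- length(keep)
  rchar <- sum(rk^2 / sqrt(1 - rk^2)) / sum(rk / sqrt(1 - rk^2))
  rchar <- min(max(rchar, 1e-6), 1 - 1e-9)
  s_ba2 <- mean((ba_e - age)^2) -
    ((1 - rchar^2) / rchar^2) * (diff(range(age))^2 / (12 * m))
  if (!is.finite(s_ba2) || s_ba2 <= 0) s_ba2 <- max(mean((ba_e - age)^2), 1e-8)
  structure(list(biomarkers = keep, q = q, k = k, s = s, r = r[keep],
                 excluded = excluded, s_ba2 = s_ba2, rchar = rchar),
            class = "kdm_model")
}

#' @rdname fit_kdm
#' @param model A fitted `kdm_model`.
#' @param data Cohort table to score (imputed).
#' @return `score_kdm()` returns a numeric vector of KDM biological ages
#'   (years).
#' @export
score_kdm <- function(model, data) {
  X <- biomarker_matrix(data, model$biomarkers)
  if (anyNA(X)) stopf("KDM needs imputed (complete) data")
  num <- as.numeric(sweep(X, 2, model$q) %*% (model$k / model$s^2)) +
    data$age / model$s_ba2
  den <- sum(model$k^2 / model$s^2) + 1 / model$s_ba2
  num / den
}

skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Homeostatic dysregulation
#'
#' Mahalanobis distance of an individual's biomarker vector from a reference
#' population considered to have optimal physiological function. The default
#' reference is individuals aged 18-30 whose values all lie within the 1st
#' and 99th percentiles of that age stratum. Right-skewed positive biomarkers
#' (skewness > 2) are log-transformed, all variables are standardized on the
#' reference, and the distance uses the reference covariance
#' (ridge-regularized with a warning if near-singular).
#'
#' @param cohort Imputed cohort table.
#' @param biomarkers Biomarker subset (default: all).
#' @param reference_filter Function of the cohort data frame returning a
#'   logical row filter for the reference candidates (default: age 18-30).
#' @param trim Percentile window applied to every variable within the
#'   reference candidates.
#' @param skew_threshold Skewness above which a positive variable is
#'   log-transformed.
#' @return An object of class `hd_model`: `mu`, `sigma` (covariance of the
#'   standardized reference), `center`, `scale`, `log_vars`,
#'   `reference_description`, `n_reference`.
#' @export
fit_hd <- function(cohort, biomarkers = NULL,
                   reference_filter = function(df) df$age >= 18 & df$age <= 30,
                   trim = c(0.01, 0.99), skew_threshold = 2) {
  biomarkers <- biomarkers %||% biomarker_names(cohort)
  X <- biomarker_matrix(cohort, biomarkers)
  if (anyNA(X)) stopf("HD needs imputed (complete) data; run impute_cohort() first")
  log_vars <- biomarkers[vapply(biomarkers, function(v) {
    min(X[, v]) > 0 && skewness(X[, v]) > skew_threshold
  }, logical(1))]
  for (v in log_vars) X[, v] <- log(X[, v])
  cand <- which(reference_filter(as.data.frame(cohort)))
  if (!length(cand)) stopf("reference filter selects no individuals")
  inside <- rep(TRUE, length(cand))
  for (j in seq_along(biomarkers)) {
    qs <- quantile(X[cand, j], probs = trim, names = FALSE)
    inside <- inside & X[cand, j] >= qs[1] & X[cand, j] <= qs[2]
  }
  ref <- cand[inside]
  if (length(ref) < 5 * length(biomarkers)) {
    stopf("reference population too small (%d rows for %d biomarkers; need >= %d)",
          length(ref), length(biomarkers), 5 * length(biomarkers))
  }
  center <- colMeans(X[ref, , drop = FALSE])
  scale_ <- apply(X[ref, , drop = FALSE], 2, sd)
  if (any(scale_ == 0)) stopf("constant biomarker in the reference population")
  Zr <- scale(X[ref, , drop = FALSE], center = center, scale = scale_)
  S <- stats::cov(Zr)
  if (rcond(S) < 1e-10) {
    warning("near-singular reference covariance; ridge-regularizing")
    S <- S + diag(1e-6 * mean(diag(S)), ncol(S))
  }
  structure(list(biomarkers = biomarkers, mu = center, scale = scale_,
                 sigma = S, log_vars = log_vars,
                 reference_description = "ages 18-30, all variables within [1st, 99th] reference percentiles",
                 n_reference = length(ref)),
            class = "hd_model")
}

#' @rdname fit_hd
#' @param model A fitted `hd_model`.
#' @param data Cohort table to score (imputed).
#' @return `score_hd()` returns the per-individual homeostatic dysregulation
#'   (unitless Mahalanobis distance).
#' @export
score_hd <- function(model, data) {
  X <- biomarker_matrix(data, model$biomarkers)
  if (anyNA(X)) stopf("HD needs imputed (complete) data")
  for (v in model$log_vars) X[, v] <- log(X[, v])
  Z <- scale(X, center = model$mu, scale = model$scale)
  as.numeric(sqrt(mahalanobis(Z, center = rep(0, ncol(Z)), cov = model$sigma)))
}

#' Decile-based Cox mortality validation
#'
#' Categorizes a physiological-age metric into sample deciles (ties assigned
#' to the lower decile) and fits a multivariate Cox proportional-hazards
#' model of mortality on the decile factor with the 5th decile as reference,
#' adjusted on sex, chronological age, year of inclusion and the age-by-year
#' interaction. Only adults (age >= 18) enter the model. Adjusters whose
#' column is constant are dropped with a message.
#'
#' @param metric Per-individual metric values, aligned with `cohort` rows.
#' @param cohort Cohort table with `followup_time` and `death`.
#' @param adjusters Adjustment terms (default
#'   `c("sex", "age", "cycle", "age:cycle")`).
#' @param min_age Minimum age for inclusion.
#' @return An object of class `hazard_table`: `deciles` (decile, hr, lo, hi,
#'   n, events, unstable), `covariates`, `aic`, and the fitted `coxph` model.
#' @export
cox_deciles <- function(metric, cohort,
                        adjusters = c("sex", "age", "cycle", "age:cycle"),
                        min_age = 18) {
  if (length(metric) != nrow(cohort)) stopf("`metric` must align with the cohort rows")
  if (!all(c("followup_time", "death") %in% names(cohort))) {
    stopf("cohort lacks survival columns `followup_time`/`death`")
  }
  keep <- cohort$age >= min_age & !is.na(metric)
  df <- as.data.frame(cohort)[keep, , drop = FALSE]
  met <- metric[keep]
  if (sum(df$death) == 0) stopf("no events among included individuals")
  breaks <- unique(quantile(met, probs = seq(0, 1, 0.1), names = FALSE))
  if (length(breaks) < 3) stopf("metric has too few distinct values for deciles")
  dec <- cut(met, breaks, include.lowest = TRUE, labels = FALSE, right = TRUE)
  df$decile <- relevel(factor(dec), ref = "5")
  base_cols <- unique(unlist(strsplit(adjusters, ":", fixed = TRUE)))
  usable <- base_cols[vapply(base_cols, function(v) {
    v %in% names(df) && length(unique(df[[v]])) > 1L
  }, logical(1))]
  dropped <- setdiff(base_cols, usable)
  if (length(dropped)) message("dropping constant/absent adjuster(s): ",
                               paste(dropped, collapse = ", "))
  adjusters <- adjusters[vapply(adjusters, function(a) {
    all(strsplit(a, ":", fixed = TRUE)[[1]] %in% usable)
  }, logical(1))]
  fml <- as.formula(paste("survival::Surv(followup_time, death) ~ decile",
                          if (length(adjusters)) paste("+", paste(adjusters, collapse = " + ")) else ""))
  fit <- survival::coxph(fml, data = df)
  sm <- summary(fit)
  co <- sm$conf.int
  dec_rows <- grepl("^decile", rownames(co))
  dec_lvl <- as.integer(sub("^decile", "", rownames(co)[dec_rows]))
  events_by <- tapply(df$death, dec, sum)
  n_by <- table(dec)
  deciles <- data.frame(decile = 1:10, hr = 1, lo = NA_real_, hi = NA_real_,
                        n = as.integer(n_by[as.character(1:10)]),
                        events = as.integer(events_by[as.character(1:10)]))
  deciles$hr[dec_lvl] <- co[dec_rows, "exp(coef)"]
  deciles$lo[dec_lvl] <- co[dec_rows, "lower .95"]
  deciles$hi[dec_lvl] <- co[dec_rows, "upper .95"]
  deciles$unstable <- !is.na(deciles$events) & deciles$events == 0
  if (any(deciles$unstable)) warning("decile(s) with zero events: unstable CI")
  cov_rows <- !dec_rows
  covariates <- data.frame(term = rownames(co)[cov_rows],
                           hr = co[cov_rows, "exp(coef)"],
                           lo = co[cov_rows, "lower .95"],
                           hi = co[cov_rows, "upper .95"])
  structure(list(deciles = deciles, covariates = covariates,
                 aic = AIC(fit), model = fit, n = nrow(df),
                 events = sum(df$death)),
            class = "hazard_table")
}

#' @export
print.hazard_table <- function(x, ...) {
  cat(sprintf("Cox decile model: n = %d, events = %d, AIC = %.1f\n",
              x$n, x$events, x$aic))
  print(transform(x$deciles, hr = round(hr, 2), lo = round(lo, 2),
                  hi = round(hi, 2)), row.names = FALSE)
  invisible(x)
}

#' Covariate associations of a physiological-age metric
#'
#' For each validation covariate, fits a linear model of the metric on the
#' covariate adjusted on chronological age and sex (adults only), reporting
#' the coefficient of each non-reference category (or the slope for a
#' continuous covariate), its p-value and the model AIC.
#'
#' @param metric Per-individual metric values aligned with `cohort`.
#' @param cohort Cohort table.
#' @param covariates Character vector of cohort column names.
#' @param min_age Minimum age for inclusion.
#' @return A list of class `association_results`, one element per covariate:
#'   `variable`, `terms` (term, estimate, p), `aic`, `n`.
#' @export
associate_covariates <- function(metric, cohort, covariates, min_age = 18) {
  if (length(metric) != nrow(cohort)) stopf("`metric` must align with the cohort rows")
  keep <- cohort$age >= min_age & !is.na(metric)
  df <- as.data.frame(cohort)[keep, , drop = FALSE]
  df$.metric <- metric[keep]
  out <- lapply(covariates, function(v) {
    if (!v %in% names(df)) stopf("covariate '%s' not in cohort", v)
    sub <- df[!is.na(df[[v]]), , drop = FALSE]
    if (is.character(sub[[v]])) sub[[v]] <- factor(sub[[v]])
    if (is.factor(sub[[v]]) && nlevels(droplevels(sub[[v]])) < 2L) {
      stopf("covariate '%s' has a single category", v)
    }
    if (!is.factor(sub[[v]]) && length(unique(sub[[v]])) < 2L) {
      stopf("covariate '%s' is constant", v)
    }
    adj <- intersect(c("age", "sex"), names(sub))
    adj <- adj[vapply(adj, function(a) length(unique(sub[[a]])) > 1L, logical(1))]
    fml <- as.formula(paste(".metric ~", v,
                            if (length(adj)) paste("+", paste(adj, collapse = " + ")) else ""))
    fit <- lm(fml, data = sub)
    sm <- summary(fit)$coefficients
    rows <- grepl(paste0("^", v), rownames(sm))
    list(variable = v,
         terms = data.frame(term = rownames(sm)[rows],
                            estimate = sm[rows, "Estimate"],
                            p = sm[rows, "Pr(>|t|)"]),
         aic = AIC(fit), n = nrow(sub))
  })
  names(out) <- covariates
  class(out) <- "association_results"
  out
}

#' Compare metrics by AIC
#'
#' Ranks competing physiological-age metrics fitted to the same covariate by
#' AIC difference from the best model (dAIC = 0 for the best).
#'
#' @param ... Named [associate_covariates()] results (or named numeric AICs),
#'   one per metric.
#' @param covariate When association results are passed, which covariate to
#'   compare on.
#' @return A data frame `metric`, `aic`, `daic`, sorted by `daic`.
#' @export
compare_aic <- function(..., covariate = NULL) {
  inputs <- list(...)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    stopf("pass named arguments, one per metric")
  }
  aic <- vapply(inputs, function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    if (inherits(x, "association_results")) {
      if (is.null(covariate)) stopf("`covariate` needed to compare association results")
      return(x[[covariate]]$aic)
    }
    if (inherits(x, "hazard_table")) return(x$aic)
    stopf("unsupported input of class %s", paste(class(x), collapse = "/"))
  }, numeric(1))
  out <- data.frame(metric = names(aic), aic = unname(aic),
                    daic = unname(aic - min(aic)))
  out[order(out$daic), ]
}
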
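#' Declare how one synthetic biomarker depends on age
#'
#' An effect specification describes a single biomarker of the synthetic
#' cohort: the shape of its age dependence, how many years of physiological
#' age an individual deviation is worth, and its raw-value scale. Four shapes
#' are supported, mirroring the behaviours seen in routine laboratory panels:
#'
#' * `linear` — the raw value drifts linearly with age over the whole
#'   observed span (e.g. blood urea nitrogen).
#' * `sigmoid` — the raw value saturates at both ends of life and moves
#'   steeply through a midpoint `center`, so that the value at which an
#'   individual matches same-aged peers is a sharp, clinically meaningful
#'   threshold (the HbA1c-like profile). `center_old` plants an age-varying
#'   threshold: the midpoint moves smoothly from `center` to `center_old`
#'   around `center_split` years.
#' * `window` — the variable is informative only inside the age window
#'   `center = c(a_lo, a_hi)` (e.g. alkaline phosphatase during growth).
#' * `null` — pure noise, no age signal, zero ground-truth contribution.
#'
#' Each individual carries an independent standard-normal deviation score per
#' variable; its ground-truth contribution in years is `amplitude` times that
#' score (zero outside a window effect, and always zero for `null`). The raw
#' value is generated from the individual's variable-specific apparent age
#' (chronological age + contribution) plus baseline heterogeneity and
#' measurement noise.
#'
#' @param variable_name Column name of the biomarker.
#' @param shape One of `"linear"`, `"sigmoid"`, `"window"`, `"null"`.
#' @param amplitude Standard deviation, in years of age, of the ground-truth
#'   contribution of this variable. Must be 0 for `shape = "null"`.
#' @param center For `sigmoid`: raw-value midpoint x0 (zero-contribution
#'   point). For `window`: numeric length-2 age window `c(a_lo, a_hi)` with
#'   `12 <= a_lo < a_hi <= 79`. Ignored for `linear`/`null`.
#' @param slope Raw units per year of apparent age (`linear`, `window`).
#' @param width Raw-value steepness of the sigmoid transition.
#' @param noise_sd Residual measurement noise SD, raw units.
#' @param baseline_mean,baseline_sd Raw-value mean and age-independent
#'   between-individual SD at the reference age (45 years).
#' @param center_old,center_split Optional age-varying sigmoid midpoint: the
#'   threshold drifts from `center` to `center_old` around age
#'   `center_split` (years).
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec("hba1c", "sigmoid", amplitude = 6, center = 5.5, width = 0.35,
#'             noise_sd = 0.1, baseline_mean = 5.5, baseline_sd = 0)
#' @export
effect_spec <- function(variable_name, shape = c("linear", "sigmoid", "window", "null"),
                        amplitude = 0, center = NULL, slope = 1, width = 1,
                        noise_sd = 1, baseline_mean = 0, baseline_sd = 0,
                        center_old = NULL, center_split = 50) {
  shape <- match.arg(shape)
  if (!is.finite(amplitude)) stopf("`amplitude` must be finite")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (baseline_sd < 0) stopf("`baseline_sd` must be >= 0")
  if (shape == "null" && amplitude != 0) stopf("shape 'null' implies amplitude = 0")
  if (shape == "window") {
    if (is.null(center) || length(center) != 2L) {
      stopf("window shape needs `center = c(a_lo, a_hi)`")
    }
    if (!(center[1] >= 12 && center[1] < center[2] && center[2] <= 79)) {
      stopf("window bounds must satisfy 12 <= a_lo < a_hi <= 79")
    }
  }
  if (shape == "sigmoid" && is.null(center)) stopf("sigmoid shape needs a `center` midpoint")
  structure(list(variable_name = variable_name, shape = shape,
                 amplitude = amplitude, center = center, slope = slope,
                 width = width, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 center_old = center_old, center_split = center_split),
            class = "effect_spec")
}

#' Default synthetic biomarker panel
#'
#' Twenty variables emulating the mixture of behaviours of a routine
#' laboratory panel: one dominant sigmoid (HbA1c-like, midpoint 5.5), a
#' second weaker sigmoid, a majority of linear drifts of varied amplitude and
#' direction, two age-window effects (an adolescence marker and a late-life
#' marker), and three pure-noise electrolytes.
#'
#' @return A list of [effect_spec()] objects.
#' @export
default_effect_panel <- function() {
  list(
    effect_spec("hba1c", "sigmoid", amplitude = 6, center = 5.5, width = 0.35,
                noise_sd = 0.3, baseline_mean = 5.5, baseline_sd = 0),
    effect_spec("glucose", "sigmoid", amplitude = 3, center = 5.6, width = 0.6,
                noise_sd = 1.0, baseline_mean = 5.6, baseline_sd = 0),
    effect_spec("bun", "linear", amplitude = 5, slope = 0.08, noise_sd = 2.5,
                baseline_mean = 5.0, baseline_sd = 2.1),
    effect_spec("creatinine", "linear", amplitude = 4, slope = 0.45, noise_sd = 21,
                baseline_mean = 75, baseline_sd = 17),
    effect_spec("urinary_creatinine", "linear", amplitude = 5, slope = -0.9,
                noise_sd = 38, baseline_mean = 120, baseline_sd = 34),
    effect_spec("mcv", "linear", amplitude = 4, slope = 0.12, noise_sd = 5.9,
                baseline_mean = 89, baseline_sd = 5.0),
    effect_spec("rdw", "linear", amplitude = 3, slope = 0.02, noise_sd = 1.05,
                baseline_mean = 13.0, baseline_sd = 0.85),
    effect_spec("hematocrit", "linear", amplitude = 2, slope = -0.05, noise_sd = 3.8,
                baseline_mean = 42, baseline_sd = 3.4),
    effect_spec("albumin", "linear", amplitude = 3, slope = -0.09, noise_sd = 4.6,
                baseline_mean = 43, baseline_sd = 3.8),
    effect_spec("triglycerides", "linear", amplitude = 2, slope = 0.012, noise_sd = 0.76,
                baseline_mean = 1.3, baseline_sd = 0.63),
    effect_spec("cholesterol", "linear", amplitude = 2, slope = 0.02, noise_sd = 1.26,
                baseline_mean = 5.0, baseline_sd = 1.05),
    effect_spec("uric_acid", "linear", amplitude = 2, slope = 1.4, noise_sd = 100,
                baseline_mean = 310, baseline_sd = 84),
    effect_spec("alt", "linear", amplitude = 1.5, slope = 0.18, noise_sd = 17,
                baseline_mean = 24, baseline_sd = 13),
    effect_spec("ggt", "linear", amplitude = 1.5, slope = 0.3, noise_sd = 29,
                baseline_mean = 26, baseline_sd = 21),
    effect_spec("folate", "linear", amplitude = 1, slope = 0.25, noise_sd = 25,
                baseline_mean = 35, baseline_sd = 17),
    effect_spec("alp", "window", amplitude = 4, center = c(12, 20), slope = -7,
                noise_sd = 56, baseline_mean = 110, baseline_sd = 35),
    effect_spec("lymphocyte_pct", "window", amplitude = 2, center = c(60, 79),
                slope = -0.35, noise_sd = 10, baseline_mean = 31, baseline_sd = 7),
    effect_spec("sodium", "null", noise_sd = 1.6, baseline_mean = 140, baseline_sd = 0.8),
    effect_spec("chloride", "null", noise_sd = 1.8, baseline_mean = 103, baseline_sd = 0.9),
    effect_spec("potassium", "null", noise_sd = 0.25, baseline_mean = 4.1, baseline_sd = 0.12)
  )
}

#' Configure the synthetic cohort generator
#'
#' The defaults emulate the study population the framework targets: ages 12-79
#' with adolescents over-represented about two-fold and a ~25% thinner tail
#' above 70, roughly balanced sexes, a routine laboratory panel
#' ([default_effect_panel()]), sub-percent uniformly random missingness, and
#' an exponential proportional-hazards mortality process whose log-hazard
#' rises with the built-in physiological deviation and with age.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param age_distribution Named or plain numeric vector of weights over the
#'   integer ages 12-79.
#' @param sex_ratio Proportion of males.
#' @param effects List of [effect_spec()] objects.
#' @param missing_rate Proportion of biomarker cells set missing, in [0, 1).
#' @param mortality_beta Log-hazard per year of true deviation.
#' @param baseline_hazard Events per person-year at the reference age for an
#'   individual with zero deviation.
#' @param age_hazard_coef Log-hazard per year of chronological age.
#' @param max_followup Administrative censoring time, years.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   cohort bit for bit.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 10000,
                             age_distribution = default_age_distribution(),
                             sex_ratio = 0.49,
                             effects = default_effect_panel(),
                             missing_rate = 0.005,
                             mortality_beta = 0.05,
                             baseline_hazard = 0.003,
                             age_hazard_coef = 0.08,
                             max_followup = 16,
                             seed = 1L) {
  if (n_individuals < 1) stopf("`n_individuals` must be >= 1 (empty cohort)")
  if (missing_rate < 0 || missing_rate >= 1) stopf("`missing_rate` must be in [0, 1)")
  if (length(age_distribution) != 68L) {
    stopf("`age_distribution` must give one weight per integer age 12-79")
  }
  if (any(age_distribution < 0) || sum(age_distribution) <= 0) {
    stopf("`age_distribution` weights must be non-negative and not all zero")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stopf("`sex_ratio` must be in [0, 1]")
  ok <- vapply(effects, inherits, logical(1), "effect_spec")
  if (!length(effects) || !all(ok)) stopf("`effects` must be a list of effect_spec objects")
  nm <- vapply(effects, `[[`, character(1), "variable_name")
  if (anyDuplicated(nm)) stopf("duplicated variable names in `effects`")
  structure(list(n_individuals = as.integer(n_individuals),
                 age_distribution = as.numeric(age_distribution),
                 sex_ratio = sex_ratio, effects = effects,
                 missing_rate = missing_rate, mortality_beta = mortality_beta,
                 baseline_hazard = baseline_hazard,
                 age_hazard_coef = age_hazard_coef,
                 max_followup = max_followup, seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_age_distribution <- function() {
  ages <- 12:79
  w <- ifelse(ages <= 20, 2, ifelse(ages >= 70, 0.75, 1))
  setNames(w / sum(w), ages)
}

.ref_age <- 45

# Raw-value mean as a function of apparent age e for one effect.
effect_raw_mean <- function(spec, e) {
  switch(spec$shape,
    linear = spec$baseline_mean + spec$slope * (e - .ref_age),
    window = {
      mid <- mean(spec$center)
      spec$baseline_mean + spec$slope * (pmin(pmax(e, spec$center[1]), spec$center[2]) - mid)
    },
    sigmoid = {
      x0 <- if (is.null(spec$center_old)) spec$center else {
        spec$center + (spec$center_old - spec$center) * plogis((e - spec$center_split) / 4)
      }
      p <- pmin(pmax((e - 12) / 67, 0.02), 0.98)
      x0 + spec$width * qlogis(p)
    },
    null = rep(spec$baseline_mean, length(e))
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws ages from the configured histogram, sexes as Bernoulli draws, one
#' standard-normal deviation score per individual and variable, and builds
#' each biomarker as `baseline draw + shape(apparent age) + noise`, where the
#' apparent age is chronological age plus the variable's ground-truth
#' contribution (in years). Missingness is then injected uniformly at random,
#' and survival columns are simulated from the exponential
#' proportional-hazards process tied to the total true deviation.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `cohort` (a [as_cohort()] table including `followup_time`/`death`),
#'   `true_contribution` (individuals x variables matrix, years),
#'   `true_deviation` (its row sums, years) and `config`.
#' @examples
#' sim <- generate_cohort(generator_config(n_individuals = 200, seed = 42))
#' dim(sim$true_contribution)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) stopf("`config` must be a generator_config")
  with_seed(config$seed, {
    n <- config$n_individuals
    ages <- sample(12:79, n, replace = TRUE, prob = config$age_distribution)
    sex <- factor(ifelse(runif(n) < config$sex_ratio, "male", "female"),
                  levels = c("female", "male"))
    cycle <- sample(seq(1999, 2017, by = 2), n, replace = TRUE)
    p <- length(config$effects)
    nm <- vapply(config$effects, `[[`, character(1), "variable_name")
    contrib <- matrix(0, n, p, dimnames = list(NULL, nm))
    X <- matrix(NA_real_, n, p, dimnames = list(NULL, nm))
    for (j in seq_len(p)) {
      spec <- config$effects[[j]]
      z <- rnorm(n)
      c_j <- switch(spec$shape,
        null = rep(0, n),
        window = ifelse(ages >= spec$center[1] & ages <= spec$center[2],
                        spec$amplitude * z, 0),
        spec$amplitude * z)
      contrib[, j] <- c_j
      e <- ages + c_j
      X[, j] <- effect_raw_mean(spec, e) +
        rnorm(n, 0, spec$baseline_sd) + rnorm(n, 0, spec$noise_sd)
    }
    cohort <- as_cohort(cbind(data.frame(id = seq_len(n), age = as.integer(ages),
                                         sex = sex, cycle = cycle),
                              as.data.frame(X)), nm)
    rownames(contrib) <- as.character(cohort$id)
    sim <- structure(list(cohort = cohort, true_contribution = contrib,
                          true_deviation = rowSums(contrib), config = config),
                     class = "synthetic_cohort")
    if (config$missing_rate > 0) {
      sim$cohort <- inject_missingness(sim$cohort, config$missing_rate,
                                       seed = config$seed + 1L)
    }
    sim$cohort <- simulate_mortality(sim, beta = config$mortality_beta,
                                     baseline = config$baseline_hazard,
                                     max_followup = config$max_followup,
                                     age_coef = config$age_hazard_coef,
                                     seed = config$seed + 2L)
    sim
  })
}

#' Mask biomarker cells completely at random
#'
#' Missingness is missing-completely-at-random across all biomarker cells:
#' independent of age, sex, and the values themselves. Identifier,
#' demographic and survival columns are never masked.
#'
#' @param cohort A cohort table.
#' @param rate Proportion of cells to mask, in [0, 1).
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stopf("`rate` must be in [0, 1)")
  if (rate == 0) return(cohort)
  vars <- biomarker_names(cohort)
  with_seed(seed, {
    for (v in vars) {
      mask <- runif(nrow(cohort)) < rate
      cohort[[v]][mask] <- NA_real_
    }
  })
  cohort
}

#' Simulate mortality from the built-in physiological deviation
#'
#' Event times are exponential under a proportional-hazards model with
#' log-hazard `log(baseline) + beta * true_deviation + age_coef * (age - 45)`
#' and administrative censoring at `max_followup` years.
#'
#' @param sim A `synthetic_cohort` (needs `true_deviation`).
#' @param beta Log-hazard per year of true deviation.
#' @param baseline Baseline hazard, events per person-year (> 0).
#' @param max_followup Censoring horizon, years.
#' @param age_coef Log-hazard per year of chronological age.
#' @param seed Integer seed.
#' @return The cohort table with `followup_time` and `death` columns.
#' @export
simulate_mortality <- function(sim, beta, baseline, max_followup,
                               age_coef = 0.08, seed = NULL) {
  if (!inherits(sim, "synthetic_cohort") || is.null(sim$true_deviation)) {
    stopf("`sim` must be a synthetic_cohort with `true_deviation`")
  }
  if (baseline <= 0) stopf("`baseline` hazard must be > 0")
  cohort <- sim$cohort
  rate <- baseline * exp(beta * sim$true_deviation +
                           age_coef * (cohort$age - .ref_age))
  with_seed(seed, {
    t_event <- rexp(nrow(cohort), rate = rate)
    cohort$followup_time <- pmin(t_event, max_followup)
    cohort$death <- as.integer(t_event <= max_followup)
  })
  rewrap_cohort(cohort, cohort)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d biomarkers, %d deaths\n",
              nrow(x$cohort), ncol(x$true_contribution), sum(x$cohort$death %||% 0)))
  cat(sprintf("true deviation: mean %.2f, sd %.2f years\n",
              mean(x$true_deviation), sd(x$true_deviation)))
  invisible(x)
}

#' Write a synthetic cohort and its ground truth to disk
#'
#' The cohort is written as CSV or Parquet (by extension) and the ground-truth
#' contribution matrix as a sibling `<stem>_truth.csv`.
#'
#' @param sim A `synthetic_cohort`.
#' @param path Output path for the cohort file.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_cohort <- function(sim, path) {
  write_cohort(sim$cohort, path)
  truth_path <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
  truth <- data.frame(id = sim$cohort$id, sim$true_contribution,
                      true_deviation = sim$true_deviation)
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(c(path, truth_path))
}

#' Planted threshold of a sigmoid effect
#'
#' Ground-truth zero-contribution value of a sigmoid effect at given ages:
#' the raw value at which an individual of that age matches same-aged peers
#' (deviation zero). This is the quantity a dependence-profile zero crossing
#' estimates.
#'
#' @param spec A sigmoid [effect_spec()].
#' @param ages Ages (years) at which to evaluate the threshold.
#' @return Numeric vector of raw-value thresholds.
#' @export
planted_threshold <- function(spec, ages) {
  if (!inherits(spec, "effect_spec") || spec$shape != "sigmoid") {
    stopf("`spec` must be a sigmoid effect_spec")
  }
  effect_raw_mean(spec, ages)
}
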
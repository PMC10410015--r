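test_that("KDM inverts noise-free linear biomarkers exactly", {
  set.seed(61)
  ages <- sample(20:70, 400, TRUE)
  ch <- as_cohort(data.frame(id = seq_along(ages), age = ages,
                             b1 = 2 + 0.5 * ages, b2 = 100 - 1.2 * ages))
  k <- fit_kdm(ch)
  expect_lt(max(abs(score_kdm(k, ch) - ch$age)), 1e-6)
  # single noise-free biomarker: exact inversion as well
  k1 <- fit_kdm(as_cohort(data.frame(id = seq_along(ages), age = ages,
                                     b1 = 2 + 0.5 * ages, b2 = 100 - 1.2 * ages)),
                biomarkers = "b1")
  expect_lt(max(abs(score_kdm(k1, ch) - ch$age)), 1e-6)
})

test_that("KDM screens uninformative biomarkers and tracks age on noisy panels", {
  set.seed(62)
  n <- 5000
  ages <- sample(12:79, n, TRUE)
  X <- sapply(1:10, function(j) 5 * j + 0.4 * ages + rnorm(n, 0, 12))
  colnames(X) <- paste0("m", 1:10)
  df <- cbind(data.frame(id = 1:n, age = ages), X, junk = rnorm(n))
  ch <- as_cohort(df)
  k <- fit_kdm(ch, screen_r = 0.1)
  expect_true("junk" %in% names(k$excluded))
  expect_false("junk" %in% k$biomarkers)
  expect_gt(cor(score_kdm(k, ch), ch$age), 0.9)
  all_junk <- as_cohort(data.frame(id = 1:1000, age = sample(20:60, 1000, TRUE),
                                   a = rnorm(1000), b = rnorm(1000)))
  expect_error(fit_kdm(all_junk), "screen")
})

test_that("homeostatic dysregulation reduces to known closed forms", {
  # hand-built model: covariance [[1, .5], [.5, 1]], deviation (1, 1)
  hd <- structure(list(biomarkers = c("a", "b"), mu = c(a = 0, b = 0),
                       scale = c(a = 1, b = 1),
                       sigma = matrix(c(1, 0.5, 0.5, 1), 2), log_vars = character(0)),
                  class = "hd_model")
  d <- as_cohort(data.frame(id = 1:2, age = c(30, 40), a = c(0, 1), b = c(0, 1)))
  sc <- score_hd(hd, d)
  expect_equal(sc[1], 0)                      # x = mu
  expect_equal(sc[2], sqrt(4 / 3), tolerance = 1e-10)
  expect_null(names(sc))
  # identity covariance: Euclidean norm of standardized deviations
  hd2 <- structure(list(biomarkers = c("a", "b"), mu = c(a = 1, b = 2),
                        scale = c(a = 2, b = 4),
                        sigma = diag(2), log_vars = character(0)),
                   class = "hd_model")
  d2 <- as_cohort(data.frame(id = 1, age = 30, a = 3, b = 6))
  expect_equal(score_hd(hd2, d2), sqrt(1 + 1), tolerance = 1e-12)
})

test_that("fitted HD matches a direct quadratic-form computation", {
  sim <- small_sim(n = 2000, seed = 63)
  ch <- impute_cohort(sim$cohort)
  hd <- fit_hd(ch)
  sc <- score_hd(hd, ch)
  X <- biomarker_matrix(ch, hd$biomarkers)
  for (v in hd$log_vars) X[, v] <- log(X[, v])
  Z <- scale(X, hd$mu, hd$scale)
  direct <- sqrt(rowSums((Z %*% solve(hd$sigma)) * Z))
  expect_lt(max(abs(sc - direct)), 1e-8)
  expect_gte(hd$n_reference, 5 * length(hd$biomarkers))
})

test_that("the decile hazard table has the reference structure", {
  sim <- generate_cohort(generator_config(n_individuals = 6000,
                                          mortality_beta = 0.08, seed = 64))
  ht <- cox_deciles(sim$true_deviation, sim$cohort)
  expect_equal(nrow(ht$deciles), 10)
  expect_equal(ht$deciles$hr[5], 1)           # reference decile
  expect_true(all(is.na(ht$deciles$lo[5])))
  with(ht$deciles[-5, ], expect_true(all(lo <= hr & hr <= hi)))
  expect_true(any(grepl("^sex", ht$covariates$term)))
  expect_true(any(grepl("^age", ht$covariates$term)))
  expect_gt(ht$events, 0)
  expect_true(is.finite(ht$aic))
  # metric must align and survival columns must exist
  expect_error(cox_deciles(1:5, sim$cohort), "align")
})

test_that("covariate associations recover a planted shift and rank models by AIC", {
  # deviation metric of realistic scale (a few years SD)
  panel <- list(
    effect_spec("u", "linear", amplitude = 2.5, slope = 0.3, noise_sd = 5, baseline_mean = 40),
    effect_spec("v", "linear", amplitude = 2, slope = -0.2, noise_sd = 4, baseline_mean = 90),
    effect_spec("w", "linear", amplitude = 1.5, slope = 0.1, noise_sd = 3, baseline_mean = 20),
    effect_spec("z", "linear", amplitude = 1, slope = 0.05, noise_sd = 2, baseline_mean = 10))
  sim <- generate_cohort(generator_config(n_individuals = 10000, effects = panel,
                                          missing_rate = 0, seed = 65))
  set.seed(66)
  exposed <- rbinom(nrow(sim$cohort), 1, 0.3)
  # a +2-year mean shift in the metric for the exposed group
  metric <- sim$true_deviation + 2 * exposed + rnorm(nrow(sim$cohort), 0, 1)
  ch <- sim$cohort
  ch$exposure <- factor(ifelse(exposed == 1, "yes", "no"))
  res <- associate_covariates(metric, ch, "exposure")
  est <- res$exposure$terms$estimate
  expect_lt(abs(est - 2), 0.3)
  # null covariate: no association
  set.seed(67)
  pn <- vapply(1:10, function(s) {
    cc <- ch
    cc$flag <- factor(sample(c("a", "b"), nrow(cc), TRUE))
    r <- associate_covariates(sim$true_deviation, cc, "flag")$flag
    c(abs(r$terms$estimate), r$terms$p)
  }, numeric(2))
  expect_gte(sum(pn[1, ] < 0.2 & pn[2, ] > 0.01), 9)
  expect_error(associate_covariates(metric, transform(ch, one = factor("x")), "one"),
               "single category")
  # dAIC: the best model is zero by construction
  cmp <- compare_aic(ppa = 100.2, kdm = 140.9, hd = 90.1)
  expect_equal(cmp$daic[cmp$metric == "hd"], 0)
  expect_equal(min(cmp$daic), 0)
})
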
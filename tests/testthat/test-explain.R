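test_that("both explanation flavors satisfy Shapley efficiency (additivity)", {
  sim <- small_sim(n = 500, seed = 23)
  m <- fit_age_model(sim$cohort, quick_hp(), seed = 3)
  pred <- predict(m, sim$cohort)
  eg <- explain_global(m, sim$cohort, background_size = 80, seed = 1)
  expect_lt(max(abs(eg$base + rowSums(eg$phi) - pred)), 1e-4)
  ec <- explain_contextualized(m, sim$cohort, min_group_size = 40)
  base_i <- ec$base[as.character(ec$groups)]
  expect_lt(max(abs(base_i + rowSums(ec$phi) - pred)), 1e-4)
  # path-dependent flavor is additive against its own learned base
  ep <- explain_global(m, sim$cohort, method = "tree_path")
  expect_lt(max(abs(ep$base + rowSums(ep$phi) - pred)), 1e-3)
})

test_that("a variable never split on receives identically zero contributions", {
  set.seed(4)
  n <- 400
  a <- sample(12:79, n, TRUE)
  ch <- as_cohort(data.frame(id = 1:n, age = a, x = a + rnorm(n, 0, 6),
                             flat = rep(2.5, n)))
  m <- fit_age_model(ch, quick_hp(), seed = 1)
  eg <- explain_global(m, ch, background_size = 50, seed = 2)
  expect_true(all(eg$phi[, "flat"] == 0))
})

test_that("contributions match a brute-force coalition-enumeration oracle", {
  # depth-1 trees over two binary variables: the closed-form two-player game
  set.seed(9)
  n <- 300
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  y <- 20 + 30 * x1 + 10 * x2 + rnorm(n, 0, 0.01)
  ch <- as_cohort(data.frame(id = 1:n, age = round(y), x1 = x1, x2 = x2))
  m <- fit_age_model(ch, list(nrounds = 40L, max_depth = 1L, eta = 0.5,
                              subsample = 1, colsample_bytree = 1,
                              min_child_weight = 1), seed = 1)
  X <- biomarker_matrix(ch)
  B <- X[1:30, ]
  eg <- explain_global(m, ch, background_size = 30, seed = 1)
  bidx <- physage:::with_seed(1, sort(sample.int(n, 30)))
  Bs <- X[bidx, ]
  for (i in c(1, 11, 61)) {
    expect_equal(unname(eg$phi[i, ]), brute_force_shap(m, X[i, ], Bs),
                 tolerance = 1e-8)
  }
  # deeper mixed-panel model against the same oracle
  sim <- small_sim(n = 250, seed = 24)
  m2 <- fit_age_model(sim$cohort, quick_hp(max_depth = 3L), seed = 2)
  e2 <- explain_global(m2, sim$cohort, background_size = 20, seed = 5)
  X2 <- biomarker_matrix(sim$cohort, m2$variables)
  b2 <- physage:::with_seed(5, sort(sample.int(nrow(X2), 20)))
  for (i in c(3, 99)) {
    expect_equal(unname(e2$phi[i, ]), brute_force_shap(m2, X2[i, ], X2[b2, ]),
                 tolerance = 1e-8)
  }
})

test_that("contextualized explanations are centered per age group and reduce to global", {
  sim <- small_sim(n = 900, seed = 25)
  m <- fit_age_model(sim$cohort, quick_hp(), seed = 4)
  ec <- explain_contextualized(m, sim$cohort, min_group_size = 50)
  dev <- unname(rowSums(ec$phi))
  grp_means <- tapply(dev, ec$groups, mean)
  expect_lt(max(abs(grp_means)), 1e-3)
  # an individual whose prediction equals its group mean has ~zero deviation
  pred <- predict(m, sim$cohort)
  base_i <- unname(ec$base[as.character(ec$groups)])
  expect_equal(dev, pred - base_i, tolerance = 1e-4)

  # single age group in the explained data: contextualized == global elementwise
  sub <- as.data.frame(sim$cohort)[sim$cohort$age >= 40 & sim$cohort$age <= 46, ]
  sub$age <- 43L
  sub <- physage:::rewrap_cohort(sub, sim$cohort)
  ecs <- explain_contextualized(m, sub, min_group_size = 10)
  egs <- explain_global(m, sub, background_size = nrow(sub), seed = 1)
  expect_equal(ecs$phi, egs$phi, tolerance = 1e-12)
})

test_that("PPA and its deviation are assembled from the two flavors", {
  sim <- small_sim(n = 600, seed = 26)
  m <- fit_age_model(sim$cohort, quick_hp(), seed = 5)
  eg <- explain_global(m, sim$cohort, background_size = nrow(sim$cohort))
  ec <- explain_contextualized(m, sim$cohort, min_group_size = 40)
  ppa <- compute_ppa(eg, ec, sim$cohort)
  expect_equal(ppa$ppa, predict(m, sim$cohort), tolerance = 1e-4)
  # efficiency averaging: mean PPA equals the global base value
  expect_lt(abs(mean(ppa$ppa) - eg$base), 1e-3)
  # deviation = prediction minus the age-group base, like a 61-year-old
  # predicted 49 having deviation 49 - base(61)
  base_i <- unname(ec$base[as.character(ec$groups)])
  expect_equal(ppa$ppa_deviation, ppa$ppa - base_i, tolerance = 1e-4)
  # id mismatch is an error
  expect_error(compute_ppa(eg, ec, sim$cohort[-1, ]), "ids")
})

test_that("importance ranking orders, normalizes and clamps", {
  phi <- matrix(c(3, -3, 1, 1, 0, 0), nrow = 2,
                dimnames = list(c("a", "b"), c("big", "mid", "zero")))
  expl <- physage:::new_explanation_matrix(phi, 0, "global")
  rk <- rank_importance(expl)
  expect_identical(rk$variable, c("big", "mid", "zero"))
  expect_equal(sum(rk$share), 1, tolerance = 1e-9)
  expect_warning(rank_importance(expl, top_k = 10), "clamped")
  zero <- physage:::new_explanation_matrix(matrix(0, 2, 3,
            dimnames = list(NULL, c("x", "y", "z"))), 0, "global")
  expect_equal(rank_importance(zero)$share, rep(1 / 3, 3))
})

test_that("a dominant planted effect is ranked first", {
  effects <- c(list(effect_spec("dom", "linear", amplitude = 15, slope = 0.5,
                                noise_sd = 2, baseline_mean = 50)),
               lapply(1:9, function(j) effect_spec(sprintf("v%d", j), "linear",
                      amplitude = 1, slope = 0.5, noise_sd = 12, baseline_mean = 30)))
  ranked_first <- vapply(1:3, function(s) {
    sim <- generate_cohort(generator_config(n_individuals = 2500, effects = effects,
                                            missing_rate = 0, seed = 400 + s))
    m <- fit_age_model(sim$cohort, quick_hp(), seed = s)
    ec <- explain_contextualized(m, sim$cohort)
    rank_importance(ec)$variable[1] == "dom"
  }, logical(1))
  expect_true(all(ranked_first))
})

test_that("duplicated variables share the single variable's attribution", {
  set.seed(2)
  n <- 2000
  a <- sample(12:79, n, TRUE)
  x <- a + rnorm(n, 0, 8)
  w <- a + rnorm(n, 0, 12)
  single <- as_cohort(data.frame(id = 1:n, age = a, x = x, w = w))
  dup <- as_cohort(data.frame(id = 1:n, age = a, x1 = x, x2 = x, w = w))
  det <- list(colsample_bytree = 1, subsample = 1, nrounds = 60L)
  mA <- fit_age_model(single, det, seed = 3)
  mB <- fit_age_model(dup, det, seed = 3)
  eA <- explain_global(mA, single, background_size = 80, seed = 7)
  eB <- explain_global(mB, dup, background_size = 80, seed = 7)
  # deterministic training uses one copy; the pair's total equals the single run
  expect_lt(max(abs(rowSums(eB$phi[, c("x1", "x2")]) - eA$phi[, "x"])), 1e-3)
  # with column subsampling both copies carry weight and the total is preserved
  mC <- fit_age_model(dup, list(colsample_bytree = 0.5, nrounds = 60L), seed = 3)
  eC <- explain_global(mC, dup, background_size = 80, seed = 7)
  shares <- colMeans(abs(eC$phi))
  expect_gt(min(shares[c("x1", "x2")]), 0)
  total_dup <- sum(shares[c("x1", "x2")])
  expect_lt(abs(total_dup - mean(abs(eA$phi[, "x"]))) / total_dup, 0.2)
})

test_that("dependence profiles locate planted thresholds and stay empty for null effects", {
  sim <- small_sim(n = 10000, seed = 27)
  sp <- split_cohort(sim$cohort, seed = 3)
  # generous leaf sizes: the null-variable check needs a model that does not
  # memorise local noise
  m <- fit_age_model(sp$train, list(nrounds = 60L, eta = 0.1,
                                    min_child_weight = 200), seed = 6)
  ec <- explain_contextualized(m, sp$test, min_group_size = 25)
  dp <- dependence_profile(ec, sp$test, "hba1c",
                           age_breaks = c(12, 30, 40, 52, 64, 80))
  spec <- small_panel()[[1]]
  mid <- dp$crossings[dp$crossings$age_bin == "[40,52)", ]
  expect_false(is.na(mid$lo))
  planted <- planted_threshold(spec, 45.5)
  # crossing bracket (within a bin on each side) contains the planted threshold
  binw <- median(diff(dp$value_breaks))
  expect_true(mid$lo - binw <= planted && planted <= mid$hi + binw)
  # null-effect variable on held-out data: no crossing, tiny mean
  # contributions in every (age, value) cell
  dpn <- dependence_profile(ec, sp$test, "sodium",
                            age_breaks = c(12, 40, 60, 80), value_bins = 12)
  expect_true(all(is.na(dpn$crossings$lo)))
  expect_lt(max(abs(dpn$grid), na.rm = TRUE), 0.2)
  expect_error(dependence_profile(ec, sp$test, "nope"), "unknown variable")
})
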
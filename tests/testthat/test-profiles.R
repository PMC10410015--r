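test_that("Mann-Whitney agrees with exhaustive enumeration for small samples", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)        # continuous: tie-free
    mw <- mann_whitney(x, y)
    expect_equal(mw$p, enumerate_mw_p(x, y), tolerance = 1e-12)
    expect_identical(mw$method, "exact")
  }
})

test_that("Mann-Whitney matches the hand-computed separated-sample case", {
  mw <- mann_whitney(11:20, 1:10)   # all values in x above all in y
  expect_equal(mw$U, 100)
  expect_equal(mw$Z, (100 - 50) / sqrt(100 * 21 / 12), tolerance = 1e-10)
  expect_equal(round(mw$Z, 2), 3.78)
  expect_equal(round(mw$r, 3), 0.845)
  # degenerate: identical constants in both groups
  dg <- mann_whitney(rep(1, 8), rep(1, 9))
  expect_equal(dg$p, 1)
  expect_equal(dg$r, 0)
  # tie-corrected normal branch agrees with the base implementation
  set.seed(8)
  x <- sample(1:5, 30, TRUE); y <- sample(2:6, 25, TRUE)
  mw2 <- mann_whitney(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(mw2$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mw2$U, unname(ref$statistic))
})

test_that("Benjamini-Hochberg adjustment matches a reference step-up implementation", {
  set.seed(12)
  for (rep in 1:5) {
    p <- runif(sample(5:40, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("cluster signatures gate on both effect size and FDR", {
  set.seed(13)
  n <- 60
  phi <- cbind(strong = c(rnorm(n, 2, 0.5), rnorm(n, -2, 0.5)),
               weak = c(rnorm(n, 0.08, 1), rnorm(n, -0.08, 1)),
               none = rnorm(2 * n),
               flat = rep(1, 2 * n))
  rownames(phi) <- seq_len(2 * n)
  expl <- physage:::new_explanation_matrix(phi, 0, "contextualized")
  assign <- structure(list(labels = setNames(rep(1:2, each = n), rownames(phi)),
                           k = 2L), class = "cluster_assignment")
  st <- signature_tests(expl, assign)
  expect_true(st$retained[st$variable == "strong"])
  expect_false(st$retained[st$variable == "none"])
  expect_false(st$retained[st$variable == "flat"])
  expect_equal(st$r[st$variable == "flat"], 0)
  expect_equal(st$p[st$variable == "flat"], 1)
  # the retained flag is exactly the conjunction of its two criteria
  expect_identical(st$retained, st$r >= 0.3 & st$q < 0.05)
  expect_true(all(st$q >= st$p))
  # a variable can be significant yet fail the effect-size gate
  set.seed(14)
  m <- 400
  phi2 <- cbind(subtle = c(rnorm(m, 0.25, 1), rnorm(m, -0.25, 1)),
                pad = rnorm(2 * m))
  rownames(phi2) <- seq_len(2 * m)
  expl2 <- physage:::new_explanation_matrix(phi2, 0, "contextualized")
  assign2 <- structure(list(labels = setNames(rep(1:2, each = m), rownames(phi2)),
                            k = 2L), class = "cluster_assignment")
  st2 <- signature_tests(expl2, assign2)
  sub <- st2[st2$variable == "subtle", ]
  expect_lt(sub$q, 0.05)
  expect_lt(sub$r, 0.3)
  expect_false(sub$retained)
})

test_that("agglomerative clustering recovers structure and behaves at the edges", {
  set.seed(15)
  n <- 120; p <- 6
  arch <- rep(1:2, each = n / 2)
  phi <- matrix(rnorm(n * p, 0, 0.4), n, p,
                dimnames = list(seq_len(n), paste0("v", 1:p)))
  phi[, 1] <- phi[, 1] + ifelse(arch == 1, 2.5, -2.5)
  ca <- cluster_explanations(phi, k = 2)
  expect_gte(adjusted_rand(ca$labels, arch), 0.9)
  # Ward merge heights are monotone non-decreasing
  expect_true(all(diff(ca$merge_heights) >= -1e-9))
  # k = n: every individual its own cluster
  singletons <- cluster_explanations(phi[1:15, ], k = 15)
  expect_equal(sort(unique(singletons$labels)), 1:15)
  expect_error(cluster_explanations(phi, k = n + 1), "exceeds")
  # row-order invariance up to relabelling
  perm <- sample(n)
  cb <- cluster_explanations(phi[perm, ], k = 2)
  expect_equal(adjusted_rand(ca$labels[perm], cb$labels), 1)
})

test_that("decision profiles accumulate to the cluster mean deviation", {
  sim <- small_sim(n = 700, seed = 33)
  m <- fit_age_model(sim$cohort, quick_hp(), seed = 2)
  ec <- explain_contextualized(m, sim$cohort, min_group_size = 40)
  ca <- cluster_explanations(ec, k = 3)
  prof <- cluster_decision_profile(ec, ca)
  dev <- rowSums(ec$phi)
  for (cl in prof) {
    expect_equal(cl$profile$cumulative[nrow(cl$profile)],
                 mean(dev[ca$labels == cl$cluster]), tolerance = 1e-6)
    # terminal value is permutation-invariant
    expect_equal(sum(cl$profile$mean_phi), cl$mean_deviation, tolerance = 1e-9)
  }
  # single cluster: terminal ~ overall mean deviation ~ 0 (group centering)
  one <- structure(list(labels = setNames(rep(1L, nrow(ec$phi)), rownames(ec$phi)),
                        k = 1L), class = "cluster_assignment")
  p1 <- cluster_decision_profile(ec, one)
  expect_lt(abs(p1[[1]]$mean_deviation), 1e-3)
})
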
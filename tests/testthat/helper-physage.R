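# Shared fixtures and small independent oracles, all built in code.

# A compact mixed panel: one sigmoid, two linear, one window, one null.
small_panel <- function() {
  list(
    effect_spec("hba1c", "sigmoid", amplitude = 6, center = 5.5, width = 0.35,
                noise_sd = 0.3, baseline_mean = 5.5, baseline_sd = 0),
    effect_spec("bun", "linear", amplitude = 4, slope = 0.3, noise_sd = 5,
                baseline_mean = 40, baseline_sd = 3),
    effect_spec("mcv", "linear", amplitude = 3, slope = -0.2, noise_sd = 4,
                baseline_mean = 90, baseline_sd = 2),
    effect_spec("alp", "window", amplitude = 3, center = c(12, 20), slope = -5,
                noise_sd = 30, baseline_mean = 110, baseline_sd = 10),
    effect_spec("sodium", "null", noise_sd = 1.5, baseline_mean = 140, baseline_sd = 1)
  )
}

small_sim <- function(n = 600, seed = 11, missing_rate = 0, effects = small_panel()) {
  generate_cohort(generator_config(n_individuals = n, effects = effects,
                                   missing_rate = missing_rate, seed = seed))
}

quick_hp <- function(...) utils::modifyList(list(nrounds = 60L, max_depth = 3L, eta = 0.2), list(...))

# Brute-force interventional Shapley values by enumeration of all coalitions,
# evaluating hybrid rows through the model's own prediction function.
brute_force_shap <- function(model, x, B) {
  parsed <- physage:::parse_booster(model)
  p <- length(x)
  fhyb <- function(S, z) {
    h <- z
    h[S] <- x[S]
    physage:::margin_predict(parsed, matrix(h, 1))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  for (i in seq_len(p)) {
    for (S in subsets) {
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      dif <- vapply(seq_len(nrow(B)), function(b) fhyb(c(S, i), B[b, ]) - fhyb(S, B[b, ]),
                    numeric(1))
      phi[i] <- phi[i] + w * mean(dif)
    }
  }
  phi
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Exact two-sided Mann-Whitney p-value by enumerating all C(n1+n2, n1)
# group labelings (tie-free samples).
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  dev_obs <- abs(u_obs - mu)
  mean(abs(us - mu) >= dev_obs - 1e-9)
}

# Reference step-up Benjamini-Hochberg implementation.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}
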
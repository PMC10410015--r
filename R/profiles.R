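#' Cluster individuals in contextualized explanation space
#'
#' Hierarchical agglomerative clustering (Ward linkage on Euclidean
#' distances) of the rows of a contextualized explanation matrix, cut at `k`
#' clusters. Chronological age is never part of the feature space: the matrix
#' holds only per-variable contributions. Cluster labels are renumbered in
#' order of first appearance so the labelling does not depend on row order.
#'
#' @param expl A contextualized `explanation_matrix` (a plain matrix is also
#'   accepted).
#' @param k Number of clusters, `2 <= k <= n`.
#' @return A list of class `cluster_assignment`: `labels` (named integer
#'   vector in 1..k), `k`, `merge_heights` (non-decreasing Ward heights) and
#'   the `hclust` tree.
#' @export
cluster_explanations <- function(expl, k) {
  phi <- if (inherits(expl, "explanation_matrix")) expl$phi else as.matrix(expl)
  n <- nrow(phi)
  if (k > n) stopf("k = %d exceeds the number of individuals (%d)", k, n)
  if (k < 2 && n > 1) stopf("k must be >= 2")
  tree <- hclust(dist(phi, method = "euclidean"), method = "ward.D2")
  raw <- cutree(tree, k = k)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  names(labels) <- rownames(phi)
  structure(list(labels = labels, k = as.integer(k),
                 merge_heights = tree$height, tree = tree),
            class = "cluster_assignment")
}

#' Silhouette-vs-k report
#'
#' Mean silhouette width of the Ward clustering for a range of cut heights,
#' to guide the choice of `k` (no automatic selection is imposed).
#'
#' @param expl Contextualized `explanation_matrix` or matrix.
#' @param k_range Candidate numbers of clusters.
#' @return A data frame `k`, `mean_silhouette`.
#' @export
silhouette_report <- function(expl, k_range = 2:12) {
  phi <- if (inherits(expl, "explanation_matrix")) expl$phi else as.matrix(expl)
  d <- as.matrix(dist(phi))
  tree <- hclust(stats::as.dist(d), method = "ward.D2")
  sil_for <- function(k) {
    lab <- cutree(tree, k = k)
    s <- vapply(seq_len(nrow(d)), function(i) {
      own <- lab == lab[i]; own[i] <- FALSE
      if (!any(own)) return(0)
      a <- mean(d[i, own])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(cl) mean(d[i, lab == cl]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  data.frame(k = k_range, mean_silhouette = vapply(k_range, sil_for, numeric(1)))
}

#' Mann-Whitney U test with rank-biserial style effect size
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison with the effect size
#' r = |Z| / sqrt(n1 + n2) used for cluster signatures. For `n1 + n2 <= 12`
#' without ties the p-value is exact (from the enumerated U null); otherwise
#' the tie-corrected normal approximation with a 0.5 continuity correction is
#' used. `Z` itself (hence `r`) carries the tie correction but no continuity
#' correction. A comparison with zero rank variance (all values tied across
#' both samples) returns `p = 1` and a zero effect size.
#'
#' @param x,y Numeric samples.
#' @return A list: `U` (statistic of `x`), `Z`, `p` (two-sided), `r`,
#'   `method` ("exact" or "normal").
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stopf("both samples must be non-empty")
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) {
    return(list(U = U, Z = 0, p = 1, r = 0, method = "degenerate"))
  }
  Z <- (U - mu) / sqrt(sig2)
  r <- abs(Z) / sqrt(n)
  if (n <= 12 && tie_term == 0) {
    p <- if (U > mu) 2 * (1 - pwilcox(U - 1, n1, n2)) else 2 * pwilcox(U, n1, n2)
    p <- min(1, p)
    return(list(U = U, Z = Z, p = p, r = r, method = "exact"))
  }
  z_cc <- max(0, abs(U - mu) - 0.5) / sqrt(sig2)
  p <- min(1, 2 * (1 - pnorm(z_cc)))
  list(U = U, Z = Z, p = p, r = r, method = "normal")
}

#' Statistical signatures of explanation clusters
#'
#' For every variable and every pair of clusters, compares the contextualized
#' contributions between the two clusters with [mann_whitney()].
#' Benjamini-Hochberg adjustment is applied across all variables within each
#' cluster pair (the default family; `family = "pooled"` adjusts across all
#' pairs at once). A variable is retained as discriminating for a pair when
#' both the effect size is at least medium (r of at least `r_min`, default 0.3) and
#' the adjusted p-value is below `alpha`.
#'
#' @param expl Contextualized `explanation_matrix`.
#' @param assignment A `cluster_assignment` over the same individuals.
#' @param r_min Minimum effect size.
#' @param alpha FDR level on the adjusted p-value.
#' @param family `"per_pair"` (default) or `"pooled"` BH family.
#' @return A data frame of class `signature_tests`: `variable`, `cluster_a`,
#'   `cluster_b`, `U`, `Z`, `r`, `p`, `q`, `retained`.
#' @export
signature_tests <- function(expl, assignment, r_min = 0.3, alpha = 0.05,
                            family = c("per_pair", "pooled")) {
  family <- match.arg(family)
  phi <- expl$phi
  lab <- assignment$labels
  if (nrow(phi) != length(lab)) stopf("assignment and explanation matrix are not aligned")
  sizes <- table(lab)
  if (any(sizes < 2)) stopf("every cluster needs at least 2 members")
  clusters <- sort(unique(lab))
  pairs <- utils::combn(clusters, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    ia <- lab == pr[1]; ib <- lab == pr[2]
    tests <- lapply(colnames(phi), function(v) mann_whitney(phi[ia, v], phi[ib, v]))
    data.frame(variable = colnames(phi), cluster_a = pr[1], cluster_b = pr[2],
               U = vapply(tests, `[[`, numeric(1), "U"),
               Z = vapply(tests, `[[`, numeric(1), "Z"),
               r = vapply(tests, `[[`, numeric(1), "r"),
               p = vapply(tests, `[[`, numeric(1), "p"))
  })
  out <- do.call(rbind, rows)
  out$q <- if (family == "per_pair") {
    grp <- paste(out$cluster_a, out$cluster_b)
    stats::ave(out$p, grp, FUN = function(p) p.adjust(p, method = "BH"))
  } else p.adjust(out$p, method = "BH")
  out$retained <- out$r >= r_min & out$q < alpha
  class(out) <- c("signature_tests", class(out))
  out
}

#' Cluster decision profiles
#'
#' Summarises every cluster by the mean contextualized contribution of each
#' variable and a decision path: the running cumulative sum of those means,
#' taken in importance order, ending (exactly) at the cluster's mean PPA
#' deviation — the profile of the cluster's "average individual".
#'
#' @param expl Contextualized `explanation_matrix`.
#' @param assignment A `cluster_assignment`.
#' @param ordering An `importance_ranking` supplying the variable order
#'   (default: computed from `expl`).
#' @param signatures Optional [signature_tests()] output used to flag each
#'   cluster's discriminating variables.
#' @return A list of class `cluster_signatures`, one element per cluster:
#'   `cluster`, `n`, `profile` (variable, mean_phi, cumulative, retained),
#'   `mean_deviation`.
#' @export
cluster_decision_profile <- function(expl, assignment, ordering = NULL,
                                     signatures = NULL) {
  phi <- expl$phi
  lab <- assignment$labels
  ordering <- ordering %||% rank_importance(expl)
  vars <- ordering$variable
  out <- lapply(sort(unique(lab)), function(cl) {
    idx <- lab == cl
    if (!any(idx)) stopf("cluster %s is empty", cl)
    m <- colMeans(phi[idx, vars, drop = FALSE])
    retained <- if (is.null(signatures)) rep(NA, length(vars)) else {
      vapply(vars, function(v) {
        any(signatures$retained & signatures$variable == v &
              (signatures$cluster_a == cl | signatures$cluster_b == cl))
      }, logical(1))
    }
    list(cluster = cl, n = sum(idx),
         profile = data.frame(variable = vars, mean_phi = unname(m),
                              cumulative = cumsum(unname(m)),
                              retained = retained),
         mean_deviation = sum(m))
  })
  structure(out, class = "cluster_signatures")
}

#' @export
print.cluster_signatures <- function(x, ...) {
  for (cl in x) {
    cat(sprintf("cluster %d (n = %d): mean PPA deviation %+.2f years\n",
                cl$cluster, cl$n, cl$mean_deviation))
  }
  invisible(x)
}
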
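# Pairwise two-sample t statistics on all between-column log-ratios,
# computed from the column means and covariances of each group: for columns
# (k,l), var(y_k - y_l) = S_kk + S_ll - 2*S_kl, so one covariance matrix per
# group yields all K(K-1)/2 tests at once.
.pairwise_logratio_p <- function(Y, idx1, idx2, var_equal = FALSE) {
  Y1 <- Y[idx1, , drop = FALSE]
  Y2 <- Y[idx2, , drop = FALSE]
  n1 <- nrow(Y1); n2 <- nrow(Y2)
  m1 <- colMeans(Y1); m2 <- colMeans(Y2)
  S1 <- stats::cov(Y1); S2 <- stats::cov(Y2)
  v1 <- outer(diag(S1), diag(S1), "+") - 2 * S1
  v2 <- outer(diag(S2), diag(S2), "+") - 2 * S2
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0   # guard tiny negative rounding
  D <- outer(m1, m1, "-") - outer(m2, m2, "-")
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- D / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- matrix(n1 + n2 - 2, nrow(tt), ncol(tt))
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- D / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  P <- 2 * stats::pt(-abs(tt), df = df)
  P[!is.finite(tt)] <- 1   # identical ratios in both groups: no evidence
  diag(P) <- 1
  dimnames(P) <- list(colnames(Y), colnames(Y))
  P
}

#' Pairwise log-ratio t-tests between two patient groups
#'
#' For every pair of clusters (k, l), computes per patient the log abundance
#' ratio `ln(a_k / a_l)` and a two-sided two-sample t-test between the
#' groups. Only ratios between components of a composition are
#' interpretable, which is why the test operates on pairs. Zero proportions
#' are replaced by half a count over the patient's total cell count
#' (`0.5 / total`), mirroring the half-quantification-limit convention, and
#' the replacement count is recorded.
#'
#' The default is Welch's unequal-variance test; the pooled equal-variance
#' variant is available via `var_equal = TRUE`.
#'
#' @param abund an `abundance_table` (patients x clusters proportions, with
#'   `groups` and optionally `counts` attributes).
#' @param group_a,group_b group labels to compare.
#' @param groups optional patient-to-group named vector overriding the
#'   table's attribute.
#' @param var_equal use the pooled equal-variance t-test.
#' @return A `pairwise_pvals` object: symmetric K x K p-value matrix
#'   (diagonal 1) with attributes `n1`, `n2`, `var_equal` and
#'   `zero_replaced` (number of replaced entries).
#' @export
logratio_pvalues <- function(abund, group_a, group_b, groups = NULL,
                             var_equal = FALSE) {
  p <- unclass(abund)
  if (ncol(p) < 2) stop("need at least 2 clusters")
  if (is.null(groups)) groups <- attr(abund, "groups")
  if (is.null(groups)) stop("no patient-to-group map available")
  ga <- rownames(p)[groups[rownames(p)] == group_a]
  gb <- rownames(p)[groups[rownames(p)] == group_b]
  if (length(ga) < 2 || length(gb) < 2)
    stop("both groups need at least 2 patients")
  counts <- attr(abund, "counts")
  zero <- p == 0
  if (any(zero)) {
    if (is.null(counts))
      stop("zero proportions present but no companion counts to set the ",
           "replacement value 0.5/total")
    totals <- rowSums(counts)
    if (any(totals == 0)) stop("patient with zero total cells")
    repl <- (0.5 / totals)[row(p)[zero]]
    p[zero] <- repl
  }
  Y <- log(p)
  P <- .pairwise_logratio_p(Y, match(ga, rownames(p)), match(gb, rownames(p)),
                            var_equal = var_equal)
  structure(P, class = c("pairwise_pvals", "matrix", "array"),
            n1 = length(ga), n2 = length(gb), var_equal = var_equal,
            zero_replaced = sum(zero))
}

#' Cluster graph at a p-value threshold
#'
#' Builds the compositional abundance graph: clusters are nodes and an edge
#' joins (k, l) when their log-ratio test is non-significant, i.e. when
#' `p >= threshold`. A disconnected graph signals abundance change, and the
#' connected components identify which clusters differ between the groups.
#'
#' @param pvals a `pairwise_pvals` matrix (or plain symmetric matrix).
#' @param threshold edge-cut threshold in \[0, 1\].
#' @return An `abundance_graph`: list with the `igraph` object, `threshold`,
#'   `membership` (component id per node) and `components` (list of node-name
#'   vectors).
#' @export
build_graph <- function(pvals, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  P <- unclass(pvals)
  adj <- (P >= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  structure(list(graph = g, threshold = threshold,
                 membership = comp$membership,
                 components = unname(members)),
            class = "abundance_graph")
}

#' @export
print.abundance_graph <- function(x, ...) {
  cat("abundance_graph:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges at threshold", x$threshold, "\n")
  cat("  components:", length(x$components),
      if (length(x$components) > 1) "(disjoint)" else "(connected)", "\n")
  invisible(x)
}

#' Export an abundance graph in DOT format
#'
#' @param graph an `abundance_graph`.
#' @param path output file.
#' @export
write_graph_dot <- function(graph, path) {
  igraph::write_graph(graph$graph, path, format = "dot")
  invisible(path)
}

#' Bottleneck p-value of the cluster graph
#'
#' The largest threshold at which the graph is still connected: the graph is
#' disjoint at threshold t if and only if `t > b`. Equals the minimum edge
#' weight on the maximum-weight spanning tree of the p-value matrix,
#' computed here with Prim's algorithm on the dense matrix. This reduces the
#' disjointness-versus-threshold sweep to a single number per replicate,
#' which is what makes the Monte-Carlo calibration cheap.
#'
#' @param pvals a `pairwise_pvals` or plain symmetric weight matrix, K >= 2.
#' @return The bottleneck value `b`.
#' @export
bottleneck_pvalue <- function(pvals) {
  P <- unclass(pvals)
  K <- nrow(P)
  if (K < 2) stop("need at least 2 nodes")
  intree <- rep(FALSE, K)
  intree[1] <- TRUE
  best <- P[, 1]
  b <- Inf
  for (i in 2:K) {
    j <- which.max(replace(best, intree, -Inf))
    b <- min(b, best[j])
    intree[j] <- TRUE
    best <- pmax(best, P[, j])
  }
  b
}

#' Monte-Carlo calibration of the edge-cut threshold
#'
#' Determines the per-edge p-value threshold that controls the family-wise
#' type-I error of wrongly obtaining a disjoint graph at level `alpha`,
#' accounting for the multiplicity and dependence of the pairwise tests.
#' Each simulation draws null per-patient abundances (iid standard normal
#' log-abundances, no group effect; the t statistic on log-ratios is
#' location/scale pivotal so the calibration does not depend on the null's
#' mean or variance), computes all pairwise log-ratio p-values and the
#' connectivity bottleneck. The point estimate is the empirical
#' `alpha`-quantile of the bottleneck values; a distribution-free 95%
#' confidence interval for that quantile comes from binomial order
#' statistics; and the chosen threshold is the CI lower bound - the
#' conservative choice, guaranteeing type-I error at most `alpha` within
#' simulation error.
#'
#' One root seed spawns per-simulation L'Ecuyer substreams, so changing
#' `n_sims` never reshuffles earlier draws.
#'
#' @param n_nodes number of clusters (graph nodes), at least 2.
#' @param n1,n2 group sizes, each at least 2.
#' @param n_sims number of simulations (default 10,000), at least 100.
#' @param alpha target family-wise type-I error (default 0.05).
#' @param seed integer root seed.
#' @param var_equal use the pooled t-test instead of Welch.
#' @return A `calibration_result`: `estimate` (quantile point estimate),
#'   `ci` (95% CI), `threshold` (CI lower bound), `type1_at_threshold`
#'   (empirical error at the chosen threshold), the simulation settings, and
#'   the sorted `bottlenecks`.
#' @export
calibrate_threshold <- function(n_nodes, n1, n2, n_sims = 10000,
                                alpha = 0.05, seed = 1, var_equal = FALSE) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 patients")
  if (n_sims < 100) stop("need at least 100 simulations")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  old_kind <- RNGkind("L'Ecuyer-CMRG")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  stream <- get(".Random.seed", globalenv())
  idx1 <- seq_len(n1)
  idx2 <- n1 + seq_len(n2)
  bs <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    assign(".Random.seed", stream, globalenv())
    # raw log-abundances: the simplex normalization is a per-patient
    # constant and cancels exactly in every pairwise log-ratio
    Y <- .null_logabund(n1 + n2, n_nodes)
    P <- .pairwise_logratio_p(Y, idx1, idx2, var_equal = var_equal)
    bs[s] <- bottleneck_pvalue(P)
    stream <- parallel::nextRNGStream(stream)
  }
  sb <- sort(bs)
  est <- unname(stats::quantile(bs, alpha))
  l <- max(1, stats::qbinom(0.025, n_sims, alpha))
  u <- min(n_sims, stats::qbinom(0.975, n_sims, alpha) + 1)
  ci <- c(lower = sb[l], upper = sb[u])
  thr <- unname(ci["lower"])
  structure(list(n_nodes = n_nodes, n1 = n1, n2 = n2, n_sims = n_sims,
                 alpha = alpha, seed = seed, var_equal = var_equal,
                 estimate = est, ci = ci, threshold = thr,
                 type1_at_threshold = mean(bs < thr),
                 bottlenecks = sb),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("threshold calibration:", x$n_sims, "simulations,", x$n_nodes,
      "nodes, groups", x$n1, "vs", x$n2, ", alpha =", x$alpha, "\n")
  cat(sprintf("  %g%% quantile estimate: %.3f (95%% CI %.2f-%.2f)\n",
              100 * x$alpha, x$estimate, x$ci["lower"], x$ci["upper"]))
  cat(sprintf("  conservative threshold: %.2f (empirical type-I %.3f)\n",
              round(x$threshold, 2), x$type1_at_threshold))
  invisible(x)
}

#' Write a calibration result as JSON
#'
#' @param result a `calibration_result`.
#' @param path output file.
#' @export
write_calibration_result <- function(result, path) {
  jsonlite::write_json(
    result[c("n_nodes", "n1", "n2", "n_sims", "alpha", "seed", "var_equal",
             "estimate", "threshold", "type1_at_threshold")] |>
      c(list(ci_lower = unname(result$ci["lower"]),
             ci_upper = unname(result$ci["upper"]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compositional test of cluster-abundance change
#'
#' Full pipeline: pairwise log-ratio p-values between the two groups, edge
#' cut at the calibrated threshold, connected components, and the
#' disjointness decision. A disjoint graph means the corresponding cluster
#' abundances changed between the groups; the components are the classes of
#' clusters whose ratios moved together.
#'
#' @param abund an `abundance_table`.
#' @param group_a,group_b group labels to compare.
#' @param threshold calibrated edge-cut threshold (see
#'   [calibrate_threshold()]).
#' @param groups optional patient-to-group override.
#' @param var_equal use the pooled t-test.
#' @return A `compositional_test` result: `disjoint` (logical),
#'   `components` (list of cluster-name vectors), `pvals`, `graph`,
#'   `threshold`.
#' @export
compositional_test <- function(abund, group_a, group_b, threshold,
                               groups = NULL, var_equal = FALSE) {
  pv <- logratio_pvalues(abund, group_a, group_b, groups = groups,
                         var_equal = var_equal)
  g <- build_graph(pv, threshold)
  structure(list(disjoint = length(g$components) > 1,
                 components = g$components,
                 pvals = pv, graph = g, threshold = threshold),
            class = "compositional_test")
}

#' @export
print.compositional_test <- function(x, ...) {
  cat("compositional abundance test at threshold", x$threshold, "\n")
  if (x$disjoint) {
    cat("  graph DISJOINT:", length(x$components),
        "classes of clusters differ between the groups\n")
    for (comp in x$components)
      cat("   ", paste(comp, collapse = ", "), "\n")
  } else cat("  graph connected: no abundance change detected\n")
  invisible(x)
}
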
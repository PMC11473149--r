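test_that("pairwise log-ratio p-values match stats::t.test pair by pair", {
  set.seed(3)
  la <- matrix(rnorm(9 * 5), 9, 5)
  groups <- setNames(rep(c("R1", "R2"), c(5, 4)), paste0("P", 1:9))
  rownames(la) <- names(groups)
  ab <- abund_from_log(la, groups)
  for (ve in c(FALSE, TRUE)) {
    pv <- logratio_pvalues(ab, "R1", "R2", var_equal = ve)
    for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
      lr <- log(unclass(ab)[, pair[1]] / unclass(ab)[, pair[2]])
      ref <- stats::t.test(lr[groups == "R1"], lr[groups == "R2"],
                           var.equal = ve)$p.value
      expect_equal(unclass(pv)[pair[1], pair[2]], ref, tolerance = 1e-12)
    }
    expect_equal(unclass(pv), t(unclass(pv)))     # symmetry
    expect_true(all(unclass(pv) >= 0 & unclass(pv) <= 1))
    expect_equal(unname(diag(unclass(pv))), rep(1, 5))
  }
})

test_that("a 10-sd separated pair is detected and degenerate data yields p = 1", {
  groups <- setNames(rep(c("R1", "R2"), c(4, 4)), paste0("P", 1:8))
  la <- cbind(c(0.01, -0.01, 0.02, -0.02, 10, 10.01, 9.99, 10.02),
              rep(0, 8))
  rownames(la) <- names(groups)
  ab <- abund_from_log(la, groups)
  pv <- logratio_pvalues(ab, "R1", "R2")
  expect_lt(unclass(pv)[1, 2], 1e-3)

  # identical abundance vectors in every patient: zero contrasts, p = 1
  same <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  rownames(same) <- names(groups)
  ab0 <- abund_from_log(same, groups)
  pv0 <- logratio_pvalues(ab0, "R1", "R2")
  expect_true(all(unclass(pv0) == 1))
})

test_that("p-values are invariant to per-patient rescaling and pivotal", {
  set.seed(8)
  la <- matrix(rnorm(8 * 4), 8, 4)
  groups <- setNames(rep(c("A", "B"), each = 4), paste0("P", 1:8))
  rownames(la) <- names(groups)
  p1 <- logratio_pvalues(abund_from_log(la, groups), "A", "B")
  # per-patient scale: multiply each patient's abundances by a constant --
  # proportions renormalize, so feed raw positive values instead
  raw <- exp(la) * runif(8, 0.5, 5)
  rownames(raw) <- names(groups)
  colnames(raw) <- paste0("C", 1:4)
  raw_tab <- structure(raw, class = "abundance_table", groups = groups)
  p2 <- logratio_pvalues(raw_tab, "A", "B")
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # location/scale changes of the log-abundances leave p untouched
  p3 <- logratio_pvalues(abund_from_log(2 * la, groups), "A", "B")
  p4 <- logratio_pvalues(abund_from_log(la + 0.7, groups), "A", "B")
  expect_equal(unclass(p1), unclass(p3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(p1), unclass(p4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero proportions use the half-count replacement and are recorded", {
  groups <- setNames(rep(c("A", "B"), each = 2), paste0("P", 1:4))
  counts <- matrix(c(0, 5, 5, 2,
                     10, 5, 5, 8,
                     10, 10, 10, 10), 4, 3,
                   dimnames = list(names(groups), c("C1", "C2", "C3")))
  prop <- counts / rowSums(counts)
  ab <- structure(prop, class = "abundance_table", groups = groups,
                  counts = counts)
  pv <- logratio_pvalues(ab, "A", "B")
  expect_equal(attr(pv, "zero_replaced"), 1)
  # oracle: replace the zero by 0.5/20 before the ratios
  prop2 <- prop; prop2[1, 1] <- 0.5 / 20
  lr <- log(prop2[, 1] / prop2[, 2])
  ref <- stats::t.test(lr[1:2], lr[3:4])$p.value
  expect_equal(unclass(pv)[1, 2], ref, tolerance = 1e-12)

  ab_nc <- structure(prop, class = "abundance_table", groups = groups)
  expect_error(logratio_pvalues(ab_nc, "A", "B"), "counts")
  expect_error(logratio_pvalues(ab, "A", "C"), "2 patients")
})

test_that("graph construction follows the edge rule at the boundaries", {
  P <- matrix(c(1, 0.9, 0.5, 0.1,
                0.9, 1, 0.6, 0.15,
                0.5, 0.6, 1, 0.12,
                0.1, 0.15, 0.12, 1), 4, 4,
              dimnames = list(paste0("C", 1:4), paste0("C", 1:4)))
  g0 <- build_graph(P, 0)
  expect_equal(length(g0$components), 1)
  expect_equal(igraph::ecount(g0$graph), 6)        # complete on 4 nodes
  # node 4 isolates at 0.2: all its p-values are below
  g2 <- build_graph(P, 0.2)
  expect_equal(length(g2$components), 2)
  expect_true(any(vapply(g2$components, identical, TRUE, "C4")))
  # threshold 1 keeps only p = 1 edges
  P1 <- P; P1["C1", "C2"] <- P1["C2", "C1"] <- 1
  g1 <- build_graph(P1, 1)
  expect_equal(igraph::ecount(g1$graph), 1)
  expect_error(build_graph(P, 1.5), "threshold")
})

test_that("bottleneck equals hand-computable cases and the igraph MST", {
  allsame <- matrix(0.7, 5, 5); diag(allsame) <- 1
  dimnames(allsame) <- list(paste0("C", 1:5), paste0("C", 1:5))
  expect_equal(bottleneck_pvalue(allsame), 0.7)

  # path 1-2-3-4 with weights 0.9, 0.4, 0.8; off-path edges 0
  path <- matrix(0, 4, 4)
  path[1, 2] <- path[2, 1] <- 0.9
  path[2, 3] <- path[3, 2] <- 0.4
  path[3, 4] <- path[4, 3] <- 0.8
  diag(path) <- 1
  dimnames(path) <- list(paste0("C", 1:4), paste0("C", 1:4))
  expect_equal(bottleneck_pvalue(path), 0.4)

  set.seed(23)
  for (i in 1:25) {
    P <- random_pmatrix(sample(3:7, 1))
    b <- bottleneck_pvalue(P)
    expect_equal(b, bottleneck_bruteforce(P))
    # independent route: min edge on igraph's maximum spanning tree
    g <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(b, min(igraph::E(mst)$weight))
  }
})

test_that("disjointness is monotone along a threshold sweep", {
  set.seed(29)
  P <- random_pmatrix(6)
  cand <- sort(unique(P[upper.tri(P)]))
  prev <- NULL
  for (t in c(0, cand, 1)) {
    comp <- build_graph(P, t)$components
    if (!is.null(prev)) {
      # every new component sits inside one old component (refinement)
      for (cc in comp) {
        holders <- vapply(prev, function(p) all(cc %in% p), logical(1))
        expect_equal(sum(holders), 1)
      }
      expect_gte(length(comp), length(prev))
    }
    prev <- comp
  }
  b <- bottleneck_pvalue(P)
  expect_equal(length(build_graph(P, b)$components), 1)
  expect_gt(length(build_graph(P, b + 1e-9)$components), 1)
})

test_that("calibration is reproducible, stream-stable and sane at alpha -> 1", {
  c1 <- calibrate_threshold(8, 4, 3, n_sims = 150, seed = 10)
  c2 <- calibrate_threshold(8, 4, 3, n_sims = 150, seed = 10)
  expect_identical(c1$bottlenecks, c2$bottlenecks)
  # substreams: growing n_sims extends, never reshuffles, earlier draws
  c3 <- calibrate_threshold(8, 4, 3, n_sims = 300, seed = 10)
  expect_true(all(c1$bottlenecks %in% c3$bottlenecks))
  expect_true(c1$ci["lower"] <= c1$estimate && c1$estimate <= c1$ci["upper"])
  expect_equal(c1$threshold, unname(c1$ci["lower"]))
  expect_lte(c1$type1_at_threshold, c1$alpha)

  chi <- calibrate_threshold(5, 3, 3, n_sims = 150, alpha = 0.99, seed = 1)
  expect_gte(chi$estimate, stats::quantile(chi$bottlenecks, 0.95))

  expect_error(calibrate_threshold(1, 7, 3), "2 nodes")
  expect_error(calibrate_threshold(5, 1, 3), "2 patients")
  expect_error(calibrate_threshold(5, 7, 3, n_sims = 10), "100")
})

test_that("the full compositional test returns components and honours t = 0", {
  set.seed(31)
  la <- matrix(rnorm(10 * 6), 10, 6)
  la[8:10, 3] <- la[8:10, 3] + 8    # strong shift isolates C3
  groups <- setNames(rep(c("R1", "R2"), c(7, 3)), paste0("P", 1:10))
  rownames(la) <- names(groups)
  ab <- abund_from_log(la, groups)
  res <- compositional_test(ab, "R1", "R2", threshold = 0.38)
  expect_true(res$disjoint)
  expect_true(any(vapply(res$components, identical, TRUE, "C3")))

  res0 <- compositional_test(ab, "R1", "R2", threshold = 0)
  expect_false(res0$disjoint)
  expect_equal(length(res0$components), 1)
})
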
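test_that("clr transform matches the log-minus-mean-log oracle", {
  # oracle: replace zeros by 0.5, then ln(x) - mean(ln(x)) per cell
  x <- rbind(c(1, 0, 3), c(2, 2, 2), c(5, 1, 4))
  oracle <- t(apply(x, 1, function(r) {
    r[r == 0] <- 0.5
    log(r) - mean(log(r))
  }))
  got <- clr_normalize(x)
  expect_equal(unclass(got), oracle, ignore_attr = TRUE)
  # every row has mean zero; constant row maps to zeros
  expect_equal(rowMeans(got), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(got)[2, ], rep(0, 3), ignore_attr = TRUE)
  expect_equal(attr(got, "replaced_fraction"), 1 / 9)
})

test_that("clr zero handling is explicit", {
  expect_equal(attr(clr_normalize(matrix(1:6, 2)), "replaced_fraction"), 0)
  expect_error(clr_normalize(rbind(c(0, 0), c(1, 2)), zero_replacement = 0),
               "all counts zero")
  expect_error(clr_normalize(matrix(-1, 1, 2)), "non-negative")
})

test_that("patient correction reproduces the worked two-patient example", {
  # group mean of cells {1,3,4,6} is 3.5; A (mean 2) and B (mean 5) both
  # shift so their cells become {2.5,4.5}
  x <- matrix(c(1, 3, 4, 6), ncol = 1)
  cells <- data.frame(patient_id = c("A", "A", "B", "B"), group_id = "g")
  h <- harmonize_patients(x, cells)
  expect_equal(as.vector(h), c(2.5, 4.5, 2.5, 4.5))
  pm <- rowsum(unclass(h), cells$patient_id) / 2
  expect_equal(as.vector(pm), c(3.5, 3.5))
})

test_that("patient correction is idempotent and preserves group contrasts", {
  set.seed(1)
  n <- 60
  cells <- data.frame(
    patient_id = rep(paste0("P", 1:6), each = 10),
    group_id = rep(c("D", "R1", "R2"), each = 20),
    batch_id = rep(c("B1", "B2"), 30))
  x <- matrix(rnorm(n * 5), n, 5) +
    rep(rnorm(6, sd = 2), each = 10)     # strong patient offsets
  h1 <- harmonize_patients(x, cells)
  h2 <- harmonize_patients(unclass(h1), cells)
  expect_equal(unclass(h2), unclass(h1), tolerance = 1e-12,
               ignore_attr = TRUE)

  gmean <- function(m) rowsum(unclass(m), cells$group_id) /
    as.vector(table(cells$group_id))
  before <- gmean(x); after <- gmean(h1)
  # between-group differences are untouched by the projection
  expect_equal(before["D", ] - before["R1", ], after["D", ] - after["R1", ],
               tolerance = 1e-13)
  expect_equal(before["R1", ] - before["R2", ], after["R1", ] - after["R2", ],
               tolerance = 1e-13)
  # identity when every patient mean already equals its group mean
  expect_equal(unclass(harmonize_patients(unclass(h1), cells)), unclass(h1),
               tolerance = 1e-13, ignore_attr = TRUE)
})

test_that("batch correction equalizes batch means and keeps the overall mean", {
  x <- matrix(c(1, 1, 3, 3, 10, 12, 14, 16), ncol = 2)
  cells <- data.frame(patient_id = "P1", group_id = "D",
                      batch_id = c("B1", "B1", "B2", "B2"))
  h <- harmonize_batches(x, cells)
  bm <- rowsum(unclass(h), cells$batch_id) / 2
  expect_equal(bm["B1", ], bm["B2", ])
  expect_equal(as.vector(bm[1, ]), c(2, 13))     # the overall means
  expect_equal(colMeans(unclass(h)), colMeans(x))
  # single batch: identity
  one <- data.frame(patient_id = "P1", group_id = "D", batch_id = "B1")
  one <- one[rep(1, 4), ]
  expect_equal(unclass(harmonize_batches(x, one)), x, ignore_attr = TRUE)
})

test_that("harmonization agrees exactly with an explicit averaging oracle", {
  set.seed(9)
  n <- 50
  cells <- data.frame(
    patient_id = sample(paste0("P", 1:5), n, replace = TRUE),
    group_id = NA, batch_id = "B1")
  cells$group_id <- ifelse(cells$patient_id %in% c("P1", "P2"), "D", "R1")
  x <- matrix(rnorm(n * 3), n, 3)
  h <- harmonize_patients(x, cells)

  oracle <- x
  for (m in 1:3) {
    for (p in unique(cells$patient_id)) {
      rows <- cells$patient_id == p
      g <- unique(cells$group_id[rows])
      grows <- cells$group_id == g
      oracle[rows, m] <- x[rows, m] - (mean(x[rows, m]) - mean(x[grows, m]))
    }
  }
  expect_equal(unclass(h), oracle, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("composite harmonization satisfies the final patient-mean invariant", {
  sim <- simulate_dataset(simulation_design(
    groups = c(D = 2, R1 = 3, R2 = 2), n_clusters = 5, n_markers = 12,
    cells_per_patient = 60, n_genes = 30, n_mito_genes = 3, seed = 21))
  clr <- clr_normalize(marker_counts(sim$dataset))
  cells <- sim$dataset$cells
  h <- harmonize(clr, cells)
  pm <- rowsum(unclass(h), cells$patient_id) /
    as.vector(table(cells$patient_id))
  gm <- rowsum(unclass(h), cells$group_id) /
    as.vector(table(cells$group_id))
  grp <- attr(h, "patient_group")
  expect_lt(max(abs(pm - gm[grp[rownames(pm)], ])), 1e-9)
  # one batch: composite equals patient correction alone
  cells1 <- cells; cells1$batch_id <- "B1"
  expect_equal(unclass(harmonize(clr, cells1)),
               unclass(harmonize_patients(clr, cells1)), tolerance = 1e-13,
               ignore_attr = TRUE)
  # a patient emptied by filtering (empty factor level) is reported by name
  cells_f <- cells
  cells_f$patient_id <- factor(cells_f$patient_id)
  keep <- cells_f$patient_id != "D_p1"
  expect_error(harmonize_patients(unclass(clr)[keep, ], cells_f[keep, ]),
               "D_p1")
})

test_that("near-zero planted effects leave harmonization close to identity", {
  sim <- simulate_dataset(simulation_design(
    groups = c(D = 2, R1 = 2, R2 = 2), n_clusters = 3, n_markers = 8,
    cells_per_patient = 200, n_genes = 20, n_mito_genes = 2,
    sigma_patient = 0, sigma_batch = 0, sigma_abund = 0,
    group_abundance_effects = data.frame(group_id = character(),
                                         cluster = integer(),
                                         effect = numeric()),
    seed = 31))
  clr <- clr_normalize(marker_counts(sim$dataset))
  h <- harmonize(clr, sim$dataset$cells)
  # corrections only remove sampling noise of patient/batch means
  expect_lt(max(abs(unclass(h) - unclass(clr))), 0.35)
  expect_lt(mean(abs(unclass(h) - unclass(clr))), 0.08)
})
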
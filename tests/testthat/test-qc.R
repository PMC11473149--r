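test_that("the five droplet rules reproduce the hand-enumerated survivors", {
  ds <- six_droplet_dataset()
  res <- filter_droplets(ds)
  expect_equal(res$report$kept_cells, "cell6")
  expect_equal(unname(res$report$removed),
               c(1, 1, 1, 1, 1))  # one cell per rule, in order
  expect_equal(unname(res$report$removed_cells),
               c("empty", "no_mito", "low_total", "high_total",
                 "high_mito_fraction"))
  # counts reconcile: removals + kept == input
  expect_equal(sum(res$report$removed) + length(res$report$kept_cells),
               res$report$n_input)
  expect_equal(dim(res$dataset)[1], 1)
})

test_that("droplet boundaries are strict: exactly 300, 10,000, 10% are kept", {
  tx <- rbind(c(30, 270),      # total exactly 300
              c(1000, 9000),   # total exactly 10,000
              c(100, 900))     # exactly 10% mitochondrial
  colnames(tx) <- c("MT-G1", "G1")
  res <- filter_droplets(toy_dataset(tx, mito_cols = 1))
  expect_equal(length(res$report$kept_cells), 3)
})

test_that("droplet filtering is idempotent and permutation-invariant", {
  set.seed(42)
  tx <- cbind(rpois(50, 30), matrix(rpois(150, 400), 50, 3))
  colnames(tx) <- c("MT-G1", "G1", "G2", "G3")
  tx[1:3, ] <- 0                        # empty droplets
  tx[4:5, 1] <- 0                       # no mito
  tx[6, ] <- c(100, 4000, 4000, 4000)   # high mito would not fire; high total?
  ds <- toy_dataset(tx, mito_cols = 1,
                    patients = rep(c("P1", "P2"), each = 25),
                    groups = rep(c("D", "R1"), each = 25))
  once <- filter_droplets(ds)
  twice <- filter_droplets(once$dataset)
  expect_identical(as.matrix(twice$dataset$counts),
                   as.matrix(once$dataset$counts))
  expect_equal(sum(twice$report$removed), 0)

  perm <- sample(nrow(tx))
  res_perm <- filter_droplets(subset_dataset(ds, cells = perm))
  expect_setequal(res_perm$report$kept_cells, once$report$kept_cells)
  expect_equal(res_perm$report$removed, once$report$removed)
})

test_that("per-sample breakdown reconciles with input shapes", {
  set.seed(7)
  tx <- cbind(rpois(60, 40), matrix(rpois(180, 300), 60, 3))
  colnames(tx) <- c("MT-G1", "G1", "G2", "G3")
  tx[c(1, 31), ] <- 0
  ds <- toy_dataset(tx, mito_cols = 1,
                    patients = rep(c("P1", "P2", "P3"), each = 20),
                    groups = rep(c("D", "R1", "R2"), each = 20))
  rep_ <- filter_droplets(ds)$report
  expect_equal(unname(rowSums(rep_$per_sample[, 1:5]) +
                        rep_$per_sample[, "kept"]),
               unname(rep_$per_sample[, "total"]))
  expect_equal(sum(rep_$per_sample[, "total"]), rep_$n_input)
})

test_that("empty input and missing transcripts are handled", {
  tx <- matrix(0, 0, 2, dimnames = list(NULL, c("MT-G1", "G1")))
  adt <- matrix(0, 0, 2, dimnames = list(NULL, c("CD3", "CD19")))
  ds <- toy_dataset(tx, counts_adt = adt, mito_cols = 1,
                    patients = character(0), groups = character(0),
                    batches = character(0))
  res <- filter_droplets(ds)
  expect_equal(dim(res$dataset)[1], 0)
  expect_equal(sum(res$report$removed), 0)

  no_tx <- subset_dataset(six_droplet_dataset(), features = 1:2)
  expect_error(filter_droplets(no_tx), "transcript")
})

test_that("singleton-gene rule removes max-one-per-cell transcripts only", {
  tx <- cbind(c(0, 1, 1, 0),   # never above 1: removed
              c(0, 0, 2, 0),   # a single cell at 2: kept
              c(3, 4, 5, 6))   # kept
  colnames(tx) <- c("G1", "G2", "G3")
  ds <- toy_dataset(tx, mito_cols = integer(0))
  res <- filter_singleton_genes(ds)
  expect_equal(res$removed_genes, "TX-G1")
  expect_equal(sum(res$dataset$features$kind == "transcript"), 2)
  # surface markers untouched
  expect_equal(sum(res$dataset$features$kind == "surface"), 2)

  all_zero <- toy_dataset(matrix(0, 3, 4), mito_cols = integer(0))
  res0 <- filter_singleton_genes(all_zero)
  expect_equal(sum(res0$dataset$features$kind == "transcript"), 0)

  # total-count reading keeps G1 (total 2 despite max-per-cell 1)
  res_tot <- filter_singleton_genes(ds, rule = "total")
  expect_false("TX-G1" %in% res_tot$removed_genes)
  tx2 <- cbind(G1 = c(1L, 0L, 0L, 0L), G2 = c(2L, 3L, 0L, 1L))
  res_tot2 <- filter_singleton_genes(toy_dataset(tx2, mito_cols = integer(0)),
                                     rule = "total")
  expect_equal(res_tot2$removed_genes, "TX-G1")
})

test_that("marker blacklist removes light chains and warns on mismatches", {
  adt <- matrix(2L, 3, 3,
                dimnames = list(NULL, c("CD3", "Igkappa", "Iglambda")))
  tx <- matrix(5L, 3, 2, dimnames = list(NULL, c("MT-G1", "G1")))
  ds <- toy_dataset(tx, counts_adt = adt, mito_cols = 1)
  out <- exclude_markers(ds)
  expect_equal(out$features$feature_name[out$features$kind == "surface"],
               "CD3")
  expect_identical(exclude_markers(ds, character(0)), ds)
  # a transcript name on the blacklist: warning, nothing removed
  expect_warning(out2 <- exclude_markers(ds, "G1"), "not found")
  expect_equal(dim(out2), dim(ds))
})
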
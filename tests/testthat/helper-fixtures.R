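# hand-built fixtures shared across test files

# minimal dataset: explicit counts, 2 surface markers + transcripts
toy_dataset <- function(counts_tx, counts_adt = NULL, mito_cols = 1,
                        patients = NULL, groups = NULL, batches = NULL) {
  n <- nrow(counts_tx)
  if (is.null(counts_adt))
    counts_adt <- matrix(5L, n, 2,
                         dimnames = list(NULL, c("CD3", "CD19")))
  if (is.null(patients)) patients <- rep("P1", n)
  if (is.null(groups)) groups <- rep("D", n)
  if (is.null(batches)) batches <- rep("B1", n)
  n_tx <- ncol(counts_tx)
  tx_names <- colnames(counts_tx)
  if (is.null(tx_names)) tx_names <- paste0("G", seq_len(n_tx))
  is_mito <- seq_len(n_tx) %in% mito_cols
  features <- data.frame(
    feature_id = c(paste0("ADT-", colnames(counts_adt)), paste0("TX-", tx_names)),
    feature_name = c(colnames(counts_adt), tx_names),
    kind = rep(c("surface", "transcript"), c(ncol(counts_adt), n_tx)),
    is_mitochondrial = c(rep(FALSE, ncol(counts_adt)), is_mito))
  cells <- data.frame(cell_id = sprintf("cell%d", seq_len(n)),
                      patient_id = patients, group_id = groups,
                      batch_id = batches)
  new_dataset(cbind(counts_adt, counts_tx), features, cells)
}

# the six-droplet QC example: totals 0 / 400 with no mito / 250 / 12,000 /
# 1,000 at 12% mito / 500 at 5% mito -- only the last survives
six_droplet_dataset <- function() {
  tx <- rbind(
    c(0, 0),        # empty
    c(0, 400),      # no mitochondrial RNA
    c(10, 240),     # total 250 < 300
    c(600, 11400),  # total 12,000 > 10,000
    c(120, 880),    # 12% mitochondrial
    c(25, 475))     # 5% mitochondrial: kept
  colnames(tx) <- c("MT-G1", "G1")
  toy_dataset(tx, mito_cols = 1)
}

# abundance table from a log-abundance matrix (rows = patients)
abund_from_log <- function(la, groups) {
  p <- exp(la)
  p <- p / rowSums(p)
  rownames(p) <- names(groups)
  colnames(p) <- paste0("C", seq_len(ncol(p)))
  structure(p, class = "abundance_table", groups = groups)
}

# brute-force bottleneck: scan all distinct p-values as thresholds and
# return the largest at which the graph (edge iff p >= t) stays connected
bottleneck_bruteforce <- function(P) {
  P <- unclass(P)
  cand <- sort(unique(P[upper.tri(P)]))
  best <- -Inf
  for (t in cand) {
    adj <- (P >= t) * 1
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no == 1) best <- max(best, t)
  }
  best
}

# random symmetric p-value matrix
random_pmatrix <- function(K) {
  P <- matrix(0, K, K)
  P[upper.tri(P)] <- runif(K * (K - 1) / 2)
  P <- P + t(P)
  diag(P) <- 1
  dimnames(P) <- list(paste0("C", 1:K), paste0("C", 1:K))
  P
}
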
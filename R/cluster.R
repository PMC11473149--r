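#' Select the most variable surface markers
#'
#' Ranks markers by a variability score and returns the top `n`. The default
#' score is the per-marker variance of the (harmonized CLR) values; a
#' mean-variance-trend variant (`method = "vst"`) standardizes each marker by
#' the trend-fitted standard deviation at its mean and scores the variance of
#' the standardized, clipped values. Ties are broken lexicographically by
#' marker name so the selection is deterministic.
#'
#' @param matrix cells x markers numeric matrix.
#' @param n number of markers to select (default 30).
#' @param method `"variance"` (default) or `"vst"`.
#' @return Character vector of `n` marker names, ordered by decreasing score.
#' @export
select_variable_markers <- function(matrix, n = 30,
                                    method = c("variance", "vst")) {
  method <- match.arg(method)
  x <- unclass(matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (n > ncol(x))
    stop("asked for ", n, " markers but only ", ncol(x), " present")
  if (method == "variance") {
    score <- apply(x, 2, stats::var)
  } else {
    mu <- colMeans(x)
    v <- apply(x, 2, stats::var)
    pos <- v > 0
    score <- rep(0, ncol(x))
    if (sum(pos) >= 4) {
      fit <- stats::loess(log10(v[pos]) ~ mu[pos], span = 0.75)
      exp_sd <- sqrt(10^stats::predict(fit, mu[pos]))
      z <- sweep(sweep(x[, pos, drop = FALSE], 2, mu[pos]), 2, exp_sd, "/")
      z <- pmin(z, sqrt(nrow(x)))  # clip extreme standardized values
      score[pos] <- apply(z, 2, stats::var)
    } else score[pos] <- v[pos]
  }
  ord <- order(-score, colnames(x))
  colnames(x)[ord[seq_len(n)]]
}

#' PCA scores and 2-D UMAP embedding of cells
#'
#' Runs PCA on the centered and scaled selected markers and embeds the first
#' `n_pca` components in two dimensions with UMAP. Deterministic given the
#' seed (single-threaded UMAP).
#'
#' @param matrix cells x markers numeric matrix (harmonized CLR values).
#' @param markers marker names to use (e.g. from
#'   [select_variable_markers()]); `NULL` uses all columns.
#' @param n_pca number of principal components retained (default 20).
#' @param seed integer seed for the UMAP optimisation.
#' @param n_neighbors UMAP neighbourhood size.
#' @return A list with `pca` (cells x `n_pca` score matrix) and `embedding`
#'   (cells x 2).
#' @export
embed_cells <- function(matrix, markers = NULL, n_pca = 20, seed = 1,
                        n_neighbors = 30) {
  x <- unclass(matrix)
  if (!is.null(markers)) x <- x[, markers, drop = FALSE]
  if (nrow(x) <= n_pca)
    stop("need more cells (", nrow(x), ") than components (", n_pca, ")")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant marker column(s); select variable markers")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  n_pca <- min(n_pca, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pca), drop = FALSE]
  emb <- uwot::umap(scores, n_neighbors = min(n_neighbors, nrow(x) - 1),
                    n_threads = 1, n_sgd_threads = 0, seed = seed,
                    verbose = FALSE)
  rownames(emb) <- rownames(x)
  list(pca = scores, embedding = emb,
       sdev = pc$sdev, params = list(n_pca = n_pca, seed = seed))
}

#' Louvain clustering on a kNN graph
#'
#' Builds an undirected k-nearest-neighbour graph on the supplied coordinates
#' (the 2-D embedding by default in this pipeline; PCA scores work equally)
#' and partitions it with Louvain modularity optimisation at the given
#' resolution.
#'
#' @param coords cells x d numeric matrix.
#' @param resolution Louvain resolution (default 0.4).
#' @param k_neighbors neighbours per cell in the kNN graph (default 30).
#' @param seed integer seed (Louvain's node sweep is randomised).
#' @return A `cluster_assignment`: integer vector of cluster labels in
#'   `1..K`, with attributes `K` and `params`.
#' @export
cluster_cells <- function(coords, resolution = 0.4, k_neighbors = 30,
                          seed = 1) {
  n <- nrow(coords)
  if (k_neighbors >= n)
    stop("k_neighbors (", k_neighbors, ") must be below the cell count (", n, ")")
  nn <- FNN::get.knn(coords, k = k_neighbors)$nn.index
  edges <- cbind(rep(seq_len(n), k_neighbors), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  names(labels) <- rownames(coords)
  structure(labels, class = "cluster_assignment",
            K = length(unique(labels)),
            params = list(resolution = resolution, k_neighbors = k_neighbors,
                          seed = seed))
}

#' Per-patient cluster abundance table
#'
#' Cluster abundance in a patient is the number of the patient's cells in
#' the cluster divided by the patient's total cell count, so each row is a
#' point on the simplex. Clusters with zero cells in a patient get
#' proportion 0; zero handling for ratio tests is the test's concern.
#'
#' @param assignment per-cell cluster labels (integer vector or
#'   `cluster_assignment`).
#' @param cells per-cell metadata with `patient_id` and `group_id`, aligned
#'   to `assignment`.
#' @return An `abundance_table`: patients x clusters proportion matrix with
#'   attributes `counts` (the companion count matrix) and `groups`
#'   (patient to group map).
#' @export
abundance_table <- function(assignment, cells) {
  labels <- as.integer(assignment)
  K <- max(attr(assignment, "K"), labels, 1)
  tab <- table(factor(cells$patient_id),
               factor(labels, levels = seq_len(K)))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = list(rownames(tab), paste0("C", colnames(tab))))
  prop <- counts / rowSums(counts)
  pg <- unique(cells[, c("patient_id", "group_id")])
  groups <- stats::setNames(as.character(pg$group_id),
                            as.character(pg$patient_id))[rownames(prop)]
  names(groups) <- rownames(prop)
  structure(prop, class = "abundance_table", counts = counts, groups = groups)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x), "patients x", ncol(x), "clusters\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Rank markers by within-cluster differential expression
#'
#' Per cluster, scores each marker as its mean inside the cluster minus its
#' mean over all other cells, and reports the `n_top` highest (more
#' expressed) and lowest (less expressed) markers; the standard summary used
#' for cluster annotation. Ties break lexicographically by marker name.
#'
#' @param matrix cells x markers numeric matrix (harmonized CLR values).
#' @param assignment per-cell cluster labels aligned to rows.
#' @param n_top markers listed per direction (default 10).
#' @return Named list, one element per cluster, each with `up` and `down`
#'   named score vectors.
#' @export
annotate_clusters <- function(matrix, assignment, n_top = 10) {
  x <- unclass(matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (n_top > ncol(x)) {
    warning("n_top exceeds marker count; truncating to ", ncol(x))
    n_top <- ncol(x)
  }
  labels <- as.integer(assignment)
  out <- list()
  for (k in sort(unique(labels))) {
    inside <- labels == k
    score <- colMeans(x[inside, , drop = FALSE])
    if (any(!inside)) score <- score - colMeans(x[!inside, , drop = FALSE])
    ord <- order(-score, colnames(x))
    out[[paste0("C", k)]] <- list(
      up = score[ord[seq_len(n_top)]],
      down = score[rev(ord)[seq_len(n_top)]])
  }
  out
}

#' Stratify recipients by subset abundances
#'
#' PCA on the patients x subsets matrix keeping the smallest leading set of
#' components whose cumulative explained variance reaches `var_explained`
#' (default 60%), then hierarchical clustering (Ward) on the retained
#' scores cut at `n_groups`, consolidated by k-means initialised at the
#' hierarchical centroids.
#'
#' @param subset_abundances patients x subsets numeric matrix.
#' @param n_groups number of strata (default 2).
#' @param var_explained cumulative explained-variance cutoff in (0, 1].
#' @param seed integer seed (k-means consolidation).
#' @param scale. scale columns to unit variance before PCA.
#' @return Named integer vector of stratum labels (`1..n_groups`), with an
#'   attribute `n_components` giving the number of retained components.
#' @export
stratify_recipients <- function(subset_abundances, n_groups = 2,
                                var_explained = 0.60, seed = 1,
                                scale. = TRUE) {
  x <- as.matrix(subset_abundances)
  if (nrow(x) < n_groups)
    stop("fewer patients (", nrow(x), ") than strata (", n_groups, ")")
  sds <- apply(x, 2, stats::sd)
  if (scale. && any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- which(cum >= var_explained)[1]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  init <- stats::cutree(hc, k = n_groups)
  centroids <- rowsum(scores, init) / as.vector(table(init))
  set.seed(seed)
  km <- stats::kmeans(scores, centers = centroids)
  structure(stats::setNames(km$cluster, rownames(x)), n_components = m)
}
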
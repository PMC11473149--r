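#' Gate patient groups per cluster before transcriptome analysis
#'
#' To limit cell-misclassification noise, any patient group holding less
#' than `min_group_fraction` (default 10%) of a cluster's cells is excluded
#' from that cluster's transcriptomic analysis; the boundary is strict, so a
#' group at exactly 10% is retained. Whether at least 100 cells remain is
#' recorded as an advisory flag (enough cells for a differential fit), not a
#' hard filter.
#'
#' @param assignment per-cell cluster labels.
#' @param cells per-cell metadata with `group_id`, aligned to `assignment`.
#' @param min_group_fraction exclusion boundary (default 0.10).
#' @return A `cluster_gate`: named list per cluster with `retained` group
#'   labels, `counts` and `fractions` per group, `min_retained_cells` and
#'   the advisory `enough_cells` flag (>100 retained cells).
#' @export
gate_groups <- function(assignment, cells, min_group_fraction = 0.10) {
  labels <- as.integer(assignment)
  out <- list()
  for (k in sort(unique(labels))) {
    grp <- cells$group_id[labels == k]
    counts <- table(grp)
    fractions <- counts / sum(counts)
    retained <- names(fractions)[fractions >= min_group_fraction]
    retained <- retained[counts[retained] > 0]
    out[[paste0("C", k)]] <- list(
      retained = retained,
      counts = stats::setNames(as.vector(counts), names(counts)),
      fractions = stats::setNames(as.vector(fractions), names(fractions)),
      min_retained_cells = if (length(retained))
        min(counts[retained]) else 0L,
      enough_cells = sum(counts[retained]) > 100)
  }
  structure(out, class = "cluster_gate",
            min_group_fraction = min_group_fraction)
}

#' Partition a cluster's genes by detecting groups
#'
#' Per cluster: genes with no transcript detected in any of the cluster's
#' cells are set aside as the cluster's absent-gene list (kept when the gene
#' is present in at least one other cluster; it helps consolidate the
#' cluster's identity). Every remaining gene is assigned to the subset
#' matching the number of retained patient groups (after [gate_groups()])
#' with at least one expressing cell in the cluster.
#'
#' @param counts cells x genes transcript count matrix (post-QC).
#' @param assignment per-cell cluster labels aligned to rows.
#' @param gate a `cluster_gate` from [gate_groups()].
#' @param cells per-cell metadata with `group_id`.
#' @return A `gene_partition`: per cluster, `absent` (gene names) and
#'   `by_groups`, a list mapping the number of expressing retained groups
#'   ("1", "2", ...) to gene-name vectors. The absent list and the subsets
#'   partition the cluster's gene universe.
#' @export
partition_genes <- function(counts, assignment, gate, cells) {
  x <- counts
  genes <- colnames(x)
  labels <- as.integer(assignment)
  # which clusters express each gene at all (for the "present elsewhere" note)
  expressed_any <- rowsum(as.matrix(x > 0) * 1, labels) > 0
  out <- list()
  for (k in sort(unique(labels))) {
    key <- paste0("C", k)
    gk <- gate[[key]]
    if (is.null(gk) || !length(gk$retained)) {
      warning("cluster ", key, " has no retained groups; skipped")
      next
    }
    in_k <- labels == k
    absent <- genes[!expressed_any[as.character(k), ]]
    elsewhere <- colSums(expressed_any) -
      expressed_any[as.character(k), , drop = TRUE]
    absent_elsewhere <- genes[!expressed_any[as.character(k), ] & elsewhere > 0]
    present <- setdiff(genes, absent)
    n_expr <- rep(0L, length(present))
    for (g in gk$retained) {
      sel <- in_k & cells$group_id == g
      if (any(sel))
        n_expr <- n_expr +
          (Matrix::colSums(x[sel, present, drop = FALSE] > 0) > 0)
    }
    by_groups <- split(present, n_expr)
    out[[key]] <- list(absent = absent,
                       absent_present_elsewhere = absent_elsewhere,
                       by_groups = by_groups)
  }
  structure(out, class = "gene_partition")
}

#' Repertoire diversity summaries
#'
#' `shannon_index` computes the Shannon diversity `H = -sum p_i log(p_i)`
#' over clonotypes with positive counts (natural log by default);
#' `clonotype_count` counts the clonotypes with positive counts. Together
#' they summarise the frequency and diversity of a B cell receptor
#' repertoire.
#'
#' @param clonotype_counts non-negative counts, at least one positive.
#' @param base logarithm base (default `exp(1)`, the ecology convention).
#' @return `shannon_index`: a scalar; `clonotype_count`: an integer.
#' @export
shannon_index <- function(clonotype_counts, base = exp(1)) {
  x <- clonotype_counts
  if (any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("all clonotype counts are zero")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' @rdname shannon_index
#' @export
clonotype_count <- function(clonotype_counts) {
  if (any(clonotype_counts < 0)) stop("counts must be non-negative")
  if (sum(clonotype_counts) == 0) stop("all clonotype counts are zero")
  sum(clonotype_counts > 0)
}

#' Read a clonotype count table
#'
#' Two-column delimited text (`clonotype_id`, `count`) as produced by
#' repertoire assembly tools.
#'
#' @param path file path.
#' @return Named integer vector of counts.
#' @export
read_clonotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("clonotype_id", "count") %in% names(df)))
    stop("clonotype table needs columns clonotype_id, count")
  stats::setNames(as.integer(df$count), df$clonotype_id)
}

#' Write gates or gene partitions as JSON
#'
#' @param x a `cluster_gate` or `gene_partition`.
#' @param path output file.
#' @export
write_gate_json <- function(x, path) {
  jsonlite::write_json(lapply(unclass(x), function(e)
    lapply(e, function(v) if (is.table(v)) as.list(v) else v)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
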
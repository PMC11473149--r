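#' Droplet quality-control filter
#'
#' Applies, separately for each sample (patient), the five droplet rules, in
#' this order with first-match attribution:
#' \enumerate{
#'   \item total transcript count 0 (empty droplet);
#'   \item no mitochondrial transcripts;
#'   \item total transcript count below `min_total` (default 300);
#'   \item total transcript count above `max_total` (default 10,000; two or
#'     more cells);
#'   \item mitochondrial fraction above `max_mito_fraction` (default 10%;
#'     dead cells).
#' }
#' All rules are evaluated on transcript counts only; surface-marker counts
#' never influence filtering. Boundaries are strict as printed: a droplet at
#' exactly 300, 10,000 or 10% is kept.
#'
#' @param dataset a `citeseq_dataset` with transcript features.
#' @param config a [run_config()] supplying the thresholds.
#' @return A list with `dataset` (the filtered `citeseq_dataset`) and
#'   `report`, a `qc_report`: per-rule removal counts, kept cell ids, and a
#'   per-sample breakdown reconciling exactly with the input cell count.
#' @export
filter_droplets <- function(dataset, config = run_config()) {
  is_tx <- dataset$features$kind == "transcript"
  if (!any(is_tx)) stop("no transcript features present; cannot QC droplets")
  tx <- dataset$counts[, is_tx, drop = FALSE]
  mito <- dataset$counts[, is_tx & dataset$features$is_mitochondrial,
                         drop = FALSE]
  total <- Matrix::rowSums(tx)
  mito_total <- Matrix::rowSums(mito)
  frac <- ifelse(total > 0, mito_total / total, 0)

  rule <- rep(NA_character_, length(total))
  rule[is.na(rule) & total == 0] <- "empty"
  rule[is.na(rule) & mito_total == 0] <- "no_mito"
  rule[is.na(rule) & total < config$min_total] <- "low_total"
  rule[is.na(rule) & total > config$max_total] <- "high_total"
  rule[is.na(rule) & frac > config$max_mito_fraction] <- "high_mito_fraction"

  rules <- c("empty", "no_mito", "low_total", "high_total",
             "high_mito_fraction")
  keep <- is.na(rule)
  per_sample <- do.call(rbind, lapply(split(rule, dataset$cells$patient_id),
    function(r) {
      counts <- table(factor(r, levels = rules))
      c(as.vector(counts), kept = sum(is.na(r)), total = length(r))
    }))
  if (length(rule)) colnames(per_sample)[seq_along(rules)] <- rules

  report <- structure(list(
    removed = stats::setNames(as.vector(table(factor(rule, levels = rules))),
                              rules),
    kept_cells = dataset$cells$cell_id[keep],
    removed_cells = stats::setNames(rule[!keep],
                                    dataset$cells$cell_id[!keep]),
    per_sample = per_sample,
    n_input = length(rule),
    thresholds = list(min_total = config$min_total,
                      max_total = config$max_total,
                      max_mito_fraction = config$max_mito_fraction)),
    class = "qc_report")
  list(dataset = subset_dataset(dataset, cells = which(keep)),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("droplet QC:", x$n_input, "cells in,", length(x$kept_cells), "kept\n")
  for (r in names(x$removed))
    cat(sprintf("  %-20s %d\n", r, x$removed[[r]]))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [filter_droplets()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(list(
    n_input = report$n_input,
    n_kept = length(report$kept_cells),
    removed = as.list(report$removed),
    thresholds = report$thresholds,
    per_sample = as.data.frame(report$per_sample)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Remove genes never seen more than once in any cell
#'
#' Applied after samples are merged: drops every transcript feature whose
#' count is at most 1 in every cell. Surface markers are untouched. The
#' alternative reading (total count over all cells at most 1) is available
#' via `rule = "total"`.
#'
#' @param dataset a `citeseq_dataset`.
#' @param rule `"max_per_cell"` (default) or `"total"`.
#' @return A list with `dataset` (filtered) and `removed_genes` (feature ids).
#' @export
filter_singleton_genes <- function(dataset, rule = c("max_per_cell", "total")) {
  rule <- match.arg(rule)
  is_tx <- dataset$features$kind == "transcript"
  tx <- dataset$counts[, is_tx, drop = FALSE]
  stat <- if (rule == "max_per_cell") {
    if (nrow(tx) == 0) rep(0, ncol(tx))
    else apply(as.matrix(tx), 2, max)
  } else Matrix::colSums(tx)
  drop_tx <- stat <= 1
  drop_ids <- dataset$features$feature_id[is_tx][drop_tx]
  keep <- !(dataset$features$feature_id %in% drop_ids)
  list(dataset = subset_dataset(dataset, features = which(keep)),
       removed_genes = drop_ids)
}

#' Drop blacklisted surface markers
#'
#' Removes the listed surface features (by feature name); by default the
#' immunoglobulin light chains, whose staining is non-specific. Names absent
#' from the dataset, or naming transcript features, are ignored with a
#' warning.
#'
#' @param dataset a `citeseq_dataset`.
#' @param blacklist character vector of surface feature names.
#' @return The filtered `citeseq_dataset`.
#' @export
exclude_markers <- function(dataset, blacklist = c("Igkappa", "Iglambda")) {
  if (!length(blacklist)) return(dataset)
  is_surface <- dataset$features$kind == "surface"
  hit <- dataset$features$feature_name %in% blacklist & is_surface
  missing <- setdiff(blacklist, dataset$features$feature_name[is_surface])
  if (length(missing))
    warning("blacklisted name(s) not found among surface markers: ",
            paste(missing, collapse = ", "))
  if (!any(hit)) return(dataset)
  subset_dataset(dataset, features = which(!hit))
}
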
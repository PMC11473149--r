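#' Pipeline configuration with published defaults
#'
#' Collects every tunable threshold of the pipeline. Defaults are the values
#' used in the source study: droplet total-count window 300--10,000 with a 10%
#' mitochondrial-fraction cap, CLR zero replacement 0.5 (half the
#' quantification limit of 1 count), 30 variable markers, 20 PCA components,
#' Louvain resolution 0.4, 10% minimum group share per cluster, and a
#' 10,000-simulation calibration at alpha = 5% for a 41-node graph with
#' recipient group sizes 7 and 3.
#'
#' @param min_total minimum transcript total per droplet (droplets strictly
#'   below are removed).
#' @param max_total maximum transcript total per droplet (strictly above
#'   removed; presumed doublets).
#' @param max_mito_fraction maximum mitochondrial share of transcript counts
#'   (strictly above removed; presumed dead cells).
#' @param zero_replacement value substituted for zero marker counts before the
#'   CLR transform.
#' @param n_variable_markers number of variable surface markers kept for PCA.
#' @param n_pca_components number of principal components fed to UMAP.
#' @param louvain_resolution resolution of Louvain community detection.
#' @param k_neighbors neighbourhood size of the kNN graph used for clustering.
#' @param min_group_fraction minimum share of a cluster's cells a patient
#'   group must hold to enter the transcriptome gating.
#' @param marker_blacklist surface marker names excluded from analysis
#'   (immunoglobulin light chains with non-specific binding).
#' @param mito_prefix feature-name prefix identifying mitochondrial genes.
#' @param batch_first if `TRUE`, batch correction is applied before patient
#'   correction in [harmonize()].
#' @param calibration list with `n_nodes`, `n1`, `n2`, `n_sims`, `alpha`,
#'   `seed` for [calibrate_threshold()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_total = 300,
                       max_total = 10000,
                       max_mito_fraction = 0.10,
                       zero_replacement = 0.5,
                       n_variable_markers = 30,
                       n_pca_components = 20,
                       louvain_resolution = 0.4,
                       k_neighbors = 30,
                       min_group_fraction = 0.10,
                       marker_blacklist = c("Igkappa", "Iglambda"),
                       mito_prefix = "MT-",
                       batch_first = TRUE,
                       calibration = list(n_nodes = 41, n1 = 7, n2 = 3,
                                          n_sims = 10000, alpha = 0.05,
                                          seed = 1)) {
  cfg <- list(min_total = min_total, max_total = max_total,
              max_mito_fraction = max_mito_fraction,
              zero_replacement = zero_replacement,
              n_variable_markers = n_variable_markers,
              n_pca_components = n_pca_components,
              louvain_resolution = louvain_resolution,
              k_neighbors = k_neighbors,
              min_group_fraction = min_group_fraction,
              marker_blacklist = marker_blacklist,
              mito_prefix = mito_prefix,
              batch_first = batch_first,
              calibration = calibration)
  num <- c(cfg$min_total, cfg$max_total, cfg$max_mito_fraction,
           cfg$zero_replacement, cfg$calibration$alpha)
  if (!all(is.finite(num))) stop("config thresholds must be finite")
  if (cfg$calibration$alpha <= 0 || cfg$calibration$alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (cfg$calibration$n_sims < 1) stop("n_sims must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
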
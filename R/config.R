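#' Pipeline configuration
#'
#' Houses every numeric constant of the analysis so no magic numbers live in
#' code. Defaults are the study conditions: a genome-wide 2-LOD call
#' threshold, a 10 cM cis window, 5.5 cM cross-phenotype merging, 10 cM / 1 cM
#' sliding windows with the 95th percentile of 1,000 position permutations as
#' the hotspot threshold, k = 10 variance-profile clusters, a 10 cM paralog
#' window and a 5 cM hotspot-membership window.
#'
#' @param lod_threshold minimum LOD for calling an eQTL peak.
#' @param cis_window_cM max distance (cM, same chromosome, inclusive) between
#'   a peak and its gene for a cis label.
#' @param merge_window_cM single-linkage distance for collapsing eQTL of one
#'   transcript across expression phenotypes.
#' @param hotspot_window_cM sliding-window width for trans-eQTL density.
#' @param hotspot_step_cM sliding-window step.
#' @param n_permutations position permutations for the hotspot threshold.
#' @param permutation_percentile percentile (0-100) of pooled permuted window
#'   counts used as the global hotspot threshold.
#' @param kmeans_k number of variance-profile clusters.
#' @param paralog_window_cM window for flagging a paralog at a trans-eQTL.
#' @param hotspot_membership_window_cM distance to a named hotspot region for
#'   the membership flag.
#' @param min_peak_separation_cM greedy suppression radius between retained
#'   peaks on one chromosome (default 2 x merge window = 11 cM).
#' @param lod_cap cap applied when the residual sum of squares underflows.
#' @param delta_floor denominator floor below which the plasticity ratio is
#'   set missing.
#' @param log_expression whether readers log2-transform abundances (off:
#'   inputs are treated as already-normalized estimates).
#' @param genotype_codes named character vector aliasing on-disk genotype
#'   codes to `A`/`B`.
#' @param seed master random seed; stages derive their own seeds from it.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(lod_threshold = 2,
                            cis_window_cM = 10,
                            merge_window_cM = 5.5,
                            hotspot_window_cM = 10,
                            hotspot_step_cM = 1,
                            n_permutations = 1000,
                            permutation_percentile = 95,
                            kmeans_k = 10,
                            paralog_window_cM = 10,
                            hotspot_membership_window_cM = 5,
                            min_peak_separation_cM = 2 * merge_window_cM,
                            lod_cap = 50,
                            delta_floor = 1e-8,
                            log_expression = FALSE,
                            genotype_codes = c(A = "A", B = "B"),
                            seed = 1) {
  cfg <- list(lod_threshold = lod_threshold,
              cis_window_cM = cis_window_cM,
              merge_window_cM = merge_window_cM,
              hotspot_window_cM = hotspot_window_cM,
              hotspot_step_cM = hotspot_step_cM,
              n_permutations = n_permutations,
              permutation_percentile = permutation_percentile,
              kmeans_k = kmeans_k,
              paralog_window_cM = paralog_window_cM,
              hotspot_membership_window_cM = hotspot_membership_window_cM,
              min_peak_separation_cM = min_peak_separation_cM,
              lod_cap = lod_cap,
              delta_floor = delta_floor,
              log_expression = log_expression,
              genotype_codes = genotype_codes,
              seed = seed)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  num_keys <- c("lod_threshold", "cis_window_cM", "merge_window_cM",
                "hotspot_window_cM", "hotspot_step_cM", "n_permutations",
                "permutation_percentile", "kmeans_k", "paralog_window_cM",
                "hotspot_membership_window_cM", "min_peak_separation_cM",
                "lod_cap", "delta_floor", "seed")
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop("config key '", k, "' must be a single number, got: ",
           deparse(cfg[[k]]))
    }
  }
  windows <- c("cis_window_cM", "merge_window_cM", "hotspot_window_cM",
               "hotspot_step_cM", "paralog_window_cM",
               "hotspot_membership_window_cM", "min_peak_separation_cM")
  for (k in windows) {
    if (cfg[[k]] <= 0) stop("config key '", k, "' must be > 0")
  }
  if (cfg$permutation_percentile <= 0 || cfg$permutation_percentile >= 100) {
    stop("permutation_percentile must lie in (0, 100)")
  }
  if (cfg$lod_threshold <= 0) stop("lod_threshold must be > 0")
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  if (!is.logical(cfg$log_expression) || length(cfg$log_expression) != 1) {
    stop("config key 'log_expression' must be a single logical")
  }
  if (!is.character(cfg$genotype_codes) ||
      !all(c("A", "B") %in% names(cfg$genotype_codes))) {
    stop("genotype_codes must be a character vector with names 'A' and 'B'")
  }
  invisible(cfg)
}

#' Load and validate a YAML pipeline configuration
#'
#' Missing keys take the [pipeline_config()] defaults; unknown keys are
#' rejected. An empty file yields the full default configuration. A
#' `simulation:` section, when present, is passed through unvalidated to
#' [plant_architecture()] / [run_pipeline()].
#'
#' @param path YAML file.
#' @return a `pipeline_config` (with an optional `simulation` element).
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a YAML mapping")
  sim <- raw$simulation
  raw$simulation <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$genotype_codes)) {
    raw$genotype_codes <- unlist(raw$genotype_codes)
  }
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(sim)) cfg$simulation <- sim
  cfg
}

# per-stage seed derived stably from the master seed and the stage name,
# kept below 2^31 so it is a valid R integer
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
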
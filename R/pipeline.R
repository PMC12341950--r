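#' Label merged eQTL cis/trans from consensus positions
#'
#' Applies [classify_cis_trans()] to a merged-eQTL table, comparing each
#' consensus position against the transcript's gene position so the label is
#' a property of the merged locus, not of any single member record.
#'
#' @param merged the `merged` table from [merge_across_phenotypes()].
#' @param gene_positions data.frame `transcript`, `chromosome`, `pos_cM`.
#' @param window cis window (cM).
#' @return `merged` with a `cis_trans` column.
#' @export
classify_merged <- function(merged, gene_positions, window = 10) {
  tmp <- data.frame(transcript = merged$transcript,
                    chromosome = merged$chromosome,
                    pos_cM = merged$consensus_cM, stringsAsFactors = FALSE)
  merged$cis_trans <- classify_cis_trans(tmp, gene_positions,
                                         window = window)$cis_trans
  merged
}

#' Match detections against a planted architecture
#'
#' A planted effect counts as recovered when a merged eQTL of its transcript
#' sits on the same chromosome within `tol_cM` of the planted locus and its
#' membership intersects the effect's expected phenotypes (control when the
#' baseline component is nonzero, SA when baseline + interaction is nonzero,
#' delta when the interaction is nonzero).
#'
#' @param merged classified merged-eQTL table.
#' @param architecture the [plant_architecture()] ground truth.
#' @param tol_cM matching radius.
#' @return list: `effects` (ground truth with `detected`, `matched_label`)
#'   and `summary` (detection_rate, cis_label_accuracy,
#'   trans_prop_planted, trans_prop_recovered).
#' @export
recovery_summary <- function(merged, architecture, tol_cM = 5) {
  eff <- architecture$effects
  eff$detected <- logical(nrow(eff))
  eff$matched_label <- rep(NA_character_, nrow(eff))
  if (nrow(eff) > 0) {
    for (i in seq_len(nrow(eff))) {
      expected <- c("control", "SA", "delta")[
        c(abs(eff$baseline_effect[i]) > 0,
          abs(eff$baseline_effect[i] + eff$interaction_effect[i]) > 0,
          abs(eff$interaction_effect[i]) > 0)]
      m <- merged[merged$transcript == eff$transcript[i] &
                    merged$chromosome == eff$chromosome[i] &
                    abs(merged$consensus_cM - eff$pos_cM[i]) <= tol_cM, ,
                  drop = FALSE]
      if (nrow(m) > 0) {
        hit <- vapply(strsplit(m$membership, ","),
                      function(s) length(intersect(s, expected)) > 0,
                      logical(1))
        if (any(hit)) {
          m <- m[hit, , drop = FALSE]
          best <- which.min(abs(m$consensus_cM - eff$pos_cM[i]))
          eff$detected[i] <- TRUE
          eff$matched_label[i] <- m$cis_trans[best]
        }
      }
    }
  }
  det <- eff[eff$detected, , drop = FALSE]
  cis_det <- det[det$type == "cis", , drop = FALSE]
  list(effects = eff,
       summary = c(
         detection_rate = if (nrow(eff) > 0) mean(eff$detected) else NA_real_,
         cis_label_accuracy = if (nrow(cis_det) > 0)
           mean(cis_det$matched_label == "cis") else NA_real_,
         trans_prop_planted = if (nrow(eff) > 0)
           mean(eff$type == "trans") else NA_real_,
         trans_prop_recovered = if (nrow(det) > 0)
           mean(det$matched_label == "trans") else NA_real_))
}

sim_section_defaults <- function() {
  list(n_lines = 210,
       chromosome_lengths = c(100, 70, 80, 80, 100),
       marker_spacing = 2,
       n_transcripts = 300,
       n_replicates = 2,
       include_parents = TRUE,
       architecture = list())
}

#' Run the full eQTL pipeline
#'
#' Orchestrates simulate (or load) -> variance -> phenotypes -> scan ->
#' classify -> hotspot -> report. Each stage draws its own seed derived
#' stably from the master seed and the stage name, so a stage re-run in
#' isolation reproduces its in-pipeline result; identical config and inputs
#' give identical outputs.
#'
#' @param config a [pipeline_config()], optionally carrying a `simulation`
#'   list (see `validate_config()`; defaults emulate the study population:
#'   210 F8 RILs, 5 chromosomes of 100/70/80/80/100 cM, two treatments, two
#'   replicates) or a `paths` list for real data (`map`, `genotypes`,
#'   `expression`, `metadata`, `genes`, `anchors`, optionally `paralogs`).
#' @param out_dir optional directory for TSV outputs and the run manifest.
#' @return list of class `plastiqtl_run`: all stage outputs (`map`,
#'   `genotypes`, `architecture`, `dataset`, `variance`, `phenotypes`,
#'   `eqtl_records`, `merged`, `hotspots`, `report`) plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_pipeline_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  simulate_mode <- is.null(config$paths)
  input_hashes <- NULL

  if (simulate_mode) {
    sim <- merge_settings(sim_section_defaults(),
                          if (is.null(config$simulation)) list()
                          else config$simulation)
    map <- make_map(unlist(sim$chromosome_lengths), sim$marker_spacing)
    genotypes <- simulate_ril_genotypes(
      map, sim$n_lines, seed = stage_seed(config$seed, "genotypes"))
    architecture <- plant_architecture(
      map, sim$n_transcripts, config = sim$architecture,
      seed = stage_seed(config$seed, "architecture"))
    dataset <- simulate_expression(
      genotypes, architecture, n_replicates = sim$n_replicates,
      include_parents = sim$include_parents,
      seed = stage_seed(config$seed, "expression"))
    gene_positions <- architecture$transcripts
    paralogs <- NULL
    parent_ids <- if (sim$include_parents) c("Bay-0", "Sha") else NULL
  } else {
    p <- config$paths
    input_hashes <- tools::md5sum(unlist(p[!vapply(p, is.null,
                                                   logical(1))]))
    map <- read_genetic_map(p$map)
    genotypes <- read_genotypes(p$genotypes, map,
                                codes = config$genotype_codes)
    dataset <- read_expression(p$expression, p$metadata)
    genes <- read_gene_positions(p$genes)
    if (!is.null(genes$pos_cM) && !anyNA(genes$pos_cM)) {
      gene_positions <- genes
    } else {
      anchors <- utils::read.delim(p$anchors, stringsAsFactors = FALSE)
      gene_positions <- interpolate_gene_positions(genes, anchors)
    }
    paralogs <- if (!is.null(p$paralogs)) read_paralogs(p$paralogs) else NULL
    architecture <- NULL
    parent_ids <- config$parent_ids
  }
  if (isTRUE(config$log_expression)) {
    dataset$values <- log2(dataset$values + 1)
  }
  tick("inputs")

  ril_ids <- rownames(genotypes)
  variance <- withCallingHandlers(
    decompose_variance(dataset, genotypes = intersect(
      unique(dataset$meta$genotype), ril_ids)),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  clusters <- NULL
  if (sum(!variance$degenerate) >= config$kmeans_k) {
    clusters <- cluster_variance_profiles(
      variance, k = config$kmeans_k,
      seed = stage_seed(config$seed, "kmeans"))
  }
  variance_parents <- NULL
  if (!is.null(parent_ids) &&
      all(parent_ids %in% dataset$meta$genotype)) {
    variance_parents <- withCallingHandlers(
      decompose_variance(dataset, genotypes = parent_ids),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
  }
  tick("variance")

  phenotypes <- phenotype_set(dataset, delta_floor = config$delta_floor)
  transgression <- NULL
  if (!is.null(parent_ids) &&
      all(parent_ids %in% rownames(phenotypes$control))) {
    transgression <- transgression_summary(phenotypes, parent_ids)
  }
  pca <- tryCatch(pca_transcriptomes(phenotypes$control, n_components = 5),
                  error = function(e) NULL)
  tick("phenotypes")

  prob <- genotype_probabilities(genotypes, map)
  records <- suppressMessages(scan_all(prob, phenotypes, map, config))
  tick("scan")

  mg <- merge_across_phenotypes(records, window = config$merge_window_cM)
  merged <- classify_merged(mg$merged, gene_positions,
                            window = config$cis_window_cM)
  merged <- effect_size(merged, prob, phenotypes, map)
  merged <- annotate_paralogs(
    merged, paralogs = paralogs, hotspot_regions = NULL,
    paralog_window_cM = config$paralog_window_cM,
    membership_window_cM = config$hotspot_membership_window_cM)
  tick("classify")

  hotspots <- NULL
  if (nrow(merged) > 0) {
    hotspots <- hotspot_profiles(merged, map, config,
                                 seed = stage_seed(config$seed, "hotspot"))
    regions <- do.call(rbind, lapply(names(hotspots), function(ph) {
      iv <- hotspots[[ph]]$intervals
      if (nrow(iv) == 0) return(NULL)
      data.frame(chromosome = iv$chromosome, start_cM = iv$start_cM,
                 end_cM = iv$end_cM, stringsAsFactors = FALSE)
    }))
    if (!is.null(regions) && nrow(regions) > 0) {
      merged <- annotate_paralogs(
        merged[, setdiff(names(merged),
                         c("paralog_flag", "n_paralogs", "hotspot_flag"))],
        paralogs = paralogs, hotspot_regions = regions,
        paralog_window_cM = config$paralog_window_cM,
        membership_window_cM = config$hotspot_membership_window_cM)
    }
  }
  tick("hotspot")

  report <- build_report(records, merged, hotspots, transgression,
                         variance, variance_parents, architecture)
  tick("report")

  manifest <- list(config = unclass(config)[setdiff(names(config),
                                                    c("simulation", "paths"))],
                   simulate_mode = simulate_mode,
                   seed = config$seed,
                   stage_seeds = vapply(
                     c("genotypes", "architecture", "expression", "kmeans",
                       "hotspot"),
                     function(s) stage_seed(config$seed, s), numeric(1)),
                   input_hashes = input_hashes,
                   timings_s = timings,
                   warnings = warnings_log,
                   outputs = character())
  run <- structure(list(map = map, genotypes = genotypes,
                        architecture = architecture, dataset = dataset,
                        variance = variance,
                        variance_parents = variance_parents,
                        variance_clusters = clusters,
                        phenotypes = phenotypes, pca = pca,
                        transgression = transgression,
                        eqtl_records = records, merged = merged,
                        hotspots = hotspots, report = report,
                        manifest = manifest),
                   class = "plastiqtl_run")
  if (!is.null(out_dir)) {
    run$manifest$outputs <- write_run_outputs(run, out_dir)
  }
  run
}

build_report <- function(records, merged, hotspots, transgression,
                         variance, variance_parents, architecture) {
  report <- list()
  report$n_records_per_phenotype <-
    if (nrow(records) > 0) table(records$phenotype) else
      table(factor(character(), levels = c("control", "SA", "delta")))
  if (nrow(merged) > 0) {
    cs <- summarize_cis_trans(merged)
    report$cis_trans <- cs$per_phenotype
    report$membership <- cs$per_membership
    report$per_transcript <- cs$per_transcript
    if ("r2_mean" %in% names(merged) && any(merged$paralog_flag)) {
      q <- stats::quantile(merged$r2_mean, c(0.25, 0.5, 0.75), na.rm = TRUE)
      quart <- cut(merged$r2_mean, breaks = c(-Inf, q, Inf),
                   labels = c("Q1", "Q2", "Q3", "Q4"))
      report$paralog_by_effect_quartile <-
        table(quartile = quart, paralog = merged$paralog_flag)
    }
  }
  if (!is.null(hotspots)) {
    report$hotspot_intervals <- do.call(rbind, lapply(
      names(hotspots), function(ph) {
        iv <- hotspots[[ph]]$intervals
        if (nrow(iv) == 0) return(NULL)
        cbind(phenotype = ph, iv, stringsAsFactors = FALSE)
      }))
    report$hotspot_thresholds <- vapply(hotspots, `[[`, numeric(1),
                                        "threshold")
  }
  if (!is.null(transgression)) {
    report$mean_transgression <- tapply(transgression$fraction_outside,
                                        transgression$phenotype, mean,
                                        na.rm = TRUE)
  }
  report$variance_means <- summarize_variance(variance)
  if (!is.null(variance_parents)) {
    report$variance_means_parents <- summarize_variance(variance_parents)
  }
  if (!is.null(architecture) && nrow(merged) > 0) {
    report$recovery <- recovery_summary(merged, architecture)$summary
  }
  report
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(df, name, num_cols = NULL) {
    p <- file.path(out_dir, name)
    if (!is.null(num_cols)) {
      num_cols <- intersect(num_cols, names(df))
      df[num_cols] <- lapply(df[num_cols], fmt_num)
    }
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wt(run$eqtl_records, "eqtl_records.tsv", c("pos_cM", "lod"))
  wt(run$merged, "eqtl_merged.tsv",
     c("consensus_cM", "lod_max", "r2_control", "r2_SA", "r2_delta",
       "r2_mean"))
  wt(as.data.frame(run$variance), "variance_decomposition.tsv",
     grep("^(SS|prop)_", names(run$variance), value = TRUE))
  if (!is.null(run$transgression)) {
    wt(run$transgression, "transgression.tsv",
       c("parent_min", "parent_max", "fraction_outside"))
  }
  if (!is.null(run$hotspots)) {
    prof <- do.call(rbind, lapply(names(run$hotspots), function(ph) {
      h <- run$hotspots[[ph]]
      cbind(phenotype = ph, h$trans_profile,
            threshold = h$threshold,
            is_hotspot = h$trans_profile$count > h$threshold,
            stringsAsFactors = FALSE)
    }))
    wt(prof, "hotspot_profile.tsv", "threshold")
    if (!is.null(run$report$hotspot_intervals)) {
      wt(run$report$hotspot_intervals, "hotspot_intervals.tsv")
    }
  }
  if (!is.null(run$architecture)) {
    write_architecture(run$architecture,
                       file.path(out_dir, "planted_architecture.tsv"))
    paths <- c(paths, file.path(out_dir, "planted_architecture.tsv"))
  }
  manifest <- run$manifest
  manifest$outputs <- basename(paths)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  c(paths, file.path(out_dir, "manifest.yaml"))
}

#' @export
print.plastiqtl_run <- function(x, ...) {
  cat("plastiqtl_run\n")
  cat("  records:", nrow(x$eqtl_records), " merged eQTL:", nrow(x$merged),
      "\n")
  if (!is.null(x$report$cis_trans)) {
    print(x$report$cis_trans)
  }
  invisible(x)
}
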
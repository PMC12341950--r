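#' Simulate selfed-RIL genotypes
#'
#' Each line is an independent two-state Markov chain along each chromosome:
#' the first marker is `A`/`B` with probability 1/2, and adjacent markers at
#' distance d cM differ with the Haldane-Waddington selfed-RIL recombination
#' fraction R = 2r/(1+2r), Haldane r = (1 - exp(-2d/100))/2. Chromosomes are
#' independent linkage groups. Genotypes are strictly homozygous biallelic:
#' residual F8 heterozygosity (~0.8% expected) is not modelled, matching an
#' analysis that treats the lines as fully inbred. The stationary formula is
#' used directly rather than simulating seven selfing generations; for F8 the
#' difference is negligible and the marginal pairwise law is exact at F-inf.
#'
#' @param map a [genetic_map()].
#' @param n_lines number of RILs to draw.
#' @param seed integer random seed (drawing is fully deterministic given it).
#' @return character matrix `n_lines` x markers with entries `"A"`/`"B"`;
#'   rownames `RIL001`, ... and colnames the marker names.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed = 1) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  set.seed(seed)
  mk <- map$markers
  out <- matrix(NA_integer_, n_lines, nrow(mk))
  for (ch in map_chromosomes(map)) {
    cols <- which(mk$chromosome == ch)
    m <- length(cols)
    state <- matrix(0L, n_lines, m)
    state[, 1] <- stats::rbinom(n_lines, 1, 0.5)
    if (m > 1) {
      d <- diff(mk$position_cM[cols])
      R <- ril_recombination(haldane_r(d))
      flips <- vapply(R, function(p) stats::rbinom(n_lines, 1, p),
                      integer(n_lines))
      if (n_lines == 1) flips <- matrix(flips, nrow = 1)
      # allele = initial state xor cumulative number of recombinations (mod 2)
      cumflips <- t(apply(flips, 1, cumsum))
      state[, -1] <- (state[, 1] + cumflips) %% 2L
    }
    out[, cols] <- state
  }
  geno <- matrix(c("A", "B")[out + 1L], n_lines, nrow(mk))
  dimnames(geno) <- list(sprintf("RIL%03d", seq_len(n_lines)), mk$marker)
  geno
}

# flat (non-recursive) defaults merge: unknown keys rejected, list-valued
# settings (e.g. hotspot specs) replaced wholesale
merge_settings <- function(defaults, x) {
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown setting(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(x)) defaults[[k]] <- x[[k]]
  defaults
}

sim_config_defaults <- function() {
  list(n_cis = 0,
       n_trans = 0,
       hotspots = list(),          # list of list(chromosome, pos_cM, n_targets)
       n_hotspots = 0,             # alternative: random hotspot loci
       targets_per_hotspot = 0,
       frac_interaction = 0.5,     # P(effect carries a treatment interaction)
       frac_opposing = 0,          # fraction of transcripts given an opposing pair
       opposing_component = "interaction",  # or "baseline"
       target_r2 = c(0.2, 0.5),    # per-effect variance-explained target range
       noise_sd = 1,
       baseline_mean = 8,
       baseline_sd = 1,
       replicate_sd = 0.25,
       cis_window_cM = 10)
}

# effect size (parental mean difference) hitting an R^2 target at noise sd,
# under +/- 1/2 allele coding: genetic variance = b^2/4; noise-free
# simulations use a unit reference scale so planted effects stay nonzero
effect_from_r2 <- function(r2, noise_sd) {
  2 * max(noise_sd, if (noise_sd > 0) 0 else 1) * sqrt(r2 / (1 - r2))
}

#' Plant a ground-truth eQTL architecture
#'
#' Assigns transcripts uniform random genomic positions, then plants cis
#' effects (at the marker nearest each transcript's own position), independent
#' trans effects, pleiotropic trans hotspots (many transcripts sharing one
#' locus, with random effect directions), and opposing pairs: two effects on
#' the same transcript at distinct loci with equal magnitude and opposite
#' sign, so the two parental lines (all-A, all-B) sum to zero and only
#' recombinant lines express the difference — the mechanism of transgressive
#' segregation.
#'
#' @param map a [genetic_map()].
#' @param n_transcripts number of transcripts to simulate.
#' @param config list of simulation settings; unset keys take the defaults of
#'   `sim_config_defaults()`: counts of cis/trans effects, hotspot loci and
#'   targets, the fraction of effects with a treatment-interaction component,
#'   the fraction of transcripts given an opposing pair, the target
#'   variance-explained (R^2) range, noise and replicate-effect SDs.
#' @param seed integer random seed.
#' @return object of class `planted_architecture`: effects and hotspot
#'   data.frames, the transcript position table, per-transcript baselines and
#'   noise SDs, and the resolved config.
#' @export
plant_architecture <- function(map, n_transcripts, config = list(), seed = 1) {
  cfg <- merge_settings(sim_config_defaults(), config)
  set.seed(seed)
  mk <- map$markers
  ids <- sprintf("T%04d", seq_len(n_transcripts))
  lens <- map$chrom_ends
  chr <- sample(names(lens), n_transcripts, replace = TRUE,
                prob = lens / sum(lens))
  pos <- stats::runif(n_transcripts, 0, lens[chr])
  transcripts <- data.frame(transcript = ids, chromosome = chr,
                            pos_cM = as.numeric(pos),
                            bp = round(as.numeric(pos) * 2.5e5),
                            stringsAsFactors = FALSE)
  draw_r2 <- function(n) stats::runif(n, cfg$target_r2[1], cfg$target_r2[2])
  new_effect <- function(transcript, marker_row, baseline, interaction) {
    data.frame(transcript = transcript,
               chromosome = mk$chromosome[marker_row],
               pos_cM = mk$position_cM[marker_row],
               baseline_effect = baseline,
               interaction_effect = interaction,
               stringsAsFactors = FALSE)
  }
  effects <- list()

  gene_row <- function(tr) match(tr, transcripts$transcript)
  # cis: locus at the marker nearest the transcript's own position
  if (cfg$n_cis > 0) {
    cis_tr <- sample(ids, cfg$n_cis)
    for (tr in cis_tr) {
      g <- gene_row(tr)
      mrow <- nearest_marker_index(map, transcripts$chromosome[g],
                                   transcripts$pos_cM[g])
      if (abs(mk$position_cM[mrow] - transcripts$pos_cM[g]) >
          cfg$cis_window_cM) {
        warning("cis effect for ", tr,
                " repositioned to nearest marker outside the cis window")
      }
      b <- effect_from_r2(draw_r2(1), cfg$noise_sd) * sample(c(-1, 1), 1)
      i <- if (stats::runif(1) < cfg$frac_interaction)
        effect_from_r2(draw_r2(1), cfg$noise_sd) * sample(c(-1, 1), 1) else 0
      effects[[length(effects) + 1L]] <- new_effect(tr, mrow, b, i)
    }
  }
  # independent trans effects: random marker outside the transcript's cis window
  if (cfg$n_trans > 0) {
    trans_tr <- sample(ids, cfg$n_trans)
    for (tr in trans_tr) {
      g <- gene_row(tr)
      repeat {
        mrow <- sample(nrow(mk), 1)
        is_cis <- mk$chromosome[mrow] == transcripts$chromosome[g] &&
          abs(mk$position_cM[mrow] - transcripts$pos_cM[g]) <= cfg$cis_window_cM
        if (!is_cis) break
      }
      b <- effect_from_r2(draw_r2(1), cfg$noise_sd) * sample(c(-1, 1), 1)
      i <- if (stats::runif(1) < cfg$frac_interaction)
        effect_from_r2(draw_r2(1), cfg$noise_sd) * sample(c(-1, 1), 1) else 0
      effects[[length(effects) + 1L]] <- new_effect(tr, mrow, b, i)
    }
  }
  # hotspots: one shared locus, many target transcripts, random directions
  hot_specs <- cfg$hotspots
  if (length(hot_specs) == 0 && cfg$n_hotspots > 0) {
    rows <- sample(nrow(mk), cfg$n_hotspots)
    hot_specs <- lapply(rows, function(r) {
      list(chromosome = mk$chromosome[r], pos_cM = mk$position_cM[r],
           n_targets = cfg$targets_per_hotspot)
    })
  }
  hot_rows <- list()
  for (h in hot_specs) {
    mrow <- nearest_marker_index(map, h$chromosome, h$pos_cM)
    targets <- sample(ids, h$n_targets)
    for (tr in targets) {
      b <- effect_from_r2(draw_r2(1), cfg$noise_sd) * sample(c(-1, 1), 1)
      i <- if (stats::runif(1) < cfg$frac_interaction)
        effect_from_r2(draw_r2(1), cfg$noise_sd) * sample(c(-1, 1), 1) else 0
      effects[[length(effects) + 1L]] <- new_effect(tr, mrow, b, i)
    }
    hot_rows[[length(hot_rows) + 1L]] <-
      data.frame(chromosome = mk$chromosome[mrow],
                 pos_cM = mk$position_cM[mrow],
                 n_targets = h$n_targets, stringsAsFactors = FALSE)
  }
  # opposing pairs: +e and -e on the same transcript at two distinct loci
  n_opp <- round(cfg$frac_opposing * n_transcripts)
  if (n_opp > 0) {
    opp_tr <- sample(ids, n_opp)
    for (tr in opp_tr) {
      rows <- sample(nrow(mk), 2)
      while (mk$chromosome[rows[1]] == mk$chromosome[rows[2]] &&
             abs(mk$position_cM[rows[1]] - mk$position_cM[rows[2]]) < 50) {
        rows <- sample(nrow(mk), 2)
      }
      e <- effect_from_r2(draw_r2(1), cfg$noise_sd)
      if (identical(cfg$opposing_component, "baseline")) {
        b <- c(e, -e); i <- c(0, 0)
      } else {
        b <- c(0, 0); i <- c(e, -e)
      }
      effects[[length(effects) + 1L]] <- new_effect(tr, rows[1], b[1], i[1])
      effects[[length(effects) + 1L]] <- new_effect(tr, rows[2], b[2], i[2])
    }
  }
  effects <- if (length(effects) > 0) do.call(rbind, effects) else
    data.frame(transcript = character(), chromosome = character(),
               pos_cM = numeric(), baseline_effect = numeric(),
               interaction_effect = numeric(), stringsAsFactors = FALSE)
  if (nrow(effects) > 0) {
    g <- match(effects$transcript, transcripts$transcript)
    effects$type <- ifelse(
      effects$chromosome == transcripts$chromosome[g] &
        abs(effects$pos_cM - transcripts$pos_cM[g]) <= cfg$cis_window_cM,
      "cis", "trans")
  } else {
    effects$type <- character()
  }
  rownames(effects) <- NULL
  hotspots <- if (length(hot_rows) > 0) do.call(rbind, hot_rows) else
    data.frame(chromosome = character(), pos_cM = numeric(),
               n_targets = integer(), stringsAsFactors = FALSE)
  structure(list(
    effects = effects[, c("transcript", "chromosome", "pos_cM", "type",
                          "baseline_effect", "interaction_effect")],
    hotspots = hotspots,
    map = map,
    transcripts = transcripts,
    baseline = stats::setNames(
      stats::rnorm(n_transcripts, cfg$baseline_mean, cfg$baseline_sd), ids),
    noise_sd = stats::setNames(rep(cfg$noise_sd, n_transcripts), ids),
    replicate_sd = cfg$replicate_sd,
    config = cfg),
    class = "planted_architecture")
}

#' @export
print.planted_architecture <- function(x, ...) {
  cat("planted_architecture:", nrow(x$transcripts), "transcripts,",
      nrow(x$effects), "effects (",
      sum(x$effects$type == "cis"), "cis /",
      sum(x$effects$type == "trans"), "trans ),",
      nrow(x$hotspots), "hotspot(s)\n")
  invisible(x)
}

#' Write the planted ground truth to TSV
#' @param architecture a [plant_architecture()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_architecture <- function(architecture, path) {
  df <- architecture$effects
  df$sign <- ifelse(df$baseline_effect + df$interaction_effect >= 0, "+", "-")
  num <- c("pos_cM", "baseline_effect", "interaction_effect")
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a treatment-responsive expression dataset
#'
#' Generative model per sample and transcript:
#' abundance = baseline + sum over the transcript's planted effects of
#' allele_code x (baseline_effect + 1\{SA\} x interaction_effect)
#' + replicate effect + Gaussian noise. The allele code is -1/2 for `A` and
#' +1/2 for `B` (0 at a missing call), so a planted `baseline_effect` equals
#' the parental mean difference. The replicate effect is one shared additive
#' shift per replicate per transcript, mirroring an experiment-wide batch
#' term.
#'
#' @param genotypes genotype matrix (lines x markers).
#' @param architecture a [plant_architecture()] result.
#' @param n_replicates biological replicates per line per treatment.
#' @param include_parents append the two parental lines (`Bay-0` all-A,
#'   `Sha` all-B)?
#' @param seed integer random seed.
#' @return an [expression_dataset()].
#' @export
simulate_expression <- function(genotypes, architecture, n_replicates = 2,
                                include_parents = TRUE, seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(seed)
  arch <- architecture
  if (include_parents) {
    parents <- matrix(rep(c("A", "B"), each = ncol(genotypes)), nrow = 2,
                      byrow = TRUE, dimnames = list(c("Bay-0", "Sha"),
                                                    colnames(genotypes)))
    genotypes <- rbind(genotypes, parents)
  }
  lines <- rownames(genotypes)
  ids <- arch$transcripts$transcript
  treatments <- c("control", "SA")
  meta <- expand.grid(genotype = lines, treatment = treatments,
                      replicate = sprintf("rep%d", seq_len(n_replicates)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_%s", meta$genotype, meta$treatment,
                         meta$replicate)
  values <- matrix(rep(arch$baseline, each = nrow(meta)),
                   nrow = nrow(meta), ncol = length(ids),
                   dimnames = list(meta$sample, ids))
  line_idx <- match(meta$genotype, lines)
  is_sa <- meta$treatment == "SA"
  if (nrow(arch$effects) > 0) {
    marker_col <- match_effect_markers(arch, colnames(genotypes))
    for (k in seq_len(nrow(arch$effects))) {
      tr <- arch$effects$transcript[k]
      g <- genotypes[, marker_col[k]]
      code <- ifelse(is.na(g), 0, ifelse(g == "B", 0.5, -0.5))
      shift <- code[line_idx] * (arch$effects$baseline_effect[k] +
                                   is_sa * arch$effects$interaction_effect[k])
      values[, tr] <- values[, tr] + shift
    }
  }
  if (arch$replicate_sd > 0) {
    rep_eff <- matrix(stats::rnorm(n_replicates * length(ids), 0,
                                   arch$replicate_sd),
                      n_replicates, length(ids),
                      dimnames = list(sprintf("rep%d", seq_len(n_replicates)),
                                      ids))
    values <- values + rep_eff[meta$replicate, , drop = FALSE]
  }
  if (any(arch$noise_sd > 0)) {
    noise <- matrix(stats::rnorm(nrow(meta) * length(ids)), nrow(meta),
                    length(ids))
    values <- values + sweep(noise, 2, arch$noise_sd, `*`)
  }
  expression_dataset(values, meta[, c("sample", "genotype", "treatment",
                                      "replicate")])
}

# locate each planted effect's marker column in a genotype matrix; effect
# loci were snapped to markers of the architecture's own map, so match on
# exact (chromosome, position) and translate to marker names.
match_effect_markers <- function(arch, marker_names) {
  map <- arch$map
  key <- paste(map$markers$chromosome, signif(map$markers$position_cM, 10))
  want <- paste(arch$effects$chromosome, signif(arch$effects$pos_cM, 10))
  idx <- match(want, key)
  cols <- match(map$markers$marker[idx], marker_names)
  if (anyNA(cols)) {
    stop("cannot locate effect loci among genotype markers; the genotype ",
         "matrix must come from the same map as the architecture")
  }
  cols
}
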
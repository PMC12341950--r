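#' Sliding-window eQTL position counts
#'
#' Windows of width `window` advance by `step` along each chromosome:
#' \[s, s+window) for s = 0, step, 2*step, ... while s + window <= the
#' chromosome end, plus a final window ending exactly at the end when the
#' grid does not reach it. Windows are half-open so a position on a shared
#' edge is counted once; a window ending at the chromosome end includes that
#' endpoint.
#'
#' @param positions data.frame with columns `chromosome`, `pos_cM` (eQTL
#'   consensus positions).
#' @param map the [genetic_map()] providing chromosome ends.
#' @param window window width in cM.
#' @param step step size in cM.
#' @return data.frame: `chromosome`, `window_start`, `window_end`, `count`.
#' @export
sliding_window_counts <- function(positions, map, window = 10, step = 1) {
  if (window <= 0 || step <= 0) stop("window and step must be > 0")
  out <- list()
  for (ch in map_chromosomes(map)) {
    end <- map$chrom_ends[[ch]]
    pos <- positions$pos_cM[positions$chromosome == ch]
    if (any(pos < 0 | pos > end)) {
      stop("position outside chromosome '", ch, "' bounds [0, ", end, "]")
    }
    starts <- seq(0, max(0, end - window), by = step)
    if (utils::tail(starts, 1) + window < end) {
      starts <- c(starts, end - window)
    }
    pos <- sort(pos)
    ends <- starts + window
    # count in [s, e): #{p < e} - #{p < s}; final windows at the chromosome
    # end are closed on the right
    n_lt <- function(x) findInterval(x, pos, left.open = TRUE)
    n_le <- function(x) findInterval(x, pos)
    upper <- ifelse(ends >= end, n_le(ends), n_lt(ends))
    cnt <- upper - n_lt(starts)
    out[[ch]] <- data.frame(chromosome = ch, window_start = starts,
                            window_end = ends, count = as.integer(cnt),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation-derived global hotspot threshold
#'
#' Each permutation redraws `n_eqtl` positions uniformly over the genetic map
#' (chromosome chosen proportional to length, position uniform within it) and
#' recomputes all sliding-window counts; the threshold is the requested
#' percentile of the pooled window counts across all permutations — the
#' global null for "how many eQTL can one window hold by chance". Uniform
#' position redraw is the minimal null for eQTL position; a
#' marker-frequency-weighted redraw would additionally condition on map
#' density.
#'
#' @param n_eqtl number of (trans-)eQTL positions per permutation.
#' @param map the [genetic_map()].
#' @param window,step sliding-window geometry.
#' @param n_permutations number of permutations (default 1000).
#' @param percentile percentile (0-100) of the pooled counts (default 95).
#' @param seed integer random seed.
#' @return single numeric threshold (0 when `n_eqtl` is 0).
#' @export
permutation_threshold <- function(n_eqtl, map, window = 10, step = 1,
                                  n_permutations = 1000, percentile = 95,
                                  seed = 1) {
  if (n_eqtl == 0) return(0)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  set.seed(seed)
  lens <- map$chrom_ends
  chroms <- names(lens)
  pooled <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    ch <- sample(chroms, n_eqtl, replace = TRUE, prob = lens / sum(lens))
    pos <- data.frame(chromosome = ch,
                      pos_cM = stats::runif(n_eqtl, 0, lens[ch]),
                      stringsAsFactors = FALSE)
    pooled[[p]] <- sliding_window_counts(pos, map, window, step)$count
  }
  as.numeric(stats::quantile(unlist(pooled), percentile / 100, names = FALSE))
}

#' Call hotspot intervals from a window profile
#'
#' Maximal runs of consecutive windows with count strictly above the
#' threshold are merged into intervals \[first window start, last window
#' end); each interval's peak is its maximum-count window (ties break to the
#' smallest start).
#'
#' @param profile a [sliding_window_counts()] result.
#' @param threshold the [permutation_threshold()] value.
#' @return data.frame: `chromosome`, `start_cM`, `end_cM`, `peak_cM`
#'   (peak window start), `peak_count` (zero rows when nothing exceeds the
#'   threshold).
#' @export
call_hotspots <- function(profile, threshold) {
  out <- list()
  for (ch in unique(profile$chromosome)) {
    d <- profile[profile$chromosome == ch, , drop = FALSE]
    d <- d[order(d$window_start), , drop = FALSE]
    hot <- d$count > threshold
    if (!any(hot)) next
    runs <- rle(hot)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (r in which(runs$values)) {
      rows <- idx_start[r]:idx_end[r]
      peak <- rows[order(-d$count[rows], d$window_start[rows])][1]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch,
        start_cM = d$window_start[rows[1]],
        end_cM = d$window_end[rows[length(rows)]],
        peak_cM = d$window_start[peak],
        peak_count = d$count[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chromosome = character(), start_cM = numeric(),
                      end_cM = numeric(), peak_cM = numeric(),
                      peak_count = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trans-eQTL hotspot profiles for every expression phenotype
#'
#' For each phenotype, counts trans-labelled merged-eQTL consensus positions
#' in sliding windows, derives that phenotype's permutation threshold (from
#' its own trans-eQTL count), and calls hotspot intervals. Cis profiles are
#' computed for plotting but never thresholded: cis-eQTL density follows
#' gene density, not hotspot structure.
#'
#' @param merged annotated merged-eQTL table (with `cis_trans`,
#'   `membership`).
#' @param map the [genetic_map()].
#' @param config a [pipeline_config()].
#' @param seed integer random seed for the permutations.
#' @return list of class `hotspot_profile`, one element per phenotype:
#'   `trans_profile`, `cis_profile`, `threshold`, `intervals`.
#' @export
hotspot_profiles <- function(merged, map, config = pipeline_config(),
                             seed = 1) {
  phs <- c("control", "SA", "delta")
  out <- list()
  for (k in seq_along(phs)) {
    ph <- phs[k]
    sel <- merged[vapply(strsplit(merged$membership, ","),
                         function(s) ph %in% s, logical(1)), , drop = FALSE]
    pos_trans <- sel[sel$cis_trans == "trans",
                     c("chromosome", "consensus_cM")]
    pos_cis <- sel[sel$cis_trans == "cis", c("chromosome", "consensus_cM")]
    names(pos_trans) <- names(pos_cis) <- c("chromosome", "pos_cM")
    prof_t <- sliding_window_counts(pos_trans, map,
                                    config$hotspot_window_cM,
                                    config$hotspot_step_cM)
    prof_c <- sliding_window_counts(pos_cis, map, config$hotspot_window_cM,
                                    config$hotspot_step_cM)
    thr <- permutation_threshold(nrow(pos_trans), map,
                                 config$hotspot_window_cM,
                                 config$hotspot_step_cM,
                                 config$n_permutations,
                                 config$permutation_percentile,
                                 seed = seed + k)
    out[[ph]] <- list(trans_profile = prof_t, cis_profile = prof_c,
                      threshold = thr,
                      intervals = call_hotspots(prof_t, thr))
  }
  structure(out, class = "hotspot_profile")
}
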
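#' Expected allele dosages from observed genotypes
#'
#' Converts genotype calls to the expected dosage of the parent-2 (`B`)
#' allele: 0 at an observed `A`, 1 at an observed `B`. Missing calls are
#' imputed as the conditional probability of `B` given the nearest
#' non-missing flanking markers under the selfed-RIL Markov transition
#' R = 2r/(1+2r) (two-step path enumeration, normalized); a terminal gap uses
#' its single available flank; a fully missing chromosome gives 0.5.
#'
#' @param genotypes genotype matrix (lines x markers, `"A"`/`"B"`/`NA`).
#' @param map the associated [genetic_map()].
#' @return numeric matrix lines x markers of dosages in \[0, 1\].
#' @export
genotype_probabilities <- function(genotypes, map) {
  validate_genotypes(genotypes, map)
  mk <- map$markers
  prob <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
                 dimnames = dimnames(genotypes))
  prob[genotypes == "A"] <- 0
  prob[genotypes == "B"] <- 1
  if (!anyNA(genotypes)) return(prob)
  # transition matrix between genotype states over d cM
  trans <- function(d) {
    R <- ril_recombination(haldane_r(d))
    matrix(c(1 - R, R, R, 1 - R), 2, 2)
  }
  for (ch in map_chromosomes(map)) {
    cols <- which(mk$chromosome == ch)
    pos <- mk$position_cM[cols]
    for (i in seq_len(nrow(genotypes))) {
      g <- genotypes[i, cols]
      na_idx <- which(is.na(g))
      if (length(na_idx) == 0) next
      obs_idx <- which(!is.na(g))
      if (length(obs_idx) == 0) {
        prob[i, cols[na_idx]] <- 0.5
        next
      }
      for (j in na_idx) {
        left <- obs_idx[obs_idx < j]
        right <- obs_idx[obs_idx > j]
        left <- if (length(left)) max(left) else NA
        right <- if (length(right)) min(right) else NA
        if (is.na(left)) {
          # terminal gap: single flank
          st <- if (g[right] == "B") 2 else 1
          prob[i, cols[j]] <- trans(pos[right] - pos[j])[st, 2]
        } else if (is.na(right)) {
          st <- if (g[left] == "B") 2 else 1
          prob[i, cols[j]] <- trans(pos[j] - pos[left])[st, 2]
        } else {
          sl <- if (g[left] == "B") 2 else 1
          sr <- if (g[right] == "B") 2 else 1
          tl <- trans(pos[j] - pos[left])
          tr <- trans(pos[right] - pos[j])
          w <- tl[sl, ] * tr[, sr]   # path weights through A / B at j
          prob[i, cols[j]] <- w[2] / sum(w)
        }
      }
    }
  }
  prob
}

#' Single-QTL Haley-Knott genome scan for one phenotype vector
#'
#' At every marker, regresses the phenotype on expected allele dosage
#' (intercept + slope) and reports LOD = (n/2) log10(RSS0 / RSS1), RSS0 being
#' the intercept-only residual sum of squares. Genotypes with a missing
#' phenotype are dropped. A zero-variance phenotype yields an all-zero,
#' flagged curve; a perfect fit is capped at `lod_cap`.
#'
#' @param probabilities dosage matrix from [genotype_probabilities()]
#'   (rownames = genotype ids).
#' @param phenotype named numeric vector (names = genotype ids).
#' @param map the [genetic_map()] aligned with `probabilities`.
#' @param lod_cap LOD cap for degenerate perfect fits.
#' @return data.frame of class `lod_curve`: `marker`, `chromosome`, `pos_cM`,
#'   `lod`, `slope`; attributes `n` (genotypes used) and `flagged`.
#' @export
scan1_hk <- function(probabilities, phenotype, map, lod_cap = 50) {
  common <- intersect(rownames(probabilities), names(phenotype))
  y <- phenotype[common]
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n < 3) stop("scan1_hk needs >= 3 genotypes with non-missing phenotype")
  G <- probabilities[common[keep], , drop = FALSE]
  yc <- y - mean(y)
  syy <- sum(yc^2)
  out <- data.frame(marker = map$markers$marker,
                    chromosome = map$markers$chromosome,
                    pos_cM = map$markers$position_cM,
                    lod = 0, slope = 0, stringsAsFactors = FALSE)
  flagged <- FALSE
  if (syy < .Machine$double.eps * n) {
    flagged <- TRUE
  } else {
    Gc <- sweep(G, 2, colMeans(G))
    sxx <- colSums(Gc^2)
    sxy <- as.numeric(crossprod(Gc, yc))
    ok <- sxx > .Machine$double.eps * n
    rss1 <- rep(syy, ncol(G))
    rss1[ok] <- syy - sxy[ok]^2 / sxx[ok]
    rss1 <- pmax(rss1, 0)
    lod <- ifelse(rss1 < syy * 10^(-2 * lod_cap / n), lod_cap,
                  (n / 2) * log10(syy / rss1))
    lod[!ok] <- 0
    out$lod <- lod
    out$slope <- ifelse(ok, sxy / sxx, 0)
  }
  attr(out, "n") <- n
  attr(out, "flagged") <- flagged
  class(out) <- c("lod_curve", class(out))
  out
}

#' Call LOD peaks on a scan curve
#'
#' Per chromosome, local maxima at or above the LOD threshold are retained
#' greedily by descending LOD, suppressing any candidate within
#' `min_peak_separation_cM` of an already accepted peak; LOD ties break to
#' the smaller position. The peak's effect sign is the sign of the regression
#' slope (direction of the parent-2 allele).
#'
#' @param curve a [scan1_hk()] result.
#' @param map the [genetic_map()].
#' @param lod_threshold minimum LOD (the genome-wide per-scan call
#'   threshold).
#' @param min_peak_separation_cM suppression radius between accepted peaks.
#' @return data.frame: `chromosome`, `pos_cM`, `lod`, `slope_sign` (one row
#'   per retained peak; zero rows when nothing clears the threshold).
#' @export
find_peaks <- function(curve, map, lod_threshold = 2,
                       min_peak_separation_cM = 11) {
  res <- list()
  for (ch in map_chromosomes(map)) {
    d <- curve[curve$chromosome == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    lod <- d$lod
    m <- length(lod)
    left <- c(-Inf, lod[-m])
    right <- c(lod[-1], -Inf)
    is_max <- lod >= left & lod >= right & lod >= lod_threshold
    cand <- which(is_max)
    if (length(cand) == 0) next
    ord <- cand[order(-lod[cand], d$pos_cM[cand])]
    accepted <- integer(0)
    for (i in ord) {
      if (length(accepted) == 0 ||
          all(abs(d$pos_cM[accepted] - d$pos_cM[i]) >
              min_peak_separation_cM)) {
        accepted <- c(accepted, i)
      }
    }
    accepted <- accepted[order(d$pos_cM[accepted])]
    res[[ch]] <- data.frame(chromosome = ch, pos_cM = d$pos_cM[accepted],
                            lod = lod[accepted],
                            slope_sign = sign(d$slope[accepted]),
                            stringsAsFactors = FALSE)
  }
  if (length(res) == 0) {
    return(data.frame(chromosome = character(), pos_cM = numeric(),
                      lod = numeric(), slope_sign = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genome scans for every transcript and expression phenotype
#'
#' Runs the Haley-Knott scan and peak calling for each transcript of each
#' expression phenotype (control, SA, delta) and concatenates the detected
#' eQTL records. Per-phenotype totals are reported via `message()`. Scans are
#' computed at observed markers only; at the dense map densities this
#' pipeline targets, pseudomarker interpolation adds nothing.
#'
#' @param probabilities dosage matrix from [genotype_probabilities()].
#' @param phenotypes a [phenotype_set()] (or any named list of genotype x
#'   transcript matrices).
#' @param map the [genetic_map()].
#' @param config a [pipeline_config()].
#' @return data.frame of eQTL records: `transcript`, `phenotype`,
#'   `chromosome`, `pos_cM`, `lod`, `slope_sign`, `n`.
#' @export
scan_all <- function(probabilities, phenotypes, map,
                     config = pipeline_config()) {
  records <- list()
  for (ph in names(phenotypes)) {
    tab <- phenotypes[[ph]]
    common <- intersect(rownames(probabilities), rownames(tab))
    if (length(common) == 0) {
      stop("no overlapping genotypes between dosages and the '", ph,
           "' phenotype table")
    }
    G <- probabilities[common, , drop = FALSE]
    tab <- tab[common, , drop = FALSE]
    n_found <- 0L
    complete <- !anyNA(tab)
    lodmat <- slopemat <- NULL
    if (complete) {
      # fast path: one matrix product covers all transcripts
      Gc <- sweep(G, 2, colMeans(G))
      Yc <- sweep(tab, 2, colMeans(tab))
      sxx <- colSums(Gc^2)
      syy <- colSums(Yc^2)
      n <- length(common)
      sxy <- crossprod(Gc, Yc)                  # markers x transcripts
      ok <- sxx > .Machine$double.eps * n
      # same RSS arithmetic as scan1_hk, batched over transcripts
      rss1 <- pmax(rep(syy, each = length(sxx)) - sxy^2 / sxx, 0)
      syy_mat <- matrix(syy, length(sxx), length(syy), byrow = TRUE)
      lodmat <- (n / 2) * log10(syy_mat / rss1)
      lodmat[rss1 < syy_mat * 10^(-2 * config$lod_cap / n)] <- config$lod_cap
      lodmat[!ok, ] <- 0
      lodmat[, syy < .Machine$double.eps * n] <- 0
      slopemat <- sxy / sxx
      slopemat[!ok, ] <- 0
    }
    for (tr in colnames(tab)) {
      if (complete) {
        curve <- data.frame(marker = map$markers$marker,
                            chromosome = map$markers$chromosome,
                            pos_cM = map$markers$position_cM,
                            lod = lodmat[, tr], slope = slopemat[, tr],
                            stringsAsFactors = FALSE)
      } else {
        y <- tab[, tr]
        names(y) <- rownames(tab)
        if (sum(!is.na(y)) < 3) next
        curve <- scan1_hk(G, y, map, lod_cap = config$lod_cap)
      }
      pk <- find_peaks(curve, map, lod_threshold = config$lod_threshold,
                       min_peak_separation_cM = config$min_peak_separation_cM)
      if (nrow(pk) > 0) {
        pk <- cbind(transcript = tr, phenotype = ph, pk,
                    n = if (complete) length(common) else attr(curve, "n"),
                    stringsAsFactors = FALSE)
        records[[length(records) + 1L]] <- pk
        n_found <- n_found + nrow(pk)
      }
    }
    message(sprintf("scan_all: %d eQTL record(s) for phenotype '%s'",
                    n_found, ph))
  }
  if (length(records) == 0) {
    return(data.frame(transcript = character(), phenotype = character(),
                      chromosome = character(), pos_cM = numeric(),
                      lod = numeric(), slope_sign = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
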
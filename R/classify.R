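#' Interpolate gene physical positions into the genetic map
#'
#' Piecewise-linear bp -> cM interpolation between flanking anchor markers on
#' each chromosome; genes outside the anchor span are clamped to the terminal
#' anchor's cM (with a warning).
#'
#' @param genes data.frame with columns `transcript`, `chromosome`, `bp`.
#' @param anchors data.frame with columns `marker`, `chromosome`, `bp`,
#'   `cM` — markers of known physical and genetic position, >= 2 per
#'   chromosome, strictly increasing in bp and non-decreasing in cM.
#' @return the `genes` data.frame with an added `pos_cM` column.
#' @export
interpolate_gene_positions <- function(genes, anchors) {
  required_g <- c("transcript", "chromosome", "bp")
  required_a <- c("chromosome", "bp", "cM")
  if (!all(required_g %in% names(genes))) {
    stop("genes table needs columns: ", paste(required_g, collapse = ", "))
  }
  if (!all(required_a %in% names(anchors))) {
    stop("anchors table needs columns: ", paste(required_a, collapse = ", "))
  }
  no_anchor <- setdiff(unique(genes$chromosome), unique(anchors$chromosome))
  if (length(no_anchor) > 0) {
    bad <- genes$transcript[genes$chromosome %in% no_anchor]
    stop("gene(s) on chromosome(s) without anchors [",
         paste(no_anchor, collapse = ", "), "]: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  genes$pos_cM <- NA_real_
  n_clamped <- 0L
  for (ch in unique(genes$chromosome)) {
    a <- anchors[anchors$chromosome == ch, , drop = FALSE]
    a <- a[order(a$bp), , drop = FALSE]
    if (nrow(a) < 2) stop("chromosome '", ch, "' has < 2 anchors")
    if (any(diff(a$bp) <= 0)) {
      stop("anchor bp not strictly increasing on chromosome '", ch, "'")
    }
    if (any(diff(a$cM) < 0)) {
      stop("anchor cM decreasing on chromosome '", ch, "'")
    }
    sel <- genes$chromosome == ch
    # rule = 2 clamps to the terminal anchors outside the span
    genes$pos_cM[sel] <- stats::approx(a$bp, a$cM, xout = genes$bp[sel],
                                       rule = 2, ties = "ordered")$y
    n_clamped <- n_clamped +
      sum(genes$bp[sel] < min(a$bp) | genes$bp[sel] > max(a$bp))
  }
  if (n_clamped > 0) {
    warning(n_clamped, " gene(s) outside the anchor span clamped to the ",
            "terminal anchor position")
  }
  genes
}

#' Label eQTL records cis or trans
#'
#' An eQTL is cis when it lies on the same chromosome as its transcript's
#' gene and within `window` cM of it (boundary inclusive); otherwise trans.
#' Records for transcripts with no known position are labelled `unplaced`
#' (retained in tables, excluded from cis/trans proportions).
#'
#' @param records eQTL record data.frame (needs `transcript`, `chromosome`,
#'   `pos_cM`).
#' @param gene_positions data.frame with `transcript`, `chromosome`,
#'   `pos_cM`.
#' @param window cis window in cM (default 10).
#' @return `records` with an added `cis_trans` column.
#' @export
classify_cis_trans <- function(records, gene_positions, window = 10) {
  if (window <= 0) stop("cis window must be > 0")
  idx <- match(records$transcript, gene_positions$transcript)
  gchr <- gene_positions$chromosome[idx]
  gpos <- gene_positions$pos_cM[idx]
  lab <- ifelse(is.na(idx) | is.na(gpos), "unplaced",
                ifelse(records$chromosome == gchr &
                         abs(records$pos_cM - gpos) <= window,
                       "cis", "trans"))
  records$cis_trans <- lab
  records
}

# single-linkage clustering of 1-d positions: split at gaps > window,
# then enforce at most one record per phenotype per cluster (keep the
# higher LOD, re-cluster the leftovers among themselves)
merge_one_transcript <- function(rec, window) {
  clusters <- list()
  pending <- rec
  while (nrow(pending) > 0) {
    leftovers <- list()
    for (ch in unique(pending$chromosome)) {
      d <- pending[pending$chromosome == ch, , drop = FALSE]
      d <- d[order(d$pos_cM, d$phenotype), , drop = FALSE]
      gap <- c(FALSE, diff(d$pos_cM) > window)
      grp <- cumsum(gap)
      for (g in unique(grp)) {
        cl <- d[grp == g, , drop = FALSE]
        if (anyDuplicated(cl$phenotype)) {
          keep <- integer(0)
          for (ph in unique(cl$phenotype)) {
            rows <- which(cl$phenotype == ph)
            best <- rows[order(-cl$lod[rows], cl$pos_cM[rows])][1]
            keep <- c(keep, best)
          }
          leftovers[[length(leftovers) + 1L]] <-
            cl[-sort(keep), , drop = FALSE]
          cl <- cl[sort(keep), , drop = FALSE]
        }
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
    pending <- if (length(leftovers) > 0) do.call(rbind, leftovers) else
      pending[0, , drop = FALSE]
  }
  clusters
}

#' Merge eQTL across expression phenotypes
#'
#' Records of one transcript on one chromosome are collapsed by
#' single-linkage clustering with linkage distance <= `window` (so chained
#' runs merge transitively); the consensus position is the arithmetic mean of
#' member positions and the membership set is the member phenotypes. If one
#' phenotype contributes two records to a cluster, the higher-LOD record is
#' kept and the other is re-clustered.
#'
#' @param records eQTL record data.frame from [scan_all()].
#' @param window merge window in cM (default 5.5).
#' @return list: `merged` (one row per merged eQTL: `merge_id`, `transcript`,
#'   `chromosome`, `consensus_cM`, `membership` — comma-joined sorted
#'   phenotype set — `n_members`, `lod_max`) and `members` (the input records
#'   with their `merge_id`).
#' @export
merge_across_phenotypes <- function(records, window = 5.5) {
  if (window <= 0) stop("merge window must be > 0")
  empty <- data.frame(merge_id = character(), transcript = character(),
                      chromosome = character(), consensus_cM = numeric(),
                      membership = character(), n_members = integer(),
                      lod_max = numeric(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    return(list(merged = empty, members = cbind(records,
                                                merge_id = character(0))))
  }
  merged_rows <- list()
  member_rows <- list()
  counter <- 0L
  for (tr in sort(unique(records$transcript))) {
    rec <- records[records$transcript == tr, , drop = FALSE]
    clusters <- merge_one_transcript(rec, window)
    # deterministic ordering regardless of input record order
    ord <- order(vapply(clusters, function(cl) cl$chromosome[1],
                        character(1)),
                 vapply(clusters, function(cl) mean(cl$pos_cM), numeric(1)))
    for (cl in clusters[ord]) {
      counter <- counter + 1L
      id <- sprintf("M%05d", counter)
      phs <- sort(unique(cl$phenotype))
      merged_rows[[counter]] <- data.frame(
        merge_id = id, transcript = tr, chromosome = cl$chromosome[1],
        consensus_cM = mean(cl$pos_cM),
        membership = paste(phs, collapse = ","),
        n_members = nrow(cl), lod_max = max(cl$lod),
        stringsAsFactors = FALSE)
      member_rows[[counter]] <- cbind(cl, merge_id = id,
                                      stringsAsFactors = FALSE)
    }
  }
  merged <- do.call(rbind, merged_rows)
  members <- do.call(rbind, member_rows)
  rownames(merged) <- rownames(members) <- NULL
  list(merged = merged, members = members)
}

#' Effect sizes (R^2) for merged eQTL
#'
#' For every merged eQTL, the variance explained by genotype: the R^2 of the
#' simple linear regression of each member phenotype on the allele dosage at
#' the marker nearest the consensus position (one locus, one genotype
#' vector). The mean over member phenotypes is stored alongside the
#' per-phenotype values. Zero phenotype variance gives R^2 = 0 with a flag.
#'
#' @param merged the `merged` data.frame from [merge_across_phenotypes()].
#' @param probabilities dosage matrix from [genotype_probabilities()].
#' @param phenotypes a [phenotype_set()].
#' @param map the [genetic_map()].
#' @return `merged` with added columns `r2_control`, `r2_SA`, `r2_delta`
#'   (NA when that phenotype is not a member), `r2_mean` and `r2_flagged`.
#' @export
effect_size <- function(merged, probabilities, phenotypes, map) {
  for (col in c("r2_control", "r2_SA", "r2_delta")) {
    merged[[col]] <- rep(NA_real_, nrow(merged))
  }
  merged$r2_flagged <- logical(nrow(merged))
  if (nrow(merged) == 0) {
    merged$r2_mean <- numeric(0)
    return(merged)
  }
  for (i in seq_len(nrow(merged))) {
    mrow <- nearest_marker_index(map, merged$chromosome[i],
                                 merged$consensus_cM[i])
    marker <- map$markers$marker[mrow]
    for (ph in strsplit(merged$membership[i], ",")[[1]]) {
      tab <- phenotypes[[ph]]
      common <- intersect(rownames(probabilities), rownames(tab))
      y <- tab[common, merged$transcript[i]]
      x <- probabilities[common, marker]
      keep <- !is.na(y)
      if (stats::var(y[keep]) < .Machine$double.eps) {
        r2 <- 0
        merged$r2_flagged[i] <- TRUE
      } else {
        r2 <- summary(stats::lm(y[keep] ~ x[keep]))$r.squared
      }
      merged[[paste0("r2_", ph)]][i] <- r2
    }
  }
  merged$r2_mean <- rowMeans(merged[, c("r2_control", "r2_SA", "r2_delta")],
                             na.rm = TRUE)
  merged
}

#' Annotate merged eQTL with paralog and hotspot-region flags
#'
#' The paralog flag marks trans eQTL with any paralog of their transcript's
#' gene family within `paralog_window_cM` of the consensus position — the
#' signature of a structural-variant origin for an apparent trans signal.
#' The hotspot flag marks eQTL whose consensus position lies within
#' `membership_window_cM` of a named hotspot region (distance 0 inside the
#' region, else distance to the nearest edge).
#'
#' @param merged a [merge_across_phenotypes()] `merged` table (after
#'   [classify_cis_trans()] so a `cis_trans` column exists).
#' @param paralogs optional paralog table (see [read_paralogs()]).
#' @param hotspot_regions optional data.frame `chromosome`, `start_cM`,
#'   `end_cM`.
#' @param paralog_window_cM paralog search radius (default 10).
#' @param membership_window_cM hotspot-region radius (default 5).
#' @return `merged` with `paralog_flag`, `n_paralogs` (per-accession counts,
#'   comma-joined `accession:count`), `hotspot_flag`.
#' @export
annotate_paralogs <- function(merged, paralogs = NULL, hotspot_regions = NULL,
                              paralog_window_cM = 10,
                              membership_window_cM = 5) {
  merged$paralog_flag <- logical(nrow(merged))
  merged$n_paralogs <- character(nrow(merged))
  merged$hotspot_flag <- logical(nrow(merged))
  if (nrow(merged) == 0) return(merged)
  for (i in seq_len(nrow(merged))) {
    if (!is.null(paralogs)) {
      p <- paralogs[paralogs$transcript == merged$transcript[i], ,
                    drop = FALSE]
      if (nrow(p) > 0) {
        cnt <- table(p$accession)
        merged$n_paralogs[i] <- paste(sprintf("%s:%d", names(cnt),
                                              as.integer(cnt)),
                                      collapse = ",")
        if (identical(merged$cis_trans[i], "trans")) {
          near <- p$paralog_chromosome == merged$chromosome[i] &
            abs(p$paralog_cM - merged$consensus_cM[i]) <= paralog_window_cM
          merged$paralog_flag[i] <- any(near)
        }
      }
    }
    if (!is.null(hotspot_regions) && nrow(hotspot_regions) > 0) {
      h <- hotspot_regions[hotspot_regions$chromosome ==
                             merged$chromosome[i], , drop = FALSE]
      if (nrow(h) > 0) {
        pos <- merged$consensus_cM[i]
        dist <- pmax(h$start_cM - pos, pos - h$end_cM, 0)
        merged$hotspot_flag[i] <- any(dist <= membership_window_cM)
      }
    }
  }
  merged
}

#' Summarize cis/trans composition
#'
#' Counts and proportions of cis vs trans merged eQTL per expression
#' phenotype (an eQTL counts toward every phenotype in its membership set)
#' and per membership subset, plus per-transcript averages. Unplaced eQTL are
#' excluded from proportions.
#'
#' @param merged an annotated merged-eQTL table with `cis_trans` and
#'   `membership` columns.
#' @param n_transcripts denominator for the per-transcript averages (default:
#'   transcripts appearing in `merged`).
#' @return list: `per_phenotype` (phenotype, n_cis, n_trans, prop_trans),
#'   `per_membership` (membership, n_cis, n_trans, mean_r2 when present),
#'   `per_transcript` (named vector: mean cis and trans eQTL per transcript).
#' @export
summarize_cis_trans <- function(merged, n_transcripts = NULL) {
  if (nrow(merged) == 0) stop("no merged eQTL to summarize")
  placed <- merged[merged$cis_trans %in% c("cis", "trans"), , drop = FALSE]
  phs <- c("control", "SA", "delta")
  per_ph <- do.call(rbind, lapply(phs, function(ph) {
    sel <- placed[vapply(strsplit(placed$membership, ","),
                         function(s) ph %in% s, logical(1)), , drop = FALSE]
    n_cis <- sum(sel$cis_trans == "cis")
    n_trans <- sum(sel$cis_trans == "trans")
    data.frame(phenotype = ph, n_cis = n_cis, n_trans = n_trans,
               prop_trans = if (n_cis + n_trans > 0)
                 n_trans / (n_cis + n_trans) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  mem <- sort(unique(placed$membership))
  per_mem <- do.call(rbind, lapply(mem, function(m) {
    sel <- placed[placed$membership == m, , drop = FALSE]
    data.frame(membership = m,
               n_cis = sum(sel$cis_trans == "cis"),
               n_trans = sum(sel$cis_trans == "trans"),
               mean_r2 = if ("r2_mean" %in% names(sel))
                 mean(sel$r2_mean) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(n_transcripts)) {
    n_transcripts <- length(unique(merged$transcript))
  }
  per_tr <- c(cis = sum(placed$cis_trans == "cis") / n_transcripts,
              trans = sum(placed$cis_trans == "trans") / n_transcripts)
  list(per_phenotype = per_ph, per_membership = per_mem,
       per_transcript = per_tr)
}
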
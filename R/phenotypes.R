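#' Per-genotype mean expression by treatment
#'
#' Averages replicate samples to one value per genotype per transcript,
#' separately within each treatment.
#'
#' @param dataset an [expression_dataset()].
#' @return named list of two genotype x transcript matrices, `control` and
#'   `SA`. Cells with no contributing sample are `NA` (with a warning).
#' @export
genotype_means <- function(dataset) {
  genos <- unique(dataset$meta$genotype)
  out <- lapply(c(control = "control", SA = "SA"), function(tr) {
    sel <- dataset$meta$treatment == tr
    if (!any(sel)) {
      warning("no samples for treatment '", tr, "'")
      m <- matrix(NA_real_, length(genos), ncol(dataset$values),
                  dimnames = list(genos, colnames(dataset$values)))
      return(m)
    }
    g <- dataset$meta$genotype[sel]
    sums <- rowsum(dataset$values[sel, , drop = FALSE], g)
    m <- sums / as.vector(table(g)[rownames(sums)])
    missing_g <- setdiff(genos, rownames(m))
    if (length(missing_g) > 0) {
      warning("genotype(s) without '", tr, "' samples: ",
              paste(utils::head(missing_g, 5), collapse = ", "))
      pad <- matrix(NA_real_, length(missing_g), ncol(m),
                    dimnames = list(missing_g, colnames(m)))
      m <- rbind(m, pad)
    }
    m[genos, , drop = FALSE]
  })
  out
}

#' Plasticity statistic (delta)
#'
#' The per-genotype plasticity phenotype of a transcript: the difference in
#' mean abundance across the two treatments divided by their average,
#' delta = (SA - control) / ((SA + control) / 2). For non-negative means the
#' statistic is bounded in \[-2, 2\]; cells where the denominator falls below
#' `floor` are set missing (count reported via `message()`).
#'
#' @param control,sa aligned genotype x transcript mean matrices.
#' @param floor denominator floor (on the data's scale).
#' @return genotype x transcript matrix of delta values.
#' @export
compute_delta <- function(control, sa, floor = 1e-8) {
  if (!identical(dim(control), dim(sa)) ||
      !identical(dimnames(control), dimnames(sa))) {
    stop("control and SA tables are not aligned")
  }
  denom <- (sa + control) / 2
  delta <- (sa - control) / denom
  bad <- !is.na(denom) & abs(denom) < floor
  if (any(bad)) {
    message("compute_delta: ", sum(bad),
            " cell(s) with near-zero denominator set missing")
    delta[bad] <- NA_real_
  }
  delta
}

#' Build the three expression phenotypes
#'
#' Control mean, SA mean, and delta plasticity per genotype per transcript —
#' the inputs to the three genome scans.
#'
#' @param dataset an [expression_dataset()].
#' @param delta_floor denominator floor for [compute_delta()].
#' @return list of class `phenotype_set` with elements `control`, `SA`,
#'   `delta` (genotype x transcript matrices).
#' @export
phenotype_set <- function(dataset, delta_floor = 1e-8) {
  means <- genotype_means(dataset)
  structure(list(control = means$control, SA = means$SA,
                 delta = compute_delta(means$control, means$SA,
                                       floor = delta_floor)),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat("phenotype_set: control / SA / delta,", nrow(x$control),
      "genotypes x", ncol(x$control), "transcripts\n")
  invisible(x)
}

#' PCA of genotype transcriptomes
#'
#' Column-centered (unscaled) principal component analysis of a genotype x
#' transcript table. An exclusion set supports re-running without the
#' transcripts that carry cis-eQTL.
#'
#' @param table genotype x transcript numeric matrix.
#' @param n_components number of components to return (default all).
#' @param exclude_transcripts transcript ids dropped before the fit.
#' @return list with `scores` (genotypes x components), `loadings`,
#'   `explained` (variance fractions).
#' @export
pca_transcriptomes <- function(table, n_components = NULL,
                               exclude_transcripts = NULL) {
  if (!is.null(exclude_transcripts)) {
    table <- table[, setdiff(colnames(table), exclude_transcripts),
                   drop = FALSE]
  }
  if (ncol(table) == 0) stop("no transcripts left after exclusion")
  if (nrow(table) < 2) stop("PCA needs >= 2 genotypes")
  table <- table[stats::complete.cases(table), , drop = FALSE]
  if (nrow(table) < 2) stop("PCA needs >= 2 complete genotypes")
  if (all(apply(table, 2, stats::var) < .Machine$double.eps)) {
    stop("constant matrix: PCA undefined")
  }
  p <- stats::prcomp(table, center = TRUE, scale. = FALSE)
  k <- if (is.null(n_components)) length(p$sdev) else
    min(n_components, length(p$sdev))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}

#' Transgressive segregation summary
#'
#' For each transcript and expression phenotype: the parental value range and
#' the fraction of RILs strictly outside it. Ties with a parental value count
#' as inside (conservative). Progeny outside the parental range are the
#' signature of recombined opposing-effect alleles.
#'
#' @param phenotypes a [phenotype_set()].
#' @param parent_ids character vector of the two parental genotype ids.
#' @return data.frame with columns `transcript`, `phenotype`, `parent_min`,
#'   `parent_max`, `fraction_outside`.
#' @export
transgression_summary <- function(phenotypes, parent_ids) {
  stopifnot(length(parent_ids) == 2)
  out <- list()
  for (ph in c("control", "SA", "delta")) {
    tab <- phenotypes[[ph]]
    miss <- setdiff(parent_ids, rownames(tab))
    if (length(miss) > 0) {
      stop("parent(s) missing from ", ph, " table: ",
           paste(miss, collapse = ", "))
    }
    par <- tab[parent_ids, , drop = FALSE]
    ril <- tab[setdiff(rownames(tab), parent_ids), , drop = FALSE]
    lo <- pmin(par[1, ], par[2, ])
    hi <- pmax(par[1, ], par[2, ])
    outside <- sweep(ril, 2, lo, `<`) | sweep(ril, 2, hi, `>`)
    frac <- colMeans(outside, na.rm = TRUE)
    frac[colSums(!is.na(outside)) == 0] <- NA_real_
    out[[ph]] <- data.frame(transcript = colnames(tab), phenotype = ph,
                            parent_min = as.numeric(lo),
                            parent_max = as.numeric(hi),
                            fraction_outside = as.numeric(frac),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
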
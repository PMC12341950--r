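#' Partition per-transcript expression variance
#'
#' Fits, for every transcript, the linear model
#' `abundance ~ replicate + genotype + treatment + genotype:treatment`
#' with sum-to-zero factor contrasts and returns the type III sum of squares
#' of each term (the SS of dropping that term from the full model under those
#' contrasts), the residual SS, and each term's proportion of the total
#' corrected SS. Replicate is fit as a fixed blocking factor: for a two-level
#' replicate term this reproduces the intent of modelling replicate as a
#' random batch while keeping the SS decomposition well defined. In a
#' balanced complete design the term and residual SS add up to the total SS
#' and the proportions sum to one.
#'
#' Zero-variance transcripts are flagged `degenerate` (all SS and proportions
#' reported as 0). A factor observed at a single level contributes SS = 0
#' with a warning.
#'
#' @param dataset an [expression_dataset()].
#' @param genotypes optional character vector restricting the fit to a subset
#'   of genotypes (e.g. the two parents, or the RILs).
#' @return data.frame of class `variance_decomposition`: one row per
#'   transcript with `SS_replicate`, `SS_genotype`, `SS_treatment`, `SS_GxT`,
#'   `SS_residual`, `SS_total`, matching `prop_*` columns and a `degenerate`
#'   flag.
#' @export
decompose_variance <- function(dataset, genotypes = NULL) {
  meta <- dataset$meta
  values <- dataset$values
  if (!is.null(genotypes)) {
    keep <- meta$genotype %in% genotypes
    if (!any(keep)) stop("no samples left after genotype subset")
    meta <- meta[keep, , drop = FALSE]
    values <- values[keep, , drop = FALSE]
  }
  if (length(unique(meta$genotype)) < 2) {
    stop("variance decomposition needs >= 2 genotypes")
  }
  fac <- data.frame(
    replicate = factor(meta$replicate),
    genotype = factor(meta$genotype),
    treatment = factor(meta$treatment))
  single <- vapply(fac, function(f) nlevels(f) < 2, logical(1))
  if (any(single)) {
    warning("factor(s) with a single level contribute SS = 0: ",
            paste(names(fac)[single], collapse = ", "))
  }
  terms_use <- names(fac)[!single]
  form <- if (all(c("genotype", "treatment") %in% terms_use)) {
    stats::reformulate(c(terms_use, "genotype:treatment"), response = "y")
  } else {
    stats::reformulate(terms_use, response = "y")
  }
  contr <- lapply(fac[terms_use], function(f) "contr.sum")
  ss_names <- c(replicate = "SS_replicate", genotype = "SS_genotype",
                treatment = "SS_treatment", `genotype:treatment` = "SS_GxT")
  out <- data.frame(transcript = colnames(values),
                    SS_replicate = 0, SS_genotype = 0, SS_treatment = 0,
                    SS_GxT = 0, SS_residual = 0, SS_total = 0,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(values))) {
    y <- values[, j]
    tss <- sum((y - mean(y))^2)
    out$SS_total[j] <- tss
    if (tss < .Machine$double.eps * length(y)) {
      out$degenerate[j] <- TRUE
      next
    }
    dat <- cbind(fac, y = y)
    fit <- stats::lm(form, data = dat, contrasts = contr)
    if (any(is.na(stats::coef(fit)))) {
      stop("singular design for transcript '", colnames(values)[j], "'")
    }
    a3 <- tryCatch(
      car::Anova(fit, type = "III"),
      # car refuses exact zero-residual fits; same SS by drop-term refits
      error = function(e) type3_ss_manual(fit))
    rn <- rownames(a3)
    for (term in names(ss_names)) {
      if (term %in% rn) out[[ss_names[[term]]]][j] <- a3[term, "Sum Sq"]
    }
    out$SS_residual[j] <- a3["Residuals", "Sum Sq"]
  }
  props <- out[, c("SS_replicate", "SS_genotype", "SS_treatment", "SS_GxT",
                   "SS_residual")] / ifelse(out$SS_total > 0, out$SS_total, 1)
  names(props) <- sub("^SS_", "prop_", names(props))
  out <- cbind(out, props)
  class(out) <- c("variance_decomposition", class(out))
  out
}

# type III SS by explicit drop-term refits on the sum-to-zero model matrix:
# SS(term) = RSS(model without the term's columns) - RSS(full model)
type3_ss_manual <- function(fit) {
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  y <- stats::model.response(stats::model.frame(fit))
  rss_full <- sum(stats::residuals(fit)^2)
  ss <- vapply(seq_along(labels), function(i) {
    keep <- asgn != i
    sum(stats::lm.fit(X[, keep, drop = FALSE], y)$residuals^2) - rss_full
  }, numeric(1))
  out <- data.frame(`Sum Sq` = c(NA, ss, rss_full), check.names = FALSE,
                    row.names = c("(Intercept)", labels, "Residuals"))
  out
}

prop_cols <- c("prop_replicate", "prop_genotype", "prop_treatment",
               "prop_GxT", "prop_residual")

#' Cluster variance profiles with k-means
#'
#' Clusters the per-transcript proportion vectors (replicate, genotype,
#' treatment, GxT, residual) into `k` profiles. Degenerate transcripts are
#' excluded. Multiple seeded restarts are used (best within-cluster sum of
#' squares kept); results are deterministic given the seed.
#'
#' @param decomposition a [decompose_variance()] result.
#' @param k number of clusters (default 10 profiles).
#' @param seed integer random seed.
#' @param nstart k-means restarts.
#' @return list with `assignment` (data.frame transcript, cluster) and
#'   `centers` (k x 5 centroid matrix).
#' @export
cluster_variance_profiles <- function(decomposition, k = 10, seed = 1,
                                      nstart = 10) {
  keep <- !decomposition$degenerate
  x <- as.matrix(decomposition[keep, prop_cols])
  if (nrow(x) < k) stop("k = ", k, " exceeds the ", nrow(x),
                        " non-degenerate transcripts")
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  list(assignment = data.frame(transcript = decomposition$transcript[keep],
                               cluster = km$cluster,
                               stringsAsFactors = FALSE),
       centers = km$centers)
}

#' Mean variance proportions across transcripts
#'
#' @param decomposition a [decompose_variance()] result.
#' @return named numeric vector: the arithmetic mean proportion of each term
#'   across non-degenerate transcripts.
#' @export
summarize_variance <- function(decomposition) {
  keep <- !decomposition$degenerate
  if (!any(keep)) stop("all transcripts are degenerate (zero variance)")
  colMeans(decomposition[keep, prop_cols])
}
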
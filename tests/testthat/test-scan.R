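test_that("dosages equal observed codes and impute missing via the Markov chain", {
  map <- tiny_map()
  geno <- matrix(c("A", "B", "A",
                   "B", "B", "A"), 2, 3, byrow = TRUE,
                 dimnames = list(c("L1", "L2"), map$markers$marker))
  pr <- genotype_probabilities(geno, map)
  expect_equal(unname(pr), matrix(c(0, 1, 1, 1, 0, 0), 2, 3))

  # missing marker midway between two A calls at d = 5 each side:
  # two-step chain enumeration gives g = R^2 / ((1-R)^2 + R^2)
  map10 <- genetic_map(data.frame(marker = c("m1", "m2", "m3"),
                                  chromosome = "1",
                                  position_cM = c(0, 10, 20)))
  gAA <- matrix(c("A", NA, "A"), 1, 3,
                dimnames = list("L1", map10$markers$marker))
  R <- ril_recombination(haldane_r(10))
  g_exp <- R^2 / ((1 - R)^2 + R^2)
  expect_equal(genotype_probabilities(gAA, map10)[1, 2], g_exp,
               tolerance = 1e-12)
  expect_equal(g_exp, 0.0318132, tolerance = 1e-5)

  # missing between opposite flanks at equal distance: symmetry gives 1/2
  gAB <- matrix(c("A", NA, "B"), 1, 3,
                dimnames = list("L1", map10$markers$marker))
  expect_equal(genotype_probabilities(gAB, map10)[1, 2], 0.5)

  # terminal gap uses the single available flank
  gT <- matrix(c(NA, "B", "B"), 1, 3,
               dimnames = list("L1", map10$markers$marker))
  expect_equal(genotype_probabilities(gT, map10)[1, 1], 1 - R)

  # imputation never changes complete-data results
  expect_identical(genotype_probabilities(geno, map),
                   genotype_probabilities(geno, map))
})

test_that("scan1_hk matches the correlation-form LOD oracle", {
  set.seed(20)
  map <- five_chrom_map(spacing = 25)
  n <- 60
  geno <- simulate_ril_genotypes(map, n, seed = 21)
  pr <- genotype_probabilities(geno, map)
  for (i in 1:10) {
    y <- rnorm(n)
    names(y) <- rownames(pr)
    curve <- scan1_hk(pr, y, map)
    oracle <- vapply(seq_len(ncol(pr)), function(j) {
      rho <- suppressWarnings(cor(y, pr[, j]))
      if (is.na(rho)) 0 else -(n / 2) * log10(1 - rho^2)
    }, numeric(1))
    expect_lt(max(abs(curve$lod - oracle)), 1e-9)
  }

  # scaling the phenotype leaves the curve unchanged
  y <- rnorm(n); names(y) <- rownames(pr)
  expect_equal(scan1_hk(pr, y, map)$lod, scan1_hk(pr, -3.2 * y, map)$lod,
               tolerance = 1e-12)

  # constant phenotype: flagged all-zero curve
  yc <- rep(1, n); names(yc) <- rownames(pr)
  flat <- scan1_hk(pr, yc, map)
  expect_true(attr(flat, "flagged"))
  expect_true(all(flat$lod == 0))

  # phenotype equal to dosage: capped at the configured maximum
  yd <- pr[, 5]; names(yd) <- rownames(pr)
  capped <- scan1_hk(pr, yd, map, lod_cap = 50)
  expect_equal(max(capped$lod), 50)
  expect_equal(capped$marker[which.max(capped$lod)], colnames(pr)[5])
})

test_that("find_peaks retains separated local maxima above threshold", {
  map <- genetic_map(data.frame(marker = sprintf("m%d", 1:11),
                                chromosome = "1",
                                position_cM = seq(0, 100, 10)))
  curve <- data.frame(marker = map$markers$marker, chromosome = "1",
                      pos_cM = map$markers$position_cM,
                      lod = c(0.5, 1, 1.5, 1, 0.5, 1, 1.9, 1, 0.5, 1, 1.2),
                      slope = 1)
  expect_equal(nrow(find_peaks(curve, map, lod_threshold = 2)), 0)

  # two separated peaks above threshold
  curve$lod <- c(0.5, 5, 1, 1, 1, 1, 8, 1, 0.5, 1, 1)
  pk <- find_peaks(curve, map, lod_threshold = 2,
                   min_peak_separation_cM = 11)
  expect_equal(pk$pos_cM, c(10, 60))
  expect_equal(pk$lod, c(5, 8))

  # peaks closer than the suppression radius: only the higher one survives
  curve$lod <- c(0.5, 5, 1, 8, 1, 1, 1, 1, 0.5, 1, 1)
  pk2 <- find_peaks(curve, map, lod_threshold = 2,
                    min_peak_separation_cM = 25)
  expect_equal(pk2$pos_cM, 30)

  # LOD tie breaks to the smaller position
  curve$lod <- c(0.5, 6, 1, 6, 1, 1, 1, 1, 0.5, 1, 1)
  pk3 <- find_peaks(curve, map, lod_threshold = 2,
                    min_peak_separation_cM = 25)
  expect_equal(pk3$pos_cM, 10)
})

test_that("planted QTL are recovered at the nearest markers", {
  map <- five_chrom_map(spacing = 2)
  n <- 210
  geno <- simulate_ril_genotypes(map, n, seed = 41)
  pr <- genotype_probabilities(geno, map)
  set.seed(42)
  # strong single QTL on chromosome 3 at 40 cM (R^2 ~ 0.5)
  x <- pr[, "c3m21"]
  y1 <- 2 * x + rnorm(n, sd = 1)
  names(y1) <- rownames(pr)
  pk <- find_peaks(scan1_hk(pr, y1, map), map, lod_threshold = 2,
                   min_peak_separation_cM = 11)
  pk <- pk[pk$lod == max(pk$lod), ]
  expect_equal(pk$chromosome, "3")
  expect_lt(abs(pk$pos_cM - 40), 2)

  # two unlinked QTLs on different chromosomes: one record each
  y2 <- 2 * pr[, "c1m26"] - 2 * pr[, "c5m26"] + rnorm(n, sd = 1)
  names(y2) <- rownames(pr)
  pk2 <- find_peaks(scan1_hk(pr, y2, map), map, lod_threshold = 2,
                    min_peak_separation_cM = 11)
  # strongest peak per chromosome among the high-LOD calls
  pk2 <- pk2[pk2$lod >= 5, ]
  top <- do.call(rbind, by(pk2, pk2$chromosome,
                           function(d) d[which.max(d$lod), ]))
  expect_true(all(c("1", "5") %in% top$chromosome))
  expect_lt(abs(top$pos_cM[top$chromosome == "1"] - 50), 6)
  expect_lt(abs(top$pos_cM[top$chromosome == "5"] - 50), 6)
  expect_equal(top$slope_sign[top$chromosome == "1"], 1)
  expect_equal(top$slope_sign[top$chromosome == "5"], -1)
})

test_that("scan_all concatenates per-phenotype records deterministically", {
  map <- five_chrom_map(spacing = 10)
  geno <- simulate_ril_genotypes(map, 100, seed = 51)
  pr <- genotype_probabilities(geno, map)
  set.seed(52)
  y <- 2 * pr[, "c2m5"] + rnorm(100, sd = 1)
  tab <- matrix(y, ncol = 1, dimnames = list(rownames(pr), "T1"))

  # identical control and SA tables: identical records, none for delta
  ph <- list(control = tab, SA = tab,
             delta = matrix(0, 100, 1, dimnames = dimnames(tab)))
  rec <- suppressMessages(scan_all(pr, ph, map, pipeline_config()))
  ctrl <- rec[rec$phenotype == "control", c("chromosome", "pos_cM", "lod")]
  sa <- rec[rec$phenotype == "SA", c("chromosome", "pos_cM", "lod")]
  rownames(ctrl) <- rownames(sa) <- NULL
  expect_identical(ctrl, sa)
  expect_equal(sum(rec$phenotype == "delta"), 0)

  # empty phenotype set
  rec0 <- suppressMessages(scan_all(pr, list(), map, pipeline_config()))
  expect_equal(nrow(rec0), 0)

  # disjoint genotypes error
  tab2 <- tab; rownames(tab2) <- paste0("x", rownames(tab))
  expect_error(suppressMessages(
    scan_all(pr, list(control = tab2), map, pipeline_config())),
    "no overlapping genotypes")

  # fast complete-data path agrees with per-transcript scan1_hk
  curve <- scan1_hk(pr, setNames(y, rownames(pr)), map)
  pk <- find_peaks(curve, map, lod_threshold = 2,
                   min_peak_separation_cM = 11)
  expect_equal(ctrl$pos_cM, pk$pos_cM)
  expect_equal(ctrl$lod, pk$lod, tolerance = 1e-12)
})
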
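test_that("make_map lays out evenly spaced markers with terminal markers", {
  m1 <- make_map(10, 5)
  expect_equal(m1$markers$position_cM, c(0, 5, 10))

  m2 <- make_map(c(100, 70, 80, 80, 100), 1)
  expect_equal(nrow(m2$markers), 101 + 71 + 81 + 81 + 101)
  expect_equal(unname(m2$chrom_ends), c(100, 70, 80, 80, 100))

  # dense spacing: floor(100/0.17) interior steps + terminal marker
  m3 <- make_map(100, 0.17)
  expect_equal(nrow(m3$markers), floor(100 / 0.17) + 2)
  expect_true(all(diff(m3$markers$position_cM) > 0))

  expect_error(make_map(10, 20), "exceeds")
  expect_error(make_map(-5, 1), "> 0")
})

test_that("RIL genotypes follow the selfed-RIL recombination law", {
  # zero distance: alleles always identical
  map0 <- genetic_map(data.frame(marker = c("a", "b"), chromosome = "1",
                                 position_cM = c(3, 3)))
  g0 <- simulate_ril_genotypes(map0, 500, seed = 11)
  expect_true(all(g0[, 1] == g0[, 2]))

  # markers on different chromosomes co-inherit at ~1/2
  map_ind <- genetic_map(data.frame(marker = c("a1", "a2", "b1", "b2"),
                                    chromosome = c("1", "1", "2", "2"),
                                    position_cM = c(0, 1, 0, 1)))
  gi <- simulate_ril_genotypes(map_ind, 2000, seed = 12)
  co <- mean(gi[, "a1"] == gi[, "b1"])
  expect_lt(abs(co - 0.5), 3 * sqrt(0.25 / 2000))

  # adjacent markers at 10 cM: recombinant fraction near R = 2r/(1+2r)
  map10 <- genetic_map(data.frame(marker = c("a", "b"), chromosome = "1",
                                  position_cM = c(0, 10)))
  g10 <- simulate_ril_genotypes(map10, 2000, seed = 13)
  R <- ril_recombination(haldane_r(10))
  obs <- mean(g10[, 1] != g10[, 2])
  expect_lt(abs(obs - R), 3 * sqrt(R * (1 - R) / 2000))

  # marginal allele frequency 1/2 at every marker
  freq <- colMeans(g10 == "B")
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 2000)))

  # map expansion: distant loci approach the RIL ceiling R -> 1/2
  map50 <- genetic_map(data.frame(marker = c("a", "b"), chromosome = "1",
                                  position_cM = c(0, 200)))
  g50 <- simulate_ril_genotypes(map50, 2000, seed = 14)
  R200 <- ril_recombination(haldane_r(200))
  expect_gt(R200, 0.49)
  expect_lt(abs(mean(g50[, 1] != g50[, 2]) - R200),
            3 * sqrt(R200 * (1 - R200) / 2000))

  # determinism: identical seed, identical draw
  expect_identical(simulate_ril_genotypes(map10, 50, seed = 5),
                   simulate_ril_genotypes(map10, 50, seed = 5))
})

test_that("plant_architecture builds the requested structures", {
  map <- five_chrom_map()
  # no effects requested
  a0 <- plant_architecture(map, 10, config = list(), seed = 1)
  expect_equal(nrow(a0$effects), 0)

  # one hotspot: all targets share one locus (snapped to the nearest marker)
  a1 <- plant_architecture(map, 300, config = list(
    hotspots = list(list(chromosome = "2", pos_cM = 48, n_targets = 200))),
    seed = 2)
  expect_equal(nrow(a1$effects), 200)
  expect_true(all(a1$effects$chromosome == "2" & a1$effects$pos_cM == 50))
  expect_equal(length(unique(a1$effects$transcript)), 200)

  # opposing pairs: signed effects on each transcript sum to zero
  a2 <- plant_architecture(map, 10, config = list(frac_opposing = 1),
                           seed = 3)
  sums <- tapply(a2$effects$baseline_effect + a2$effects$interaction_effect,
                 a2$effects$transcript, sum)
  expect_equal(as.numeric(sums), rep(0, 10))
  expect_equal(nrow(a2$effects), 20)

  # cis effects sit within the cis window of their transcript
  a3 <- plant_architecture(map, 100, config = list(n_cis = 20), seed = 4)
  expect_true(all(a3$effects$type == "cis"))
  g <- a3$transcripts[match(a3$effects$transcript,
                            a3$transcripts$transcript), ]
  expect_true(all(a3$effects$chromosome == g$chromosome &
                    abs(a3$effects$pos_cM - g$pos_cM) <= 10))
})

test_that("simulate_expression follows the generative formula exactly", {
  map <- tiny_map()
  geno <- matrix(c("A", "A", "A", "B", "B", "B"), 2, 3, byrow = TRUE,
                 dimnames = list(c("L1", "L2"), map$markers$marker))

  # zero noise, zero effects: every sample equals its baseline
  a0 <- plant_architecture(map, 3, config = list(
    noise_sd = 0, replicate_sd = 0, baseline_sd = 0, baseline_mean = 5),
    seed = 1)
  ds0 <- simulate_expression(geno, a0, n_replicates = 2,
                             include_parents = FALSE, seed = 1)
  expect_true(all(ds0$values == 5))

  # single baseline effect of 2: between-genotype difference exactly 2 in
  # both treatments, delta difference 0
  a1 <- plant_architecture(map, 1, config = list(
    noise_sd = 0, replicate_sd = 0, baseline_sd = 0, baseline_mean = 5),
    seed = 1)
  a1$effects <- data.frame(transcript = "T0001", chromosome = "1",
                           pos_cM = 0, type = "cis", baseline_effect = 2,
                           interaction_effect = 0)
  ds1 <- simulate_expression(geno, a1, n_replicates = 1,
                             include_parents = FALSE, seed = 1)
  ph <- phenotype_set(ds1)
  expect_equal(unname(ph$control["L2", ] - ph$control["L1", ]), 2)
  expect_equal(unname(ph$SA["L2", ] - ph$SA["L1", ]), 2)
  expect_equal(unname(ph$delta["L2", ] - ph$delta["L1", ]), 0)

  # generative variance: planted genetic variance + noise variance
  map2 <- genetic_map(data.frame(marker = c("a", "b"), chromosome = "1",
                                 position_cM = c(0, 100)))
  # (two markers 100 cM apart; effect planted at the first)
  g2 <- simulate_ril_genotypes(map2, 2000, seed = 21)
  av <- plant_architecture(map2, 1, config = list(
    noise_sd = 0.5, replicate_sd = 0, baseline_sd = 0), seed = 1)
  av$effects <- data.frame(transcript = "T0001", chromosome = "1",
                           pos_cM = 0, type = "trans", baseline_effect = 2,
                           interaction_effect = 0)
  av$map <- map2
  dsv <- simulate_expression(g2, av, n_replicates = 1,
                             include_parents = FALSE, seed = 22)
  ctrl <- dsv$values[dsv$meta$treatment == "control", 1]
  expected_var <- 2^2 * 0.25 + 0.5^2
  expect_lt(abs(var(ctrl) / expected_var - 1), 0.1)
})

test_that("opposing interaction pair reproduces the transgression mechanism", {
  # two unlinked loci with interaction effects +1 / -1 and zero noise:
  # parental genotypes (AA, BB) share the same SA response; a recombinant
  # carrying A at locus 1 and B at locus 2 is shifted by 1
  map <- genetic_map(data.frame(marker = c("l1a", "l1b", "l2a", "l2b"),
                                chromosome = c("1", "1", "2", "2"),
                                position_cM = c(0, 50, 0, 50)))
  geno <- matrix(c("A", "A", "A", "A",
                   "B", "B", "B", "B",
                   "A", "A", "B", "B",
                   "B", "B", "A", "A"), 4, 4, byrow = TRUE,
                 dimnames = list(c("AA", "BB", "AB", "BA"),
                                 map$markers$marker))
  arch <- plant_architecture(map, 1, config = list(
    noise_sd = 0, replicate_sd = 0, baseline_sd = 0, baseline_mean = 5),
    seed = 1)
  arch$effects <- data.frame(transcript = "T0001",
                             chromosome = c("1", "2"), pos_cM = 0,
                             type = "trans", baseline_effect = 0,
                             interaction_effect = c(1, -1))
  ds <- simulate_expression(geno, arch, n_replicates = 1,
                            include_parents = FALSE, seed = 1)
  ph <- phenotype_set(ds)
  sa_resp <- ph$SA - ph$control
  expect_equal(unname(sa_resp["AA", ]), unname(sa_resp["BB", ]))
  expect_equal(unname(sa_resp["AB", ] - sa_resp["AA", ]), -1)
  expect_equal(unname(sa_resp["BA", ] - sa_resp["AA", ]), 1)
})
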
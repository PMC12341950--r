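test_that("gene positions interpolate linearly between anchors and clamp", {
  anchors <- data.frame(marker = c("a1", "a2", "a3"), chromosome = "1",
                        bp = c(1e6, 2e6, 4e6), cM = c(10, 20, 30))
  genes <- data.frame(transcript = c("t1", "t2", "t3", "t4"),
                      chromosome = "1",
                      bp = c(1e6, 1.5e6, 3e6, 5e6))
  res <- suppressWarnings(interpolate_gene_positions(genes, anchors))
  expect_equal(res$pos_cM, c(10, 15, 25, 30))
  expect_warning(interpolate_gene_positions(genes, anchors), "clamped")

  genes_bad <- data.frame(transcript = "tX", chromosome = "9", bp = 1)
  expect_error(interpolate_gene_positions(genes_bad, anchors),
               "without anchors.*tX")
})

test_that("cis/trans labels respect the inclusive distance window", {
  gp <- data.frame(transcript = "t1", chromosome = "1", pos_cM = 30)
  rec <- data.frame(transcript = "t1",
                    chromosome = c("1", "2", "1", "1"),
                    pos_cM = c(39.9, 30, 40.0, 40.1))
  lab <- classify_cis_trans(rec, gp, window = 10)$cis_trans
  expect_equal(lab, c("cis", "trans", "cis", "trans"))

  # unknown gene position: unplaced
  rec2 <- data.frame(transcript = "t9", chromosome = "1", pos_cM = 30)
  expect_equal(classify_cis_trans(rec2, gp, window = 10)$cis_trans,
               "unplaced")
})

test_that("cross-phenotype merging reproduces the worked examples", {
  # SA @ 40 and delta @ 45 on one chromosome merge at the mean position
  rec <- data.frame(transcript = "t1", phenotype = c("SA", "delta"),
                    chromosome = "3", pos_cM = c(40, 45), lod = c(4, 3))
  mg <- merge_across_phenotypes(rec, window = 5.5)
  expect_equal(nrow(mg$merged), 1)
  expect_equal(mg$merged$consensus_cM, 42.5)
  expect_equal(mg$merged$membership, "SA,delta")

  # 6 cM apart: two separate eQTL
  rec2 <- rec; rec2$pos_cM <- c(40, 46)
  mg2 <- merge_across_phenotypes(rec2, window = 5.5)
  expect_equal(nrow(mg2$merged), 2)

  # chained 0/5/10: single-linkage joins all three, consensus 5
  rec3 <- data.frame(transcript = "t1",
                     phenotype = c("control", "SA", "delta"),
                     chromosome = "1", pos_cM = c(0, 5, 10), lod = 3)
  mg3 <- merge_across_phenotypes(rec3, window = 5.5)
  expect_equal(nrow(mg3$merged), 1)
  expect_equal(mg3$merged$consensus_cM, 5)
  expect_equal(mg3$merged$n_members, 3L)
})

test_that("merging is order-invariant and partitions the records", {
  set.seed(60)
  rec <- data.frame(
    transcript = sample(c("t1", "t2"), 12, replace = TRUE),
    phenotype = sample(c("control", "SA", "delta"), 12, replace = TRUE),
    chromosome = sample(c("1", "2"), 12, replace = TRUE),
    pos_cM = round(runif(12, 0, 60), 1),
    lod = round(runif(12, 2, 9), 2))
  mg <- merge_across_phenotypes(rec, window = 5.5)
  for (i in 1:5) {
    perm <- sample(nrow(rec))
    mgp <- merge_across_phenotypes(rec[perm, ], window = 5.5)
    expect_equal(mgp$merged[, c("transcript", "chromosome", "consensus_cM",
                                "membership", "n_members")],
                 mg$merged[, c("transcript", "chromosome", "consensus_cM",
                               "membership", "n_members")])
  }
  # every record lands in exactly one merged eQTL
  expect_equal(nrow(mg$members), nrow(rec))
  expect_equal(sum(mg$merged$n_members), nrow(rec))

  # a phenotype contributing two records keeps the higher LOD, the other
  # re-clusters on its own
  rec_dup <- data.frame(transcript = "t1", phenotype = "SA",
                        chromosome = "1", pos_cM = c(10, 14),
                        lod = c(3, 7))
  mgd <- merge_across_phenotypes(rec_dup, window = 5.5)
  expect_equal(nrow(mgd$merged), 2)
  expect_equal(mgd$merged$consensus_cM[mgd$merged$lod_max == 7], 14)
})

test_that("effect sizes satisfy the LOD identity and edge cases", {
  map <- five_chrom_map(spacing = 5)
  n <- 210
  geno <- simulate_ril_genotypes(map, n, seed = 61)
  pr <- genotype_probabilities(geno, map)
  set.seed(62)
  y <- 1.5 * pr[, "c2m10"] + rnorm(n, sd = 1)
  tab <- matrix(y, ncol = 1, dimnames = list(rownames(pr), "T1"))
  ph <- list(control = tab, SA = tab,
             delta = matrix(rnorm(n), ncol = 1, dimnames = dimnames(tab)))
  rec <- suppressMessages(scan_all(pr, ph, map, pipeline_config()))
  mg <- merge_across_phenotypes(rec, window = 5.5)
  res <- effect_size(mg$merged, pr, ph, map)
  # identity: R^2 = 1 - 10^(-2 LOD / n) at the same marker
  for (i in seq_len(nrow(res))) {
    members <- mg$members[mg$members$merge_id == res$merge_id[i], ]
    at_marker <- members[abs(members$pos_cM - res$consensus_cM[i]) < 1e-9, ]
    if (nrow(at_marker) == 1) {
      expect_equal(res[[paste0("r2_", at_marker$phenotype)]][i],
                   1 - 10^(-2 * at_marker$lod / n), tolerance = 1e-9)
    }
  }

  # phenotype exactly equal to dosage: R^2 = 1
  tab_x <- matrix(pr[, "c2m10"], ncol = 1,
                  dimnames = list(rownames(pr), "T1"))
  m1 <- data.frame(merge_id = "M1", transcript = "T1", chromosome = "2",
                   consensus_cM = 45, membership = "control",
                   n_members = 1L, lod_max = 50)
  suppressWarnings(r1 <- effect_size(m1, pr, list(control = tab_x), map))
  expect_equal(r1$r2_control, 1, tolerance = 1e-12)

  # zero phenotype variance: R^2 = 0 with flag
  tab_c <- matrix(1, n, 1, dimnames = list(rownames(pr), "T1"))
  r2 <- effect_size(m1, pr, list(control = tab_c), map)
  expect_equal(r2$r2_control, 0)
  expect_true(r2$r2_flagged)
})

test_that("permuted phenotypes give R^2 near the null expectation 1/(n-1)", {
  map <- five_chrom_map(spacing = 20)
  n <- 210
  geno <- simulate_ril_genotypes(map, n, seed = 63)
  pr <- genotype_probabilities(geno, map)
  set.seed(64)
  x <- pr[, 10]
  r2s <- replicate(400, summary(lm(sample(rnorm(n)) ~ x))$r.squared)
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * sd(r2s) / sqrt(400))
})

test_that("paralog and hotspot-region annotation follows the windows", {
  merged <- data.frame(
    merge_id = c("M1", "M2", "M3"), transcript = c("t1", "t2", "t3"),
    chromosome = c("2", "2", "5"), consensus_cM = c(50, 50, 30),
    membership = "SA", n_members = 1L, lod_max = 5,
    cis_trans = c("trans", "trans", "trans"))
  paralogs <- data.frame(transcript = c("t1", "t1"),
                         accession = c("Bay-0", "Col-0"),
                         paralog_chromosome = c("2", "1"),
                         paralog_cM = c(58, 20))
  regions <- data.frame(chromosome = "5", start_cM = 33, end_cM = 40)
  ann <- annotate_paralogs(merged, paralogs, regions,
                           paralog_window_cM = 10, membership_window_cM = 5)
  expect_true(ann$paralog_flag[1])           # paralog at 58, |58-50| <= 10
  expect_false(ann$paralog_flag[2])          # no paralogs listed for t2
  expect_equal(ann$n_paralogs[1], "Bay-0:1,Col-0:1")
  expect_true(ann$hotspot_flag[3])           # distance 3 to [33,40] <= 5
  expect_false(ann$hotspot_flag[1])

  # cis eQTL never get the paralog flag
  merged_cis <- merged; merged_cis$cis_trans <- "cis"
  ann2 <- annotate_paralogs(merged_cis, paralogs, regions)
  expect_false(any(ann2$paralog_flag))
})

test_that("cis/trans summaries count per phenotype and membership subset", {
  merged <- data.frame(
    merge_id = sprintf("M%d", 1:4),
    transcript = c("t1", "t2", "t3", "t4"),
    chromosome = "1", consensus_cM = 10,
    membership = c("SA", "SA", "SA", "SA"),
    n_members = 1L, lod_max = 5,
    cis_trans = c("trans", "trans", "trans", "cis"))
  s <- summarize_cis_trans(merged)
  sa_row <- s$per_phenotype[s$per_phenotype$phenotype == "SA", ]
  expect_equal(sa_row$prop_trans, 0.75)
  expect_equal(s$per_phenotype[s$per_phenotype$phenotype == "delta",
                               "n_trans"], 0)
  expect_equal(s$per_membership$membership, "SA")
  expect_equal(unname(s$per_transcript["trans"]), 3 / 4)
})
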
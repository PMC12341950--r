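# shared in-code fixtures; everything is generated, nothing read from disk

tiny_map <- function() {
  genetic_map(data.frame(
    marker = c("m1", "m2", "m3"),
    chromosome = "1",
    position_cM = c(0, 5, 10)))
}

five_chrom_map <- function(spacing = 5) {
  make_map(c(`1` = 100, `2` = 70, `3` = 80, `4` = 80, `5` = 100),
           marker_spacing = spacing)
}

write_map_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# minimal 2-genotype x 2-treatment x 2-replicate dataset from explicit values
tiny_dataset <- function(values_by_cell) {
  meta <- expand.grid(genotype = c("g1", "g2"),
                      treatment = c("control", "SA"),
                      replicate = c("rep1", "rep2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_%s", meta$genotype, meta$treatment,
                         meta$replicate)
  vals <- vapply(seq_len(nrow(meta)), function(i) {
    values_by_cell(meta$genotype[i], meta$treatment[i], meta$replicate[i])
  }, numeric(1))
  m <- matrix(vals, ncol = 1, dimnames = list(meta$sample, "T1"))
  expression_dataset(m, meta)
}

# balanced-design type III oracle: for a fully balanced factorial the type
# III SS equal the classical closed-form main-effect / interaction SS
balanced_anova_oracle <- function(y, genotype, treatment, replicate) {
  grand <- mean(y)
  ss_main <- function(f) {
    m <- tapply(y, f, mean)
    n <- table(f)
    sum(n * (m - grand)^2)
  }
  ss_g <- ss_main(genotype)
  ss_t <- ss_main(treatment)
  ss_r <- ss_main(replicate)
  cell <- tapply(y, list(genotype, treatment), mean)
  mg <- tapply(y, genotype, mean)
  mt <- tapply(y, treatment, mean)
  n_cell <- table(genotype, treatment)
  dev <- sweep(sweep(cell, 1, mg - grand), 2, mt - grand) - grand
  ss_gt <- sum(n_cell * dev^2)
  tss <- sum((y - grand)^2)
  list(SS_replicate = ss_r, SS_genotype = ss_g, SS_treatment = ss_t,
       SS_GxT = ss_gt, SS_residual = tss - ss_r - ss_g - ss_t - ss_gt,
       SS_total = tss)
}

# dosage matrix straight from a genotype matrix with no missing data
dosage_of <- function(geno) {
  d <- matrix(0, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  d[geno == "B"] <- 1
  d
}
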
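test_that("spearman_assoc matches the brute-force rank oracle", {
  d <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  y <- c(1.2, 0.8, 2.1, 1.9, 3.3, 3.0, 1.1, 2.0, 3.1, 1.8)
  got <- spearman_assoc(d, y)
  expect_equal(got$rho, oracle_spearman(d, y), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    d <- sample(0:2, 30, replace = TRUE)
    y <- rnorm(30) + d * 0.3
    expect_equal(spearman_assoc(d, y)$rho, oracle_spearman(d, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman_assoc handles monotone, skip and symmetry cases", {
  d <- rep(0:2, each = 4)
  y <- d * 2  # monotone in dosage, tied within genotype class
  expect_equal(spearman_assoc(d, y)$rho, 1)
  expect_equal(spearman_assoc(d, rep(1, 12))$skip_reason, "constant_trait")
  expect_equal(spearman_assoc(rep(1, 12), rnorm(12))$skip_reason,
               "single_genotype_class")
  expect_equal(spearman_assoc(d[1:6], y[1:6])$skip_reason, "too_few_samples")
  # negating dosage flips the sign but not the magnitude
  set.seed(32)
  d <- sample(0:2, 40, replace = TRUE); y <- rnorm(40) + d
  expect_equal(spearman_assoc(2 - d, y)$rho, -spearman_assoc(d, y)$rho,
               tolerance = 1e-12)
})

test_that("weighted-Z meta-analysis closed forms hold", {
  expect_equal(meta_weighted_z(2.0, 50)$meta_z, 2.0)
  expect_equal(meta_weighted_z(c(1, 1), c(80, 80))$meta_z, sqrt(2),
               tolerance = 1e-12)
  expect_equal(meta_weighted_z(c(2, -2), c(80, 80))$meta_z, 0)
  # invariant to cohort order
  expect_equal(meta_weighted_z(c(1.2, -0.4), c(90, 40))$meta_z,
               meta_weighted_z(c(-0.4, 1.2), c(40, 90))$meta_z)
  expect_error(meta_weighted_z(c(1, 2), 50), "length")
  expect_error(meta_weighted_z(NA_real_, 50), "valid")
})

test_that("permutation FDR reproduces the counting formula on a toy set", {
  obs <- c(f1 = 5.0, f2 = 4.0, f3 = 3.0, f4 = 2.0, f5 = 1.0)
  nulls <- rbind(c(4.5, 2.5, 1.5, 0.5, 0.2),
                 c(3.5, 2.8, 1.2, 0.8, 0.1))
  got <- permutation_fdr(obs, nulls, alpha = 0.25)
  # hand computation: FDR(t) = mean_b #{null_b >= t} / #{obs >= t}
  hand <- sapply(obs, function(t) {
    mean(c(sum(nulls[1, ] >= t), sum(nulls[2, ] >= t))) / sum(obs >= t)
  })
  expect_equal(got$fdr, unname(pmin(1, hand)))
  expect_equal(got$fdr[1], 0)            # no null reaches 5.0
  expect_equal(got$fdr[5], (3 / 1) / 5)  # 3 null tails on average, 5 observed
  # degenerate: null identical to observed -> FDR ~ 1 everywhere
  sat <- permutation_fdr(obs, rbind(obs), alpha = 0.05)
  expect_true(all(sat$fdr == 1))
  expect_error(permutation_fdr(obs, nulls[0, , drop = FALSE]), "permutation")
})

test_that("cis QTL mapping is deterministic and recovers planted eQTLs", {
  sim <- small_sim(seed = 33, fraction_eqtl = 0.2, fraction_meqtl = 0,
                   fraction_eqtm = 0)
  r1 <- map_cis_qtl(sim$genotypes, sim$expression, sim$sample_sheet,
                    n_perm = 5, seed = 99)
  r2 <- map_cis_qtl(sim$genotypes, sim$expression, sim$sample_sheet,
                    n_perm = 5, seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  truth <- subset(sim$truth, effect_kind == "eqtl")
  sig <- unique(r1$feature_id[r1$significant])
  expect_gt(mean(truth$right_id %in% sig), 0.8)
  # recovered planted pairs never flip sign
  hits <- merge(as.data.frame(r1[r1$significant, ]),
                truth, by.x = c("snp_id", "feature_id"),
                by.y = c("left_id", "right_id"))
  expect_true(all(sign(hits$meta_z) == sign(hits$true_slope)))
  # exactly one top pair per feature
  tops <- tapply(r1$is_top, r1$feature_id, sum)
  expect_true(all(tops == 1))
})

test_that("significant set is monotone in alpha", {
  sim <- small_sim(seed = 34, fraction_eqtl = 0.15)
  r_strict <- map_cis_qtl(sim$genotypes, sim$expression, sim$sample_sheet,
                          n_perm = 5, alpha = 0.01, seed = 7)
  r_loose <- map_cis_qtl(sim$genotypes, sim$expression, sim$sample_sheet,
                         n_perm = 5, alpha = 0.10, seed = 7)
  expect_true(all(r_strict$feature_id[r_strict$significant] %in%
                    r_loose$feature_id[r_loose$significant]))
})

test_that("meQTL mode drops SNP-in-probe pairs and maps planted meQTLs", {
  sim <- small_sim(seed = 35, fraction_meqtl = 0.2, fraction_eqtl = 0,
                   fraction_eqtm = 0)
  r <- map_cis_qtl(sim$genotypes, sim$methylation, sim$sample_sheet,
                   mode = "meqtl", n_perm = 5, seed = 1)
  ann <- sim$methylation$annotation
  spos <- sim$genotypes$annotation$pos[
    match(r$snp_id, sim$genotypes$annotation$snp_id)]
  ps <- ann$probe_start[match(r$feature_id, ann$cpg_id)]
  pe <- ann$probe_end[match(r$feature_id, ann$cpg_id)]
  expect_true(all(spos < ps | spos > pe))
  truth <- subset(sim$truth, effect_kind == "meqtl")
  sig <- unique(r$feature_id[r$significant])
  expect_gt(mean(truth$right_id %in% sig), 0.7)
})

test_that("eQTL/meQTL overlap recovers the planted opposite-direction fraction", {
  sim <- small_sim(seed = 36, n_snps = 300, n_cpgs = 300, n_probes = 200,
                   fraction_meqtl = 0.5, fraction_eqtl = 0.4,
                   fraction_shared_snp = 0.9, fraction_opposite = 0.7,
                   fraction_eqtm = 0)
  eq <- map_cis_qtl(sim$genotypes, sim$expression, sim$sample_sheet,
                    n_perm = 5, seed = 2)
  mq <- map_cis_qtl(sim$genotypes, sim$methylation, sim$sample_sheet,
                    mode = "meqtl", n_perm = 5, seed = 3)
  ov <- overlap_eqtl_meqtl(eq, mq, sim$methylation$annotation)
  expect_gt(nrow(ov), 20)
  smry <- overlap_direction_summary(ov)
  # planted truth: shared SNP effects, opposite w.p. 0.7
  truth_eq <- subset(sim$truth, effect_kind == "eqtl")
  truth_mq <- subset(sim$truth, effect_kind == "meqtl")
  shared <- merge(truth_eq, truth_mq, by = "left_id")
  n_sh <- nrow(shared)
  planted_frac <- mean(shared$direction.x != shared$direction.y)
  ci <- qbinom(c(0.025, 0.975), n_sh, 0.7) / n_sh
  expect_gte(planted_frac, ci[1]); expect_lte(planted_frac, ci[2])
  # recovered gene-level fraction within binomial bounds of the planted 0.7
  decided <- smry$gene_summary$gene_class != "mixed"
  n_g <- sum(decided)
  cig <- qbinom(c(0.005, 0.995), n_g, 0.7) / n_g
  expect_gte(smry$fraction_opposite_genes, cig[1])
  expect_lte(smry$fraction_opposite_genes, cig[2])
  # toy definitional case
  eq1 <- tibble::tibble(snp_id = "rs1", feature_id = "p1", gene = "G",
                        meta_z = 3, significant = TRUE)
  mq1 <- tibble::tibble(snp_id = "rs1", feature_id = "c1",
                        meta_z = -3, significant = TRUE)
  ov1 <- overlap_eqtl_meqtl(eq1, mq1,
                            tibble::tibble(cpg_id = "c1", gene = "G",
                                           cgi_relation = "island"))
  expect_equal(ov1$direction_class, "opposite")
  # empty input
  expect_equal(nrow(overlap_eqtl_meqtl(eq1[0, ], mq1,
                                       tibble::tibble(cpg_id = "c1",
                                                      gene = "G",
                                                      cgi_relation = "island"))),
               0)
})

test_that("mapping errors when no cohort overlaps genotypes and traits", {
  sim <- small_sim(seed = 37)
  geno <- sim$genotypes
  colnames(geno$values) <- paste0("x_", colnames(geno$values))
  expect_error(map_cis_qtl(geno, sim$expression, sim$sample_sheet),
               "no cohort")
})
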
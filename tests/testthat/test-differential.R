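make_meth <- function(betas, cgi = "other") {
  ann <- tibble::tibble(cpg_id = rownames(betas), chrom = "chr1",
                        pos = seq_len(nrow(betas)),
                        cgi_relation = rep_len(cgi, nrow(betas)))
  methylation_matrix(betas, ann)
}

test_that("beta difference is fetal minus adult and the null is quiet", {
  set.seed(21)
  n <- 12
  grp <- rep(c("fetal", "adult"), each = n)
  betas <- rbind(
    shifted = pmin(pmax(c(rnorm(n, 0.84, 0.03), rnorm(n, 0.36, 0.03)), 0), 1),
    flat = rep(0.5, 2 * n))
  colnames(betas) <- paste0("s", seq_len(2 * n))
  dm <- suppressWarnings(diff_methylation(make_meth(betas), grp))
  expect_equal(dm$effect[dm$feature_id == "shifted"], 0.48, tolerance = 0.05)
  expect_equal(dm$direction[dm$feature_id == "shifted"], "up_in_fetal")
  expect_equal(dm$effect[dm$feature_id == "flat"], 0)
  expect_false(dm$significant[dm$feature_id == "flat"])
})

test_that("BH q-values match an independent step-up implementation", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  set.seed(22)
  p2 <- runif(200)
  expect_equal(p.adjust(p2, "BH"), oracle_bh(p2), tolerance = 1e-12)
})

test_that("planted expression shifts are recovered and dual-thresholded", {
  cfg <- sim_config(design = data.frame(cohort = "A",
                                        group = c("fetal", "adult"),
                                        tissue = "liver", n = c(20, 20)),
                    n_snps = 20, n_cpgs = 20, n_probes = 55,
                    fraction_eqtl = 0, fraction_eqtm = 0, fraction_meqtl = 0,
                    fraction_dm = 0, fraction_de = 5 / 55, de_log2fc = 3,
                    seed = 23)
  sim <- simulate_study(cfg)
  de <- diff_expression(sim$expression, sim$sample_sheet)
  planted <- subset(sim$truth, effect_kind == "diff_expr")
  got <- de[match(planted$right_id, de$feature_id), ]
  expect_true(all(got$significant))
  expect_equal(abs(got$effect), rep(3, nrow(got)), tolerance = 1.2)
  # survivor set equals an independent filter pass on the same statistics
  manual <- de$feature_id[de$fdr_q < 0.05 & abs(de$effect) > 1]
  expect_setequal(de$feature_id[de$significant], manual)
})

test_that("significance is monotone in thresholds and alpha", {
  cfgf <- sim_config(design = data.frame(cohort = "A",
                                         group = c("fetal", "adult"),
                                         tissue = "liver", n = c(15, 25)),
                     n_snps = 50, n_cpgs = 120, n_probes = 40,
                     fraction_dm = 0.2, seed = 25)
  simf <- simulate_study(cfgf)
  strict <- diff_methylation(simf$methylation, simf$sample_sheet,
                             delta_threshold = 0.3, alpha = 0.01)
  loose <- diff_methylation(simf$methylation, simf$sample_sheet,
                            delta_threshold = 0.2, alpha = 0.05)
  expect_true(all(strict$feature_id[strict$significant] %in%
                    loose$feature_id[loose$significant]))
  # q-values invariant to input order
  perm <- sample(nrow(simf$methylation$values))
  shuf <- methylation_matrix(simf$methylation$values[perm, ],
                             simf$methylation$annotation[perm, ])
  dm1 <- diff_methylation(simf$methylation, simf$sample_sheet)
  dm2 <- diff_methylation(shuf, simf$sample_sheet)
  expect_equal(dm2$fdr_q[match(dm1$feature_id, dm2$feature_id)], dm1$fdr_q)
})

test_that("contingency statistic equals the closed-form chi-squared", {
  counts <- rbind(hypo = c(80, 30, 10, 40), hyper = c(12, 28, 9, 41))
  colnames(counts) <- c("island", "shore", "shelf", "other")
  expect_equal(unname(suppressWarnings(
    chisq.test(counts, correct = FALSE)$statistic)),
    oracle_chisq(counts), tolerance = 1e-10)
  # through the package path with a constructed DM result
  dm <- tibble::tibble(
    feature_id = sprintf("cg%03d", 1:250),
    effect = c(rep(-0.5, 160), rep(0.5, 90)),
    raw_p = 1e-6, fdr_q = 1e-5, significant = TRUE,
    direction = ifelse(c(rep(-0.5, 160), rep(0.5, 90)) >= 0,
                       "up_in_fetal", "down_in_fetal"))
  ann <- tibble::tibble(
    cpg_id = dm$feature_id,
    cgi_relation = c(rep("island", 92), rep("shore", 58), rep("shelf", 19),
                     rep("other", 81)))
  res <- cgi_direction_contingency(dm, ann)
  expect_equal(res$statistic, oracle_chisq(res$counts), tolerance = 1e-10)
  expect_equal(sum(res$counts), 250)
})

test_that("degenerate one-direction table reports fractions but no statistic", {
  dm <- tibble::tibble(feature_id = c("cg1", "cg2"), effect = c(-0.4, -0.3),
                       raw_p = 1e-5, fdr_q = 1e-4, significant = TRUE,
                       direction = "down_in_fetal")
  ann <- tibble::tibble(cpg_id = c("cg1", "cg2"),
                        cgi_relation = c("island", "shore"))
  res <- cgi_direction_contingency(dm, ann)
  expect_true(is.na(res$statistic))
  occupied <- res$hypo_fraction$n > 0
  expect_true(all(res$hypo_fraction$hypo_fraction[occupied] == 1))
})

test_that("island CpGs planted as fetal-hypomethylated dominate the island class", {
  cfg <- sim_config(design = data.frame(cohort = "A",
                                        group = c("fetal", "adult"),
                                        tissue = "liver", n = c(14, 40)),
                    n_snps = 50, n_cpgs = 400, n_probes = 40,
                    fraction_dm = 0.3, island_hypo_fetal = 0.86,
                    other_hypo_fetal = 0.5, seed = 26)
  sim <- simulate_study(cfg)
  dm <- diff_methylation(sim$methylation, sim$sample_sheet)
  res <- cgi_direction_contingency(dm, sim$methylation$annotation)
  hf <- res$hypo_fraction
  island <- hf$hypo_fraction[hf$cgi_relation == "island"]
  non_island <- sum(res$counts["hypo_in_fetal", -1]) /
    sum(res$counts[, -1])
  expect_gt(island, non_island)
  expect_gt(island, 0.7)
})

test_that("DE/DM gene intersection classifies directions and flags discordance", {
  de <- tibble::tibble(
    feature_id = c("p1", "p2a", "p2b", "p3", "p4"),
    effect = c(2, 1.5, -1.5, -2, 2), raw_p = 1e-6, fdr_q = 1e-5,
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    direction = ifelse(c(2, 1.5, -1.5, -2, 2) >= 0, "up_in_fetal",
                       "down_in_fetal"))
  dm <- tibble::tibble(
    feature_id = c("c1", "c2", "c3", "c5"),
    effect = c(-0.3, 0.4, -0.5, 0.3), raw_p = 1e-6, fdr_q = 1e-5,
    significant = TRUE,
    direction = ifelse(c(-0.3, 0.4, -0.5, 0.3) >= 0, "up_in_fetal",
                       "down_in_fetal"))
  probe_ann <- tibble::tibble(probe_id = c("p1", "p2a", "p2b", "p3", "p4"),
                              gene = c("G1", "G2", "G2", "G3", "G5"))
  cpg_ann <- tibble::tibble(cpg_id = c("c1", "c2", "c3", "c5"),
                            gene = c("G1", "G2", "G3", "G5"))
  got <- intersect_de_dm(de, dm, probe_ann, cpg_ann)
  expect_setequal(got$gene, c("G1", "G2", "G3"))  # G5 has no significant DE
  expect_equal(got$expr_direction[got$gene == "G2"], "discordant")
  expect_true(got$discordant[got$gene == "G2"])
  expect_equal(got$expr_direction[got$gene == "G1"], "up_in_fetal")
  expect_equal(got$meth_direction[got$gene == "G1"], "down_in_fetal")
  # direction classes partition the intersection
  expect_equal(sum(got$expr_direction %in%
                     c("up_in_fetal", "down_in_fetal", "discordant")),
               nrow(got))
  # disjoint universes -> empty
  empty <- intersect_de_dm(de, dm, probe_ann,
                           tibble::tibble(cpg_id = c("c1", "c2", "c3", "c5"),
                                          gene = paste0("X", 1:4)))
  expect_equal(nrow(empty), 0)
})
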
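test_that("cis pair enumeration matches a brute-force double loop", {
  set.seed(1)
  snps <- tibble::tibble(snp_id = sprintf("rs%02d", 1:10), chrom = "chr1",
                         pos = sort(sample.int(2e6, 10)))
  cpgs <- tibble::tibble(cpg_id = sprintf("cg%02d", 1:10), chrom = "chr1",
                         pos = sort(sample.int(2e6, 10)))
  win <- 250000
  got <- enumerate_cis_pairs(snps, cpgs, win)
  # brute force over all 100 combinations
  expected <- list()
  for (i in 1:10) for (j in 1:10) {
    d <- cpgs$pos[j] - snps$pos[i]
    if (abs(d) <= win) {
      expected[[length(expected) + 1]] <-
        data.frame(left_id = snps$snp_id[i], right_id = cpgs$cpg_id[j],
                   distance_bp = d)
    }
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected$left_id, expected$right_id), ]
  expect_equal(got$left_id, expected$left_id)
  expect_equal(got$right_id, expected$right_id)
  expect_equal(got$distance_bp, expected$distance_bp)
})

test_that("cis window bound is inclusive and zero distance is kept", {
  left <- tibble::tibble(snp_id = "rs1", chrom = "chr1", pos = 100000L)
  right <- tibble::tibble(cpg_id = c("cg_at", "cg_edge", "cg_far"),
                          chrom = "chr1",
                          pos = c(100000L, 350000L, 350001L))
  got <- enumerate_cis_pairs(left, right, 250000)
  expect_setequal(got$right_id, c("cg_at", "cg_edge"))
  expect_equal(got$distance_bp[got$right_id == "cg_at"], 0L)
  expect_equal(got$distance_bp[got$right_id == "cg_edge"], 250000L)
})

test_that("probe anchors use the interval midpoint and unordered pairs are symmetric", {
  probes <- tibble::tibble(probe_id = "p1", chrom = "chr1",
                           probe_start = 1000L, probe_end = 1049L)
  cpgs <- tibble::tibble(cpg_id = "cg1", chrom = "chr1", pos = 900L)
  fwd <- enumerate_cis_pairs(cpgs, probes, 250000)
  expect_equal(fwd$distance_bp, 1024L - 900L)  # floor((1000+1049)/2) - 900
  rev <- enumerate_cis_pairs(probes, cpgs, 250000)
  expect_equal(rev$distance_bp, -fwd$distance_bp)
  expect_equal(nrow(fwd), nrow(rev))
})

test_that("unknown chromosome labels error, empty inputs do not", {
  snps <- tibble::tibble(snp_id = "rs1", chrom = "chrX", pos = 1L)
  cpgs <- tibble::tibble(cpg_id = "cg1", chrom = "chr1", pos = 1L)
  expect_error(enumerate_cis_pairs(snps, cpgs, 1000, chromosomes = "chr1"),
               "chrX")
  expect_equal(nrow(enumerate_cis_pairs(snps[0, ], cpgs, 1000)), 0)
})

test_that("SNP-in-probe conflicts are removed by interval membership", {
  set.seed(7)
  snps <- tibble::tibble(snp_id = sprintf("rs%02d", 1:20), chrom = "chr1",
                         pos = sample.int(5000, 20))
  cpgs <- tibble::tibble(cpg_id = sprintf("cg%02d", 1:20), chrom = "chr1",
                         pos = sample.int(5000, 20))
  cpgs$probe_start <- cpgs$pos
  cpgs$probe_end <- cpgs$pos + 49L
  # place 6 SNPs inside 6 distinct probe intervals (others may conflict by
  # chance; the brute-force scan below is the reference either way)
  snps$pos[1:6] <- cpgs$probe_start[1:6] + 10L
  pairs <- enumerate_cis_pairs(snps, cpgs, 250000)
  kept <- exclude_probe_snp_conflicts(pairs, snps, cpgs)
  removed <- attr(kept, "removed")
  # independent interval scan
  manual <- mapply(function(l, r) {
    p <- snps$pos[match(l, snps$snp_id)]
    p >= cpgs$probe_start[match(r, cpgs$cpg_id)] &
      p <= cpgs$probe_end[match(r, cpgs$cpg_id)]
  }, pairs$left_id, pairs$right_id)
  expect_equal(nrow(removed), sum(manual))
  expect_equal(nrow(kept), sum(!manual))
  expect_true(all(sprintf("rs%02d", 1:6) %in% removed$left_id))
  # boundary: SNP 1 bp outside is retained
  b_snp <- tibble::tibble(snp_id = "rsb", chrom = "chr1",
                          pos = cpgs$probe_end[7] + 1L)
  b_pairs <- enumerate_cis_pairs(b_snp, cpgs[7, ], 250000)
  expect_equal(nrow(exclude_probe_snp_conflicts(b_pairs, b_snp, cpgs)), 1)
  # unknown probe errors
  bad <- pairs
  bad$right_id[1] <- "cg_unknown"
  expect_error(exclude_probe_snp_conflicts(bad, snps, cpgs), "unknown probe")
})

test_that("variable-CpG filter equals direct SD computation and is idempotent", {
  set.seed(3)
  n_cpg <- 100
  betas <- matrix(stats::runif(n_cpg * 30), n_cpg, 30,
                  dimnames = list(sprintf("cg%03d", 1:n_cpg), sprintf("s%02d", 1:30)))
  betas[5, ] <- 0.5                     # constant row
  betas[6, ] <- 0.5 + rep(c(-0.005, 0.005), 15)  # tiny variance
  ann <- tibble::tibble(cpg_id = rownames(betas), chrom = "chr1",
                        pos = seq_len(n_cpg), cgi_relation = "other")
  m <- methylation_matrix(betas, ann)
  sds <- apply(betas, 1, sd)
  for (thr in c(0, 0.02, 0.1)) {
    got <- suppressMessages(filter_variable_cpgs(m, thr))
    expect_setequal(rownames(got$values), rownames(betas)[sds >= thr])
  }
  expect_false("cg005" %in%
                 rownames(suppressMessages(filter_variable_cpgs(m, 1e-9))$values))
  once <- suppressMessages(filter_variable_cpgs(m, 0.02))
  twice <- suppressMessages(filter_variable_cpgs(once, 0.02))
  expect_identical(rownames(once$values), rownames(twice$values))
})

test_that("SNP QC matches an independent per-SNP recomputation", {
  set.seed(11)
  n_snp <- 200; n <- 120
  maf <- runif(n_snp, 0.01, 0.5)
  d <- t(vapply(maf, function(p) rbinom(n, 2, p), numeric(n)))
  d[sample(length(d), 400)] <- NA
  d[1, ] <- 0  # monomorphic
  dimnames(d) <- list(sprintf("rs%03d", 1:n_snp), sprintf("s%03d", 1:n))
  ann <- tibble::tibble(snp_id = rownames(d), chrom = "chr1",
                        pos = seq_len(n_snp), effect_allele = "A",
                        other_allele = "G")
  g <- genotype_matrix(d, ann)
  got <- suppressMessages(filter_snps(g, maf_min = 0.05, hwe_alpha = 1e-3,
                                      max_missing = 0.04))
  keep_manual <- vapply(seq_len(n_snp), function(i) {
    x <- d[i, ]; x <- x[!is.na(x)]
    p <- mean(x) / 2; maf_i <- min(p, 1 - p)
    hp <- hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
    miss <- mean(is.na(d[i, ]))
    !is.nan(maf_i) && maf_i >= 0.05 && hp >= 1e-3 && miss <= 0.04
  }, logical(1))
  expect_setequal(rownames(got$values), rownames(d)[keep_manual])
  expect_false("rs001" %in% rownames(got$values))
  # idempotence
  again <- suppressMessages(filter_snps(got, 0.05, 1e-3, 0.04))
  expect_identical(rownames(again$values), rownames(got$values))
})

test_that("HWE exact test is sane at perfect proportions and extremes", {
  # counts (25, 50, 25): exactly HWE, p should be large
  expect_gt(hwe_exact_p(25, 50, 25), 0.5)
  # grossly distorted: all hets
  expect_lt(hwe_exact_p(0, 100, 0), 1e-6)
  # agrees with chi-squared asymptotics for large balanced samples
  p_exact <- hwe_exact_p(360, 480, 160)
  tab_chi <- local({
    n <- 1000; p <- (2 * 360 + 480) / 2000
    e <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * n
    stats::pchisq(sum((c(360, 480, 160) - e)^2 / e), df = 1,
                  lower.tail = FALSE)
  })
  expect_equal(p_exact, tab_chi, tolerance = 0.25)
  expect_equal(hwe_exact_p(50, 0, 0), 1)
})

test_that("matrix TSV round-trips ids and values", {
  set.seed(5)
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
  m[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read_matrix_tsv(path)
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_equal(back, m, tolerance = 1e-12)
})

test_that("VCF genotypes read as ALT dosage", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t0/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes_vcf(path)
  expect_equal(unname(g$values["rs1", ]), c(0, 1, 2))
  expect_equal(unname(g$values["rs2", ]), c(1, NA, 0))
  expect_equal(g$annotation$effect_allele, c("A", "T"))
})

test_that("sample sheet validation enforces completeness and uniqueness", {
  ok <- data.frame(sample_id = c("a", "b"), cohort = "A",
                   group = c("fetal", "adult"), tissue = "liver")
  expect_s3_class(sample_sheet(ok), "tbl_df")
  dup <- ok; dup$sample_id <- c("a", "a")
  expect_error(sample_sheet(dup), "unique")
  bad <- ok; bad$tissue <- c("liver", "brain")
  expect_error(sample_sheet(bad), "tissue")
})
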
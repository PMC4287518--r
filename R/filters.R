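#' Keep CpGs that vary across samples
#'
#' Array-wide association scans are restricted to CpGs whose beta value
#' actually varies in the cohort; near-constant probes carry no signal and
#' inflate the multiple-testing burden. The criterion is a cross-sample
#' standard deviation of the beta value of at least `min_sd`. The default of
#' 0.02 is a pragmatic stand-in for the common "variable probe" filters used
#' with 450K data; it is configurable and the retained count is reported.
#'
#' @param methylation A [methylation_matrix()].
#' @param min_sd Non-negative SD threshold on the beta scale.
#' @return The filtered `methylation_matrix` (annotation subset in step).
#' @export
filter_variable_cpgs <- function(methylation, min_sd = 0.02) {
  stopifnot(inherits(methylation, "methylation_matrix"))
  if (min_sd < 0) rlang::abort("`min_sd` must be >= 0")
  keep <- row_sds(methylation$values) >= min_sd
  if (!any(keep)) rlang::warn("no CpG passed the variability filter")
  rlang::inform(sprintf("filter_variable_cpgs: kept %d of %d CpGs (sd >= %g)",
                        sum(keep), length(keep), min_sd))
  subset_omic(methylation, features = rownames(methylation$values)[keep])
}

#' Standard SNP quality control
#'
#' Removes SNPs failing any of: minor allele frequency below `maf_min`,
#' exact-test Hardy-Weinberg equilibrium p below `hwe_alpha`, or missing
#' genotype fraction above `max_missing`. Per-filter counts are reported.
#' Missing dosages are never altered here; association routines mean-impute
#' them transiently.
#'
#' @param genotypes A [genotype_matrix()].
#' @param maf_min MAF threshold in \[0, 0.5\].
#' @param hwe_alpha Exact HWE p-value threshold (SNPs with p below it drop).
#' @param max_missing Maximum tolerated missing fraction.
#' @return The filtered `genotype_matrix`, with a `"qc"` attribute giving the
#'   per-filter failure counts.
#' @export
filter_snps <- function(genotypes, maf_min = 0.05, hwe_alpha = 1e-6,
                        max_missing = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 0.5) rlang::abort("`maf_min` must be in [0, 0.5]")
  d <- genotypes$values
  maf <- snp_maf(d)
  miss <- rowMeans(is.na(d))
  hwe_p <- apply(d, 1, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  fail_maf <- maf < maf_min | is.nan(maf)
  fail_hwe <- hwe_p < hwe_alpha
  fail_miss <- miss > max_missing
  keep <- !(fail_maf | fail_hwe | fail_miss)
  qc <- tibble::tibble(filter = c("maf", "hwe", "missingness"),
                       failed = c(sum(fail_maf), sum(fail_hwe), sum(fail_miss)))
  rlang::inform(sprintf(
    "filter_snps: kept %d of %d SNPs (maf fail %d, hwe fail %d, missing fail %d)",
    sum(keep), length(keep), sum(fail_maf), sum(fail_hwe), sum(fail_miss)))
  out <- subset_omic(genotypes, features = rownames(d)[keep])
  attr(out, "qc") <- qc
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on biallelic genotype counts (the standard
#' enumeration of heterozygote counts conditional on allele counts): the
#' p-value is the total probability of all heterozygote configurations no
#' more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major hom, het, minor hom in any
#'   consistent order).
#' @return Exact two-sided p-value; 1 for empty or monomorphic input.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log-probability of each possible heterozygote count given allele counts
  lp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) + hets * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}
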
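#' Coefficient of determination of an OLS fit
#'
#' Fits `outcome ~ predictors` by ordinary least squares (intercept always
#' included) and returns the unadjusted R-squared. Perfectly collinear
#' predictor columns are dropped via the QR decomposition's pivoting (with a
#' warning), so nested predictor sets always yield a non-decreasing R2.
#'
#' @param outcome Numeric response vector.
#' @param predictors Numeric vector or matrix of predictors.
#' @return A list with `r2`, `adj_r2`, `rss`, `rank` (number of non-constant
#'   predictor columns actually used) and `n`. A constant outcome gives
#'   `r2 = NA` (coded, not an error).
#' @export
fit_r2 <- function(outcome, predictors) {
  x <- as.matrix(predictors)
  n <- length(outcome)
  if (nrow(x) != n) rlang::abort("outcome and predictors must align")
  tss <- sum((outcome - mean(outcome))^2)
  if (tss == 0) {
    return(list(r2 = NA_real_, adj_r2 = NA_real_, rss = NA_real_,
                rank = NA_integer_, n = n))
  }
  xx <- cbind(`(Intercept)` = 1, x)
  qrx <- qr(xx)
  if (qrx$rank < ncol(xx)) {
    rlang::warn(sprintf("dropped %d collinear predictor column(s)",
                        ncol(xx) - qrx$rank))
  }
  if (n <= qrx$rank) rlang::abort("need n > number of (independent) predictors")
  rss <- sum(qr.resid(qrx, outcome)^2)
  p <- qrx$rank - 1  # predictors excluding intercept
  r2 <- 1 - rss / tss
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       rss = rss, rank = p, n = n)
}

#' Nested-model F-test
#'
#' Compares two nested OLS fits through their residual sums of squares:
#' `F = ((rss_small - rss_full) / (p_full - p_small)) /
#' (rss_full / (n - p_full - 1))`, with the p-value from the corresponding
#' F distribution. The null hypothesis is that both models fit equally well.
#'
#' @param rss_small,rss_full Residual sums of squares of the reduced and
#'   full model (`rss_full <= rss_small` up to a small tolerance).
#' @param p_small,p_full Number of predictors (excluding intercept) in each.
#' @param n Number of observations (`n > p_full + 1`).
#' @return A one-row tibble with `f_stat` and `p`.
#' @examples
#' nested_f_test(10, 1, 8, 3, 50)
#' @export
nested_f_test <- function(rss_small, p_small, rss_full, p_full, n) {
  if (p_full <= p_small) rlang::abort("models are not nested: p_full <= p_small")
  if (rss_full > rss_small * (1 + 1e-10) + 1e-12) {
    rlang::abort("models are not nested: rss_full > rss_small")
  }
  if (n <= p_full + 1) rlang::abort("need n > p_full + 1")
  f <- max(0, (rss_small - rss_full) / (p_full - p_small)) /
    (rss_full / (n - p_full - 1))
  tibble::tibble(f_stat = f, p = stats::pf(f, p_full - p_small,
                                           n - p_full - 1,
                                           lower.tail = FALSE))
}

#' Partition expression variance between a SNP and CpG methylation
#'
#' Fits the four nested linear models for a single expression probe: SNP
#' dosage only, top CpG only, SNP + top CpG, and SNP + all associated CpGs,
#' reporting each model's R2, the unique contributions
#' (`unique_snp = r2_snp_cpg - r2_cpg`, `unique_cpg = r2_snp_cpg - r2_snp`),
#' the shared component (which can be negative under suppression; flagged),
#' and the F-test comparing SNP + top CpG against SNP + all CpGs.
#'
#' @param expression_probe Numeric expression vector for one probe.
#' @param snp_dosage Numeric dosage vector (additive coding; missing values
#'   mean-imputed).
#' @param top_cpg Numeric methylation vector of the representative CpG.
#' @param all_assoc_cpgs Matrix (samples x CpGs) of all CpGs with an eQTM
#'   effect on this probe; must contain `top_cpg` (duplicates are dropped by
#'   the fit's pivoting).
#' @return A one-row tibble with the R2 chain, adjusted R2s, unique and
#'   shared contributions, `f_stat`, `f_p`, significance stars
#'   (`*` < 0.05, `**` < 0.005) and a `suppression` flag.
#' @export
partition <- function(expression_probe, snp_dosage, top_cpg,
                      all_assoc_cpgs) {
  m_all <- as.matrix(all_assoc_cpgs)
  if (ncol(m_all) == 0) rlang::abort("`all_assoc_cpgs` must not be empty")
  if (anyNA(snp_dosage)) {
    snp_dosage[is.na(snp_dosage)] <- mean(snp_dosage, na.rm = TRUE)
  }
  y <- expression_probe
  n <- length(y)
  f_snp <- fit_r2(y, cbind(snp = snp_dosage))
  f_cpg <- fit_r2(y, cbind(cpg = top_cpg))
  f_both <- fit_r2(y, cbind(snp = snp_dosage, cpg = top_cpg))
  f_all <- suppressWarnings(
    fit_r2(y, cbind(snp = snp_dosage, m_all)))
  # after dropping collinear columns the "all CpGs" model may add nothing
  # beyond SNP + top CpG; the F-test is then undefined, not an error
  ft <- if (f_all$rank > f_both$rank) {
    nested_f_test(f_both$rss, f_both$rank, f_all$rss, f_all$rank, n)
  } else {
    tibble::tibble(f_stat = NA_real_, p = NA_real_)
  }
  unique_snp <- f_both$r2 - f_cpg$r2
  unique_cpg <- f_both$r2 - f_snp$r2
  shared <- f_both$r2 - unique_snp - unique_cpg
  tibble::tibble(
    r2_snp = f_snp$r2, r2_cpg = f_cpg$r2, r2_snp_cpg = f_both$r2,
    r2_snp_all_cpgs = f_all$r2,
    adj_r2_snp = f_snp$adj_r2, adj_r2_cpg = f_cpg$adj_r2,
    adj_r2_snp_cpg = f_both$adj_r2, adj_r2_snp_all_cpgs = f_all$adj_r2,
    unique_snp = unique_snp, unique_cpg = unique_cpg, shared = shared,
    suppression = shared < -1e-10,
    f_stat = ft$f_stat, f_p = ft$p,
    f_stars = dplyr::case_when(is.na(ft$p) ~ "", ft$p < 0.005 ~ "**",
                               ft$p < 0.05 ~ "*", TRUE ~ ""),
    n = n, n_cpgs = ncol(m_all))
}

#' Variance partition across all probes with both eQTL and eQTM support
#'
#' Drives [partition()] over every expression probe that carries both a
#' significant cis-eQTL and at least one significant eQTM. The
#' representative SNP is the probe's strongest significant eQTL (largest
#' absolute meta z), the representative CpG its strongest significant eQTM
#' (largest absolute rho); "all CpGs" are all CpGs with a significant eQTM
#' to that probe.
#'
#' @param expression An [expression_matrix()].
#' @param genotypes A [genotype_matrix()].
#' @param methylation A [methylation_matrix()].
#' @param eqtl_results A significant-capable [map_cis_qtl()] output
#'   (`mode = "eqtl"`).
#' @param eqtm_results A [map_eqtm()] output.
#' @param samples Optional character vector of sample ids to use (defaults
#'   to the samples shared by the three matrices).
#' @return A tibble of class `varpart_result`, one row per eligible probe,
#'   with `probe_id`, `gene`, `snp_id`, `cpg_id` and the [partition()]
#'   columns.
#' @export
partition_variance <- function(expression, genotypes, methylation,
                               eqtl_results, eqtm_results, samples = NULL) {
  eq <- dplyr::filter(tibble::as_tibble(eqtl_results), .data$significant)
  em <- dplyr::filter(tibble::as_tibble(eqtm_results), .data$significant)
  ids <- intersect(intersect(colnames(expression$values),
                             colnames(genotypes$values)),
                   colnames(methylation$values))
  if (!is.null(samples)) ids <- intersect(ids, samples)
  probes <- intersect(unique(eq$feature_id), unique(em$probe_id))
  rows <- purrr::map_dfr(probes, function(pid) {
    eq_p <- eq[eq$feature_id == pid, ]
    top_snp <- eq_p$snp_id[which.max(abs(eq_p$meta_z))]
    em_p <- em[em$probe_id == pid, ]
    top_cpg <- em_p$cpg_id[which.max(abs(em_p$rho))]
    all_cpgs <- unique(em_p$cpg_id)
    y <- expression$values[pid, ids]
    g <- genotypes$values[top_snp, ids]
    m_all <- t(methylation$values[all_cpgs, ids, drop = FALSE])
    dplyr::bind_cols(
      tibble::tibble(probe_id = pid,
                     gene = eq_p$gene[1],
                     snp_id = top_snp, cpg_id = top_cpg),
      partition(y, g, methylation$values[top_cpg, ids], m_all))
  })
  structure(rows, class = c("varpart_result", class(rows)))
}
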
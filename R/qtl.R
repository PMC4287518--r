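#' Spearman association between dosage and a trait
#'
#' Rank correlation with average ranks for ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` and the
#' z-score is the signed standard-normal quantile of that p carrying the
#' sign of rho. Pairs that cannot be tested (fewer than 10 paired
#' observations, a constant trait, or a single genotype class) are not
#' errors: they return `NA` statistics with a coded `skip_reason`.
#'
#' @param dosage Numeric dosage vector (0/1/2, `NA` allowed).
#' @param trait Numeric trait vector of the same length.
#' @return A one-row tibble with `rho`, `p`, `z`, `n`, `skip_reason`.
#' @examples
#' spearman_assoc(c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1),
#'                c(1.2, 0.8, 2.1, 1.9, 3.3, 3.0, 1.1, 2.0, 3.1, 1.8))
#' @export
spearman_assoc <- function(dosage, trait) {
  if (length(dosage) != length(trait)) {
    rlang::abort("`dosage` and `trait` must have the same length")
  }
  keep <- !is.na(dosage) & !is.na(trait)
  d <- dosage[keep]; y <- trait[keep]; n <- sum(keep)
  skip <- function(reason) {
    tibble::tibble(rho = NA_real_, p = NA_real_, z = NA_real_, n = n,
                   skip_reason = reason)
  }
  if (n < 10) return(skip("too_few_samples"))
  if (stats::sd(y) == 0) return(skip("constant_trait"))
  if (length(unique(d)) < 2) return(skip("single_genotype_class"))
  rho <- stats::cor(d, y, method = "spearman")
  rc <- max(min(rho, 1 - 1e-15), -1 + 1e-15)
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  tibble::tibble(rho = rho, p = p, z = p_to_z(p, sign(rho)), n = n,
                 skip_reason = NA_character_)
}

#' Sample-size-weighted Z meta-analysis
#'
#' Combines per-cohort correlation z-scores with square-root-of-n weights:
#' `meta_z = sum(sqrt(n_i) * z_i) / sqrt(sum(n_i))`, which reduces to the
#' single-cohort z when one cohort is supplied. Cohorts with `NA` z are
#' dropped; at least one valid cohort is required.
#'
#' @param cohort_zs Numeric z-scores, one per cohort.
#' @param cohort_ns Matching sample sizes.
#' @return A one-row tibble with `meta_z` and `meta_p` (two-sided normal).
#' @examples
#' meta_weighted_z(c(1, 1), c(50, 50))  # sqrt(2)
#' @export
meta_weighted_z <- function(cohort_zs, cohort_ns) {
  if (length(cohort_zs) != length(cohort_ns)) {
    rlang::abort("`cohort_zs` and `cohort_ns` must have the same length")
  }
  ok <- !is.na(cohort_zs) & !is.na(cohort_ns)
  if (!any(ok)) rlang::abort("no cohort with a valid z-score")
  z <- cohort_zs[ok]; n <- cohort_ns[ok]
  meta_z <- sum(sqrt(n) * z) / sqrt(sum(n))
  tibble::tibble(meta_z = meta_z, meta_p = 2 * stats::pnorm(-abs(meta_z)))
}

#' Permutation-based feature-level FDR
#'
#' Given the observed per-feature top statistic (the largest absolute meta
#' z across a feature's cis SNPs) and the same quantity computed on
#' permuted data, estimates for each observed value `t`
#' `FDR(t) = mean over permutations of #(null top >= t) / #(observed top >= t)`,
#' capped at 1. A feature is declared significant when the FDR at its top
#' statistic is below `alpha`; the significance threshold reported is the
#' smallest observed top statistic among significant features.
#'
#' @param observed_top_stats Named numeric vector (names = feature ids).
#' @param null_top_stats Matrix of permuted top statistics, one row per
#'   permutation, columns in any order (only the pooled values are used).
#' @param alpha Nominal FDR level.
#' @return A tibble with `feature_id`, `top_stat`, `fdr`, `significant`, and
#'   a `"threshold"` attribute (`Inf` when nothing is significant).
#' @export
permutation_fdr <- function(observed_top_stats, null_top_stats,
                            alpha = 0.05) {
  if (is.null(dim(null_top_stats))) {
    null_top_stats <- matrix(null_top_stats, nrow = 1)
  }
  n_perm <- nrow(null_top_stats)
  if (n_perm < 1) rlang::abort("at least one permutation is required")
  obs <- observed_top_stats[!is.na(observed_top_stats)]
  nulls <- as.numeric(null_top_stats)
  nulls <- nulls[!is.na(nulls)]
  fdr <- vapply(obs, function(t) {
    denom <- sum(obs >= t)
    if (denom == 0) return(NA_real_)
    min(1, (sum(nulls >= t) / n_perm) / denom)
  }, numeric(1))
  sig <- fdr < alpha
  out <- tibble::tibble(feature_id = names(obs), top_stat = unname(obs),
                        fdr = unname(fdr), significant = unname(sig))
  attr(out, "threshold") <- if (any(sig)) min(obs[sig]) else Inf
  out
}

# unit-norm centered ranks (or raw values for pearson); rows with zero
# spread become all-NA so downstream correlations propagate NA
unit_rows <- function(m, statistic) {
  if (statistic == "spearman") m <- rank_rows(m)
  mu <- rowMeans(m)
  c_m <- m - mu
  s <- sqrt(rowSums(c_m^2))
  z <- c_m / s
  z[s == 0, ] <- NA_real_
  z
}

mean_impute_rows <- function(m) {
  if (!anyNA(m)) return(m)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- rowMeans(m, na.rm = TRUE)[idx[, 1]]
  m[is.na(m)] <- 0  # rows that were entirely missing
  m
}

rho_to_z <- function(rho, n) {
  rc <- pmax(pmin(rho, 1 - 1e-15), -1 + 1e-15)
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p_to_z(p, sign(rc))
}

#' Map cis QTLs with cohort meta-analysis and permutation FDR
#'
#' The discovery engine for both eQTL (`mode = "eqtl"`, trait = expression)
#' and meQTL (`mode = "meqtl"`, trait = methylation) mapping. The pipeline:
#' enumerate SNP-feature pairs within `window_bp` (for meQTLs, pairs whose
#' SNP falls inside the target CpG probe interval are removed first); in
#' each cohort of adult samples compute the Spearman correlation between
#' dosage and trait and convert it to a z-score; combine cohorts by
#' sqrt(n)-weighted meta-analysis; estimate the feature-level FDR by
#' re-running the scan on data with the genotype-trait sample linkage
#' shuffled within cohort (`n_perm` times) and comparing per-feature top
#' statistics via [permutation_fdr()]. Missing dosages are mean-imputed per
#' SNP within cohort for the computation only.
#'
#' @param genotypes A [genotype_matrix()].
#' @param traits An [expression_matrix()] or [methylation_matrix()].
#' @param sheet Sample sheet; only adult samples of `tissue` are used.
#' @param window_bp Cis window half-width (default 250 kb).
#' @param n_perm Number of permutations (default 10).
#' @param alpha Nominal feature-level FDR (default 0.05).
#' @param mode `"eqtl"` or `"meqtl"`.
#' @param tissue Tissue to analyse (default `"liver"`).
#' @param statistic `"spearman"` (default) or `"pearson"`.
#' @param seed Seed for the permutation stream.
#' @return A tibble of class `qtl_result`, one row per tested pair:
#'   `snp_id`, `feature_id`, `gene`, `distance_bp`, per-cohort `rho_*`,
#'   `n_*`, `z_*`, `meta_z`, `meta_p`, `fdr` (feature-level), `direction`,
#'   `is_top` (strongest pair of its feature) and `significant`. Attributes:
#'   `feature_fdr` (per-feature table), `threshold`, `mode`, `alpha`,
#'   `n_perm`, `statistic`.
#' @export
map_cis_qtl <- function(genotypes, traits, sheet,
                        window_bp = 250000, n_perm = 10, alpha = 0.05,
                        mode = c("eqtl", "meqtl"), tissue = "liver",
                        statistic = c("spearman", "pearson"), seed = 1) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (n_perm < 1) rlang::abort("`n_perm` must be >= 1")
  sheet <- sample_sheet(sheet)
  sheet <- dplyr::filter(sheet, .data$group == "adult",
                         .data$tissue == !!tissue)
  pairs <- enumerate_cis_pairs(genotypes$annotation, traits$annotation,
                               window_bp)
  if (mode == "meqtl") {
    pairs <- exclude_probe_snp_conflicts(pairs, genotypes$annotation,
                                         traits$annotation)
  }
  trait_ann <- traits$annotation
  gene <- if ("gene" %in% names(trait_ann)) {
    trait_ann$gene[match(pairs$right_id, trait_ann[[1]])]
  } else NA_character_
  res <- tibble::tibble(snp_id = pairs$left_id, feature_id = pairs$right_id,
                        gene = gene, distance_bp = pairs$distance_bp)
  if (nrow(res) == 0) {
    rlang::warn("no cis pair to test")
    return(structure(res, class = c("qtl_result", class(res))))
  }

  cohorts <- sort(unique(sheet$cohort))
  cohort_data <- list()
  for (co in cohorts) {
    ids <- sheet$sample_id[sheet$cohort == co]
    ids <- intersect(intersect(ids, colnames(genotypes$values)),
                     colnames(traits$values))
    if (length(ids) >= 10) {
      G <- mean_impute_rows(genotypes$values[, ids, drop = FALSE])
      Y <- traits$values[, ids, drop = FALSE]
      cohort_data[[co]] <- list(
        zg = unit_rows(G, statistic), zy = unit_rows(Y, statistic),
        n = length(ids))
    }
  }
  if (length(cohort_data) == 0) {
    rlang::abort("no cohort with overlapping genotype and trait samples")
  }

  sidx <- match(res$snp_id, rownames(genotypes$values))
  fidx <- match(res$feature_id, rownames(traits$values))
  feat <- factor(res$feature_id)

  pair_meta <- function(perm_of = NULL) {
    zs <- matrix(NA_real_, nrow(res), length(cohort_data))
    ns <- numeric(length(cohort_data))
    rhos <- zs
    for (k in seq_along(cohort_data)) {
      cd <- cohort_data[[k]]
      zy <- cd$zy
      if (!is.null(perm_of)) zy <- zy[, perm_of[[k]], drop = FALSE]
      rho <- unname(rowSums(cd$zg[sidx, , drop = FALSE] *
                              zy[fidx, , drop = FALSE]))
      rhos[, k] <- rho
      zs[, k] <- rho_to_z(rho, cd$n)
      ns[k] <- cd$n
    }
    w <- sqrt(ns)
    ok <- !is.na(zs)
    num <- rowSums(sweep(ok * replace(zs, !ok, 0), 2, w, `*`))
    den <- sqrt(rowSums(sweep(ok, 2, ns, `*`)))
    meta_z <- ifelse(den > 0, num / den, NA_real_)
    list(rho = rhos, z = zs, meta_z = meta_z, ns = ns)
  }

  top_stat <- function(v) {
    as.numeric(tapply(v, feat, function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    }))
  }
  obs <- pair_meta()
  top_obs <- top_stat(abs(obs$meta_z))

  set.seed(seed)
  null_top <- matrix(NA_real_, n_perm, nlevels(feat))
  for (b in seq_len(n_perm)) {
    perm_of <- lapply(cohort_data, function(cd) sample.int(cd$n))
    pm <- pair_meta(perm_of)
    null_top[b, ] <- top_stat(abs(pm$meta_z))
  }
  fdr_tbl <- permutation_fdr(stats::setNames(as.numeric(top_obs),
                                             levels(feat)),
                             null_top, alpha)
  thr <- attr(fdr_tbl, "threshold")

  for (k in seq_along(cohort_data)) {
    co <- names(cohort_data)[k]
    res[[paste0("rho_", co)]] <- obs$rho[, k]
    res[[paste0("n_", co)]] <- obs$ns[k]
    res[[paste0("z_", co)]] <- obs$z[, k]
  }
  res$meta_z <- obs$meta_z
  res$meta_p <- 2 * stats::pnorm(-abs(res$meta_z))
  res$fdr <- fdr_tbl$fdr[match(res$feature_id, fdr_tbl$feature_id)]
  res$direction <- ifelse(res$meta_z >= 0, "+", "-")
  abs_z <- abs(res$meta_z)
  top_of <- tapply(abs_z, feat, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  res$is_top <- !is.na(abs_z) &
    abs_z == as.numeric(top_of[as.character(res$feature_id)])
  # break ties: keep only the first top pair per feature
  dup_top <- res$is_top & duplicated(paste(res$feature_id, res$is_top))
  res$is_top[dup_top] <- FALSE
  res$significant <- !is.na(abs_z) & abs_z >= thr
  structure(res, feature_fdr = fdr_tbl, threshold = thr, mode = mode,
            alpha = alpha, n_perm = n_perm, statistic = statistic,
            class = c("qtl_result", class(res)))
}

#' Overlap of eQTL and meQTL signals with allelic direction classes
#'
#' Finds SNPs that are significantly associated with both the expression of
#' a gene and the methylation of a CpG annotated to that same gene (exact
#' SNP identity). Each overlap record is classified `"opposite"` when the
#' effect allele moves methylation and expression in opposite directions,
#' `"same"` otherwise.
#'
#' @param eqtl_results,meqtl_results [map_cis_qtl()] outputs (only rows with
#'   `significant == TRUE` are used).
#' @param cpg_annotation CpG annotation with `cpg_id`, `gene` and
#'   `cgi_relation`.
#' @return A tibble of overlap records: `snp_id`, `gene`, `probe_id`,
#'   `cpg_id`, `z_expr`, `z_meth`, `cgi_relation`, `direction_class`.
#' @seealso [overlap_direction_summary()]
#' @export
overlap_eqtl_meqtl <- function(eqtl_results, meqtl_results, cpg_annotation) {
  take_sig <- function(x) {
    x <- tibble::as_tibble(x)
    if ("significant" %in% names(x)) dplyr::filter(x, .data$significant)
    else x
  }
  eq <- take_sig(eqtl_results)
  mq <- take_sig(meqtl_results)
  empty <- tibble::tibble(snp_id = character(), gene = character(),
                          probe_id = character(), cpg_id = character(),
                          z_expr = numeric(), z_meth = numeric(),
                          cgi_relation = character(),
                          direction_class = character())
  if (nrow(eq) == 0 || nrow(mq) == 0) return(empty)
  mq$gene <- cpg_annotation$gene[match(mq$feature_id, cpg_annotation$cpg_id)]
  mq$cgi_relation <- cpg_annotation$cgi_relation[
    match(mq$feature_id, cpg_annotation$cpg_id)]
  dplyr::inner_join(
    dplyr::select(eq, "snp_id", "gene", probe_id = "feature_id",
                  z_expr = "meta_z"),
    dplyr::select(mq, "snp_id", "gene", cpg_id = "feature_id",
                  z_meth = "meta_z", "cgi_relation"),
    by = c("snp_id", "gene"), relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::mutate(direction_class = ifelse(
      sign(.data$z_expr) * sign(.data$z_meth) < 0, "opposite", "same"))
}

#' Summarise eQTL/meQTL overlap directions
#'
#' Gene-level classification (majority class of a gene's overlap records;
#' exact ties are `"mixed"`), the overall fraction of opposite-direction
#' genes, and the record-level breakdown by CpG island context.
#'
#' @param overlaps Output of [overlap_eqtl_meqtl()].
#' @return A list with `gene_summary`, `fraction_opposite_genes`, `by_cgi`.
#' @export
overlap_direction_summary <- function(overlaps) {
  if (nrow(overlaps) == 0) {
    return(list(gene_summary = tibble::tibble(),
                fraction_opposite_genes = NA_real_,
                by_cgi = tibble::tibble()))
  }
  gene_summary <- overlaps |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_overlaps = dplyr::n(),
      frac_opposite = mean(.data$direction_class == "opposite"),
      gene_class = dplyr::case_when(
        frac_opposite > 0.5 ~ "opposite",
        frac_opposite < 0.5 ~ "same",
        TRUE ~ "mixed"),
      .groups = "drop")
  decided <- gene_summary$gene_class != "mixed"
  by_cgi <- overlaps |>
    dplyr::group_by(.data$cgi_relation) |>
    dplyr::summarise(n = dplyr::n(),
                     frac_opposite = mean(.data$direction_class == "opposite"),
                     .groups = "drop")
  list(gene_summary = gene_summary,
       fraction_opposite_genes =
         mean(gene_summary$gene_class[decided] == "opposite"),
       by_cgi = by_cgi)
}
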
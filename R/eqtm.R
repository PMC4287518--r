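#' Map expression-methylation associations (eQTMs)
#'
#' For every CpG-probe pair within the cis window, computes the Spearman
#' correlation between methylation beta values and log2 expression across
#' adult samples, and a permutation p-value obtained by shuffling the sample
#' linkage between the methylation and expression matrices. The add-one
#' estimator is used: `perm_p = (1 + #(|rho_null| >= |rho_obs|)) /
#' (1 + n_perm)`, so perm_p is never exactly zero and is bounded below by
#' `1 / (1 + n_perm)`. Significance is `perm_p < alpha`; a Benjamini-
#' Hochberg q-value over perm_p is reported alongside so either convention
#' can be applied downstream.
#'
#' The signed distance is the CpG position minus the probe interval
#' midpoint (plus-strand convention; probe strand is not modelled).
#'
#' @param methylation A [methylation_matrix()].
#' @param expression An [expression_matrix()].
#' @param sheet Optional sample sheet; when given, only adult samples of
#'   `tissue` are used, otherwise the shared columns of the two matrices.
#' @param window_bp Cis window half-width (default 250 kb).
#' @param n_perm Number of permutations (default 999). Values below 19 make
#'   alpha = 0.05 unreachable and trigger a warning.
#' @param alpha Significance level on the permutation p (default 0.05).
#' @param tissue Tissue to analyse when `sheet` is given.
#' @param seed Seed for the permutation stream.
#' @return A tibble of class `eqtm_result`: `cpg_id`, `probe_id`, `gene`,
#'   `rho`, `p` (t approximation), `perm_p`, `fdr_q` (BH over perm_p),
#'   `distance_bp`, `direction` (`negative`/`positive`), `significant`.
#' @export
map_eqtm <- function(methylation, expression, sheet = NULL,
                     window_bp = 250000, n_perm = 999, alpha = 0.05,
                     tissue = "liver", seed = 1) {
  if (n_perm < 1) rlang::abort("`n_perm` must be >= 1")
  if (n_perm < 19) {
    rlang::warn(sprintf(
      "n_perm = %d cannot reach perm_p < 0.05 (minimum is %.3f)",
      n_perm, 1 / (1 + n_perm)))
  }
  ids <- intersect(colnames(methylation$values), colnames(expression$values))
  if (!is.null(sheet)) {
    sheet <- sample_sheet(sheet)
    keep <- sheet$sample_id[sheet$group == "adult" & sheet$tissue == tissue]
    ids <- intersect(ids, keep)
  }
  if (length(ids) < 10) rlang::abort("fewer than 10 shared samples")
  # probe on the left so distance_bp = CpG anchor - probe midpoint
  pairs <- enumerate_cis_pairs(expression$annotation, methylation$annotation,
                               window_bp)
  res <- tibble::tibble(
    cpg_id = pairs$right_id, probe_id = pairs$left_id,
    gene = expression$annotation$gene[
      match(pairs$left_id, expression$annotation$probe_id)],
    distance_bp = pairs$distance_bp)
  if (nrow(res) == 0) {
    rlang::warn("no cis pair to test")
    return(structure(res, class = c("eqtm_result", class(res))))
  }
  n <- length(ids)
  zm <- unit_rows(methylation$values[, ids, drop = FALSE], "spearman")
  ze <- unit_rows(expression$values[, ids, drop = FALSE], "spearman")
  mi <- match(res$cpg_id, rownames(methylation$values))
  pi <- match(res$probe_id, rownames(expression$values))
  rho <- unname(rowSums(zm[mi, , drop = FALSE] * ze[pi, , drop = FALSE]))
  set.seed(seed)
  exceed <- integer(nrow(res))
  for (b in seq_len(n_perm)) {
    zperm <- ze[, sample.int(n), drop = FALSE]
    rho_b <- rowSums(zm[mi, , drop = FALSE] * zperm[pi, , drop = FALSE])
    exceed <- exceed + as.integer(!is.na(rho_b) & !is.na(rho) &
                                    abs(rho_b) >= abs(rho))
  }
  res$rho <- rho
  rc <- pmax(pmin(rho, 1 - 1e-15), -1 + 1e-15)
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  res$p <- 2 * stats::pt(-abs(tstat), n - 2)
  res$perm_p <- (1 + exceed) / (1 + n_perm)
  res$perm_p[is.na(rho)] <- NA_real_
  res$fdr_q <- stats::p.adjust(res$perm_p, method = "BH")
  res$direction <- ifelse(rho < 0, "negative", "positive")
  res$significant <- !is.na(res$perm_p) & res$perm_p < alpha
  structure(res, alpha = alpha, n_perm = n_perm, n = n,
            class = c("eqtm_result", class(res)))
}

#' eQTM direction by correlation strength and by distance
#'
#' Bins significant eQTMs by absolute Spearman correlation and, separately,
#' by absolute CpG-probe distance, and reports the fraction of
#' negative-direction associations per bin. Empty bins report `NA`, not
#' zero.
#'
#' @param results An [map_eqtm()] result (rows with `significant == TRUE`
#'   are used; if none are flagged, all rows are used with a warning).
#' @param rho_bins Breaks on the absolute-correlation axis.
#' @param distance_bins Breaks (bp) on the absolute-distance axis.
#' @return A tibble of class `eqtm_direction_summary` with `axis`
#'   (`"abs_rho"` or `"abs_distance"`), `bin` (label), `lower`, `upper`,
#'   `n`, `frac_negative`.
#' @export
direction_distance_summary <- function(results,
                                       rho_bins = c(0, 0.3, 0.4, 0.5, 1),
                                       distance_bins = c(0, 50e3, 100e3,
                                                         150e3, 250e3)) {
  res <- tibble::as_tibble(results)
  if ("significant" %in% names(res) && any(res$significant)) {
    res <- dplyr::filter(res, .data$significant)
  } else {
    rlang::warn("no significant eQTM; summarising all tested pairs")
  }
  if (nrow(res) == 0) rlang::abort("no eQTM to summarise")
  one_axis <- function(x, breaks, axis) {
    cut_idx <- cut(x, breaks, include.lowest = TRUE)
    lv <- levels(cut_idx)
    purrr::map_dfr(seq_along(lv), function(i) {
      inb <- !is.na(cut_idx) & cut_idx == lv[i]
      tibble::tibble(
        axis = axis, bin = lv[i],
        lower = breaks[i], upper = breaks[i + 1],
        n = sum(inb),
        frac_negative = if (any(inb)) {
          mean(res$direction[inb] == "negative")
        } else NA_real_)
    })
  }
  out <- dplyr::bind_rows(
    one_axis(abs(res$rho), rho_bins, "abs_rho"),
    one_axis(abs(res$distance_bp), distance_bins, "abs_distance"))
  structure(out, class = c("eqtm_direction_summary", class(out)))
}
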
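#' Fetal-versus-adult differential methylation and expression
#'
#' Both tests share the same machinery: a per-feature Welch (unequal
#' variance) two-sided t-test comparing fetal against adult samples, with
#' Benjamini-Hochberg FDR across all tested features, and a dual
#' significance rule that additionally requires a minimum effect size. For
#' methylation the effect is the beta-value difference
#' `delta_beta = mean(fetal) - mean(adult)` with a default threshold of 0.2;
#' for expression it is the log2 fold change `mean(fetal) - mean(adult)`
#' with a default threshold of 1.0. Both use FDR < `alpha`.
#'
#' @param methylation A [methylation_matrix()].
#' @param expression An [expression_matrix()].
#' @param groups Either a sample sheet (its `group` column is used; samples
#'   are matched to matrix columns by `sample_id`) or a character vector of
#'   `"fetal"`/`"adult"` aligned with the matrix columns.
#' @param delta_threshold Minimum absolute beta difference (methylation).
#' @param lfc_threshold Minimum absolute log2 fold change (expression).
#' @param alpha FDR threshold.
#' @return A tibble of class `diff_result` with columns `feature_id`,
#'   `effect` (fetal minus adult), `raw_p`, `fdr_q`, `significant` and
#'   `direction` (`up_in_fetal`/`down_in_fetal`).
#' @examples
#' cfg <- sim_config(n_snps = 40, n_cpgs = 80, n_probes = 40,
#'                   design = data.frame(cohort = "A", group = c("fetal", "adult"),
#'                                       tissue = "liver", n = c(8, 12)),
#'                   seed = 7)
#' sim <- simulate_study(cfg)
#' dm <- diff_methylation(sim$methylation, sim$sample_sheet)
#' head(dm)
#' @name differential-testing
NULL

resolve_groups <- function(values, groups) {
  if (is.data.frame(groups)) {
    groups <- sample_sheet(groups)
    common <- intersect(colnames(values), groups$sample_id)
    g <- groups$group[match(common, groups$sample_id)]
    list(values = values[, common, drop = FALSE], group = g)
  } else {
    if (length(groups) != ncol(values)) {
      rlang::abort("`groups` must align with the matrix columns")
    }
    list(values = values, group = as.character(groups))
  }
}

diff_two_group <- function(values, group, effect_threshold, alpha) {
  fetal <- group == "fetal"
  adult <- group == "adult"
  if (sum(fetal) < 2 || sum(adult) < 2) {
    rlang::abort("each group needs at least 2 samples")
  }
  xf <- values[, fetal, drop = FALSE]
  xa <- values[, adult, drop = FALSE]
  nf <- rowSums(!is.na(xf)); na <- rowSums(!is.na(xa))
  mf <- row_means(xf); ma <- row_means(xa)
  vf <- row_vars(xf); va <- row_vars(xa)
  effect <- mf - ma
  se2 <- vf / nf + va / na
  tstat <- effect / sqrt(se2)
  df <- se2^2 / ((vf / nf)^2 / (nf - 1) + (va / na)^2 / (na - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- vf == 0 & va == 0
  if (any(degenerate)) {
    rlang::warn(sprintf("%d feature(s) have zero variance in both groups; p set to 1",
                        sum(degenerate)))
    p[degenerate] <- 1
  }
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    feature_id = rownames(values),
    effect = unname(effect), raw_p = unname(p), fdr_q = unname(q),
    significant = unname(q < alpha & abs(effect) > effect_threshold),
    direction = unname(ifelse(effect >= 0, "up_in_fetal", "down_in_fetal"))
  )
}

#' @rdname differential-testing
#' @export
diff_methylation <- function(methylation, groups, delta_threshold = 0.2,
                             alpha = 0.05) {
  stopifnot(inherits(methylation, "methylation_matrix"))
  g <- resolve_groups(methylation$values, groups)
  out <- diff_two_group(g$values, g$group, delta_threshold, alpha)
  structure(out, kind = "methylation", class = c("diff_result", class(out)))
}

#' @rdname differential-testing
#' @export
diff_expression <- function(expression, groups, lfc_threshold = 1.0,
                            alpha = 0.05) {
  stopifnot(inherits(expression, "expression_matrix"))
  g <- resolve_groups(expression$values, groups)
  out <- diff_two_group(g$values, g$group, lfc_threshold, alpha)
  structure(out, kind = "expression", class = c("diff_result", class(out)))
}

#' CpG island context of differential methylation direction
#'
#' Cross-tabulates significant differentially methylated CpGs by direction
#' (hypo- vs hypermethylated in fetal samples) against their CpG island
#' context (island/shore/shelf/other) and tests for association with a
#' Pearson chi-squared test without continuity correction. If the table has
#' an all-zero row or column the statistic is undefined and reported as
#' `NA` with an explanatory note; the per-class hypomethylated fractions are
#' reported regardless.
#'
#' @param dm_results A [diff_methylation()] result.
#' @param cpg_annotation CpG annotation with `cpg_id` and `cgi_relation`.
#' @return A list of class `cgi_contingency`: `counts` (2 x 4 matrix),
#'   `statistic`, `p_value`, `hypo_fraction` (tibble per class), `note`.
#' @export
cgi_direction_contingency <- function(dm_results, cpg_annotation) {
  sig <- dplyr::filter(tibble::as_tibble(dm_results), .data$significant)
  if (nrow(sig) == 0) rlang::abort("no significant CpG to tabulate")
  rel <- cpg_annotation$cgi_relation[
    match(sig$feature_id, cpg_annotation$cpg_id)]
  if (anyNA(rel)) rlang::abort("significant CpG(s) missing from annotation")
  dir <- factor(ifelse(sig$effect < 0, "hypo_in_fetal", "hyper_in_fetal"),
                levels = c("hypo_in_fetal", "hyper_in_fetal"))
  rel <- factor(rel, levels = c("island", "shore", "shelf", "other"))
  counts <- table(dir, rel)
  hypo_fraction <- tibble::tibble(
    cgi_relation = colnames(counts),
    n = as.integer(colSums(counts)),
    hypo_fraction = ifelse(colSums(counts) > 0,
                           counts["hypo_in_fetal", ] / colSums(counts),
                           NA_real_)
  )
  zero_margin <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (zero_margin) {
    res <- list(statistic = NA_real_, p_value = NA_real_,
                note = "chi-squared undefined: table has an empty row or column")
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                note = NA_character_)
  }
  structure(c(list(counts = unclass(counts), hypo_fraction = hypo_fraction),
              res),
            class = "cgi_contingency")
}

#' @export
print.cgi_contingency <- function(x, ...) {
  cat("Differential methylation direction by CpG island context\n")
  print(x$counts)
  if (is.na(x$statistic)) {
    cat(x$note, "\n")
  } else {
    cat(sprintf("chi-squared = %.3f, p = %.3g\n", x$statistic, x$p_value))
  }
  invisible(x)
}

#' Genes both differentially expressed and differentially methylated
#'
#' Intersects the gene sets behind significant differential-expression
#' probes and differential-methylation CpGs and classifies each gene's
#' expression and methylation direction. A gene whose multiple probes (or
#' CpGs) disagree in direction is labelled `"discordant"` rather than forced
#' into one class. Features without a gene annotation are skipped with a
#' warning.
#'
#' @param de_results A [diff_expression()] result.
#' @param dm_results A [diff_methylation()] result.
#' @param probe_annotation Probe annotation with `probe_id` and `gene`.
#' @param cpg_annotation CpG annotation with `cpg_id` and `gene`.
#' @return A tibble with one row per intersecting gene: `gene`,
#'   `n_de_probes`, `n_dm_cpgs`, `expr_direction`, `meth_direction`,
#'   `discordant` (expression or methylation direction conflicts).
#' @export
intersect_de_dm <- function(de_results, dm_results, probe_annotation,
                            cpg_annotation) {
  class_dir <- function(res, ann, id_col) {
    sig <- dplyr::filter(tibble::as_tibble(res), .data$significant)
    gene <- ann$gene[match(sig$feature_id, ann[[id_col]])]
    skipped <- sum(is.na(gene))
    if (skipped > 0) {
      rlang::warn(sprintf("%d significant feature(s) without gene annotation skipped",
                          skipped))
    }
    sig$gene <- gene
    sig |>
      dplyr::filter(!is.na(.data$gene)) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(
        n = dplyr::n(),
        dir = dplyr::case_when(
          all(.data$direction == "up_in_fetal") ~ "up_in_fetal",
          all(.data$direction == "down_in_fetal") ~ "down_in_fetal",
          TRUE ~ "discordant"),
        .groups = "drop")
  }
  de <- class_dir(de_results, probe_annotation, "probe_id")
  dm <- class_dir(dm_results, cpg_annotation, "cpg_id")
  dplyr::inner_join(de, dm, by = "gene", suffix = c("_de", "_dm")) |>
    dplyr::transmute(
      .data$gene,
      n_de_probes = .data$n_de, n_dm_cpgs = .data$n_dm,
      expr_direction = .data$dir_de, meth_direction = .data$dir_dm,
      discordant = .data$dir_de == "discordant" |
        .data$dir_dm == "discordant")
}
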
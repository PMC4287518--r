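#' Plot differential-methylation direction by CpG island context
#'
#' Bar chart of the percentage of significant CpGs that are hyper- or
#' hypomethylated in fetal samples within each CpG island class.
#'
#' @param x A [cgi_direction_contingency()] result.
#' @return A ggplot object.
#' @export
plot_cgi_direction <- function(x) {
  df <- tidy(x) |>
    dplyr::group_by(.data$cgi_relation) |>
    dplyr::mutate(pct = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cgi_relation, y = .data$pct,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(hypo_in_fetal = "grey60",
                                          hyper_in_fetal = "grey10")) +
    ggplot2::labs(x = "CpG island context", y = "% of significant CpGs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot eQTM direction proportions by bin
#'
#' Stacked proportions of negative vs positive methylation-expression
#' correlations across absolute-correlation and absolute-distance bins.
#'
#' @param x A [direction_distance_summary()] result.
#' @return A ggplot object.
#' @export
plot_eqtm_direction <- function(x) {
  df <- tibble::as_tibble(x) |>
    dplyr::filter(.data$n > 0) |>
    tidyr::pivot_longer(cols = "frac_negative", values_to = "frac") |>
    dplyr::mutate(direction = "negative") |>
    dplyr::bind_rows(
      tibble::as_tibble(x) |>
        dplyr::filter(.data$n > 0) |>
        dplyr::mutate(frac = 1 - .data$frac_negative,
                      direction = "positive"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$frac,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(negative = "grey60",
                                          positive = "grey10")) +
    ggplot2::labs(x = NULL, y = "proportion of eQTMs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the variance-partition R2 chain
#'
#' Per-probe bars for the four nested models (SNP only, CpG only,
#' SNP + CpG, SNP + all CpGs), ordered by the joint model's R2.
#'
#' @param x A [partition_variance()] result.
#' @param top_n Number of probes to show (default 20, by joint R2).
#' @return A ggplot object.
#' @export
plot_variance_partition <- function(x, top_n = 20) {
  df <- tibble::as_tibble(x) |>
    dplyr::slice_max(.data$r2_snp_cpg, n = top_n) |>
    tidyr::pivot_longer(cols = c("r2_snp", "r2_cpg", "r2_snp_cpg",
                                 "r2_snp_all_cpgs"),
                        names_to = "model", values_to = "r2") |>
    dplyr::mutate(model = factor(.data$model,
                                 levels = c("r2_snp", "r2_cpg", "r2_snp_cpg",
                                            "r2_snp_all_cpgs"),
                                 labels = c("SNP", "CpG", "SNP+CpG",
                                            "SNP+all CpGs")))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$probe_id, .data$r2), y = .data$r2,
    fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(R^2), fill = "model") +
    ggplot2::theme_minimal()
}
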
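#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a CpG-island contingency result
#'
#' @param x A [cgi_direction_contingency()] result.
#' @param ... Unused.
#' @return A tibble with one row per (direction, CpG class) cell.
#' @export
tidy.cgi_contingency <- function(x, ...) {
  as.data.frame(as.table(x$counts)) |>
    tibble::as_tibble() |>
    rlang::set_names(c("direction", "cgi_relation", "count"))
}

#' @rdname tidy.cgi_contingency
#' @export
glance.cgi_contingency <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_significant = sum(x$counts), note = x$note)
}

#' Tidy a cross-tissue overlap report
#'
#' @param x A [cross_tissue_overlap()] result.
#' @param ... Unused.
#' @return The Venn region counts as a tibble.
#' @export
tidy.overlap_report <- function(x, ...) x$regions

#' @rdname tidy.overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(n_union = x$n_union, concordance = x$concordance,
                 n_opposite = nrow(x$opposite_effects))
}

#' Glance at a matched-probe enrichment result
#'
#' @param x A [matched_probe_enrichment()] result.
#' @param ... Unused.
#' @return A one-row tibble with the fold enrichment and chi-squared test.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(fold = x$fold, chisq_stat = x$chisq_stat,
                 chisq_p = x$chisq_p,
                 n_target = sum(x$counts["target", ]),
                 n_matched = sum(x$counts["matched", ]))
}
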
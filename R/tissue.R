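#' Cross-tissue overlap of association sets
#'
#' Exact set algebra over association keys across tissues: for QTLs the key
#' is the SNP-feature pair, for eQTMs the CpG-probe pair. Replication is
#' strict by default: a key counts as shared between two tissues only when
#' it is significant in both. Every region of the k-set Venn partition is
#' reported, together with pairwise sharing proportions and allelic
#' direction concordance for shared keys.
#'
#' @param result_sets_by_tissue Named list (tissue -> result tibble). Rows
#'   with a `significant` column are filtered to the significant ones.
#' @param key_cols Columns pasted into the key. Defaults to
#'   `c("snp_id", "feature_id")` when present, else
#'   `c("cpg_id", "probe_id")`.
#' @param direction_col Column carrying the signed statistic (default
#'   `meta_z`, falling back to `rho`).
#' @return A list of class `overlap_report`: `regions` (tibble of Venn
#'   region counts; regions are disjoint and sum to the union size),
#'   `pairwise` (tibble of tissue pairs with `n_shared` and `prop_a_shared`
#'   = shared / size of the first tissue's set), `concordance` (fraction of
#'   multi-tissue keys with identical direction everywhere),
#'   `opposite_effects` (per-key directions for discordant keys), `n_union`.
#' @export
cross_tissue_overlap <- function(result_sets_by_tissue, key_cols = NULL,
                                 direction_col = NULL) {
  tissues <- names(result_sets_by_tissue)
  if (length(tissues) < 2) rlang::abort("need results for at least 2 tissues")
  prep <- function(df, tissue) {
    df <- tibble::as_tibble(df)
    if ("significant" %in% names(df)) df <- dplyr::filter(df, .data$significant)
    kc <- key_cols %||% if (all(c("snp_id", "feature_id") %in% names(df))) {
      c("snp_id", "feature_id")
    } else c("cpg_id", "probe_id")
    dc <- direction_col %||% if ("meta_z" %in% names(df)) "meta_z" else "rho"
    key <- do.call(paste, c(df[kc], sep = "|"))
    if (anyDuplicated(key)) {
      rlang::abort(sprintf("duplicate keys within tissue '%s'", tissue))
    }
    tibble::tibble(key = key, tissue = tissue, sign = sign(df[[dc]]))
  }
  long <- dplyr::bind_rows(purrr::imap(result_sets_by_tissue, prep))
  membership <- long |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      in_tissues = paste(sort(unique(.data$tissue)), collapse = ","),
      .groups = "drop")
  all_regions <- unlist(lapply(seq_along(tissues), function(k) {
    utils::combn(sort(tissues), k, paste, collapse = ",")
  }))
  regions <- tibble::tibble(tissues = all_regions) |>
    dplyr::left_join(dplyr::count(membership, .data$in_tissues),
                     by = c(tissues = "in_tissues")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::select("tissues", "count")
  sets <- split(long$key, long$tissue)
  pairwise <- purrr::map_dfr(tissues, function(a) {
    purrr::map_dfr(setdiff(tissues, a), function(b) {
      tibble::tibble(tissue_a = a, tissue_b = b,
                     n_a = length(sets[[a]]),
                     n_shared = length(intersect(sets[[a]], sets[[b]])),
                     prop_a_shared = ifelse(length(sets[[a]]) > 0,
                                            length(intersect(sets[[a]],
                                                             sets[[b]])) /
                                              length(sets[[a]]), NA_real_))
    })
  })
  conc <- direction_concordance(long)
  structure(list(regions = regions, pairwise = pairwise,
                 concordance = conc$fraction_same,
                 opposite_effects = conc$opposite_list,
                 n_union = nrow(membership)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> union of %d keys; concordance %.3f\n",
              x$n_union, x$concordance))
  print(x$regions)
  invisible(x)
}

#' Allelic direction concordance of shared effects
#'
#' Over keys present in two or more tissues, the fraction whose effect sign
#' is identical in every tissue carrying them, plus the list of discordant
#' keys with their per-tissue signs.
#'
#' @param shared_effects Long tibble with columns `key`, `tissue`, `sign`
#'   (as built by [cross_tissue_overlap()], which calls this internally).
#' @return A list with `fraction_same` (`NA` when no key is shared) and
#'   `opposite_list` (tibble `key`, `tissues`, `signs`).
#' @export
direction_concordance <- function(shared_effects) {
  per_key <- shared_effects |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_tissues = dplyr::n(),
                     same = dplyr::n_distinct(.data$sign) == 1,
                     tissues = paste(.data$tissue, collapse = ","),
                     signs = paste(ifelse(.data$sign >= 0, "+", "-"),
                                   collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_tissues >= 2)
  if (nrow(per_key) == 0) {
    return(list(fraction_same = NA_real_,
                opposite_list = tibble::tibble(key = character(),
                                               tissues = character(),
                                               signs = character())))
  }
  list(fraction_same = mean(per_key$same),
       opposite_list = dplyr::select(dplyr::filter(per_key, !.data$same),
                                     "key", "tissues", "signs"))
}

#' Matched-probe enrichment
#'
#' Tests whether a target probe set (e.g. probes up-regulated in adult
#' liver) is enriched for a binary property (e.g. "has an eQTL") relative
#' to a control set matched on expression level and variability. For each
#' target probe, the nearest unused pool probe in z-scored
#' (median, SD) space is taken greedily, in a random target order fixed by
#' `seed`, without replacement; ties break on pool order. The enrichment is
#' `fold = flagged fraction in targets / flagged fraction in the matched
#' set`, with a 2x2 chi-squared test (no continuity correction).
#'
#' @param target_probes Character vector of target probe ids.
#' @param pool_probes Character vector of candidate control ids (disjoint
#'   from the targets; at least as many as targets).
#' @param expression_summary Tibble with `probe_id`, `median`, `sd` covering
#'   targets and pool (see [expression_summary()]).
#' @param flags Named logical vector (probe id -> flagged) covering targets
#'   and pool.
#' @param seed Seed fixing the matching order.
#' @return A list of class `enrichment_result`: `fold` (`Inf` when the
#'   matched set has zero flagged probes), `chisq_stat`, `chisq_p`,
#'   `counts` (2x2), `matched_set`.
#' @export
matched_probe_enrichment <- function(target_probes, pool_probes,
                                     expression_summary, flags, seed = 1) {
  pool_probes <- setdiff(pool_probes, target_probes)
  if (length(pool_probes) < length(target_probes)) {
    rlang::abort("pool must be at least as large as the target set")
  }
  es <- tibble::as_tibble(expression_summary)
  stop_if_not_cols(es, c("probe_id", "median", "sd"), "expression_summary")
  need <- c(target_probes, pool_probes)
  if (!all(need %in% es$probe_id)) {
    rlang::abort("expression_summary must cover all target and pool probes")
  }
  zmed <- zscore(es$median); zsd <- zscore(es$sd)
  coord <- cbind(zmed, zsd)
  rownames(coord) <- es$probe_id
  set.seed(seed)
  order_t <- sample(target_probes)
  avail <- pool_probes
  matched <- character(length(order_t))
  for (i in seq_along(order_t)) {
    d2 <- (coord[avail, 1] - coord[order_t[i], 1])^2 +
      (coord[avail, 2] - coord[order_t[i], 2])^2
    j <- which.min(d2)  # ties: first in pool order
    matched[i] <- avail[j]
    avail <- avail[-j]
  }
  ft <- flags[target_probes]; fm <- flags[matched]
  counts <- rbind(target = c(flagged = sum(ft), unflagged = sum(!ft)),
                  matched = c(flagged = sum(fm), unflagged = sum(!fm)))
  fold <- if (sum(fm) == 0) Inf else mean(ft) / mean(fm)
  if (any(colSums(counts) == 0)) {
    stat <- NA_real_; pv <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    stat <- unname(ct$statistic); pv <- ct$p.value
  }
  structure(list(fold = fold, chisq_stat = stat, chisq_p = pv,
                 counts = counts, matched_set = matched),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> fold = %.3f, chi-squared p = %.3g\n",
              x$fold, x$chisq_p))
  print(x$counts)
  invisible(x)
}

#' Per-probe median and SD of expression
#'
#' Convenience summary used as the matching space of
#' [matched_probe_enrichment()].
#'
#' @param expression An [expression_matrix()].
#' @param samples Optional sample ids to restrict to.
#' @return A tibble with `probe_id`, `median`, `sd`.
#' @export
expression_summary <- function(expression, samples = NULL) {
  v <- expression$values
  if (!is.null(samples)) v <- v[, intersect(samples, colnames(v)),
                                drop = FALSE]
  tibble::tibble(probe_id = rownames(v),
                 median = apply(v, 1, stats::median),
                 sd = row_sds(v))
}

#' Positional context of opposite-direction meQTL CpGs
#'
#' Descriptive counts of where discordant (opposite allelic direction
#' across tissues) meQTL CpGs sit relative to gene bodies, with plain
#' chi-squared tests against the remaining CpGs: inside vs outside gene
#' bodies, and exon vs intron within gene bodies.
#'
#' @param opposite_cpgs Character vector of CpG ids with opposite-direction
#'   effects.
#' @param cpg_annotation CpG annotation with `cpg_id` and `body_region`.
#' @return A list with `counts` (body_region x opposite/other),
#'   `p_outside_body` and `p_exon_vs_intron`.
#' @export
opposite_meqtl_context <- function(opposite_cpgs, cpg_annotation) {
  ann <- tibble::as_tibble(cpg_annotation)
  grp <- factor(ifelse(ann$cpg_id %in% opposite_cpgs, "opposite", "other"),
                levels = c("opposite", "other"))
  counts <- table(ann$body_region, grp)
  test_p <- function(tab) {
    if (any(dim(tab) < 2) || any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
      return(NA_real_)
    }
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  outside <- table(ann$body_region == "intergenic", grp)
  inbody <- ann$body_region %in% c("exon", "intron")
  exin <- table(ann$body_region[inbody], grp[inbody])
  list(counts = unclass(counts),
       p_outside_body = test_p(outside),
       p_exon_vs_intron = test_p(exin))
}
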
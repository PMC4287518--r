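#' Enumerate cis feature pairs within a genomic window
#'
#' Pairs every left-hand feature (SNP or CpG) with every right-hand feature
#' (CpG or expression probe) on the same chromosome whose anchors lie within
#' `window_bp` of each other. The anchor of a point feature (SNP, CpG) is its
#' annotated position; the anchor of an interval feature (expression probe)
#' is the interval midpoint, rounded down. The window bound is inclusive:
#' a pair at exactly `window_bp` is kept.
#'
#' @param left,right Annotation tibbles. The first column is taken as the
#'   feature id; a `chrom` column is required, plus either `pos` or
#'   `probe_start`/`probe_end`.
#' @param window_bp Positive window half-width in base pairs (default
#'   250 kb, the conventional cis window).
#' @param chromosomes Optional character vector of admissible chromosome
#'   labels; any label outside it raises an error naming the offender.
#' @return A tibble with columns `left_id`, `right_id`, `chrom`,
#'   `distance_bp` (right anchor minus left anchor, signed) and `pair_kind`,
#'   sorted by (`left_id`, `right_id`). Empty inputs give an empty tibble.
#' @examples
#' snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                    pos = c(1000L, 400000L))
#' cpgs <- data.frame(cpg_id = "cg1", chrom = "1", pos = 2000L)
#' enumerate_cis_pairs(snps, cpgs, 250000)
#' @export
enumerate_cis_pairs <- function(left, right, window_bp = 250000,
                                chromosomes = NULL) {
  if (window_bp <= 0) rlang::abort("`window_bp` must be positive")
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)
  kind <- paste(sub("_id$", "", names(left)[1]),
                sub("_id$", "", names(right)[1]), sep = "-")
  empty <- tibble::tibble(left_id = character(), right_id = character(),
                          chrom = character(), distance_bp = integer(),
                          pair_kind = character())
  if (nrow(left) == 0 || nrow(right) == 0) return(empty)
  check_chroms <- function(a, side) {
    stop_if_not_cols(a, "chrom", paste(side, "annotation"))
    if (anyNA(a$chrom)) rlang::abort(sprintf("NA chromosome on %s side", side))
    if (!is.null(chromosomes)) {
      bad <- setdiff(unique(a$chrom), chromosomes)
      if (length(bad)) {
        rlang::abort(sprintf("unknown chromosome label(s) on %s side: %s",
                             side, paste(bad, collapse = ", ")))
      }
    }
  }
  check_chroms(left, "left"); check_chroms(right, "right")
  l <- tibble::tibble(left_id = as.character(left[[1]]), chrom = left$chrom,
                      .lpos = anchor_position(left))
  r <- tibble::tibble(right_id = as.character(right[[1]]), chrom = right$chrom,
                      .rpos = anchor_position(right))
  pairs <- dplyr::inner_join(l, r, by = "chrom",
                             relationship = "many-to-many") |>
    dplyr::mutate(distance_bp = as.integer(.data$.rpos - .data$.lpos)) |>
    dplyr::filter(abs(.data$distance_bp) <= window_bp) |>
    dplyr::transmute(.data$left_id, .data$right_id, .data$chrom,
                     .data$distance_bp, pair_kind = kind) |>
    dplyr::arrange(.data$left_id, .data$right_id)
  pairs
}

#' Anchor positions of an annotation table
#'
#' Point features use `pos`; interval features use the midpoint of
#' `probe_start`/`probe_end` (floored).
#'
#' @param annotation Annotation tibble.
#' @return Numeric vector of anchor coordinates.
#' @export
anchor_position <- function(annotation) {
  if ("pos" %in% names(annotation)) {
    as.numeric(annotation$pos)
  } else if (all(c("probe_start", "probe_end") %in% names(annotation))) {
    floor((annotation$probe_start + annotation$probe_end) / 2)
  } else {
    rlang::abort("annotation needs `pos` or `probe_start`/`probe_end`")
  }
}

#' Drop SNP-in-probe conflicts from a pair list
#'
#' A SNP whose position falls inside the hybridisation interval of the
#' target methylation probe can perturb the probe signal directly; such
#' SNP-CpG pairs are removed before meQTL mapping. The interval test is
#' 1-based inclusive on both ends.
#'
#' @param pairs Pair tibble from [enumerate_cis_pairs()] with SNPs on the
#'   left and CpGs (or probes) on the right.
#' @param snp_annotation SNP annotation with `snp_id` and `pos`.
#' @param probe_intervals Annotation for the right-hand features with the id
#'   in the first column plus `probe_start` and `probe_end`.
#' @return The retained pairs, with the removed pairs attached as the
#'   `"removed"` attribute (retrieve with `attr(x, "removed")`).
#' @export
exclude_probe_snp_conflicts <- function(pairs, snp_annotation,
                                        probe_intervals) {
  pairs <- tibble::as_tibble(pairs)
  probe_intervals <- tibble::as_tibble(probe_intervals)
  stop_if_not_cols(probe_intervals, c("probe_start", "probe_end"),
                   "probe_intervals")
  unknown <- setdiff(pairs$right_id, as.character(probe_intervals[[1]]))
  if (length(unknown)) {
    rlang::abort(sprintf("pair(s) reference unknown probe(s): %s",
                         paste(utils::head(unknown, 5), collapse = ", ")))
  }
  pidx <- match(pairs$right_id, as.character(probe_intervals[[1]]))
  sidx <- match(pairs$left_id, as.character(snp_annotation$snp_id))
  if (anyNA(sidx)) rlang::abort("pair(s) reference unknown SNP(s)")
  spos <- snp_annotation$pos[sidx]
  conflict <- spos >= probe_intervals$probe_start[pidx] &
    spos <= probe_intervals$probe_end[pidx]
  kept <- pairs[!conflict, ]
  attr(kept, "removed") <- pairs[conflict, ]
  kept
}
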
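#' Omic matrix bundles
#'
#' The package carries each assay as a light S3 bundle of a numeric
#' features-by-samples matrix plus a feature annotation tibble. Three flavours
#' exist: `genotype_matrix` (allele dosages 0/1/2, `NA` allowed),
#' `methylation_matrix` (beta values in \[0, 1\]) and `expression_matrix`
#' (log2 intensities). Rows are features (SNPs, CpGs, expression probes),
#' columns are samples; the on-disk TSV layout mirrors this with the feature
#' id in the first column.
#'
#' @param dosages,betas,log2_intensity Numeric matrix, features in rows and
#'   samples in columns, with feature ids as rownames and sample ids as
#'   colnames.
#' @param snp_annotation,cpg_annotation,probe_annotation Data frame of
#'   per-feature annotation. SNPs need `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` (`maf` is recomputed from the dosages if
#'   absent); CpGs need `cpg_id`, `chrom`, `pos`, `cgi_relation` (one of
#'   island/shore/shelf/other), `gene`, `body_region`, `probe_start`,
#'   `probe_end`; expression probes need `probe_id`, `chrom`, `probe_start`,
#'   `probe_end`, `gene`, `tss_pos`. Coordinates are 1-based inclusive.
#'
#' @return An object of class `genotype_matrix`, `methylation_matrix` or
#'   `expression_matrix`: a list with elements `values` (the matrix) and
#'   `annotation` (a tibble, ordered as the matrix rows).
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 1, 2, 1), 1, 4, dimnames = list("rs1", paste0("s", 1:4))),
#'   data.frame(snp_id = "rs1", chrom = "chr1", pos = 100L,
#'              effect_allele = "A", other_allele = "G")
#' )
#' g$annotation$maf
#' @name omic-matrices
NULL

new_omic_matrix <- function(values, annotation, id_col, class) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (features x samples)")
  }
  annotation <- tibble::as_tibble(annotation)
  stop_if_not_cols(annotation, id_col, "annotation")
  ids <- annotation[[id_col]]
  if (anyDuplicated(ids)) rlang::abort("feature ids must be unique")
  if (is.null(rownames(values))) rownames(values) <- ids
  if (!identical(rownames(values), as.character(ids))) {
    annotation <- annotation[match(rownames(values), ids), ]
    if (anyNA(annotation[[id_col]])) {
      rlang::abort("matrix rownames and annotation ids do not match")
    }
  }
  structure(list(values = values, annotation = annotation),
            id_col = id_col, class = c(class, "omic_matrix"))
}

#' @rdname omic-matrices
#' @export
genotype_matrix <- function(dosages, snp_annotation) {
  stop_if_not_cols(snp_annotation, c("snp_id", "chrom", "pos",
                                     "effect_allele", "other_allele"),
                   "snp_annotation")
  bad <- dosages[!is.na(dosages) & !dosages %in% c(0, 1, 2)]
  if (length(bad)) rlang::abort("dosages must be 0, 1, 2 or NA")
  x <- new_omic_matrix(dosages, snp_annotation, "snp_id", "genotype_matrix")
  if (!"maf" %in% names(x$annotation)) {
    x$annotation$maf <- snp_maf(x$values)
  }
  if (any(x$annotation$maf < 0 | x$annotation$maf > 0.5, na.rm = TRUE)) {
    rlang::abort("maf must lie in [0, 0.5]")
  }
  if (any(x$annotation$pos <= 0)) rlang::abort("positions must be positive")
  x
}

#' @rdname omic-matrices
#' @export
methylation_matrix <- function(betas, cpg_annotation) {
  stop_if_not_cols(cpg_annotation, c("cpg_id", "chrom", "pos", "cgi_relation"),
                   "cpg_annotation")
  if (any(betas < 0 | betas > 1, na.rm = TRUE)) {
    rlang::abort("beta values must lie in [0, 1]")
  }
  ok <- cpg_annotation$cgi_relation %in% c("island", "shore", "shelf", "other")
  if (!all(ok)) {
    rlang::abort("cgi_relation must be one of island/shore/shelf/other")
  }
  new_omic_matrix(betas, cpg_annotation, "cpg_id", "methylation_matrix")
}

#' @rdname omic-matrices
#' @export
expression_matrix <- function(log2_intensity, probe_annotation) {
  stop_if_not_cols(probe_annotation, c("probe_id", "chrom", "probe_start",
                                       "probe_end", "gene"),
                   "probe_annotation")
  if (any(!is.finite(log2_intensity))) {
    rlang::abort("expression values must be finite")
  }
  new_omic_matrix(log2_intensity, probe_annotation, "probe_id",
                  "expression_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d features x %d samples\n", class(x)[1],
              nrow(x$values), ncol(x$values)))
  print(utils::head(x$annotation, 3))
  invisible(x)
}

#' @export
dim.omic_matrix <- function(x) dim(x$values)

# minor allele frequency from a dosage matrix (rows = SNPs)
snp_maf <- function(dosages) {
  p <- rowMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Subset an omic matrix by features and/or samples
#'
#' @param x An omic matrix bundle.
#' @param features,samples Character vectors of ids to keep (order is
#'   honoured); `NULL` keeps everything.
#' @return A bundle of the same class.
#' @export
subset_omic <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omic_matrix"))
  v <- x$values
  a <- x$annotation
  if (!is.null(features)) {
    idx <- match(features, rownames(v))
    if (anyNA(idx)) rlang::abort("unknown feature id(s) in `features`")
    v <- v[idx, , drop = FALSE]
    a <- a[idx, ]
  }
  if (!is.null(samples)) {
    idx <- match(samples, colnames(v))
    if (anyNA(idx)) rlang::abort("unknown sample id(s) in `samples`")
    v <- v[, idx, drop = FALSE]
  }
  structure(list(values = v, annotation = a),
            id_col = attr(x, "id_col"), class = class(x))
}

#' Validate a sample sheet
#'
#' A sample sheet is a plain tibble with one row per sample and columns
#' `sample_id`, `cohort`, `group` (fetal/adult) and `tissue`
#' (liver/muscle/SAT/VAT). Extra columns (e.g. `individual_id` from the
#' simulator) pass through untouched.
#'
#' @param df A data frame.
#' @return The validated tibble.
#' @export
sample_sheet <- function(df) {
  df <- tibble::as_tibble(df)
  stop_if_not_cols(df, c("sample_id", "cohort", "group", "tissue"),
                   "sample sheet")
  if (anyDuplicated(df$sample_id)) rlang::abort("sample_id must be unique")
  if (!all(df$group %in% c("fetal", "adult"))) {
    rlang::abort("group must be 'fetal' or 'adult'")
  }
  if (!all(df$tissue %in% c("liver", "muscle", "SAT", "VAT"))) {
    rlang::abort("tissue must be one of liver/muscle/SAT/VAT")
  }
  cc <- stats::complete.cases(df[c("sample_id", "cohort", "group", "tissue")])
  if (!all(cc)) rlang::abort("every sample needs all four fields")
  df
}
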
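#' Read and write the package's TSV formats
#'
#' All matrices travel as UTF-8 TSV with the feature id in the first column
#' and one column per sample; missing values are written as `NA` and read
#' back from either `NA` or `.`. Annotations and sample sheets are plain TSV
#' with their documented headers. Coordinates are 1-based inclusive
#' throughout.
#'
#' @param x For `write_matrix_tsv`, an omic matrix bundle or a plain numeric
#'   matrix with rownames; for `write_annotation_tsv`, a data frame.
#' @param path File path.
#' @param id_col Name used for the feature-id column on write (defaults to
#'   the bundle's id column, or `"feature_id"` for a bare matrix).
#' @return `read_matrix_tsv` returns a numeric matrix with feature rownames;
#'   `read_annotation_tsv` and `read_sample_sheet` return tibbles; the
#'   writers return `path` invisibly.
#' @name tsv-io
NULL

#' @rdname tsv-io
#' @export
write_matrix_tsv <- function(x, path, id_col = NULL) {
  if (inherits(x, "omic_matrix")) {
    id_col <- id_col %||% attr(x, "id_col")
    x <- x$values
  }
  id_col <- id_col %||% "feature_id"
  df <- tibble::as_tibble(x, rownames = id_col)
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname tsv-io
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, na = c("NA", "."), show_col_types = FALSE,
                        progress = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname tsv-io
#' @export
write_annotation_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  invisible(path)
}

#' @rdname tsv-io
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, na = c("NA", "."), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname tsv-io
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(read_annotation_tsv(path))
}

#' Read genotype dosages from a VCF
#'
#' Converts the GT field to the dosage of the ALT allele (0/1/2; missing or
#' half-called genotypes become `NA`). Multi-allelic records are dropped with
#' a message. The ALT allele is taken as the effect allele.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    rlang::inform(sprintf("dropping %d multi-allelic record(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, ]
  alt_count <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dos <- apply(gt, c(1, 2), alt_count)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(dos) <- ids
  ann <- tibble::tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF
  )
  genotype_matrix(dos, ann)
}

#' Export feature intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start - 1` is written.
#'
#' @param annotation Data frame with `chrom` plus either `pos` (point
#'   features) or `probe_start`/`probe_end`.
#' @param path Output path.
#' @param id_col Column holding the feature name.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path, id_col = names(annotation)[1]) {
  a <- tibble::as_tibble(annotation)
  if (all(c("probe_start", "probe_end") %in% names(a))) {
    start <- a$probe_start; end <- a$probe_end
  } else {
    start <- a$pos; end <- a$pos
  }
  bed <- tibble::tibble(chrom = a$chrom, start = start - 1L, end = end,
                        name = a[[id_col]])
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
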
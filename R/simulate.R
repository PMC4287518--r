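#' Simulation configuration
#'
#' Builds the configuration for the multi-cohort, multi-tissue simulator.
#' The defaults mirror a two-cohort hepatic study design: cohort A
#' contributes 96 adult and 14 fetal liver samples, cohort B contributes 85
#' adults sampled in liver, muscle, subcutaneous (SAT) and visceral (VAT)
#' adipose tissue. Genotypes are constant across tissues of the same
#' individual; methylation and expression noise is redrawn per tissue.
#'
#' Effect sizes are standardized slopes: a planted slope `b` adds
#' `b * z(dosage) * noise_sd` to the trait, so the induced correlation is
#' `b / sqrt(1 + b^2)`. Methylation is generated on a latent M-value-like
#' scale and mapped to beta values through `beta = 2^m / (2^m + 1)`.
#'
#' @param design Tibble with columns `cohort`, `group`, `tissue`, `n` giving
#'   the per-cell sample counts. Individuals are shared across tissues
#'   within a (cohort, group).
#' @param n_snps,n_cpgs,n_probes Feature counts.
#' @param n_chrom Number of simulated chromosomes.
#' @param snp_spacing_bp Mean spacing between SNPs; fixes chromosome length.
#' @param maf_range Range the per-SNP minor allele frequency is drawn from
#'   (uniform); must lie within \[0, 0.5\].
#' @param fraction_meqtl Fraction of CpGs given a cis SNP effect.
#' @param fraction_eqtl Fraction of probes given a cis SNP effect.
#' @param fraction_eqtm Fraction of probes given a cis CpG effect.
#' @param slope_meqtl,slope_eqtl,slope_eqtm Standardized planted slopes.
#' @param fraction_negative_eqtm Probability a planted eQTM slope is
#'   negative (default 0.584, the typical excess of negative
#'   methylation-expression correlations).
#' @param fraction_shared_snp Fraction of planted meQTLs whose SNP also
#'   drives expression of the linked gene (creating eQTL/meQTL overlaps).
#' @param fraction_opposite For shared SNP effects, probability that the
#'   allele raising methylation lowers expression (default 0.7).
#' @param fraction_both Fraction of the eQTM quota placed on probes that
#'   already carry an eQTL (the joint SNP+CpG regime used for variance
#'   partitioning).
#' @param tissue_sharing Named probabilities (`eqtl`, `meqtl`, `eqtm`) that
#'   a liver effect is also active in each other tissue. Defaults 0.45 /
#'   0.70 / 0.04: SNP-methylation effects travel across tissues far more
#'   than SNP-expression effects, and methylation-expression coupling is
#'   almost entirely tissue-specific.
#' @param tissue_flip Probability that a shared effect flips its allelic
#'   direction in a non-liver tissue (default 0.02).
#' @param fraction_dm,fraction_de Fractions of CpGs / probes given a
#'   fetal-vs-adult group effect (defaults 0.08 and 0.07).
#' @param dm_latent_shift Latent-scale fetal shift for affected CpGs; the
#'   default 2.5 yields expected absolute beta differences above 0.2.
#' @param de_log2fc Fetal log2 fold change for affected probes.
#' @param island_hypo_fetal,other_hypo_fetal Probability an affected CpG is
#'   hypomethylated in fetal samples, for island vs non-island CpGs
#'   (defaults 0.86 and 0.5: islands lose methylation in fetal tissue far
#'   more often than they gain it).
#' @param cohort_offset_sd SD of additive per-feature cohort batch offsets.
#' @param noise_sd_m,noise_sd_e Residual SDs on the latent methylation and
#'   log2 expression scales.
#' @param mu_cpg_sd SD of per-CpG latent baselines (mean 0, i.e. beta 0.5).
#' @param mu_probe_mean,mu_probe_sd Per-probe baseline log2 intensity.
#' @param cgi_props Named proportions of island/shore/shelf/other CpGs.
#' @param probe_len Length in bp of CpG and expression probe intervals.
#' @param window_bp Cis window used when placing planted effects.
#' @param seed Mandatory integer seed; fixing it fixes every output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(design = sim_design_default(),
                       n_snps = 600, n_cpgs = 600, n_probes = 300,
                       n_chrom = 4, snp_spacing_bp = 25000,
                       maf_range = c(0.05, 0.5),
                       fraction_meqtl = 0.10, fraction_eqtl = 0.05,
                       fraction_eqtm = 0.05,
                       slope_meqtl = 0.6, slope_eqtl = 0.6, slope_eqtm = 0.5,
                       fraction_negative_eqtm = 0.584,
                       fraction_shared_snp = 0.3, fraction_opposite = 0.7,
                       fraction_both = 0.5,
                       tissue_sharing = c(eqtl = 0.45, meqtl = 0.70,
                                          eqtm = 0.04),
                       tissue_flip = 0.02,
                       fraction_dm = 0.08, fraction_de = 0.07,
                       dm_latent_shift = 2.5, de_log2fc = 3,
                       island_hypo_fetal = 0.86, other_hypo_fetal = 0.5,
                       cohort_offset_sd = 0.3,
                       noise_sd_m = 1, noise_sd_e = 1,
                       mu_cpg_sd = 2, mu_probe_mean = 8, mu_probe_sd = 2,
                       cgi_props = c(island = 0.31, shore = 0.23,
                                     shelf = 0.10, other = 0.36),
                       probe_len = 50L, window_bp = 250000,
                       seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  design <- sample_sheet_design(design)
  fr <- c(fraction_meqtl, fraction_eqtl, fraction_eqtm,
          fraction_negative_eqtm, fraction_shared_snp, fraction_opposite,
          fraction_both, tissue_sharing, tissue_flip, fraction_dm,
          fraction_de, island_hypo_fetal, other_hypo_fetal)
  if (any(fr < 0 | fr > 1)) rlang::abort("all fractions must lie in [0, 1]")
  if (any(c(n_snps, n_cpgs, n_probes) <= 0)) {
    rlang::abort("feature counts must be positive")
  }
  if (min(maf_range) < 0 || max(maf_range) > 0.5) {
    rlang::abort("`maf_range` must lie within [0, 0.5]")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
sim_design_default <- function() {
  tibble::tibble(
    cohort = c("A", "A", "B", "B", "B", "B"),
    group  = c("fetal", "adult", "adult", "adult", "adult", "adult"),
    tissue = c("liver", "liver", "liver", "muscle", "SAT", "VAT"),
    n      = c(14L, 96L, 85L, 85L, 85L, 85L)
  )
}

sample_sheet_design <- function(design) {
  design <- tibble::as_tibble(design)
  stop_if_not_cols(design, c("cohort", "group", "tissue", "n"), "design")
  if (all(design$n == 0)) rlang::abort("design has zero samples everywhere")
  design
}

# ---- internal generators ------------------------------------------------

make_sample_sheet <- function(design) {
  inds <- design |>
    dplyr::group_by(.data$cohort, .data$group) |>
    dplyr::summarise(n_ind = max(.data$n), .groups = "drop")
  rows <- purrr::pmap(design, function(cohort, group, tissue, n) {
    if (n == 0) return(NULL)
    ind <- sprintf("%s_%s_%03d", cohort, group, seq_len(n))
    tibble::tibble(
      sample_id = paste(ind, tissue, sep = "."),
      individual_id = ind, cohort = cohort, group = group, tissue = tissue
    )
  })
  sample_sheet(dplyr::bind_rows(rows))
}

make_annotations <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  per_chr <- function(n) {
    k <- rep(floor(n / cfg$n_chrom), cfg$n_chrom)
    k[seq_len(n - sum(k))] <- k[seq_len(max(0, n - sum(k)))] + 1
    k
  }
  chrom_len <- ceiling(cfg$n_snps / cfg$n_chrom) * cfg$snp_spacing_bp
  place <- function(n) {
    k <- per_chr(n)
    tibble::tibble(
      chrom = rep(chroms, k),
      pos = unlist(lapply(k, function(ki) {
        sort(sample.int(chrom_len, ki, replace = FALSE))
      }))
    )
  }
  snp <- place(cfg$n_snps) |>
    dplyr::mutate(snp_id = sprintf("rs%05d", dplyr::row_number()),
                  effect_allele = "A", other_allele = "G",
                  maf = stats::runif(dplyr::n(), cfg$maf_range[1],
                                     cfg$maf_range[2])) |>
    dplyr::select("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "maf")
  probe <- place(cfg$n_probes) |>
    dplyr::mutate(probe_id = sprintf("ILMN_%05d", dplyr::row_number()),
                  probe_start = .data$pos,
                  probe_end = .data$pos + cfg$probe_len - 1L,
                  gene = sprintf("GENE%04d", dplyr::row_number()),
                  tss_pos = .data$pos) |>
    dplyr::select("probe_id", "chrom", "probe_start", "probe_end", "gene",
                  "tss_pos")
  cpg <- place(cfg$n_cpgs) |>
    dplyr::mutate(
      cpg_id = sprintf("cg%07d", dplyr::row_number()),
      cgi_relation = sample(names(cfg$cgi_props), dplyr::n(), replace = TRUE,
                            prob = cfg$cgi_props),
      body_region = sample(c("TSS-proximal", "exon", "intron", "intergenic"),
                           dplyr::n(), replace = TRUE,
                           prob = c(0.3, 0.2, 0.3, 0.2)),
      probe_start = .data$pos, probe_end = .data$pos + cfg$probe_len - 1L
    )
  # assign each CpG the gene of the nearest probe within the cis window
  pm <- floor((probe$probe_start + probe$probe_end) / 2)
  cpg$gene <- purrr::map2_chr(cpg$chrom, cpg$pos, function(ch, p) {
    i <- which(probe$chrom == ch)
    if (!length(i)) return(NA_character_)
    d <- abs(pm[i] - p)
    j <- i[which.min(d)]
    if (min(d) <= cfg$window_bp) probe$gene[j] else NA_character_
  })
  cpg <- dplyr::select(cpg, "cpg_id", "chrom", "pos", "cgi_relation", "gene",
                       "body_region", "probe_start", "probe_end")
  list(snp = snp, cpg = cpg, probe = probe)
}

#' Simulate genotype dosages
#'
#' Draws a per-SNP allele frequency uniformly from `maf_range` and samples
#' genotypes under Hardy-Weinberg proportions per individual; all tissues of
#' an individual carry identical genotypes.
#'
#' @param config A [sim_config()].
#' @param sheet Optional sample sheet (defaults to the config's design).
#' @param snp_annotation Optional SNP annotation with a `maf` column; built
#'   from the config when absent.
#' @param reseed Set the RNG to `config$seed` first (default `TRUE`; the
#'   internal pipeline passes `FALSE` to keep one seeded stream).
#' @return A [genotype_matrix()] with samples as columns.
#' @export
simulate_genotypes <- function(config, sheet = NULL, snp_annotation = NULL,
                               reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  if (is.null(sheet)) sheet <- make_sample_sheet(config$design)
  if (is.null(snp_annotation)) snp_annotation <- make_annotations(config)$snp
  inds <- unique(sheet$individual_id %||% sheet$sample_id)
  dos_ind <- vapply(snp_annotation$maf, function(p) {
    stats::rbinom(length(inds), 2L, p)
  }, numeric(length(inds)))
  dos_ind <- t(dos_ind)  # SNPs x individuals
  dimnames(dos_ind) <- list(snp_annotation$snp_id, inds)
  ind_of <- sheet$individual_id %||% sheet$sample_id
  dos <- dos_ind[, match(ind_of, inds), drop = FALSE]
  colnames(dos) <- sheet$sample_id
  genotype_matrix(dos, snp_annotation)
}

# theoretical standardization of a dosage row under HWE at frequency p
z_dosage <- function(d, p) {
  s <- sqrt(2 * p * (1 - p))
  if (s == 0) return(rep(0, length(d)))
  (d - 2 * p) / s
}

tissue_activity <- function(tissues, active_str, flipped_str) {
  act <- strsplit(active_str, ",", fixed = TRUE)[[1]]
  flp <- if (is.na(flipped_str) || flipped_str == "") character() else
    strsplit(flipped_str, ",", fixed = TRUE)[[1]]
  sgn <- ifelse(tissues %in% flp, -1, 1)
  sgn * as.numeric(tissues %in% act)
}

draw_tissues <- function(cfg, kind) {
  others <- c("muscle", "SAT", "VAT")
  shared <- others[stats::runif(3) < cfg$tissue_sharing[[kind]]]
  active <- c("liver", shared)
  flipped <- shared[stats::runif(length(shared)) < cfg$tissue_flip]
  list(active = paste(active, collapse = ","),
       flipped = paste(flipped, collapse = ","))
}

truth_row <- function(kind, left, right, slope, tis) {
  tibble::tibble(effect_kind = kind, left_id = left, right_id = right,
                 true_slope = slope,
                 direction = ifelse(slope >= 0, "+", "-"),
                 tissues_active = tis$active, flipped_tissues = tis$flipped,
                 cohorts_active = "A,B")
}

nearest_within <- function(chrom, pos, ann, window) {
  i <- which(ann$chrom == chrom)
  if (!length(i)) return(NA_integer_)
  d <- abs(anchor_position(ann)[i] - pos)
  j <- which.min(d)
  if (d[j] <= window) i[j] else NA_integer_
}

#' Simulate methylation beta values
#'
#' Generates a latent per-CpG value `m = mu + a*z(dosage) + fetal shift +
#' cohort offset + noise` and maps it to the beta scale via
#' `beta = 2^m / (2^m + 1)`. Plants cis meQTLs on a fraction of CpGs (using
#' the nearest SNP within the cis window) and fetal/adult group effects whose
#' direction depends on CpG island context. The planted effects are returned
#' in the `"truth"` attribute; the latent matrix in the `"latent"` attribute.
#'
#' @param genotypes A [genotype_matrix()] whose columns cover the sheet.
#' @param sheet Sample sheet.
#' @param config A [sim_config()].
#' @param cpg_annotation Optional CpG annotation (built from config if NULL).
#' @param reseed As in [simulate_genotypes()].
#' @return A [methylation_matrix()] with `"truth"` and `"latent"` attributes.
#' @export
simulate_methylation <- function(genotypes, sheet, config,
                                 cpg_annotation = NULL, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  cfg <- config
  if (is.null(cpg_annotation)) cpg_annotation <- make_annotations(cfg)$cpg
  ann <- cpg_annotation
  n_c <- nrow(ann); n_s <- nrow(sheet)
  mu <- stats::rnorm(n_c, 0, cfg$mu_cpg_sd)
  lat <- matrix(stats::rnorm(n_c * n_s, 0, cfg$noise_sd_m), n_c, n_s,
                dimnames = list(ann$cpg_id, sheet$sample_id))
  lat <- lat + mu
  cohorts <- sort(unique(sheet$cohort))
  off <- matrix(stats::rnorm(n_c * length(cohorts), 0, cfg$cohort_offset_sd),
                n_c, length(cohorts), dimnames = list(NULL, cohorts))
  lat <- lat + off[, match(sheet$cohort, cohorts), drop = FALSE]

  truth <- list()
  # group (fetal vs adult) effects, island-aware direction
  n_dm <- round(cfg$fraction_dm * n_c)
  if (n_dm > 0 && any(sheet$group == "fetal")) {
    dm_idx <- sample.int(n_c, n_dm)
    p_hypo <- ifelse(ann$cgi_relation[dm_idx] == "island",
                     cfg$island_hypo_fetal, cfg$other_hypo_fetal)
    sgn <- ifelse(stats::runif(n_dm) < p_hypo, -1, 1)
    shift <- sgn * cfg$dm_latent_shift
    fetal <- sheet$group == "fetal"
    lat[dm_idx, fetal] <- lat[dm_idx, fetal] + shift
    truth$dm <- tibble::tibble(
      effect_kind = "diff_meth", left_id = NA_character_,
      right_id = ann$cpg_id[dm_idx], true_slope = shift,
      direction = ifelse(sgn > 0, "+", "-"),
      tissues_active = "liver,muscle,SAT,VAT", flipped_tissues = "",
      cohorts_active = "A,B")
  }
  # cis meQTLs on the nearest SNP
  n_mq <- round(cfg$fraction_meqtl * n_c)
  if (n_mq > 0) {
    cand <- sample.int(n_c, n_c)  # shuffled candidate order
    rows <- list()
    snp_ann <- genotypes$annotation
    for (ci in cand) {
      if (length(rows) >= n_mq) break
      si <- nearest_within(ann$chrom[ci], ann$pos[ci], snp_ann, cfg$window_bp)
      if (is.na(si)) next
      sgn <- sample(c(-1, 1), 1)
      tis <- draw_tissues(cfg, "meqtl")
      slope <- sgn * cfg$slope_meqtl
      zd <- z_dosage(genotypes$values[si, ], snp_ann$maf[si])
      mult <- tissue_activity(sheet$tissue, tis$active, tis$flipped)
      lat[ci, ] <- lat[ci, ] + slope * cfg$noise_sd_m * zd * mult
      rows[[length(rows) + 1]] <-
        truth_row("meqtl", snp_ann$snp_id[si], ann$cpg_id[ci], slope, tis)
    }
    truth$meqtl <- dplyr::bind_rows(rows)
  }
  beta <- 2^lat / (2^lat + 1)
  out <- methylation_matrix(beta, ann)
  attr(out, "latent") <- lat
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Simulate expression log2 intensities
#'
#' Generates `y = mu + b*z(dosage) + c*z(latent methylation) + fetal log2FC +
#' cohort offset + noise`. Plants cis eQTLs (a configurable fraction sharing
#' the SNP of an existing meQTL on the same gene, with an opposite allelic
#' direction with probability `fraction_opposite`), eQTMs (negative slope
#' with probability `fraction_negative_eqtm`, preferentially on probes that
#' already carry an eQTL), and fetal/adult group effects. Planted effects are
#' returned in the `"truth"` attribute.
#'
#' @param genotypes A [genotype_matrix()].
#' @param methylation A [simulate_methylation()] result (its `"latent"` and
#'   `"truth"` attributes are used).
#' @param sheet Sample sheet.
#' @param config A [sim_config()].
#' @param probe_annotation Optional probe annotation.
#' @param reseed As in [simulate_genotypes()].
#' @return An [expression_matrix()] with a `"truth"` attribute.
#' @export
simulate_expression <- function(genotypes, methylation, sheet, config,
                                probe_annotation = NULL, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  cfg <- config
  if (is.null(probe_annotation)) probe_annotation <- make_annotations(cfg)$probe
  ann <- probe_annotation
  lat <- attr(methylation, "latent")
  meth_truth <- attr(methylation, "truth") %||% tibble::tibble()
  cpg_ann <- methylation$annotation
  snp_ann <- genotypes$annotation
  n_p <- nrow(ann); n_s <- nrow(sheet)
  mu <- stats::rnorm(n_p, cfg$mu_probe_mean, cfg$mu_probe_sd)
  y <- matrix(stats::rnorm(n_p * n_s, 0, cfg$noise_sd_e), n_p, n_s,
              dimnames = list(ann$probe_id, sheet$sample_id))
  y <- y + mu
  cohorts <- sort(unique(sheet$cohort))
  off <- matrix(stats::rnorm(n_p * length(cohorts), 0, cfg$cohort_offset_sd),
                n_p, length(cohorts), dimnames = list(NULL, cohorts))
  y <- y + off[, match(sheet$cohort, cohorts), drop = FALSE]

  truth <- list()
  # fetal/adult group effects
  n_de <- round(cfg$fraction_de * n_p)
  if (n_de > 0 && any(sheet$group == "fetal")) {
    de_idx <- sample.int(n_p, n_de)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    fetal <- sheet$group == "fetal"
    y[de_idx, fetal] <- y[de_idx, fetal] + sgn * cfg$de_log2fc
    truth$de <- tibble::tibble(
      effect_kind = "diff_expr", left_id = NA_character_,
      right_id = ann$probe_id[de_idx], true_slope = sgn * cfg$de_log2fc,
      direction = ifelse(sgn > 0, "+", "-"),
      tissues_active = "liver,muscle,SAT,VAT", flipped_tissues = "",
      cohorts_active = "A,B")
  }

  add_eqtl <- function(pi, si, slope, tis) {
    zd <- z_dosage(genotypes$values[si, ], snp_ann$maf[si])
    mult <- tissue_activity(sheet$tissue, tis$active, tis$flipped)
    y[pi, ] <<- y[pi, ] + slope * cfg$noise_sd_e * zd * mult
    truth_row("eqtl", snp_ann$snp_id[si], ann$probe_id[pi], slope, tis)
  }

  # eQTLs: first shared-SNP effects piggybacking on planted meQTLs
  n_eq <- round(cfg$fraction_eqtl * n_p)
  rows <- list()
  used_probes <- integer()
  mq <- if (nrow(meth_truth)) {
    dplyr::filter(meth_truth, .data$effect_kind == "meqtl")
  } else tibble::tibble()
  if (nrow(mq) > 0 && cfg$fraction_shared_snp > 0 && n_eq > 0) {
    shared_take <- which(stats::runif(nrow(mq)) < cfg$fraction_shared_snp)
    for (k in shared_take) {
      if (length(rows) >= n_eq) break
      gene <- cpg_ann$gene[match(mq$right_id[k], cpg_ann$cpg_id)]
      if (is.na(gene)) next
      pi <- match(gene, ann$gene)
      if (is.na(pi) || pi %in% used_probes) next
      si <- match(mq$left_id[k], snp_ann$snp_id)
      # SNP must be cis to the probe too
      pmid <- floor((ann$probe_start[pi] + ann$probe_end[pi]) / 2)
      if (ann$chrom[pi] != snp_ann$chrom[si] ||
          abs(pmid - snp_ann$pos[si]) > cfg$window_bp) next
      opp <- stats::runif(1) < cfg$fraction_opposite
      slope <- if (opp) -sign(mq$true_slope[k]) * cfg$slope_eqtl
               else sign(mq$true_slope[k]) * cfg$slope_eqtl
      tis <- draw_tissues(cfg, "eqtl")
      rows[[length(rows) + 1]] <- add_eqtl(pi, si, slope, tis)
      used_probes <- c(used_probes, pi)
    }
  }
  # then independent eQTLs up to the quota
  for (pi in sample.int(n_p, n_p)) {
    if (length(rows) >= n_eq) break
    if (pi %in% used_probes) next
    pmid <- floor((ann$probe_start[pi] + ann$probe_end[pi]) / 2)
    si <- nearest_within(ann$chrom[pi], pmid, snp_ann, cfg$window_bp)
    if (is.na(si)) next
    slope <- sample(c(-1, 1), 1) * cfg$slope_eqtl
    tis <- draw_tissues(cfg, "eqtl")
    rows[[length(rows) + 1]] <- add_eqtl(pi, si, slope, tis)
    used_probes <- c(used_probes, pi)
  }
  truth$eqtl <- dplyr::bind_rows(rows)

  # eQTMs: couple expression to the latent methylation of a cis CpG
  n_em <- round(cfg$fraction_eqtm * n_p)
  em_rows <- list()
  if (n_em > 0 && !is.null(lat)) {
    n_on_eqtl <- min(round(cfg$fraction_both * n_em), length(used_probes))
    pool_eqtl <- if (n_on_eqtl > 0) {
      sample(used_probes, n_on_eqtl)
    } else integer()
    pool_rest <- setdiff(sample.int(n_p, n_p), used_probes)
    targets <- c(pool_eqtl, pool_rest)
    for (pi in targets) {
      if (length(em_rows) >= n_em) break
      pmid <- floor((ann$probe_start[pi] + ann$probe_end[pi]) / 2)
      # prefer a CpG of the same gene, else the nearest cis CpG
      ci <- which(cpg_ann$gene %in% ann$gene[pi] &
                    cpg_ann$chrom == ann$chrom[pi] &
                    abs(cpg_ann$pos - pmid) <= cfg$window_bp)
      if (!length(ci)) {
        ci <- nearest_within(ann$chrom[pi], pmid, cpg_ann, cfg$window_bp)
        if (is.na(ci)) next
      } else ci <- ci[which.min(abs(cpg_ann$pos[ci] - pmid))]
      sgn <- if (stats::runif(1) < cfg$fraction_negative_eqtm) -1 else 1
      slope <- sgn * cfg$slope_eqtm
      zl <- zscore(lat[ci, ])
      tis <- draw_tissues(cfg, "eqtm")
      mult <- tissue_activity(sheet$tissue, tis$active, tis$flipped)
      y[pi, ] <- y[pi, ] + slope * cfg$noise_sd_e * zl * mult
      em_rows[[length(em_rows) + 1]] <-
        truth_row("eqtm", cpg_ann$cpg_id[ci], ann$probe_id[pi], slope, tis)
    }
  }
  truth$eqtm <- dplyr::bind_rows(em_rows)

  out <- expression_matrix(y, ann)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Simulate a complete multi-cohort, multi-tissue study
#'
#' Composes [simulate_genotypes()], [simulate_methylation()] and
#' [simulate_expression()] under a single seeded RNG stream and collects the
#' planted effects into one truth table.
#'
#' @param config A [sim_config()].
#' @return A list of class `regulome_sim` with elements `sample_sheet`,
#'   `genotypes`, `methylation`, `expression`, `truth` (the planted-effect
#'   registry) and `config`. Matrices span all samples; use
#'   [subset_omic()] with the sample sheet to extract a
#'   (cohort, group, tissue) cell.
#' @examples
#' cfg <- sim_config(n_snps = 60, n_cpgs = 60, n_probes = 30,
#'                   design = data.frame(cohort = "A", group = "adult",
#'                                       tissue = "liver", n = 20),
#'                   seed = 1)
#' sim <- simulate_study(cfg)
#' sim$truth
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ann <- make_annotations(config)
  sheet <- make_sample_sheet(config$design)
  geno <- simulate_genotypes(config, sheet, ann$snp, reseed = FALSE)
  meth <- simulate_methylation(geno, sheet, config, ann$cpg, reseed = FALSE)
  expr <- simulate_expression(geno, meth, sheet, config, ann$probe,
                              reseed = FALSE)
  truth <- dplyr::bind_rows(attr(meth, "truth"), attr(expr, "truth"))
  structure(list(sample_sheet = sheet, genotypes = geno, methylation = meth,
                 expression = expr, truth = truth, config = config),
            class = "regulome_sim")
}

#' @export
print.regulome_sim <- function(x, ...) {
  cat(sprintf(
    "<regulome_sim> %d samples | %d SNPs, %d CpGs, %d probes | %d planted effects\n",
    nrow(x$sample_sheet), nrow(x$genotypes$values), nrow(x$methylation$values),
    nrow(x$expression$values), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated study to TSV files
#'
#' Writes the genotype, methylation and expression matrices, their
#' annotations, the sample sheet and the truth table into `dir` using the
#' package's TSV dialect.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  stopifnot(inherits(sim, "regulome_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(sim$genotypes, p("genotypes.tsv"))
  write_matrix_tsv(sim$methylation, p("methylation.tsv"))
  write_matrix_tsv(sim$expression, p("expression.tsv"))
  write_annotation_tsv(sim$genotypes$annotation, p("snp_annotation.tsv"))
  write_annotation_tsv(sim$methylation$annotation, p("cpg_annotation.tsv"))
  write_annotation_tsv(sim$expression$annotation, p("probe_annotation.tsv"))
  write_annotation_tsv(sim$sample_sheet, p("sample_sheet.tsv"))
  write_annotation_tsv(sim$truth, p("truth_table.tsv"))
  invisible(dir)
}
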
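# Genotype / variant / cell quality control and allele-dropout estimation.
#
# All comparators are strict, exactly as the QC rules are stated for this
# assay: quality > 30, depth > 10, alt fraction > 20% (non-WT calls only),
# variant genotyped in > 50% of cells, mutated in >= 1% of cells, cell with
# >= 50% of genotypes present, population MAF <= 0.01 unless whitelisted.

#' QC thresholds for genotype, variant and cell filtering
#'
#' @param gq_min genotype-quality floor (calls kept when quality > gq_min)
#' @param dp_min read-depth floor (kept when depth > dp_min)
#' @param af_min alternate-allele-fraction floor for non-WT calls
#' @param variant_genotyped_min minimum genotyped fraction for a variant
#' @param variant_mutated_min minimum mutated (HET/HOM) cell fraction
#' @param cell_genotyped_min minimum genotyped fraction for a cell
#' @param maf_max maximum population minor-allele frequency (whitelisted
#'   variants bypass this filter only)
#' @return list of class `qc_thresholds`
#' @export
qc_thresholds <- function(gq_min = 30, dp_min = 10, af_min = 0.20,
                          variant_genotyped_min = 0.50,
                          variant_mutated_min = 0.01,
                          cell_genotyped_min = 0.50, maf_max = 0.01) {
  fr <- c(af_min, variant_genotyped_min, variant_mutated_min,
          cell_genotyped_min, maf_max)
  stopifnot(all(fr >= 0 & fr <= 1), gq_min >= 0, dp_min >= 0)
  structure(as.list(environment())[
    c("gq_min", "dp_min", "af_min", "variant_genotyped_min",
      "variant_mutated_min", "cell_genotyped_min", "maf_max")],
    class = "qc_thresholds")
}

#' Filter individual genotype calls on quality, depth and allele fraction
#'
#' Calls failing any per-call threshold are set to `MISSING`. The
#' alternate-allele-fraction criterion applies to non-WT calls only
#' (reference calls carry no alternate reads by definition).
#'
#' @param x a [genotype_matrix()]
#' @param thresholds a [qc_thresholds()]
#' @return a [genotype_matrix()] with failing calls set to `MISSING`
#' @export
filter_genotype_calls <- function(x, thresholds = qc_thresholds()) {
  called <- x$gt != "MISSING"
  fail <- called & (
    !(x$quality > thresholds$gq_min) |
    !(x$depth > thresholds$dp_min) |
    (x$gt != "WT" & !(x$alt_fraction > thresholds$af_min))
  )
  fail[is.na(fail)] <- TRUE
  fail <- fail & called
  if (any(fail)) {
    rlang::inform(sprintf("genotype-call QC: %d of %d calls set to MISSING",
                          sum(fail), sum(called)))
  }
  x$gt[fail] <- "MISSING"
  x$depth[fail] <- NA
  x$quality[fail] <- NA
  x$alt_fraction[fail] <- NA
  x
}

variant_fractions <- function(x) {
  genotyped <- colMeans(x$gt != "MISSING")
  mutated_of_all <- colMeans(x$gt == "HET" | x$gt == "HOM")
  tibble::tibble(variant_id = x$variants$variant_id,
                 genotyped_fraction = genotyped,
                 mutated_fraction = mutated_of_all)
}

#' Filter variants after per-call QC
#'
#' Keeps variants genotyped in more than half the cells, mutated in at
#' least 1% of cells, with a protein-affecting consequence, and rare in the
#' population (or whitelisted, which bypasses the MAF filter only).
#' Variants failing the genotyped-fraction rule but showing good residual
#' quality (median quality and median alt fraction above the per-call
#' floors among mutated cells) are returned as `reported_only`: visible in
#' reports but never used to define a clone.
#'
#' @param x a [genotype_matrix()] already passed through
#'   [filter_genotype_calls()]
#' @param thresholds a [qc_thresholds()]
#' @param whitelist character vector of variant_ids known from bulk
#'   sequencing (bypass the population-MAF filter)
#' @return list with `kept` (a [genotype_matrix()] restricted to kept
#'   variants), `summary` (tibble with one row per variant and a `status`
#'   column in kept/reported_only/dropped plus the failing rule)
#' @export
filter_variants <- function(x, thresholds = qc_thresholds(),
                            whitelist = character(0)) {
  if (length(x$barcodes) == 0 || nrow(x$variants) == 0) {
    rlang::abort("empty genotype matrix")
  }
  fr <- variant_fractions(x)
  v <- x$variants
  wl <- v$whitelisted | v$variant_id %in% whitelist
  pass_gt <- fr$genotyped_fraction > thresholds$variant_genotyped_min
  pass_mut <- fr$mutated_fraction >= thresholds$variant_mutated_min
  pass_csq <- v$consequence %in% NONSYN_CONSEQUENCES
  pass_maf <- wl | !(v$population_maf > thresholds$maf_max)
  kept <- pass_gt & pass_mut & pass_csq & pass_maf

  # rescue lane: well-supported variants on under-genotyped amplicons
  med_q <- med_af <- rep(NA_real_, nrow(v))
  for (j in which(!pass_gt & pass_mut & pass_csq & pass_maf)) {
    mut <- x$gt[, j] %in% c("HET", "HOM")
    if (!any(mut)) next
    med_q[j] <- stats::median(x$quality[mut, j], na.rm = TRUE)
    med_af[j] <- stats::median(x$alt_fraction[mut, j], na.rm = TRUE)
  }
  reported <- !kept & !is.na(med_q) & med_q > thresholds$gq_min &
    med_af > thresholds$af_min

  status <- dplyr::case_when(kept ~ "kept", reported ~ "reported_only",
                             TRUE ~ "dropped")
  reason <- dplyr::case_when(
    kept ~ NA_character_,
    !pass_maf ~ "population_maf",
    !pass_csq ~ "consequence",
    !pass_mut ~ "mutated_fraction",
    !pass_gt & !reported ~ "genotyped_fraction",
    TRUE ~ "genotyped_fraction")
  summary <- dplyr::bind_cols(fr, tibble::tibble(
    gene = v$gene, consequence = v$consequence,
    population_maf = v$population_maf, whitelisted = wl,
    status = status, drop_reason = reason))
  list(kept = gm_subset(x, variants = which(kept)), summary = summary)
}

#' Remove cells with too few genotyped calls
#'
#' @param x a [genotype_matrix()] (after variant filtering)
#' @param thresholds a [qc_thresholds()]; cells with genotyped fraction
#'   strictly below `cell_genotyped_min` are removed
#' @return a filtered [genotype_matrix()]
#' @export
filter_cells <- function(x, thresholds = qc_thresholds()) {
  if (nrow(x$variants) == 0) return(x)  # no genotypes demanded of any cell
  frac <- rowMeans(x$gt != "MISSING")
  keep <- !(frac < thresholds$cell_genotyped_min)
  if (!any(keep)) rlang::abort("all cells removed by cell QC")
  if (any(!keep)) {
    rlang::inform(sprintf("cell QC: %d of %d cells removed",
                          sum(!keep), length(keep)))
  }
  gm_subset(x, cells = which(keep))
}

#' Variant allele frequency by cell count
#'
#' Category-based VAF: `100 * (n_HET + 2 n_HOM) / (2 n_genotyped)`, the
#' percentage of mutated alleles among genotyped alleles.
#'
#' @param gt_column character vector of calls for one variant
#' @return percentage in [0, 100]
#' @export
vaf_by_cell_count <- function(gt_column) {
  n_gen <- sum(gt_column != "MISSING")
  if (n_gen == 0) rlang::abort("no genotyped cells for this variant")
  100 * (sum(gt_column == "HET") + 2 * sum(gt_column == "HOM")) / (2 * n_gen)
}

#' Select germline heterozygous variants from a paired sample
#'
#' Germline heterozygous variants anchor allele-dropout estimation: they
#' are mutated (HET or HOM) in at least 92% of genotyped cells at BOTH
#' timepoints and their VAF-by-cell-count sits close to 50% (inside
#' [49.2, 52.7]) at both.
#'
#' @param gm_dx,gm_tx [genotype_matrix()] at diagnosis / post-treatment
#'   (after per-call QC), sharing a variant table
#' @param mutated_min minimum mutated fraction of genotyped cells (0.92)
#' @param vaf_window VAF-by-cell-count window in percent
#' @return tibble of selected variants with per-timepoint VAF and mutated
#'   fractions
#' @export
select_germline_het <- function(gm_dx, gm_tx, mutated_min = 0.92,
                                vaf_window = c(49.2, 52.7)) {
  shared <- intersect(gm_dx$variants$variant_id, gm_tx$variants$variant_id)
  if (!length(shared)) rlang::abort("no shared variants across timepoints")
  stats_one <- function(gm) {
    j <- match(shared, gm$variants$variant_id)
    purrr::map_dfr(j, function(k) {
      col <- gm$gt[, k]
      gen <- col != "MISSING"
      tibble::tibble(
        mutated = if (any(gen)) mean(col[gen] %in% c("HET", "HOM")) else 0,
        vaf = if (any(gen)) vaf_by_cell_count(col) else NA_real_)
    })
  }
  a <- stats_one(gm_dx)
  b <- stats_one(gm_tx)
  ok <- a$mutated >= mutated_min & b$mutated >= mutated_min &
    !is.na(a$vaf) & !is.na(b$vaf) &
    a$vaf >= vaf_window[1] & a$vaf <= vaf_window[2] &
    b$vaf >= vaf_window[1] & b$vaf <= vaf_window[2]
  tibble::tibble(variant_id = shared,
                 mutated_dx = a$mutated, mutated_tx = b$mutated,
                 vaf_dx = a$vaf, vaf_tx = b$vaf)[ok, ]
}

#' Estimate the allele-dropout rate of a sample
#'
#' At a germline heterozygous site every cell is truly HET, so apparent WT
#' or HOM calls are dropout events: per-variant
#' `ADO = 100 * (n_WT + n_HOM) / n_genotyped`. The sample estimate averages
#' the five selected variants whose VAF-by-cell-count is nearest 50% (all
#' of them, with a warning, when fewer than five qualify).
#'
#' @param gm a [genotype_matrix()] for one sample (after per-call QC)
#' @param germline_variants character vector of selected germline
#'   heterozygous variant ids (see [select_germline_het()])
#' @param n_variants number of variants averaged (5)
#' @return list of class `ado_estimate`: `sample_ado` (percent),
#'   `per_variant` tibble, `variants_used`
#' @export
ado_rate <- function(gm, germline_variants, n_variants = 5) {
  j <- match(germline_variants, gm$variants$variant_id)
  j <- j[!is.na(j)]
  if (!length(j)) {
    rlang::abort(paste0(
      "no germline heterozygous variants available for ADO estimation; ",
      "check the VAF window and mutated-fraction criteria"))
  }
  per <- purrr::map_dfr(j, function(k) {
    col <- gm$gt[, k]
    gen <- sum(col != "MISSING")
    tibble::tibble(variant_id = gm$variants$variant_id[k],
                   n_genotyped = gen,
                   ado = 100 * sum(col %in% c("WT", "HOM")) / gen,
                   vaf = vaf_by_cell_count(col))
  })
  if (nrow(per) < n_variants) {
    rlang::warn(sprintf(
      "only %d germline variants qualify (target %d); averaging all",
      nrow(per), n_variants))
    used <- per
  } else {
    used <- per[order(abs(per$vaf - 50))[seq_len(n_variants)], ]
  }
  structure(list(sample_ado = mean(used$ado), per_variant = per,
                 variants_used = used$variant_id),
            class = "ado_estimate")
}

#' @export
print.ado_estimate <- function(x, ...) {
  cat(sprintf("<ado_estimate> sample ADO %.2f%% from %d variants\n",
              x$sample_ado, length(x$variants_used)))
  invisible(x)
}

#' Run the full DNA QC lane on one sample
#'
#' Convenience wrapper: per-call filter, variant filter, cell filter.
#'
#' @param gm a [genotype_matrix()]
#' @param thresholds a [qc_thresholds()]
#' @param whitelist variant ids from bulk sequencing
#' @return list with `genotype` (QC-passing matrix over kept variants),
#'   `calls_qc` (matrix after per-call QC, all variants — the substrate for
#'   germline/ADO work), `variant_summary`
#' @export
qc_sample <- function(gm, thresholds = qc_thresholds(),
                      whitelist = character(0)) {
  calls <- filter_genotype_calls(gm, thresholds)
  vres <- filter_variants(calls, thresholds, whitelist)
  kept <- if (nrow(vres$kept$variants) > 0) {
    filter_cells(vres$kept, thresholds)
  } else {
    vres$kept
  }
  list(genotype = kept, calls_qc = calls, variant_summary = vres$summary)
}
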
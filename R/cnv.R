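# Amplicon-count normalization and clone-level ploidy against a wild-type
# diploid baseline; CNV-clone detection from heterozygous-VAF shifts.

#' Drop amplicons detected in fewer than half the cells
#'
#' "Detected" means at least one read in a cell.
#'
#' @param am an [amplicon_matrix()]
#' @param min_cell_fraction detection-fraction floor (0.5; amplicons
#'   strictly below it are removed)
#' @return a filtered [amplicon_matrix()]
#' @export
filter_amplicons <- function(am, min_cell_fraction = 0.5) {
  detected <- colMeans(am$counts > 0)
  keep <- !(detected < min_cell_fraction)
  if (!any(keep)) rlang::abort("all amplicons removed by detection filter")
  if (any(!keep)) {
    rlang::inform(sprintf("amplicon filter: %d of %d amplicons removed",
                          sum(!keep), length(keep)))
  }
  amplicon_matrix(am$counts[, keep, drop = FALSE],
                  am$amplicons[keep, , drop = FALSE], am$barcodes)
}

#' Normalize amplicon reads for cell and amplicon effects
#'
#' Two-step normalization: each cell's counts are divided by that cell's
#' total (removing library-size effects), then each amplicon is divided by
#' its mean across cells (removing amplification-efficiency effects). After
#' both steps every amplicon has mean 1 across cells.
#'
#' @param am an [amplicon_matrix()] (after [filter_amplicons()])
#' @return list of class `normalized_amplicons`: `values` (cells x
#'   amplicons), `amplicons`, `barcodes`
#' @export
normalize_reads <- function(am) {
  totals <- rowSums(am$counts)
  zero <- totals == 0
  if (any(zero)) {
    rlang::warn(sprintf("%d zero-total cells removed before normalization",
                        sum(zero)))
  }
  counts <- am$counts[!zero, , drop = FALSE]
  vals <- counts / rowSums(counts)
  vals <- sweep(vals, 2, colMeans(vals), "/")
  structure(list(values = vals, amplicons = am$amplicons,
                 barcodes = am$barcodes[!zero]),
            class = "normalized_amplicons")
}

#' Per-clone per-amplicon ploidy against a diploid baseline
#'
#' `ploidy(clone, amplicon) = 2 * median over clone cells / median over
#' baseline cells` of the normalized counts, so the baseline clone sits at
#' exactly 2 copies by construction. Region-level calls take the median
#' ploidy over a region's amplicons: loss below `loss_cutoff`, gain above
#' `gain_cutoff` (midpoints between integer copy states).
#'
#' @param norm a [normalize_reads()] result
#' @param assignments tibble (`barcode`, `clone_id`) from [call_clones()]
#' @param baseline clone id known to be diploid (default `"WT"`)
#' @param min_baseline_cells floor on baseline size (50)
#' @param loss_cutoff,gain_cutoff region-call thresholds (1.5 / 2.5)
#' @param regions optional tibble (`region`, `chrom`, `start`, `end`);
#'   defaults to one region per chromosome in the panel
#' @return list of class `ploidy_table`: `ploidy` (tibble `clone_id`,
#'   `amplicon_id`, `ploidy`), `region_calls` (tibble `clone_id`, `region`,
#'   `median_ploidy`, `call`)
#' @export
compute_ploidy <- function(norm, assignments, baseline = "WT",
                           min_baseline_cells = 50,
                           loss_cutoff = 1.5, gain_cutoff = 2.5,
                           regions = NULL) {
  asg <- assignments[assignments$barcode %in% norm$barcodes, ]
  base_cells <- asg$barcode[asg$clone_id == baseline]
  if (length(base_cells) < min_baseline_cells) {
    alt <- names(sort(table(asg$clone_id), decreasing = TRUE))[1]
    rlang::abort(sprintf(
      "baseline clone '%s' has %d cells (< %d); consider baseline '%s'",
      baseline, length(base_cells), min_baseline_cells, alt))
  }
  base_med <- apply(norm$values[match(base_cells, norm$barcodes), ,
                                drop = FALSE], 2, stats::median)
  base_med[base_med == 0] <- NA  # undetected in baseline: not evaluable
  clone_ids <- unique(asg$clone_id)
  ploidy <- purrr::map_dfr(clone_ids, function(cid) {
    rows <- match(asg$barcode[asg$clone_id == cid], norm$barcodes)
    med <- apply(norm$values[rows, , drop = FALSE], 2, stats::median)
    tibble::tibble(clone_id = cid, amplicon_id = norm$amplicons$amplicon_id,
                   n_cells = length(rows), ploidy = 2 * med / base_med)
  })
  if (is.null(regions)) {
    regions <- norm$amplicons |>
      dplyr::group_by(region = .data$chrom, chrom = .data$chrom) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
  }
  amp_region <- purrr::map_chr(seq_len(nrow(norm$amplicons)), function(i) {
    a <- norm$amplicons[i, ]
    hit <- regions$chrom == a$chrom & regions$start <= a$start &
      regions$end >= a$end
    if (any(hit)) regions$region[which(hit)[1]] else NA_character_
  })
  region_calls <- ploidy |>
    dplyr::mutate(region = amp_region[match(.data$amplicon_id,
                                            norm$amplicons$amplicon_id)]) |>
    dplyr::filter(!is.na(.data$region), !is.na(.data$ploidy)) |>
    dplyr::group_by(.data$clone_id, .data$region) |>
    dplyr::summarise(median_ploidy = stats::median(.data$ploidy),
                     n_amplicons = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(call = dplyr::case_when(
      .data$median_ploidy < loss_cutoff ~ "loss",
      .data$median_ploidy > gain_cutoff ~ "gain",
      TRUE ~ "neutral"))
  structure(list(ploidy = ploidy, region_calls = region_calls,
                 baseline = baseline),
            class = "ploidy_table")
}

#' @export
print.ploidy_table <- function(x, ...) {
  nonneutral <- sum(x$region_calls$call != "neutral")
  cat(sprintf("<ploidy_table> %d clones x %d amplicons; %d non-neutral region calls\n",
              dplyr::n_distinct(x$ploidy$clone_id),
              dplyr::n_distinct(x$ploidy$amplicon_id), nonneutral))
  invisible(x)
}

#' Detect CNV-defined clones from heterozygous-VAF shifts
#'
#' Copy-number events unbalance the within-cell allele fraction of
#' germline heterozygous variants on the affected region: a loss pushes the
#' alt fraction towards 0 or 1, a gain towards 1/3 or 2/3. Each clone's
#' per-cell alt fractions at the region's het variants are compared against
#' the wild-type clone's; a clone is flagged when the absolute difference
#' in means exceeds `shift_min` with rank-sum confirmation.
#'
#' @param gm a [genotype_matrix()]; pass raw (pre-call-QC) calls so that
#'   strongly shifted alleles, which per-call QC would blank, stay visible
#' @param region list or tibble row with `chrom` and optional
#'   `start`/`end` bounds
#' @param assignments tibble (`barcode`, `clone_id`)
#' @param het_variants variant ids of germline heterozygous variants
#' @param baseline baseline clone id ("WT")
#' @param shift_min minimum absolute mean alt-fraction shift (0.15)
#' @param alpha rank-sum confirmation level (0.05)
#' @return tibble per clone: `clone_id`, `evaluable`, `cnv_flag`,
#'   `mean_af`, `baseline_af`, `shift`, `p_value`, `direction`
#' @export
detect_cnv_clone <- function(gm, region, assignments, het_variants,
                             baseline = "WT", shift_min = 0.15,
                             alpha = 0.05) {
  v <- gm$variants
  in_region <- v$variant_id %in% het_variants & v$chrom == region$chrom
  if (!is.null(region$start)) {
    in_region <- in_region & v$pos >= region$start & v$pos < region$end
  }
  clone_ids <- setdiff(unique(assignments$clone_id), baseline)
  if (!any(in_region)) {
    return(tibble::tibble(clone_id = clone_ids, evaluable = FALSE,
                          cnv_flag = NA, mean_af = NA_real_,
                          baseline_af = NA_real_, shift = NA_real_,
                          p_value = NA_real_, direction = NA_character_))
  }
  af_cells <- function(cid) {
    rows <- match(assignments$barcode[assignments$clone_id == cid],
                  gm$barcodes)
    rows <- rows[!is.na(rows)]
    af <- gm$alt_fraction[rows, in_region, drop = FALSE]
    het <- gm$gt[rows, in_region, drop = FALSE] == "HET"
    af[het & !is.na(af)]
  }
  base_af <- af_cells(baseline)
  purrr::map_dfr(clone_ids, function(cid) {
    af <- af_cells(cid)
    if (length(af) < 10 || length(base_af) < 10) {
      return(tibble::tibble(clone_id = cid, evaluable = FALSE,
                            cnv_flag = NA, mean_af = NA_real_,
                            baseline_af = NA_real_, shift = NA_real_,
                            p_value = NA_real_, direction = NA_character_))
    }
    shift <- mean(af) - mean(base_af)
    p <- stats::wilcox.test(af, base_af, exact = FALSE)$p.value
    flag <- abs(shift) > shift_min && p < alpha
    direction <- if (!flag) NA_character_ else {
      # loss skews towards 0/1, gain towards 1/3 or 2/3
      d_loss <- min(abs(mean(af) - 0), abs(mean(af) - 1))
      d_gain <- min(abs(mean(af) - 1 / 3), abs(mean(af) - 2 / 3))
      if (d_loss < d_gain) "loss" else "gain"
    }
    tibble::tibble(clone_id = cid, evaluable = TRUE, cnv_flag = flag,
                   mean_af = mean(af), baseline_af = mean(base_af),
                   shift = shift, p_value = p, direction = direction)
  })
}
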
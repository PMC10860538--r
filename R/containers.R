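#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

GT_LEVELS <- c("WT", "HET", "HOM", "MISSING")

# numeric Tapestri-style codes accepted on load
GT_CODE_MAP <- c(`0` = "WT", `1` = "HET", `2` = "HOM", `3` = "MISSING")

CONSEQUENCE_LEVELS <- c("missense", "nonsense", "frameshift", "splice",
                        "synonymous", "other")
NONSYN_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice")

TIMEPOINT_LEVELS <- c("diagnosis", "post_treatment")

#' Construct a cell-by-variant genotype matrix
#'
#' Bundles the four aligned call layers of a targeted single-cell DNA run:
#' the categorical genotype call, its read depth, its phred-like genotype
#' quality, and the fraction of alternate-allele reads. Rows are cell
#' barcodes, columns are variants.
#'
#' @param gt character matrix of calls in `c("WT","HET","HOM","MISSING")`;
#'   numeric codes 0/1/2/3 are accepted and mapped. Any other code is mapped
#'   to `MISSING` with a warning.
#' @param depth,quality,alt_fraction numeric matrices aligned with `gt`.
#'   Entries may be `NA` where `gt` is `MISSING`.
#' @param variants tibble with one row per column of `gt`; must contain
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, and
#'   may contain `population_maf`, `whitelisted`, `pathogenicity`.
#' @param barcodes character vector of unique cell identifiers (defaults to
#'   the rownames of `gt`).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `gt`, `depth`, `quality`, `alt_fraction` (matrices), `variants`
#'   (tibble) and `barcodes`.
#' @export
genotype_matrix <- function(gt, depth, quality, alt_fraction, variants,
                            barcodes = rownames(gt)) {
  gt <- as.matrix(gt)
  if (is.numeric(gt)) {
    gt <- matrix(as.character(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  if (is.null(barcodes)) abort("barcodes are required (rownames or argument)")
  if (anyDuplicated(barcodes)) abort("duplicate cell barcodes")
  coded <- gt %in% names(GT_CODE_MAP)
  gt[coded] <- GT_CODE_MAP[gt[coded]]
  bad <- !(gt %in% GT_LEVELS)
  if (any(bad)) {
    warn(sprintf("%d unknown genotype codes mapped to MISSING", sum(bad)))
    gt[bad] <- "MISSING"
  }
  variants <- as_tibble(variants)
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- paste0(variants$chrom, ":", variants$pos, ":",
                                  variants$ref, ">", variants$alt)
  }
  key <- with(variants, paste(chrom, pos, ref, alt))
  if (anyDuplicated(key)) abort("duplicate (chrom,pos,ref,alt) in variant table")
  if (!"population_maf" %in% names(variants)) variants$population_maf <- 0
  variants$population_maf[is.na(variants$population_maf)] <- 0
  if (!"whitelisted" %in% names(variants)) variants$whitelisted <- FALSE
  for (layer in list(depth, quality, alt_fraction)) {
    if (!all(dim(layer) == dim(gt))) {
      abort(sprintf("layer dimensions %dx%d do not match gt %dx%d",
                    nrow(layer), ncol(layer), nrow(gt), ncol(gt)))
    }
  }
  if (nrow(gt) != length(barcodes)) abort("gt rows do not match barcode count")
  if (ncol(gt) != nrow(variants)) abort("gt columns do not match variant count")
  af <- alt_fraction[!is.na(alt_fraction)]
  if (length(af) && (min(af) < 0 || max(af) > 1)) {
    abort("alt_fraction outside [0, 1]")
  }
  dn <- list(barcodes, variants$variant_id)
  dimnames(gt) <- dimnames(depth) <- dimnames(quality) <-
    dimnames(alt_fraction) <- dn
  structure(
    list(gt = gt, depth = depth, quality = quality,
         alt_fraction = alt_fraction, variants = variants,
         barcodes = barcodes),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d cells x %d variants\n",
              length(x$barcodes), nrow(x$variants)))
  tab <- table(factor(x$gt, levels = GT_LEVELS))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by cells and/or variants
#' @param x a `genotype_matrix`
#' @param cells,variants logical/integer/character index vectors
#' @return a `genotype_matrix`
#' @export
gm_subset <- function(x, cells = NULL, variants = NULL) {
  ci <- if (is.null(cells)) seq_along(x$barcodes) else cells
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(vi)) vi <- match(vi, x$variants$variant_id)
  genotype_matrix(
    gt = x$gt[ci, vi, drop = FALSE],
    depth = x$depth[ci, vi, drop = FALSE],
    quality = x$quality[ci, vi, drop = FALSE],
    alt_fraction = x$alt_fraction[ci, vi, drop = FALSE],
    variants = x$variants[vi, , drop = FALSE],
    barcodes = x$barcodes[ci]
  )
}

#' Construct a cell-by-amplicon read count matrix
#'
#' @param counts non-negative integer matrix, cells in rows.
#' @param amplicons tibble with `amplicon_id`, `chrom`, `start`, `end`,
#'   `gene`; coordinates are 0-based half-open (BED convention).
#' @param barcodes unique cell identifiers.
#' @return an object of class `amplicon_matrix`.
#' @export
amplicon_matrix <- function(counts, amplicons, barcodes = rownames(counts)) {
  counts <- as.matrix(counts)
  amplicons <- as_tibble(amplicons)
  if (is.null(barcodes)) abort("barcodes required")
  if (anyDuplicated(barcodes)) abort("duplicate cell barcodes")
  if (anyDuplicated(amplicons$amplicon_id)) abort("duplicate amplicon ids")
  if (any(counts < 0)) abort("negative amplicon counts")
  if (any(amplicons$start >= amplicons$end)) {
    abort("amplicon with start >= end (coordinates are 0-based half-open)")
  }
  if (nrow(counts) != length(barcodes) || ncol(counts) != nrow(amplicons)) {
    abort("count dimensions do not match barcodes/amplicons")
  }
  dimnames(counts) <- list(barcodes, amplicons$amplicon_id)
  structure(list(counts = counts, amplicons = amplicons, barcodes = barcodes),
            class = "amplicon_matrix")
}

#' @export
print.amplicon_matrix <- function(x, ...) {
  cat(sprintf("<amplicon_matrix> %d cells x %d amplicons (%d genes)\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$amplicons$gene)))
  invisible(x)
}

#' Construct a cell-by-antibody ADT count matrix
#'
#' @param counts non-negative integer matrix, cells in rows.
#' @param antibodies tibble with `antibody` and logical `is_isotype`; at
#'   least one isotype control is required (it anchors denoising).
#' @param barcodes unique cell identifiers.
#' @return an object of class `adt_matrix`.
#' @export
adt_matrix <- function(counts, antibodies, barcodes = rownames(counts)) {
  counts <- as.matrix(counts)
  antibodies <- as_tibble(antibodies)
  if (is.null(barcodes)) abort("barcodes required")
  if (anyDuplicated(barcodes)) abort("duplicate cell barcodes")
  if (any(counts < 0)) abort("negative ADT counts")
  if (!any(antibodies$is_isotype)) {
    abort("at least one isotype control antibody is required")
  }
  if (nrow(counts) != length(barcodes) || ncol(counts) != nrow(antibodies)) {
    abort("count dimensions do not match barcodes/antibodies")
  }
  dimnames(counts) <- list(barcodes, antibodies$antibody)
  structure(list(counts = counts, antibodies = antibodies,
                 barcodes = barcodes),
            class = "adt_matrix")
}

#' @export
print.adt_matrix <- function(x, ...) {
  cat(sprintf("<adt_matrix> %d cells x %d antibodies (%d isotype controls)\n",
              nrow(x$counts), ncol(x$counts), sum(x$antibodies$is_isotype)))
  invisible(x)
}

#' Assemble per-sample matrices into a cohort
#'
#' Joins the three modalities of each sample on cell barcode (intersection:
#' DNA and protein QC legitimately retain different cell sets) and indexes
#' samples by patient and timepoint. Patients with both a diagnosis and a
#' post-treatment sample are flagged paired.
#'
#' @param samples list of per-sample lists, each with elements `meta`
#'   (one-row tibble or list: `patient_id`, `timepoint`, `response`,
#'   optional `hi_flag`, `mcr_flag`), `genotype`, and optionally
#'   `amplicon` and `adt`.
#' @return an object of class `cohort`: `samples` (named list keyed
#'   `<patient>_<timepoint>`) and `meta` (tibble with a `paired` column and
#'   per-sample barcode bookkeeping).
#' @export
assemble_cohort <- function(samples) {
  parsed <- purrr::map(samples, function(s) {
    m <- as_tibble(as.list(s$meta)[c("patient_id", "timepoint", "response",
                                     "hi_flag", "mcr_flag")] |>
                     purrr::compact())
    if (!m$timepoint %in% TIMEPOINT_LEVELS) {
      abort(sprintf("unknown timepoint '%s'", m$timepoint))
    }
    bcs <- s$genotype$barcodes
    dropped <- 0L
    for (mod in c("amplicon", "adt")) {
      if (!is.null(s[[mod]])) bcs <- intersect(bcs, s[[mod]]$barcodes)
    }
    all_bcs <- unique(c(s$genotype$barcodes,
                        s$amplicon$barcodes, s$adt$barcodes))
    dropped <- length(all_bcs) - length(bcs)
    if (dropped > 0) {
      inform(sprintf("%s/%s: %d cells dropped (absent from >=1 modality)",
                     m$patient_id, m$timepoint, dropped))
    }
    out <- list(meta = m)
    out$genotype <- gm_subset(s$genotype,
                              cells = match(bcs, s$genotype$barcodes))
    if (!is.null(s$amplicon)) {
      out$amplicon <- amplicon_matrix(
        s$amplicon$counts[match(bcs, s$amplicon$barcodes), , drop = FALSE],
        s$amplicon$amplicons, bcs)
    }
    if (!is.null(s$adt)) {
      out$adt <- adt_matrix(
        s$adt$counts[match(bcs, s$adt$barcodes), , drop = FALSE],
        s$adt$antibodies, bcs)
    }
    out$meta$n_cells <- length(bcs)
    out$meta$n_dropped <- dropped
    out
  })
  meta <- purrr::map_dfr(parsed, "meta")
  key <- paste(meta$patient_id, meta$timepoint, sep = "_")
  if (anyDuplicated(key)) {
    abort("a patient has two samples at the same timepoint")
  }
  # order-invariance: canonical sort by patient then timepoint
  ord <- order(meta$patient_id, match(meta$timepoint, TIMEPOINT_LEVELS))
  parsed <- parsed[ord]
  meta <- meta[ord, ]
  key <- key[ord]
  names(parsed) <- key
  meta$sample_id <- key
  meta <- meta |>
    group_by(.data$patient_id) |>
    mutate(paired = all(TIMEPOINT_LEVELS %in% .data$timepoint)) |>
    ungroup()
  structure(list(samples = parsed, meta = meta), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples, %d patients (%d paired)\n",
              nrow(x$meta), dplyr::n_distinct(x$meta$patient_id),
              dplyr::n_distinct(x$meta$patient_id[x$meta$paired])))
  invisible(x)
}
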
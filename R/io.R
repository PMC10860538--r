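# On-disk sample container: one directory per sample holding plain-text
# layers. Genotype layers are dense CSV (cells x variants are small on a
# targeted panel); count matrices are MatrixMarket; all tables are CSV.
#   gt.csv depth.csv quality.csv alt_fraction.csv   variants.csv
#   amplicon_counts.mtx amplicons.csv               adt_counts.mtx
#   antibodies.csv barcodes.csv meta.csv

read_layer_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_layer_csv <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(barcode = rownames(m)), df)
  readr::write_csv(df, path, progress = FALSE)
}

#' Read a genotype container from disk
#'
#' Loads the four aligned genotype layers (`gt.csv`, `depth.csv`,
#' `quality.csv`, `alt_fraction.csv`) from a sample directory together with
#' the variant table, and validates them into a [genotype_matrix()].
#' Unknown genotype codes are mapped to `MISSING` with a warning.
#'
#' @param path sample directory holding the layer CSVs (first column:
#'   barcode; remaining columns: variants in table order).
#' @param variant_table_path CSV of variant records (`chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, optional `population_maf`, `whitelisted`,
#'   `pathogenicity`). Defaults to `variants.csv` inside `path`.
#' @return a [genotype_matrix()]
#' @export
read_genotype_container <- function(path,
                                    variant_table_path = file.path(path, "variants.csv")) {
  layers <- c("gt", "depth", "quality", "alt_fraction")
  files <- file.path(path, paste0(layers, ".csv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    rlang::abort(sprintf("missing layer file(s): %s",
                         paste(files[missing], collapse = ", ")))
  }
  mats <- lapply(files, read_layer_csv)
  names(mats) <- layers
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    off <- layers[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]]
    rlang::abort(sprintf("layer '%s' dimensions disagree with 'gt'", off))
  }
  variants <- readr::read_csv(variant_table_path, show_col_types = FALSE,
                              progress = FALSE)
  genotype_matrix(gt = mats$gt,
                  depth = apply_storage(mats$depth),
                  quality = apply_storage(mats$quality),
                  alt_fraction = apply_storage(mats$alt_fraction),
                  variants = variants, barcodes = rownames(mats$gt))
}

apply_storage <- function(m) {
  storage.mode(m) <- "double"
  m
}

#' Write a genotype matrix to a sample container directory
#' @param x a [genotype_matrix()]
#' @param path directory (created if needed)
#' @return `path`, invisibly
#' @export
write_genotype_container <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_layer_csv(x$gt, file.path(path, "gt.csv"))
  write_layer_csv(x$depth, file.path(path, "depth.csv"))
  write_layer_csv(x$quality, file.path(path, "quality.csv"))
  write_layer_csv(x$alt_fraction, file.path(path, "alt_fraction.csv"))
  readr::write_csv(x$variants, file.path(path, "variants.csv"),
                   progress = FALSE)
  invisible(path)
}

#' Read an amplicon panel definition
#'
#' BED-convention table: columns `chrom`, `start`, `end`, `amplicon_id`,
#' `gene`, coordinates 0-based half-open.
#'
#' @param path CSV/TSV panel file (delimiter sniffed by readr).
#' @return tibble of amplicons in file order, with the amplicon and gene
#'   counts reported via a message.
#' @export
read_panel <- function(path) {
  panel <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "amplicon_id", "gene")
  if (!all(need %in% names(panel))) {
    rlang::abort(sprintf("panel must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  if (any(panel$start >= panel$end)) {
    rlang::abort("panel row with start >= end (0-based half-open expected)")
  }
  if (anyDuplicated(panel$amplicon_id)) {
    rlang::abort("duplicate amplicon_id in panel")
  }
  rlang::inform(sprintf("panel: %d amplicons over %d genes",
                        nrow(panel), dplyr::n_distinct(panel$gene)))
  panel[, need]
}

#' Read an antibody table
#'
#' @param path CSV with columns `antibody` and logical/0-1 `is_isotype`.
#' @return tibble with a logical `is_isotype` column.
#' @export
read_antibody_table <- function(path) {
  ab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ab$is_isotype <- as.logical(ab$is_isotype)
  ab
}

#' Write a full sample (all modalities) to a container directory
#' @param sample list with `meta`, `genotype`, optional `amplicon`, `adt`
#' @param path directory
#' @return `path`, invisibly
#' @export
write_sample_container <- function(sample, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_genotype_container(sample$genotype, path)
  readr::write_csv(tibble::as_tibble(sample$meta), file.path(path, "meta.csv"),
                   progress = FALSE)
  if (!is.null(sample$amplicon)) {
    Matrix::writeMM(Matrix::Matrix(sample$amplicon$counts, sparse = TRUE),
                    file.path(path, "amplicon_counts.mtx"))
    readr::write_csv(sample$amplicon$amplicons,
                     file.path(path, "amplicons.csv"), progress = FALSE)
    readr::write_csv(tibble::tibble(barcode = sample$amplicon$barcodes),
                     file.path(path, "amplicon_barcodes.csv"),
                     progress = FALSE)
  }
  if (!is.null(sample$adt)) {
    Matrix::writeMM(Matrix::Matrix(sample$adt$counts, sparse = TRUE),
                    file.path(path, "adt_counts.mtx"))
    readr::write_csv(sample$adt$antibodies,
                     file.path(path, "antibodies.csv"), progress = FALSE)
    readr::write_csv(tibble::tibble(barcode = sample$adt$barcodes),
                     file.path(path, "adt_barcodes.csv"), progress = FALSE)
  }
  invisible(path)
}

#' Read a full sample container written by [write_sample_container()]
#' @param path directory
#' @return list with `meta`, `genotype`, and any of `amplicon`, `adt` found
#' @export
read_sample_container <- function(path) {
  out <- list(
    meta = readr::read_csv(file.path(path, "meta.csv"),
                           show_col_types = FALSE, progress = FALSE),
    genotype = read_genotype_container(path)
  )
  if (file.exists(file.path(path, "amplicon_counts.mtx"))) {
    counts <- as.matrix(Matrix::readMM(file.path(path, "amplicon_counts.mtx")))
    storage.mode(counts) <- "integer"
    out$amplicon <- amplicon_matrix(
      counts,
      readr::read_csv(file.path(path, "amplicons.csv"),
                      show_col_types = FALSE, progress = FALSE),
      readr::read_csv(file.path(path, "amplicon_barcodes.csv"),
                      show_col_types = FALSE, progress = FALSE)$barcode)
  }
  if (file.exists(file.path(path, "adt_counts.mtx"))) {
    counts <- as.matrix(Matrix::readMM(file.path(path, "adt_counts.mtx")))
    storage.mode(counts) <- "integer"
    out$adt <- adt_matrix(
      counts,
      read_antibody_table(file.path(path, "antibodies.csv")),
      readr::read_csv(file.path(path, "adt_barcodes.csv"),
                      show_col_types = FALSE, progress = FALSE)$barcode)
  }
  out
}
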
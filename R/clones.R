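# Clone calling, ADO-artifact clone removal, phylogeny reconstruction,
# clone-level statistics, CHIP flags, and paired-timepoint dynamics.

#' Call clones by genotype identity
#'
#' Cells are grouped by their exact (variant -> zygosity) vector over the
#' kept variants. Cells with any MISSING call among kept variants cannot be
#' assigned a complete signature and are set aside as unassigned. Clones
#' holding less than `minor_fraction` of assigned cells are pooled into a
#' `"minor"` clone unless their signature touches a whitelisted variant.
#'
#' @param gm a QC-passed [genotype_matrix()] restricted to kept variants
#' @param minor_fraction pooling threshold for small clones (0.01)
#' @param whitelist variant ids exempting a small clone from pooling
#' @return list of class `clone_set`: `clones` (tibble: `clone_id`,
#'   `signature`, `n_mutations`, `is_wt`, `n_cells`, `fraction_all`,
#'   `fraction_mutant`), `assignments` (tibble `barcode`, `clone_id`),
#'   `signatures` (named list), `unassigned` (barcodes)
#' @export
call_clones <- function(gm, minor_fraction = 0.01, whitelist = character(0)) {
  nv <- nrow(gm$variants)
  if (nv == 0) {
    rlang::warn("no kept variants: returning a single WT clone")
    n <- length(gm$barcodes)
    clones <- tibble::tibble(clone_id = "WT", signature = "WT",
                             n_mutations = 0L, is_wt = TRUE, n_cells = n,
                             fraction_all = 1, fraction_mutant = NA_real_)
    return(structure(list(clones = clones,
                          assignments = tibble::tibble(
                            barcode = gm$barcodes, clone_id = "WT"),
                          signatures = list(WT = character(0)),
                          unassigned = character(0)),
                     class = "clone_set"))
  }
  complete <- rowSums(gm$gt == "MISSING") == 0
  unassigned <- gm$barcodes[!complete]
  gt <- gm$gt[complete, , drop = FALSE]
  vids <- gm$variants$variant_id
  sig_of_row <- function(row) {
    mut <- row != "WT"
    stats::setNames(row[mut], vids[mut])
  }
  keys <- apply(gt, 1, function(row) signature_string(sig_of_row(row)))
  assignments <- tibble::tibble(barcode = gm$barcodes[complete],
                                signature = unname(keys))
  sizes <- sort(table(keys), decreasing = TRUE)
  sigs <- purrr::map(names(sizes), parse_signature)
  is_wt <- names(sizes) == "WT"
  n_assigned <- sum(sizes)
  frac <- as.numeric(sizes) / n_assigned
  wl_hit <- purrr::map_lgl(sigs, ~ any(names(.x) %in% whitelist))
  minor <- frac < minor_fraction & !is_wt & !wl_hit
  # stable ids: WT, then C1.. by decreasing size among retained mutant clones
  retained <- which(!minor & !is_wt)
  ids <- character(length(sizes))
  ids[is_wt] <- "WT"
  ids[retained] <- paste0("C", seq_along(retained))
  ids[minor] <- "minor"
  id_of_key <- stats::setNames(ids, names(sizes))
  assignments$clone_id <- unname(id_of_key[assignments$signature])
  clone_rows <- tibble::tibble(
    clone_id = ids[!minor], signature = names(sizes)[!minor],
    n_mutations = purrr::map_int(sigs[!minor], length),
    is_wt = is_wt[!minor], n_cells = as.integer(sizes[!minor]))
  if (any(minor)) {
    clone_rows <- dplyr::bind_rows(clone_rows, tibble::tibble(
      clone_id = "minor", signature = NA_character_,
      n_mutations = NA_integer_, is_wt = FALSE,
      n_cells = as.integer(sum(sizes[minor]))))
  }
  signatures <- purrr::map(clone_rows$signature,
                           ~ if (is.na(.x)) NULL else parse_signature(.x))
  names(signatures) <- clone_rows$clone_id
  structure(list(clones = finish_fractions(clone_rows, n_assigned),
                 assignments = assignments[, c("barcode", "clone_id")],
                 signatures = signatures, unassigned = unassigned),
            class = "clone_set")
}

finish_fractions <- function(clone_rows, n_assigned) {
  mutant_cells <- sum(clone_rows$n_cells[!clone_rows$is_wt])
  clone_rows$fraction_all <- clone_rows$n_cells / n_assigned
  clone_rows$fraction_mutant <- ifelse(
    clone_rows$is_wt, NA_real_,
    if (mutant_cells > 0) clone_rows$n_cells / mutant_cells else NA_real_)
  clone_rows
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("<clone_set> %d clones (%d mutant), %d assigned / %d unassigned cells\n",
              nrow(x$clones), sum(!x$clones$is_wt & x$clones$clone_id != "minor"),
              sum(x$clones$n_cells), length(x$unassigned)))
  invisible(x)
}

# clones eligible for analysis (not WT, not the pooled minor bucket)
mutant_clones <- function(cs) {
  dplyr::filter(cs$clones, !.data$is_wt, .data$clone_id != "minor")
}

#' Merge allele-dropout artifact clones into their parent
#'
#' A dropout event at one heterozygous site converts parent-clone cells
#' into an apparent clone whose signature differs by exactly one HET -> WT
#' or HET -> HOM substitution. A candidate is merged into a larger clone
#' when such a single-substitution relation holds and its size does not
#' exceed the dropout expectation, `parent cells * ado/100 * safety`.
#'
#' @param cs a [call_clones()] result
#' @param ado an [ado_rate()] result or a numeric ADO percentage
#' @param safety multiplier on the dropout expectation (1.5)
#' @return a `clone_set` with artifact clones merged; merges are recorded
#'   in attribute `"ado_merges"` and reported
#' @export
flag_ado_clones <- function(cs, ado, safety = 1.5) {
  ado_pct <- if (inherits(ado, "ado_estimate")) ado$sample_ado else ado
  if (ado_pct <= 0) return(cs)
  repeat {
    cl <- mutant_clones(cs)
    if (nrow(cl) < 1) break
    merge <- NULL
    ord <- order(cl$n_cells)  # try smallest candidates first
    for (i in ord) {
      cand <- cl[i, ]
      cand_sig <- cs$signatures[[cand$clone_id]]
      parents <- dplyr::filter(cs$clones, .data$n_cells > cand$n_cells,
                               .data$clone_id != "minor",
                               .data$clone_id != cand$clone_id)
      for (pid in parents$clone_id) {
        psig <- cs$signatures[[pid]]
        if (!is_single_dropout(psig, cand_sig)) next
        expectation <- parents$n_cells[parents$clone_id == pid] *
          ado_pct / 100 * safety
        if (cand$n_cells <= expectation) {
          merge <- c(cand$clone_id, pid)
          break
        }
      }
      if (!is.null(merge)) break
    }
    if (is.null(merge)) break
    cs <- merge_clone(cs, from = merge[1], into = merge[2])
    attr(cs, "ado_merges") <- c(attr(cs, "ado_merges"),
                                paste(merge[1], "->", merge[2]))
  }
  if (!is.null(attr(cs, "ado_merges"))) {
    rlang::inform(sprintf("ADO-clone removal: %s",
                          paste(attr(cs, "ado_merges"), collapse = ", ")))
  }
  cs
}

# TRUE if `cand` equals `parent` except for exactly one site where parent
# is HET and cand is WT (site absent) or HOM
is_single_dropout <- function(parent, cand) {
  all_v <- union(names(parent), names(cand))
  pz <- ZYG_RANK[ifelse(all_v %in% names(parent), parent[all_v], "WT")]
  cz <- ZYG_RANK[ifelse(all_v %in% names(cand), cand[all_v], "WT")]
  diff <- which(pz != cz)
  length(diff) == 1 && pz[diff] == 1L  # parent HET at the differing site
}

merge_clone <- function(cs, from, into) {
  cs$assignments$clone_id[cs$assignments$clone_id == from] <- into
  idx_into <- cs$clones$clone_id == into
  cs$clones$n_cells[idx_into] <- cs$clones$n_cells[idx_into] +
    cs$clones$n_cells[cs$clones$clone_id == from]
  cs$clones <- cs$clones[cs$clones$clone_id != from, ]
  cs$signatures[[from]] <- NULL
  cs$clones <- finish_fractions(cs$clones, sum(cs$clones$n_cells))
  cs
}

#' Reconstruct the clonal phylogeny
#'
#' Orders clones by mutation-set inclusion with zygosity progression (HET
#' at a site may precede HOM at the same site, never the reverse). Each
#' clone's parent is its largest proper ancestor; the root is the WT clone
#' (inserted as a virtual root when absent). Pairs of variants whose clone
#' pattern violates nested ancestry are recorded as conflicts rather than
#' raised.
#'
#' @param cs a `clone_set`
#' @return list of class `clone_phylogeny`: `edges` (tibble `parent`,
#'   `child`), `root`, `topology` ("linear"/"branched"), `conflicts`
#'   (tibble of variant pairs), `clones`
#' @export
build_phylogeny <- function(cs) {
  cl <- dplyr::filter(cs$clones, .data$clone_id != "minor")
  sigs <- cs$signatures[cl$clone_id]
  if (!any(cl$is_wt)) {
    cl <- dplyr::bind_rows(
      tibble::tibble(clone_id = "WT", signature = "WT", n_mutations = 0L,
                     is_wt = TRUE, n_cells = 0L, fraction_all = 0,
                     fraction_mutant = NA_real_), cl)
    sigs <- c(list(WT = stats::setNames(character(0), character(0))), sigs)
  }
  n <- nrow(cl)
  edges <- NULL
  for (i in seq_len(n)) {
    if (cl$is_wt[i]) next
    anc <- which(purrr::map_lgl(seq_len(n), function(j) {
      j != i && sig_ancestor_of(sigs[[j]], sigs[[i]]) &&
        !identical(sigs[[j]][order(names(sigs[[j]]))],
                   sigs[[i]][order(names(sigs[[i]]))])
    }))
    if (!length(anc)) next
    # parent = largest proper ancestor: most mutations, ties by cell count
    score <- order(cl$n_mutations[anc], cl$n_cells[anc], decreasing = TRUE)
    parent <- anc[score[1]]
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      parent = cl$clone_id[parent], child = cl$clone_id[i]))
  }
  edges <- edges %||% tibble::tibble(parent = character(0),
                                     child = character(0))
  kids <- table(edges$parent)
  topology <- if (all(kids <= 1)) "linear" else "branched"
  structure(list(edges = edges, root = "WT", topology = topology,
                 conflicts = find_conflicts(sigs), clones = cl),
            class = "clone_phylogeny")
}

# infinite-sites check: variants u,v conflict when clones exist carrying
# u-without-v, v-without-u, and u-with-v (mutation presence, zygosity aside)
find_conflicts <- function(sigs) {
  vars <- unique(unlist(purrr::map(sigs, names)))
  if (length(vars) < 2) {
    return(tibble::tibble(variant_a = character(0), variant_b = character(0)))
  }
  has <- vapply(vars, function(v) purrr::map_lgl(sigs, ~ v %in% names(.x)),
                logical(length(sigs)))
  out <- NULL
  pairs <- utils::combn(seq_along(vars), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- has[, pairs[1, k]]
    b <- has[, pairs[2, k]]
    if (any(a & !b) && any(b & !a) && any(a & b)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        variant_a = vars[pairs[1, k]], variant_b = vars[pairs[2, k]]))
    }
  }
  out %||% tibble::tibble(variant_a = character(0), variant_b = character(0))
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat(sprintf("<clone_phylogeny> %d clones, %s topology, %d conflicts\n",
              nrow(x$clones), x$topology, nrow(x$conflicts)))
  invisible(x)
}

#' Clone-level summary statistics
#'
#' Shannon diversity (natural log) over mutant-clone fractions renormalised
#' to mutant cells, the number of mutant clones, and the predominant-clone
#' fraction (largest mutant clone over all mutant cells).
#'
#' @param cs a `clone_set`
#' @return one-row tibble: `n_mutant_clones`, `shannon`,
#'   `predominant_fraction`, `mutant_fraction` (mutant cells over assigned
#'   cells)
#' @export
clone_stats <- function(cs) {
  mut <- mutant_clones(cs)
  total <- sum(cs$clones$n_cells)
  if (nrow(mut) == 0) {
    return(tibble::tibble(n_mutant_clones = 0L, shannon = NA_real_,
                          predominant_fraction = NA_real_,
                          mutant_fraction = 0))
  }
  h <- as.numeric(vegan::diversity(mut$n_cells, index = "shannon"))
  tibble::tibble(
    n_mutant_clones = nrow(mut), shannon = h,
    predominant_fraction = max(mut$n_cells) / sum(mut$n_cells),
    mutant_fraction = sum(mut$n_cells) / total)
}

#' First-clone and predominant-clone gene attribution
#'
#' The first clone is the earliest non-WT ancestor on every root-to-leaf
#' path (ties reported as a set); the predominant clone is the largest
#' mutant clone. Gene symbols are read off the clone signatures via the
#' variant table.
#'
#' @param phylo a [build_phylogeny()] result
#' @param cs the `clone_set` the phylogeny was built from
#' @param variants variant table mapping `variant_id` to `gene`
#' @return list with `first_clones`, `first_clone_genes`,
#'   `predominant_clone`, `predominant_clone_genes`
#' @export
clone_gene_attribution <- function(phylo, cs, variants) {
  mut <- mutant_clones(cs)
  genes_of <- function(cid) {
    sig <- cs$signatures[[cid]]
    unique(variants$gene[match(names(sig), variants$variant_id)])
  }
  if (nrow(mut) == 0) {
    return(list(first_clones = character(0), first_clone_genes = character(0),
                predominant_clone = character(0),
                predominant_clone_genes = character(0)))
  }
  first <- phylo$edges$child[phylo$edges$parent == phylo$root]
  first <- intersect(first, mut$clone_id)
  if (length(first) > 1) {
    rlang::inform(sprintf("first-clone tie between: %s",
                          paste(first, collapse = ", ")))
  }
  pred <- mut$clone_id[which.max(mut$n_cells)]
  list(first_clones = first,
       first_clone_genes = unique(unlist(purrr::map(first, genes_of))),
       predominant_clone = pred,
       predominant_clone_genes = genes_of(pred))
}

CHIP_CORE3 <- c("TET2", "DNMT3A", "ASXL1")
CHIP_CORE5 <- c(CHIP_CORE3, "SF3B1", "TP53")

#' Clonal-hematopoiesis (CHIP) flags per clone
#'
#' Three definitions: `core3` (TET2/DNMT3A/ASXL1), `core5` (plus
#' SF3B1/TP53), and `driver_vaf2` (any driver-gene mutation whose
#' VAF-by-cell-count exceeds 2%).
#'
#' @param cs a `clone_set`
#' @param variants variant table (`variant_id`, `gene`)
#' @param definition one of "core3", "core5", "driver_vaf2"
#' @param gm genotype matrix, required for `driver_vaf2` (VAF computed on
#'   the kept-variant matrix)
#' @param driver_genes character vector of driver genes (required for
#'   `driver_vaf2`)
#' @param vaf_min VAF percentage cutoff for `driver_vaf2` (2)
#' @return tibble `clone_id`, `definition`, `chip`
#' @export
chip_flags <- function(cs, variants, definition = c("core3", "core5",
                                                    "driver_vaf2"),
                       gm = NULL, driver_genes = NULL, vaf_min = 2) {
  definition <- match.arg(definition)
  mut <- mutant_clones(cs)
  if (definition == "driver_vaf2") {
    if (is.null(driver_genes)) {
      rlang::abort("driver_vaf2 requires a driver gene list")
    }
    if (is.null(gm)) rlang::abort("driver_vaf2 requires the genotype matrix")
    vaf <- apply(gm$gt, 2, vaf_by_cell_count)
    names(vaf) <- gm$variants$variant_id
  }
  flag <- purrr::map_lgl(mut$clone_id, function(cid) {
    sig <- cs$signatures[[cid]]
    genes <- variants$gene[match(names(sig), variants$variant_id)]
    switch(definition,
      core3 = any(genes %in% CHIP_CORE3),
      core5 = any(genes %in% CHIP_CORE5),
      driver_vaf2 = any(genes %in% driver_genes &
                          vaf[names(sig)] > vaf_min))
  })
  tibble::tibble(clone_id = mut$clone_id, definition = definition,
                 chip = flag)
}

#' Classify paired-timepoint clonal dynamics
#'
#' Matches clones across timepoints by signature and applies the pattern
#' rules: *shrinkage* when every diagnosis mutant clone falls below
#' `shrink_factor` times its diagnosis fraction of all cells and no new
#' clone at or above `new_clone_min` appears; *expansion* when a new clone
#' at or above `new_clone_min` appears or a minority clone (diagnosis
#' fraction below the predominant clone's) more than doubles; otherwise
#' *stable*.
#'
#' @param cs_dx,cs_tx `clone_set`s at diagnosis and post-treatment, called
#'   over the union of kept variants
#' @param shrink_factor shrinkage multiplier threshold (0.5)
#' @param new_clone_min minimum fraction for a new clone to count (0.02)
#' @return list of class `dynamics_call`: `pattern`, `deltas` (per-clone
#'   tibble), `mutant_fraction`, `predominant_fraction` per timepoint
#' @export
classify_dynamics <- function(cs_dx, cs_tx, shrink_factor = 0.5,
                              new_clone_min = 0.02) {
  mdx <- mutant_clones(cs_dx)
  mtx <- mutant_clones(cs_tx)
  deltas <- dplyr::full_join(
    dplyr::select(mdx, "signature", dx_fraction = "fraction_all"),
    dplyr::select(mtx, "signature", tx_fraction = "fraction_all"),
    by = "signature") |>
    tidyr::replace_na(list(dx_fraction = 0, tx_fraction = 0)) |>
    dplyr::mutate(delta = .data$tx_fraction - .data$dx_fraction)
  new_clone <- any(deltas$dx_fraction == 0 &
                     deltas$tx_fraction >= new_clone_min)
  if (nrow(mdx) == 0 && nrow(mtx) == 0) {
    rlang::warn("no mutant clones at either timepoint; pattern is stable")
  }
  diag <- deltas[deltas$dx_fraction > 0, ]
  all_shrunk <- nrow(diag) > 0 &&
    all(diag$tx_fraction < shrink_factor * diag$dx_fraction)
  pred_dx <- if (nrow(diag)) max(diag$dx_fraction) else NA_real_
  minority_doubled <- nrow(diag) > 0 && any(
    diag$dx_fraction < pred_dx & diag$tx_fraction > 2 * diag$dx_fraction)
  pattern <- if (all_shrunk && !new_clone) {
    "shrinkage"
  } else if (new_clone || minority_doubled) {
    "expansion"
  } else {
    "stable"
  }
  st_dx <- clone_stats(cs_dx)
  st_tx <- clone_stats(cs_tx)
  structure(list(
    pattern = pattern, deltas = deltas,
    mutant_fraction = c(diagnosis = st_dx$mutant_fraction,
                        post_treatment = st_tx$mutant_fraction),
    predominant_fraction = c(diagnosis = st_dx$predominant_fraction,
                             post_treatment = st_tx$predominant_fraction)),
    class = "dynamics_call")
}

#' @export
print.dynamics_call <- function(x, ...) {
  cat(sprintf("<dynamics_call> pattern: %s (mutant fraction %.3f -> %.3f)\n",
              x$pattern, x$mutant_fraction[1], x$mutant_fraction[2]))
  invisible(x)
}

#' Long-format clone fractions for fishplot-style export
#'
#' @param cs_dx,cs_tx `clone_set`s at the two timepoints
#' @param patient_id label added as a column
#' @return tibble (`patient_id`, `clone_id`, `signature`, `timepoint`,
#'   `fraction`)
#' @export
fishplot_table <- function(cs_dx, cs_tx, patient_id = NA_character_) {
  one <- function(cs, tp) {
    cl <- dplyr::filter(cs$clones, .data$clone_id != "minor")
    tibble::tibble(patient_id = patient_id, clone_id = cl$clone_id,
                   signature = cl$signature, timepoint = tp,
                   fraction = cl$fraction_all)
  }
  dplyr::bind_rows(one(cs_dx, "diagnosis"), one(cs_tx, "post_treatment"))
}
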
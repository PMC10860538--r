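# Genotype x phenotype integration: join clone assignments with cell
# annotations, lineage-restriction summaries, gene x lineage enrichment,
# mutant/WT compositional dynamics, and the end-to-end pipeline driver.

MYELOID_POOL <- c("progenitors", "immature_erythroid", "myeloid")
LYMPHOID_POOL <- c("T", "NK", "B")

#' Join clone assignments with cell annotations
#'
#' Inner join on barcode: only cells passing both the DNA and the protein
#' QC lanes are integrated; join losses are reported per modality.
#'
#' @param assignments tibble (`barcode`, `clone_id`) from [call_clones()]
#' @param annotation a [annotate_cells()] result (or its `cells` tibble)
#' @param signatures named list of clone signatures (for the per-cell
#'   mutation count); clones absent from it get `NA` mutations
#' @param sample_info optional tibble columns recycled onto every row
#'   (e.g. `patient_id`, `timepoint`, `response`)
#' @return tibble: `barcode`, `clone_id`, `n_mutations`, `mutant_flag`,
#'   `population`, `compartment`, plus `sample_info` columns
#' @export
join_modalities <- function(assignments, annotation, signatures = NULL,
                            sample_info = NULL) {
  cells <- if (inherits(annotation, "cell_annotation")) annotation$cells
           else annotation
  joined <- dplyr::inner_join(assignments, cells, by = "barcode")
  if (nrow(joined) == 0) rlang::abort("no shared barcodes across modalities")
  lost_dna <- nrow(assignments) - nrow(joined)
  lost_adt <- nrow(cells) - nrow(joined)
  if (lost_dna || lost_adt) {
    rlang::inform(sprintf(
      "integration: %d DNA-only and %d protein-only cells excluded",
      lost_dna, lost_adt))
  }
  n_mut <- if (is.null(signatures)) {
    rep(NA_integer_, nrow(joined))
  } else {
    sizes <- purrr::map_int(signatures, length)
    unname(sizes[joined$clone_id])
  }
  joined$n_mutations <- n_mut
  joined$mutant_flag <- !is.na(n_mut) & n_mut > 0
  if (!is.null(sample_info)) {
    joined <- dplyr::bind_cols(joined,
                               sample_info[rep(1, nrow(joined)), ,
                                           drop = FALSE])
  }
  joined
}

#' Mutant-cell fraction by compartment with a paired lineage test
#'
#' Per patient, the mutant-cell fraction in the pooled
#' progenitor/erythroid/myeloid compartment is compared against the pooled
#' lymphoid (T/NK/B) compartment with a paired Wilcoxon signed-rank test
#' across patients.
#'
#' @param integrated an integrated cell tibble from [join_modalities()]
#'   with `patient_id`, `compartment`, `mutant_flag`
#' @return list with `fractions` (tibble per patient x pool), `test`
#'   (tibble or NULL when untestable), `excluded_patients`
#' @export
mutant_fraction_by_compartment <- function(integrated) {
  pooled <- integrated |>
    dplyr::filter(.data$compartment %in% c(MYELOID_POOL, LYMPHOID_POOL),
                  .data$clone_id != "minor") |>
    dplyr::mutate(pool = dplyr::if_else(.data$compartment %in% MYELOID_POOL,
                                        "prog_ery_mye", "lymphoid")) |>
    dplyr::group_by(.data$patient_id, .data$pool) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mutant_fraction = mean(.data$mutant_flag),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(pooled, id_cols = "patient_id",
                             names_from = "pool",
                             values_from = "mutant_fraction")
  complete <- !is.na(wide$prog_ery_mye) & !is.na(wide$lymphoid)
  excluded <- wide$patient_id[!complete]
  if (length(excluded)) {
    rlang::inform(sprintf("patients without both pools excluded: %s",
                          paste(excluded, collapse = ", ")))
  }
  wide <- wide[complete, ]
  test <- NULL
  d <- wide$prog_ery_mye - wide$lymphoid
  if (nrow(wide) >= 2 && any(d != 0)) {
    test <- wilcoxon_signed_rank(wide$prog_ery_mye, wide$lymphoid)
  }
  list(fractions = pooled, per_patient = wide, test = test,
       excluded_patients = excluded)
}

#' Gene x lineage enrichment of mutant cells
#'
#' For each gene, mutant vs wild-type cells are crossed with the pooled
#' progenitor/erythroid/myeloid vs lymphoid compartments in a 2x2 table;
#' two-sided Fisher p-values are Bonferroni-adjusted over the genes tested.
#'
#' @param integrated integrated cell tibble with `clone_id`, `compartment`,
#'   `mutant_flag`
#' @param gene_of_clone named list/character: for each clone id, the gene
#'   symbols mutated in it (e.g. from clone signatures + variant table)
#' @param genes genes to test (default: all genes appearing in any clone)
#' @return tibble per gene: counts of the 2x2 table, `p_value`,
#'   `p_adjusted`, `direction`
#' @export
gene_lineage_enrichment <- function(integrated, gene_of_clone,
                                    genes = NULL) {
  pool_cells <- integrated |>
    dplyr::filter(.data$compartment %in% c(MYELOID_POOL, LYMPHOID_POOL)) |>
    dplyr::mutate(pool = dplyr::if_else(.data$compartment %in% MYELOID_POOL,
                                        "prog_ery_mye", "lymphoid"))
  genes <- genes %||% sort(unique(unlist(gene_of_clone)))
  if (!length(genes)) {
    return(tibble::tibble(gene = character(0)))
  }
  res <- purrr::map_dfr(genes, function(g) {
    carries <- names(gene_of_clone)[purrr::map_lgl(gene_of_clone,
                                                   ~ g %in% .x)]
    mut <- pool_cells$clone_id %in% carries
    tab <- table(factor(mut, levels = c(TRUE, FALSE)),
                 factor(pool_cells$pool,
                        levels = c("prog_ery_mye", "lymphoid")))
    if (sum(tab[1, ]) == 0) return(NULL)  # gene without mutant cells here
    p <- fisher_exact(tab)$p_value
    tibble::tibble(
      gene = g,
      mutant_mye = tab[1, 1], mutant_lym = tab[1, 2],
      wt_mye = tab[2, 1], wt_lym = tab[2, 2],
      p_value = p,
      direction = dplyr::if_else(
        tab[1, 1] / sum(tab[, 1]) > tab[1, 2] / sum(tab[, 2]),
        "prog_ery_mye", "lymphoid"))
  })
  if (nrow(res)) res$p_adjusted <- bonferroni(res$p_value)
  res
}

#' Compositional dynamics of mutant and wild-type populations
#'
#' Builds per-sample population counts split by mutant flag and runs the
#' compositional test on the requested contrast separately for the mutant
#' and the wild-type partition.
#'
#' @param integrated integrated cell tibble with `patient_id`, `timepoint`,
#'   `response`, `population`, `mutant_flag`
#' @param contrast `"timepoint"` (within `response_group`) or `"response"`
#'   (at `timepoint_at`)
#' @param response_group which response arm for a timepoint contrast
#' @param timepoint_at which timepoint for a response contrast
#' @param fdr,n_boot,seed passed to [composition_test()]
#' @return list with `mutant` and `wt` `composition_test` objects (either
#'   may be NULL when that partition has too few samples) and `counts`
#' @export
mutant_population_dynamics <- function(integrated,
                                       contrast = c("timepoint", "response"),
                                       response_group = "responder",
                                       timepoint_at = "post_treatment",
                                       fdr = 0.1, n_boot = 500, seed = 1) {
  contrast <- match.arg(contrast)
  cells <- dplyr::filter(integrated, .data$population != "unassigned",
                         .data$clone_id != "minor")
  if (contrast == "timepoint") {
    cells <- dplyr::filter(cells, .data$response == response_group)
    cond_col <- "timepoint"
  } else {
    cells <- dplyr::filter(cells, .data$timepoint == timepoint_at)
    cond_col <- "response"
  }
  if (nrow(cells) == 0) rlang::abort("no cells left for this contrast")
  counts_of <- function(df) {
    tab <- df |>
      dplyr::count(.data$patient_id, .data[[cond_col]], .data$population) |>
      tidyr::pivot_wider(names_from = "population", values_from = "n",
                         values_fill = 0L)
    tab
  }
  run_one <- function(df) {
    tab <- counts_of(df)
    cond <- tab[[cond_col]]
    mat <- as.matrix(tab[, setdiff(names(tab),
                                   c("patient_id", cond_col)),
                         drop = FALSE])
    rownames(mat) <- paste(tab$patient_id, cond, sep = "_")
    if (length(unique(cond)) < 2 || any(table(cond) < 3)) return(NULL)
    composition_test(mat, cond, fdr = fdr, n_boot = n_boot, seed = seed)
  }
  list(mutant = run_one(dplyr::filter(cells, .data$mutant_flag)),
       wt = run_one(dplyr::filter(cells, !.data$mutant_flag)),
       counts = counts_of(cells))
}

#' Run the full pipeline on a simulated or assembled cohort
#'
#' Executes the stages in order — per-sample DNA QC, germline selection and
#' ADO estimation, paired clone calling with ADO-clone removal, phylogeny
#' and clone statistics, ploidy, cohort-wide protein lane (QC, CLR,
#' denoising, clustering, annotation, LISI), dynamics classification, the
#' dynamics x response association, lineage restriction and composition
#' tests — and writes tidy CSV tables plus a JSON run log.
#'
#' @param cohort a [assemble_cohort()] result (e.g. from
#'   [simulate_cohort()])
#' @param out_dir output directory for the CSV report bundle (NULL: no
#'   files written)
#' @param seed integer seed controlling clustering and bootstrap stages
#' @param thresholds a [qc_thresholds()]
#' @param marker_rules see [annotate_cells()]
#' @param n_boot bootstrap replicates for composition tests
#' @param cluster_resolution Louvain resolution for the protein lane
#' @param whitelist bulk-sequencing variant whitelist
#' @return list of report tables (all tibbles): `patient_summary`,
#'   `clone_table`, `fishplot`, `dynamics`, `ado`, `ploidy_calls`,
#'   `annotation_summary`, `lisi_summary`, `lineage_test`,
#'   `gene_enrichment`, `dynamics_response`, `composition`, `run_log`
#' @export
run_pipeline <- function(cohort, out_dir = NULL, seed = 1,
                         thresholds = qc_thresholds(),
                         marker_rules = default_marker_rules(),
                         n_boot = 200, cluster_resolution = 0.8,
                         whitelist = character(0)) {
  meta <- cohort$meta
  paired_patients <- unique(meta$patient_id[meta$paired])
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  # --- DNA lane: QC + germline + ADO + clones, per paired patient -----
  per_patient <- list()
  ado_tbl <- NULL
  clone_tbl <- NULL
  fish_tbl <- NULL
  dyn_tbl <- NULL
  assignments_all <- NULL
  gene_of_clone_all <- list()
  for (pid in paired_patients) {
    per_patient[[pid]] <- stage(paste0("dna:", pid), {
      s_dx <- cohort$samples[[paste0(pid, "_diagnosis")]]
      s_tx <- cohort$samples[[paste0(pid, "_post_treatment")]]
      q_dx <- suppressMessages(qc_sample(s_dx$genotype, thresholds, whitelist))
      q_tx <- suppressMessages(qc_sample(s_tx$genotype, thresholds, whitelist))
      germ <- select_germline_het(q_dx$calls_qc, q_tx$calls_qc)
      ado_dx <- ado_rate(q_dx$calls_qc, germ$variant_id)
      ado_tx <- ado_rate(q_tx$calls_qc, germ$variant_id)
      # clone-defining variants: union of kept variants across timepoints
      kept_union <- union(q_dx$genotype$variants$variant_id,
                          q_tx$genotype$variants$variant_id)
      sub <- function(q) {
        keep <- intersect(kept_union, q$calls_qc$variants$variant_id)
        suppressMessages(filter_cells(gm_subset(q$calls_qc, variants = keep),
                                      thresholds))
      }
      gm_dx <- sub(q_dx)
      gm_tx <- sub(q_tx)
      cs_dx <- suppressMessages(flag_ado_clones(call_clones(gm_dx,
                                  whitelist = whitelist), ado_dx))
      cs_tx <- suppressMessages(flag_ado_clones(call_clones(gm_tx,
                                  whitelist = whitelist), ado_tx))
      dyn <- classify_dynamics(cs_dx, cs_tx)
      phylo <- build_phylogeny(cs_dx)
      attribution <- clone_gene_attribution(phylo, cs_dx,
                                            s_dx$genotype$variants)
      list(qc_dx = q_dx, qc_tx = q_tx, germline = germ, ado_dx = ado_dx,
           ado_tx = ado_tx, gm_dx = gm_dx, gm_tx = gm_tx, cs_dx = cs_dx,
           cs_tx = cs_tx, dynamics = dyn, phylo = phylo,
           attribution = attribution)
    })
    pp <- per_patient[[pid]]
    ado_tbl <- dplyr::bind_rows(ado_tbl, tibble::tibble(
      patient_id = pid, timepoint = TIMEPOINT_LEVELS,
      sample_ado = c(pp$ado_dx$sample_ado, pp$ado_tx$sample_ado),
      n_germline = nrow(pp$germline)))
    fish_tbl <- dplyr::bind_rows(fish_tbl,
                                 fishplot_table(pp$cs_dx, pp$cs_tx, pid))
    clone_tbl <- dplyr::bind_rows(
      clone_tbl,
      dplyr::mutate(pp$cs_dx$clones, patient_id = pid,
                    timepoint = "diagnosis"),
      dplyr::mutate(pp$cs_tx$clones, patient_id = pid,
                    timepoint = "post_treatment"))
    has_mutant <- nrow(mutant_clones(pp$cs_dx)) > 0 ||
      nrow(mutant_clones(pp$cs_tx)) > 0
    dyn_tbl <- dplyr::bind_rows(dyn_tbl, tibble::tibble(
      patient_id = pid,
      response = meta$response[meta$patient_id == pid][1],
      pattern = pp$dynamics$pattern, has_mutant_clones = has_mutant,
      mutant_fraction_dx = pp$dynamics$mutant_fraction[[1]],
      mutant_fraction_tx = pp$dynamics$mutant_fraction[[2]],
      # predominant clone size as a fraction of all cells (the quantity
      # whose paired reduction is tested across responders)
      predominant_dx = max(c(mutant_clones(pp$cs_dx)$fraction_all, 0)),
      predominant_tx = max(c(mutant_clones(pp$cs_tx)$fraction_all, 0))))
    for (tp in c("dx", "tx")) {
      cs <- pp[[paste0("cs_", tp)]]
      smp <- paste0(pid, "_", if (tp == "dx") "diagnosis"
                    else "post_treatment")
      asg <- dplyr::mutate(cs$assignments, sample_id = smp,
                           patient_id = pid,
                           timepoint = if (tp == "dx") "diagnosis"
                                       else "post_treatment")
      assignments_all <- dplyr::bind_rows(assignments_all, asg)
      variants <- cohort$samples[[smp]]$genotype$variants
      for (cid in names(cs$signatures)) {
        sig <- cs$signatures[[cid]]
        if (is.null(sig) || !length(sig)) next
        gene_of_clone_all[[paste(smp, cid, sep = ":")]] <-
          unique(variants$gene[match(names(sig), variants$variant_id)])
      }
    }
  }

  # dynamics x response association (patients without mutant clones are
  # excluded, mirroring how a case with no panel lesion cannot be scored)
  dyn_scored <- dplyr::filter(dyn_tbl, .data$has_mutant_clones)
  dynamics_response <- NULL
  if (nrow(dyn_scored) >= 2 &&
      length(unique(dyn_scored$response)) == 2) {
    tab <- table(factor(dyn_scored$pattern == "shrinkage",
                        levels = c(TRUE, FALSE)),
                 factor(dyn_scored$response,
                        levels = c("responder", "nonresponder")))
    dynamics_response <- dplyr::bind_cols(
      tibble::tibble(shrinkage_responders = tab[1, 1],
                     shrinkage_nonresponders = tab[1, 2],
                     other_responders = tab[2, 1],
                     other_nonresponders = tab[2, 2]),
      fisher_exact(tab))
  }
  # paired predominant-clone and mutant-fraction reduction tests
  pred_test <- NULL
  scored <- dyn_scored[!is.na(dyn_scored$predominant_dx) &
                         !is.na(dyn_scored$predominant_tx), ]
  resp <- scored[scored$response == "responder", ]
  if (nrow(resp) >= 2) {
    pred_test <- tibble::tibble(
      comparison = c("mutant_fraction", "predominant_fraction"),
      p_value = c(
        wilcoxon_signed_rank(resp$mutant_fraction_tx,
                             resp$mutant_fraction_dx)$p_value,
        wilcoxon_signed_rank(resp$predominant_tx,
                             resp$predominant_dx)$p_value))
  }

  # --- ploidy lane ----------------------------------------------------
  ploidy_calls <- NULL
  for (pid in paired_patients) {
    smp <- paste0(pid, "_diagnosis")
    s <- cohort$samples[[smp]]
    if (is.null(s$amplicon)) next
    pc <- stage(paste0("ploidy:", pid), {
      asg <- dplyr::filter(assignments_all, .data$sample_id == smp)
      norm <- suppressMessages(normalize_reads(
        suppressMessages(filter_amplicons(s$amplicon))))
      base_size <- sum(asg$clone_id == "WT" &
                         asg$barcode %in% norm$barcodes)
      if (base_size < 50) NULL
      else compute_ploidy(norm, asg[, c("barcode", "clone_id")])
    })
    if (!is.null(pc)) {
      ploidy_calls <- dplyr::bind_rows(
        ploidy_calls, dplyr::mutate(pc$region_calls, patient_id = pid))
    }
  }

  # --- protein lane (cohort-wide) ------------------------------------
  protein <- stage("protein", {
    adt_list <- purrr::compact(purrr::map(cohort$samples, "adt"))
    if (!length(adt_list)) return(NULL)
    sample_ids <- rep(names(adt_list),
                      vapply(adt_list, function(a) length(a$barcodes), 1L))
    counts <- do.call(rbind, purrr::map(adt_list, "counts"))
    adt <- adt_matrix(counts, adt_list[[1]]$antibodies,
                      unlist(purrr::map(adt_list, "barcodes")))
    names(sample_ids) <- adt$barcodes
    adt <- suppressMessages(qc_adt_cells(adt))
    nadt <- denoise_isotypes(normalize_clr(adt))
    clusters <- cluster_cells(nadt, resolution = cluster_resolution,
                              seed = seed)
    clusters <- suppressMessages(drop_artifact_clusters(nadt, clusters))
    annot <- suppressMessages(
      annotate_cells(nadt, clusters, marker_rules,
                     sample_of = sample_ids[nadt$barcodes]))
    lisi_cells <- if (length(nadt$barcodes) > 5000) {
      with_seed(seed, sample(length(nadt$barcodes), 5000))
    } else seq_along(nadt$barcodes)
    lis <- lisi(clusters$embedding[lisi_cells, , drop = FALSE],
                sample_ids[nadt$barcodes][lisi_cells])
    list(annot = annot, clusters = clusters, lisi = lis,
         sample_ids = sample_ids)
  })

  # --- integration ----------------------------------------------------
  integrated <- NULL
  lineage_test <- NULL
  gene_enrichment <- NULL
  composition <- NULL
  if (!is.null(protein)) {
    integrated <- stage("integration", {
      sig_sizes <- list()
      rows <- NULL
      for (smp in unique(assignments_all$sample_id)) {
        asg <- dplyr::filter(assignments_all, .data$sample_id == smp)
        pid <- asg$patient_id[1]
        cs <- per_patient[[pid]][[
          if (grepl("_diagnosis$", smp)) "cs_dx" else "cs_tx"]]
        info <- meta[meta$sample_id == smp,
                     c("patient_id", "timepoint", "response")]
        j <- suppressMessages(join_modalities(
          asg[, c("barcode", "clone_id")], protein$annot, cs$signatures,
          sample_info = info))
        rows <- dplyr::bind_rows(rows, j)
      }
      rows
    })
    lineage_test <- stage("lineage", mutant_fraction_by_compartment(
      dplyr::filter(integrated, .data$timepoint == "diagnosis")))
    gene_of_clone <- list()
    dx <- dplyr::filter(integrated, .data$timepoint == "diagnosis")
    for (pid in paired_patients) {
      cs <- per_patient[[pid]]$cs_dx
      variants <- cohort$samples[[paste0(pid, "_diagnosis")]]$genotype$variants
      for (cid in names(cs$signatures)) {
        sig <- cs$signatures[[cid]]
        if (is.null(sig) || !length(sig)) next
        gene_of_clone[[cid]] <- unique(c(
          gene_of_clone[[cid]],
          variants$gene[match(names(sig), variants$variant_id)]))
      }
    }
    gene_enrichment <- stage("gene_enrichment",
                             gene_lineage_enrichment(dx, gene_of_clone))
    composition <- stage("composition", {
      resp_patients <- meta$patient_id[meta$response == "responder" &
                                         meta$paired]
      if (length(unique(resp_patients)) >= 3) {
        mutant_population_dynamics(
          dplyr::filter(integrated,
                        .data$patient_id %in% resp_patients),
          contrast = "timepoint", response_group = "responder",
          n_boot = n_boot, seed = seed)
      } else NULL
    })
  }

  # --- patient-level summary -----------------------------------------
  patient_summary <- purrr::map_dfr(paired_patients, function(pid) {
    pp <- per_patient[[pid]]
    st <- clone_stats(pp$cs_dx)
    chip <- chip_flags(pp$cs_dx, cohort$samples[[
      paste0(pid, "_diagnosis")]]$genotype$variants, "core3")
    dplyr::bind_cols(
      tibble::tibble(
        patient_id = pid,
        response = meta$response[meta$patient_id == pid][1],
        pattern = pp$dynamics$pattern,
        sample_ado_dx = pp$ado_dx$sample_ado,
        sample_ado_tx = pp$ado_tx$sample_ado,
        first_clone_genes = paste(pp$attribution$first_clone_genes,
                                  collapse = ";"),
        predominant_clone_genes = paste(
          pp$attribution$predominant_clone_genes, collapse = ";"),
        chip_core3 = any(chip$chip)),
      st)
  })

  report <- list(
    patient_summary = patient_summary,
    clone_table = clone_tbl, fishplot = fish_tbl, dynamics = dyn_tbl,
    ado = ado_tbl, ploidy_calls = ploidy_calls,
    annotation_summary = if (!is.null(protein)) {
      dplyr::count(protein$annot$cells, .data$population, .data$compartment)
    },
    lisi_summary = if (!is.null(protein)) {
      tibble::tibble(mean_lisi = protein$lisi$mean,
                     median_lisi = protein$lisi$median,
                     n_samples = protein$lisi$n_labels)
    },
    lineage_test = if (!is.null(lineage_test)) lineage_test$per_patient,
    lineage_p = if (!is.null(lineage_test) && !is.null(lineage_test$test)) {
      lineage_test$test
    },
    gene_enrichment = gene_enrichment,
    dynamics_response = dynamics_response,
    paired_reduction = pred_test,
    composition = if (!is.null(composition)) {
      dplyr::bind_rows(
        if (!is.null(composition$mutant)) {
          dplyr::mutate(tidy(composition$mutant), partition = "mutant")
        },
        if (!is.null(composition$wt)) {
          dplyr::mutate(tidy(composition$wt), partition = "wt")
        })
    },
    run_log = tibble::tibble(
      stage = "pipeline", seed = seed,
      n_patients = length(paired_patients),
      n_cells_dna = sum(purrr::map_int(
        per_patient, ~ length(.x$gm_dx$barcodes) +
          length(.x$gm_tx$barcodes))),
      package_version = as.character(utils::packageVersion("clonepulse")))
  )
  report$integrated <- integrated

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      tab <- report[[nm]]
      if (is.null(tab) || !inherits(tab, "data.frame")) next
      readr::write_csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
    jsonlite::write_json(list(seed = seed,
                              tables = names(purrr::compact(report))),
                         file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE)
  }
  report
}
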
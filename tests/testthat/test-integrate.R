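ann_fixture <- function(barcodes, population, compartment) {
  tibble::tibble(barcode = barcodes, cluster = "0",
                 population = population, compartment = compartment)
}

test_that("modality join is an inner join that never invents cells", {
  asg <- tibble::tibble(barcode = c("a", "b", "c"),
                        clone_id = c("WT", "C1", "C1"))
  ann <- ann_fixture(c("b", "c", "d"), "T", "T")
  sigs <- list(WT = character(0), C1 = c(v1 = "HET", v2 = "HOM"))
  j <- suppressMessages(join_modalities(asg, ann, sigs))
  expect_setequal(j$barcode, c("b", "c"))
  expect_true(all(j$n_mutations == 2))
  expect_true(all(j$mutant_flag))
  expect_error(join_modalities(asg, ann_fixture("z", "T", "T"), sigs),
               "no shared")
})

test_that("per-cell mutation counts equal the truth on simulations", {
  set.seed(81)
  ps <- patient_spec("PX", "responder", "stable", 3)
  ps$panel <- tiny_panel()
  pt <- simulate_patient(ps, sim_config(n_cells = 800, ado_rate = 0,
                                        genotype_error_rate = 0,
                                        missing_rate = 0), seed = 2)
  q <- suppressMessages(qc_sample(pt$samples[[1]]$genotype))
  cs <- call_clones(q$genotype)
  truth <- pt$truth_cells[pt$truth_cells$timepoint == "diagnosis", ]
  ann <- ann_fixture(truth$barcode, truth$cell_type,
                     unname(truth$compartment))
  j <- suppressMessages(join_modalities(cs$assignments, ann,
                                        cs$signatures))
  sig_size <- stats::setNames(
    vapply(ps$clones, function(cl) length(cl$signature), 1L),
    vapply(ps$clones, `[[`, "", "clone_id"))
  truth_n <- sig_size[truth$clone_id[match(j$barcode, truth$barcode)]]
  expect_identical(unname(j$n_mutations), unname(as.integer(truth_n)))
})

test_that("lineage restriction yields the expected pooled fractions", {
  # all mutant cells myeloid, all lymphoid WT -> fractions (1, 0)
  cells <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 40),
    barcode = paste0("c", 1:80),
    clone_id = rep(c("C1", "WT"), 40),
    mutant_flag = rep(c(TRUE, FALSE), 40),
    compartment = rep(c("myeloid", "T"), 40))
  res <- mutant_fraction_by_compartment(cells)
  expect_true(all(res$per_patient$prog_ery_mye == 1))
  expect_true(all(res$per_patient$lymphoid == 0))

  # no mutant cells anywhere: fractions zero, test skipped
  wt <- dplyr::mutate(cells, mutant_flag = FALSE, clone_id = "WT")
  res0 <- mutant_fraction_by_compartment(wt)
  expect_true(all(res0$per_patient$prog_ery_mye == 0))
  expect_null(res0$test)
})

test_that("planted myeloid restriction is detected across patients", {
  set.seed(82)
  cells <- purrr::map_dfr(1:10, function(p) {
    n <- 300
    comp <- sample(c("progenitors", "immature_erythroid", "myeloid",
                     "T", "NK", "B"), n, replace = TRUE)
    myeloid <- comp %in% c("progenitors", "immature_erythroid", "myeloid")
    mutant <- ifelse(myeloid, runif(n) < 0.5, runif(n) < 0.05)
    tibble::tibble(patient_id = paste0("p", p),
                   barcode = paste0("p", p, "_", 1:n),
                   clone_id = ifelse(mutant, "C1", "WT"),
                   mutant_flag = mutant, compartment = comp)
  })
  res <- mutant_fraction_by_compartment(cells)
  expect_lt(res$test$p_value, 0.05)
  expect_true(all(res$per_patient$prog_ery_mye >
                    res$per_patient$lymphoid))
})

test_that("gene x lineage enrichment builds the right tables", {
  cells <- tibble::tibble(
    clone_id = c(rep("C1", 100), rep("WT", 200)),
    compartment = c(rep("myeloid", 100), rep("myeloid", 100), rep("T", 100)),
    mutant_flag = c(rep(TRUE, 100), rep(FALSE, 200)))
  res <- gene_lineage_enrichment(cells, list(C1 = "TET2"))
  expect_equal(res$mutant_mye, 100)
  expect_equal(res$mutant_lym, 0)
  expect_lt(res$p_adjusted, 0.05)
  expect_equal(res$direction, "prog_ery_mye")

  # proportional split: p near 1
  prop <- tibble::tibble(
    clone_id = rep(c("C1", "WT"), each = 100),
    compartment = rep(rep(c("myeloid", "T"), each = 50), 2),
    mutant_flag = rep(c(TRUE, FALSE), each = 100))
  res2 <- gene_lineage_enrichment(prop, list(C1 = "ASXL1"))
  expect_gt(res2$p_value, 0.5)

  # lymphoid-restricted mutation flags the lymphoid direction
  tcell <- tibble::tibble(
    clone_id = c(rep("C1", 95), rep("WT", 105), rep("C1", 5)),
    compartment = c(rep("T", 95), rep("myeloid", 100), rep("T", 5),
                    rep("myeloid", 5)),
    mutant_flag = c(rep(TRUE, 95), rep(FALSE, 105), rep(TRUE, 5)))
  tcell <- tcell[1:200, ]
  res3 <- gene_lineage_enrichment(tcell, list(C1 = "STAG2"))
  expect_equal(res3$direction, "lymphoid")
  expect_lt(res3$p_adjusted, 0.05)
})

test_that("mutant/WT compositional dynamics recover a planted depletion", {
  set.seed(83)
  # 6 paired patients; mutant cells lose HSPC share post-treatment, WT stable
  pops <- c("HSPC", "Monocyte", "T", "B")
  base <- c(HSPC = 0.4, Monocyte = 0.3, T = 0.2, B = 0.1)
  post <- c(HSPC = 0.1, Monocyte = 0.4, T = 0.3, B = 0.2)
  cells <- purrr::map_dfr(1:6, function(p) {
    purrr::map_dfr(c("diagnosis", "post_treatment"), function(tp) {
      n_mut <- 600
      n_wt <- 600
      p_mut <- if (tp == "diagnosis") base else post
      tibble::tibble(
        patient_id = paste0("p", p), timepoint = tp,
        response = "responder",
        barcode = paste0("p", p, tp, 1:(n_mut + n_wt)),
        clone_id = c(rep("C1", n_mut), rep("WT", n_wt)),
        mutant_flag = c(rep(TRUE, n_mut), rep(FALSE, n_wt)),
        population = c(sample(pops, n_mut, TRUE, p_mut),
                       sample(pops, n_wt, TRUE, base)))
    })
  })
  res <- mutant_population_dynamics(cells, contrast = "timepoint",
                                    n_boot = 100, seed = 3)
  mt <- tidy(res$mutant)
  wt <- tidy(res$wt)
  expect_true(mt$credible[mt$population == "HSPC"])
  expect_false(isTRUE(wt$credible[wt$population == "HSPC"]))
})

test_that("the pipeline runs end to end and is deterministic", {
  cfg <- cohort_config(sim_config(n_cells = 800), seed = 19,
                       panel = default_panel()[c(1:10, 241:260), ])
  sc <- simulate_cohort(cfg)
  out1 <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(sc$cohort, out_dir = out1, seed = 7,
                                      n_boot = 50))
  expect_true(all(c("patient_summary", "dynamics", "fishplot",
                    "ado") %in% names(r1)))
  expect_gt(nrow(r1$patient_summary), 0)
  expect_gt(nrow(r1$fishplot), 0)
  expect_true(file.exists(file.path(out1, "patient_summary.csv")))
  expect_true(file.exists(file.path(out1, "run_log.json")))

  r2 <- suppressWarnings(run_pipeline(sc$cohort, seed = 7, n_boot = 50))
  expect_identical(r1$dynamics, r2$dynamics)
  expect_identical(r1$clone_table, r2$clone_table)
  expect_identical(r1$composition, r2$composition)
  expect_identical(r1$annotation_summary, r2$annotation_summary)

  # dynamics x response table mirrors the designed cohort split
  expect_equal(r1$dynamics_response$shrinkage_responders, 7)
  expect_equal(r1$dynamics_response$other_nonresponders, 6)
  expect_lt(r1$dynamics_response$p_value, 0.001)
})

test_that("plot helpers return ggplot objects", {
  fish <- tibble::tibble(patient_id = "p", clone_id = c("C1", "C1"),
                         signature = "A:HET",
                         timepoint = c("diagnosis", "post_treatment"),
                         fraction = c(0.4, 0.1))
  expect_s3_class(plot_fishplot(fish), "ggplot")
  d <- dm_counts(3)
  r <- composition_test(d$counts, d$condition, n_boot = 30, seed = 1)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})
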
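test_that("per-call filters apply strict thresholds, WT exempt from AF", {
  gt <- matrix(c("HET", "HET", "HET", "WT", "HET", "HOM"), 1)
  depth <- matrix(c(12, 12, 10, 50, 12, 12), 1)
  quality <- matrix(c(35, 30, 35, 90, 35, 35), 1)
  alt <- matrix(c(0.25, 0.25, 0.25, 0.01, 0.20, 0.98), 1)
  gm <- toy_gm(gt, depth, quality, alt)
  out <- suppressMessages(filter_genotype_calls(gm))
  # (q35,d12,af.25) kept; q exactly 30 fails ">30"; d exactly 10 fails;
  # WT with tiny AF kept; HET at af exactly 0.20 fails ">20%"; HOM kept
  expect_identical(as.vector(out$gt),
                   c("HET", "MISSING", "MISSING", "WT", "MISSING", "HOM"))
  # all-zero thresholds leave a positive-valued matrix unchanged
  zero <- qc_thresholds(gq_min = 0, dp_min = 0, af_min = 0)
  gm2 <- toy_gm(matrix(c("WT", "HET", "HOM"), 1))
  expect_identical(filter_genotype_calls(gm2, zero)$gt, gm2$gt)
})

test_that("variant filter keeps, rescues, and drops by the printed rules", {
  # 10 cells x 5 variants
  # v1: genotyped 40%, strong calls -> reported_only
  # v2: mutated in 0 of 10 cells (all WT) -> dropped (mutated fraction)
  # v3: synonymous -> dropped
  # v4: maf 0.02 but whitelisted -> kept
  # v5: ordinary kept
  gt <- cbind(
    c(rep("HET", 4), rep("MISSING", 6)),
    rep("WT", 10),
    rep("HET", 10),
    rep("HET", 10),
    c(rep("HET", 3), rep("WT", 7)))
  gm <- toy_gm(gt, consequence = c("missense", "missense", "synonymous",
                                   "missense", "missense"),
               maf = c(0, 0, 0, 0.02, 0),
               whitelisted = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  res <- filter_variants(gm)
  expect_identical(res$summary$status,
                   c("reported_only", "dropped", "dropped", "kept", "kept"))
  expect_identical(res$summary$drop_reason[2:3],
                   c("mutated_fraction", "consequence"))
  expect_setequal(res$kept$variants$variant_id, c("v4", "v5"))

  # non-whitelisted maf 0.02 is dropped; genotyped exactly 50% is dropped
  gm2 <- toy_gm(cbind(rep("HET", 10),
                      c(rep("HET", 5), rep("MISSING", 5))),
                maf = c(0.02, 0))
  res2 <- filter_variants(gm2)
  expect_identical(res2$summary$drop_reason[1], "population_maf")
  expect_false(res2$summary$status[2] == "kept")  # 50% fails strict ">50%"
  expect_error(filter_variants(gm_subset(gm, cells = integer(0))), "empty")
})

test_that("cell filter removes cells under half genotyped, boundary kept", {
  gt <- rbind(c(rep("HET", 3), rep("MISSING", 7)),   # 30% -> removed
              c(rep("HET", 5), rep("MISSING", 5)),   # exactly 50% -> kept
              rep("HET", 10))                        # fully genotyped
  gm <- toy_gm(gt)
  out <- suppressMessages(filter_cells(gm))
  expect_identical(out$barcodes, c("cell2", "cell3"))
  full <- toy_gm(matrix("HET", 4, 3))
  expect_identical(filter_cells(full)$barcodes, full$barcodes)
})

test_that("QC filters are idempotent and monotone in their thresholds", {
  set.seed(20)
  ps <- patient_spec("P01", "responder", "stable", 2)
  ps$panel <- tiny_panel()
  pt <- simulate_patient(ps, sim_config(n_cells = 300), seed = 2)
  gm <- pt$samples[[1]]$genotype
  once <- suppressMessages(filter_genotype_calls(gm))
  twice <- suppressMessages(filter_genotype_calls(once))
  expect_identical(once$gt, twice$gt)
  v_once <- filter_variants(once)
  v_twice <- filter_variants(v_once$kept)
  expect_setequal(v_twice$kept$variants$variant_id,
                  v_once$kept$variants$variant_id)
  c_once <- suppressMessages(filter_cells(v_once$kept))
  expect_identical(suppressMessages(filter_cells(c_once))$barcodes,
                   c_once$barcodes)

  # relaxing thresholds never shrinks the kept set
  strict <- qc_thresholds()
  loose <- qc_thresholds(gq_min = 10, dp_min = 3, af_min = 0.05,
                         variant_genotyped_min = 0.3,
                         variant_mutated_min = 0.005,
                         cell_genotyped_min = 0.2, maf_max = 0.05)
  k_strict <- suppressMessages(qc_sample(gm, strict))
  k_loose <- suppressMessages(qc_sample(gm, loose))
  expect_true(all(k_strict$genotype$variants$variant_id %in%
                    k_loose$genotype$variants$variant_id))
  expect_true(all(k_strict$genotype$barcodes %in% k_loose$genotype$barcodes))
  expect_true(sum(k_loose$calls_qc$gt != "MISSING") >=
                sum(k_strict$calls_qc$gt != "MISSING"))
})

test_that("VAF by cell count follows the category formula", {
  expect_equal(vaf_by_cell_count(rep("HET", 100)), 50)
  expect_equal(vaf_by_cell_count(c(rep("HET", 50), rep("HOM", 50))), 75)
  expect_equal(vaf_by_cell_count(c("HET", "MISSING", "MISSING")), 50)
  expect_error(vaf_by_cell_count(rep("MISSING", 3)), "no genotyped")
})

test_that("germline heterozygous selection demands both timepoints", {
  # v1 qualifies at both (symmetric dropout keeps VAF at 50); v2 fails the
  # mutated fraction at one timepoint; v3 fails the VAF window (excess HOM)
  mk <- function(n_wt, n_hom, n = 200) {
    c(rep("HET", n - n_wt - n_hom), rep("HOM", n_hom), rep("WT", n_wt))
  }
  gm_a <- toy_gm(cbind(mk(5, 5), mk(5, 5), mk(0, 40)))
  gm_b <- toy_gm(cbind(mk(4, 4), mk(24, 0), mk(0, 40)))
  sel <- select_germline_het(gm_a, gm_b)
  expect_identical(sel$variant_id, "v1")

  set.seed(22)
  ps <- patient_spec("P02", "responder", "stable", 2)
  ps$panel <- tiny_panel()
  pt <- simulate_patient(ps, sim_config(n_cells = 2000, ado_rate = 0,
                                        genotype_error_rate = 0,
                                        missing_rate = 0), seed = 4)
  sel2 <- select_germline_het(pt$samples[[1]]$genotype,
                              pt$samples[[2]]$genotype)
  expect_setequal(sel2$variant_id, ps$germline_ids)
})

test_that("ADO formula and averaging match the definition", {
  gm <- toy_gm(matrix(c(rep("HET", 80), rep("WT", 10), rep("HOM", 10)),
                      ncol = 1))
  est <- suppressWarnings(ado_rate(gm, "v1"))
  expect_equal(est$per_variant$ado, 20)
  expect_equal(est$sample_ado, 20)
  # fewer than five qualifying variants: averaged with a warning
  expect_warning(ado_rate(gm, "v1"), "qualify")
  pure <- toy_gm(matrix(rep("HET", 50), ncol = 1))
  expect_equal(suppressWarnings(ado_rate(pure, "v1"))$sample_ado, 0)
  expect_error(ado_rate(gm, "nope"), "no germline")
})

test_that("the ADO estimator recovers a planted 10% dropout rate", {
  set.seed(24)
  ps <- patient_spec("P03", "responder", "stable", 2)
  ps$panel <- tiny_panel()
  pt <- simulate_patient(ps, sim_config(n_cells = 2000, ado_rate = 0.10),
                         seed = 6)
  lane <- dna_lane(pt)
  for (est in lane$ado) {
    expect_gte(est$sample_ado, 8)
    expect_lte(est$sample_ado, 12)
  }
})
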
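test_that("clones are groups of identical signatures over kept variants", {
  gm <- gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HET", B = "HET")),
    c(50, 30, 20))
  cs <- call_clones(gm)
  expect_equal(nrow(cs$clones), 3)
  expect_equal(sum(!cs$clones$is_wt), 2)
  expect_equal(cs$clones$n_cells[cs$clones$is_wt], 50)

  expect_warning(
    wt_only <- call_clones(gm_from_signatures(list(character(0)), 40)),
    "no kept variants")
  expect_equal(nrow(wt_only$clones), 1)
  expect_true(wt_only$clones$is_wt)

  # MISSING among kept variants -> unassigned, not imputed
  gm2 <- gm_from_signatures(list(c(A = "HET")), 10)
  gm2$gt[1, "A"] <- "MISSING"
  cs2 <- call_clones(gm2)
  expect_equal(length(cs2$unassigned), 1)
  expect_equal(sum(cs2$clones$n_cells), 9)
})

test_that("noiseless simulation is recovered exactly by clone calling", {
  for (seed in c(31, 32)) {
    set.seed(seed)
    ps <- patient_spec("PX", "responder", "stable", 3)
    ps$panel <- tiny_panel()
    pt <- simulate_patient(ps, sim_config(n_cells = 600, ado_rate = 0,
                                          genotype_error_rate = 0,
                                          missing_rate = 0), seed = seed)
    q <- suppressMessages(qc_sample(pt$samples[[1]]$genotype))
    cs <- call_clones(q$genotype)
    truth <- pt$truth_cells[pt$truth_cells$timepoint == "diagnosis", ]
    truth <- truth[match(cs$assignments$barcode, truth$barcode), ]
    # same partition: every called clone maps 1:1 onto a true clone
    tab <- table(cs$assignments$clone_id, truth$clone_id)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
    expect_equal(nrow(cs$clones), length(ps$clones))
  }
})

test_that("ADO-artifact clones merge by the dropout-expectation rule", {
  gm <- gm_from_signatures(
    list(character(0), c(A = "HET", B = "HET"), c(A = "HET", B = "HOM")),
    c(500, 1000, 40))
  cs <- call_clones(gm)
  merged <- suppressMessages(flag_ado_clones(cs, ado = 10))
  expect_equal(sum(!merged$clones$is_wt), 1)   # 40 <= 1000 * 0.10 * 1.5
  expect_equal(max(merged$clones$n_cells), 1040)

  gm2 <- gm_from_signatures(
    list(character(0), c(A = "HET", B = "HET"), c(A = "HET", B = "HOM")),
    c(500, 1000, 400))
  kept <- suppressMessages(flag_ado_clones(call_clones(gm2), ado = 10))
  expect_equal(sum(!kept$clones$is_wt), 2)     # 400 > 150: a real clone

  none <- flag_ado_clones(call_clones(gm2), ado = 0)
  expect_identical(none$clones, call_clones(gm2)$clones)
})

test_that("flag_ado_clones spares clones well above the expectation", {
  set.seed(33)
  for (seed in 1:5) {
    ps <- patient_spec("PX", "responder", "stable", 3)
    ps$panel <- tiny_panel()
    pt <- simulate_patient(ps, sim_config(n_cells = 3000, ado_rate = 0.05),
                           seed = seed)
    lane <- dna_lane(pt)
    truth <- pt$truth_cells[pt$truth_cells$timepoint == "diagnosis", ]
    true_sizes <- table(truth$clone_id)
    cs <- lane$clones[[1]]
    # every true clone with >= 6% of cells must survive ADO-clone removal
    big <- names(true_sizes)[true_sizes / sum(true_sizes) >= 0.06 &
                               names(true_sizes) != "WT"]
    expect_gte(sum(!cs$clones$is_wt & cs$clones$clone_id != "minor"),
               length(big))
  }
})

test_that("phylogeny orders clones by inclusion with zygosity progression", {
  chain <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HET", B = "HET"),
         c(A = "HET", B = "HET", C = "HET")), c(40, 30, 20, 10)))
  ph <- build_phylogeny(chain)
  expect_equal(ph$topology, "linear")
  expect_equal(nrow(ph$conflicts), 0)
  # C1 is the largest mutant clone {A}; chain follows size order here
  expect_setequal(ph$edges$parent, c("WT", "C1", "C2"))

  branch <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HET", B = "HET"),
         c(A = "HET", C = "HET")), c(40, 30, 20, 10)))
  phb <- build_phylogeny(branch)
  expect_equal(phb$topology, "branched")
  expect_equal(sum(phb$edges$parent == "C1"), 2)

  zyg <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HOM")), c(40, 30, 10)))
  phz <- build_phylogeny(zyg)
  het_id <- zyg$clones$clone_id[zyg$clones$signature == "A:HET"]
  hom_id <- zyg$clones$clone_id[zyg$clones$signature == "A:HOM"]
  expect_true(any(phz$edges$parent == het_id & phz$edges$child == hom_id))

  confl <- call_clones(gm_from_signatures(
    list(c(A = "HET", B = "HET"), c(B = "HET", C = "HET"),
         c(A = "HET", C = "HET")), c(30, 30, 30)))
  expect_gt(nrow(build_phylogeny(confl)$conflicts), 0)
})

test_that("noiseless hierarchies are recovered as isomorphic phylogenies", {
  set.seed(35)
  for (seed in c(41, 42, 43)) {
    ps <- patient_spec("PX", "responder", "stable",
                       n_mutant_clones = sample(3:4, 1))
    ps$panel <- tiny_panel()
    pt <- simulate_patient(ps, sim_config(n_cells = 800, ado_rate = 0,
                                          genotype_error_rate = 0,
                                          missing_rate = 0), seed = seed)
    q <- suppressMessages(qc_sample(pt$samples[[1]]$genotype))
    cs <- call_clones(q$genotype)
    ph <- build_phylogeny(cs)
    # map called clones to true clones by signature, compare edge sets
    true_sig <- stats::setNames(
      vapply(ps$clones, function(cl) {
        if (!length(cl$signature)) return("WT")
        ord <- order(names(cl$signature))
        paste(names(cl$signature)[ord], cl$signature[ord], sep = ":",
              collapse = ";")
      }, ""),
      vapply(ps$clones, `[[`, "", "clone_id"))
    called_to_true <- stats::setNames(
      names(true_sig)[match(cs$clones$signature, true_sig)],
      cs$clones$clone_id)
    true_edges <- purrr::map_dfr(ps$clones, function(cl) {
      if (is.na(cl$parent_id)) return(NULL)
      tibble::tibble(parent = cl$parent_id, child = cl$clone_id)
    })
    mapped <- tibble::tibble(parent = called_to_true[ph$edges$parent],
                             child = called_to_true[ph$edges$child])
    expect_setequal(paste(mapped$parent, mapped$child),
                    paste(true_edges$parent, true_edges$child))
  }
})

test_that("clone statistics match closed forms", {
  one <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET")), c(50, 50)))
  st <- clone_stats(one)
  expect_equal(st$shannon, 0)
  expect_equal(st$predominant_fraction, 1)

  two <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(B = "HET")), c(40, 30, 30)))
  expect_equal(clone_stats(two)$shannon, log(2), tolerance = 1e-12)

  three <- call_clones(gm_from_signatures(
    list(c(A = "HET"), c(B = "HET"), c(C = "HET")), c(70, 20, 10)))
  expect_equal(clone_stats(three)$shannon, 0.8018, tolerance = 1e-4)

  none <- suppressWarnings(
    call_clones(gm_from_signatures(list(character(0)), 30)))
  st0 <- clone_stats(none)
  expect_true(is.na(st0$shannon))
  expect_true(is.na(st0$predominant_fraction))
})

test_that("Shannon diversity is permutation-invariant, maximal when even", {
  set.seed(37)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    counts <- sample(10:500, n)
    h <- as.numeric(vegan::diversity(counts))
    h_perm <- as.numeric(vegan::diversity(sample(counts)))
    expect_equal(h, h_perm)
    expect_lte(h, log(n) + 1e-12)
  }
})

test_that("gene attribution reads first and predominant clones", {
  gm <- gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HET", B = "HET")),
    c(40, 20, 30))
  gm$variants$gene <- c("TET2", "ASXL1")
  cs <- call_clones(gm)
  ph <- build_phylogeny(cs)
  att <- clone_gene_attribution(ph, cs, gm$variants)
  expect_identical(att$first_clone_genes, "TET2")
  # predominant = larger mutant clone = {A,B}
  expect_setequal(att$predominant_clone_genes, c("TET2", "ASXL1"))

  wt <- suppressWarnings(
    call_clones(gm_from_signatures(list(character(0)), 10)))
  att0 <- clone_gene_attribution(build_phylogeny(wt), wt,
                                 tibble::tibble(variant_id = character(0),
                                                gene = character(0)))
  expect_length(att0$first_clone_genes, 0)

  # tie: two equal-size children of the root
  tie <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(B = "HET")), c(40, 30, 30)))
  expect_message(
    att_tie <- clone_gene_attribution(build_phylogeny(tie), tie,
                                      toy_gm(matrix("WT", 1, 2))$variants |>
                                        dplyr::mutate(variant_id = c("A", "B"))),
    "tie")
  expect_length(att_tie$first_clones, 2)
})

test_that("CHIP flags follow the three definitions", {
  gm <- gm_from_signatures(
    list(character(0), c(A = "HET"), c(B = "HET")), c(940, 30, 30))
  gm$variants$gene <- c("DNMT3A", "SF3B1")
  cs <- call_clones(gm)
  core3 <- chip_flags(cs, gm$variants, "core3")
  expect_identical(core3$chip,
                   gm$variants$gene[match(
                     sapply(cs$signatures[core3$clone_id], names),
                     gm$variants$variant_id)] == "DNMT3A")
  core5 <- chip_flags(cs, gm$variants, "core5")
  expect_true(all(core5$chip))

  # driver at VAF-by-cell-count 1.5% fails the 2% rule
  gm2 <- gm_from_signatures(list(character(0), c(A = "HET")), c(970, 30))
  gm2$variants$gene <- "TP53"
  cs2 <- call_clones(gm2)
  dv <- chip_flags(cs2, gm2$variants, "driver_vaf2", gm = gm2,
                   driver_genes = "TP53")
  expect_false(dv$chip)  # VAF = 30 / 2000 = 1.5%
  expect_error(chip_flags(cs2, gm2$variants, "driver_vaf2", gm = gm2),
               "driver gene list")
})

test_that("dynamics rules classify the three archetypes", {
  dx <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HET", B = "HET")),
    c(400, 400, 200)))
  tx_shrunk <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HET", B = "HET")),
    c(930, 50, 20)))
  expect_equal(classify_dynamics(dx, tx_shrunk)$pattern, "shrinkage")
  expect_equal(classify_dynamics(dx, dx)$pattern, "stable")
  tx_new <- call_clones(gm_from_signatures(
    list(character(0), c(A = "HET"), c(A = "HET", B = "HET"),
         c(A = "HET", B = "HET", C = "HET")),
    c(400, 350, 150, 100)))
  expect_equal(classify_dynamics(dx, tx_new)$pattern, "expansion")
})

test_that("pattern calls recover the generating pattern on simulations", {
  set.seed(39)
  for (pattern in c("shrinkage", "stable", "expansion")) {
    hits <- vapply(1:8, function(seed) {
      set.seed(seed + 100)
      ps <- patient_spec("PX", "responder", pattern, sample(2:4, 1))
      ps$panel <- tiny_panel()
      pt <- simulate_patient(ps, sim_config(n_cells = 3000,
                                            ado_rate = 0.05),
                             seed = seed)
      dna_lane(pt)$dynamics$pattern == pattern
    }, TRUE)
    expect_gte(mean(hits), 7 / 8)
  }
})
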
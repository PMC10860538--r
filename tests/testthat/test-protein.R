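adt_fixture <- function(counts, iso = 1) {
  k <- ncol(counts)
  adt_matrix(counts, tibble::tibble(
    antibody = c(paste0("ab", seq_len(k - iso)), paste0("iso", seq_len(iso))),
    is_isotype = c(rep(FALSE, k - iso), rep(TRUE, iso))),
    barcodes = paste0("c", seq_len(nrow(counts))))
}

test_that("ADT cell QC keeps totals in [200, 100000] inclusive", {
  counts <- rbind(c(100L, 50L, 0L),       # 150: out
                  c(150L, 80L, 20L),      # 250: in
                  c(149000L, 900L, 100L), # 150000: out
                  c(150L, 50L, 0L),       # exactly 200: kept
                  c(99000L, 900L, 100L))  # exactly 100000: kept
  out <- suppressMessages(qc_adt_cells(adt_fixture(counts)))
  expect_setequal(out$barcodes, c("c2", "c4", "c5"))
  ok <- adt_fixture(matrix(100L, 4, 3))
  expect_identical(qc_adt_cells(ok)$counts, ok$counts)
})

test_that("CLR transform matches its closed form and sums to zero", {
  uni <- normalize_clr(adt_fixture(matrix(25L, 3, 4)))
  expect_true(all(abs(uni$clr) < 1e-12))

  x <- adt_fixture(matrix(c(10L, 30L, 60L), 1), iso = 0 + 1)
  # direct evaluation of CPM+1 then centered log over the 3 columns
  cpm <- c(10, 30, 60) / 100 * 1e6 + 1
  expected <- log(cpm) - mean(log(cpm))
  got <- normalize_clr(adt_fixture(matrix(c(10L, 30L, 60L), 1)))$clr[1, ]
  expect_equal(unname(got), expected, tolerance = 1e-12)
  expect_equal(unname(round(expected, 3)), c(-0.963, 0.135, 0.828))

  set.seed(61)
  big <- adt_fixture(matrix(rnbinom(50 * 8, mu = 40, size = 5) + 1L, 50, 8))
  clr <- normalize_clr(big)$clr
  expect_true(all(abs(rowSums(clr)) < 1e-9))
})

test_that("isotype denoising subtracts background and floors at zero", {
  nadt <- normalize_clr(adt_fixture(matrix(c(30L, 10L, 20L), 1), iso = 1))
  manual <- nadt$clr[1, 1:2] - nadt$clr[1, 3]
  out <- denoise_isotypes(nadt)
  expect_equal(unname(out$clr[1, ]), unname(pmax(manual, 0)))
  expect_false(any(out$antibodies$is_isotype))
  expect_true(all(out$clr >= 0))
  no_iso <- structure(nadt, class = "normalized_adt")
  no_iso$antibodies$is_isotype <- FALSE
  expect_error(denoise_isotypes(no_iso), "isotype")
})

test_that("denoising cancels a planted cell-level background shift", {
  set.seed(62)
  n <- 400
  k <- 10
  base <- matrix(rnbinom(n * k, mu = 20, size = 10), n, k)
  # half the cells carry doubled nonspecific background on every antibody
  shift <- rep(c(1, 2), each = n / 2)
  counts <- matrix(rnbinom(n * k, mu = 20 * shift, size = 10), n, k)
  out <- denoise_isotypes(normalize_clr(adt_fixture(counts, iso = 2)))
  null_ab <- out$clr[, 1]
  expect_lt(abs(mean(null_ab[shift == 1]) - mean(null_ab[shift == 2])), 0.05)
})

test_that("clustering separates blobs and is deterministic", {
  set.seed(63)
  n <- 300
  # two Gaussian blobs in normalized space, separation >> spread
  mk_nadt <- function(clr) {
    structure(list(clr = clr,
                   antibodies = tibble::tibble(
                     antibody = paste0("ab", seq_len(ncol(clr))),
                     is_isotype = FALSE),
                   barcodes = paste0("c", seq_len(nrow(clr))),
                   totals = rep(1000, nrow(clr)), denoised = TRUE),
              class = "normalized_adt")
  }
  clr <- rbind(matrix(rnorm(n * 6, 0), n, 6),
               matrix(rnorm(n * 6, 20), n, 6))
  nadt <- mk_nadt(clr)
  cl <- cluster_cells(nadt, n_components = 4, resolution = 0.1, seed = 2)
  expect_equal(nlevels(cl$cluster), 2)
  split_ok <- table(cl$cluster, rep(1:2, each = n))
  expect_true(all(rowSums(split_ok > 0) == 1))

  n1 <- mk_nadt(matrix(rnorm(2 * n * 6), 2 * n, 6))
  cl1 <- cluster_cells(n1, n_components = 4, resolution = 0.01, seed = 2)
  expect_equal(nlevels(cl1$cluster), 1)

  cl_a <- cluster_cells(nadt, n_components = 4, resolution = 0.1, seed = 9)
  cl_b <- cluster_cells(nadt, n_components = 4, resolution = 0.1, seed = 9)
  expect_identical(cl_a$cluster, cl_b$cluster)
  expect_error(cluster_cells(n1, k = 2 * n), "more than k")
})

test_that("flat-profile clusters are dropped as artifacts", {
  set.seed(64)
  n <- 200
  structured <- matrix(rnbinom(n * 8, mu = rep(c(300, rep(8, 7)), each = n),
                               size = 20), n, 8)
  flat <- matrix(rnbinom(n * 8, mu = 40, size = 20), n, 8)
  nadt <- denoise_isotypes(normalize_clr(adt_fixture(rbind(structured, flat),
                                                     iso = 1)))
  cl <- cluster_cells(nadt, n_components = 4, resolution = 0.1, seed = 5)
  out <- suppressMessages(drop_artifact_clusters(nadt, cl,
                                                 min_variance = 0.05))
  dropped <- attr(out, "artifact_clusters")
  expect_gte(length(dropped), 1)
  # the flat cells are the unassigned ones
  expect_gt(mean(out$cluster[(n + 1):(2 * n)] == "unassigned"), 0.9)
  # threshold zero removes nothing
  none <- drop_artifact_clusters(nadt, cl, min_variance = 0)
  expect_length(attr(none, "artifact_clusters"), 0)
})

test_that("marker rules annotate clusters and flag sample-private ones", {
  set.seed(65)
  n <- 150
  mk_type <- function(hi) {
    mu <- rep(8, 6)
    mu[hi] <- 200
    matrix(rnbinom(n * 6, mu = rep(mu, each = n), size = 20), n, 6)
  }
  counts <- rbind(mk_type(1), mk_type(2), mk_type(3))
  adt <- adt_matrix(counts, tibble::tibble(
    antibody = c("CD3", "CD19", "CD34", "CD56", "CD71", "iso1"),
    is_isotype = c(rep(FALSE, 5), TRUE)),
    barcodes = paste0("c", seq_len(3 * n)))
  nadt <- denoise_isotypes(normalize_clr(adt))
  cl <- cluster_cells(nadt, n_components = 4, resolution = 0.1, seed = 4)
  rules <- tibble::tibble(
    population = c("T", "B", "HSPC"),
    high = list("CD3", "CD19", "CD34"),
    low = list(c("CD19", "CD56"), character(0), character(0)),
    high_cutoff = 1.5, low_cutoff = 0.5,
    compartment = c("T", "B", "progenitors"))
  ann <- annotate_cells(nadt, cl, rules)
  truth <- rep(c("T", "B", "HSPC"), each = n)
  expect_gt(mean(ann$cells$population == truth), 0.95)
  expect_equal(unname(ann$cells$compartment[ann$cells$population == "HSPC"][1]),
               "progenitors")

  # population drawn >90% from one sample is excluded from compartments
  sample_of <- stats::setNames(
    c(rep("s1", n), rep(c("s1", "s2"), n / 2), rep(c("s1", "s2"), n / 2)),
    adt$barcodes)
  ann2 <- suppressMessages(
    annotate_cells(nadt, cl, rules, sample_of = sample_of))
  expect_true("T" %in% ann2$rare_single_sample)
  expect_true(all(ann2$cells$compartment[ann2$cells$population == "T"]
                  == "rare"))
  expect_error(annotate_cells(nadt, cl, rules[0, ]), "empty")
})

test_that("LISI reflects mixing: interleaved near 2, separated near 1", {
  n <- 300
  x <- matrix(seq_len(n), ncol = 1)
  inter <- rep(c("a", "b"), n / 2)
  li <- lisi(x, inter, perplexity = 15)
  expect_gt(li$mean, 1.8)
  sep <- rep(c("a", "b"), each = n / 2)
  li2 <- lisi(x, sep, perplexity = 15)
  expect_lt(li2$mean, 1.1)
  expect_gte(min(li2$lisi), 1)

  # invariant to relabeling
  flip <- ifelse(inter == "a", "z", "y")
  expect_equal(lisi(x, flip, perplexity = 15)$lisi, li$lisi)

  # single label: all ones by convention
  expect_equal(lisi(x, rep("a", n))$mean, 1)

  # monotone along a mixing path
  set.seed(66)
  vals <- vapply(c(0, 0.25, 0.5), function(mix) {
    x2 <- rbind(matrix(rnorm(200, 0), ncol = 1),
                matrix(rnorm(200, 10 * (1 - mix)), ncol = 1))
    lisi(x2, rep(c("a", "b"), each = 200), perplexity = 20)$mean
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the default cohort's planted cell types are recovered", {
  set.seed(67)
  ps <- patient_spec("PX", "responder", "stable", 2)
  ps$panel <- tiny_panel()
  pt <- simulate_patient(ps, sim_config(n_cells = 2500), seed = 5)
  adt <- suppressMessages(qc_adt_cells(pt$samples[[1]]$adt))
  nadt <- denoise_isotypes(normalize_clr(adt))
  truth <- pt$truth_cells[pt$truth_cells$timepoint == "diagnosis", ]
  tt <- truth$cell_type[match(nadt$barcodes, truth$barcode)]
  cl <- suppressMessages(
    drop_artifact_clusters(nadt, cluster_cells(nadt, seed = 3)))
  ann <- annotate_cells(nadt, cl)
  pop <- ifelse(ann$cells$population == "rare_CD11c_CD49d_CD62P", "Rare",
                ann$cells$population)
  keep <- pop != "unassigned"
  expect_gte(dplyr::n_distinct(pop[keep]), 6)
  expect_gte(mclust::adjustedRandIndex(tt[keep], pop[keep]), 0.9)
  expect_lt(mean(!keep), 0.1)
})
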
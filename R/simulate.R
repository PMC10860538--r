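# Synthetic cohort generator -------------------------------------------
#
# Emulates the statistical structure of droplet targeted-amplicon
# single-cell DNA + ADT runs on bone marrow: clonal genotype signatures
# with zygosity, symmetric allele dropout at heterozygous sites,
# genotype-quality/depth noise, negative-binomial amplicon depths with
# planted copy-number events, cell-type-specific ADT means over a shared
# isotype background, and paired-timepoint clone-proportion dynamics
# (shrinkage / stable / expansion). Every sample is emitted together with
# its ground truth so downstream estimators can be tested for recovery.

CELL_TYPES <- c("HSPC", "CMP", "Erythroid", "Monocyte", "Granulocyte",
                "T", "NK", "B", "Rare")

COMPARTMENT_MAP <- c(
  HSPC = "progenitors", CMP = "progenitors",
  Erythroid = "immature_erythroid",
  Monocyte = "myeloid", Granulocyte = "myeloid",
  T = "T", NK = "NK", B = "B", Rare = "rare"
)

PANEL_GENES <- c(
  # recurrently mutated myeloid genes (chromosome of the canonical locus)
  TET2 = "4", ASXL1 = "20", RUNX1 = "21", TP53 = "17", U2AF1 = "21",
  BCOR = "X", DNMT3A = "2", EZH2 = "7", ZRSR2 = "X", STAG2 = "X",
  NRAS = "1", IDH1 = "2", PHF6 = "X", PTEN = "10", NF1 = "17",
  CUX1 = "7", SF3B1 = "2", IDH2 = "15", JAK2 = "9", KRAS = "12",
  SRSF2 = "17", SETBP1 = "18", CBL = "11", CALR = "19", CEBPA = "19",
  CSF3R = "1", ETV6 = "12", FLT3 = "13", GATA2 = "3", GNAS = "20",
  KIT = "4", MPL = "1", NPM1 = "5", NOTCH1 = "9", PPM1D = "17",
  PTPN11 = "12", RAD21 = "8", RB1 = "13", SH2B3 = "12", SMC1A = "X",
  SMC3 = "10", WT1 = "11", KDM6A = "X", KMT2A = "11", MYD88 = "3",
  BRAF = "7", ABL1 = "9", CSNK1A1 = "5", DDX41 = "5", ANKRD26 = "10",
  GATA1 = "X", EP300 = "22", CREBBP = "16"
)

#' Default synthetic amplicon panel
#'
#' A deterministic 519-amplicon panel tiling 53 recurrently mutated myeloid
#' genes, mirroring the size and layout of a commercial MDS targeted panel.
#' Coordinates are synthetic (0-based half-open) but chromosome assignments
#' follow the genes' canonical loci so region-level copy-number logic has
#' realistic structure.
#'
#' @return tibble with `chrom`, `start`, `end`, `amplicon_id`, `gene`
#' @export
default_panel <- function() {
  genes <- names(PANEL_GENES)
  n_amp <- c(rep(10L, 42), rep(9L, 11))  # 42*10 + 11*9 = 519
  purrr::map2_dfr(genes, n_amp, function(g, k) {
    base <- 1e6 + 1000 * match(g, genes)
    tibble::tibble(
      chrom = paste0("chr", PANEL_GENES[[g]]),
      start = base + (seq_len(k) - 1L) * 300L,
      end = base + (seq_len(k) - 1L) * 300L + 250L,
      amplicon_id = sprintf("AMP_%s_%02d", g, seq_len(k)),
      gene = g
    )
  })
}

#' Default synthetic antibody panel
#'
#' 42 surface-marker antibodies plus 3 isotype controls, mirroring a
#' heme-oncology ADT cocktail.
#'
#' @return tibble with `antibody`, `is_isotype`
#' @export
default_antibodies <- function() {
  targets <- c("CD1c", "CD2", "CD3", "CD4", "CD5", "CD7", "CD8", "CD10",
               "CD11b", "CD11c", "CD13", "CD14", "CD16", "CD19", "CD22",
               "CD25", "CD26", "CD30", "CD32", "CD33", "CD34", "CD38",
               "CD42b", "CD45", "CD45RA", "CD49d", "CD56", "CD62P", "CD64",
               "CD69", "CD71", "CD83", "CD90", "CD117", "CD123", "CD138",
               "CD141", "CD163", "CD303", "CD304", "HLA-DR", "FCER1A")
  isotypes <- c("IgG1_iso", "IgG2a_iso", "IgG2b_iso")
  tibble::tibble(antibody = c(targets, isotypes),
                 is_isotype = c(rep(FALSE, length(targets)),
                                rep(TRUE, length(isotypes))))
}

# mean ADT signal per (cell type, antibody); baseline 8, lineage markers high
default_adt_means <- function(antibodies = default_antibodies()) {
  ab <- antibodies$antibody
  m <- matrix(8, nrow = length(CELL_TYPES), ncol = length(ab),
              dimnames = list(CELL_TYPES, ab))
  m[, antibodies$is_isotype] <- 0  # isotypes carry background only
  hi <- list(
    HSPC = c(CD34 = 150, CD117 = 100, CD90 = 80, CD45 = 40),
    CMP = c(CD34 = 130, CD38 = 100, CD123 = 90, CD45 = 40),
    Erythroid = c(CD71 = 180),
    Monocyte = c(CD11b = 140, CD14 = 150, CD33 = 110, CD64 = 90,
                 `HLA-DR` = 100, CD45 = 90),
    Granulocyte = c(CD11b = 120, CD16 = 130, CD13 = 100, CD33 = 60,
                    CD45 = 60),
    T = c(CD3 = 160, CD5 = 110, CD7 = 100, CD2 = 90, CD45 = 100),
    NK = c(CD56 = 150, CD7 = 110, CD16 = 80, CD2 = 60, CD45 = 100),
    B = c(CD19 = 150, CD22 = 110, CD45RA = 80, `HLA-DR` = 90, CD45 = 100),
    Rare = c(CD11c = 140, CD45 = 120, CD49d = 110, CD62P = 100)
  )
  m["HSPC", "CD38"] <- 4     # CD38-low distinguishes HSPC from CMP
  m["Erythroid", "CD45"] <- 3
  for (ct in names(hi)) m[ct, names(hi[[ct]])] <- hi[[ct]]
  m
}

# default lineage mixtures: mutant clones are skewed to the stem/myeloid
# side, the WT clone carries most of the lymphoid compartment
default_mutant_mix <- function() {
  c(HSPC = 0.22, CMP = 0.18, Erythroid = 0.18, Monocyte = 0.14,
    Granulocyte = 0.14, T = 0.06, NK = 0.03, B = 0.04, Rare = 0.01)
}

default_wt_mix <- function() {
  c(HSPC = 0.05, CMP = 0.06, Erythroid = 0.12, Monocyte = 0.12,
    Granulocyte = 0.12, T = 0.30, NK = 0.08, B = 0.14, Rare = 0.01)
}

#' Simulation noise configuration
#'
#' Per-sample noise model for the synthetic generator. Defaults reflect the
#' study conditions: roughly 3,000 cells per sample (the study's 90,721
#' cells over 28 samples), allele dropout around 5%, targeted-panel depth
#' of ~40 reads per amplicon per cell with negative-binomial dispersion.
#'
#' @param n_cells cells per sample
#' @param ado_rate symmetric allele-dropout probability per HET call: the
#'   call flips to WT or HOM with probability `ado_rate/2` each
#' @param genotype_error_rate probability a call is replaced by a uniform
#'   draw from WT/HET/HOM (independent of dropout)
#' @param missing_rate probability a call is emitted as MISSING
#' @param depth_mean,depth_size negative-binomial mean/size of per-call and
#'   per-amplicon read depth
#' @param depth_fail_rate probability a call's depth collapses (Poisson
#'   mean 5), exercising the depth QC filter
#' @param gq_pass_rate probability a call's genotype quality lands above
#'   the QC cutoff (pass: uniform on 31-99; fail: uniform on 0-30)
#' @param lib_sd lognormal sd of per-cell amplicon library size factors
#' @param adt_size negative-binomial size of ADT signal counts
#' @param isotype_background mean of the flat background added to every
#'   antibody (isotypes carry only this background)
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_cells = 3000, ado_rate = 0.05,
                       genotype_error_rate = 0.002, missing_rate = 0.03,
                       depth_mean = 40, depth_size = 8,
                       depth_fail_rate = 0.02, gq_pass_rate = 0.98,
                       lib_sd = 0.2, adt_size = 4, isotype_background = 3) {
  stopifnot(ado_rate >= 0, ado_rate <= 1, genotype_error_rate >= 0,
            genotype_error_rate <= 1, missing_rate >= 0, missing_rate <= 1,
            depth_mean > 0, isotype_background >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Specify a clone for simulation
#'
#' @param clone_id clone label ("WT" for the wild-type clone)
#' @param signature named character vector `variant_id -> "HET"/"HOM"`;
#'   empty for the WT clone
#' @param parent_id parental clone label or `NA`
#' @param proportions named numeric: fraction of cells at `diagnosis` and
#'   `post_treatment`
#' @param celltype_mix named numeric over [CELL_TYPES]; defaults depend on
#'   whether the clone is mutant
#' @param post_celltype_mix optional distinct mixture post-treatment
#' @param cnv_events tibble(`chrom`, `start`, `end`, `copies`) of planted
#'   copy-number events (copies in 1/2/3), or NULL
#' @return list of class `clone_spec`
#' @export
clone_spec <- function(clone_id, signature = character(0), parent_id = NA,
                       proportions = c(diagnosis = 0, post_treatment = 0),
                       celltype_mix = NULL, post_celltype_mix = NULL,
                       cnv_events = NULL) {
  if (is.null(celltype_mix)) {
    celltype_mix <- if (length(signature)) default_mutant_mix()
                    else default_wt_mix()
  }
  celltype_mix <- celltype_mix / sum(celltype_mix)
  if (!is.null(post_celltype_mix)) {
    post_celltype_mix <- post_celltype_mix / sum(post_celltype_mix)
  }
  structure(list(clone_id = clone_id, signature = signature,
                 parent_id = parent_id, proportions = proportions,
                 celltype_mix = celltype_mix,
                 post_celltype_mix = post_celltype_mix,
                 cnv_events = cnv_events),
            class = "clone_spec")
}

#' Evolve clone proportions across timepoints
#'
#' Applies one of the three paired-timepoint dynamics patterns observed
#' under hypomethylating therapy to a diagnosis proportion vector.
#'
#' @param pattern `"shrinkage"`, `"stable"`, or `"expansion"`
#' @param base_props named numeric over clones (must include `"WT"`),
#'   summing to 1
#' @param factor shrink multiplier(s) for mutant clones (must be < 0.5);
#'   scalar or per-mutant-clone vector. Default draws one factor per clone
#'   uniformly on [0.1, 0.35] from the current RNG stream.
#' @param new_clone_fraction post-treatment fraction of the newly appearing
#'   clone under `"expansion"` (>= 0.05), carved out of the WT fraction
#' @return list with `diagnosis` and `post_treatment` named proportion
#'   vectors; under expansion `post_treatment` gains a `"new"` entry
#' @export
simulate_dynamics <- function(pattern, base_props, factor = NULL,
                              new_clone_fraction = 0.10) {
  if (!pattern %in% c("shrinkage", "stable", "expansion")) {
    rlang::abort(sprintf("unknown dynamics pattern '%s'", pattern))
  }
  if (abs(sum(base_props) - 1) > 1e-9) {
    rlang::abort("clone proportions must sum to 1")
  }
  mut <- setdiff(names(base_props), "WT")
  post <- base_props
  if (pattern == "shrinkage" && length(mut)) {
    f <- factor %||% stats::runif(length(mut), 0.1, 0.35)
    if (any(f >= 0.5)) rlang::abort("shrinkage factor must be < 0.5")
    post[mut] <- base_props[mut] * f
    post["WT"] <- 1 - sum(post[mut])
  } else if (pattern == "expansion") {
    if (new_clone_fraction < 0.05) {
      rlang::abort("new clone fraction must be >= 0.05")
    }
    take <- min(new_clone_fraction, unname(post["WT"]) * 0.9)
    post["WT"] <- post["WT"] - take
    post <- c(post, new = take)
  }
  list(diagnosis = base_props, post_treatment = post)
}

#' Randomly construct the clonal architecture of one synthetic patient
#'
#' Draws a small rooted clone hierarchy (linear or branched), one new
#' somatic variant per clone, germline heterozygous variants for ADO
#' estimation, and diagnosis proportions; then applies [simulate_dynamics()]
#' for the requested pattern. The first acquired mutation is biased towards
#' TET2, the most frequent initiating lesion in this disease setting.
#'
#' @param patient_id label
#' @param response `"responder"` or `"nonresponder"`
#' @param pattern dynamics pattern for [simulate_dynamics()]
#' @param n_mutant_clones number of mutant clones at diagnosis (0 allowed:
#'   a patient with no detectable mutant clones on the panel)
#' @param cnv_events optional tibble of copy-number events planted in the
#'   largest mutant clone
#' @param post_hspc_depletion if TRUE (default for shrinkage), surviving
#'   mutant cells post-treatment shift away from the HSPC state
#' @return list with `clones` (list of [clone_spec()]), `variants`
#'   (tibble), `germline_ids`, `pattern`, `response`, `patient_id`
#' @export
patient_spec <- function(patient_id, response, pattern,
                         n_mutant_clones = sample(2:4, 1),
                         cnv_events = NULL,
                         post_hspc_depletion = (pattern == "shrinkage")) {
  genes <- names(PANEL_GENES)
  first_gene <- sample(c("TET2", genes), 1,
                       prob = c(0.4, rep(0.6 / length(genes), length(genes))))
  other_genes <- sample(setdiff(genes, first_gene), max(n_mutant_clones, 1))
  mk_variant <- function(gene, id) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    tibble::tibble(
      variant_id = id, chrom = paste0("chr", PANEL_GENES[[gene]]),
      pos = sample(1e6:2e6, 1), ref = ref,
      alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1), gene = gene,
      consequence = sample(NONSYN_CONSEQUENCES, 1, prob = c(.6, .15, .15, .1)),
      population_maf = 0, whitelisted = FALSE, is_germline = FALSE)
  }
  variants <- list()
  clones <- list()
  if (n_mutant_clones > 0) {
    clone_genes <- c(first_gene, other_genes[seq_len(n_mutant_clones - 1)])
    sig <- character(0)
    parents <- character(0)
    branched <- n_mutant_clones >= 3 && stats::runif(1) < 0.5
    for (i in seq_len(n_mutant_clones)) {
      vid <- sprintf("%s_v%d_%s", patient_id, i, clone_genes[i])
      variants[[i]] <- mk_variant(clone_genes[i], vid)
      cid <- sprintf("C%d", i)
      if (i == 1) {
        sig_i <- stats::setNames("HET", vid)
        parent <- "WT"
      } else if (branched && i == n_mutant_clones) {
        # branch off the first clone instead of extending the chain
        sig_i <- c(clones[[2]]$signature, stats::setNames("HET", vid))
        parent <- clones[[2]]$clone_id
      } else {
        sig_i <- c(clones[[i]]$signature, stats::setNames("HET", vid))
        parent <- clones[[i]]$clone_id
      }
      clones[[i + 1]] <- clone_spec(cid, sig_i, parent)
    }
  }
  clones[[1]] <- clone_spec("WT")
  # diagnosis proportions: WT keeps 25-50%, mutants split the rest
  wt_frac <- stats::runif(1, 0.25, 0.5)
  if (n_mutant_clones > 0) {
    w <- stats::rgamma(n_mutant_clones, 4)  # moderately even split
    mut_frac <- (1 - wt_frac) * w / sum(w)
    mut_frac <- pmax(mut_frac, 0.06)        # keep clones well above QC floors
    mut_frac <- (1 - wt_frac) * mut_frac / sum(mut_frac)
  } else {
    mut_frac <- numeric(0)
    wt_frac <- 1
  }
  props <- stats::setNames(c(wt_frac, mut_frac),
                           c("WT", vapply(clones[-1], `[[`, "", "clone_id")))
  dyn <- simulate_dynamics(pattern, props)
  new_variant <- NULL
  if ("new" %in% names(dyn$post_treatment)) {
    # the expanding clone carries a superset signature: one extra mutation
    ng <- sample(setdiff(genes, c(first_gene, other_genes)), 1)
    vid <- sprintf("%s_vnew_%s", patient_id, ng)
    new_variant <- mk_variant(ng, vid)
    biggest <- which.max(props[-1])
    base_clone <- clones[[biggest + 1]]
    clones <- c(clones, list(clone_spec(
      "Cnew", c(base_clone$signature, stats::setNames("HET", vid)),
      base_clone$clone_id)))
    names(dyn$post_treatment)[names(dyn$post_treatment) == "new"] <- "Cnew"
    dyn$diagnosis <- c(dyn$diagnosis, Cnew = 0)
  }
  for (i in seq_along(clones)) {
    cid <- clones[[i]]$clone_id
    clones[[i]]$proportions <- c(
      diagnosis = unname(dyn$diagnosis[cid]),
      post_treatment = unname(dyn$post_treatment[cid]))
    if (post_hspc_depletion && cid != "WT") {
      mix <- clones[[i]]$celltype_mix
      mix["HSPC"] <- mix["HSPC"] / 4
      clones[[i]]$post_celltype_mix <- mix / sum(mix)
    }
  }
  if (!is.null(cnv_events) && n_mutant_clones > 0) {
    biggest <- which.max(props[-1]) + 1
    clones[[biggest]]$cnv_events <- cnv_events
  }
  # five germline heterozygous SNPs (common population variants): two on
  # CNV-informative chromosomes (7, 8), the rest spread elsewhere
  germ_chr <- c("chr7", "chr8", "chr2", "chr4", "chr17")
  germ <- purrr::map_dfr(seq_along(germ_chr), function(i) {
    tibble::tibble(
      variant_id = sprintf("%s_germ%d", patient_id, i),
      chrom = germ_chr[i], pos = 1.5e6 + i, ref = "G", alt = "A",
      gene = sprintf("SNP%d", i), consequence = "synonymous",
      population_maf = 0.25, whitelisted = FALSE, is_germline = TRUE)
  })
  variants <- dplyr::bind_rows(c(variants, list(new_variant), list(germ)))
  list(patient_id = patient_id, response = response, pattern = pattern,
       clones = clones, variants = variants,
       germline_ids = germ$variant_id)
}

# beta parameters for alt-fraction draws centred on `m` with concentration k
raf <- function(n, m, k = 60) stats::rbeta(n, m * k, (1 - m) * k)

# simulate one sample (one timepoint of one patient); assumes the caller
# seeded the RNG
simulate_sample <- function(pspec, timepoint, sim, prefix) {
  clones <- pspec$clones
  variants <- pspec$variants
  nv <- nrow(variants)
  n <- sim$n_cells
  props <- vapply(clones, function(cl) unname(cl$proportions[[timepoint]]),
                  numeric(1))
  props[is.na(props)] <- 0
  ids <- vapply(clones, `[[`, "", "clone_id")
  clone_of <- sample(ids, n, replace = TRUE, prob = props)
  barcodes <- sprintf("%s_c%05d", prefix, seq_len(n))

  # true genotype: clone signature over somatic variants, HET at germline
  true_gt <- matrix("WT", n, nv, dimnames = list(barcodes, variants$variant_id))
  true_gt[, variants$is_germline] <- "HET"
  for (cl in clones) {
    if (!length(cl$signature)) next
    rows <- clone_of == cl$clone_id
    for (v in names(cl$signature)) true_gt[rows, v] <- cl$signature[[v]]
  }

  gt <- true_gt
  # symmetric allele dropout at heterozygous sites
  het <- which(gt == "HET")
  if (sim$ado_rate > 0 && length(het)) {
    drop <- het[stats::runif(length(het)) < sim$ado_rate]
    gt[drop] <- sample(c("WT", "HOM"), length(drop), replace = TRUE)
  }
  if (sim$genotype_error_rate > 0) {
    err <- which(stats::runif(n * nv) < sim$genotype_error_rate)
    gt[err] <- sample(c("WT", "HET", "HOM"), length(err), replace = TRUE)
  }
  if (sim$missing_rate > 0) {
    gt[stats::runif(n * nv) < sim$missing_rate] <- "MISSING"
  }

  depth <- matrix(stats::rnbinom(n * nv, mu = sim$depth_mean,
                                 size = sim$depth_size), n, nv)
  fail <- stats::runif(n * nv) < sim$depth_fail_rate
  depth[fail] <- stats::rpois(sum(fail), 5)
  quality <- matrix(stats::runif(n * nv, 31, 99), n, nv)
  qfail <- stats::runif(n * nv) >= sim$gq_pass_rate
  quality[qfail] <- stats::runif(sum(qfail), 0, 30)

  af <- matrix(NA_real_, n, nv)
  af[gt == "WT"] <- raf(sum(gt == "WT"), 0.02)
  af[gt == "HET"] <- raf(sum(gt == "HET"), 0.5)
  af[gt == "HOM"] <- raf(sum(gt == "HOM"), 0.98)

  # copy-number events shift the within-cell allele balance of germline
  # heterozygous variants on the affected region
  for (cl in clones) {
    if (is.null(cl$cnv_events)) next
    rows <- which(clone_of == cl$clone_id)
    for (j in seq_len(nrow(cl$cnv_events))) {
      ev <- cl$cnv_events[j, ]
      hit <- which(variants$is_germline & variants$chrom == ev$chrom &
                     variants$pos >= ev$start & variants$pos < ev$end)
      for (v in hit) {
        het_rows <- rows[gt[rows, v] == "HET"]
        if (!length(het_rows)) next
        centre <- if (ev$copies == 1) {
          sample(c(0.03, 0.97), 1)            # one allele lost
        } else {
          sample(c(1 / 3, 2 / 3), 1)          # one allele duplicated
        }
        af[het_rows, v] <- raf(length(het_rows), centre)
      }
    }
  }
  depth[gt == "MISSING"] <- NA
  quality[gt == "MISSING"] <- NA
  af[gt == "MISSING"] <- NA

  geno <- genotype_matrix(gt, depth, quality, af,
                          variants[, setdiff(names(variants), "is_germline")],
                          barcodes)

  # amplicon counts: NB depth scaled by cell library size and clone copy
  # number over the event region
  panel <- pspec$panel %||% default_panel()
  na <- nrow(panel)
  cn <- matrix(1, length(ids), na, dimnames = list(ids, panel$amplicon_id))
  for (ci in seq_along(clones)) {
    cl <- clones[[ci]]
    if (is.null(cl$cnv_events)) next
    for (j in seq_len(nrow(cl$cnv_events))) {
      ev <- cl$cnv_events[j, ]
      hit <- panel$chrom == ev$chrom & panel$start >= ev$start &
        panel$end <= ev$end
      cn[cl$clone_id, hit] <- ev$copies / 2
    }
  }
  lib <- stats::rlnorm(n, 0, sim$lib_sd)
  amp_mean <- pspec$amplicon_means %||%
    rep(sim$depth_mean, na)
  mu <- (lib %o% amp_mean) * cn[clone_of, , drop = FALSE]
  counts <- matrix(stats::rnbinom(n * na, mu = mu, size = sim$depth_size),
                   n, na)
  storage.mode(counts) <- "integer"
  amp <- amplicon_matrix(counts, panel, barcodes)

  # ADT: cell-type signal + shared flat isotype background
  antibodies <- pspec$antibodies %||% default_antibodies()
  adt_means <- pspec$adt_means %||% default_adt_means(antibodies)
  mix_of <- function(cl) {
    if (timepoint == "post_treatment" && !is.null(cl$post_celltype_mix)) {
      cl$post_celltype_mix
    } else cl$celltype_mix
  }
  type_of <- character(n)
  for (cl in clones) {
    rows <- which(clone_of == cl$clone_id)
    if (!length(rows)) next
    mix <- mix_of(cl)
    type_of[rows] <- sample(names(mix), length(rows), replace = TRUE,
                            prob = mix)
  }
  nab <- nrow(antibodies)
  mu_sig <- adt_means[type_of, , drop = FALSE]
  adt_counts <- matrix(stats::rnbinom(n * nab, mu = mu_sig,
                                      size = sim$adt_size), n, nab) +
    matrix(stats::rnbinom(n * nab, mu = sim$isotype_background, size = 10),
           n, nab)
  storage.mode(adt_counts) <- "integer"
  adt <- adt_matrix(adt_counts, antibodies, barcodes)

  truth_cells <- tibble::tibble(
    patient_id = pspec$patient_id, timepoint = timepoint,
    barcode = barcodes, clone_id = clone_of, cell_type = type_of,
    compartment = unname(COMPARTMENT_MAP[type_of]))

  list(sample = list(
         meta = tibble::tibble(patient_id = pspec$patient_id,
                               timepoint = timepoint,
                               response = pspec$response),
         genotype = geno, amplicon = amp, adt = adt),
       truth_cells = truth_cells)
}

#' Simulate both timepoints of one patient
#'
#' @param pspec a [patient_spec()] (optionally with elements `panel`,
#'   `antibodies`, `adt_means`, `amplicon_means` overriding the defaults)
#' @param sim a [sim_config()]
#' @param seed integer seed; both samples and all noise draws derive from it
#' @return list with `samples` (diagnosis, post_treatment) and `truth_cells`
#' @export
simulate_patient <- function(pspec, sim = sim_config(), seed = 1) {
  seeds <- child_seeds(seed, 2)
  dx <- with_seed(seeds[1],
                  simulate_sample(pspec, "diagnosis", sim,
                                  paste0(pspec$patient_id, "_dx")))
  px <- with_seed(seeds[2],
                  simulate_sample(pspec, "post_treatment", sim,
                                  paste0(pspec$patient_id, "_tx")))
  list(samples = list(dx$sample, px$sample),
       truth_cells = dplyr::bind_rows(dx$truth_cells, px$truth_cells))
}

#' Default study-scale cohort configuration
#'
#' Mirrors the study conditions: 14 patients with paired diagnosis /
#' post-treatment marrow samples; 8 responders, of whom 7 show mutant-clone
#' shrinkage and 1 carries no mutant clone detectable on the panel; 6
#' nonresponders, 5 with stable clonal architecture and 1 with expansion /
#' new-clone appearance. One stable nonresponder carries a monosomy-7 clone
#' and another a trisomy-8 clone.
#'
#' @param sim a [sim_config()]
#' @param seed integer seed controlling the random per-patient architecture
#' @param n_cells convenience override of `sim$n_cells`
#' @param panel,antibodies optional shared panel/antibody tables (defaults:
#'   [default_panel()], [default_antibodies()])
#' @return list of class `cohort_config` with `patients`, `sim`, `seed`
#' @export
cohort_config <- function(sim = sim_config(), seed = 20260920,
                          n_cells = NULL, panel = default_panel(),
                          antibodies = default_antibodies()) {
  if (!is.null(n_cells)) sim$n_cells <- n_cells
  plan <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:14),
    response = c(rep("responder", 8), rep("nonresponder", 6)),
    pattern = c(rep("shrinkage", 8), rep("stable", 5), "expansion"),
    n_clones = c(2, 3, 2, 4, 3, 2, 3, 0, 3, 2, 3, 2, 4, 2)
  )
  seeds <- child_seeds(seed, nrow(plan))
  adt_means <- default_adt_means(antibodies)
  patients <- purrr::map(seq_len(nrow(plan)), function(i) {
    with_seed(seeds[i], {
      cnv <- if (plan$patient_id[i] == "P09") {
        tibble::tibble(chrom = "chr7", start = 0, end = 3e6, copies = 1)
      } else if (plan$patient_id[i] == "P10") {
        tibble::tibble(chrom = "chr8", start = 0, end = 3e6, copies = 3)
      } else NULL
      ps <- patient_spec(plan$patient_id[i], plan$response[i],
                         plan$pattern[i], plan$n_clones[i], cnv_events = cnv)
      ps$panel <- panel
      ps$antibodies <- antibodies
      ps$adt_means <- adt_means
      ps
    })
  })
  structure(list(patients = patients, sim = sim, seed = seed),
            class = "cohort_config")
}

#' Simulate a full cohort with ground truth
#'
#' @param config a [cohort_config()]
#' @return list with `cohort` (a [assemble_cohort()] result) and `truth`
#'   (list: `cells`, `clones`, `patterns`, `cnv`, `germline`, `ado_rate`)
#' @export
simulate_cohort <- function(config) {
  seeds <- child_seeds(config$seed + 1L, length(config$patients))
  sims <- purrr::map2(config$patients, seeds,
                      ~ simulate_patient(.x, config$sim, .y))
  samples <- purrr::flatten(purrr::map(sims, "samples"))
  truth_cells <- purrr::map_dfr(sims, "truth_cells")
  truth_clones <- purrr::map_dfr(config$patients, function(ps) {
    purrr::map_dfr(ps$clones, function(cl) {
      tibble::tibble(patient_id = ps$patient_id, clone_id = cl$clone_id,
                     parent_id = cl$parent_id,
                     signature = signature_string(cl$signature),
                     n_mutations = length(cl$signature),
                     prop_diagnosis = unname(cl$proportions[["diagnosis"]]),
                     prop_post = unname(cl$proportions[["post_treatment"]]))
    })
  })
  cnv <- purrr::map_dfr(config$patients, function(ps) {
    purrr::map_dfr(ps$clones, function(cl) {
      if (is.null(cl$cnv_events)) return(NULL)
      dplyr::mutate(cl$cnv_events, patient_id = ps$patient_id,
                    clone_id = cl$clone_id)
    })
  })
  patterns <- purrr::map_dfr(config$patients, function(ps) {
    tibble::tibble(patient_id = ps$patient_id, response = ps$response,
                   pattern = ps$pattern)
  })
  germline <- purrr::map_dfr(config$patients, function(ps) {
    tibble::tibble(patient_id = ps$patient_id, variant_id = ps$germline_ids)
  })
  list(cohort = assemble_cohort(samples),
       truth = list(cells = truth_cells, clones = truth_clones,
                    patterns = patterns, cnv = cnv, germline = germline,
                    ado_rate = config$sim$ado_rate))
}
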
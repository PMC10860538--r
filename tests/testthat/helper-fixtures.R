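# Shared fixture builders. Everything is generated in code; no stored data
# beyond the synthetic panel/antibody CSVs under inst/extdata.

# tiny genotype matrix from a character gt grid; depth/quality/alt filled
# with passing values unless overridden
toy_gm <- function(gt, depth = NULL, quality = NULL, alt = NULL,
                   genes = NULL, consequence = "missense", maf = 0,
                   whitelisted = FALSE) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  v <- ncol(gt)
  if (is.null(depth)) depth <- matrix(50, n, v)
  if (is.null(quality)) quality <- matrix(90, n, v)
  if (is.null(alt)) {
    alt <- matrix(0.5, n, v)
    alt[gt == "WT"] <- 0.01
    alt[gt == "HOM"] <- 0.98
  }
  if (is.null(genes)) genes <- paste0("G", seq_len(v))
  variants <- tibble::tibble(
    variant_id = paste0("v", seq_len(v)), chrom = "chr1",
    pos = seq_len(v) * 100, ref = "A", alt = "T", gene = genes,
    consequence = rep_len(consequence, v),
    population_maf = rep_len(maf, v),
    whitelisted = rep_len(whitelisted, v))
  genotype_matrix(gt, depth, quality, alt, variants,
                  barcodes = paste0("cell", seq_len(n)))
}

# genotype matrix whose cells follow given clone signatures exactly
gm_from_signatures <- function(sig_list, n_cells_per) {
  all_v <- sort(unique(unlist(lapply(sig_list, names))))
  rows <- list()
  for (i in seq_along(sig_list)) {
    row <- stats::setNames(rep("WT", length(all_v)), all_v)
    sig <- sig_list[[i]]
    row[names(sig)] <- sig
    rows[[i]] <- matrix(rep(row, n_cells_per[i]), nrow = n_cells_per[i],
                        byrow = TRUE)
  }
  gt <- do.call(rbind, rows)
  colnames(gt) <- all_v
  gm <- toy_gm(gt)
  gm$variants$variant_id <- all_v
  colnames(gm$gt) <- colnames(gm$depth) <- colnames(gm$quality) <-
    colnames(gm$alt_fraction) <- all_v
  gm
}

# Dirichlet-multinomial cohort counts for composition tests: `conc` is the
# between-sample concentration (CV ~ 10% at the default)
dm_counts <- function(seed, n_per_group = 6, n_cells = 3000,
                      deplete_pop = NULL, fold = 3, conc = 100) {
  set.seed(seed)
  base <- c(10, 8, 6, 5, 4, 3, 2, 2)
  base <- base / sum(base)
  rdir <- function(alpha) {
    g <- stats::rgamma(length(alpha), alpha)
    g / sum(g)
  }
  mk <- function(n, p) {
    t(sapply(seq_len(n), function(i) {
      stats::rmultinom(1, n_cells, rdir(p * conc))[, 1]
    }))
  }
  p1 <- base
  if (!is.null(deplete_pop)) {
    p1[deplete_pop] <- p1[deplete_pop] / fold
    p1 <- p1 / sum(p1)
  }
  counts <- rbind(mk(n_per_group, base), mk(n_per_group, p1))
  colnames(counts) <- paste0("pop", seq_along(base))
  list(counts = counts,
       condition = rep(c("a", "b"), each = n_per_group))
}

# run the paired DNA lane (QC -> germline -> ADO -> clones -> dynamics)
# on one simulated patient; returns the pieces tests assert on
dna_lane <- function(pt) {
  q1 <- suppressMessages(qc_sample(pt$samples[[1]]$genotype))
  q2 <- suppressMessages(qc_sample(pt$samples[[2]]$genotype))
  germ <- select_germline_het(q1$calls_qc, q2$calls_qc)
  a1 <- ado_rate(q1$calls_qc, germ$variant_id)
  a2 <- ado_rate(q2$calls_qc, germ$variant_id)
  kept_union <- union(q1$genotype$variants$variant_id,
                      q2$genotype$variants$variant_id)
  sub <- function(q) {
    suppressMessages(filter_cells(gm_subset(
      q$calls_qc,
      variants = intersect(kept_union, q$calls_qc$variants$variant_id))))
  }
  c1 <- suppressMessages(flag_ado_clones(call_clones(sub(q1)), a1))
  c2 <- suppressMessages(flag_ado_clones(call_clones(sub(q2)), a2))
  list(qc = list(q1, q2), germ = germ, ado = list(a1, a2),
       clones = list(c1, c2),
       dynamics = suppressWarnings(classify_dynamics(c1, c2)))
}

tiny_panel <- function(n = 8) default_panel()[seq_len(n), ]

# exact enumeration oracles -------------------------------------------

# two-sided Fisher p by enumerating all tables with the observed margins
fisher_oracle <- function(tab) {
  r <- rowSums(tab)
  c1 <- colSums(tab)[1]
  amin <- max(0, c1 - r[2])
  amax <- min(r[1], c1)
  a_vals <- amin:amax
  probs <- stats::dhyper(a_vals, r[1], r[2], c1)
  p_obs <- stats::dhyper(tab[1, 1], r[1], r[2], c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact signed-rank p by enumerating all 2^n sign assignments
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(grid) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact rank-sum p by enumerating all group assignments
rank_sum_oracle <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(all_v), nx)
  w_all <- apply(combs, 2, function(i) sum(r[i]))
  mu <- nx * (length(all_v) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
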
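# ADT surface-protein lane: cell QC, CPM+1 / CLR normalization, isotype
# denoising, PCA + SNN graph clustering (Louvain), artifact-cluster
# removal, marker-rule annotation, and LISI mixing diagnostics.

#' Remove cells with out-of-range total ADT counts
#'
#' @param adt an [adt_matrix()]
#' @param min_total,max_total inclusive bounds on per-cell total counts
#'   (cells strictly below 200 or strictly above 100,000 are discarded)
#' @return a filtered [adt_matrix()]
#' @export
qc_adt_cells <- function(adt, min_total = 200, max_total = 100000) {
  totals <- rowSums(adt$counts)
  keep <- !(totals < min_total | totals > max_total)
  if (!any(keep)) rlang::abort("all cells removed by ADT QC")
  if (any(!keep)) {
    rlang::inform(sprintf("ADT QC: %d of %d cells removed",
                          sum(!keep), length(keep)))
  }
  adt_matrix(adt$counts[keep, , drop = FALSE], adt$antibodies,
             adt$barcodes[keep])
}

#' CPM + 1 / centered-log-ratio normalization of ADT counts
#'
#' Per cell: counts are scaled to counts-per-million over all antibody
#' columns (isotypes included; denoising comes later), a +1 pseudocount is
#' added, and the centered log ratio is taken:
#' `clr_i = ln x'_i - mean_j ln x'_j`. CLR values therefore sum to zero
#' within each cell.
#'
#' @param adt a QC-passed [adt_matrix()]
#' @return list of class `normalized_adt`: `clr` (cells x antibodies),
#'   `antibodies`, `barcodes`, `totals` (raw per-cell totals),
#'   `denoised` = FALSE
#' @export
normalize_clr <- function(adt) {
  totals <- rowSums(adt$counts)
  if (any(totals == 0)) rlang::abort("zero-total cell reached normalization")
  cpm <- adt$counts / totals * 1e6 + 1
  lg <- log(cpm)
  clr <- lg - rowMeans(lg)
  structure(list(clr = clr, antibodies = adt$antibodies,
                 barcodes = adt$barcodes, totals = totals,
                 denoised = FALSE),
            class = "normalized_adt")
}

#' Remove cell-to-cell background using isotype controls
#'
#' Isotype control antibodies bind nothing specific, so their CLR level
#' measures each cell's nonspecific background. That per-cell mean is
#' subtracted from every target antibody and the result floored at zero;
#' isotype columns are then dropped.
#'
#' @param nadt a [normalize_clr()] result
#' @return a `normalized_adt` with `denoised = TRUE` and target antibodies
#'   only
#' @export
denoise_isotypes <- function(nadt) {
  iso <- nadt$antibodies$is_isotype
  if (!any(iso)) rlang::abort("no isotype columns available for denoising")
  bg <- rowMeans(nadt$clr[, iso, drop = FALSE])
  clr <- pmax(nadt$clr[, !iso, drop = FALSE] - bg, 0)
  structure(list(clr = clr, antibodies = nadt$antibodies[!iso, ],
                 barcodes = nadt$barcodes, totals = nadt$totals,
                 denoised = TRUE),
            class = "normalized_adt")
}

#' @export
print.normalized_adt <- function(x, ...) {
  cat(sprintf("<normalized_adt> %d cells x %d antibodies%s\n",
              nrow(x$clr), ncol(x$clr),
              if (x$denoised) " (denoised)" else ""))
  invisible(x)
}

#' Cluster cells on the normalized protein matrix
#'
#' Linear dimensionality reduction (PCA) to `n_components`, exact
#' k-nearest-neighbor graph, shared-nearest-neighbor edge weighting, and
#' Louvain community detection, all deterministic given `seed`.
#'
#' @param nadt a denoised `normalized_adt`
#' @param n_components PCA dimensionality (15, capped at n antibodies - 1)
#' @param k neighbors for the SNN graph (20)
#' @param resolution Louvain resolution (0.8)
#' @param seed integer seed
#' @return list of class `adt_clusters`: `cluster` (factor per cell),
#'   `barcodes`, `embedding` (PCA scores), `k`, `resolution`
#' @export
cluster_cells <- function(nadt, n_components = 15, k = 20, resolution = 0.8,
                          seed = 1) {
  n <- nrow(nadt$clr)
  if (n <= k) rlang::abort(sprintf("need more than k=%d cells", k))
  n_components <- min(n_components, ncol(nadt$clr) - 1, n - 1)
  pca <- stats::prcomp(nadt$clr, rank. = n_components, center = TRUE,
                       scale. = FALSE)
  emb <- pca$x
  rownames(emb) <- nadt$barcodes
  graph <- Seurat::FindNeighbors(emb, k.param = k, nn.method = "rann",
                                 verbose = FALSE)
  clusters <- with_seed(seed,
    Seurat::FindClusters(graph$snn, resolution = resolution, algorithm = 1,
                         random.seed = seed, verbose = FALSE))
  structure(list(cluster = factor(clusters[[1]]), barcodes = nadt$barcodes,
                 embedding = emb, k = k, resolution = resolution),
            class = "adt_clusters")
}

#' Re-cluster the cells of one cluster at higher resolution
#'
#' @param clusters an [cluster_cells()] result
#' @param nadt the `normalized_adt` it was computed from
#' @param which cluster label to split
#' @param resolution sub-clustering resolution
#' @param k,seed as in [cluster_cells()]
#' @return an `adt_clusters` with the chosen cluster replaced by
#'   `<which>_0`, `<which>_1`, ...
#' @export
subcluster_cells <- function(clusters, nadt, which, resolution = 0.8,
                             k = 20, seed = 1) {
  idx <- clusters$cluster == which
  if (sum(idx) <= k) rlang::abort("cluster too small to subcluster")
  sub <- structure(list(clr = nadt$clr[idx, , drop = FALSE],
                        antibodies = nadt$antibodies,
                        barcodes = nadt$barcodes[idx],
                        totals = nadt$totals[idx], denoised = nadt$denoised),
                   class = "normalized_adt")
  subcl <- cluster_cells(sub, k = k, resolution = resolution, seed = seed)
  lab <- as.character(clusters$cluster)
  lab[idx] <- paste0(which, "_", as.character(subcl$cluster))
  clusters$cluster <- factor(lab)
  clusters
}

#' Drop clusters with a flat antibody profile
#'
#' Clusters whose mean CLR profile is near-constant across antibodies carry
#' no lineage signal and are treated as technical artifacts: their cells
#' are marked unassigned.
#'
#' @param nadt the `normalized_adt` used for clustering
#' @param clusters an `adt_clusters`
#' @param min_variance across-antibody variance floor on the cluster mean
#'   profile (0.05)
#' @return an `adt_clusters` whose dropped cells carry cluster level
#'   `"unassigned"`; dropped labels recorded in attribute
#'   `"artifact_clusters"`
#' @export
drop_artifact_clusters <- function(nadt, clusters, min_variance = 0.05) {
  labs <- levels(clusters$cluster)
  profile_var <- vapply(labs, function(l) {
    stats::var(colMeans(nadt$clr[clusters$cluster == l, , drop = FALSE]))
  }, numeric(1))
  drop <- labs[profile_var < min_variance]
  if (length(drop)) {
    rlang::inform(sprintf("artifact clusters dropped: %s",
                          paste(drop, collapse = ", ")))
    lab <- as.character(clusters$cluster)
    lab[lab %in% drop] <- "unassigned"
    clusters$cluster <- factor(lab)
  }
  attr(clusters, "artifact_clusters") <- drop
  clusters
}

#' Default marker rules for bone-marrow populations
#'
#' One row per population: required-high and required-low markers with
#' cutoffs on the standardized cluster mean profile (z-scores across
#' antibodies, which cancels the additive library-size shift that CLR
#' leaves in cluster means), plus the compartment each population rolls up
#' to. Rules are evaluated in order; the first match labels the cluster.
#'
#' @param high_cutoff,low_cutoff cutoffs in profile z-score units
#' @return tibble (`population`, `high`, `low`, `high_cutoff`,
#'   `low_cutoff`, `compartment`)
#' @export
default_marker_rules <- function(high_cutoff = 2.0, low_cutoff = 0.5) {
  tibble::tibble(
    population = c("rare_CD11c_CD49d_CD62P", "HSPC", "CMP", "Erythroid",
                   "Monocyte", "Granulocyte", "T", "NK", "B"),
    high = list(c("CD11c", "CD49d", "CD62P"), c("CD34"), c("CD34", "CD38"),
                c("CD71"), c("CD11b", "CD14"), c("CD11b", "CD16"),
                c("CD3"), c("CD56"), c("CD19")),
    low = list(c("CD3", "CD19", "CD34"), c("CD38"), character(0),
               c("CD34", "CD3"), character(0), c("CD14"),
               character(0), c("CD3"), character(0)),
    high_cutoff = high_cutoff, low_cutoff = low_cutoff,
    compartment = c("rare", "progenitors", "progenitors",
                    "immature_erythroid", "myeloid", "myeloid",
                    "T", "NK", "B"))
}

#' Annotate clusters with marker rules and roll up to compartments
#'
#' Each cluster is labeled by the first rule whose required-high markers
#' all exceed `high_cutoff` and required-low markers all fall below
#' `low_cutoff` on the standardized cluster-mean CLR profile (z-scores
#' across antibodies); unmatched clusters stay unassigned. Populations drawing more than `single_sample_max` of their
#' cells from one sample are flagged rare-single-sample and excluded from
#' the compartment rollup.
#'
#' @param nadt the denoised `normalized_adt`
#' @param clusters an `adt_clusters`
#' @param rules a marker-rule tibble (see [default_marker_rules()])
#' @param sample_of optional named character: sample id per barcode (for
#'   the single-sample rarity check)
#' @param single_sample_max fraction above which a population is considered
#'   sample-private (0.9)
#' @return list of class `cell_annotation`: `cells` (tibble `barcode`,
#'   `cluster`, `population`, `compartment`), `cluster_labels`,
#'   `rare_single_sample`
#' @export
annotate_cells <- function(nadt, clusters, rules = default_marker_rules(),
                           sample_of = NULL, single_sample_max = 0.9) {
  if (nrow(rules) == 0) rlang::abort("empty marker rule table")
  labs <- setdiff(levels(clusters$cluster), "unassigned")
  label_of <- stats::setNames(rep("unassigned", length(labs)), labs)
  for (l in labs) {
    prof <- colMeans(nadt$clr[clusters$cluster == l, , drop = FALSE])
    prof <- (prof - mean(prof)) / max(stats::sd(prof), 1e-9)
    for (r in seq_len(nrow(rules))) {
      hi <- rules$high[[r]]
      lo <- rules$low[[r]]
      if (all(hi %in% names(prof)) &&
          all(prof[hi] > rules$high_cutoff[r]) &&
          all(prof[lo] < rules$low_cutoff[r])) {
        label_of[l] <- rules$population[r]
        break
      }
    }
  }
  pop <- dplyr::if_else(as.character(clusters$cluster) == "unassigned",
                        "unassigned",
                        unname(label_of[as.character(clusters$cluster)]))
  comp_map <- stats::setNames(rules$compartment, rules$population)
  comp <- dplyr::if_else(pop == "unassigned", "unassigned",
                         unname(comp_map[pop]))
  rare_ss <- character(0)
  if (!is.null(sample_of)) {
    smp <- sample_of[clusters$barcodes]
    for (p in setdiff(unique(pop), "unassigned")) {
      tab <- table(smp[pop == p])
      if (max(tab) / sum(tab) > single_sample_max) rare_ss <- c(rare_ss, p)
    }
    if (length(rare_ss)) {
      rlang::inform(sprintf(
        "sample-private populations excluded from compartments: %s",
        paste(rare_ss, collapse = ", ")))
      comp[pop %in% rare_ss] <- "rare"
    }
  }
  structure(list(
    cells = tibble::tibble(barcode = clusters$barcodes,
                           cluster = as.character(clusters$cluster),
                           population = pop, compartment = comp),
    cluster_labels = label_of, rare_single_sample = rare_ss),
    class = "cell_annotation")
}

#' @export
print.cell_annotation <- function(x, ...) {
  tab <- sort(table(x$cells$population), decreasing = TRUE)
  cat(sprintf("<cell_annotation> %d cells, %d populations\n",
              nrow(x$cells), length(tab)))
  print(utils::head(tab, 10))
  invisible(x)
}

#' Local inverse Simpson index of label mixing
#'
#' For every cell, neighbors are weighted with a Gaussian kernel calibrated
#' so the neighborhood's Shannon perplexity matches `perplexity`; label
#' probabilities are the summed weights per label, and the score is the
#' inverse Simpson index `1 / sum(p_l^2)` — the effective number of labels
#' in the neighborhood. Near 1: separated; near the label count: well
#' mixed. Resolving `L` labels requires `perplexity` comfortably above `L`.
#'
#' @param embedding numeric matrix (cells x dimensions), e.g. PCA scores
#' @param labels per-cell labels (e.g. sample ids)
#' @param perplexity target effective neighborhood size (30)
#' @param n_neighbors neighbors searched (3 * perplexity)
#' @return list of class `lisi_result`: `lisi` per cell, `mean`, `median`,
#'   `n_labels`
#' @export
lisi <- function(embedding, labels, perplexity = 30,
                 n_neighbors = 3 * perplexity) {
  embedding <- as.matrix(embedding)
  labels <- as.factor(labels)
  n <- nrow(embedding)
  if (nlevels(labels) < 2) {
    return(structure(list(lisi = rep(1, n), mean = 1, median = 1,
                          n_labels = nlevels(labels)),
                     class = "lisi_result"))
  }
  k <- min(n_neighbors, n - 1)
  if (n < 3 * perplexity) {
    rlang::warn("fewer cells than 3x perplexity; LISI will be compressed")
  }
  nn <- RANN::nn2(embedding, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  d2 <- nn$nn.dists[, -1, drop = FALSE]^2
  lab_int <- as.integer(labels)
  target <- log(perplexity)
  vals <- vapply(seq_len(n), function(i) {
    w <- calibrate_gaussian(d2[i, ], target)
    p <- tapply(w, lab_int[idx[i, ]], sum)
    1 / sum((p / sum(p))^2)
  }, numeric(1))
  structure(list(lisi = vals, mean = mean(vals),
                 median = stats::median(vals), n_labels = nlevels(labels)),
            class = "lisi_result")
}

# binary-search the Gaussian bandwidth so Shannon entropy hits `target`
calibrate_gaussian <- function(d2, target, tol = 1e-5, iter = 50) {
  beta <- 1
  lo <- -Inf
  hi <- Inf
  for (it in seq_len(iter)) {
    w <- exp(-d2 * beta)
    s <- sum(w)
    if (s == 0) {
      h <- 0
    } else {
      p <- w / s
      h <- -sum(ifelse(p > 0, p * log(p), 0))
    }
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) {       # entropy too high: narrow the kernel
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
    }
  }
  w <- exp(-d2 * beta)
  if (sum(w) == 0) w[] <- 1
  w / sum(w)
}

#' @export
print.lisi_result <- function(x, ...) {
  cat(sprintf("<lisi_result> mean %.2f / median %.2f over %d labels\n",
              x$mean, x$median, x$n_labels))
  invisible(x)
}
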
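# Compositional abundance testing (Dirichlet-multinomial with automatic
# reference and FDR-thresholded credibility) and thin wrappers around the
# exact small-sample tests used throughout the result tables.

# negative log-likelihood of counts under DM(alpha); x: samples x K
dm_nll <- function(log_alpha, x) {
  alpha <- exp(log_alpha)
  a0 <- sum(alpha)
  n <- rowSums(x)
  -sum(lgamma(a0) - lgamma(a0 + n) +
         rowSums(lgamma(sweep(x, 2, alpha, "+")) -
                   matrix(lgamma(alpha), nrow(x), length(alpha),
                          byrow = TRUE)))
}

# gradient of dm_nll wrt log_alpha
dm_nll_grad <- function(log_alpha, x) {
  alpha <- exp(log_alpha)
  a0 <- sum(alpha)
  n <- rowSums(x)
  per_j <- colSums(digamma(sweep(x, 2, alpha, "+"))) -
    nrow(x) * digamma(alpha)
  common <- nrow(x) * digamma(a0) - sum(digamma(a0 + n))
  -(alpha * (common + per_j))
}

# ML fit of a Dirichlet-multinomial to a samples x K count matrix.
# log-alpha is box-bounded: in the near-multinomial regime the likelihood
# is flat in the total concentration and unbounded optimization overflows;
# at the bound the alpha ratios still track the sample proportions, which
# is all the effect scale uses.
dm_fit <- function(x) {
  p <- colSums(x) / sum(x)
  p <- pmax(p, 1e-8)
  start <- log(p * 20)  # moderate concentration start
  fit <- tryCatch(
    stats::optim(start, dm_nll, gr = dm_nll_grad, x = x,
                 method = "L-BFGS-B", lower = -12, upper = 8,
                 control = list(maxit = 200)),
    error = function(e) NULL)
  a <- if (is.null(fit)) rep(NA_real_, length(p)) else exp(fit$par)
  if (!all(is.finite(a))) a <- p * 50  # moment fallback
  a
}

# reference-ratio log effects between two DM fits
dm_effects <- function(x0, x1, ref_idx) {
  a0 <- dm_fit(x0)
  a1 <- dm_fit(x1)
  log(a1 / a1[ref_idx]) - log(a0 / a0[ref_idx])
}

#' Compositional abundance test across two conditions
#'
#' Cell-type counts are modeled as Dirichlet-multinomial draws per
#' condition; per-population condition effects are log-fold-changes on the
#' reference-ratio scale (the reference population, auto-selected as the
#' one with the lowest across-sample coefficient of variation of its
#' proportion, has effect 0 by construction). Inclusion probabilities come
#' from bootstrap effect stability: samples are resampled within condition,
#' the model refit, and a population's inclusion is the fraction of
#' replicates whose effect matches the point estimate's sign with magnitude
#' at least `min_effect` — the bootstrap probability of a biologically
#' meaningful effect in the estimated direction (the spike-and-slab role in
#' the Bayesian formulation this test mirrors). Populations are declared credible by expected-false-discovery
#' control: the largest prefix of populations, ordered by inclusion, whose
#' mean (1 - inclusion) stays at or below `fdr`.
#'
#' @param counts samples x populations count matrix or data frame (row
#'   names or a `sample_id` column identify samples)
#' @param condition factor/character of length n samples with two levels
#' @param fdr expected false-discovery threshold (0.1)
#' @param n_boot bootstrap replicates (500)
#' @param seed integer seed
#' @param reference optional population name to force as reference
#' @param min_effect smallest log-fold-change treated as a real effect
#'   (log(1.5): a 1.5-fold change on the reference-ratio scale)
#' @return object of class `composition_test`; see [tidy.composition_test()]
#' @export
composition_test <- function(counts, condition, fdr = 0.1, n_boot = 500,
                             seed = 1, reference = NULL,
                             min_effect = log(1.5)) {
  counts <- as.data.frame(counts)
  if ("sample_id" %in% names(counts)) {
    rownames(counts) <- counts$sample_id
    counts$sample_id <- NULL
  }
  x <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) rlang::abort("condition must have two levels")
  if (any(table(condition) < 3)) {
    rlang::abort(paste0("need at least 3 samples per condition; ",
                        "use fisher_exact/wilcoxon for smaller designs"))
  }
  if (any(rowSums(x) == 0)) rlang::abort("sample with zero total count")
  all_zero <- colSums(x) == 0
  if (any(all_zero)) {
    rlang::warn(sprintf("dropping all-zero populations: %s",
                        paste(colnames(x)[all_zero], collapse = ", ")))
    x <- x[, !all_zero, drop = FALSE]
  }
  props <- x / rowSums(x)
  cv <- apply(props, 2, function(p) stats::sd(p) / max(mean(p), 1e-12))
  ref_idx <- if (is.null(reference)) which.min(cv)
             else match(reference, colnames(x))
  if (is.na(ref_idx)) rlang::abort("reference population not found")
  lev <- levels(condition)
  i0 <- which(condition == lev[1])
  i1 <- which(condition == lev[2])
  effect <- dm_effects(x[i0, , drop = FALSE], x[i1, , drop = FALSE], ref_idx)

  seeds <- child_seeds(seed, n_boot)
  boot_eff <- matrix(0, n_boot, ncol(x))
  for (b in seq_len(n_boot)) {
    boot_eff[b, ] <- with_seed(seeds[b], {
      b0 <- sample(i0, length(i0), replace = TRUE)
      b1 <- sample(i1, length(i1), replace = TRUE)
      dm_effects(x[b0, , drop = FALSE], x[b1, , drop = FALSE], ref_idx)
    })
  }
  agree <- sweep(sign(boot_eff), 2, sign(effect), "==") &
    abs(boot_eff) >= min_effect
  inclusion <- colMeans(agree)
  inclusion[ref_idx] <- 0
  effect[ref_idx] <- 0

  ord <- order(inclusion, decreasing = TRUE)
  credible <- rep(FALSE, ncol(x))
  cum_fd <- cumsum(1 - inclusion[ord]) / seq_along(ord)
  m <- which(cum_fd <= fdr)
  if (length(m)) credible[ord[seq_len(max(m))]] <- TRUE
  credible[ref_idx] <- FALSE

  structure(list(
    result = tibble::tibble(
      population = colnames(x), effect = effect, inclusion = inclusion,
      credible = credible, is_reference = seq_len(ncol(x)) == ref_idx),
    reference = colnames(x)[ref_idx], fdr = fdr, n_boot = n_boot,
    min_effect = min_effect,
    condition_levels = lev, n_samples = nrow(x), seed = seed),
    class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf(
    "<composition_test> %s vs %s over %d samples; reference '%s' (FDR %.2f)\n",
    x$condition_levels[1], x$condition_levels[2], x$n_samples,
    x$reference, x$fdr))
  hits <- x$result[x$result$credible, ]
  if (nrow(hits) == 0) {
    cat("  no credible populations\n")
  } else {
    for (i in seq_len(nrow(hits))) {
      cat(sprintf("  %s: effect %+.2f (inclusion %.2f)\n",
                  hits$population[i], hits$effect[i], hits$inclusion[i]))
    }
  }
  invisible(x)
}

#' @rdname composition_test
#' @param x a `composition_test`
#' @param ... unused
#' @return `tidy()`: tibble with one row per population (`population`,
#'   `effect`, `inclusion`, `credible`, `is_reference`)
#' @method tidy composition_test
#' @export
tidy.composition_test <- function(x, ...) x$result

#' @rdname composition_test
#' @return `glance()`: one-row tibble summarising the fit
#' @method glance composition_test
#' @export
glance.composition_test <- function(x, ...) {
  tibble::tibble(reference = x$reference, fdr = x$fdr, n_boot = x$n_boot,
                 n_samples = x$n_samples,
                 n_populations = nrow(x$result),
                 n_credible = sum(x$result$credible))
}

#' Two-sided Fisher exact test
#'
#' Exact two-sided p-value for a 2x2 table by the minimum-likelihood
#' convention: the sum of hypergeometric probabilities of all tables with
#' the observed margins that are no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @return tibble with `p_value`, `odds_ratio`
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) rlang::abort("negative entries in contingency table")
  ft <- stats::fisher.test(table, alternative = "two.sided")
  tibble::tibble(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate))
}

#' Paired Wilcoxon signed-rank test (exact for small n)
#'
#' @param x,y paired numeric vectors (or `y` omitted for differences)
#' @return tibble with `p_value`, `statistic`, `n_nonzero`, `exact`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  if (!length(d)) rlang::abort("all paired differences are zero")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = !exact))
  tibble::tibble(p_value = wt$p.value, statistic = unname(wt$statistic),
                 n_nonzero = length(d), exact = exact)
}

#' Unpaired Wilcoxon rank-sum test (exact for small n)
#'
#' @param x,y numeric vectors for the two groups
#' @return tibble with `p_value`, `statistic`, `exact`
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) rlang::abort("both groups must be nonempty")
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  tibble::tibble(p_value = wt$p.value, statistic = unname(wt$statistic),
                 exact = exact)
}

#' Spearman rank correlation
#'
#' Midrank ties; exact permutation p for n <= 9 (untied), t-approximation
#' otherwise.
#'
#' @param x,y numeric vectors, length >= 3
#' @return tibble with `rho`, `p_value`
#' @export
spearman_cor <- function(x, y) {
  if (length(x) < 3) rlang::abort("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 9 && !any(duplicated(x)) &&
                      !any(duplicated(y))))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Bonferroni adjustment
#'
#' @param p vector of p-values
#' @param m number of comparisons (defaults to `length(p)`)
#' @return adjusted p-values, `min(1, m * p)`
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p outside [0, 1]")
  pmin(1, m * p)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
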
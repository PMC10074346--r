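## Meta-analysis and multiple-testing machinery for the genome-wide scan.

#' Sample-size weighted Z (Stouffer/METAL-style) meta-analysis
#'
#' Each stratum contributes a signed normal quantile
#' \eqn{Z_i = \Phi^{-1}(1 - p_i/2)\,\mathrm{sign}(effect_i)} weighted by
#' \eqn{\sqrt{n_i}}; the combined statistic is
#' \eqn{Z = \sum w_i Z_i / \sqrt{\sum w_i^2}} with two-sided p value.
#' A stratum with effect direction 0 (odds ratio exactly 1) contributes
#' \eqn{Z_i = 0}.
#'
#' @param p per-stratum two-sided p values in (0, 1].
#' @param direction per-stratum effect signs (-1, 0, 1), e.g.
#'   `sign(log(OR))`.
#' @param n per-stratum sample sizes.
#' @return list of class `meta_result`: `z`, `p`, `k_strata`, `direction`
#'   (a string of "+", "-", "?" per stratum).
#' @export
stouffer_meta <- function(p, direction, n) {
  if (length(p) == 0) stop("at least one stratum required")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p values must be in (0, 1]")
  if (length(direction) != length(p) || length(n) != length(p))
    stop("p/direction/n misaligned")
  z_i <- stats::qnorm(1 - p / 2) * sign(direction)
  w <- sqrt(n)
  z <- sum(w * z_i) / sqrt(sum(w^2))
  dir_str <- paste(ifelse(direction > 0, "+", ifelse(direction < 0, "-", "?")),
                   collapse = "")
  structure(list(z = z, p = min(max(2 * stats::pnorm(-abs(z)), 1e-300), 1),
                 k_strata = length(p), direction = dir_str),
            class = "meta_result")
}

#' Cross-analysis consistency filter
#'
#' A result is discarded when the joint analysis is highly significant
#' (p < `joint_cut`) but either meta-analysis fails to support it
#' (p > `meta_cut`). Missing meta p values are treated as consistent.
#'
#' @param joint_p,meta_eth_p,meta_pipe_p p values of the joint analysis and
#'   of the trans-ethnic / trans-pipeline meta-analyses.
#' @param joint_cut,meta_cut rule thresholds (defaults 0.001 and 0.05).
#' @return logical: TRUE if the result is kept.
#' @export
consistency_filter <- function(joint_p, meta_eth_p, meta_pipe_p,
                               joint_cut = 0.001, meta_cut = 0.05) {
  meta_eth_p[is.na(meta_eth_p)] <- 0
  meta_pipe_p[is.na(meta_pipe_p)] <- 0
  !(joint_p < joint_cut & (meta_eth_p > meta_cut | meta_pipe_p > meta_cut))
}

#' Effective number of tests from the eigenvalue variance
#'
#' Computes the correlation matrix of per-gene statistics across the M
#' variant sets, and estimates the effective number of independent sets as
#' \eqn{M_{eff} = 1 + (M-1)\,(1 - \mathrm{Var}(\lambda)/M)} where
#' \eqn{\lambda} are the eigenvalues and the variance uses the sample
#' (M-1) denominator. The value is clipped to [1, M].
#'
#' @param stat_matrix genes x variant-sets matrix of (signed) statistics;
#'   rows with missing entries are dropped (`use = "complete"`) or retained
#'   via pairwise-complete correlations (`use = "pairwise"`).
#' @param use correlation strategy.
#' @return list: `meff` (effective sets), `m` (columns used), `eigenvalues`.
#' @export
eigen_meff <- function(stat_matrix, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  stat_matrix <- as.matrix(stat_matrix)
  keep <- apply(stat_matrix, 2, function(col) sum(!is.na(col)) >= 2)
  stat_matrix <- stat_matrix[, keep, drop = FALSE]
  if (ncol(stat_matrix) < 2) stop("need at least 2 columns with statistics")
  cr <- if (use == "complete")
    stats::cor(stat_matrix[stats::complete.cases(stat_matrix), , drop = FALSE])
  else stats::cor(stat_matrix, use = "pairwise.complete.obs")
  if (anyNA(cr)) stop("correlation matrix has missing entries ",
                      "(constant or empty columns)")
  m <- ncol(cr)
  ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
  meff <- 1 + (m - 1) * (1 - stats::var(ev) / m)
  list(meff = min(max(meff, 1), m), m = m, eigenvalues = ev)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_genes number of genes analyzed with at least one variant set.
#' @param meff_sets effective number of variant sets per gene.
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test threshold `alpha / (n_genes * meff_sets)`.
#' @export
bonferroni_threshold <- function(n_genes, meff_sets, alpha = 0.05) {
  if (n_genes < 1 || meff_sets < 1) stop("n_genes and meff_sets must be >= 1")
  alpha / (n_genes * meff_sets)
}
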
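## Common-variant QC, LD pruning, and principal components for
## stratification covariates. Thresholds follow common practice for
## case-control PCA: MAF > 1%, call rate > 99%, HWE p > 1e-5, greedy
## sliding-window pruning at r^2 <= 0.4.

#' QC threshold bundle
#'
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param callrate_min minimum call rate (exclusive).
#' @param hwe_p_min minimum Hardy-Weinberg p value (exclusive).
#' @param r2_max maximum pairwise r^2 retained after pruning.
#' @param window,step pruning window size and advance, in variants.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(maf_min = 0.01, callrate_min = 0.99,
                          hwe_p_min = 1e-5, r2_max = 0.4,
                          window = 50L, step = 5L) {
  stopifnot(maf_min >= 0, maf_min < 0.5, callrate_min >= 0, callrate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, r2_max > 0, window >= step,
            step >= 1)
  list(maf_min = maf_min, callrate_min = callrate_min, hwe_p_min = hwe_p_min,
       r2_max = r2_max, window = as.integer(window), step = as.integer(step))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' 1-df chi-square test of the observed genotype counts against the
#' expectation at the estimated allele frequency. Monomorphic sites return
#' p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("no genotypes")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Common-variant QC filter
#'
#' Keeps diploid autosomal variants passing MAF, call-rate and HWE
#' thresholds simultaneously.
#'
#' @param G samples x variants dosage matrix (0/1/2, NA = missing).
#' @param thresholds see [qc_thresholds()].
#' @return integer indices of retained columns.
#' @export
qc_filter <- function(G, thresholds = qc_thresholds()) {
  G <- as.matrix(G)
  n <- nrow(G)
  callrate <- colMeans(!is.na(G))
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    if (length(g) == 0) return(0)
    hwe_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))
  which(maf > thresholds$maf_min & callrate > thresholds$callrate_min &
          hwe > thresholds$hwe_p_min)
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window` variants (ordered by position within
#' chromosome), while any retained pair has r^2 above `r2_max`, the member
#' with the lower MAF is dropped (ties: the later position). The window then
#' advances by `step` variants.
#'
#' @param G samples x variants dosage matrix.
#' @param thresholds see [qc_thresholds()].
#' @return integer indices of retained columns.
#' @export
ld_prune <- function(G, thresholds = qc_thresholds()) {
  G <- as.matrix(G)
  m <- ncol(G)
  if (m <= 1) return(seq_len(m))
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  dropped <- rep(FALSE, m)
  start <- 1L
  repeat {
    end <- min(start + thresholds$window - 1L, m)
    idx <- setdiff(seq(start, end), which(dropped))
    if (length(idx) > 1) {
      r2 <- suppressWarnings(
        stats::cor(G[, idx, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      repeat {
        mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (r2[mx[1], mx[2]] <= thresholds$r2_max) break
        pair <- idx[c(mx[1], mx[2])]
        drop_v <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                  else if (maf[pair[2]] < maf[pair[1]]) pair[2]
                  else max(pair)
        dropped[drop_v] <- TRUE
        k <- which(idx == drop_v)
        r2[k, ] <- 0; r2[, k] <- 0
      }
    }
    if (end >= m) break
    start <- start + thresholds$step
  }
  which(!dropped)
}

#' Principal components of a genotype matrix
#'
#' Columns are mean-centered and scaled by \eqn{\sqrt{2p(1-p)}}; missing
#' entries are mean-imputed. Scores are the top-k left singular vectors
#' scaled by their singular values, with the sign of each component fixed so
#' that its largest-magnitude variant loading is positive.
#'
#' @param G samples x variants dosage matrix (post QC/pruning).
#' @param k number of components.
#' @return samples x k matrix of PC coordinates (columns PC1..PCk).
#' @export
compute_pcs <- function(G, k = 5L) {
  G <- as.matrix(G)
  if (k < 1) stop("k must be >= 1")
  if (nrow(G) < k + 1) stop("need at least k+1 samples")
  if (ncol(G) < k) stop("need at least k variants")
  p <- colMeans(G, na.rm = TRUE) / 2
  sc <- sqrt(2 * p * (1 - p))
  sc[sc == 0] <- 1
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sc, "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = k)
  if (sum(sv$d > 1e-8) < k) stop("k exceeds the rank of the matrix")
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] * flip, nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(G)
  scores
}

#' QC + prune + PCA in one step
#'
#' @inheritParams compute_pcs
#' @param thresholds see [qc_thresholds()].
#' @return list: `pcs` (samples x k), `retained` (variant indices used).
#' @export
pca_pipeline <- function(G, k = 5L, thresholds = qc_thresholds()) {
  keep <- qc_filter(G, thresholds)
  if (length(keep) < k) stop("fewer than k variants pass QC")
  pruned <- keep[ld_prune(G[, keep, drop = FALSE], thresholds)]
  list(pcs = compute_pcs(G[, pruned, drop = FALSE], k), retained = pruned)
}
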
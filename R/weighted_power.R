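## Frequency-weighted common+rare burden score and Monte-Carlo power
## estimation for the 2x2 conditional-Firth burden test.

#' Madsen-Browning frequency weight
#'
#' \eqn{w = 1/\sqrt{q(1-q)}}: rarer alleles get larger weights, so rare and
#' common variants can contribute to one gene score on comparable scales.
#'
#' @param af allele frequency in (0, 1).
#' @return weight(s).
#' @export
frequency_weight <- function(af) {
  if (any(af <= 0 | af >= 1)) stop("allele frequency must be in (0, 1)")
  1 / sqrt(af * (1 - af))
}

#' Control-estimated allele frequency with an add-one pseudocount
#'
#' @param G samples x variants dosage matrix.
#' @param status binary case indicator (controls = 0).
#' @param ploidy per-sample x variant ploidy matrix (or vector).
#' @return per-variant allele frequency `(ac + 1) / (an + 2)`, always
#'   inside (0, 1).
#' @export
control_af <- function(G, status, ploidy = 2L) {
  G <- as.matrix(G)
  ctrl <- status == 0
  Gc <- G[ctrl, , drop = FALSE]
  P <- if (is.matrix(ploidy)) ploidy[ctrl, , drop = FALSE]
       else matrix(rep_len(ploidy, nrow(Gc) * ncol(Gc)), nrow(Gc))
  miss <- is.na(Gc)
  Gc[miss] <- 0; P[miss] <- 0
  (colSums(Gc) + 1) / (colSums(P) + 2)
}

#' Frequency-weighted burden test (common + rare variants)
#'
#' The per-sample score is the weighted sum of minor-allele dosages,
#' \eqn{\sum_j w_j d_{ij}} with Madsen-Browning weights from
#' control-estimated allele frequencies (unit weights reduce the score to a
#' plain allele count). The score is tested with the same conditional-Firth
#' LRT machinery as the collapsed scores.
#'
#' @param G samples x variants dosage matrix for the gene (no AF ceiling
#'   beyond the caller's class rule).
#' @param status binary case indicator.
#' @param covariates optional covariate matrix.
#' @param weights per-variant weights; default Madsen-Browning from
#'   control allele frequencies.
#' @param ploidy per-sample x variant ploidy (for the control AF).
#' @param ... passed to [burden_test()] (e.g. `ci = FALSE`).
#' @return an `assoc_result`; OR is per unit of the weighted score.
#' @export
weighted_burden_test <- function(G, status, covariates = NULL,
                                 weights = NULL, ploidy = 2L, ...) {
  G <- as.matrix(G)
  if (ncol(G) < 1) stop("need at least one qualifying variant")
  if (is.null(weights))
    weights <- frequency_weight(control_af(G, status, ploidy))
  D <- G; D[is.na(D)] <- 0
  score <- drop(D %*% weights)
  if (stats::var(score) == 0) {
    return(burden_test(numeric(length(status)), as.numeric(status),
                       covariates, model = "weighted", ...))
  }
  burden_test(score, as.numeric(status), covariates, model = "weighted", ...)
}

## Fast 2x2 conditional-Firth LRT on carrier counts.
burden_p_2x2 <- function(case_carriers, n_case, ctrl_carriers, n_ctrl,
                         firth_threshold = 0.05, min_carriers = 3L) {
  if (case_carriers + ctrl_carriers < min_carriers) return(NA_real_)
  y <- c(1, 1, 0, 0); x <- c(1, 0, 1, 0)
  w <- c(case_carriers, n_case - case_carriers,
         ctrl_carriers, n_ctrl - ctrl_carriers)
  keep <- w > 0
  if (length(unique(x[keep])) < 2 || length(unique(y[keep])) < 2)
    return(1)
  X <- cbind(1, score = x)
  ml_full <- tryCatch(fit_ml(y, X, weights = w), error = function(e) NULL)
  ml_null <- fit_ml(y, X[, 1, drop = FALSE], weights = w)
  p_ml <- if (!is.null(ml_full) && ml_full$converged)
    lrt(ml_full, ml_null) else NA_real_
  if (!is.na(p_ml) && p_ml >= firth_threshold) return(p_ml)
  fi_full <- fit_firth(y, X, weights = w)
  fi_null <- fit_firth(y, X, weights = w, fixed = c(score = 0))
  lrt(fi_full, fi_null)
}

#' Monte-Carlo power of the case-control burden design
#'
#' Per replicate, control carriers are drawn Binomial(`n_ctrl`, PD) and
#' case carriers Binomial(`n_case`, PD·RR / (PD·RR + 1 − PD)) — the
#' carrier probability among cases implied by a carrier relative risk RR
#' when controls approximate the general infected population. Each 2x2
#' table is tested with the conditional-Firth LRT and power is the
#' fraction of replicates with p < `alpha`.
#'
#' @param pd population carrier frequency, in (0, 1).
#' @param rr carrier relative risk of critical disease, > 0.
#' @param n_case,n_ctrl group sizes.
#' @param alpha significance threshold (default the exome-wide 2.5e-6).
#' @param reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list: `power`, `ci_low`, `ci_high` (exact binomial 95% CI),
#'   `reps`, `alpha`.
#' @export
power_sim <- function(pd, rr, n_case, n_ctrl, alpha = 2.5e-6, reps = 1000L,
                      seed = 1L) {
  stopifnot(pd > 0, pd < 1, rr > 0, n_case >= 1, n_ctrl >= 1,
            alpha > 0, alpha < 1, reps >= 1)
  p_case <- pd * rr / (pd * rr + 1 - pd)
  if (n_case * p_case < 1 && n_ctrl * pd < 1)
    warning("expected carrier count below 1 in both groups")
  hits <- with_stream(seed, "power_sim", {
    a <- stats::rbinom(reps, n_case, p_case)
    b <- stats::rbinom(reps, n_ctrl, pd)
    vapply(seq_len(reps), function(i) {
      p <- burden_p_2x2(a[i], n_case, b[i], n_ctrl)
      !is.na(p) && p < alpha
    }, logical(1))
  })
  ci <- stats::binom.test(sum(hits), reps)$conf.int
  list(power = mean(hits), ci_low = ci[1], ci_high = ci[2],
       reps = reps, alpha = alpha)
}
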
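## Maximum-likelihood and Firth-penalized logistic regression.
##
## Both fitters accept frequency weights so that aggregated data (e.g. a
## 2x2 carrier-by-status table expanded to four rows) give exactly the same
## estimates as the fully expanded sample; this is what makes the
## Monte-Carlo power simulation cheap.

logit_mu <- function(eta) {
  ## numerically safe inverse logit
  p <- 1 / (1 + exp(-eta))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

loglik_binom <- function(y, p, w) sum(w * (y * log(p) + (1 - y) * log(1 - p)))

#' Maximum-likelihood logistic regression
#'
#' Newton-Raphson with step-halving. Used as the first-pass fitter of the
#' burden test; separation is reported through `converged = FALSE` rather
#' than an error, so callers can fall back to the Firth fit.
#'
#' @param y binary outcome vector (0/1).
#' @param X design matrix including an intercept column.
#' @param weights optional frequency weights (replicate counts); default 1.
#' @param tol convergence tolerance on the max absolute score component.
#' @param maxit maximum Newton iterations.
#' @param maxhalf maximum step-halvings per iteration.
#' @return A list of class `rv_fit`: `coef`, `loglik`, `converged`,
#'   `iterations`, `vcov` (inverse observed information), `penalized = FALSE`,
#'   and `diverging` naming a coefficient that appears to diverge (separation)
#'   or `NA`.
#' @export
fit_ml <- function(y, X, weights = NULL, tol = 1e-8, maxit = 50L,
                   maxhalf = 25L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  check_logistic_inputs(y, X, weights)

  beta <- numeric(ncol(X))
  eta <- drop(X %*% beta)
  p <- logit_mu(eta)
  ll <- loglik_binom(y, p, weights)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    U <- drop(crossprod(X, weights * (y - p)))
    if (max(abs(U)) <= tol) { converged <- TRUE; iter <- iter - 1L; break }
    if (iter > maxit) break
    W <- weights * p * (1 - p)
    I <- crossprod(X, W * X)
    step <- tryCatch(solve(I, U), error = function(e) NULL)
    if (is.null(step)) break
    new_ll <- -Inf
    half <- 0L
    while (half <= maxhalf) {
      cand <- beta + step
      eta_c <- drop(X %*% cand)
      p_c <- logit_mu(eta_c)
      new_ll <- loglik_binom(y, p_c, weights)
      if (new_ll >= ll - 1e-12) break
      step <- step / 2
      half <- half + 1L
    }
    beta <- beta + step
    eta <- drop(X %*% beta)
    p <- logit_mu(eta)
    ll <- loglik_binom(y, p, weights)
  }
  W <- weights * p * (1 - p)
  I <- crossprod(X, W * X)
  vc <- tryCatch(solve(I), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  diverging <- NA_character_
  ## under separation the likelihood is monotone in some coefficient; the
  ## score only vanishes because fitted probabilities saturate, so a huge
  ## coefficient (|log-odds| > 20) marks the fit as diverging
  if (converged && max(abs(beta)) > 20) converged <- FALSE
  if (!converged) {
    j <- which.max(abs(beta))
    diverging <- colnames(X)[j] %||% paste0("beta", j)
  }
  structure(list(coef = stats::setNames(beta, colnames(X)), loglik = ll,
                 converged = converged, iterations = iter, vcov = vc,
                 penalized = FALSE, diverging = diverging),
            class = "rv_fit")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

check_logistic_inputs <- function(y, X, weights) {
  if (any(!y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (any(weights < 0)) stop("weights must be nonnegative")
  wy <- sum(weights * y); wn <- sum(weights * (1 - y))
  if (wy == 0 || wn == 0) stop("outcome is all-one or all-zero")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  invisible(TRUE)
}

## Penalized log-likelihood: ll + 0.5 * log det X'WX (Jeffreys prior).
penalized_loglik <- function(y, X, beta, weights) {
  eta <- drop(X %*% beta)
  p <- logit_mu(eta)
  W <- weights * p * (1 - p)
  I <- crossprod(X, W * X)
  ld <- determinant(I, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  loglik_binom(y, p, weights) + 0.5 * as.numeric(ld$modulus)
}

#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell(\beta) + \tfrac12 \log\det I(\beta)} by modified-score Newton
#' iterations with hat-value adjustment and step-halving. Estimates are
#' finite under complete separation; in the covariate-free two-group case
#' the slope equals the log cross-product ratio of the 2x2 table with 0.5
#' added to every cell.
#'
#' @inheritParams fit_ml
#' @param fixed optional named numeric vector fixing some coefficients at
#'   given values (used by the profile-likelihood CI); the penalty is still
#'   computed from the full-model information.
#' @return A list of class `rv_fit` with `penalized = TRUE`; `loglik` is the
#'   penalized log-likelihood.
#' @export
fit_firth <- function(y, X, weights = NULL, tol = 1e-8, maxit = 50L,
                      maxhalf = 25L, fixed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(!y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")

  m <- ncol(X)
  free <- seq_len(m)
  beta <- numeric(m)
  if (!is.null(fixed)) {
    idx <- match(names(fixed), colnames(X))
    if (anyNA(idx)) stop("fixed coefficients must name design columns")
    beta[idx] <- fixed
    free <- setdiff(free, idx)
    if (length(free) == 0) {
      pl <- penalized_loglik(y, X, beta, weights)
      return(structure(list(coef = stats::setNames(beta, colnames(X)),
                            loglik = pl, converged = TRUE, iterations = 0L,
                            vcov = NULL, penalized = TRUE,
                            diverging = NA_character_), class = "rv_fit"))
    }
  }

  pl <- penalized_loglik(y, X, beta, weights)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- logit_mu(eta)
    W <- weights * p * (1 - p)
    I <- crossprod(X, W * X)
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) break
    ## h_i = w_i p_i q_i x_i' I^{-1} x_i (leverage of the augmented fit)
    h <- W * rowSums((X %*% Iinv) * X)
    Ustar <- drop(crossprod(X, weights * (y - p) + h * (0.5 - p)))[free]
    if (max(abs(Ustar)) <= tol) { converged <- TRUE; iter <- iter - 1L; break }
    if (iter > maxit) break
    Iff <- I[free, free, drop = FALSE]
    step <- tryCatch(solve(Iff, Ustar), error = function(e) NULL)
    if (is.null(step)) break
    ## monotone ascent: only accept improving steps; when even the smallest
    ## halved step cannot improve the penalized likelihood the current
    ## point is the optimum to machine precision
    half <- 0L
    improved <- FALSE
    repeat {
      cand <- beta
      cand[free] <- beta[free] + step
      pl_new <- penalized_loglik(y, X, cand, weights)
      if (pl_new > pl + 1e-13) { improved <- TRUE; break }
      if (half >= maxhalf) break
      step <- step / 2
      half <- half + 1L
    }
    if (!improved) { converged <- TRUE; break }
    beta[free] <- beta[free] + step
    pl <- pl_new
  }
  eta <- drop(X %*% beta)
  p <- logit_mu(eta)
  W <- weights * p * (1 - p)
  I <- crossprod(X, W * X)
  vc <- tryCatch(solve(I), error = function(e) matrix(NA_real_, m, m))
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coef = stats::setNames(beta, colnames(X)), loglik = pl,
                 converged = converged, iterations = iter, vcov = vc,
                 penalized = TRUE, diverging = NA_character_),
            class = "rv_fit")
}

#' Likelihood-ratio test between nested fits
#'
#' Both fits must be of the same likelihood flavor (plain with plain,
#' penalized with penalized). The statistic is clipped at zero; a negative
#' statistic beyond a small numerical slack signals convergence failure and
#' is an error.
#'
#' @param full,null `rv_fit` objects, `null` nested in `full`.
#' @param df degrees of freedom of the test.
#' @return two-sided p value in (0, 1], clamped below at 1e-300.
#' @export
lrt <- function(full, null, df = 1L) {
  if (!identical(full$penalized, null$penalized))
    stop("LRT requires both fits under the same likelihood flavor")
  stat <- 2 * (full$loglik - null$loglik)
  if (stat < -1e-8) stop("negative LRT statistic: convergence failure")
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  min(max(p, 1e-300), 1)
}

#' Profile-penalized-likelihood confidence interval for one coefficient
#'
#' Endpoints are the values of the target coefficient at which the profile
#' of the penalized log-likelihood drops by half the chi-square(1) quantile
#' from its maximum. Finite even with zero cells. If bracketing fails the
#' Wald interval from the Firth fit is returned with `wald = TRUE`.
#'
#' @inheritParams fit_ml
#' @param target column name or index of the coefficient of interest.
#' @param level confidence level; `level = 0` gives a degenerate interval at
#'   the estimate.
#' @return list with `low`, `high` (log-odds scale), `estimate`, `wald` flag.
#' @export
profile_ci_firth <- function(y, X, target, level = 0.95, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.numeric(target)) target <- colnames(X)[target]
  fit <- fit_firth(y, X, weights = weights)
  est <- fit$coef[[target]]
  if (level <= 0) return(list(low = est, high = est, estimate = est, wald = FALSE))
  drop_pl <- stats::qchisq(level, df = 1) / 2
  plmax <- fit$loglik

  pl_at <- function(b) {
    f <- fit_firth(y, X, weights = weights,
                   fixed = stats::setNames(b, target))
    f$loglik
  }
  find_endpoint <- function(dir) {
    se <- sqrt(fit$vcov[target, target])
    if (!is.finite(se) || se <= 0) se <- 1
    step <- se
    b0 <- est
    for (k in 1:40) {
      b1 <- est + dir * step
      if (pl_at(b1) < plmax - drop_pl) {
        r <- stats::uniroot(function(b) pl_at(b) - (plmax - drop_pl),
                            lower = min(b0, b1), upper = max(b0, b1),
                            tol = 1e-6)
        return(r$root)
      }
      b0 <- b1
      step <- step * 1.6
    }
    NA_real_
  }
  lo <- find_endpoint(-1)
  hi <- find_endpoint(1)
  if (is.na(lo) || is.na(hi)) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(fit$vcov[target, target])
    return(list(low = est - z * se, high = est + z * se, estimate = est,
                wald = TRUE))
  }
  list(low = lo, high = hi, estimate = est, wald = FALSE)
}

#' Conditional-Firth burden test
#'
#' Association test between a per-gene genetic score and case/control status,
#' adjusted for covariates. An ML likelihood-ratio test is computed first;
#' if its p value falls below `firth_threshold` (or the ML fit fails to
#' converge, e.g. under separation), the model is refitted under the Firth
#' penalty and the penalized LRT (score coefficient fixed at zero within
#' the full model, so the penalty cancels), Firth odds ratio and
#' profile-penalized-likelihood CI are reported instead.
#'
#' @param score per-sample genetic score (0/1/2 collapsed score, or a
#'   real-valued weighted score).
#' @param status binary case indicator (1 = case).
#' @param covariates optional numeric matrix/data.frame (sex, age, PCs),
#'   aligned to `score`.
#' @param weights optional frequency weights.
#' @param firth_threshold ML p value below which the Firth refit is used.
#' @param min_carriers minimum carriers (score > 0) for the test to run.
#' @param ci compute the confidence interval (profile-penalized under Firth,
#'   Wald under ML); disable for bulk calibration runs where only p values
#'   are needed.
#' @param gene,model,spec_id labels carried into the result.
#' @return list of class `assoc_result`: carrier counts, `or`, `ci_low`,
#'   `ci_high`, `p`, `method` ("ML-LRT" or "Firth-LRT"), `beta`,
#'   `skipped`, `reason`.
#' @export
burden_test <- function(score, status, covariates = NULL, weights = NULL,
                        firth_threshold = 0.05, min_carriers = 3L,
                        ci = TRUE, gene = NA_character_,
                        model = NA_character_, spec_id = NA) {
  status <- as.numeric(status)
  if (length(score) != length(status)) stop("score/status misaligned")
  aggregate_ok <- is.null(weights) && is.null(covariates)
  if (is.null(weights)) weights <- rep(1, length(score))
  counts <- carrier_counts(score, status, weights = weights)
  skip <- function(reason) {
    structure(c(list(gene = gene, model = model, spec_id = spec_id),
                counts,
                list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p = NA_real_, beta = NA_real_, method = NA_character_,
                     skipped = TRUE, reason = reason)),
              class = "assoc_result")
  }
  n_carriers <- sum(weights[score > 0])
  if (n_carriers < min_carriers) return(skip("fewer than 3 carriers"))
  if (stats::var(score) == 0) return(skip("zero-variance score"))
  if (length(unique(status)) < 2) return(skip("single outcome class"))

  ## with no covariates the likelihood only depends on the (score, status)
  ## cell counts: aggregate to frequency weights for speed (identical fit)
  us <- unique(score)
  if (aggregate_ok && length(us) <= 8) {
    cell <- match(score, us) * 2L + status
    idx <- which(!duplicated(cell))
    weights <- tabulate(cell, nbins = max(cell))[cell[idx]]
    score <- score[idx]
    status <- status[idx]
  }
  Xn <- cbind(`(Intercept)` = rep(1, length(score)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(score)) stop("covariates misaligned")
    Xn <- cbind(Xn, covariates)
  }
  Xf <- cbind(Xn[, 1, drop = FALSE], score = score)
  if (ncol(Xn) > 1) Xf <- cbind(Xf, Xn[, -1, drop = FALSE])

  ml_full <- tryCatch(fit_ml(status, Xf, weights = weights),
                      error = function(e) NULL)
  ml_null <- tryCatch(fit_ml(status, Xn, weights = weights),
                      error = function(e) NULL)
  if (is.null(ml_full) || is.null(ml_null)) return(skip("ML fit failed"))
  p_ml <- if (ml_full$converged && ml_null$converged)
    lrt(ml_full, ml_null, df = 1L) else NA_real_

  use_firth <- is.na(p_ml) || p_ml < firth_threshold
  if (use_firth) {
    fi_full <- fit_firth(status, Xf, weights = weights)
    ## penalized LRT: the null fixes the score coefficient at 0 inside the
    ## full model, so the Jeffreys penalty cancels correctly (logistf-style
    ## penalized profile-likelihood test)
    fi_null <- fit_firth(status, Xf, weights = weights,
                         fixed = c(score = 0))
    p <- lrt(fi_full, fi_null, df = 1L)
    beta <- fi_full$coef[["score"]]
    bounds <- if (ci) profile_ci_firth(status, Xf, "score", weights = weights)
              else list(low = NA_real_, high = NA_real_)
    res <- list(or = exp(beta), ci_low = exp(bounds$low),
                ci_high = exp(bounds$high), p = p, beta = beta,
                method = "Firth-LRT")
  } else {
    beta <- ml_full$coef[["score"]]
    se <- sqrt(ml_full$vcov["score", "score"])
    z <- stats::qnorm(0.975)
    res <- list(or = exp(beta),
                ci_low = if (ci) exp(beta - z * se) else NA_real_,
                ci_high = if (ci) exp(beta + z * se) else NA_real_,
                p = p_ml, beta = beta, method = "ML-LRT")
  }
  structure(c(list(gene = gene, model = model, spec_id = spec_id), counts,
              res, list(skipped = FALSE, reason = NA_character_)),
            class = "assoc_result")
}

#' Genomic inflation factor
#'
#' Median chi-square(1) statistic implied by the p values divided by the
#' null median 0.4549.
#'
#' @param p vector of p values in (0, 1]; NAs dropped.
#' @return lambda_GC.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p values")
  if (any(p <= 0 | p > 1)) stop("p values must be in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
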
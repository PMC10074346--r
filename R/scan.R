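## Genome-wide burden scan: joint analysis with global PCs, trans-ethnic
## and trans-pipeline sample-size-weighted meta-analyses with
## stratum-specific PCs, consistency filtering, per-model genomic inflation
## and the eigenvalue-based effective number of tests.

drop_constant_cols <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  X[, keep, drop = FALSE]
}

scan_covariates <- function(samples, pcs) {
  X <- cbind(male = as.numeric(samples$sex == "M"), age = samples$age)
  if (!is.null(pcs)) X <- cbind(X, pcs)
  X
}

stratum_pcs <- function(G_common, rows, k) {
  if (length(rows) <= k + 1) return(NULL)
  tryCatch(pca_pipeline(G_common[rows, , drop = FALSE], k = k)$pcs,
           error = function(e) NULL)
}

#' Run the genome-wide gene-based burden scan
#'
#' For every gene x variant set x genetic model with at least
#' `min_carriers` carriers, runs the joint conditional-Firth burden test on
#' all samples (adjusted for sex, age and the top global PCs), then
#' re-tests within each ancestry stratum and each pipeline stratum using
#' stratum-specific PCs and combines the strata with the sample-size
#' weighted Z meta-analysis. Results failing the consistency rule
#' (joint p < 0.001 but either meta p > 0.05) are flagged `kept = FALSE`.
#'
#' @param cohort a `cohort`.
#' @param specs variant-set specifications (default the nine sets).
#' @param models genetic models to scan.
#' @param npcs number of principal components (global and per stratum).
#' @param min_carriers minimum carriers for a test to run.
#' @param meta_ethnic,meta_pipeline run the corresponding meta-analyses.
#' @param ci compute confidence intervals (disable for large calibration
#'   scans; profile-penalized CIs dominate runtime).
#' @param meff_use correlation strategy for the effective number of tests.
#' @return list of class `scan_summary`: `results` (one row per tested
#'   gene x model x spec), `skipped` (untestable combinations), `summary`
#'   (per model: genes analyzed, Meff for the sets, total effective tests,
#'   Bonferroni threshold, genomic lambda).
#' @export
run_scan <- function(cohort, specs = enumerate_specs(),
                     models = c("codominant", "heterozygous", "recessive"),
                     npcs = 5L, min_carriers = 3L,
                     meta_ethnic = TRUE, meta_pipeline = TRUE,
                     ci = TRUE, meff_use = "complete") {
  validate_cohort(cohort)
  samples <- cohort$samples
  status <- as.numeric(samples$status == "case")
  n <- nrow(samples)

  ## PCA on common autosomal variants (rare ones fail the MAF filter)
  auto <- cohort$variants$chrom != "X"
  G_auto <- cohort$genotypes[, auto, drop = FALSE]
  pcs <- tryCatch(pca_pipeline(G_auto, k = npcs)$pcs, error = function(e) NULL)
  covars <- drop_constant_cols(scan_covariates(samples, pcs))

  strata_of <- function(field, enabled) {
    if (!enabled) return(list())
    lv <- unique(samples[[field]])
    if (length(lv) < 2) return(list())
    out <- lapply(lv, function(s) {
      rows <- which(samples[[field]] == s)
      spcs <- stratum_pcs(G_auto, rows, npcs)
      list(rows = rows,
           covars = drop_constant_cols(scan_covariates(samples[rows, ], spcs)))
    })
    stats::setNames(out, lv)
  }
  eth <- strata_of("ancestry", meta_ethnic)
  pipe <- strata_of("pipeline", meta_pipeline)

  rare <- cohort$variants[cohort$variants$vclass != "other", , drop = FALSE]
  msc <- stats::setNames(cohort$msc$msc, cohort$msc$gene)
  sets <- build_gene_sets(rare, specs, msc)

  results <- list()
  skipped <- list()
  score_cache <- new.env(parent = emptyenv())
  test_cache <- new.env(parent = emptyenv())
  for (gene in names(sets)) {
    for (si in seq_len(nrow(specs))) {
      sid <- as.character(specs$spec_id[si])
      ids <- sets[[gene]][[sid]]
      if (length(ids) == 0) next
      ckey <- paste(ids, collapse = ";")
      scores <- if (!is.null(score_cache[[ckey]])) score_cache[[ckey]] else {
        P <- ploidy_matrix(cohort, ids)
        Gg <- cohort$genotypes[, ids, drop = FALSE]
        sc <- lapply(models, function(mod) gene_score(Gg, P, model = mod))
        score_cache[[ckey]] <- stats::setNames(sc, models)
        score_cache[[ckey]]
      }
      for (mod in models) {
        score <- scores[[mod]]
        if (!testable(score, min_carriers)) {
          skipped[[length(skipped) + 1]] <- data.frame(
            gene = gene, model = mod, spec_id = specs$spec_id[si],
            reason = "fewer than 3 carriers", stringsAsFactors = FALSE)
          next
        }
        tkey <- paste(mod, ckey)
        if (!is.null(test_cache[[tkey]])) {
          row <- test_cache[[tkey]]
          row$spec_id <- specs$spec_id[si]
          results[[length(results) + 1]] <- row
          next
        }
        joint <- burden_test(score, status, covars,
                             min_carriers = min_carriers, ci = ci,
                             gene = gene, model = mod,
                             spec_id = specs$spec_id[si])
        meta_one <- function(strata) {
          ps <- c(); dirs <- c(); ns <- c()
          for (st in strata) {
            sc_s <- score[st$rows]; y_s <- status[st$rows]
            if (!testable(sc_s, min_carriers) ||
                length(unique(y_s)) < 2) next
            r <- burden_test(sc_s, y_s, st$covars,
                             min_carriers = min_carriers, ci = FALSE)
            if (r$skipped || is.na(r$p)) next
            ps <- c(ps, r$p); dirs <- c(dirs, sign(r$beta))
            ns <- c(ns, length(st$rows))
          }
          if (length(ps) == 0) return(list(p = NA_real_, z = NA_real_,
                                           k = 0L))
          m <- stouffer_meta(ps, dirs, ns)
          list(p = m$p, z = m$z, k = m$k_strata)
        }
        me <- if (length(eth)) meta_one(eth) else
          list(p = joint$p, z = NA_real_, k = 1L)
        mp <- if (length(pipe)) meta_one(pipe) else
          list(p = joint$p, z = NA_real_, k = 1L)
        row <- data.frame(
          gene = gene, model = mod, spec_id = specs$spec_id[si],
          case_mono = joint$case_mono, case_bi = joint$case_bi,
          ctrl_mono = joint$ctrl_mono, ctrl_bi = joint$ctrl_bi,
          or = joint$or, ci_low = joint$ci_low, ci_high = joint$ci_high,
          p = joint$p, beta = joint$beta, method = joint$method,
          meta_eth_p = me$p, meta_eth_k = me$k,
          meta_pipe_p = mp$p, meta_pipe_k = mp$k,
          stringsAsFactors = FALSE)
        test_cache[[tkey]] <- row
        results[[length(results) + 1]] <- row
      }
    }
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame(gene = character(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(0))
  if (nrow(results)) {
    results$kept <- consistency_filter(results$p, results$meta_eth_p,
                                       results$meta_pipe_p)
    results <- results[order(results$p, -results$or, results$gene), ]
    rownames(results) <- NULL
  }

  summary <- do.call(rbind, lapply(models, function(mod) {
    rs <- results[results$model == mod, , drop = FALSE]
    if (nrow(rs) == 0)
      return(data.frame(model = mod, n_genes = 0L, meff_sets = NA_real_,
                        meff_total = NA_real_, threshold = NA_real_,
                        lambda = NA_real_, stringsAsFactors = FALSE))
    n_genes <- length(unique(rs$gene))
    zmat <- matrix(NA_real_, nrow = n_genes, ncol = nrow(specs),
                   dimnames = list(unique(rs$gene),
                                   as.character(specs$spec_id)))
    z <- sign(rs$beta) * stats::qnorm(1 - rs$p / 2)
    zmat[cbind(match(rs$gene, rownames(zmat)),
               match(as.character(rs$spec_id), colnames(zmat)))] <- z
    meff <- tryCatch(eigen_meff(zmat, use = meff_use)$meff,
                     error = function(e) NA_real_)
    data.frame(model = mod, n_genes = n_genes, meff_sets = meff,
               meff_total = n_genes * meff,
               threshold = if (is.na(meff)) NA_real_ else
                 bonferroni_threshold(n_genes, meff),
               lambda = genomic_lambda(rs$p), stringsAsFactors = FALSE)
  }))

  structure(list(results = results, skipped = skipped, summary = summary),
            class = "scan_summary")
}
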
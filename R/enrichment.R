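## Candidate gene-set burden analysis with a matched-gene resampling null,
## zygosity-differential odds-ratio testing, and reporting arithmetic.

#' Define a candidate gene-set burden analysis
#'
#' The default per-gene rule is pLOF variants at gnomAD AF < 1e-3.
#' Per-gene overrides support restricting a member to biochemically proven
#' LOF variants (`blof_only`) and adding branchpoint variants
#' (`include_bp`), mirroring candidate type-I-IFN set analyses where one
#' locus is screened at the bLOF level and intronic branchpoint variants
#' are counted as pLOF.
#'
#' @param genes member gene symbols.
#' @param af_max allele-frequency ceiling of the default rule.
#' @param class_rule "PLOF_ONLY" or "MISSLOF".
#' @param include_bp include branchpoint variants for all members.
#' @param overrides named list gene -> list(blof_only=, include_bp=).
#' @return list of class `gene_set_spec`.
#' @export
gene_set_spec <- function(genes, af_max = 1e-3, class_rule = "PLOF_ONLY",
                          include_bp = FALSE, overrides = list()) {
  if (length(genes) < 1) stop("a gene set needs at least one gene")
  bad <- setdiff(names(overrides), genes)
  if (length(bad)) stop("override for non-member gene(s): ",
                        paste(bad, collapse = ", "))
  structure(list(genes = unique(genes), af_max = af_max,
                 class_rule = class_rule, include_bp = include_bp,
                 overrides = overrides),
            class = "gene_set_spec")
}

set_variant_ids <- function(cohort, set_spec) {
  v <- cohort$variants
  missing <- setdiff(set_spec$genes, v$gene)
  if (length(missing)) stop("gene set member(s) absent from annotation: ",
                            paste(missing, collapse = ", "))
  msc <- stats::setNames(cohort$msc$msc, cohort$msc$gene)
  key <- variant_key(v)
  ids <- character(0)
  for (g in set_spec$genes) {
    ov <- set_spec$overrides[[g]]
    spec <- list(class_rule = set_spec$class_rule, af_max = set_spec$af_max,
                 cadd_rule = "NONE",
                 include_bp = isTRUE(set_spec$include_bp) ||
                   isTRUE(ov$include_bp))
    rows <- v$gene == g
    q <- qualifies(v[rows, , drop = FALSE], spec, msc)
    gid <- key[rows][q]
    if (isTRUE(ov$blof_only)) gid <- restrict_blof(gid, v)
    ids <- c(ids, gid)
  }
  unique(ids)
}

#' Burden test of a pooled candidate gene set
#'
#' Pools the qualifying variants of all member genes into one super-gene
#' score under the requested genetic model, then applies the
#' conditional-Firth burden test. Pooled carriers are counted once however
#' many member genes they hit.
#'
#' @param cohort a `cohort`.
#' @param set_spec a [gene_set_spec()].
#' @param model genetic model ("codominant", "heterozygous", "recessive").
#' @param covariates covariate matrix aligned to the cohort samples.
#' @return an `assoc_result` (skip record when the pooled set is empty).
#' @export
set_burden_test <- function(cohort, set_spec, model = "codominant",
                            covariates = NULL) {
  ids <- set_variant_ids(cohort, set_spec)
  if (length(ids) == 0) {
    return(burden_test(numeric(nrow(cohort$samples)),
                       as.numeric(cohort$samples$status == "case"),
                       covariates, gene = "set", model = model))
  }
  P <- ploidy_matrix(cohort, ids)
  score <- gene_score(cohort$genotypes[, ids, drop = FALSE], P, model = model)
  burden_test(score, as.numeric(cohort$samples$status == "case"),
              covariates, gene = "set", model = model)
}

#' Draw matched null gene sets
#'
#' For each replicate, every target gene is replaced by a distinct gene
#' drawn uniformly from the genes whose pLI is within `tol_pli` and CoNeS
#' within `tol_cones` of the target's, without replacement within the
#' replicate. Deterministic under `seed`.
#'
#' @param targets target gene symbols.
#' @param gene_features data.frame(gene, pli, cones) over the gene universe.
#' @param R number of replicates.
#' @param tol_pli,tol_cones matching tolerances (Inf = no matching).
#' @param seed RNG seed.
#' @return list of R character vectors.
#' @export
sample_matched_sets <- function(targets, gene_features, R = 1000L,
                                tol_pli = 0.1, tol_cones = 0.5, seed = 1L) {
  gf <- gene_features
  ti <- match(targets, gf$gene)
  if (anyNA(ti)) stop("target gene(s) absent from the feature table: ",
                      paste(targets[is.na(ti)], collapse = ", "))
  pools <- lapply(seq_along(targets), function(i) {
    ok <- abs(gf$pli - gf$pli[ti[i]]) <= tol_pli &
      abs(gf$cones - gf$cones[ti[i]]) <= tol_cones &
      !(gf$gene %in% targets)
    pool <- gf$gene[ok]
    if (length(pool) == 0)
      stop("target ", targets[i], " has an empty match pool (pool size 0)")
    pool
  })
  with_stream(seed, "matched_sets", {
    lapply(seq_len(R), function(r) {
      chosen <- character(0)
      for (i in seq_along(targets)) {
        avail <- setdiff(pools[[i]], chosen)
        if (length(avail) == 0)
          stop("match pool for ", targets[i],
               " exhausted within a replicate")
        chosen <- c(chosen, avail[sample.int(length(avail), 1L)])
      }
      chosen
    })
  })
}

#' Empirical p value with the add-one rule
#'
#' @param observed observed statistic (smaller = more extreme, e.g. a p
#'   value).
#' @param nulls statistics of the null replicates.
#' @return `(1 + #\{null <= observed\}) / (R + 1)`, never below `1/(R+1)`.
#' @export
empirical_p <- function(observed, nulls) {
  if (length(nulls) < 1) stop("need at least one null replicate")
  (1 + sum(nulls <= observed, na.rm = TRUE)) / (sum(!is.na(nulls)) + 1)
}

#' Matched-resampling enrichment analysis of a candidate gene set
#'
#' Tests the observed set, then repeats the identical burden test on R
#' matched random sets and reports the empirical p value of the observed
#' test p among the null p values.
#'
#' @inheritParams set_burden_test
#' @param R replicates.
#' @param tol_pli,tol_cones matching tolerances.
#' @param seed RNG seed.
#' @return list of class `enrichment_result`: `observed` (assoc_result),
#'   `empirical_p`, `R`, `null_p`.
#' @export
enrichment_test <- function(cohort, set_spec, model = "codominant",
                            covariates = NULL, R = 1000L, tol_pli = 0.1,
                            tol_cones = 0.5, seed = 1L) {
  obs <- set_burden_test(cohort, set_spec, model, covariates)
  if (obs$skipped) stop("observed gene set is untestable: ", obs$reason)
  null_sets <- sample_matched_sets(set_spec$genes, cohort$gene_features, R,
                                   tol_pli, tol_cones, seed)
  ## pooling a gene set is the element-wise max of the member genes' scores
  ## (a biallelic/monoallelic genotype anywhere in the union is one in some
  ## member), so per-gene scores are computed once and reused across
  ## replicates
  status <- as.numeric(cohort$samples$status == "case")
  msc <- stats::setNames(cohort$msc$msc, cohort$msc$gene)
  v <- cohort$variants
  key <- variant_key(v)
  base_spec <- list(class_rule = set_spec$class_rule,
                    af_max = set_spec$af_max, cadd_rule = "NONE",
                    include_bp = set_spec$include_bp)
  qual_ids <- key[qualifies(v, base_spec, msc)]
  need <- unique(unlist(null_sets))
  gene_scores <- new.env(parent = emptyenv())
  score_of <- function(g) {
    if (is.null(gene_scores[[g]])) {
      ids <- qual_ids[v$gene[match(qual_ids, key)] == g]
      gene_scores[[g]] <- if (length(ids) == 0)
        integer(length(status))
      else gene_score(cohort$genotypes[, ids, drop = FALSE],
                      ploidy_matrix(cohort, ids), model = model)
    }
    gene_scores[[g]]
  }
  null_p <- vapply(null_sets, function(gs) {
    pooled <- Reduce(pmax, lapply(gs, score_of))
    r <- burden_test(pooled, status, covariates, ci = FALSE)
    if (r$skipped) NA_real_ else r$p
  }, numeric(1))
  structure(list(observed = obs, empirical_p = empirical_p(obs$p, null_p),
                 R = R, null_p = null_p),
            class = "enrichment_result")
}

#' Zygosity-differential odds-ratio equality test
#'
#' Likelihood-ratio test (1 df) comparing a Firth model with separate
#' log-odds parameters for monoallelic and biallelic carriers against a
#' Firth model with a single any-carrier parameter; a small p value means
#' the biallelic and monoallelic odds ratios differ.
#'
#' @param het,bi 0/1 indicators of monoallelic and biallelic carriage.
#' @param status binary case indicator.
#' @param covariates optional covariate matrix.
#' @return p value.
#' @export
zygosity_equality_test <- function(het, bi, status, covariates = NULL) {
  if (sum(bi) < 1) stop("no biallelic carriers: test undefined")
  if (sum(het) < 1) stop("no monoallelic carriers: test undefined")
  if (all(het == bi)) stop("rank-deficient design: het and bi identical")
  ## parametrize as any-carrier effect + biallelic increment, so the null
  ## (equal odds ratios) is the increment fixed at zero within the full
  ## model and the Jeffreys penalty cancels in the LRT
  Xf <- cbind(`(Intercept)` = 1, carrier = as.numeric(het | bi),
              bi_extra = bi)
  if (!is.null(covariates)) Xf <- cbind(Xf, as.matrix(covariates))
  full <- fit_firth(as.numeric(status), Xf)
  null <- fit_firth(as.numeric(status), Xf, fixed = c(bi_extra = 0))
  lrt(full, null, df = 1L)
}

#' Carrier proportion as a printed percentage
#'
#' @param n_carriers carrier count.
#' @param denominator group size.
#' @return `100 * n / d` rounded half-up to one decimal.
#' @export
carrier_proportion <- function(n_carriers, denominator) {
  if (denominator < 1) stop("denominator must be >= 1")
  if (any(n_carriers < 0) || any(n_carriers > denominator))
    stop("carrier count outside [0, denominator]")
  floor(1000 * n_carriers / denominator + 0.5) / 10
}

#' Welch two-sample comparison of group means
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @return list: `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p` (two-sided Welch
#'   t-test).
#' @export
compare_group_means <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 values per group")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(mean_a = mean(values_a), sd_a = 0, mean_b = mean(values_b),
                  sd_b = 0, p = 1))
    stop("degenerate variance in both groups")
  }
  tt <- stats::t.test(values_a, values_b)
  list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b),
       p = tt$p.value)
}
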
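## Simulation configuration for synthetic stratified case-control cohorts.
##
## The generator emulates an international severe-infection case-control
## study design: multiple ancestry and processing-pipeline strata, cases
## older and more often male than controls, rare variants at
## reference-database-style frequencies across consequence classes,
## X-chromosome hemizygosity in males, and planted risk genes with
## heterozygous or biallelic effects. Disease is assigned in a large
## virtual population via a logistic model and cases/controls are then
## ascertained to quota.

## Labeled RNG streams: every stochastic component draws under a seed
## derived from (root seed, label), so adding a gene or component never
## perturbs the draws of another.
derive_seed <- function(root, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147481053
  as.integer((as.numeric(root) * 48271 + h) %% 2147481053)
}

with_stream <- function(root, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(root, label))
  expr
}

default_strata <- function() {
  ## ancestry x pipeline composition loosely following a large
  ## multi-ancestry cohort: mostly European, two processing pipelines
  data.frame(
    ancestry = c("EUR", "EUR", "MDE", "AMR", "SAS"),
    pipeline = c("central", "other", "central", "central", "other"),
    weight = c(0.40, 0.20, 0.15, 0.15, 0.10),
    stringsAsFactors = FALSE)
}

default_gene_freqs <- function(n_genes = 30L, x_genes = 2L) {
  ## per-gene per-class population carrier frequencies; a handful of genes
  ## live on X. Carrier frequencies are for monoallelic carriers except for
  ## planted recessive genes (see sim_config()).
  genes <- sprintf("G%03d", seq_len(n_genes))
  chrom <- as.character(rep_len(1:22, n_genes))
  if (x_genes > 0) chrom[seq_len(min(x_genes, n_genes))] <- "X"
  do.call(rbind, lapply(seq_len(n_genes), function(i) {
    data.frame(gene = genes[i], chrom = chrom[i],
               class = c("pLOF", "missense", "synonymous"),
               carrier_freq = c(2e-3, 8e-3, 8e-3),
               stringsAsFactors = FALSE)
  }))
}

#' Build a simulation configuration
#'
#' Defaults describe the stated study world: case/control totals at the
#' scale requested, case mean age 55.7 (SD 17.4) years with male:female
#' 2.4, control mean age 43.8 (SD 20.1) with male fraction 0.395, ~3%
#' prevalence of critical disease among the infected, and a multi-ancestry,
#' two-pipeline composition. Age and sex log-odds effects, when not given,
#' are derived from the per-status moments (Gaussian discriminant slope for
#' age; log odds-ratio of the male fractions for sex).
#'
#' @param n_cases,n_controls cohort quotas.
#' @param strata data.frame(ancestry, pipeline, weight); weights sum to 1.
#' @param gene_freqs data.frame(gene, chrom, class, carrier_freq):
#'   population carrier frequency per gene per variant class. For a gene
#'   planted with a recessive/x_recessive effect, the `pLOF` carrier
#'   frequency is interpreted as the frequency of *biallelic* (or male
#'   hemizygous) carriers.
#' @param planted data.frame(gene, model, beta): risk genes, their genetic
#'   model ("codominant", "recessive", "x_recessive") and log-odds per
#'   score unit.
#' @param baseline_logodds baseline disease log-odds; NA = calibrate so the
#'   virtual-population prevalence equals `prevalence`.
#' @param prevalence target prevalence of critical disease among infected
#'   (default 0.03).
#' @param beta_age,beta_male covariate log-odds effects; NA = derive from
#'   the per-status age/sex marginals.
#' @param age_case_mean,age_case_sd,age_ctrl_mean,age_ctrl_sd,male_frac_case,male_frac_ctrl
#'   per-status covariate marginals (years; fractions).
#' @param n_common_background number of common variants for PCA.
#' @param fst ancestry divergence parameter in [0, 1).
#' @param pop_multiplier virtual-population size as a multiple of
#'   `n_cases + n_controls` (default 20).
#' @param n_variants_per_class rare variants simulated per gene per class.
#' @param seed root seed; all component streams derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases, n_controls,
                       strata = default_strata(),
                       gene_freqs = default_gene_freqs(),
                       planted = NULL,
                       baseline_logodds = NA_real_,
                       prevalence = 0.03,
                       beta_age = NA_real_, beta_male = NA_real_,
                       age_case_mean = 55.7, age_case_sd = 17.4,
                       age_ctrl_mean = 43.8, age_ctrl_sd = 20.1,
                       male_frac_case = 2.4 / 3.4, male_frac_ctrl = 0.395,
                       n_common_background = 400L, fst = 0.05,
                       pop_multiplier = 20, n_variants_per_class = 2L,
                       seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, fst >= 0, fst < 1,
            prevalence > 0, prevalence < 1, pop_multiplier >= 1,
            n_common_background >= 0, n_variants_per_class >= 1)
  if (abs(sum(strata$weight) - 1) > 1e-8) stop("stratum weights must sum to 1")
  if (any(gene_freqs$carrier_freq < 0 | gene_freqs$carrier_freq > 1))
    stop("carrier frequencies must be in [0, 1]")
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("gene", "model", "beta") %in% names(planted)))
    bad <- setdiff(planted$gene, gene_freqs$gene)
    if (length(bad)) stop("planted gene(s) not in gene_freqs: ",
                          paste(bad, collapse = ", "))
    if (!all(planted$model %in% c("codominant", "recessive", "x_recessive")))
      stop("planted model must be codominant, recessive or x_recessive")
    for (i in seq_len(nrow(planted))) {
      g <- planted$gene[i]
      cf <- gene_freqs$carrier_freq[gene_freqs$gene == g &
                                      gene_freqs$class == "pLOF"]
      if (length(cf) == 0 || all(cf == 0))
        stop("planted gene ", g, " has zero pLOF carrier frequency: ",
             "its effect can never be observed")
      if (planted$model[i] == "x_recessive" &&
          !any(gene_freqs$chrom[gene_freqs$gene == g] == "X"))
        stop("planted gene ", g, " is x_recessive but not on chromosome X")
    }
  }
  if (is.na(beta_age)) {
    pooled_var <- (age_case_sd^2 + age_ctrl_sd^2) / 2
    beta_age <- (age_case_mean - age_ctrl_mean) / pooled_var
  }
  if (is.na(beta_male)) {
    beta_male <- log((male_frac_case / (1 - male_frac_case)) /
                       (male_frac_ctrl / (1 - male_frac_ctrl)))
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 strata = strata, gene_freqs = gene_freqs, planted = planted,
                 baseline_logodds = baseline_logodds, prevalence = prevalence,
                 beta_age = beta_age, beta_male = beta_male,
                 age_ctrl_mean = age_ctrl_mean, age_ctrl_sd = age_ctrl_sd,
                 n_common_background = as.integer(n_common_background),
                 fst = fst, pop_multiplier = pop_multiplier,
                 n_variants_per_class = as.integer(n_variants_per_class),
                 seed = as.integer(seed)),
            class = "sim_config")
}
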
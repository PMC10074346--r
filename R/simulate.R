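## Synthetic cohort simulation.

#' Simulate common-variant background genotypes
#'
#' Two-level allele-frequency divergence (Balding-Nichols) model: each
#' variant has an ancestral frequency Uniform(0.1, 0.9); each ancestry
#' stratum draws its own frequency from Beta with mean the ancestral value
#' and variance controlled by `fst`; genotypes are then Hardy-Weinberg
#' within the stratum. `fst = 0` collapses to identical frequencies in all
#' strata.
#'
#' @param config a [sim_config()].
#' @param ancestry optional per-sample ancestry labels; default: labels
#'   drawn from the configured stratum weights for
#'   `n_cases + n_controls` samples.
#' @return samples x variants dosage matrix (0/1/2).
#' @export
simulate_common_background <- function(config, ancestry = NULL) {
  m <- config$n_common_background
  if (m < 1) stop("n_common_background must be >= 1")
  if (is.null(ancestry)) {
    ancestry <- with_stream(config$seed, "common_strata", {
      idx <- sample.int(nrow(config$strata), config$n_cases + config$n_controls,
                        replace = TRUE, prob = config$strata$weight)
      config$strata$ancestry[idx]
    })
  }
  groups <- unique(config$strata$ancestry)
  if (!all(ancestry %in% groups)) groups <- unique(c(groups, ancestry))
  fst <- config$fst
  with_stream(config$seed, "common_background", {
    p_anc <- stats::runif(m, 0.1, 0.9)
    freq <- sapply(groups, function(g) {
      if (fst == 0) return(p_anc)
      stats::rbeta(m, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
    })
    freq <- matrix(freq, nrow = m, dimnames = list(NULL, groups))
    G <- matrix(0L, nrow = length(ancestry), ncol = m)
    for (g in unique(ancestry)) {
      rows <- which(ancestry == g)
      G[rows, ] <- matrix(stats::rbinom(length(rows) * m, 2L,
                                        rep(freq[, g], each = length(rows))),
                          nrow = length(rows))
    }
    attr(G, "freq") <- freq
    G
  })
}

## Build the rare-variant annotation table implied by a config.
## Per-variant allele frequencies split the configured carrier frequency:
## for monoallelic carrier frequencies c over k variants at Hardy-Weinberg,
## q = c / (2k) autosomal and q = c / k on X (male carriers); for planted
## (x_)recessive genes c is the biallelic-carrier frequency, so
## q = sqrt(c / k) autosomal and q = c / k on X.
build_variant_table <- function(config) {
  gf <- config$gene_freqs
  gf <- gf[gf$carrier_freq > 0, , drop = FALSE]
  k <- config$n_variants_per_class
  planted_rec <- character(0)
  if (!is.null(config$planted))
    planted_rec <- config$planted$gene[
      config$planted$model %in% c("recessive", "x_recessive")]
  genes <- unique(gf$gene)
  rows <- lapply(seq_len(nrow(gf)), function(i) {
    g <- gf$gene[i]; cls <- gf$class[i]; cf <- gf$carrier_freq[i]
    on_x <- gf$chrom[i] == "X"
    recessive_freq <- g %in% planted_rec && cls == "pLOF"
    q <- if (on_x) cf / k
         else if (recessive_freq) sqrt(cf / k)
         else cf / (2 * k)
    gi <- match(g, genes)
    base <- gi * 100000L + match(cls, VARIANT_CLASSES) * 1000L
    with_stream(config$seed, paste0("variants:", g, ":", cls), {
      cadd <- switch(cls,
                     pLOF = stats::runif(k, 28, 45),
                     missense = stats::runif(k, 0, 40),
                     inframe = stats::runif(k, 5, 35),
                     branchpoint = rep(NA_real_, k),
                     stats::runif(k, 0, 8))
      data.frame(chrom = gf$chrom[i], pos = base + seq_len(k),
                 ref = "A", alt = "T", gene = g, vclass = cls,
                 gnomad_af = pmin(q * stats::runif(k, 0.6, 1.4), 0.0099),
                 cadd = cadd,
                 blof = ifelse(cls == "pLOF",
                               sample(c("deleterious", "untested"), k,
                                      replace = TRUE, prob = c(0.6, 0.4)),
                               "untested"),
                 bp_flag = as.integer(cls == "branchpoint"),
                 allele_freq = q,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Simulate a stratified case-control cohort
#'
#' A virtual population of `pop_multiplier * (n_cases + n_controls)`
#' individuals is drawn: stratum membership, sex and age from the
#' population (control-like) distributions, rare genotypes per variant
#' under Hardy-Weinberg within the configured carrier frequencies (males
#' hemizygous on X), and common background genotypes under the divergence
#' model. Disease status is assigned by the logistic model
#' baseline + beta_age (age - mean) + beta_male male + sum of planted gene
#' effects, with the baseline calibrated to the configured prevalence when
#' not given; cases and controls are then sampled to quota without
#' replacement. Identical seeds give identical cohorts.
#'
#' @param config a [sim_config()].
#' @return list of class `cohort`: `samples`, `variants`, `genotypes`
#'   (samples x variants dosage, column names chrom:pos:ref:alt),
#'   `gene_features` (gene, pli, cones), `msc` (gene, msc).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- ceiling(config$pop_multiplier * (config$n_cases + config$n_controls))
  seed <- config$seed

  strat_idx <- with_stream(seed, "strata", {
    sample.int(nrow(config$strata), N, replace = TRUE,
               prob = config$strata$weight)
  })
  ancestry <- config$strata$ancestry[strat_idx]
  pipeline <- config$strata$pipeline[strat_idx]
  demo <- with_stream(seed, "demographics", {
    male_frac_pop <- 0.5  # population sex ratio; case excess comes from beta_male
    sex <- ifelse(stats::runif(N) < male_frac_pop, "M", "F")
    age <- round(pmax(stats::rnorm(N, config$age_ctrl_mean,
                                   config$age_ctrl_sd), 0.1), 1)
    list(sex = sex, age = age)
  })
  sex <- demo$sex; age <- demo$age

  variants <- build_variant_table(config)
  vkey <- variant_key(variants)
  G <- matrix(0L, nrow = N, ncol = nrow(variants),
              dimnames = list(NULL, vkey))
  male <- sex == "M"
  for (g in unique(variants$gene)) {
    cols <- which(variants$gene == g)
    G[, cols] <- with_stream(seed, paste0("geno:", g), {
      sub <- matrix(0L, N, length(cols))
      for (j in seq_along(cols)) {
        q <- variants$allele_freq[cols[j]]
        if (variants$chrom[cols[j]] == "X") {
          sub[male, j] <- stats::rbinom(sum(male), 1L, q)
          sub[!male, j] <- stats::rbinom(sum(!male), 2L, q)
        } else {
          sub[, j] <- stats::rbinom(N, 2L, q)
        }
      }
      sub
    })
  }

  ## genetic contribution of planted genes
  genetic <- numeric(N)
  if (!is.null(config$planted)) {
    for (i in seq_len(nrow(config$planted))) {
      g <- config$planted$gene[i]
      model <- config$planted$model[i]
      score_model <- if (model == "x_recessive") "recessive" else model
      cols <- which(variants$gene == g & variants$vclass == "pLOF")
      ploidy <- ifelse(variants$chrom[cols[1]] == "X" & male, 1L, 2L)
      sc <- gene_score(G[, cols, drop = FALSE], ploidy, model = score_model)
      genetic <- genetic + config$planted$beta[i] * sc
    }
  }

  eta0 <- config$beta_age * (age - config$age_ctrl_mean) +
    config$beta_male * (sex == "M") + genetic
  b0 <- config$baseline_logodds
  if (is.na(b0)) {
    f <- function(b) mean(stats::plogis(b + eta0)) - config$prevalence
    b0 <- stats::uniroot(f, c(-30, 30))$root
  }
  status_pop <- with_stream(seed, "status", {
    as.integer(stats::runif(N) < stats::plogis(b0 + eta0))
  })
  if (sum(status_pop) < config$n_cases)
    stop("case quota unreachable: virtual population produced ",
         sum(status_pop), " cases for a quota of ", config$n_cases,
         "; increase pop_multiplier or prevalence")
  if (sum(1 - status_pop) < config$n_controls)
    stop("control quota unreachable; increase pop_multiplier")
  picked <- with_stream(seed, "ascertainment", {
    c(sample(which(status_pop == 1), config$n_cases),
      sample(which(status_pop == 0), config$n_controls))
  })

  n <- length(picked)
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    status = c(rep("case", config$n_cases), rep("control", config$n_controls)),
    sex = sex[picked], age = age[picked],
    ancestry = ancestry[picked], pipeline = pipeline[picked],
    auto_ab = "neg", stringsAsFactors = FALSE)

  Gc <- G[picked, , drop = FALSE]
  if (config$n_common_background > 0) {
    Gcommon <- simulate_common_background(config, ancestry = ancestry)
    freq <- attr(Gcommon, "freq")
    Gcommon <- Gcommon[picked, , drop = FALSE]
    m <- ncol(Gcommon)
    common_variants <- data.frame(
      chrom = as.character(rep_len(1:22, m)),
      pos = 90000000L + seq_len(m), ref = "G", alt = "C",
      gene = sprintf("BG%04d", seq_len(m)), vclass = "other",
      gnomad_af = rowMeans(freq), cadd = NA_real_, blof = "untested",
      bp_flag = 0L, allele_freq = rowMeans(freq), stringsAsFactors = FALSE)
    colnames(Gcommon) <- variant_key(common_variants)
    variants <- rbind(variants, common_variants)
    Gc <- cbind(Gc, Gcommon)
  }
  rownames(Gc) <- samples$sample_id

  genes <- unique(variants$gene)
  feats <- with_stream(seed, "gene_features", {
    data.frame(gene = genes,
               pli = round(stats::rbeta(length(genes), 0.4, 0.4), 4),
               cones = round(stats::rnorm(length(genes), 0, 1), 4),
               stringsAsFactors = FALSE)
  })
  msc <- with_stream(seed, "msc", {
    data.frame(gene = genes,
               msc = round(stats::runif(length(genes), 3, 25), 3),
               stringsAsFactors = FALSE)
  })
  variants$allele_freq <- NULL

  cohort <- structure(list(samples = samples, variants = variants,
                           genotypes = Gc, gene_features = feats, msc = msc),
                      class = "cohort")
  validate_cohort(cohort)
  cohort
}

#' Validate a cohort object
#'
#' @param cohort a `cohort` list.
#' @return invisibly TRUE; errors on structural violations.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$samples
  if (anyDuplicated(s$sample_id)) stop("duplicate sample ids")
  if (!all(colnames(cohort$genotypes) == variant_key(cohort$variants)))
    stop("genotype columns do not match the variant table")
  if (!all(cohort$variants$gene %in% cohort$gene_features$gene))
    stop("variant gene absent from gene_features")
  if (!all(cohort$variants$gene %in% cohort$msc$gene))
    stop("variant gene absent from the MSC table")
  invisible(TRUE)
}

#' Per-sample ploidy for a set of variants
#'
#' Ploidy 1 for males at X-chromosome variants, 2 otherwise (the whole X is
#' treated as non-pseudoautosomal).
#'
#' @param cohort a `cohort`.
#' @param variant_ids variant keys (columns of the genotype matrix).
#' @return samples x variants integer matrix of ploidies.
#' @export
ploidy_matrix <- function(cohort, variant_ids) {
  chrom <- cohort$variants$chrom[match(variant_ids,
                                       variant_key(cohort$variants))]
  male <- cohort$samples$sex == "M"
  P <- matrix(2L, nrow = nrow(cohort$samples), ncol = length(variant_ids))
  P[male, chrom == "X"] <- 1L
  P
}
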
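## Collapsing qualifying genotypes into per-gene genetic scores.
##
## Genetic models:
##   codominant   : 2 if any biallelic qualifying genotype, 1 if any
##                  monoallelic, 0 otherwise
##   heterozygous : 1 iff at least one monoallelic genotype
##   recessive    : 1 iff at least one biallelic genotype
##   dominant     : 1 iff carrier of any qualifying variant
## Hemizygous males (ploidy 1 on X) are equivalent to homozygous females:
## a dosage of 1 at ploidy 1 is biallelic.

GENETIC_MODELS <- c("codominant", "heterozygous", "recessive", "dominant")

#' Zygosity of a genotype
#'
#' @param dosage alternate-allele dosage (0/1/2 at ploidy 2; 0/1 at ploidy 1).
#' @param ploidy 1 (male X) or 2; recycled against `dosage`.
#' @return character vector in \{"none", "monoallelic", "biallelic"\};
#'   hemizygous carriers (dosage 1, ploidy 1) are biallelic.
#' @export
zygosity <- function(dosage, ploidy) {
  n <- max(length(dosage), length(ploidy))
  dosage <- rep_len(dosage, n); ploidy <- rep_len(ploidy, n)
  if (!all(ploidy %in% c(1, 2))) stop("ploidy must be 1 or 2")
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= ploidy)
  if (!all(ok)) stop("dosage exceeds ploidy or is negative")
  out <- rep("none", n)
  out[!is.na(dosage) & dosage == 1 & ploidy == 2] <- "monoallelic"
  out[!is.na(dosage) & dosage > 0 & dosage == ploidy] <- "biallelic"
  out
}

#' Collapse a gene's qualifying genotypes into a genetic score
#'
#' Missing genotypes are scored as dosage 0 (no invented carriers).
#' Compound heterozygotes (two monoallelic variants in one gene) are not
#' treated as biallelic unless `compound_het = TRUE`, since phase is unknown.
#'
#' @param G samples x variants dosage matrix for the gene's qualifying
#'   variants (0 columns allowed).
#' @param ploidy per-sample ploidy vector, or a matrix conforming to `G`
#'   when variants mix chromosomes (pooled gene sets).
#' @param model one of `"codominant"`, `"heterozygous"`, `"recessive"`,
#'   `"dominant"`.
#' @param compound_het if TRUE, two or more monoallelic variants in the gene
#'   count as biallelic.
#' @return integer per-sample score (0/1/2 codominant; 0/1 otherwise).
#' @export
gene_score <- function(G, ploidy, model = "codominant", compound_het = FALSE) {
  model <- match.arg(model, GENETIC_MODELS)
  G <- as.matrix(G)
  n <- nrow(G)
  if (ncol(G) == 0) return(integer(n))
  if (is.matrix(ploidy)) {
    if (!all(dim(ploidy) == dim(G))) stop("ploidy matrix must conform to G")
    P <- ploidy
  } else {
    P <- matrix(rep(ploidy, ncol(G)), nrow = n)
  }
  D <- G
  D[is.na(D)] <- 0
  if (any(D > P)) stop("dosage exceeds ploidy")
  bi_m <- (D > 0) & (D == P)
  mono_m <- (D == 1) & (P == 2)
  has_bi <- rowSums(bi_m) > 0
  n_mono <- rowSums(mono_m)
  if (compound_het) has_bi <- has_bi | n_mono >= 2
  has_mono <- n_mono > 0
  switch(model,
         codominant = as.integer(ifelse(has_bi, 2L, ifelse(has_mono, 1L, 0L))),
         heterozygous = as.integer(has_mono),
         recessive = as.integer(has_bi),
         dominant = as.integer(has_mono | has_bi))
}

#' Carrier counts by status
#'
#' For a codominant score, monoallelic carriers have score 1 and biallelic
#' carriers score 2; binary-model scores report all carriers under `mono`
#' (heterozygous/dominant) or `bi` (handled by the caller). Real-valued
#' weighted scores are counted as carriers when positive.
#'
#' @param score per-sample genetic score.
#' @param status binary case indicator.
#' @param weights optional frequency weights.
#' @return list with `case_mono`, `case_bi`, `ctrl_mono`, `ctrl_bi`,
#'   `case_carriers`, `ctrl_carriers`, `n_case`, `n_ctrl`.
#' @export
carrier_counts <- function(score, status, weights = NULL) {
  if (length(score) != length(status)) stop("score/status misaligned")
  if (is.null(weights)) weights <- rep(1, length(score))
  cs <- status == 1
  list(case_mono = sum(weights[cs & score == 1]),
       case_bi = sum(weights[cs & score == 2]),
       ctrl_mono = sum(weights[!cs & score == 1]),
       ctrl_bi = sum(weights[!cs & score == 2]),
       case_carriers = sum(weights[cs & score > 0]),
       ctrl_carriers = sum(weights[!cs & score > 0]),
       n_case = sum(weights[cs]), n_ctrl = sum(weights[!cs]))
}

#' Minimum-carrier rule
#'
#' A burden test is only performed when at least `min_carriers` samples
#' carry a positive score across the whole cohort.
#'
#' @param score per-sample genetic score.
#' @param min_carriers threshold (default 3).
#' @return TRUE iff the gene/set is testable.
#' @export
testable <- function(score, min_carriers = 3L) {
  sum(score > 0) >= min_carriers
}
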
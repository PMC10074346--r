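## Qualifying-variant set definitions.
##
## Nine numbered sets are screened per gene: sets 1-3 are pLOF-only at
## gnomAD AF < 1%, 0.1%, 0.01%; sets 4-6 add missense/in-frame variants with
## CADD >= the gene's mutation significance cut-off (MSC); sets 7-9 are the
## same class union without the CADD rule. The CADD/MSC rule is applied to
## missense and in-frame variants only; pLOF variants are exempt.

VARIANT_CLASSES <- c("pLOF", "missense", "inframe", "branchpoint",
                     "synonymous", "other")

#' Enumerate the nine qualifying-variant set specifications
#'
#' @return data.frame with columns `spec_id` (1-9), `class_rule`
#'   ("PLOF_ONLY"/"MISSLOF"), `af_max`, `cadd_rule` ("GE_MSC"/"NONE"),
#'   `include_bp` (all FALSE).
#' @export
enumerate_specs <- function() {
  af <- c(1e-2, 1e-3, 1e-4)
  data.frame(
    spec_id = 1:9,
    class_rule = rep(c("PLOF_ONLY", "MISSLOF", "MISSLOF"), each = 3),
    af_max = rep(af, times = 3),
    cadd_rule = rep(c("NONE", "GE_MSC", "NONE"), each = 3),
    include_bp = FALSE,
    stringsAsFactors = FALSE)
}

#' Does a variant qualify under a set specification?
#'
#' Vectorized over the rows of `variants`. Class rule: pLOF always counts
#' (under both PLOF_ONLY and MISSLOF); missense and in-frame count under
#' MISSLOF; branchpoint variants count (as pLOF-class) only when
#' `include_bp`; synonymous/other never. AF rule: gnomAD AF strictly below
#' `af_max`, with missing AF treated as 0 (absent from the reference
#' database = ultra-rare). CADD rule (GE_MSC): missense/in-frame must have
#' CADD >= the gene's MSC; missing CADD fails the rule; pLOF is exempt.
#'
#' @param variants data.frame with columns `gene`, `vclass`, `gnomad_af`,
#'   `cadd` (and `bp_flag` ignored here; branchpoint status is the class).
#' @param spec one row of [enumerate_specs()] (or a list with the same
#'   fields).
#' @param msc named numeric vector of per-gene CADD thresholds; required for
#'   every gene with missense/in-frame variants when `cadd_rule == "GE_MSC"`.
#' @return logical vector along the rows of `variants`.
#' @export
qualifies <- function(variants, spec, msc = NULL) {
  vclass <- variants$vclass
  if (!all(vclass %in% VARIANT_CLASSES)) stop("unknown variant class")
  plof_like <- vclass == "pLOF" |
    (isTRUE(spec$include_bp) & vclass == "branchpoint")
  class_ok <- if (spec$class_rule == "PLOF_ONLY") plof_like
              else plof_like | vclass %in% c("missense", "inframe")
  af <- variants$gnomad_af
  af[is.na(af)] <- 0
  af_ok <- af < spec$af_max
  cadd_ok <- rep(TRUE, length(vclass))
  if (spec$cadd_rule == "GE_MSC") {
    subj <- vclass %in% c("missense", "inframe")
    if (any(subj)) {
      if (is.null(msc)) stop("MSC table required under the GE_MSC rule")
      th <- msc[variants$gene[subj]]
      if (anyNA(th))
        stop("missing MSC for gene(s): ",
             paste(unique(variants$gene[subj][is.na(th)]), collapse = ", "))
      cadd <- variants$cadd[subj]
      cadd_ok[subj] <- !is.na(cadd) & cadd >= th
    }
  }
  class_ok & af_ok & cadd_ok
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Build the gene -> spec -> qualifying-variant index
#'
#' @param variants annotated variant table (one row per biallelic
#'   alternate allele; duplicate chrom:pos:ref:alt keys are an error).
#' @param specs data.frame of set specifications (default the nine sets).
#' @param msc named per-gene MSC vector.
#' @return named list gene -> named list (by spec_id) -> character vector of
#'   variant keys; genes with no qualifying variant under a spec hold an
#'   empty vector there.
#' @export
build_gene_sets <- function(variants, specs = enumerate_specs(), msc = NULL) {
  genes <- unique(variants$gene)
  if (nrow(variants) == 0) return(stats::setNames(list(), character(0)))
  if (anyNA(variants$gene)) stop("every variant must have a gene")
  key <- variant_key(variants)
  if (anyDuplicated(key))
    stop("duplicate variant rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  qual <- lapply(seq_len(nrow(specs)),
                 function(i) qualifies(variants, specs[i, ], msc))
  out <- lapply(genes, function(g) {
    in_gene <- variants$gene == g
    sets <- lapply(seq_along(qual), function(i) key[in_gene & qual[[i]]])
    stats::setNames(sets, as.character(specs$spec_id))
  })
  stats::setNames(out, genes)
}

#' Restrict a variant set to biochemically proven LOF variants
#'
#' @param ids variant keys.
#' @param annotation variant table with a `blof` column in
#'   \{"deleterious", "neutral", "untested"\}.
#' @return the subset of `ids` whose variants are blof = "deleterious".
#' @export
restrict_blof <- function(ids, annotation) {
  if (is.null(annotation$blof)) stop("annotation lacks a blof column")
  key <- variant_key(annotation)
  keep <- key[annotation$blof == "deleterious"]
  ids[ids %in% keep]
}
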
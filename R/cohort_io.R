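## Plain-text cohort serialization: a VCF v4.2 with GT-only genotypes (one
## ALT per record) plus tab-separated annotation, sample sheet, MSC and
## gene-feature files. read_cohort(write_cohort(c)) reproduces the cohort.

VCF_CONTIGS <- c(as.character(1:22), "X")

format_gt <- function(dosage, ploidy) {
  ifelse(ploidy == 1,
         ifelse(is.na(dosage), ".", as.character(dosage)),
         ifelse(is.na(dosage), "./.",
                c("0/0", "0/1", "1/1")[dosage + 1]))
}

parse_gt <- function(gt) {
  ## returns dosage; "." or "./." -> NA
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
}

#' Write a cohort to a directory
#'
#' Emits `genotypes.vcf` (VCF v4.2, GT only; male X genotypes are written
#' haploid, e.g. `1` rather than `1/1`), `annotation.tsv`, `samples.tsv`,
#' `msc.tsv` and `gene_features.tsv`.
#'
#' @param cohort a `cohort`.
#' @param dir destination directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- cohort$variants
  if (!all(v$chrom %in% VCF_CONTIGS))
    stop("variant chromosome not in the VCF contig list: ",
         paste(setdiff(unique(v$chrom), VCF_CONTIGS), collapse = ", "))

  ord <- order(match(v$chrom, VCF_CONTIGS), v$pos)
  v <- v[ord, , drop = FALSE]
  G <- cohort$genotypes[, ord, drop = FALSE]
  P <- ploidy_matrix(cohort, variant_key(v))

  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", VCF_CONTIGS, ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$samples$sample_id),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    gt <- format_gt(G[, i], P[, i])
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", ".", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  paths <- file.path(dir, c("genotypes.vcf", "annotation.tsv", "samples.tsv",
                            "msc.tsv", "gene_features.tsv"))
  writeLines(c(header, body), paths[1])
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(cohort$variants[, c("chrom", "pos", "ref", "alt", "gene",
                                "vclass", "gnomad_af", "cadd", "blof",
                                "bp_flag")], paths[2])
  write_tsv(cohort$samples, paths[3])
  write_tsv(cohort$msc, paths[4])
  write_tsv(cohort$gene_features, paths[5])
  invisible(paths)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir directory containing the five cohort files.
#' @return a `cohort` list.
#' @export
read_cohort <- function(dir) {
  read_tsv <- function(name) {
    utils::read.delim(file.path(dir, name), stringsAsFactors = FALSE,
                      colClasses = NA)
  }
  samples <- read_tsv("samples.tsv")
  variants <- read_tsv("annotation.tsv")
  variants$chrom <- as.character(variants$chrom)
  msc <- read_tsv("msc.tsv")
  feats <- read_tsv("gene_features.tsv")

  lines <- readLines(file.path(dir, "genotypes.vcf"))
  if (!startsWith(lines[1], "##fileformat=VCFv4.2"))
    stop("not a VCF v4.2 file")
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  sample_ids <- cols[-(1:9)]
  if (!identical(sample_ids, samples$sample_id))
    stop("VCF sample columns do not match the sample sheet")
  body <- lines[-seq_len(hdr)]
  fields <- strsplit(body, "\t")
  chrom <- vapply(fields, `[[`, "", 1)
  pos <- as.integer(vapply(fields, `[[`, "", 2))
  ref <- vapply(fields, `[[`, "", 4)
  alt <- vapply(fields, `[[`, "", 5)
  G <- t(vapply(fields, function(f) parse_gt(f[-(1:9)]),
                integer(length(sample_ids))))
  key_vcf <- paste(chrom, pos, ref, alt, sep = ":")
  key_ann <- variant_key(variants)
  if (!setequal(key_vcf, key_ann))
    stop("VCF records do not match the annotation table")
  G <- G[match(key_ann, key_vcf), , drop = FALSE]
  G <- t(G)
  dimnames(G) <- list(samples$sample_id, key_ann)
  cohort <- structure(list(samples = samples, variants = variants,
                           genotypes = G, gene_features = feats, msc = msc),
                      class = "cohort")
  validate_cohort(cohort)
  cohort
}
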
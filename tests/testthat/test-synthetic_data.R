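# hand-built two-sample, one-variant cohort for format checks
tiny_cohort <- function(chrom = "1", dosage = c(1L, 0L),
                        sex = c("M", "F")) {
  variants <- data.frame(chrom = chrom, pos = 100L, ref = "A", alt = "T",
                         gene = "G1", vclass = "pLOF", gnomad_af = 1e-4,
                         cadd = 35, blof = "untested", bp_flag = 0L,
                         stringsAsFactors = FALSE)
  G <- matrix(dosage, nrow = 2, ncol = 1,
              dimnames = list(c("S1", "S2"), rvburden:::variant_key(variants)))
  structure(list(
    samples = data.frame(sample_id = c("S1", "S2"),
                         status = c("case", "control"), sex = sex,
                         age = c(50.5, 40), ancestry = "EUR",
                         pipeline = "central", auto_ab = "neg",
                         stringsAsFactors = FALSE),
    variants = variants, genotypes = G,
    gene_features = data.frame(gene = "G1", pli = 0.9, cones = -1.2),
    msc = data.frame(gene = "G1", msc = 10)), class = "cohort")
}

test_that("simulation is a pure function of (config, seed)", {
  co1 <- small_cohort(n_cases = 100, n_controls = 80, seed = 5)
  co2 <- small_cohort(n_cases = 100, n_controls = 80, seed = 5)
  expect_identical(co1, co2)
  co3 <- small_cohort(n_cases = 100, n_controls = 80, seed = 6)
  expect_false(identical(co1$genotypes, co3$genotypes))
})

test_that("marginal counts, labels and hemizygous X dosages are as configured", {
  co <- small_cohort(n_cases = 120, n_controls = 90, seed = 3)
  expect_equal(sum(co$samples$status == "case"), 120)
  expect_equal(sum(co$samples$status == "control"), 90)
  expect_true(all(co$samples$sex %in% c("M", "F")))
  # male dosages on X never exceed ploidy 1
  xcols <- which(co$variants$chrom == "X")
  male <- co$samples$sex == "M"
  expect_lte(max(co$genotypes[male, xcols]), 1L)
  validate_cohort(co)
})

test_that("null planted effects give equal carrier frequencies by status", {
  cfg <- sim_config(n_cases = 1200, n_controls = 1200,
                    gene_freqs = rvburden:::default_gene_freqs(10, 1),
                    planted = NULL, n_common_background = 50,
                    pop_multiplier = 6, prevalence = 0.25, seed = 13)
  co <- simulate_cohort(cfg)
  case <- co$samples$status == "case"
  for (g in unique(co$variants$gene[co$variants$vclass == "pLOF"])) {
    ids <- rvburden:::variant_key(co$variants)[co$variants$gene == g &
                                                 co$variants$vclass != "other"]
    sc <- gene_score(co$genotypes[, ids, drop = FALSE],
                     ploidy_matrix(co, ids), "dominant")
    f1 <- mean(sc[case]); f0 <- mean(sc[!case])
    # difference inside a 99% binomial CI of the pooled frequency
    pool <- mean(sc)
    se <- sqrt(pool * (1 - pool) * (1 / sum(case) + 1 / sum(!case)))
    expect_lt(abs(f1 - f0), max(qnorm(0.995) * se, 1e-12) + 1e-9)
  }
})

test_that("planted X-linked recessive carriers match the Bayes-rule oracle", {
  gf <- rvburden:::default_gene_freqs(8, 1)
  gf$carrier_freq[gf$gene == "G001" & gf$class == "pLOF"] <- 0.01
  cfg <- sim_config(n_cases = 2500, n_controls = 2500, gene_freqs = gf,
                    planted = data.frame(gene = "G001", model = "x_recessive",
                                         beta = 3),
                    n_common_background = 100, pop_multiplier = 25, seed = 11)
  co <- simulate_cohort(cfg)
  ids <- rvburden:::variant_key(co$variants)[co$variants$gene == "G001" &
                                               co$variants$vclass == "pLOF"]
  sc <- gene_score(co$genotypes[, ids, drop = FALSE],
                   ploidy_matrix(co, ids), "recessive")
  male <- co$samples$sex == "M"; case <- co$samples$status == "case"
  obs_case <- mean(sc[male & case]); obs_ctrl <- mean(sc[male & !case])
  expect_gt(obs_case, obs_ctrl)

  # independent oracle: Monte-Carlo Bayes on the stated generative model
  set.seed(999)
  M <- 4e5
  age <- pmax(rnorm(M, 43.8, 20.1), 0.1)
  sexm <- runif(M) < 0.5
  carrier <- sexm & (runif(M) < 0.01)  # female biallelic freq ~1e-4, ignored
  eta0 <- cfg$beta_age * (age - 43.8) + cfg$beta_male * sexm + 3 * carrier
  b0 <- uniroot(function(b) mean(plogis(b + eta0)) - 0.03, c(-30, 30))$root
  pcase <- plogis(b0 + eta0)
  oracle_case <- sum(pcase[carrier]) / sum(pcase[sexm])
  oracle_ctrl <- sum(1 - pcase[carrier]) / sum(1 - pcase[sexm])
  n_mc <- sum(male & case)
  se <- sqrt(oracle_case * (1 - oracle_case) / n_mc)
  expect_lt(abs(obs_case - oracle_case), 4 * se)
  se0 <- sqrt(oracle_ctrl * (1 - oracle_ctrl) / sum(male & !case))
  expect_lt(abs(obs_ctrl - oracle_ctrl), 4 * se0 + 0.002)
})

test_that("control carrier frequencies recover the configured values", {
  # genes without planted effects: the control carrier fraction must sit
  # within 3 binomial SDs of the configured population frequency
  cfg <- sim_config(n_cases = 2500, n_controls = 2500,
                    gene_freqs = rvburden:::default_gene_freqs(8, 1),
                    planted = NULL, n_common_background = 50,
                    pop_multiplier = 25, seed = 17)
  co <- simulate_cohort(cfg)
  ctrl <- co$samples$status == "control"
  for (g in c("G002", "G005", "G008")) {
    ids <- rvburden:::variant_key(co$variants)[co$variants$gene == g &
                                                 co$variants$vclass == "pLOF"]
    sc <- gene_score(co$genotypes[ctrl, ids, drop = FALSE],
                     ploidy_matrix(co, ids)[ctrl, , drop = FALSE], "dominant")
    target <- 2e-3  # default pLOF carrier frequency
    sd3 <- 3 * sqrt(target * (1 - target) / sum(ctrl))
    expect_lt(abs(mean(sc) - target), sd3)
  }
})

test_that("impossible configurations fail loudly", {
  gf <- rvburden:::default_gene_freqs(4, 1)
  gf$carrier_freq[gf$gene == "G002"] <- 0
  expect_error(
    sim_config(n_cases = 10, n_controls = 10, gene_freqs = gf,
               planted = data.frame(gene = "G002", model = "codominant",
                                    beta = 2)),
    "G002")
  # case quota unreachable at this multiplier/prevalence
  cfg <- sim_config(n_cases = 500, n_controls = 100,
                    gene_freqs = rvburden:::default_gene_freqs(4, 1),
                    n_common_background = 10, pop_multiplier = 2,
                    prevalence = 0.03, seed = 1)
  expect_error(simulate_cohort(cfg), "quota unreachable")
  expect_error(sim_config(n_cases = 10, n_controls = 10, fst = 1), "fst")
})

test_that("common background divergence behaves at the fst extremes", {
  cfg0 <- sim_config(n_cases = 400, n_controls = 400,
                     strata = data.frame(ancestry = c("A", "B"),
                                         pipeline = "p",
                                         weight = c(0.5, 0.5)),
                     n_common_background = 300, fst = 0, seed = 19)
  anc <- rep(c("A", "B"), each = 400)
  G <- simulate_common_background(cfg0, ancestry = anc)
  # fst = 0: allele-frequency homogeneity chi-squares are not enriched
  ps <- vapply(seq_len(ncol(G)), function(j) {
    tab <- rbind(c(sum(G[anc == "A", j]), 2 * 400 - sum(G[anc == "A", j])),
                 c(sum(G[anc == "B", j]), 2 * 400 - sum(G[anc == "B", j])))
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  # a single requested variant gives a single column
  cfg1 <- sim_config(n_cases = 5, n_controls = 5, n_common_background = 1,
                     seed = 2)
  expect_equal(ncol(simulate_common_background(cfg1)), 1L)
})

test_that("write_cohort emits VCF v4.2 with correct GT encoding", {
  d <- withr::local_tempdir()
  write_cohort(tiny_cohort(), d)
  vcf <- readLines(file.path(d, "genotypes.vcf"))
  expect_equal(vcf[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("^##contig=<ID=X>$", vcf)))
  data_lines <- vcf[!startsWith(vcf, "#")]
  expect_length(data_lines, 1L)
  expect_equal(strsplit(data_lines, "\t")[[1]][10:11], c("0/1", "0/0"))
  # male X carrier is encoded haploid
  d2 <- withr::local_tempdir()
  write_cohort(tiny_cohort(chrom = "X", dosage = c(1L, 2L)), d2)
  line <- grep("^X\t", readLines(file.path(d2, "genotypes.vcf")), value = TRUE)
  expect_equal(strsplit(line, "\t")[[1]][10:11], c("1", "1/1"))
  # unknown contig is rejected
  bad <- tiny_cohort(chrom = "MT")
  expect_error(write_cohort(bad, withr::local_tempdir()), "contig")
})

test_that("a simulated cohort round-trips through the on-disk format", {
  co <- small_cohort(n_cases = 60, n_controls = 40, seed = 23)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  for (nm in names(co))
    expect_equal(back[[nm]], co[[nm]], ignore_attr = TRUE, tolerance = 1e-12)
})
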
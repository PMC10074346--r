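# gene-set enrichment, matched nulls, zygosity test, reporting arithmetic

null_universe_cohort <- function(seed = 55, ng = 60, n = 800) {
  gf <- data.frame(gene = sprintf("U%03d", seq_len(ng)),
                   chrom = as.character(rep_len(1:22, ng)),
                   class = "pLOF", carrier_freq = 0.01,
                   stringsAsFactors = FALSE)
  cfg <- sim_config(n_cases = n / 2, n_controls = n / 2, gene_freqs = gf,
                    strata = data.frame(ancestry = "EUR", pipeline = "p",
                                        weight = 1),
                    n_common_background = 30, pop_multiplier = 5,
                    prevalence = 0.25, n_variants_per_class = 1, seed = seed)
  simulate_cohort(cfg)
}

test_that("a one-gene set reproduces the single-gene burden test", {
  co <- small_cohort(n_cases = 300, n_controls = 200, seed = 7)
  ids <- rvburden:::variant_key(co$variants)[co$variants$gene == "G001" &
                                               co$variants$vclass == "pLOF"]
  sc <- gene_score(co$genotypes[, ids, drop = FALSE],
                   ploidy_matrix(co, ids), "codominant")
  direct <- burden_test(sc, as.numeric(co$samples$status == "case"))
  pooled <- set_burden_test(co, gene_set_spec("G001", af_max = 1e-2))
  expect_equal(pooled$p, direct$p)
  expect_equal(pooled$or, direct$or)
  expect_equal(pooled$case_carriers, direct$case_carriers)
})

test_that("pooled carriers equal the union of per-gene carrier sets", {
  co <- null_universe_cohort(seed = 31)
  members <- sprintf("U%03d", 1:13)
  sp <- gene_set_spec(members, af_max = 1e-2)
  r <- set_burden_test(co, sp)
  per_gene_carriers <- lapply(members, function(g) {
    ids <- rvburden:::variant_key(co$variants)[co$variants$gene == g]
    which(gene_score(co$genotypes[, ids, drop = FALSE],
                     ploidy_matrix(co, ids), "dominant") > 0)
  })
  union_size <- length(unique(unlist(per_gene_carriers)))
  expect_equal(r$case_carriers + r$ctrl_carriers, union_size)
})

test_that("heterozygous-only and recessive set models split carriers by zygosity", {
  co <- small_cohort(n_cases = 500, n_controls = 300, seed = 13)
  sp <- gene_set_spec(c("G001", "G003"), af_max = 1e-2)
  het <- set_burden_test(co, sp, model = "heterozygous")
  rec <- set_burden_test(co, sp, model = "recessive")
  cod <- set_burden_test(co, sp, model = "codominant")
  # monoallelic + biallelic carriers partition the codominant carriers
  expect_equal((het$case_carriers + het$ctrl_carriers) +
                 (rec$case_carriers + rec$ctrl_carriers),
               cod$case_carriers + cod$ctrl_carriers)
})

test_that("planted member genes make the pooled test stronger than singles", {
  gf <- rvburden:::default_gene_freqs(20, 1)
  planted <- data.frame(gene = c("G002", "G003", "G004"),
                        model = "codominant", beta = 1.5)
  cfg <- sim_config(n_cases = 1200, n_controls = 800, gene_freqs = gf,
                    planted = planted, n_common_background = 50,
                    pop_multiplier = 25, seed = 41)
  co <- simulate_cohort(cfg)
  members <- sprintf("G%03d", 2:14)  # 13 loci, 3 carrying planted effects
  pooled <- set_burden_test(co, gene_set_spec(members, af_max = 1e-2))
  singles <- vapply(members, function(g) {
    r <- set_burden_test(co, gene_set_spec(g, af_max = 1e-2))
    if (r$skipped) NA_real_ else r$p
  }, numeric(1))
  expect_lt(pooled$p, median(singles, na.rm = TRUE))
  expect_gt(pooled$or, 1)
})

test_that("matched null sets respect tolerances and determinism", {
  gfeat <- data.frame(gene = sprintf("M%03d", 1:300),
                      pli = rep(seq(0, 1, length.out = 50), 6),
                      cones = rep(seq(-2, 2, length.out = 6), each = 50))
  targets <- c("M001", "M100", "M200")
  sets <- sample_matched_sets(targets, gfeat, R = 50, tol_pli = 0.1,
                              tol_cones = 0.5, seed = 3)
  expect_length(sets, 50)
  for (s in sets[1:5]) {
    expect_length(s, 3)
    expect_false(any(duplicated(s)))
    expect_false(any(s %in% targets))
    for (i in seq_along(targets)) {
      ti <- match(targets[i], gfeat$gene); si <- match(s[i], gfeat$gene)
      expect_lte(abs(gfeat$pli[ti] - gfeat$pli[si]), 0.1)
      expect_lte(abs(gfeat$cones[ti] - gfeat$cones[si]), 0.5)
    }
  }
  # deterministic under seed
  expect_identical(sets,
                   sample_matched_sets(targets, gfeat, R = 50, tol_pli = 0.1,
                                       tol_cones = 0.5, seed = 3))
  # zero tolerance in a duplicated-feature universe: exact feature match
  dupfeat <- data.frame(gene = sprintf("D%02d", 1:30),
                        pli = rep(c(0.1, 0.9), each = 15),
                        cones = rep(c(-1, 0, 1), 10))
  s0 <- sample_matched_sets("D01", dupfeat, R = 5, tol_pli = 0,
                            tol_cones = 0, seed = 1)
  for (s in s0) {
    si <- match(s, dupfeat$gene)
    expect_equal(dupfeat$pli[si], dupfeat$pli[1])
    expect_equal(dupfeat$cones[si], dupfeat$cones[1])
  }
  # empty pool is an explicit failure naming the gene
  lone <- rbind(gfeat, data.frame(gene = "LONE", pli = 0.5, cones = 99))
  expect_error(sample_matched_sets("LONE", lone, R = 2, tol_pli = 0.01,
                                   tol_cones = 0.01, seed = 1), "LONE")
})

test_that("matching on constraint features preserves gene variant counts", {
  # synthetic universe where high-pLI genes carry more variants: matched
  # nulls preserve the targets' mean variant count; unmatched ones do not
  set.seed(19)
  gfeat <- data.frame(gene = sprintf("V%03d", 1:400),
                      pli = runif(400), cones = 0)
  nvar <- round(3 + 17 * gfeat$pli)  # variant count rises with pLI
  names(nvar) <- gfeat$gene
  targets <- gfeat$gene[order(-gfeat$pli)][1:13]  # high-pLI candidates
  matched <- sample_matched_sets(targets, gfeat, R = 200, tol_pli = 0.05,
                                 tol_cones = Inf, seed = 11)
  loose <- sample_matched_sets(targets, gfeat, R = 200, tol_pli = Inf,
                               tol_cones = Inf, seed = 11)
  target_mean <- mean(nvar[targets])
  matched_mean <- mean(vapply(matched, function(s) mean(nvar[s]), numeric(1)))
  loose_mean <- mean(vapply(loose, function(s) mean(nvar[s]), numeric(1)))
  expect_lt(abs(matched_mean - target_mean) / target_mean, 0.10)
  expect_gt(abs(loose_mean - target_mean) / target_mean, 0.10)
})

test_that("empirical_p follows the add-one order statistics", {
  expect_equal(empirical_p(1e-10, runif(999, 0.01, 1)), 1 / 1000)
  expect_equal(empirical_p(2, runif(99)), 1)
  nulls <- seq(0.001, 0.999, length.out = 999)
  expect_equal(empirical_p(median(nulls), nulls), 0.5, tolerance = 0.01)
  expect_gte(empirical_p(0, runif(99)), 1 / 100)
})

test_that("enrichment_test returns a calibrated machinery end to end", {
  co <- null_universe_cohort(seed = 23)
  er <- enrichment_test(co, gene_set_spec(sprintf("U%03d", 1:8),
                                          af_max = 1e-2),
                        R = 49, tol_pli = Inf, tol_cones = Inf, seed = 5)
  expect_gte(er$empirical_p, 1 / 50)
  expect_lte(er$empirical_p, 1)
  expect_length(er$null_p, 49)
  # deterministic under seed
  er2 <- enrichment_test(co, gene_set_spec(sprintf("U%03d", 1:8),
                                           af_max = 1e-2),
                         R = 49, tol_pli = Inf, tol_cones = Inf, seed = 5)
  expect_identical(er$empirical_p, er2$empirical_p)
})

test_that("zygosity equality test is calibrated and detects OR differences", {
  set.seed(29)
  reps <- 300
  null_ps <- numeric(reps); alt_ps <- numeric(reps)
  n <- 700
  for (i in seq_len(reps)) {
    het <- rbinom(n, 1, 0.06)
    bi <- ifelse(het == 1, 0, rbinom(n, 1, 0.03))
    # equal log-odds for het and hom carriers: null of the test
    y0 <- rbinom(n, 1, plogis(-0.5 + 1.0 * (het | bi)))
    null_ps[i] <- zygosity_equality_test(het, bi, y0)
    # hom effect much larger than het effect
    y1 <- rbinom(n, 1, plogis(-0.5 + 0.3 * het + 2.5 * bi))
    alt_ps[i] <- zygosity_equality_test(het, bi, y1)
  }
  ks <- suppressWarnings(ks.test(null_ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(median(alt_ps), 0.05)
  # degenerate inputs
  expect_error(zygosity_equality_test(rep(0, 10), rbinom(10, 1, 0.5),
                                      rbinom(10, 1, 0.5)), "monoallelic")
  expect_error(zygosity_equality_test(rbinom(10, 1, 0.5), rep(0, 10),
                                      rbinom(10, 1, 0.5)), "biallelic")
  x <- c(1, 1, 0, 0, 1, 0)
  expect_error(zygosity_equality_test(x, x, c(1, 0, 1, 0, 1, 0)),
               "rank-deficient")
})

test_that("carrier_proportion rounds half-up to one decimal", {
  expect_equal(carrier_proportion(57, 3269), 1.7)
  expect_equal(carrier_proportion(25, 3269), 0.8)
  expect_equal(carrier_proportion(0, 100), 0.0)
  expect_equal(carrier_proportion(1, 1), 100.0)
  # half-up at the boundary (0.05% rounds to 0.1%)
  expect_equal(carrier_proportion(5, 10000), 0.1)
  expect_error(carrier_proportion(5, 4), "outside")
})

test_that("compare_group_means is a calibrated Welch comparison", {
  g <- rnorm(50)
  r <- compare_group_means(g, g)
  expect_equal(r$p, 1, tolerance = 1e-10)
  expect_equal(r$mean_a, r$mean_b)
  set.seed(37)
  null_ps <- replicate(300, compare_group_means(rnorm(40), rnorm(40))$p)
  expect_gt(suppressWarnings(ks.test(null_ps, "punif"))$p.value, 0.01)
  # 1-SD shift at n=100 is detected nearly always
  power <- mean(replicate(100, compare_group_means(rnorm(100),
                                                   rnorm(100, 1))$p < 0.01))
  expect_gte(power, 0.95)
  expect_error(compare_group_means(1, c(1, 2)), "2 values")
})
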
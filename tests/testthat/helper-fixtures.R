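# Shared fixtures: tiny hand-built variant tables and cohorts.

toy_variants <- function() {
  data.frame(
    chrom = c("1", "1", "1", "2", "X"),
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "T",
    gene = c("G1", "G1", "G1", "G2", "GX"),
    vclass = c("pLOF", "missense", "synonymous", "missense", "pLOF"),
    gnomad_af = c(5e-4, 5e-5, 1e-5, 5e-3, 1e-4),
    cadd = c(40, 10, 1, 30, 38),
    blof = c("deleterious", "untested", "untested", "neutral", "deleterious"),
    bp_flag = 0L,
    stringsAsFactors = FALSE)
}

toy_msc <- function() c(G1 = 20, G2 = 25, GX = 15)

# deterministic small cohort with one planted X-linked recessive gene
small_cohort <- function(n_cases = 300, n_controls = 200, seed = 7,
                         beta = 3, n_genes = 15) {
  cfg <- sim_config(
    n_cases = n_cases, n_controls = n_controls,
    gene_freqs = rvburden:::default_gene_freqs(n_genes, 2),
    planted = data.frame(gene = "G001", model = "x_recessive", beta = beta),
    n_common_background = 150, pop_multiplier = 25, seed = seed)
  simulate_cohort(cfg)
}

# exact-correlation column pairs for eigen_meff tests
cols_with_cor <- function(r) {
  x <- c(1, 1, -1, -1)
  z <- c(1, -1, 1, -1)
  cbind(x = x, y = r * x + sqrt(1 - r^2) * z)
}
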
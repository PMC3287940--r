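test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_populations = 3, n_per_population = 20,
                           n_genes = 8, sites_per_gene = 5,
                           n_causal_genes = 2, het_effect_sd = 0.3,
                           confound_gamma = 0.1, seed = 99)
  d1 <- suppressMessages(simulate_dataset(cfg))
  d2 <- suppressMessages(simulate_dataset(cfg))
  expect_identical(d1$genotypes$genotypes, d2$genotypes$genotypes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$truth$causal_genes, d2$truth$causal_genes)
})

test_that("truth is consistent with the configuration and the data", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 30,
                           n_genes = 10, sites_per_gene = 6,
                           n_causal_genes = 3, seed = 5)
  d <- suppressMessages(simulate_dataset(cfg))
  expect_length(d$truth$causal_genes, 3)
  expect_true(all(d$truth$causal_genes %in% unique(d$genotypes$site_gene)))
  expect_lte(length(d$truth$causal_sites), 3 * cfg$causal_variants_per_gene)
  expect_gte(length(d$truth$causal_sites), 3)
  expect_true(all(d$truth$causal_sites %in% d$genotypes$site_ids))
  expect_identical(dim(d$genotypes$genotypes), c(60L, 60L))
  expect_identical(nrow(d$phenotypes), 60L)
})

test_that("a pure null leaves the trait unrelated to genotypes", {
  cfg <- simulation_config(n_populations = 1, n_per_population = 200,
                           n_genes = 20, sites_per_gene = 7, divergence_F = 0,
                           beta_age = 0, beta_smoke = 0, seed = 12)
  d <- simulate_dataset(cfg)
  burden <- rowSums(d$genotypes$genotypes > 0)
  expect_lt(abs(cor(d$phenotypes$Q, burden)), 0.2)
})

test_that("realized frequencies follow the configured spectrum", {
  cfg <- simulation_config(n_populations = 1, n_per_population = 400,
                           n_genes = 150, sites_per_gene = 7,
                           divergence_F = 0, spectrum_shape1 = 0.2,
                           spectrum_shape2 = 1.8, seed = 31)
  d <- simulate_dataset(cfg)
  realized <- colMeans(d$genotypes$genotypes) / 2
  # clipped Beta(0.2, 1.8) mean, computed by quadrature
  clipped_mean <- integrate(function(p) {
    pmin(pmax(p, cfg$freq_min), cfg$freq_max) * dbeta(p, 0.2, 1.8)
  }, 0, 1)$value
  expect_equal(mean(realized), clipped_mean, tolerance = 0.05)
})

test_that("population differentiation increases with the divergence F", {
  fst_hat <- vapply(c(0.02, 0.1, 0.3), function(F) {
    cfg <- simulation_config(n_populations = 4, n_per_population = 50,
                             n_genes = 40, sites_per_gene = 7,
                             divergence_F = F, spectrum_shape1 = 1,
                             spectrum_shape2 = 3, seed = 61)
    d <- simulate_dataset(cfg)
    g <- d$genotypes
    freqs <- vapply(split(seq_along(g$population), g$population),
                    function(rows) colMeans(g$genotypes[rows, , drop = FALSE]) / 2,
                    numeric(ncol(g$genotypes)))
    pbar <- rowMeans(freqs)
    keep <- pbar > 0.01 & pbar < 0.99
    mean(apply(freqs[keep, ], 1, var) / (pbar[keep] * (1 - pbar[keep])))
  }, numeric(1))
  expect_true(all(diff(fst_hat) > 0))
})

test_that("the heterozygosity tilt creates the configured confound", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 100,
                           n_genes = 200, sites_per_gene = 7,
                           het_effect_sd = 0.8, confound_gamma = 0.25,
                           pop_shifts = c(-0.5, 0.5), seed = 13)
  d <- simulate_dataset(cfg)
  expect_gt(d$truth$het_trait_correlation, 0.1)
  expect_lt(d$truth$het_trait_correlation, 0.35)
})

test_that("written datasets round-trip through the readers", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 15,
                           n_genes = 4, sites_per_gene = 5,
                           n_causal_genes = 1, seed = 3)
  d <- suppressMessages(simulate_dataset(cfg))
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir, genotype_format = "vcf")
  gm <- read_gene_map(paths[["gene_map"]])
  g <- suppressMessages(read_vcf(paths[["genotypes"]], gm))
  expect_identical(g$genotypes[d$genotypes$individual_ids,
                               d$genotypes$site_ids],
                   d$genotypes$genotypes)
  ph <- read_phenotype_tsv(paths[["phenotypes"]])
  expect_equal(ph$Q, d$phenotypes$Q, tolerance = 1e-12)
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_identical(truth$causal_genes, d$truth$causal_genes)

  paths2 <- write_dataset(d, dir, genotype_format = "tsv")
  g2 <- suppressMessages(read_genotype_tsv(paths2[["genotypes"]],
                                           gm,
                                           positions = d$genotypes$site_positions))
  expect_identical(g2$genotypes, d$genotypes$genotypes)
})
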
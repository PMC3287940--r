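test_that("heterozygosity is the fraction of het sites", {
  g <- genotype_matrix(rbind(c(0L, 0L, 0L, 0L),
                             c(1L, 1L, 1L, 1L),
                             c(0L, 1L, 2L, 1L),
                             c(NA, 1L, 0L, NA)),
                       paste0("s", 1:4), 1:4, rep("g", 4), paste0("i", 1:4))
  het <- individual_heterozygosity(g)
  expect_equal(unname(het), c(0, 1, 0.5, 0.5))  # i4: 1 het of 2 non-missing
})

test_that("PC loadings separate diverged populations deterministically", {
  set.seed(19)
  cfg <- simulation_config(n_populations = 2, n_per_population = 40,
                           n_genes = 60, sites_per_gene = 6,
                           divergence_F = 0.25, spectrum_shape1 = 1,
                           spectrum_shape2 = 3, seed = 23)
  d <- simulate_dataset(cfg)
  pc <- pc_loadings(d$genotypes, 4)
  pop <- d$genotypes$population
  sep <- vapply(1:4, function(j) {
    s <- pc$scores[, j]
    abs(mean(s[pop == "pop1"]) - mean(s[pop == "pop2"])) /
      sd(s - stats::ave(s, pop))
  }, numeric(1))
  expect_gt(max(sep), 2)  # some component is dominated by population
  expect_lte(sum(pc$variance_fraction), 1)
  # duplicated individuals get identical loading vectors
  g2 <- d$genotypes
  g2$genotypes[2, ] <- g2$genotypes[1, ]
  pc2 <- pc_loadings(genotype_matrix(g2$genotypes, g2$site_ids,
                                     g2$site_positions, g2$site_gene,
                                     g2$individual_ids, g2$population), 3)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
  # repeated runs give the same signs
  expect_identical(pc_loadings(d$genotypes, 4)$scores, pc$scores)
})

test_that("pc_loadings rejects a constant matrix", {
  g <- genotype_matrix(matrix(1L, 5, 3), paste0("s", 1:3), 1:3,
                       rep("g", 3), paste0("i", 1:5))
  expect_error(pc_loadings(g, 2), "degenerate")
})

test_that("backwards BIC selection keeps a strong Age effect only", {
  set.seed(4)
  n <- 500
  dat <- data.frame(Age = rnorm(n, 45, 12), Sex = rbinom(n, 1, 0.5),
                    Smoke = rbinom(n, 1, 0.3))
  dat$Q <- 2 * dat$Age + rnorm(n, 0, 5)
  dp <- residualize(dat, "Q", c("Age", "Sex", "Smoke"))
  expect_identical(dp$retained_terms, "Age")
  expect_equal(mean(dp$values), 0, tolerance = 1e-9)
  expect_equal(sd(dp$values), 1, tolerance = 1e-9)
  # residuals orthogonal to the retained covariate
  expect_lt(abs(sum(dp$values * scale(dat$Age, scale = FALSE))), 1e-8)
  # selection is invariant to candidate ordering
  dp2 <- residualize(dat, "Q", c("Smoke", "Sex", "Age"))
  expect_identical(dp2$retained_terms, dp$retained_terms)
  expect_equal(dp2$values, dp$values)
})

test_that("pure-noise traits mostly select the intercept-only model", {
  set.seed(40)
  keeps <- replicate(30, {
    n <- 200
    dat <- data.frame(Age = rnorm(n, 45, 12), Sex = rbinom(n, 1, 0.5),
                      Smoke = rbinom(n, 1, 0.3), Q = rnorm(n))
    length(residualize(dat, "Q", c("Age", "Sex", "Smoke"))$retained_terms)
  })
  expect_gte(mean(keeps == 0), 0.8)
})

test_that("refitting a selected model transfers without re-selection", {
  set.seed(6)
  n <- 300
  make_data <- function() {
    dat <- data.frame(Age = rnorm(n, 45, 12), Sex = rbinom(n, 1, 0.5),
                      Smoke = rbinom(n, 1, 0.3))
    dat$Q <- 1.5 * dat$Age + rnorm(n, 0, 4)
    dat
  }
  dat <- make_data()
  dp <- residualize(dat, "Q", c("Age", "Sex", "Smoke"))
  # same data, same terms: identical residuals
  rf <- refit_selected(dp, dat)
  expect_equal(rf$values, dp$values)
  # a replicate from the same model: coefficients re-estimated, noise scale
  # recovered
  rf2 <- refit_selected(dp, make_data())
  expect_equal(rf2$residual_sd, 4, tolerance = 0.15)
  expect_error(refit_selected(dp, data.frame(Q = rnorm(10))), "lacks")
  # an empty model standardizes the trait itself
  dp0 <- dp; dp0$retained_terms <- character(0)
  rf0 <- refit_selected(dp0, dat)
  expect_equal(rf0$values, as.numeric(scale(dat$Q)))
})

test_that("aliased candidates are dropped before selection", {
  set.seed(10)
  n <- 100
  dat <- data.frame(Age = rnorm(n, 45, 12))
  dat$Age2 <- dat$Age          # perfectly collinear
  dat$Q <- dat$Age + rnorm(n)
  expect_message(dp <- residualize(dat, "Q", c("Age", "Age2")), "aliased")
  expect_identical(dp$retained_terms, "Age")
  expect_error(residualize(dat[1:3, ], "Q", c("Age", "Age2")),
               "insufficient")
})

test_that("PC residualization removes a planted heterozygosity confound", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 60,
                           n_genes = 120, sites_per_gene = 7,
                           het_effect_sd = 0.8, confound_gamma = 0.25,
                           pop_shifts = c(-0.5, 0.5), seed = 77)
  d <- simulate_dataset(cfg)
  het <- individual_heterozygosity(d$genotypes)
  raw_cor <- cor(d$phenotypes$Q, het)
  expect_gt(abs(raw_cor), 0.1)
  pc <- pc_loadings(d$genotypes, 6)
  ph <- cbind(d$phenotypes, pc$scores)
  dp <- suppressMessages(
    residualize(ph, "Q", c("Age", "Sex", "Smoke", paste0("PC", 1:6))))
  expect_lt(abs(cor(dp$values, het)), abs(raw_cor) / 2)
})
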
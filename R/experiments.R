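# Calibration, power, confound and model-recovery studies. These are the
# package's reference experiments: they generate their own data with
# simulate_dataset(), run the full scan pipeline, and summarise rejection
# rates. Study conditions (two populations of 100, a 1-noise-sd trait mean
# shift between them, Balding-Nichols F = 0.1, 7 rare-skewed sites per gene)
# are fixed here so that tests and scripts measure the same thing.

two_pop_config <- function(n_genes, seed, ...) {
  simulation_config(n_populations = 2, n_per_population = 100,
                    n_genes = n_genes, sites_per_gene = 7,
                    divergence_F = 0.1, pop_shifts = c(-0.5, 0.5),
                    seed = seed, ...)
}

#' Type-I error of the stratified and unstratified scans under the null
#'
#' Simulates genes with no genotype effect on the trait but a mean shift
#' between two diverged populations, scans them once with within-population
#' permutation and once unstratified, and reports the fraction of genes
#' rejected at `alpha` on \eqn{S_j}. Under the structured null the
#' stratified scan should hold its level while the unstratified scan
#' inflates.
#'
#' @param n_genes Number of null genes.
#' @param n_reps Permutation replicates per gene.
#' @param alpha Significance level.
#' @param j Which \eqn{S_j} to test (default 5).
#' @param k Disjoint-node budget.
#' @param seed Integer seed.
#' @param unstratified Also run the unstratified scan?
#' @return List with `rate_stratified`, `rate_unstratified` (NA when not
#'   run), `n_genes`, and the two scan tables.
#' @export
calibration_experiment <- function(n_genes = 1000, n_reps = 999,
                                   alpha = 0.05, j = 5, k = 5, seed = 1,
                                   unstratified = TRUE) {
  d <- simulate_dataset(two_pop_config(n_genes, seed = derive_seed(seed,
                                                                   "calib")))
  strat <- scan_genes(d$genotypes, d$phenotypes, trait = "Q", k = k,
                      n_reps = n_reps, seed = derive_seed(seed, "strat"))
  pj <- strat[[paste0("p_", j)]]
  out <- list(rate_stratified = mean(pj <= alpha),
              rate_unstratified = NA_real_,
              n_genes = n_genes, scan_stratified = strat,
              scan_unstratified = NULL)
  if (unstratified) {
    unstrat <- scan_genes(d$genotypes, d$phenotypes, trait = "Q",
                          strata_column = NULL, k = k, n_reps = n_reps,
                          seed = derive_seed(seed, "unstrat"))
    out$rate_unstratified <- mean(unstrat[[paste0("p_", j)]] <= alpha)
    out$scan_unstratified <- unstrat
  }
  out
}

#' Power to detect causal genes, S_1 versus S_5
#'
#' Simulates a mixture of causal and null genes in the two-population design
#' (causal effects spread over several rare variants per gene, carrier
#' effect about half a trait sd), scans with within-population permutation,
#' and reports power and type-I error at `alpha` for \eqn{S_1} and
#' \eqn{S_j}.
#'
#' @param n_genes Total genes.
#' @param n_causal Causal genes among them.
#' @param n_reps,alpha,j,k,seed As in [calibration_experiment()].
#' @return List with `power_s1`, `power_sj`, `type1_s1`, `type1_sj`,
#'   `causal_genes`, and the scan table.
#' @export
power_experiment <- function(n_genes = 200, n_causal = 20, n_reps = 999,
                             alpha = 0.05, j = 5, k = 5, seed = 1) {
  cfg <- two_pop_config(n_genes, seed = derive_seed(seed, "power"),
                        n_causal_genes = n_causal,
                        causal_variants_per_gene = 4, causal_beta = 0.5)
  d <- simulate_dataset(cfg)
  scan <- scan_genes(d$genotypes, d$phenotypes, trait = "Q", k = k,
                     n_reps = n_reps, seed = derive_seed(seed, "powerscan"))
  causal <- scan$gene %in% d$truth$causal_genes
  pj <- scan[[paste0("p_", j)]]
  list(power_s1 = mean(scan$p_1[causal] <= alpha),
       power_sj = mean(pj[causal] <= alpha),
       type1_s1 = mean(scan$p_1[!causal] <= alpha),
       type1_sj = mean(pj[!causal] <= alpha),
       causal_genes = d$truth$causal_genes, scan = scan)
}

#' Heterozygosity confound and its principal-component correction
#'
#' Simulates null genes with a genome-wide heterozygosity axis (lognormal
#' per-individual tilt of heterozygote probabilities) and a trait coupled to
#' standardized heterozygosity, so that the raw-trait scan rejects too often
#' even with within-population permutation. The trait is then residualized by
#' backwards-BIC selection over Age, Sex, Smoke and the first `n_pcs`
#' principal-component loadings of the allele-count matrix, and the scan is
#' repeated on the derived phenotype.
#'
#' @param n_genes Number of null genes.
#' @param n_reps,alpha,j,k,seed As in [calibration_experiment()].
#' @param het_effect_sd,confound_gamma Confound strength (defaults give a
#'   realized trait-heterozygosity correlation around 0.2).
#' @param n_pcs Number of PC loadings offered to the selection.
#' @return List with `rate_raw`, `rate_residualized`,
#'   `het_trait_correlation` (realized, raw trait),
#'   `het_residual_correlation`, the retained model, and both scan tables.
#' @export
confound_experiment <- function(n_genes = 1000, n_reps = 999, alpha = 0.05,
                                j = 5, k = 5, seed = 1,
                                het_effect_sd = 0.8, confound_gamma = 0.25,
                                n_pcs = 6) {
  cfg <- two_pop_config(n_genes, seed = derive_seed(seed, "confound"),
                        het_effect_sd = het_effect_sd,
                        confound_gamma = confound_gamma)
  d <- simulate_dataset(cfg)
  raw <- scan_genes(d$genotypes, d$phenotypes, trait = "Q", k = k,
                    n_reps = n_reps, seed = derive_seed(seed, "rawscan"))
  pc <- pc_loadings(d$genotypes, n_components = n_pcs)
  ph <- cbind(d$phenotypes, pc$scores[match(d$phenotypes$id,
                                            rownames(pc$scores)), ,
                                      drop = FALSE])
  dp <- suppressMessages(
    residualize(ph, "Q", c("Age", "Sex", "Smoke",
                           paste0("PC", seq_len(n_pcs)))))
  ph$Q_resid <- dp$values
  resid_scan <- scan_genes(d$genotypes, ph, trait = "Q_resid", k = k,
                           n_reps = n_reps,
                           seed = derive_seed(seed, "residscan"))
  het <- individual_heterozygosity(d$genotypes)
  pj <- function(s) s[[paste0("p_", j)]]
  list(rate_raw = mean(pj(raw) <= alpha),
       rate_residualized = mean(pj(resid_scan) <= alpha),
       het_trait_correlation = d$truth$het_trait_correlation,
       het_residual_correlation = stats::cor(dp$values, het),
       model = dp, scan_raw = raw, scan_residualized = resid_scan,
       n_genes = n_genes)
}

#' Recovery of a planted covariate effect by backwards-BIC selection
#'
#' Simulates replicates of a trait driven only by Age (planted coefficient
#' `beta_age`) plus noise, offers Age, Sex and Smoke as candidates, and
#' counts how often the selection retains exactly the Age term.
#'
#' @param n_replicates Number of simulated replicates.
#' @param n Sample size per replicate.
#' @param beta_age Planted Age coefficient (per year).
#' @param noise_sd Trait noise sd.
#' @param seed Integer seed.
#' @return List with `recovery_rate`, `age_retained_rate`,
#'   `null_dropped_rate`, `n_replicates`.
#' @export
bic_recovery_experiment <- function(n_replicates = 100, n = 500,
                                    beta_age = 2, noise_sd = 5, seed = 1) {
  set.seed(derive_seed(seed, "bic"))
  exact <- age_in <- nulls_out <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    dat <- data.frame(Age = stats::rnorm(n, 45, 12),
                      Sex = stats::rbinom(n, 1, 0.5),
                      Smoke = stats::rbinom(n, 1, 0.3))
    dat$Q <- beta_age * dat$Age + stats::rnorm(n, 0, noise_sd)
    dp <- residualize(dat, "Q", c("Age", "Sex", "Smoke"))
    age_in[r] <- "Age" %in% dp$retained_terms
    nulls_out[r] <- !any(c("Sex", "Smoke") %in% dp$retained_terms)
    exact[r] <- age_in[r] && nulls_out[r]
  }
  list(recovery_rate = mean(exact), age_retained_rate = mean(age_in),
       null_dropped_rate = mean(nulls_out), n_replicates = n_replicates)
}
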
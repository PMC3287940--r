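#' Configuration for the structured-population simulator
#'
#' Defines a mini-exome-like study: several populations, many rare variants
#' per gene, covariate effects on the trait, and optional confounds. Per
#' site, an ancestral alternate-allele frequency is drawn from a rare-skewed
#' Beta spectrum; population frequencies disperse around it following the
#' Balding-Nichols construction with divergence `divergence_F`; diploid
#' genotypes are Hardy-Weinberg draws, optionally tilted per individual
#' toward or away from heterozygosity (`het_effect_sd`) to mimic
#' coverage-artifact-like variation in called heterozygosity. The trait sums
#' causal carrier effects, covariate effects, a population mean shift, an
#' optional genome-wide-heterozygosity confound, and Gaussian noise.
#'
#' Defaults emulate the scale of a seven-population mini-exome panel
#' (about 100 individuals per population, 7 sites per gene).
#'
#' @param n_populations Number of populations.
#' @param n_per_population Individuals per population (recycled to length
#'   `n_populations`).
#' @param n_genes Number of genes.
#' @param sites_per_gene Variant sites per gene.
#' @param divergence_F Balding-Nichols divergence in `[0, 1)`.
#' @param spectrum_shape1,spectrum_shape2 Beta parameters of the ancestral
#'   alternate-allele frequency spectrum (defaults skew strongly rare).
#' @param freq_min,freq_max Clipping bounds for ancestral frequencies.
#' @param n_causal_genes Number of genes carrying trait effects.
#' @param causal_variants_per_gene Causal variants within each causal gene.
#' @param causal_beta Trait shift per carried causal variant (carrier
#'   indicator coding, matching the BMG collapsing the test targets).
#' @param causal_freq_range Pooled carrier-frequency window from which causal
#'   variants are drawn.
#' @param pop_shifts Per-population trait mean shifts (`NULL` = all zero).
#' @param age_mean,age_sd,age_pop_sd Age model: individual ages are normal
#'   around a population mean, itself drawn around `age_mean` with sd
#'   `age_pop_sd` (populations differ in age structure).
#' @param sex_prob,smoke_prob Bernoulli probabilities for the binary
#'   covariates.
#' @param beta_age,beta_sex,beta_smoke Covariate effects on the trait
#'   (per year for Age).
#' @param het_effect_sd SD of the per-individual log tilt applied to
#'   heterozygote probabilities (0 disables the heterozygosity axis).
#' @param confound_gamma Coefficient of standardized genome-wide
#'   heterozygosity in the trait (0 disables the confound).
#' @param noise_sd SD of the Gaussian trait noise.
#' @param seed Optional integer seed; `simulate_dataset()` is deterministic
#'   given it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_populations = 7, n_per_population = 100,
                              n_genes = 100, sites_per_gene = 7,
                              divergence_F = 0.1,
                              spectrum_shape1 = 0.2, spectrum_shape2 = 1.8,
                              freq_min = 0.001, freq_max = 0.5,
                              n_causal_genes = 0,
                              causal_variants_per_gene = 4,
                              causal_beta = 0.5,
                              causal_freq_range = c(0.02, 0.2),
                              pop_shifts = NULL,
                              age_mean = 45, age_sd = 12, age_pop_sd = 5,
                              sex_prob = 0.5, smoke_prob = 0.3,
                              beta_age = 0.02, beta_sex = 0, beta_smoke = 0.3,
                              het_effect_sd = 0, confound_gamma = 0,
                              noise_sd = 1, seed = NULL) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_populations >= 1, all(n_per_population >= 1), n_genes >= 1,
              sites_per_gene >= 1, divergence_F >= 0, divergence_F < 1,
              spectrum_shape1 > 0, spectrum_shape2 > 0,
              freq_min > 0, freq_max <= 0.5,
              n_causal_genes >= 0, n_causal_genes <= n_genes,
              causal_variants_per_gene >= 1,
              sex_prob >= 0, sex_prob <= 1, smoke_prob >= 0, smoke_prob <= 1,
              het_effect_sd >= 0, noise_sd > 0)
  })
  cfg$n_per_population <- rep(cfg$n_per_population,
                              length.out = cfg$n_populations)
  if (is.null(cfg$pop_shifts)) {
    cfg$pop_shifts <- rep(0, cfg$n_populations)
  } else if (length(cfg$pop_shifts) != cfg$n_populations) {
    gt_stop("pop_shifts must have one value per population")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a structured genotype/phenotype dataset with known truth
#'
#' See [simulation_config()] for the generative model. Causal genes whose
#' drawn sites contain no variant in the configured carrier-frequency window
#' have their sites redrawn (bounded retries, reported); if the window stays
#' empty the most polymorphic sites are used.
#'
#' @param config A `sim_config`.
#' @return An object of class `sim_dataset`: list with `genotypes` (a
#'   [genotype_matrix()]), `phenotypes` (data frame: id, population, Q, Age,
#'   Sex, Smoke), and `truth` (causal genes/sites/betas, the realized
#'   heterozygosity-trait correlation, and the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)

  npop <- cf$n_populations
  nper <- cf$n_per_population
  n <- sum(nper)
  pop <- rep(paste0("pop", seq_len(npop)), times = nper)
  genes <- sprintf("gene%04d", seq_len(cf$n_genes))
  spg <- cf$sites_per_gene
  S <- cf$n_genes * spg
  site_gene <- rep(genes, each = spg)
  site_pos <- as.integer(rep((seq_len(cf$n_genes) - 1) * 10000,
                             each = spg) + seq_len(spg) * 100)
  site_ids <- paste0(site_gene, "_s", rep(seq_len(spg), cf$n_genes))

  w <- exp(stats::rnorm(n, 0, cf$het_effect_sd))   # heterozygosity tilt

  draw_sites <- function(n_sites) {
    p_anc <- stats::rbeta(n_sites, cf$spectrum_shape1, cf$spectrum_shape2)
    p_anc <- pmin(pmax(p_anc, cf$freq_min), cf$freq_max)
    pf <- matrix(0, npop, n_sites)
    if (cf$divergence_F > 0) {
      a <- p_anc * (1 - cf$divergence_F) / cf$divergence_F
      b <- (1 - p_anc) * (1 - cf$divergence_F) / cf$divergence_F
      for (kpop in seq_len(npop)) pf[kpop, ] <- stats::rbeta(n_sites, a, b)
      pf <- pmin(pmax(pf, 0), 1)
    } else {
      pf <- matrix(rep(p_anc, each = npop), npop, n_sites)
    }
    list(p_anc = p_anc, pf = pf)
  }

  draw_genotypes <- function(pf, cols = seq_len(ncol(pf))) {
    G <- matrix(0L, n, length(cols))
    offset <- 0L
    for (kpop in seq_len(npop)) {
      rows <- offset + seq_len(nper[kpop])
      offset <- offset + nper[kpop]
      p <- pf[kpop, cols]
      q <- 1 - p
      q2 <- matrix(q^2, length(rows), length(cols), byrow = TRUE)
      p2 <- matrix(p^2, length(rows), length(cols), byrow = TRUE)
      het <- outer(w[rows], 2 * p * q)
      z <- q2 + het + p2
      u <- matrix(stats::runif(length(rows) * length(cols)), length(rows))
      G[rows, ] <- (u > q2 / z) + (u > (q2 + het) / z)
    }
    G
  }

  sites <- draw_sites(S)
  G <- draw_genotypes(sites$pf)

  # causal architecture: carrier indicators at selected variants
  causal_genes <- character(0)
  causal_sites <- integer(0)
  genetic <- numeric(n)
  if (cf$n_causal_genes > 0) {
    causal_genes <- sort(sample(genes, cf$n_causal_genes))
    for (cg in causal_genes) {
      cols <- which(site_gene == cg)
      carrier_freq <- colMeans(G[, cols, drop = FALSE] > 0)
      # a causal gene must segregate: redraw fully monomorphic genes
      for (attempt in seq_len(10)) {
        if (any(carrier_freq > 0 & carrier_freq < 1)) break
        message("causal gene ", cg, " monomorphic; redrawing its sites ",
                "(attempt ", attempt, ")")
        redraw <- draw_sites(length(cols))
        sites$pf[, cols] <- redraw$pf
        sites$p_anc[cols] <- redraw$p_anc
        G[, cols] <- draw_genotypes(sites$pf, cols)
        carrier_freq <- colMeans(G[, cols, drop = FALSE] > 0)
      }
      if (all(carrier_freq %in% c(0, 1))) {
        gt_stop("causal gene ", cg, " stayed monomorphic after 10 redraws; ",
                "widen the frequency spectrum")
      }
      nv <- cf$causal_variants_per_gene
      ok <- which(carrier_freq >= cf$causal_freq_range[1] &
                    carrier_freq <= cf$causal_freq_range[2])
      picked <- if (length(ok) > nv) ok[sample.int(length(ok), nv)] else ok
      if (length(picked) < nv) {
        # top up with the most polymorphic remaining sites
        extra <- setdiff(order(-pmin(carrier_freq, 1 - carrier_freq)), picked)
        extra <- extra[carrier_freq[extra] > 0 & carrier_freq[extra] < 1]
        picked <- c(picked, extra[seq_len(min(length(extra),
                                              nv - length(picked)))])
      }
      pick <- cols[sort(picked)]
      causal_sites <- c(causal_sites, pick)
      genetic <- genetic +
        cf$causal_beta * rowSums(G[, pick, drop = FALSE] > 0)
    }
  }

  age_pop_means <- stats::rnorm(npop, cf$age_mean, cf$age_pop_sd)
  Age <- stats::rnorm(n, rep(age_pop_means, times = nper), cf$age_sd)
  Sex <- stats::rbinom(n, 1, cf$sex_prob)
  Smoke <- stats::rbinom(n, 1, cf$smoke_prob)
  het <- rowMeans(G == 1L)
  het_std <- if (stats::sd(het) > 0) as.numeric(scale(het)) else numeric(n)

  Q <- rep(cf$pop_shifts, times = nper) +
    cf$beta_age * (Age - cf$age_mean) + cf$beta_sex * Sex +
    cf$beta_smoke * Smoke + genetic +
    cf$confound_gamma * het_std +
    stats::rnorm(n, 0, cf$noise_sd)

  ids <- sprintf("ind%04d", seq_len(n))
  g <- genotype_matrix(G, site_ids, site_pos, site_gene, ids, pop)
  phen <- data.frame(id = ids, population = pop, Q = Q, Age = Age,
                     Sex = Sex, Smoke = Smoke)
  truth <- list(causal_genes = causal_genes,
                causal_sites = site_ids[causal_sites],
                causal_beta = cf$causal_beta,
                het_trait_correlation = if (stats::sd(het) > 0)
                  stats::cor(Q, het) else NA_real_,
                config = unclass(cf))
  structure(list(genotypes = g, phenotypes = phen, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", length(x$genotypes$individual_ids), "individuals,",
      length(unique(x$genotypes$site_gene)), "genes,",
      length(x$truth$causal_genes), "causal\n")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genotypes.tsv` (or `genotypes.vcf`), `gene_map.tsv`,
#' `phenotypes.tsv`, and `truth.json` into `out_dir`; files round-trip
#' through [read_genotype_tsv()] / [read_vcf()] and [read_phenotype_tsv()].
#'
#' @param d A `sim_dataset`.
#' @param out_dir Output directory (created if needed).
#' @param genotype_format `"tsv"` or `"vcf"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(d, out_dir, genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- d$genotypes
  paths <- c(gene_map = file.path(out_dir, "gene_map.tsv"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             truth = file.path(out_dir, "truth.json"))
  utils::write.table(data.frame(gene = g$site_gene, site_id = g$site_ids),
                     paths["gene_map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(d$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- d$truth
  truth$config$seed <- if (is.null(truth$config$seed)) NA else
    truth$config$seed
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (genotype_format == "tsv") {
    paths["genotypes"] <- file.path(out_dir, "genotypes.tsv")
    tab <- data.frame(id = g$individual_ids, g$genotypes,
                      check.names = FALSE)
    utils::write.table(tab, paths["genotypes"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    paths["genotypes"] <- file.path(out_dir, "genotypes.vcf")
    write_vcf(g, paths["genotypes"])
  }
  invisible(paths)
}

#' Write a genotype matrix as a minimal VCF (v4.2)
#'
#' Biallelic sites on one chromosome with GT-only genotypes; allele counts
#' 0/1/2 map to `0/0`, `0/1`, `1/1` and missing to `./.`.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(g, path) {
  m <- g$genotypes
  gt <- matrix("./.", nrow(m), ncol(m))
  gt[!is.na(m) & m == 0L] <- "0/0"
  gt[!is.na(m) & m == 1L] <- "0/1"
  gt[!is.na(m) & m == 2L] <- "1/1"
  body <- vapply(seq_len(ncol(m)), function(j) {
    paste(c("1", g$site_positions[j], g$site_ids[j], "A", "T", ".", "PASS",
            ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  # VCF requires rows sorted by position
  body <- body[order(g$site_positions)]
  writeLines(c("##fileformat=VCFv4.2",
               "##source=genotree",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$individual_ids), collapse = "\t"),
               body), path)
  invisible(path)
}
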
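#' Per-individual heterozygosity
#'
#' The fraction of an individual's non-missing sites with allele count
#' exactly 1, averaged over all sites. Genome-wide heterozygosity can act as
#' a trait confounder (e.g. through coverage-dependent variant calling), and
#' this statistic is what the principal-component correction is meant to
#' absorb.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector, one value per individual (`NA`, with a
#'   warning, for individuals whose genotypes are all missing).
#' @export
individual_heterozygosity <- function(g) {
  m <- g$genotypes
  nonmiss <- rowSums(!is.na(m))
  out <- rowSums(m == 1L, na.rm = TRUE) / nonmiss
  if (any(nonmiss == 0)) {
    warning(sum(nonmiss == 0), " individual(s) with all genotypes missing")
    out[nonmiss == 0] <- NA_real_
  }
  stats::setNames(out, g$individual_ids)
}

#' Principal-component loadings of the allele-count matrix
#'
#' Individual scores from a PCA of the column-centred allele counts (missing
#' entries are imputed with the site mean before centring). Component signs
#' are fixed deterministically: the largest-magnitude element of each
#' rotation vector is made positive.
#'
#' @param g A [genotype_matrix()].
#' @param n_components Number of components to return (default 6).
#' @return List with `scores` (individuals x components, columns `PC1..`),
#'   `variance_fraction` (per returned component), and `sdev`.
#' @export
pc_loadings <- function(g, n_components = 6) {
  m <- g$genotypes
  if (nrow(m) < n_components) {
    gt_stop("need at least as many individuals as components")
  }
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  if (all(apply(m, 2, function(col) length(unique(col))) == 1L)) {
    gt_stop("constant genotype matrix: PCA is degenerate")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2,
                  flip[seq_len(n_components)], `*`)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- g$individual_ids
  total_var <- sum(pc$sdev^2)
  list(scores = scores,
       variance_fraction = pc$sdev[seq_len(n_components)]^2 / total_var,
       sdev = pc$sdev[seq_len(n_components)])
}

#' Derived (residual) phenotype by backwards stepwise BIC selection
#'
#' Fits the full linear model `trait ~ candidates`, then repeatedly removes
#' the term whose removal most decreases the Bayesian information criterion,
#' stopping when no removal decreases it (ties are broken by dropping the
#' term with the smallest absolute t statistic). The derived phenotype is the
#' vector of standardized residuals (mean 0, sample sd 1) of the retained
#' model, used in place of the raw trait to control covariate- and
#' structure-driven confounding.
#'
#' @param data Data frame containing the trait and all candidate columns.
#' @param trait Name of the trait column.
#' @param candidates Character vector of candidate term names (e.g.
#'   `c("Age", "Sex", "Smoke", "PC1", ...)`). Aliased (perfectly collinear)
#'   terms are dropped up front with a message.
#' @param name Optional label for the derived phenotype.
#' @return An object of class `derived_phenotype`: list with `name`,
#'   `base_trait`, `retained_terms`, `coefficients`, `residual_sd` (the
#'   fitted noise scale of the retained model), `bic_trace`, and `values`
#'   (standardized residuals).
#' @export
residualize <- function(data, trait, candidates,
                        name = paste0(trait, ".resid")) {
  if (!trait %in% names(data)) gt_stop("trait column not found: ", trait)
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols)) {
    gt_stop("candidate column(s) not in data: ",
            paste(missing_cols, collapse = ", "))
  }
  n <- nrow(data)
  if (n <= length(candidates) + 1) {
    gt_stop("insufficient data: n must exceed the number of candidates + 1")
  }
  candidates <- sort(unique(candidates))  # selection is order-invariant anyway
  fit <- stats::lm(stats::reformulate(c("1", candidates), trait), data = data)
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased)) {
    message("dropping aliased term(s): ", paste(aliased, collapse = ", "))
    candidates <- setdiff(candidates, aliased)
    fit <- stats::lm(stats::reformulate(c("1", candidates), trait),
                     data = data)
  }
  terms_now <- candidates
  trace <- data.frame(step = 0L, dropped = NA_character_, bic = stats::BIC(fit))
  step <- 0L
  while (length(terms_now) > 0) {
    bic_now <- stats::BIC(fit)
    drops <- vapply(terms_now, function(tm) {
      stats::BIC(stats::update(fit, stats::as.formula(paste(". ~ . -", tm))))
    }, numeric(1))
    best <- min(drops)
    if (best >= bic_now) break
    cand <- terms_now[drops == best]
    if (length(cand) > 1) {                 # tie: weakest |t| goes
      tstats <- summary(fit)$coefficients[, "t value"]
      cand <- cand[which.min(abs(tstats[cand]))]
    } else {
      cand <- cand[1]
    }
    fit <- stats::update(fit, stats::as.formula(paste(". ~ . -", cand)))
    terms_now <- setdiff(terms_now, cand)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = cand,
                                     bic = stats::BIC(fit)))
  }
  res <- stats::residuals(fit)
  structure(list(name = name, base_trait = trait,
                 retained_terms = terms_now,
                 coefficients = coef(fit),
                 residual_sd = summary(fit)$sigma,
                 bic_trace = trace,
                 values = as.numeric(scale(res))),
            class = "derived_phenotype")
}

#' @export
print.derived_phenotype <- function(x, ...) {
  cat("derived_phenotype", x$name, ": ", x$base_trait, "~",
      if (length(x$retained_terms)) paste(x$retained_terms, collapse = " + ")
      else "1", "\n")
  cat("  residual sd:", signif(x$residual_sd, 4), "  n:", length(x$values),
      "\n")
  invisible(x)
}

#' Refit a selected residual model on new data
#'
#' Re-estimates the coefficients of an already-selected model (no
#' re-selection) on a new phenotype table and returns the standardized
#' residuals, the intended workflow when one data set chooses the model and
#' replicate data sets reuse it.
#'
#' @param model A `derived_phenotype` (its `retained_terms` are reused).
#' @param newdata Data frame containing the base trait and every retained
#'   term.
#' @return A new `derived_phenotype` fitted to `newdata`.
#' @export
refit_selected <- function(model, newdata) {
  needed <- c(model$base_trait, model$retained_terms)
  missing_cols <- setdiff(needed, names(newdata))
  if (length(missing_cols)) {
    gt_stop("newdata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(c("1", model$retained_terms),
                                      model$base_trait), data = newdata)
  structure(list(name = model$name, base_trait = model$base_trait,
                 retained_terms = model$retained_terms,
                 coefficients = coef(fit),
                 residual_sd = summary(fit)$sigma,
                 bic_trace = NULL,
                 values = as.numeric(scale(stats::residuals(fit)))),
            class = "derived_phenotype")
}
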
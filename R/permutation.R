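#' Randomly relabel a trait within population strata
#'
#' Each stratum's trait values are independently and uniformly permuted among
#' its own members; across strata nothing is exchanged, so every stratum's
#' trait multiset (hence mean and standard deviation) is preserved exactly in
#' every replicate. Singleton strata are fixed points.
#'
#' @param trait Numeric trait vector.
#' @param strata Stratum (population) label per individual; `NULL` means one
#'   stratum (plain permutation).
#' @return The permuted trait vector.
#' @export
stratified_permutation <- function(trait, strata = NULL) {
  if (is.null(strata)) return(trait[sample.int(length(trait))])
  if (length(strata) != length(trait)) {
    gt_stop("strata must have one label per individual")
  }
  out <- trait
  for (idx in split(seq_along(trait), as.character(strata))) {
    out[idx] <- trait[idx[sample.int(length(idx))]]
  }
  out
}

#' Permutation test of the tree scan statistic for one gene
#'
#' The genotype tree is fixed; each replicate relabels the trait within
#' strata, re-scores every node and recomputes \eqn{S_1 \dots S_k}
#' (implemented in compiled code; see [best_disjoint()] for the statistic).
#' p-values use the add-one estimator
#' \eqn{p_j = (1 + \#\{S_j^* \ge S_j\}) / (n_{reps} + 1)}, which is never
#' zero and is a valid permutation p-value; the minimum attainable value is
#' \eqn{1 / (n_{reps} + 1)}.
#'
#' @param t A `genotype_tree`.
#' @param trait Numeric vector over the tree's individuals.
#' @param strata Population label per individual, or `NULL` for unstratified
#'   permutation.
#' @param k Disjoint-node budget (default 10).
#' @param f_spec Score transform, see [transform_scores()].
#' @param n_reps Number of permutation replicates (>= 1).
#' @param seed Optional integer seed (set before the replicate stream).
#' @param keep_replicates Return the replicate S matrix (n_reps x k)?
#' @return An object of class `permutation_result`: list with `gene`,
#'   `n_reps`, `observed` (a `scan_stats`), `p_values` (length k), `seed`,
#'   and optionally `replicates`.
#' @export
permutation_test <- function(t, trait, strata = NULL, k = 10,
                             f_spec = "square", n_reps = 1000, seed = NULL,
                             keep_replicates = FALSE) {
  if (!is.numeric(n_reps) || n_reps < 1) gt_stop("n_reps must be >= 1")
  n_ind <- length(t$members[[1]])
  if (length(trait) != n_ind) {
    gt_stop("trait length does not match the tree's individuals")
  }
  if (!is.null(strata) && length(strata) != n_ind) {
    gt_stop("strata length does not match the tree's individuals")
  }
  stats_df <- compute_node_stats(t, trait, f_spec)
  observed <- best_disjoint(t, stats_df$score, k)

  strata_idx <- if (is.null(strata)) list(seq_len(n_ind)) else
    split(seq_len(n_ind), as.character(strata))
  singletons <- sum(lengths(strata_idx) == 1L)
  if (singletons > 0) {
    message(singletons, " singleton stratum(s): fixed points under permutation")
  }
  if (!is.null(seed)) set.seed(seed)
  res <- perm_scan_cpp(t$child0, t$child1, t$leaf_of, as.numeric(trait),
                       strata_idx, as.integer(k), f_spec_code(f_spec),
                       as.integer(n_reps), isTRUE(keep_replicates))
  if (max(abs(res$S_obs - observed$S)) > 1e-8 * (1 + max(abs(observed$S)))) {
    gt_stop("internal inconsistency between scoring paths")  # nocov
  }
  out <- list(gene = t$gene, n_reps = as.integer(n_reps), observed = observed,
              p_values = (1 + res$exceed) / (n_reps + 1),
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  if (keep_replicates) out$replicates <- res$replicates
  structure(out, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result for gene", x$gene, "(", x$n_reps, "replicates )\n")
  cat("  S:", paste(signif(x$observed$S, 4), collapse = " "), "\n")
  cat("  p:", paste(signif(x$p_values, 4), collapse = " "), "\n")
  invisible(x)
}

#' Genome scan: one permutation test per gene
#'
#' Recode, build the tree, and run the stratified permutation test for every
#' gene of a genotype matrix. Each gene draws its permutations from a seed
#' derived deterministically from the master seed and the gene label
#' ([derive_seed()]), so results are identical whatever the evaluation order
#' and genes can be processed in parallel or in chunks. Genes whose recoded
#' BMGs are all identical (no polymorphic site) are flagged degenerate and
#' reported with S = 0 and p = 1 without spending permutations.
#'
#' @param g A [genotype_matrix()].
#' @param phenotypes Data frame with columns `id`, `population`, the trait,
#'   and any covariates; joined to `g` via [join_phenotypes()].
#' @param trait Name of the trait column.
#' @param strata_column Column holding the permutation strata (default
#'   `"population"`); `NULL` requests unstratified permutation.
#' @param k,f_spec,n_reps See [permutation_test()].
#' @param seed Master seed (integer).
#' @param polarize,missing_policy Passed to [recode_to_bmg()].
#' @param site_order Passed to [build_tree()] (`NULL` = genomic order).
#' @param genes Optional subset of gene labels to scan.
#' @return A data frame with one row per gene: `gene`, `n_sites`, `n_leaves`,
#'   `S_1..S_k`, `p_1..p_k`, `best_set` (semicolon-joined node ids of the
#'   budget-k maximiser), `degenerate`, `seed`.
#' @export
scan_genes <- function(g, phenotypes, trait, strata_column = "population",
                       k = 10, f_spec = "square", n_reps = 1000, seed = 1,
                       polarize = FALSE, missing_policy = "as_common",
                       site_order = NULL, genes = NULL) {
  if (!trait %in% names(phenotypes)) gt_stop("trait column not found: ", trait)
  joined <- join_phenotypes(g, phenotypes)
  g <- joined$genotypes
  ph <- joined$phenotypes
  x <- as.numeric(ph[[trait]])
  if (anyNA(x) || any(!is.finite(x))) gt_stop("trait has missing/non-finite values")
  strata <- if (is.null(strata_column)) NULL else {
    if (!strata_column %in% names(ph)) {
      gt_stop("strata column not found: ", strata_column)
    }
    as.character(ph[[strata_column]])
  }
  all_genes <- unique(g$site_gene)
  if (!is.null(genes)) {
    missing <- setdiff(genes, all_genes)
    if (length(missing)) gt_stop("unknown gene(s): ",
                                 paste(missing, collapse = ", "))
    all_genes <- genes
  }
  k <- as.integer(k)

  rows <- lapply(all_genes, function(gene) {
    b <- suppressMessages(recode_to_bmg(g, gene, polarize = polarize,
                                        missing_policy = missing_policy))
    poly <- any(colSums(b$codes) > 0 & colSums(b$codes) < nrow(b$codes))
    gene_seed <- derive_seed(seed, gene)
    if (!poly) {
      return(data.frame(gene = gene, n_sites = ncol(b$codes), n_leaves = 1L,
                        rbind(stats::setNames(rep(0, k), paste0("S_", 1:k))),
                        rbind(stats::setNames(rep(1, k), paste0("p_", 1:k))),
                        best_set = "", degenerate = TRUE, seed = gene_seed))
    }
    tr <- build_tree(b, site_order = site_order)
    pr <- suppressMessages(
      permutation_test(tr, x, strata = strata, k = k, f_spec = f_spec,
                       n_reps = n_reps, seed = gene_seed))
    data.frame(gene = gene, n_sites = ncol(b$codes),
               n_leaves = sum(is.na(tr$child0)),
               rbind(stats::setNames(pr$observed$S, paste0("S_", 1:k))),
               rbind(stats::setNames(pr$p_values, paste0("p_", 1:k))),
               best_set = paste(pr$observed$best_sets[[k]], collapse = ";"),
               degenerate = FALSE, seed = gene_seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "master_seed") <- as.integer(seed)
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_genes Number of genes tested (>= 1).
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(alpha, n_genes) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    gt_stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(n_genes) || n_genes < 1) gt_stop("n_genes must be >= 1")
  alpha / n_genes
}

#' Write a genome-scan results table as TSV with a provenance header
#'
#' @param results A data frame from [scan_genes()].
#' @param path Output path.
#' @param seed Master seed to record (defaults to the attribute stored by
#'   [scan_genes()]).
#' @return The path, invisibly.
#' @export
write_scan_tsv <- function(results, path,
                           seed = attr(results, "master_seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# genotree scan ",
                      as.character(utils::packageVersion("genotree"))),
               paste0("# master_seed=", if (is.null(seed)) "NA" else seed)),
             con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
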
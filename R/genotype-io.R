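#' Construct a genotype matrix
#'
#' The raw-data container: an individuals-by-sites matrix of alternate-allele
#' counts (0, 1, 2, or `NA` for a missing genotype) together with site and
#' individual metadata. Columns are re-ordered so that sites belonging to one
#' gene are contiguous (genes in order of first appearance) and strictly
#' increasing by genomic position within each gene; duplicated positions
#' within a gene are rejected.
#'
#' @param genotypes Integer matrix, individuals in rows, sites in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param site_ids Character vector of unique site identifiers (one per column).
#' @param site_positions Integer genomic coordinates (1-based, as in VCF).
#' @param site_gene Gene label per site.
#' @param individual_ids Unique identifiers, one per row.
#' @param population Population label per individual (non-empty strings).
#'   Defaults to a single `"unspecified"` stratum when the source format
#'   carries no population column; labels are normally supplied by the
#'   phenotype table at join time.
#' @return An object of class `genotype_matrix`.
#' @seealso [read_genotype_tsv()], [read_vcf()], [recode_to_bmg()]
#' @export
genotype_matrix <- function(genotypes, site_ids, site_positions, site_gene,
                            individual_ids,
                            population = rep("unspecified", nrow(genotypes))) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (length(site_ids) != p || length(site_positions) != p ||
      length(site_gene) != p) {
    gt_stop("site metadata length does not match the number of genotype columns")
  }
  if (length(individual_ids) != n || length(population) != n) {
    gt_stop("individual metadata length does not match the number of rows")
  }
  if (anyDuplicated(individual_ids)) gt_stop("individual ids must be unique")
  if (anyDuplicated(site_ids)) gt_stop("site ids must be unique")
  if (any(!is.na(genotypes) & !(genotypes %in% 0:2))) {
    bad <- genotypes[!is.na(genotypes) & !(genotypes %in% 0:2)][1]
    gt_stop("allele counts must be 0, 1, 2 or NA; found ", bad)
  }
  population <- as.character(population)
  if (any(is.na(population) | !nzchar(population))) {
    gt_stop("population labels must be non-empty")
  }
  site_gene <- as.character(site_gene)
  site_positions <- as.integer(site_positions)

  # canonical column order: genes by first appearance, positions within gene
  gene_rank <- match(site_gene, unique(site_gene))
  ord <- order(gene_rank, site_positions)
  genotypes <- genotypes[, ord, drop = FALSE]
  site_ids <- site_ids[ord]
  site_positions <- site_positions[ord]
  site_gene <- site_gene[ord]
  dup <- stats::ave(site_positions, site_gene,
                    FUN = function(x) duplicated(x)) > 0
  if (any(dup)) {
    gt_stop("duplicated site position within gene ", site_gene[which(dup)[1]])
  }
  dimnames(genotypes) <- list(as.character(individual_ids), site_ids)

  structure(list(genotypes = genotypes,
                 site_ids = site_ids,
                 site_positions = site_positions,
                 site_gene = site_gene,
                 individual_ids = as.character(individual_ids),
                 population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individual_ids), "individuals x",
      length(x$site_ids), "sites,", length(unique(x$site_gene)), "genes,",
      length(unique(x$population)), "population(s)\n")
  nm <- sum(is.na(x$genotypes))
  if (nm > 0) cat("  missing genotypes:", nm, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix by individuals
#'
#' @param g A `genotype_matrix`.
#' @param idx Integer or logical index over individuals.
#' @return A `genotype_matrix` restricted to the selected rows.
#' @export
subset_individuals <- function(g, idx) {
  genotype_matrix(g$genotypes[idx, , drop = FALSE],
                  g$site_ids, g$site_positions, g$site_gene,
                  g$individual_ids[idx], g$population[idx])
}

#' Read a genotype matrix from a TSV file
#'
#' Expects a header row with an `id` column followed by one column per site,
#' and one row per individual; entries must be 0, 1, 2 or NA.
#'
#' @param path Path to the TSV file.
#' @param gene_map Optional data frame from [read_gene_map()] assigning sites
#'   to genes. Without it every site is placed in a single gene `"all"`.
#' @param positions Optional integer positions per site; defaults to column
#'   order.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, gene_map = NULL, positions = NULL) {
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) != 1L) {
    bad <- which(fields != fields[1])[1]
    gt_stop("ragged TSV: row ", bad, " of ", path, " has ", fields[bad],
            " fields, expected ", fields[1])
  }
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"id" %in% names(tab)) {
    gt_stop("genotype TSV must have an 'id' column: ", path)
  }
  ids <- tab$id
  tab <- tab[, setdiff(names(tab), "id"), drop = FALSE]
  m <- suppressWarnings(matrix(as.integer(as.matrix(tab)), nrow = nrow(tab)))
  raw <- as.matrix(tab)
  bad <- !is.na(raw) & toupper(raw) != "NA" & is.na(m)
  if (any(bad)) gt_stop("non-numeric genotype entry '", raw[bad][1], "' in ", path)
  out_of_range <- !is.na(m) & !(m %in% 0:2)
  if (any(out_of_range)) {
    gt_stop("allele count out of range in ", path, ": ", m[out_of_range][1])
  }
  site_ids <- names(tab)
  if (is.null(positions)) positions <- seq_along(site_ids)
  site_gene <- map_sites_to_genes(site_ids, positions, gene_map)
  keep <- !is.na(site_gene)
  if (!all(keep)) {
    message(sum(!keep), " site(s) not mapped to any gene; dropped")
    if (!any(keep)) gt_stop("no sites mapped to any gene")
  }
  g <- genotype_matrix(m[, keep, drop = FALSE], site_ids[keep],
                       positions[keep], site_gene[keep], ids)
  message("read ", length(g$individual_ids), " individuals x ",
          length(g$site_ids), " sites from ", path)
  g
}

#' Read a gene map
#'
#' Two layouts are accepted: explicit site assignment with columns
#' `gene`, `site_id`; or BED-like intervals with columns `gene`, `chrom`,
#' `start`, `end` (1-based inclusive), matched on position.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame with class attribute recording the layout.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (all(c("gene", "site_id") %in% names(tab))) {
    attr(tab, "layout") <- "site_id"
  } else if (all(c("gene", "chrom", "start", "end") %in% names(tab))) {
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
    attr(tab, "layout") <- "interval"
  } else {
    gt_stop("gene map needs columns (gene, site_id) or (gene, chrom, start, end)")
  }
  tab
}

# internal: assign a gene label (or NA) to each site
map_sites_to_genes <- function(site_ids, positions, gene_map,
                               chrom = rep("1", length(site_ids))) {
  if (is.null(gene_map)) return(rep("all", length(site_ids)))
  layout <- attr(gene_map, "layout")
  if (is.null(layout)) {
    layout <- if ("site_id" %in% names(gene_map)) "site_id" else "interval"
  }
  if (layout == "site_id") {
    gene_map$gene[match(site_ids, gene_map$site_id)]
  } else {
    out <- rep(NA_character_, length(site_ids))
    for (r in seq_len(nrow(gene_map))) {
      hit <- chrom == gene_map$chrom[r] &
        positions >= gene_map$start[r] & positions <= gene_map$end[r]
      out[hit & is.na(out)] <- gene_map$gene[r]
    }
    out
  }
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF (v4.x) into alternate-allele counts: any
#' non-reference allele counts as alternate, so a `1/2` genotype at a
#' multi-allelic site is 2 and `./.` is missing. Sites are assigned to genes
#' through `gene_map`; unmapped sites are dropped with a message.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param gene_map A gene map from [read_gene_map()] (or an equivalent data
#'   frame); `NULL` puts every site in one gene `"all"`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, gene_map = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) gt_stop("malformed VCF ", path, ": ",
                                              conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) gt_stop("VCF has no GT genotypes: ", path)
  site_ids <- fix[, "ID"]
  noid <- is.na(site_ids) | site_ids == "."
  site_ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  positions <- as.integer(fix[, "POS"])

  # map every distinct GT string once, then index
  codes <- unique(as.vector(gt))
  counts <- vapply(codes, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(gsub("\\|", "/", s), "/", fixed = TRUE)[[1]]
    if (any(al == "." | al == "")) return(NA_integer_)
    sum(al != "0")
  }, integer(1))
  m <- matrix(counts[match(as.vector(gt), codes)], nrow = nrow(gt))
  m <- t(m)  # individuals x sites

  site_gene <- map_sites_to_genes(site_ids, positions, gene_map,
                                  chrom = fix[, "CHROM"])
  keep <- !is.na(site_gene)
  if (!any(keep)) gt_stop("no VCF sites mapped to any gene")
  if (!all(keep)) message(sum(!keep), " VCF site(s) not in the gene map; dropped")
  genotype_matrix(m[, keep, drop = FALSE], site_ids[keep], positions[keep],
                  site_gene[keep], colnames(gt))
}

#' Read a phenotype/covariate table
#'
#' @param path TSV with a header containing at least `id` and `population`;
#'   remaining columns are traits and covariates (e.g. Age, Sex, Smoke).
#' @return A data frame.
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("id", "population") %in% names(tab))) {
    gt_stop("phenotype table needs 'id' and 'population' columns: ", path)
  }
  tab$id <- as.character(tab$id)
  tab$population <- as.character(tab$population)
  tab
}

#' Join a genotype matrix with a phenotype table
#'
#' Restricts both objects to the individuals present in both (dropped rows are
#' reported), aligns the phenotype rows to the genotype row order, and copies
#' the phenotype table's population labels onto the genotype matrix.
#'
#' @param g A `genotype_matrix`.
#' @param phenotypes A data frame with columns `id` and `population`.
#' @return A list with elements `genotypes` and `phenotypes`, row-aligned.
#' @export
join_phenotypes <- function(g, phenotypes) {
  idx <- match(g$individual_ids, phenotypes$id)
  drop_g <- is.na(idx)
  if (any(drop_g)) {
    message(sum(drop_g), " genotyped individual(s) missing from the ",
            "phenotype table; dropped")
    if (all(drop_g)) gt_stop("no individuals shared between genotypes and phenotypes")
    g <- subset_individuals(g, !drop_g)
    idx <- idx[!drop_g]
  }
  ph <- phenotypes[idx, , drop = FALSE]
  cc <- stats::complete.cases(ph)
  if (!all(cc)) {
    message(sum(!cc), " individual(s) with missing phenotype/covariate values; dropped")
    g <- subset_individuals(g, cc)
    ph <- ph[cc, , drop = FALSE]
  }
  g$population <- as.character(ph$population)
  rownames(ph) <- NULL
  list(genotypes = g, phenotypes = ph)
}

#' Recode allele counts into a binary multilocus genotype (BMG) matrix
#'
#' At each site of the gene an individual is coded 0 if homozygous for the
#' common allele and 1 otherwise (i.e. 1 marks carriers of at least one copy
#' of the rarer allele). The per-gene vectors of these bits are the binary
#' multilocus genotypes on which genotype trees are built.
#'
#' @param g A [genotype_matrix()].
#' @param gene Gene label to extract.
#' @param polarize If `FALSE` (default) the reference allele is taken as the
#'   common allele, so bit = `allele count != 0`. If `TRUE` the sample-major
#'   allele is taken as common at each site (ties keep the reference), so at
#'   sites where the alternate allele is the majority the bit is
#'   `allele count != 2`.
#' @param missing_policy `"as_common"` treats a missing genotype as homozygous
#'   common (bit 0; the count of affected entries is reported), `"error"`
#'   refuses missing data.
#' @param drop_monomorphic Drop sites whose recoded bits are constant across
#'   individuals. They never split a tree node, so this only shortens codes.
#' @return An object of class `bmg_matrix`: list with `gene`, `codes`
#'   (individuals x sites 0/1 integer matrix), `site_ids`.
#' @examples
#' g <- example_genotype_matrix()
#' b <- recode_to_bmg(g, "exampleGene")
#' table(apply(b$codes, 1, paste, collapse = "-"))
#' @export
recode_to_bmg <- function(g, gene, polarize = FALSE,
                          missing_policy = c("as_common", "error"),
                          drop_monomorphic = FALSE) {
  missing_policy <- match.arg(missing_policy)
  sites <- which(g$site_gene == gene)
  if (length(sites) == 0) gt_stop("gene not found: ", gene)
  counts <- g$genotypes[, sites, drop = FALSE]
  if (anyNA(counts)) {
    if (missing_policy == "error") {
      w <- which(is.na(counts), arr.ind = TRUE)[1, ]
      gt_stop("missing genotype at site ", colnames(counts)[w[2]],
              " for individual ", rownames(counts)[w[1]])
    }
    message(sum(is.na(counts)), " missing genotype(s) in ", gene,
            " treated as homozygous common")
  }
  if (polarize) {
    alt_freq <- colMeans(counts, na.rm = TRUE) / 2
    alt_freq[is.nan(alt_freq)] <- 0
    alt_common <- alt_freq > 0.5            # tie keeps the reference as common
    bits <- matrix(0L, nrow(counts), ncol(counts))
    bits[, !alt_common] <- (counts[, !alt_common, drop = FALSE] != 0L) * 1L
    bits[, alt_common] <- (counts[, alt_common, drop = FALSE] != 2L) * 1L
  } else {
    bits <- (counts != 0L) * 1L
  }
  bits[is.na(bits)] <- 0L
  if (drop_monomorphic) {
    poly <- colSums(bits) > 0 & colSums(bits) < nrow(bits)
    bits <- bits[, poly, drop = FALSE]
    sites <- sites[poly]
  }
  bmg_matrix(gene, bits, g$site_ids[sites])
}

#' Construct a BMG matrix
#'
#' @param gene Gene label.
#' @param codes Integer 0/1 matrix, individuals x sites.
#' @param site_ids Site identifiers in column order.
#' @return An object of class `bmg_matrix`.
#' @export
bmg_matrix <- function(gene, codes, site_ids) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (anyNA(codes) || any(!(codes %in% 0:1))) gt_stop("BMG bits must be 0 or 1")
  if (length(site_ids) != ncol(codes)) {
    gt_stop("site_ids length must equal the number of code columns")
  }
  colnames(codes) <- site_ids
  structure(list(gene = gene, codes = codes, site_ids = as.character(site_ids)),
            class = "bmg_matrix")
}

#' @export
print.bmg_matrix <- function(x, ...) {
  cat("bmg_matrix for gene", x$gene, ":", nrow(x$codes), "individuals x",
      ncol(x$codes), "sites,",
      nrow(unique(x$codes)), "distinct codes\n")
  invisible(x)
}
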
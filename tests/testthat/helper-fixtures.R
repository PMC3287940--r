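# fixtures are generated in code; callers set the seed

random_bmg <- function(n_ind, n_sites, gene = "g") {
  freq <- runif(n_sites, 0.1, 0.9)
  codes <- vapply(freq, function(p) rbinom(n_ind, 1, p), integer(n_ind))
  bmg_matrix(gene, matrix(codes, n_ind), paste0("s", seq_len(n_sites)))
}

# a genotype tree with at most max_nodes nodes (resamples until small enough)
random_tree <- function(max_nodes = 25, n_ind = NULL, n_sites = NULL) {
  repeat {
    b <- random_bmg(if (is.null(n_ind)) sample(4:12, 1) else n_ind,
                    if (is.null(n_sites)) sample(2:5, 1) else n_sites)
    t <- build_tree(b)
    if (t$n_nodes <= max_nodes) return(t)
  }
}

# direct (non-bottom-up) node z computation used as an oracle
direct_node_stats <- function(tree, trait, f_spec = "square") {
  z <- vapply(tree$members, node_z, numeric(1), trait = trait)
  data.frame(node_id = seq_len(tree$n_nodes), z = z,
             score = transform_scores(z, f_spec))
}

# minimal multi-allelic VCF text fixture exercising GT parsing corner cases
vcf_fixture_lines <- function() {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "indA", "indB", "indC"), collapse = "\t"),
    paste(c("1", "101", "rs1", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("1", "202", "rs2", "G", "T,C", ".", "PASS", ".", "GT",
            "1/2", "0|2", "./."), collapse = "\t"))
}
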
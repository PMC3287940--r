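#' Worked-example genotype counts
#'
#' A small four-site gene observed in 100 individuals (51 controls, 49
#' cases), summarised at the level of binary multilocus genotype codes. Six
#' distinct codes occur; several different allele-count genotypes (e.g.
#' `0-0-1-0` and `0-0-2-0`) collapse to the same code because any
#' variant-carrying genotype is coded 1.
#'
#' @return Data frame with columns `code`, `controls`, `cases`.
#' @examples
#' sum(example_genotype_counts()[, c("controls", "cases")])  # 100
#' @export
example_genotype_counts <- function() {
  data.frame(
    code     = c("0-0-0-0", "0-0-0-1", "0-0-1-0", "0-0-1-1", "0-1-0-0",
                 "1-0-0-0"),
    controls = c(27L, 7L, 4L, 0L, 9L, 4L),
    cases    = c(18L, 8L, 13L, 6L, 4L, 0L))
}

#' Expand the worked-example counts into a genotype matrix
#'
#' One individual per count, with allele counts equal to the code bits (all
#' carriers heterozygous) and case/control status carried in the population
#' column (`"control"` / `"case"`).
#'
#' @return A [genotype_matrix()] of 100 individuals at 4 sites in one gene
#'   `"exampleGene"`.
#' @export
example_genotype_matrix <- function() {
  tab <- example_genotype_counts()
  codes <- do.call(rbind, lapply(strsplit(tab$code, "-"), as.integer))
  reps <- tab$controls + tab$cases
  m <- codes[rep(seq_len(nrow(codes)), times = reps), , drop = FALSE]
  status <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    rep(c("control", "case"), times = c(tab$controls[i], tab$cases[i]))
  }))
  genotype_matrix(m,
                  site_ids = paste0("site", 1:4),
                  site_positions = 1:4,
                  site_gene = rep("exampleGene", 4),
                  individual_ids = sprintf("ind%03d", seq_len(nrow(m))),
                  population = status)
}
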
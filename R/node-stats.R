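#' z score of a node's trait mean
#'
#' The partial test statistic at a tree node: with \eqn{x_{ij}}, j = 1..n_i
#' the trait values of the node's members,
#' \deqn{z_i = \sqrt{n_i}\,(\bar x_i - \bar x)/s,}
#' where \eqn{\bar x} and s are the sample mean and (n-1 denominator)
#' standard deviation of the trait over all individuals. A node containing
#' every individual therefore scores exactly 0, and z is invariant under
#' positive affine transforms of the trait.
#'
#' @param members Integer indices of the node's individuals.
#' @param trait Numeric trait vector over all individuals.
#' @return The node z score.
#' @examples
#' node_z(c(3, 4), c(1, 2, 3, 4))  # sqrt(2) * (3.5 - 2.5) / sd(1:4)
#' @export
node_z <- function(members, trait) {
  if (length(members) == 0) gt_stop("node has no members")
  s <- stats::sd(trait)
  if (!is.finite(s) || s == 0) gt_stop("degenerate trait: zero variance")
  sqrt(length(members)) * (mean(trait[members]) - mean(trait)) / s
}

#' Transform node z scores
#'
#' The score actually summed over disjoint nodes is f(z). The default
#' `square` (z^2) is two-sided and monotone in |z|; `abs` is |z|;
#' `positive_part` is max(z, 0)^2, sensitive only to trait-raising nodes.
#'
#' @param z Numeric vector of z scores.
#' @param f_spec One of `"square"`, `"abs"`, `"positive_part"`.
#' @return Numeric vector of scores.
#' @export
transform_scores <- function(z, f_spec = c("square", "abs", "positive_part")) {
  switch(match.arg(f_spec),
         square = z^2,
         abs = abs(z),
         positive_part = pmax(z, 0)^2)
}

# internal: map an f_spec string to the integer code used by the C++ engine
f_spec_code <- function(f_spec = c("square", "abs", "positive_part")) {
  match(match.arg(f_spec), c("square", "abs", "positive_part")) - 1L
}

#' Compute z scores and transformed scores at every tree node
#'
#' Node trait sums are accumulated bottom-up: each leaf sums its members'
#' trait values and every internal node adds its two children's sums, so a
#' full re-scoring (as done once per permutation replicate) is linear in the
#' number of nodes. The overall mean and standard deviation are computed once
#' from the full sample; they are unchanged by any relabelling of the trait.
#'
#' @param t A `genotype_tree`.
#' @param trait Numeric vector, one value per individual (tree row order).
#' @param f_spec Score transform, see [transform_scores()].
#' @return A data frame with columns `node_id`, `n`, `node_mean`, `z`, `score`.
#' @export
compute_node_stats <- function(t, trait, f_spec = "square") {
  n_ind <- length(t$members[[1]])
  if (length(trait) != n_ind) {
    gt_stop("trait length (", length(trait), ") does not match the tree's ",
            n_ind, " individuals")
  }
  xbar <- mean(trait)
  s <- stats::sd(trait)
  if (!is.finite(s) || s == 0) gt_stop("degenerate trait: zero variance")

  nn <- t$n_nodes
  sums <- numeric(nn)
  nmem <- vapply(t$members, length, integer(1))
  for (v in tree_postorder(t)) {
    c0 <- t$child0[v]
    sums[v] <- if (is.na(c0)) sum(trait[t$members[[v]]]) else
      sums[c0] + sums[t$child1[v]]
  }
  node_mean <- sums / nmem
  z <- sqrt(nmem) * (node_mean - xbar) / s
  z[nmem == n_ind] <- 0  # a node holding the whole sample is exactly null
  data.frame(node_id = seq_len(nn), n = nmem, node_mean = node_mean, z = z,
             score = transform_scores(z, f_spec))
}
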
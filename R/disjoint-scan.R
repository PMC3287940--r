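#' Best sums of scores over disjoint tree nodes
#'
#' Computes \eqn{S_j} for j = 1..k: the maximum, over sets of at most j
#' pairwise disjoint nodes (no node an ancestor of another -- an antichain),
#' of the summed node scores. The dynamic program works post-order: for node
#' v and budget m,
#' \deqn{best(v, m) = \max\big(score(v), \max_{m_0 + m_1 = m}
#'   best(c_0, m_0) + best(c_1, m_1)\big),}
#' with \eqn{best(\cdot, 0) = 0} and the empty selection always allowed, so a
#' branch contributes 0 rather than a forced negative pick and
#' \eqn{S_1 \le S_2 \le \dots \le S_k}. All intermediate \eqn{S_j} fall out
#' of the same pass. One maximising antichain per budget is recovered by
#' backtracking; ties prefer smaller sets, then the lexicographically
#' smallest node-id sequence (a parent always has a smaller id than its
#' descendants).
#'
#' @param t A `genotype_tree`.
#' @param scores Numeric vector, one score per node.
#' @param k Budget: maximum number of disjoint nodes (default 10).
#' @return An object of class `scan_stats`: list with `gene`, `k`, `S`
#'   (numeric vector of length k) and `best_sets` (list of integer node-id
#'   vectors, one per budget).
#' @examples
#' b <- bmg_matrix("g", rbind(0, 1), "s1")  # two leaves under the root
#' t <- build_tree(b)
#' best_disjoint(t, c(0, 3, 2), k = 2)$S    # 3, then 3 + 2
#' @export
best_disjoint <- function(t, scores, k = 10) {
  if (!is.numeric(k) || k < 1) gt_stop("k must be a positive integer")
  k <- as.integer(k)
  nn <- t$n_nodes
  if (length(scores) != nn) gt_stop("need one score per node")

  best <- matrix(0, nn, k + 1)
  size <- matrix(0L, nn, k + 1)
  dec <- matrix(-1L, nn, k + 1)  # -1: take this node (or nothing); j: split
  for (v in tree_postorder(t)) {
    c0 <- t$child0[v]
    if (is.na(c0)) {
      if (scores[v] > 0) {
        best[v, 2:(k + 1)] <- scores[v]
        size[v, 2:(k + 1)] <- 1L
      }
    } else {
      c1 <- t$child1[v]
      for (m in seq_len(k)) {
        bv <- max(0, scores[v])
        sv <- if (scores[v] > 0) 1L else 0L
        dv <- -1L
        for (j in 0:m) {
          val <- best[c0, j + 1] + best[c1, m - j + 1]
          sz <- size[c0, j + 1] + size[c1, m - j + 1]
          if (val > bv || (val == bv && sz < sv)) {
            bv <- val; sv <- sz; dv <- j
          }
        }
        best[v, m + 1] <- bv
        size[v, m + 1] <- sv
        dec[v, m + 1] <- dv
      }
    }
  }

  recover <- function(v, m) {
    if (m == 0L || size[v, m + 1] == 0L) return(integer(0))
    d <- dec[v, m + 1]
    if (d < 0) return(v)
    c(recover(t$child0[v], d), recover(t$child1[v], m - d))
  }
  best_sets <- lapply(seq_len(k), function(m) sort(recover(1L, m)))

  structure(list(gene = t$gene, k = k, S = best[1, 2:(k + 1)],
                 best_sets = best_sets),
            class = "scan_stats")
}

#' @export
print.scan_stats <- function(x, ...) {
  cat("scan_stats for gene", x$gene, "\n  S_1..S_", x$k, ": ",
      paste(signif(x$S, 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Exhaustive maximisation over disjoint node sets
#'
#' Independent oracle for [best_disjoint()]: enumerates every antichain of
#' size at most k by depth-first extension with pairwise comparability
#' pruning, and records the exact maxima. Guarded to small trees.
#'
#' @inheritParams best_disjoint
#' @param max_nodes Guard against combinatorial blowup (default 30).
#' @return A `scan_stats` object (best sets are the first-found maximisers).
#' @export
brute_force_disjoint <- function(t, scores, k = 10, max_nodes = 30) {
  if (t$n_nodes > max_nodes) {
    gt_stop("tree too large for exhaustive enumeration (", t$n_nodes,
            " nodes > ", max_nodes, ")")
  }
  if (!is.numeric(k) || k < 1) gt_stop("k must be a positive integer")
  k <- as.integer(k)
  comp <- comparable_matrix(t)
  nn <- t$n_nodes
  bestS <- numeric(k)
  best_sets <- rep(list(integer(0)), k)

  rec <- function(start, chosen, total) {
    m <- length(chosen)
    if (m > 0 && total > bestS[m]) {
      bestS[m] <<- total
      best_sets[[m]] <<- chosen
    }
    if (m == k || start > nn) return(invisible(NULL))
    for (v in start:nn) {
      if (m == 0 || !any(comp[v, chosen])) {
        rec(v + 1L, c(chosen, v), total + scores[v])
      }
    }
    invisible(NULL)
  }
  rec(1L, integer(0), 0)

  # a budget never does worse than a smaller one (empty picks allowed)
  for (m in seq_len(k)) {
    if (m > 1 && bestS[m - 1] > bestS[m]) {
      bestS[m] <- bestS[m - 1]
      best_sets[[m]] <- best_sets[[m - 1]]
    }
    if (bestS[m] < 0) {
      bestS[m] <- 0
      best_sets[[m]] <- integer(0)
    }
  }
  structure(list(gene = t$gene, k = k, S = bestS,
                 best_sets = lapply(best_sets, sort)),
            class = "scan_stats")
}
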
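#' Build a lexical genotype tree from binary multilocus genotypes
#'
#' All individuals start at the root. Sites are processed one at a time in
#' `site_order`; whenever the individuals at a current leaf differ at the site
#' the leaf is split, 0-carriers going to `child0` and 1-carriers to `child1`.
#' After all sites are processed the leaves are in one-to-one correspondence
#' with the distinct observed BMGs, and internal nodes carry partial BMGs
#' (patterns with `#` at positions where their members differ). Node ids are
#' assigned in construction order, so a child id is always larger than its
#' parent's id.
#'
#' @param b A [bmg_matrix()].
#' @param site_order Permutation of `seq_len(ncol(b$codes))`; defaults to the
#'   stored (genomic-position) order. `"rarest_first"` / `"commonest_first"`
#'   order sites by carrier count.
#' @return An object of class `genotype_tree` with fields `gene`, `site_order`,
#'   `n_nodes`, `members` (list of individual indices per node), `child0`,
#'   `child1`, `split_site` (all `NA` for leaves), `parent`, `leaf_of`
#'   (leaf node id per individual), and the `codes` matrix.
#' @examples
#' b <- bmg_matrix("g", rbind(c(0, 0), c(0, 1), c(1, 1)), c("s1", "s2"))
#' t <- build_tree(b)
#' t$n_nodes  # 5: root, two internal splits, three leaves
#' @export
build_tree <- function(b, site_order = NULL) {
  codes <- b$codes
  n <- nrow(codes)
  p <- ncol(codes)
  if (n == 0) gt_stop("empty BMG matrix")
  if (is.null(site_order)) {
    site_order <- seq_len(p)
  } else if (is.character(site_order)) {
    carriers <- colSums(codes)
    site_order <- switch(match.arg(site_order,
                                   c("rarest_first", "commonest_first")),
                         rarest_first = order(carriers, seq_len(p)),
                         commonest_first = order(-carriers, seq_len(p)))
  }
  if (!identical(sort(as.integer(site_order)), seq_len(p))) {
    gt_stop("site_order must be a permutation of the gene's sites")
  }

  members <- list(seq_len(n))
  child0 <- child1 <- split_site <- NA_integer_
  active <- 1L
  for (s in site_order) {
    nxt <- integer(0)
    for (v in active) {
      bits <- codes[members[[v]], s]
      if (any(bits == 0L) && any(bits == 1L)) {
        i0 <- length(members) + 1L
        i1 <- i0 + 1L
        members[[i0]] <- members[[v]][bits == 0L]
        members[[i1]] <- members[[v]][bits == 1L]
        child0[v] <- i0
        child1[v] <- i1
        split_site[v] <- s
        child0[c(i0, i1)] <- NA_integer_
        child1[c(i0, i1)] <- NA_integer_
        split_site[c(i0, i1)] <- NA_integer_
        nxt <- c(nxt, i0, i1)
      } else {
        nxt <- c(nxt, v)
      }
    }
    active <- nxt
  }
  nn <- length(members)
  parent <- rep(NA_integer_, nn)
  parent[child0[!is.na(child0)]] <- which(!is.na(child0))
  parent[child1[!is.na(child1)]] <- which(!is.na(child1))
  leaf_of <- integer(n)
  for (v in which(is.na(child0))) leaf_of[members[[v]]] <- v

  structure(list(gene = b$gene, site_order = as.integer(site_order),
                 site_ids = b$site_ids, n_nodes = nn, members = members,
                 child0 = child0, child1 = child1, split_site = split_site,
                 parent = parent, leaf_of = leaf_of, codes = codes),
            class = "genotype_tree")
}

#' @export
print.genotype_tree <- function(x, ...) {
  cat("genotype_tree for gene", x$gene, ":", x$n_nodes, "nodes,",
      sum(is.na(x$child0)), "leaves,", length(x$members[[1]]),
      "individuals at the root\n")
  invisible(x)
}

#' Node patterns (partial BMGs)
#'
#' Patterns are derived lazily from member sets rather than stored: position
#' t of the pattern of node v (in `site_order` sequence) is the shared bit of
#' v's members at that site, or `#` where members differ. Leaf patterns are
#' full-length BMGs without `#`.
#'
#' @param tree A `genotype_tree`.
#' @return Character vector of patterns, one per node.
#' @export
node_patterns <- function(tree) {
  ord <- tree$site_order
  vapply(tree$members, function(m) {
    sub <- tree$codes[m, ord, drop = FALSE]
    cs <- colSums(sub)
    paste(ifelse(cs == 0L, "0", ifelse(cs == nrow(sub), "1", "#")),
          collapse = "")
  }, character(1))
}

# internal: ids in post-order (children before parents); because construction
# assigns child ids greater than parent ids, decreasing id order suffices
tree_postorder <- function(tree) rev(seq_len(tree$n_nodes))

# internal: nn x nn logical, comp[u, v] TRUE if u is an ancestor of v or
# vice versa (or u == v)
comparable_matrix <- function(tree) {
  nn <- tree$n_nodes
  comp <- diag(nn) > 0
  for (v in seq_len(nn)) {
    a <- tree$parent[v]
    while (!is.na(a)) {
      comp[a, v] <- comp[v, a] <- TRUE
      a <- tree$parent[a]
    }
  }
  comp
}

#' Export a genotype tree as DOT or JSON
#'
#' DOT output (graphviz dialect) labels each node with its pattern and member
#' count, optionally appending a per-node annotation (e.g. the z score) and a
#' fill colour from `highlight`. JSON output round-trips the full tree through
#' [tree_from_json()]; its schema is
#' `{gene, site_order, site_ids, nodes:[{id, pattern, n, members, split_site,
#' child0, child1}]}`.
#'
#' @param t A `genotype_tree`.
#' @param format `"dot"` or `"json"`.
#' @param annotations Optional numeric vector (one value per node) shown in
#'   DOT labels.
#' @param highlight Optional character vector of fill colours per node
#'   (`NA` = none); see [z_highlight()] for the standard z-score classes.
#' @param file Optional path; when given the text is also written there.
#' @return The exported text, invisibly when `file` is given.
#' @export
export_tree <- function(t, format = c("dot", "json"), annotations = NULL,
                        highlight = NULL, file = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    nodes <- lapply(seq_len(t$n_nodes), function(v) {
      list(id = v, pattern = node_patterns(t)[v],
           n = length(t$members[[v]]), members = t$members[[v]],
           split_site = t$split_site[v],
           child0 = t$child0[v], child1 = t$child1[v])
    })
    txt <- jsonlite::toJSON(list(gene = t$gene, site_order = t$site_order,
                                 site_ids = t$site_ids, nodes = nodes),
                            auto_unbox = TRUE, na = "null", digits = NA)
    txt <- as.character(txt)
  } else {
    pat <- node_patterns(t)
    lab <- paste0(pat, "\\nn=", vapply(t$members, length, integer(1)))
    if (!is.null(annotations)) {
      lab <- paste0(lab, "\\nz=", formatC(annotations, digits = 3,
                                          format = "fg"))
    }
    style <- rep("", t$n_nodes)
    if (!is.null(highlight)) {
      has <- !is.na(highlight)
      style[has] <- paste0(", style=filled, fillcolor=\"",
                           highlight[has], "\"")
    }
    lines <- c("digraph genotype_tree {",
               "  node [shape=box];",
               sprintf("  n%d [label=\"%s\"%s];", seq_len(t$n_nodes), lab,
                       style))
    int <- which(!is.na(t$child0))
    if (length(int)) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"0\"];", int, t$child0[int]),
                 sprintf("  n%d -> n%d [label=\"1\"];", int, t$child1[int]))
    }
    txt <- paste(c(lines, "}"), collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Rebuild a genotype tree from its JSON export
#'
#' @param txt JSON text (or a path to a JSON file).
#' @param codes Optional BMG code matrix to re-attach; when omitted the codes
#'   are reconstructed from the leaf patterns.
#' @return A `genotype_tree`.
#' @export
tree_from_json <- function(txt, codes = NULL) {
  if (length(txt) == 1 && file.exists(txt)) txt <- paste(readLines(txt),
                                                         collapse = "\n")
  obj <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  nodes <- obj$nodes
  nn <- nrow(nodes)
  members <- nodes$members
  if (is.matrix(members)) {
    members <- lapply(seq_len(nrow(members)), function(i) members[i, ])
  } else if (!is.list(members)) {
    members <- as.list(members)
  }
  members <- lapply(members, as.integer)
  child0 <- as.integer(nodes$child0)
  child1 <- as.integer(nodes$child1)
  split_site <- as.integer(nodes$split_site)
  n_ind <- length(members[[1]])
  if (is.null(codes)) {
    p <- length(obj$site_ids)
    codes <- matrix(0L, n_ind, p)
    ord <- as.integer(obj$site_order)
    for (v in which(is.na(child0))) {
      bits <- as.integer(strsplit(nodes$pattern[v], "")[[1]])
      codes[members[[v]], ord] <- matrix(bits, length(members[[v]]), p,
                                         byrow = TRUE)
    }
    colnames(codes) <- obj$site_ids
  }
  parent <- rep(NA_integer_, nn)
  parent[child0[!is.na(child0)]] <- which(!is.na(child0))
  parent[child1[!is.na(child1)]] <- which(!is.na(child1))
  leaf_of <- integer(n_ind)
  for (v in which(is.na(child0))) leaf_of[members[[v]]] <- v
  structure(list(gene = obj$gene, site_order = as.integer(obj$site_order),
                 site_ids = obj$site_ids, n_nodes = nn, members = members,
                 child0 = child0, child1 = child1, split_site = split_site,
                 parent = parent, leaf_of = leaf_of, codes = codes),
            class = "genotype_tree")
}

#' Highlight class for a node z score
#'
#' The display convention for annotated trees: `red` for z > 2, `pink` for
#' 1 <= z <= 2, `green` for -2 <= z <= -1, none otherwise. Thresholds are
#' overridable.
#'
#' @param z Numeric vector of node z scores.
#' @param red Lower bound for the red class.
#' @param pink Bounds for the pink class.
#' @param green Bounds for the green class.
#' @return Character vector of colours (`NA` where unclassified).
#' @export
z_highlight <- function(z, red = 2, pink = c(1, 2), green = c(-2, -1)) {
  out <- rep(NA_character_, length(z))
  out[z >= green[1] & z <= green[2]] <- "green"
  out[z >= pink[1] & z <= pink[2]] <- "pink"
  out[z > red] <- "red"
  out
}
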
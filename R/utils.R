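#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Genome scans run one permutation test per gene; so that genes can be
#' evaluated in any order (or in parallel) yet give identical p-values, each
#' gene draws its permutations from a seed derived deterministically from the
#' master seed and the gene label.
#'
#' @param seed Integer master seed.
#' @param label Character scalar (e.g. a gene name).
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "geneA")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  h <- 0
  for (cc in utf8ToInt(as.character(label))) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# internal: stop() with call.=FALSE for cleaner user-facing errors
gt_stop <- function(...) stop(..., call. = FALSE)
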
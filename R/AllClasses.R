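#' @useDynLib signedgroups, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.PAIR_TYPES <- c("trophic", "mutualism", "competition",
                 "commensalism", "amensalism", "none")

#' SignedNetwork: a signed directed interaction web
#'
#' An S x S signed adjacency matrix over an ordered set of species labels.
#' Entry (i, j) is +1 if the growth rate of species j depends positively on
#' the presence of species i, -1 if negatively, and 0 if j does not depend
#' on i. Diagonal entries (self-effects) are permitted. The matrix is the
#' sign structure of the community matrix, not an energy-flow matrix.
#'
#' @slot species character vector of unique, order-stable species labels.
#' @slot signs integer matrix with entries in \{-1, 0, +1\} and dimnames
#'   equal to \code{species}.
#' @export
setClass("SignedNetwork",
         representation(species = "character", signs = "matrix"))

setValidity("SignedNetwork", function(object) {
  s <- object@species
  m <- object@signs
  if (length(s) == 0L) return("network must contain at least one species")
  if (anyDuplicated(s)) return("species labels must be unique")
  if (!is.numeric(m)) return("sign matrix must be numeric")
  if (nrow(m) != length(s) || ncol(m) != length(s))
    return("sign matrix must be S x S with S = number of species")
  if (!all(m %in% c(-1L, 0L, 1L)))
    return("sign matrix entries must be in {-1, 0, +1}")
  if (!identical(rownames(m), s) || !identical(colnames(m), s))
    return("sign matrix dimnames must equal the species labels")
  TRUE
})

#' Partition: an assignment of species to groups
#'
#' Maps each species to one of g groups. Group labels are integers 1..g;
#' a canonical partition (see \code{\link{canonicalizePartition}}) numbers
#' groups in order of first appearance and has no empty groups.
#'
#' @slot species character vector of species labels.
#' @slot groups integer vector of group indices, one per species.
#' @export
setClass("Partition",
         representation(species = "character", groups = "integer"))

setValidity("Partition", function(object) {
  if (length(object@species) != length(object@groups))
    return("species and groups must have equal length")
  if (length(object@groups) == 0L) return("partition must be non-empty")
  if (anyDuplicated(object@species)) return("species labels must be unique")
  if (anyNA(object@groups) || any(object@groups < 1L))
    return("group indices must be positive integers")
  TRUE
})

#' BlockCounts: sufficient statistics of a partitioned signed network
#'
#' For a network cut into g groups, the g x g matrices of link counts
#' (nonzero cells), positive-link counts and zero-cell counts between every
#' ordered pair of groups. These are the sufficient statistics of the
#' blocked likelihood; diagonal blocks include the diagonal cells of the
#' adjacency matrix, so L + Z summed over blocks equals S^2.
#'
#' @slot L g x g matrix, number of nonzero cells from group i to group j.
#' @slot K g x g matrix, number of +1 cells from group i to group j.
#' @slot Z g x g matrix, number of zero cells from group i to group j.
#' @slot sizes integer vector of group sizes.
#' @export
setClass("BlockCounts",
         representation(L = "matrix", K = "matrix", Z = "matrix",
                        sizes = "integer"))

setValidity("BlockCounts", function(object) {
  g <- length(object@sizes)
  for (nm in c("L", "K", "Z")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(g, g))) return("count matrices must be g x g")
    if (any(m < 0)) return("counts must be non-negative")
  }
  if (any(object@K > object@L)) return("K must not exceed L in any block")
  n <- object@sizes
  if (!all(object@L + object@Z == outer(n, n)))
    return("L + Z must equal n_i * n_j in every block")
  TRUE
})

#' ComparisonResult: information-theoretic comparison of two partitions
#'
#' @slot H_A entropy of the first partition, nats.
#' @slot H_B entropy of the second partition, nats.
#' @slot H_AB joint entropy, nats.
#' @slot MI mutual information, nats.
#' @slot MI_max upper bound on MI given the two entropies, nats.
#' @slot p_value randomization-test p-value (NA if no test was run).
#' @slot n_randomizations number of randomizations used for the p-value.
#' @export
setClass("ComparisonResult",
         representation(H_A = "numeric", H_B = "numeric", H_AB = "numeric",
                        MI = "numeric", MI_max = "numeric",
                        p_value = "numeric", n_randomizations = "numeric"))

setValidity("ComparisonResult", function(object) {
  if (object@MI < -1e-9) return("MI must be non-negative")
  if (!is.na(object@p_value) &&
      (object@p_value < 0 || object@p_value > 1))
    return("p_value must lie in [0, 1]")
  TRUE
})

#' SearchResult: outcome of a partition search
#'
#' @slot bestPartition the best (highest marginal likelihood) partition found.
#' @slot bestLogMarginal its log marginal likelihood, nats.
#' @slot trace data.frame of per-chain score traces
#'   (columns sweep, chain, logMarginal).
#' @slot seed RNG seed used for the run (NA for deterministic searches).
#' @export
setClass("SearchResult",
         representation(bestPartition = "Partition",
                        bestLogMarginal = "numeric",
                        trace = "data.frame", seed = "numeric"))
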
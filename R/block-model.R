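#' Block counts of a partitioned signed network
#'
#' For every ordered pair of groups (i, j), counts the nonzero cells
#' (L_ij), the +1 cells (K_ij) and the zero cells (Z_ij) of the sign
#' matrix restricted to rows in group i and columns in group j. Every cell
#' of the S x S matrix, including the diagonal, is counted exactly once,
#' so L_ij + Z_ij = n_i n_j and the block sums reproduce the network
#' totals L, K and Z = S^2 - L.
#'
#' @param net a \code{SignedNetwork}.
#' @param part a \code{Partition} describing \code{net}.
#' @return a \code{BlockCounts}.
#' @export
blockCounts <- function(net, part) {
  .checkDescribes(net, part)
  part <- canonicalizePartition(part)
  grp <- part@groups
  g <- max(grp)
  m <- net@signs
  agg <- function(x) {
    r <- rowsum(x, grp, reorder = TRUE)
    t(rowsum(t(r), grp, reorder = TRUE))
  }
  L <- agg((m != 0L) + 0)
  K <- agg((m == 1L) + 0)
  sizes <- tabulate(grp, g)
  Z <- outer(sizes, sizes) - L
  dn <- list(seq_len(g), seq_len(g))
  dimnames(L) <- dimnames(K) <- dimnames(Z) <- dn
  new("BlockCounts", L = L, K = K, Z = Z, sizes = sizes)
}

setMethod("show", "BlockCounts", function(object) {
  cat("BlockCounts over", length(object@sizes), "groups (sizes:",
      paste(object@sizes, collapse = " "), ")\n")
  cat("total links:", sum(object@L), " positive:", sum(object@K),
      " zeros:", sum(object@Z), "\n")
})

#' Maximum-likelihood connection and sign rates per block
#'
#' The blocked Bernoulli likelihood is maximized at
#' \eqn{\hat c_{ij} = L_{ij}/(L_{ij}+Z_{ij})} (connection probability) and
#' \eqn{\hat\pi_{ij} = K_{ij}/L_{ij}} (probability that a link is
#' positive). For empty blocks (L_ij = 0) \eqn{\hat\pi_{ij}} is reported
#' as 0; the corresponding likelihood terms vanish, so the convention is
#' inert.
#'
#' @param counts a \code{BlockCounts}.
#' @return list with matrices \code{c_hat} and \code{pi_hat}.
#' @export
mleRates <- function(counts) {
  tot <- counts@L + counts@Z
  c_hat <- ifelse(tot > 0, counts@L / tot, 0)
  pi_hat <- ifelse(counts@L > 0, counts@K / counts@L, 0)
  list(c_hat = c_hat, pi_hat = pi_hat)
}

# x * log(p) with the 0 * log(0) = 0 convention
.xlogy <- function(x, p) ifelse(x > 0, x * log(p), 0)

#' Maximized blocked log-likelihood
#'
#' The log of the blocked Bernoulli likelihood evaluated at the per-block
#' maximum-likelihood rates: for each ordered group pair,
#' \eqn{L_{ij}\ln\hat c_{ij} + K_{ij}\ln\hat\pi_{ij} +
#' Z_{ij}\ln(1-\hat c_{ij}) + (L_{ij}-K_{ij})\ln(1-\hat\pi_{ij})},
#' with 0 ln 0 = 0. Always <= 0; equal to 0 (likelihood 1) when every
#' species is in its own group, since every block then contains a single
#' cell fit perfectly.
#'
#' @param net a \code{SignedNetwork}.
#' @param part a \code{Partition} describing \code{net}.
#' @return log-likelihood in nats.
#' @export
logLikelihoodMLE <- function(net, part) {
  counts <- blockCounts(net, part)
  r <- mleRates(counts)
  with_terms <- .xlogy(counts@L, r$c_hat) + .xlogy(counts@K, r$pi_hat) +
    .xlogy(counts@Z, 1 - r$c_hat) +
    .xlogy(counts@L - counts@K, 1 - r$pi_hat)
  sum(with_terms)
}

# log marginal likelihood from block count matrices (uniform Beta priors
# on every c_ij and pi_ij, integrated analytically)
.logMarginalFromCounts <- function(L, K, Z) {
  sum(lgamma(K + 1) + lgamma(Z + 1) + lgamma(L - K + 1) -
        log1p(L) - lgamma(L + Z + 2))
}

#' Log marginal likelihood of a partition
#'
#' The blocked likelihood with every per-block connection probability
#' c_ij and sign probability pi_ij integrated out under independent
#' uniform priors on [0, 1]. Each block contributes two Beta integrals,
#' giving the closed form
#' \deqn{\prod_{ij} \frac{K_{ij}!\,Z_{ij}!\,(L_{ij}-K_{ij})!}
#'   {(1+L_{ij})\,(1+L_{ij}+Z_{ij})!}}
#' evaluated in log space via log-Gamma. This integrated score is the
#' model-selection criterion: partitions with higher marginal likelihood
#' are preferred, and the ratio of two marginal likelihoods is the Bayes
#' factor between groupings.
#'
#' @param net a \code{SignedNetwork}.
#' @param part a \code{Partition} describing \code{net}.
#' @return log marginal likelihood in nats (finite, <= 0).
#' @export
logMarginalLikelihood <- function(net, part) {
  counts <- blockCounts(net, part)
  .logMarginalFromCounts(counts@L, counts@K, counts@Z)
}

#' Log Bayes factor between two partitions
#'
#' \code{logMarginalLikelihood(net, part1) -
#' logMarginalLikelihood(net, part2)}; positive values favour
#' \code{part1}. Antisymmetric in its partition arguments. No prior over
#' partitions is applied.
#'
#' @param net a \code{SignedNetwork}.
#' @param part1,part2 \code{Partition}s describing \code{net}.
#' @return log Bayes factor in nats.
#' @export
logBayesFactor <- function(net, part1, part2) {
  logMarginalLikelihood(net, part1) - logMarginalLikelihood(net, part2)
}
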
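# fast MI of two integer label vectors (1..gA, 1..gB), in nats
.miFromLabels <- function(ga, gb, gA, gB) {
  N <- length(ga)
  nab <- tabulate((ga - 1L) * gB + gb, nbins = gA * gB)
  na <- tabulate(ga, gA)
  nb <- tabulate(gb, gB)
  pos <- nab > 0L
  # nab is flattened a-major: cell (a,b) sits at (a-1)*gB + b
  prod_ab <- rep(na, each = gB) * rep.int(nb, gA)
  sum(nab[pos] / N * log(nab[pos] * N / prod_ab[pos]))
}

#' Entropy of a partition
#'
#' Shannon entropy of group membership, \eqn{H(A) = -\sum_a p(a)\ln p(a)}
#' with p(a) the fraction of species in group a, in nats; 0 ln 0 = 0.
#' Ranges from 0 (single group) to ln N (all singletons).
#'
#' @param part a \code{Partition}.
#' @return entropy in nats.
#' @examples
#' partitionEntropy(Partition(c(1, 2, 1, 2, 1)))  # 0.673
#' @export
partitionEntropy <- function(part) {
  p <- groupSizes(part) / nSpecies(part)
  -sum(.xlogy(p, p))
}

#' Joint entropy of two aligned partitions
#'
#' \eqn{H(A,B) = -\sum_{a,b} p(a,b)\ln p(a,b)} over the joint group
#' memberships; satisfies max(H(A), H(B)) <= H(A,B) <= H(A) + H(B).
#'
#' @param a,b \code{Partition}s over the same species in the same order.
#' @return joint entropy in nats.
#' @export
jointEntropy <- function(a, b) {
  tab <- jointCounts(a, b)
  p <- tab$counts / tab$N
  -sum(.xlogy(p, p))
}

#' Joint count table of two aligned partitions
#'
#' Cell (i, j) counts the species in group i of \code{a} and group j of
#' \code{b}; row and column marginals are the group sizes.
#'
#' @param a,b \code{Partition}s over the same species in the same order.
#' @return list with \code{counts} (gA x gB matrix), \code{row_marginals},
#'   \code{col_marginals} and \code{N}.
#' @export
jointCounts <- function(a, b) {
  .checkAligned(a, b)
  a <- canonicalizePartition(a)
  b <- canonicalizePartition(b)
  gA <- max(a@groups)
  gB <- max(b@groups)
  counts <- matrix(tabulate((b@groups - 1L) * gA + a@groups,
                            nbins = gA * gB), gA, gB)
  list(counts = counts,
       row_marginals = rowSums(counts),
       col_marginals = colSums(counts),
       N = length(a@groups))
}

#' Mutual information between two partitions
#'
#' The shared entropy \eqn{MI = H(A) + H(B) - H(A,B)}, equivalently
#' \eqn{\sum_{a,b} p(a,b) \ln\frac{p(a,b)}{p(a)p(b)}}, in nats. Symmetric,
#' non-negative, and bounded by min(H(A), H(B)). MI quantifies how much
#' knowing one grouping reduces uncertainty about the other.
#'
#' @param a,b \code{Partition}s over the same species in the same order.
#' @return mutual information in nats.
#' @export
mutualInformation <- function(a, b) {
  .checkAligned(a, b)
  a <- canonicalizePartition(a)
  b <- canonicalizePartition(b)
  .miFromLabels(a@groups, b@groups, max(a@groups), max(b@groups))
}

#' Upper bound on the mutual information of two partitions
#'
#' Defined here as min(H(A), H(B)), the entropy bound on MI; it depends
#' only on the two group-size profiles, so it is conserved by the
#' group-size-preserving shuffles of the randomization test. The ratio
#' MI / MI_max is the normalized similarity used for jackknife stability.
#'
#' @param a,b \code{Partition}s over the same species in the same order.
#' @return MI upper bound in nats.
#' @export
miMax <- function(a, b) {
  .checkAligned(a, b)
  min(partitionEntropy(a), partitionEntropy(b))
}

#' Randomization test for the significance of MI
#'
#' Shuffles both partitions independently and uniformly at random
#' (permuting labels over species, which conserves each partition's
#' group-size profile and hence MI_max), recomputes MI each time, and
#' estimates the p-value as the fraction of randomizations with
#' MI >= the observed MI.
#'
#' @param a,b \code{Partition}s over the same species in the same order.
#' @param n_reps number of randomizations (the reference analysis uses
#'   1e6; smaller values are fine for exploration).
#' @param seed optional integer seed for reproducibility.
#' @param conservative if TRUE use the (r+1)/(n+1) estimator instead of
#'   the plain proportion r/n.
#' @return p-value in [0, 1].
#' @export
randomizationTest <- function(a, b, n_reps = 1e6, seed = NULL,
                              conservative = FALSE) {
  .checkAligned(a, b)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a <- canonicalizePartition(a)
  b <- canonicalizePartition(b)
  ga <- a@groups
  gb <- b@groups
  gA <- max(ga)
  gB <- max(gb)
  obs <- .miFromLabels(ga, gb, gA, gB)
  n <- length(ga)
  r <- 0L
  for (i in seq_len(n_reps)) {
    mi <- .miFromLabels(ga[sample.int(n)], gb[sample.int(n)], gA, gB)
    if (mi >= obs - 1e-12) r <- r + 1L
  }
  if (conservative) (r + 1) / (n_reps + 1) else r / n_reps
}

#' Full information-theoretic comparison of two partitions
#'
#' Bundles entropies, joint entropy, mutual information, the MI upper
#' bound and (optionally) the randomization-test p-value into a
#' \code{ComparisonResult}.
#'
#' @param a,b \code{Partition}s over the same species in the same order.
#' @param n_reps randomizations for the p-value; 0 skips the test
#'   (p_value = NA).
#' @param seed optional integer seed for the randomization test.
#' @return a \code{ComparisonResult}.
#' @export
comparePartitions <- function(a, b, n_reps = 1e6, seed = NULL) {
  .checkAligned(a, b)
  H_A <- partitionEntropy(a)
  H_B <- partitionEntropy(b)
  H_AB <- jointEntropy(a, b)
  p <- if (n_reps >= 1) randomizationTest(a, b, n_reps, seed) else NA_real_
  new("ComparisonResult", H_A = H_A, H_B = H_B, H_AB = H_AB,
      MI = H_A + H_B - H_AB, MI_max = min(H_A, H_B),
      p_value = p, n_randomizations = as.numeric(max(n_reps, 0)))
}

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult: H(A)=%.4f H(B)=%.4f H(A,B)=%.4f\n",
              object@H_A, object@H_B, object@H_AB))
  cat(sprintf("  MI=%.4f  MI_max=%.4f  MI/MI_max=%.4f\n", object@MI,
              object@MI_max,
              if (object@MI_max > 0) object@MI / object@MI_max else NaN))
  if (!is.na(object@p_value))
    cat(sprintf("  p=%.4g (%g randomizations)\n", object@p_value,
                object@n_randomizations))
})
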
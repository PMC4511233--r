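#' Generate a signed network from a planted block structure
#'
#' Draws each ordered cell (i, j) of the sign matrix independently:
#' nonzero with probability \code{C[g(i), g(j)]} and, given nonzero,
#' positive with probability \code{P[g(i), g(j)]}, where g(.) is the
#' planted group of a species. This is exactly the generative reading of
#' the blocked likelihood, so the planted partition is the ground truth
#' the search should recover when the block contrast is strong.
#'
#' @param sizes integer vector of planted group sizes (all >= 1).
#' @param C g x g matrix of connection probabilities in [0, 1] (a scalar
#'   is recycled).
#' @param P g x g matrix of positive-sign probabilities in [0, 1] (a
#'   scalar is recycled).
#' @param seed optional integer RNG seed.
#' @param selfInteractions if TRUE (default) diagonal cells are generated
#'   like any other cell, consistent with Z = S^2 - L; set FALSE to forbid
#'   self-effects.
#' @param species optional species labels.
#' @return list with \code{network} (a \code{SignedNetwork}) and
#'   \code{partition} (the planted \code{Partition}).
#' @examples
#' sim <- generatePlantedNetwork(c(10, 10), C = rbind(c(.5, .05), c(.05, .5)),
#'                               P = 1, seed = 1)
#' sim$network
#' @export
generatePlantedNetwork <- function(sizes, C, P, seed = NULL,
                                   selfInteractions = TRUE, species = NULL) {
  g <- length(sizes)
  if (any(sizes < 1)) stop("group sizes must be >= 1")
  C <- matrix(C, g, g)
  P <- matrix(P, g, g)
  if (any(C < 0 | C > 1) || any(P < 0 | P > 1))
    stop("probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  S <- sum(sizes)
  grp <- rep(seq_len(g), sizes)
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(S))
  cC <- C[cbind(rep(grp, times = S), rep(grp, each = S))]
  cP <- P[cbind(rep(grp, times = S), rep(grp, each = S))]
  nz <- stats::runif(S * S) < cC
  pos <- stats::runif(S * S) < cP
  m <- matrix(ifelse(nz, ifelse(pos, 1L, -1L), 0L), S, S)
  if (!selfInteractions) diag(m) <- 0L
  list(network = SignedNetwork(m, species),
       partition = Partition(grp, species))
}

#' Five-species worked example of partition comparison
#'
#' Two fixed partitions of five species: A = (1, 2, 1, 2, 1) and
#' B = (alpha, beta, gamma, beta, beta). Their entropies are 0.673 and
#' 0.950 nats and their joint count table has marginals (3, 2) and
#' (1, 3, 1); they are the standard small worked example for the MI
#' machinery.
#'
#' @return list with \code{A} and \code{B}, both \code{Partition}s over
#'   species \code{v1..v5}.
#' @export
workedExamplePartitions <- function() {
  sp <- paste0("v", 1:5)
  list(A = Partition(c(1, 2, 1, 2, 1), sp),
       B = Partition(c("alpha", "beta", "gamma", "beta", "beta"), sp))
}

#' Deterministic 10-species refinement example
#'
#' A fixed three-level web: four plants (a1..a4), four herbivores that
#' consume every plant, and two predators that consume every herbivore.
#' Nontrophic structure distinguishes two plant subgroups: a1 and a2 are
#' mutualists of each other and of predator p1, and compete with a3 and
#' a4. On the trophic-only subnetwork the optimal grouping (verified by
#' exhaustive enumeration) is the three trophic levels; on the full
#' network the nontrophic links split the plant level into \{a1, a2\} and
#' \{a3, a4\}, refining (never contradicting) the trophic grouping.
#' Entries are frozen constants so tests on this fixture are exact.
#'
#' @return list with \code{network} (a \code{SignedNetwork}) and
#'   \code{partition} (the three-level trophic \code{Partition}).
#' @export
refinementExampleNetwork <- function() {
  sp <- c("a1", "a2", "a3", "a4", "h1", "h2", "h3", "h4", "p1", "p2")
  m <- matrix(0L, 10, 10, dimnames = list(sp, sp))
  plants <- 1:4; herbs <- 5:8; preds <- 9:10
  for (a in plants) for (h in herbs) { m[a, h] <- 1L; m[h, a] <- -1L }
  for (h in herbs) for (p in preds) { m[h, p] <- 1L; m[p, h] <- -1L }
  for (a in c(1L, 2L)) for (b in c(3L, 4L)) { m[a, b] <- -1L; m[b, a] <- -1L }
  m[1, 2] <- 1L; m[2, 1] <- 1L                           # mutualism a1-a2
  for (a in c(1L, 2L)) { m[9, a] <- 1L; m[a, 9] <- 1L }  # mutualism p1-a1/a2
  list(network = SignedNetwork(m, sp),
       partition = Partition(rep(1:3, c(4, 4, 2)), sp))
}
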
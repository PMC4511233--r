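# small seeded fixtures shared across test files

randomSignedNetwork <- function(S, seed, p_link = 0.4, p_pos = 0.5) {
  set.seed(seed)
  nz <- stats::runif(S * S) < p_link
  pos <- stats::runif(S * S) < p_pos
  m <- matrix(ifelse(nz, ifelse(pos, 1L, -1L), 0L), S, S)
  SignedNetwork(m, paste0("x", seq_len(S)))
}

randomPartitionFor <- function(net, g, seed) {
  set.seed(seed)
  S <- nSpecies(net)
  g <- min(g, S)
  lab <- c(seq_len(g), sample.int(g, S - g, replace = TRUE))
  Partition(lab[sample.int(S)], speciesNames(net))
}

# the 2 x 2 consumer-resource toy used throughout: a benefits b, b harms a
toyNet <- function() {
  SignedNetwork(rbind(c(0L, 1L), c(-1L, 0L)), c("a", "b"))
}

# numerical double integration of one block's likelihood over (c, pi),
# scaled by the integrand's value near its mode for conditioning;
# independent of the closed-form marginal likelihood
blockIntegralOracle <- function(L, K, Z) {
  f <- function(c, p) c^L * p^K * (1 - c)^Z * (1 - p)^(L - K)
  ch <- if (L + Z > 0) L / (L + Z) else 0.5
  ph <- if (L > 0) K / L else 0.5
  mx <- f(max(min(ch, 0.999), 0.001), max(min(ph, 0.999), 0.001))
  if (mx <= 0) mx <- 1
  I <- pracma::integral2(function(c, p) f(c, p) / mx,
                         0, 1, 0, 1, reltol = 1e-10)$Q
  log(I) + log(mx)
}

logMarginalByIntegration <- function(net, part) {
  bc <- blockCounts(net, part)
  g <- length(bc@sizes)
  tot <- 0
  for (i in seq_len(g)) for (j in seq_len(g))
    tot <- tot + blockIntegralOracle(bc@L[i, j], bc@K[i, j], bc@Z[i, j])
  tot
}

# brute-force MI straight from the definition, independent of the
# package's tabulation path
bruteForceMI <- function(a, b) {
  ga <- groupAssignments(canonicalizePartition(a))
  gb <- groupAssignments(canonicalizePartition(b))
  N <- length(ga)
  mi <- 0
  for (i in unique(ga)) for (j in unique(gb)) {
    nij <- sum(ga == i & gb == j)
    if (nij > 0)
      mi <- mi + nij / N * log(nij * N / (sum(ga == i) * sum(gb == j)))
  }
  mi
}
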
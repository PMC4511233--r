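test_that("block counts enumerate every matrix cell exactly once", {
  net <- toyNet()
  bc1 <- blockCounts(net, Partition(c(1, 1), c("a", "b")))
  expect_identical(sum(bc1@L), 2)
  expect_identical(sum(bc1@K), 1)
  expect_identical(sum(bc1@Z), 2)

  # 3 species, groups {a} {b,c}, single link a->b
  m <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- 1L
  bc <- blockCounts(SignedNetwork(m), Partition(c(1, 2, 2), c("a", "b", "c")))
  expect_equal(bc@L[1, 2], 1)
  expect_equal(bc@K[1, 2], 1)
  expect_equal(bc@Z[1, 2], 1)
  expect_equal(bc@Z[1, 1], 1)
  expect_equal(bc@Z[2, 1], 2)
  expect_equal(bc@Z[2, 2], 4)

  # all-zero network: Z_ij = n_i n_j everywhere
  zero <- SignedNetwork(matrix(0L, 4, 4), paste0("s", 1:4))
  bcz <- blockCounts(zero, Partition(c(1, 1, 2, 2), paste0("s", 1:4)))
  expect_true(all(bcz@L == 0))
  expect_equal(bcz@Z, outer(c(2, 2), c(2, 2)), ignore_attr = TRUE)

  # block sums reproduce network totals on random instances
  for (k in 1:10) {
    net <- randomSignedNetwork(8, seed = 40 + k)
    part <- randomPartitionFor(net, 3, seed = 140 + k)
    bc <- blockCounts(net, part)
    expect_equal(sum(bc@L), linkCount(net))
    expect_equal(sum(bc@K), positiveCount(net))
    expect_equal(sum(bc@Z), 64 - linkCount(net))
    expect_true(all(bc@K <= bc@L))
  }
  expect_error(blockCounts(net, Partition(c(1, 2), c("a", "b"))), "match")
})

test_that("maximum-likelihood rates are the block proportions", {
  net <- toyNet()
  r <- mleRates(blockCounts(net, Partition(c(1, 1), c("a", "b"))))
  expect_equal(r$c_hat[1, 1], 0.5)
  expect_equal(r$pi_hat[1, 1], 0.5)

  zero <- SignedNetwork(matrix(0L, 2, 2), c("a", "b"))
  rz <- mleRates(blockCounts(zero, Partition(c(1, 1), c("a", "b"))))
  expect_equal(rz$c_hat[1, 1], 0)
  expect_equal(rz$pi_hat[1, 1], 0)  # convention for empty blocks

  sat <- SignedNetwork(matrix(1L, 2, 2), c("a", "b"))
  rs <- mleRates(blockCounts(sat, Partition(c(1, 1), c("a", "b"))))
  expect_equal(rs$c_hat[1, 1], 1)
  expect_equal(rs$pi_hat[1, 1], 1)
})

test_that("MLE log-likelihood matches hand values and is a maximum", {
  net <- toyNet()
  expect_equal(logLikelihoodMLE(net, Partition(c(1, 1), c("a", "b"))),
               log(0.015625), tolerance = 1e-12)
  # singleton partition: likelihood exactly 1 on any network
  for (k in 1:5) {
    rnd <- randomSignedNetwork(6, seed = 70 + k)
    expect_identical(
      logLikelihoodMLE(rnd, Partition(1:6, speciesNames(rnd))), 0)
  }
  zero <- SignedNetwork(matrix(0L, 3, 3), paste0("s", 1:3))
  expect_identical(logLikelihoodMLE(zero, Partition(c(1, 1, 1),
                                                    paste0("s", 1:3))), 0)

  # the MLE rates maximize the blocked likelihood: grid spot-check
  rnd <- randomSignedNetwork(5, seed = 77)
  part <- randomPartitionFor(rnd, 2, seed = 78)
  bc <- blockCounts(rnd, part)
  atRates <- function(ch, ph) {
    t1 <- ifelse(bc@L > 0, bc@L * log(ch), 0) +
      ifelse(bc@K > 0, bc@K * log(ph), 0) +
      ifelse(bc@Z > 0, bc@Z * log(1 - ch), 0) +
      ifelse(bc@L - bc@K > 0, (bc@L - bc@K) * log(1 - ph), 0)
    sum(t1)
  }
  best <- logLikelihoodMLE(rnd, part)
  for (ch in c(0.2, 0.5, 0.8)) for (ph in c(0.2, 0.5, 0.8))
    expect_lte(atRates(ch, ph), best + 1e-12)
})

test_that("marginal likelihood matches closed-form hand values", {
  one <- SignedNetwork(matrix(0L, 1, 1), "x")
  expect_equal(logMarginalLikelihood(one, Partition(1, "x")), log(1 / 2),
               tolerance = 1e-12)
  expect_equal(logMarginalLikelihood(toyNet(),
                                     Partition(c(1, 1), c("a", "b"))),
               log(1 / 180), tolerance = 1e-12)
})

test_that("marginal likelihood agrees with numerical double integration", {
  skip_if_not_installed("pracma")
  worst <- 0
  for (k in 1:20) {
    S <- 3 + (k %% 3)
    net <- randomSignedNetwork(S, seed = 500 + k, p_link = 0.5)
    part <- randomPartitionFor(net, 1 + (k %% 3), seed = 600 + k)
    ana <- logMarginalLikelihood(net, part)
    num <- logMarginalByIntegration(net, part)
    worst <- max(worst, abs(num - ana) / abs(ana))
  }
  expect_lt(worst, 1e-6)
})

test_that("marginal likelihood is invariant to transposition, relabeling
           and joint species permutation", {
  for (k in 1:10) {
    net <- randomSignedNetwork(7, seed = 800 + k)
    part <- randomPartitionFor(net, 3, seed = 900 + k)
    ana <- logMarginalLikelihood(net, part)
    tnet <- SignedNetwork(t(signMatrix(net)), speciesNames(net))
    expect_equal(logMarginalLikelihood(tnet, part), ana, tolerance = 1e-12)
    # group relabeling
    grp_old <- canonicalizePartition(part)@groups
    relab <- new("Partition", species = speciesNames(net),
                 groups = as.integer(max(grp_old) + 1 - grp_old))
    expect_equal(logMarginalLikelihood(net, relab), ana, tolerance = 1e-12)
    # joint permutation of species and assignment
    set.seed(k)
    perm <- sample.int(7)
    pnet <- SignedNetwork(signMatrix(net)[perm, perm],
                          speciesNames(net)[perm])
    ppart <- new("Partition", species = speciesNames(net)[perm],
                 groups = part@groups[perm])
    expect_equal(logMarginalLikelihood(pnet, ppart), ana, tolerance = 1e-12)
  }
})

test_that("Bayes factors are antisymmetric and favour planted structure", {
  net <- toyNet()
  p1 <- Partition(c(1, 2), c("a", "b"))
  p2 <- Partition(c(1, 1), c("a", "b"))
  expect_identical(logBayesFactor(net, p1, p1), 0)
  expect_equal(logBayesFactor(net, p1, p2), -logBayesFactor(net, p2, p1),
               tolerance = 1e-12)
  for (k in 1:5) {
    rnd <- randomSignedNetwork(6, seed = 950 + k)
    a <- randomPartitionFor(rnd, 2, seed = 20 + k)
    b <- randomPartitionFor(rnd, 3, seed = 30 + k)
    expect_equal(logBayesFactor(rnd, a, b), -logBayesFactor(rnd, b, a),
                 tolerance = 1e-12)
  }
  # strongly contrasted 2-block web: true split beats the merge
  sim <- generatePlantedNetwork(c(10, 10),
                                C = rbind(c(0.6, 0.05), c(0.05, 0.6)),
                                P = rbind(c(0.95, 0.5), c(0.5, 0.05)),
                                seed = 123)
  merged <- Partition(rep(1, 20), speciesNames(sim$network))
  expect_gt(logBayesFactor(sim$network, sim$partition, merged), 0)
})

test_that("canonicalization relabels by first appearance, preserves scores", {
  p <- Partition(c(3, 1, 3), c("a", "b", "c"))
  expect_identical(canonicalizePartition(p)@groups, c(1L, 2L, 1L))
  q <- Partition(c(1, 2, 1), c("a", "b", "c"))
  expect_identical(canonicalizePartition(q)@groups, q@groups)
  for (k in 1:5) {
    net <- randomSignedNetwork(6, seed = 45 + k)
    raw <- new("Partition", species = speciesNames(net),
               groups = as.integer(c(5, 2, 5, 9, 2, 1))[1:6])
    expect_equal(logMarginalLikelihood(net, canonicalizePartition(raw)),
                 logMarginalLikelihood(net, raw), tolerance = 1e-12)
  }
})

test_that("partition files round-trip through the TSV format", {
  p <- Partition(c(2, 1, 2, 3), c("sp a", "sp_b", "c", "d"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePartition(p, f)
  back <- readPartition(f)
  expect_identical(speciesNames(back), speciesNames(p))
  expect_identical(canonicalizePartition(back)@groups,
                   canonicalizePartition(p)@groups)
})
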
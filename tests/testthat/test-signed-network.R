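test_that("edge-list and matrix files round-trip exactly", {
  net <- toyNet()
  el <- withr::local_tempfile(fileext = ".tsv")
  mt <- withr::local_tempfile(fileext = ".csv")

  writeSignedNetwork(net, el, "edgelist")
  back <- readSignedNetwork(el, "edgelist")
  expect_identical(speciesNames(back), speciesNames(net))
  expect_identical(signMatrix(back), signMatrix(net))

  # seeded 10-species network, both formats, plus matrix -> edgelist -> matrix
  rnd <- randomSignedNetwork(10, seed = 11)
  writeSignedNetwork(rnd, el, "edgelist")
  writeSignedNetwork(rnd, mt, "matrix")
  expect_identical(signMatrix(readSignedNetwork(el, "edgelist")),
                   signMatrix(rnd))
  expect_identical(signMatrix(readSignedNetwork(mt, "matrix")),
                   signMatrix(rnd))
  via <- readSignedNetwork(mt, "matrix")
  writeSignedNetwork(via, el, "edgelist")
  expect_identical(signMatrix(readSignedNetwork(el, "edgelist")),
                   signMatrix(rnd))
})

test_that("edge-list reader honours declared species and rejects conflicts", {
  el <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tsign", "a\tb\t+1", "b\ta\t-1"), el)
  net <- readSignedNetwork(el, "edgelist")
  expect_identical(signMatrix(net)["a", "b"], 1L)
  expect_identical(signMatrix(net)["b", "a"], -1L)

  # empty edge list with declared species: all-zero matrix, Z = S^2
  writeLines(c("# species: a\tb", "source\ttarget\tsign"), el)
  empty <- readSignedNetwork(el, "edgelist")
  expect_identical(nSpecies(empty), 2L)
  expect_identical(linkCount(empty), 0L)
  expect_identical(zeroCount(empty), 4L)

  # duplicate edge with conflicting sign is an error; consistent dup is not
  writeLines(c("source\ttarget\tsign", "a\tb\t+1", "a\tb\t-1"), el)
  expect_error(readSignedNetwork(el, "edgelist"), "conflicting")

  mt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",a,b,c", "a,0,2,0", "b,0,0,0", "c,0,0,0"), mt)
  expect_error(readSignedNetwork(mt, "matrix"), "outside")
  writeLines(c(",a,b", "a,0,1,0", "b,0,0,1"), mt)
  expect_error(readSignedNetwork(mt, "matrix"))
})

test_that("sign matrices outside the ternary domain are rejected", {
  expect_error(SignedNetwork(rbind(c(0, 2), c(0, 0))), "-1, 0, \\+1")
  expect_error(SignedNetwork(matrix(0, 2, 3)))
  expect_error(SignedNetwork(matrix(0, 2, 2), c("a", "a")), "unique")
})

test_that("pair classification covers all sign pairs and is symmetric", {
  expect_identical(classifyPair(1, -1), "trophic")
  expect_identical(classifyPair(1, 0), "commensalism")
  expect_identical(classifyPair(0, 0), "none")
  expect_identical(classifyPair(1, 1), "mutualism")
  expect_identical(classifyPair(-1, -1), "competition")
  expect_identical(classifyPair(-1, 0), "amensalism")
  for (x in c(-1, 0, 1)) for (y in c(-1, 0, 1))
    expect_identical(classifyPair(x, y), classifyPair(y, x))
  expect_error(classifyPair(2, 0), "signs")
})

test_that("pair-type census counts each unordered pair once", {
  expect_identical(pairTypeCensus(toyNet()),
                   c(trophic = 1L, mutualism = 0L, competition = 0L,
                     commensalism = 0L, amensalism = 0L, none = 0L))
  zero3 <- SignedNetwork(matrix(0L, 3, 3), c("a", "b", "c"))
  expect_identical(pairTypeCensus(zero3)[["none"]], 3L)

  # 4 species: one trophic, one mutualistic, one amensal pair, 3 absent
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- 1L; m["b", "a"] <- -1L
  m["a", "c"] <- 1L; m["c", "a"] <- 1L
  m["b", "d"] <- -1L
  cen <- pairTypeCensus(SignedNetwork(m))
  expect_identical(cen, c(trophic = 1L, mutualism = 1L, competition = 0L,
                          commensalism = 0L, amensalism = 1L, none = 3L))
  expect_identical(sum(cen), 6L)  # 4 choose 2

  # census over 20 random networks sums to S(S-1)/2
  for (k in 1:20) {
    net <- randomSignedNetwork(7, seed = 300 + k)
    expect_identical(sum(pairTypeCensus(net)), 21L)
  }
})

test_that("interaction-type filtering keeps species and partitions links", {
  net <- refinementExampleNetwork()$network
  tro <- subnetworkByType(net, "trophic")
  non <- subnetworkByType(net, c("mutualism", "competition",
                                 "commensalism", "amensalism"))
  expect_identical(speciesNames(tro), speciesNames(net))
  expect_identical(speciesNames(non), speciesNames(net))
  # trophic and nontrophic nonzeros partition the original links
  expect_identical(linkCount(tro) + linkCount(non), linkCount(net))
  allTypes <- c("trophic", "mutualism", "competition", "commensalism",
                "amensalism", "none")
  expect_identical(signMatrix(subnetworkByType(net, allTypes)),
                   signMatrix(net))
  # keeping a class absent from the web zeroes everything, keeps species
  pure <- subnetworkByType(toyNet(), "mutualism")
  expect_identical(linkCount(pure), 0L)
  expect_identical(speciesNames(pure), c("a", "b"))
  expect_error(subnetworkByType(net, character(0)), "at least one")
  # Z = S^2 - L after the transformation
  expect_identical(zeroCount(tro), 100L - linkCount(tro))
})

test_that("species removal induces the correct subnetwork", {
  m <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- 1L; m["b", "a"] <- -1L
  net <- SignedNetwork(m)
  sub <- removeSpecies(net, "c")
  expect_identical(speciesNames(sub), c("a", "b"))
  expect_identical(signMatrix(sub), signMatrix(toyNet()))
  expect_identical(signMatrix(removeSpecies(net, character(0))),
                   signMatrix(net))
  big <- randomSignedNetwork(5, seed = 4)
  drop <- c("x2", "x4")
  sub <- removeSpecies(big, drop)
  keep <- setdiff(speciesNames(big), drop)
  expect_identical(signMatrix(sub), signMatrix(big)[keep, keep])
  expect_error(removeSpecies(big, "nope"), "unknown")
})

test_that("largest weak component ignores direction and sign", {
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- 1L; m["b", "c"] <- -1L  # chain a->b->c, d isolated
  net <- SignedNetwork(m)
  comp <- largestWeakComponent(net)
  expect_identical(speciesNames(comp), c("a", "b", "c"))

  full <- randomSignedNetwork(5, seed = 6, p_link = 0.9)
  expect_identical(signMatrix(largestWeakComponent(full)), signMatrix(full))

  # components of size 3 and 2: the triple wins
  m5 <- matrix(0L, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m5["a", "b"] <- 1L; m5["b", "c"] <- 1L
  m5["d", "e"] <- -1L
  expect_identical(speciesNames(largestWeakComponent(SignedNetwork(m5))),
                   c("a", "b", "c"))
})
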
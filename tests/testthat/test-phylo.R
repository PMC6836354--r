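test_that("p-distances: identical sequences give a zero matrix", {
  seqs <- setNames(rep(strrep("ACGT", 25), 3), c("a", "b", "c"))
  dm <- pairwise_distances(seqs)
  expect_true(all(dm == 0))
  expect_equal(rownames(dm), c("a", "b", "c"))
})

test_that("p-distance equals the direct proportion of differing residues", {
  a <- strrep("K", 224)
  b <- paste0(strrep("K", 197), strrep("R", 27))
  dm <- pairwise_distances(setNames(c(a, b, a), c("x", "y", "z")),
                           level = "protein")
  expect_equal(dm["x", "y"], 27 / 224)
  expect_equal(dm["x", "z"], 0)
})

test_that("p-distance matrices are symmetric for arbitrary inputs", {
  set.seed(70)
  for (i in 1:5) {
    seqs <- setNames(vapply(1:4, function(j) rand_seq(sample(80:120, 1)),
                            character(1)), paste0("t", 1:4))
    dm <- pairwise_distances(seqs)
    expect_identical(dm, t(dm))
    expect_true(all(diag(dm) == 0))
  }
  expect_error(pairwise_distances(setNames(c("AC", "AC"), c("a", "b"))),
               "three")
})

test_that("three-taxon trees follow the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  # b1 = (d12 + d13 - d23)/2 = 1, b2 = 2, b3 = 4
  expect_match(tr$newick, "a:1.000000")
  expect_match(tr$newick, "b:2.000000")
  expect_match(tr$newick, "c:4.000000")
  t <- ape::read.tree(text = tr$newick)
  expect_setequal(t$tip.label, c("a", "b", "c"))
})

test_that("neighbor joining recovers additive trees exactly", {
  skip_if_not_installed("ape")
  set.seed(80)
  for (n in 4:8) {
    ra <- random_additive_matrix(n)
    tr <- neighbor_joining(ra$dm)
    expect_true(same_topology(tr$newick, ra$tree))
    # branch length sum is preserved on additive input
    t1 <- ape::read.tree(text = tr$newick)
    expect_equal(sum(t1$edge.length), sum(ra$tree$edge.length), tolerance = 1e-6)
  }
})

test_that("the package tree matches ape's neighbor joining on random matrices", {
  skip_if_not_installed("ape")
  set.seed(90)
  for (i in 1:5) {
    n <- sample(4:7, 1)
    m <- matrix(runif(n * n, 0.1, 1), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- ape::read.tree(text = neighbor_joining(m)$newick)
    theirs <- ape::nj(as.dist(m))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs))[[1]], 0)
  }
})

test_that("taxon order does not change the tree topology", {
  skip_if_not_installed("ape")
  set.seed(100)
  ra <- random_additive_matrix(6)
  perm <- sample(rownames(ra$dm))
  t1 <- neighbor_joining(ra$dm)
  t2 <- neighbor_joining(ra$dm[perm, perm])
  expect_true(same_topology(t1$newick, ape::read.tree(text = t2$newick)))
})

test_that("newick output round-trips through a parser", {
  skip_if_not_installed("ape")
  set.seed(110)
  ra <- random_additive_matrix(5)
  tr <- neighbor_joining(ra$dm)
  parsed <- ape::read.tree(text = tr$newick)
  expect_setequal(parsed$tip.label, rownames(ra$dm))
  expect_equal(ape::write.tree(parsed), ape::write.tree(parsed))
})

test_that("invalid distance matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(m), "at least 3")
  m3 <- matrix(c(0, 1, 2, 3, 0, 4, 2, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(m3), "symmetric")
})
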
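make_orf_nt <- function(n_codons) {
  # stop-free random codons after ATG, closed with TAA
  pool <- setdiff(names(Biostrings::GENETIC_CODE),
                  c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(pool, n_codons - 1, replace = TRUE), "TAA"),
        collapse = "")
}

test_that("a minimal ORF is called with correct coordinates and protein", {
  g <- circular_genome("TTTATGAAATGA", id = "t", circular = FALSE)
  o <- find_orfs(g, 1)
  expect_equal(nrow(o), 1L)
  expect_equal(o$protein, "MK")
  expect_equal(o$nt_length, 9L)
  expect_equal(o$start, 3L)
  expect_equal(o$end, 12L)
})

test_that("ORF nucleotide length is 3*(protein_length+1)", {
  set.seed(8)
  nt <- make_orf_nt(224)
  g <- circular_genome(paste0("TTAATTAATTAA", nt, "TTAATTAATTAA"),
                       id = "g", circular = FALSE)
  o <- find_orfs(g, 101)
  expect_equal(o$protein_length, 224L)
  expect_equal(o$nt_length, 675L)
})

test_that("ORFs spanning the origin of a circular genome are recovered", {
  set.seed(12)
  nt <- make_orf_nt(101)          # 306 nt
  filler <- cmsscan:::orf_free_dna(700, 90)
  # put the last 30 nt of the ORF at the genome start
  s <- paste0(substring(nt, 31), filler, "TAA", substr(nt, 1, 30))
  g <- circular_genome(s, id = "circ")
  o <- find_orfs(g, 90)
  hit <- o[o$start == nchar(s) - 30, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$protein_length, 101L)
  expect_gt(hit$end, nchar(s))
  expect_identical(hit$nt_seq, nt)
})

test_that("ORF calls mirror under reverse complement", {
  set.seed(21)
  s <- paste0(rand_seq(300), make_orf_nt(110), rand_seq(200),
              reverse_complement(make_orf_nt(120)), rand_seq(300))
  g <- circular_genome(s, id = "g", circular = FALSE)
  o1 <- find_orfs(g, 50)
  o2 <- find_orfs(circular_genome(reverse_complement(s), id = "g2",
                                  circular = FALSE), 50)
  expect_equal(nrow(o1), nrow(o2))
  L <- nchar(s)
  key1 <- sort(paste(o1$start, o1$end, o1$strand))
  key2 <- sort(paste(L - o2$end, L - o2$start,
                     ifelse(o2$strand == "+", "-", "+")))
  expect_identical(key1, key2)
  expect_setequal(o1$protein, o2$protein)
})

test_that("every reported ORF satisfies the record invariants", {
  set.seed(33)
  s <- paste0(rand_seq(2000), make_orf_nt(150), rand_seq(1500))
  g <- circular_genome(s, id = "g")
  o <- find_orfs(g, 30)
  expect_gt(nrow(o), 0)
  expect_true(all(o$nt_length == 3L * (o$protein_length + 1L)))
  expect_true(all(substr(o$nt_seq, 1, 3) == "ATG"))
  expect_true(all(substring(o$nt_seq, o$nt_length - 2L) %in%
                    c("TAA", "TAG", "TGA")))
  expect_false(any(grepl("*", o$protein, fixed = TRUE)))
  expect_true(all(o$nt_length %% 3L == 0L))
})

test_that("raising the protein-length floor never adds ORFs", {
  set.seed(44)
  s <- paste0(rand_seq(1000), make_orf_nt(130), rand_seq(500),
              make_orf_nt(105), rand_seq(1000))
  g <- circular_genome(s, id = "g")
  o_low <- find_orfs(g, 50)
  o_high <- find_orfs(g, 120)
  expect_true(all(paste(o_high$start, o_high$strand) %in%
                    paste(o_low$start, o_low$strand)))
  expect_lte(nrow(o_high), nrow(o_low))
})

test_that("presence calls: self is present, unrelated sequence is absent", {
  set.seed(55)
  s <- paste0(rand_seq(1500), make_orf_nt(120), rand_seq(1500))
  g <- circular_genome(s, id = "g")
  o <- find_orfs(g, 101)
  pc <- call_presence(o[1, ], g)
  expect_equal(pc$verdict, "present")
  expect_equal(pc$coverage, 1)
  expect_equal(pc$identity, 100)
  other <- circular_genome(rand_seq(4000), id = "other")
  pc2 <- call_presence(o[1, ], other)
  expect_equal(pc2$verdict, "absent")
})

test_that("a genome compared against itself yields no specific ORFs", {
  set.seed(66)
  s <- paste0(rand_seq(1200), make_orf_nt(150), rand_seq(1200))
  g <- circular_genome(s, id = "g")
  expect_equal(nrow(specific_orfs(g, g, min_protein_length = 101)), 0L)
})
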
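test_that("substitution classes follow the purine/pyrimidine rule", {
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_error(classify_substitution("C", "C"), "not a variant")
  expect_error(classify_substitution("C", "U"), "A,C,G,T")
  nts <- c("A", "C", "G", "T")
  classes <- c()
  for (x in nts) for (y in setdiff(nts, x)) {
    classes <- c(classes, classify_substitution(x, y))
  }
  expect_equal(sum(classes == "transition"), 4L)
  expect_equal(sum(classes == "transversion"), 8L)
})

test_that("third-position changes in 4-fold degenerate codons are synonymous", {
  gc4 <- Biostrings::GENETIC_CODE
  fams <- unique(substr(names(gc4), 1, 2))
  four_fold <- fams[vapply(fams, function(p) {
    length(unique(gc4[paste0(p, c("A", "C", "G", "T"))])) == 1L
  }, logical(1))]
  expect_gte(length(four_fold), 8L)
  for (p in four_fold) {
    for (ref in c("A", "C", "G", "T")) for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- paste0("ATG", p, ref, "TAA")
      b <- paste0("ATG", p, alt, "TAA")
      cmp <- compare_cds("x", a, b)
      expect_equal(cmp$snps$effect, "synonymous",
                   info = paste(p, ref, alt))
    }
  }
})

test_that("a single coding substitution is fully annotated", {
  cmp <- compare_cds("toy", "ATGGAATAA", "ATGAAATAA")
  s <- cmp$snps
  expect_equal(nrow(s), 1L)
  expect_equal(s$cds_position, 4L)
  expect_equal(s$codon_index, 2L)
  expect_equal(c(s$ref_nt, s$alt_nt), c("G", "A"))
  expect_equal(c(s$ref_aa, s$alt_aa), c("E", "K"))
  expect_equal(s$effect, "nonsynonymous")
  expect_equal(s$substitution_class, "transition")
  expect_equal(nrow(cmp$indels), 0L)
})

test_that("identical CDS yield no records; internal stops warn", {
  set.seed(2)
  cds <- cmsscan:::gene_cds(100)
  cmp <- compare_cds("g", cds, cds)
  expect_equal(nrow(cmp$snps), 0L)
  expect_equal(nrow(cmp$indels), 0L)
  bad <- paste0("ATG", "TAA", "AAA", "TAA")
  good <- paste0("ATG", "GAA", "AAA", "TAA")
  expect_warning(compare_cds("g", bad, good), "internal stop")
})

test_that("swapping the inputs swaps ref and alt but keeps the columns", {
  set.seed(14)
  a <- cmsscan:::gene_cds(120)
  b <- a
  for (p in c(31, 92, 200)) {
    ref <- substr(b, p, p)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), ref)[1]
  }
  ab <- compare_cds("g", a, b)$snps
  ba <- compare_cds("g", b, a)$snps
  expect_equal(ab$cds_position, ba$cds_position)
  expect_equal(ab$ref_nt, ba$alt_nt)
  expect_equal(ab$alt_nt, ba$ref_nt)
  expect_equal(ab$effect, ba$effect)
  expect_equal(ab$substitution_class, ba$substitution_class)
})

test_that("an in-frame 33 bp insertion is reported as one 11-residue indel", {
  set.seed(26)
  b <- cmsscan:::gene_cds(300)
  ins <- paste(sample(cmsscan:::codons_for(cmsscan:::POLAR_AA), 11,
                      replace = TRUE), collapse = "")
  a <- paste0(substr(b, 1, 450), ins, substring(b, 451))
  cmp <- compare_cds("rps3", a, b)
  expect_equal(nrow(cmp$indels), 1L)
  expect_equal(cmp$indels$length, 33L)
  expect_true(cmp$indels$in_frame)
  expect_equal(cmp$indels$aa_length, 11L)
  expect_equal(nrow(cmp$snps), 0L)
})

test_that("whole-genome diff of identical genomes is empty and 100% identical", {
  set.seed(37)
  g <- circular_genome(rand_seq(8000), id = "g")
  sd <- summarize_genome_diff(g, g)
  expect_equal(sd$snp_count, 0L)
  expect_equal(sd$gap_count, 0L)
  expect_equal(sd$coverage, 100)
  expect_equal(sd$identity, 100)
})

test_that("planted chloroplast-style SNPs and short gaps are recovered exactly", {
  dp <- simulate_diverged_pair(seed = 19)
  sd <- summarize_genome_diff(dp$a, dp$b)
  expect_equal(sd$snp_count, sum(dp$truth$kind == "snp"))
  expect_equal(sd$gap_count, sum(dp$truth$kind == "indel"))
  expect_equal(unname(sd$gap_length_histogram[">5"]), 0L)
  expect_gt(sd$coverage, 99)
  expect_gt(sd$identity, 99.5)
})
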
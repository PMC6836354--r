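test_that("genome construction normalises case and rejects bad alphabets", {
  g <- circular_genome("acgu", id = "x")
  expect_equal(g$sequence, "ACGT")
  expect_error(circular_genome("ACGR", id = "x"), "outside")
  expect_error(circular_genome("", id = "x"), "single character|empty")
})

test_that("GC content matches hand counts, excludes N, rounds half-up", {
  expect_equal(gc_content("ATGC"), 50.00)
  expect_equal(gc_content("AANT"), 0.00)
  # 1 GC in 800 ACGT bases = 0.125% -> 0.13 under half-up (0.12 to-even)
  expect_equal(gc_content(paste0(strrep("A", 799), "G")), 0.13)
  expect_error(gc_content("NNN"), "all N")
})

test_that("GC content is invariant under reverse complement", {
  set.seed(42)
  for (i in 1:20) {
    s <- rand_seq(sample(50:500, 1))
    expect_identical(gc_content(s), gc_content(reverse_complement(s)))
  }
})

test_that("reverse complement is an involution and maps N to N", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("NNA"), "TNN")
  set.seed(7)
  for (i in 1:20) {
    s <- rand_seq(sample(1:200, 1), alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("AXG"), "outside")
})

test_that("circular slices agree with slicing the doubled sequence", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    s <- rand_seq(n)
    g <- circular_genome(s, id = "g")
    doubled <- paste0(s, s)
    start <- sample(0:(n - 1), 1)
    end <- start + sample(1:n, 1)
    expect_identical(circular_slice(g, start, end),
                     substr(doubled, start + 1, end))
  }
  g <- circular_genome("ACGTACGTAC", id = "g")
  expect_identical(circular_slice(g, 8, 13), "ACACG")
  expect_identical(circular_slice(g, 0, g$length), g$sequence)
  lin <- circular_genome("ACGT", id = "l", circular = FALSE)
  expect_error(circular_slice(lin, 2, 6), "non-circular")
})

test_that("annotation summaries count features by type", {
  g <- circular_genome(strrep("ACGT", 50), id = "g")
  expect_equal(sum(annotation_summary(g)$counts), 0L)
  ann <- rbind(feature_table(1, "nad3", "CDS", 0, 30),
               feature_table(2, "trnA", "tRNA", 40, 60),
               feature_table(3, "nad3", "CDS", 80, 110),
               feature_table(4, "rrn26", "rRNA", 120, 150))
  g2 <- circular_genome(strrep("ACGT", 50), id = "g2", annotations = ann)
  s <- annotation_summary(g2)
  expect_equal(unname(s$counts[c("CDS", "tRNA", "rRNA")]), c(2L, 1L, 1L))
  expect_equal(s$duplicated_genes, "nad3")
})

test_that("synthetic genome with three planted CDS reports a CDS count of 3", {
  set.seed(5)
  ann <- rbind(feature_table(1, "g1", "CDS", 10, 40),
               feature_table(2, "g2", "CDS", 50, 80),
               feature_table(3, "g3", "CDS", 100, 130))
  g <- circular_genome(rand_seq(200), id = "s", annotations = ann)
  expect_equal(unname(annotation_summary(g)$counts[["CDS"]]), 3L)
})

test_that("FASTA round trip preserves sequence and id", {
  set.seed(3)
  g <- circular_genome(rand_seq(333), id = "mito1")
  fa <- tempfile(fileext = ".fasta")
  write_genome(g, fa, "fasta")
  g2 <- read_genome(fa, "fasta")
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$id, g$id)
})

test_that("GenBank round trip preserves sequence and join coordinates", {
  set.seed(4)
  ann <- rbind(feature_table(1, "rps3", "CDS", c(9, 49), c(30, 70), "+"),
               feature_table(2, "cob", "CDS", 100, 160, "-"),
               feature_table(3, "trnK", "tRNA", 200, 272, "+"))
  g <- circular_genome(rand_seq(300), id = "MT1", annotations = ann)
  gb <- tempfile(fileext = ".gb")
  write_genome(g, gb, "genbank")
  g2 <- read_genome(gb)
  expect_identical(g2$sequence, g$sequence)
  expect_true(g2$circular)
  a2 <- g2$annotations
  rps3 <- a2[a2$gene_name == "rps3", ]
  expect_equal(rps3$start, c(9, 49))   # join(10..30,50..70), 0-based half-open
  expect_equal(rps3$end, c(30, 70))
  expect_equal(a2$strand[a2$gene_name == "cob"], "-")
  expect_equal(unname(annotation_summary(g2)$counts[c("CDS", "tRNA")]), c(2L, 1L))
})

test_that("feature sequences are exon-joined on the coding strand", {
  s <- paste0("AAAA", "ATGCCC", "TTTT", "GGGTAA", "AAAA")
  ann <- rbind(feature_table(1, "x", "CDS", c(4, 14), c(10, 20), "+"))
  g <- circular_genome(s, id = "g", annotations = ann)
  expect_identical(feature_sequence(g, 1), "ATGCCCGGGTAA")
  # minus strand: same footprint, reverse-complemented
  ann2 <- feature_table(1, "y", "CDS", 4, 10, "-")
  g2 <- circular_genome(s, id = "g2", annotations = ann2)
  expect_identical(feature_sequence(g2, 1), reverse_complement("ATGCCC"))
})

test_that("GFF3 output has the expected shape", {
  set.seed(6)
  g <- circular_genome(rand_seq(100), id = "g",
                       annotations = feature_table(1, "nad1", "CDS", 10, 40))
  p <- tempfile(fileext = ".gff3")
  write_gff3(g$annotations, g, p)
  lines <- readLines(p)
  expect_match(lines[1], "gff-version 3")
  expect_match(lines[3], "\tCDS\t11\t40\t")
})
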
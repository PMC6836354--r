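test_that("the same seed reproduces byte-identical genomes", {
  s1 <- simulate_trio(sim_config(seed = 7))
  s2 <- simulate_trio(sim_config(seed = 7))
  for (nm in c("donor", "recipient", "cms")) {
    expect_identical(s1$genomes[[nm]]$sequence, s2$genomes[[nm]]$sequence)
    expect_identical(s1$genomes[[nm]]$annotations, s2$genomes[[nm]]$annotations)
  }
  expect_identical(s1$truth$orfs, s2$truth$orfs)
  s3 <- simulate_trio(sim_config(seed = 8))
  expect_false(identical(s1$genomes$cms$sequence, s3$genomes$cms$sequence))
})

test_that("the truth table is complete and internally consistent", {
  sim <- get_trio()
  cfg <- sim$config
  expect_equal(nrow(sim$truth$orfs), nrow(cfg$orf_plan))
  expect_equal(nrow(sim$truth$snps), nrow(cfg$snp_plan))
  expect_equal(nrow(sim$truth$repeats), nrow(cfg$repeat_plan))
  expect_equal(nrow(sim$truth$indels), length(cfg$indel_plan))
  # planted ORFs really sit at their recorded cms coordinates
  cms <- sim$genomes$cms
  for (i in seq_len(nrow(sim$truth$orfs))) {
    tr <- sim$truth$orfs[i, ]
    nt <- circular_slice(cms, tr$start, tr$end)
    if (tr$strand == "-") nt <- reverse_complement(nt)
    expect_identical(substr(nt, 1, 3), "ATG")
    expect_true(substring(nt, tr$nt_length - 2L) %in% c("TAA", "TAG", "TGA"))
    prot <- translate_cds(nt)
    expect_equal(nchar(prot) - 1L, tr$protein_length)
    expect_false(grepl("*", substr(prot, 1, nchar(prot) - 1L), fixed = TRUE))
  }
  # planted repeats really are exact copies with the recorded orientation
  for (i in seq_len(nrow(sim$truth$repeats))) {
    rp <- sim$truth$repeats[i, ]
    a <- circular_slice(cms, rp$pos_a, rp$pos_a + rp$length)
    b <- circular_slice(cms, rp$pos_b, rp$pos_b + rp$length)
    if (rp$orientation_cms == "inverted") b <- reverse_complement(b)
    expect_identical(a, b)
  }
})

test_that("planted synonymous substitutions never change the protein", {
  sim <- get_trio()
  donor_cds <- cmsscan:::core_gene_set(sim$genomes$donor)
  recip_cds <- cmsscan:::core_gene_set(sim$genomes$recipient)
  syn <- sim$truth$snps[sim$truth$snps$effect == "synonymous", ]
  expect_gt(nrow(syn), 0)
  for (g in unique(syn$gene)) {
    only_syn <- all(sim$truth$snps$effect[sim$truth$snps$gene == g] ==
                      "synonymous")
    if (only_syn) {
      expect_identical(translate_cds(donor_cds[[g]]),
                       translate_cds(recip_cds[[g]]))
    }
  }
  # per-site check: the recipient/donor nucleotides differ as recorded
  for (i in seq_len(nrow(sim$truth$snps))) {
    s <- sim$truth$snps[i, ]
    expect_identical(substr(recip_cds[[s$gene]], s$cds_position, s$cds_position),
                     s$recipient_nt)
    expect_identical(substr(donor_cds[[s$gene]], s$cds_position, s$cds_position),
                     s$donor_nt)
  }
})

test_that("fixture bundles load back through the standard readers", {
  sim <- get_trio()
  dir <- tempfile("bundle")
  paths <- write_fixture_bundle(sim, dir)
  expect_true(all(file.exists(paths)))
  expect_no_warning(g <- read_genome(paths[["cms.fasta"]]))
  expect_identical(g$sequence, sim$genomes$cms$sequence)
  truth <- read.table(paths[["truth_orfs"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), nrow(sim$truth$orfs))
  gff <- readLines(paths[["cms.gff3"]])
  expect_match(gff[1], "gff-version")
})

test_that("infeasible ORF layouts are rejected at configuration time", {
  plan <- default_orf_plan()
  plan$fragment_length[plan$name == "orf224"] <- 700L  # longer than the ORF
  expect_error(sim_config(orf_plan = plan), "shorter than")
})
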
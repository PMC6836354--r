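fake_orf <- function(nt, id = "orfX") {
  list(orf_id = id, nt_seq = nt, start = 0L, end = nchar(nt), strand = "+")
}

test_that("full-length core gene copies are excluded from chimera calls", {
  set.seed(15)
  cox1 <- cmsscan:::gene_cds(300)
  hits <- detect_chimera(fake_orf(cox1), c(cox1 = cox1))
  expect_equal(nrow(hits), 0L)
  expect_true(attr(hits, "core_copy"))
})

test_that("random ORFs yield no chimera hits", {
  set.seed(25)
  core <- list(atp8 = cmsscan:::gene_cds(200), cox1 = cmsscan:::gene_cds(400))
  orf <- fake_orf(rand_seq(700))
  hits <- detect_chimera(orf, core)
  expect_equal(nrow(hits), 0L)
  expect_false(attr(hits, "core_copy"))
})

test_that("a planted diverged atp8 fragment is detected on either strand", {
  set.seed(35)
  atp8 <- cmsscan:::gene_cds(250)
  frag <- substr(atp8, 101, 275)                       # 175 nt
  fv <- strsplit(frag, "")[[1]]
  for (m in sample(175, 4)) fv[m] <- sample(setdiff(c("A", "C", "G", "T"), fv[m]), 1)
  frag <- paste(fv, collapse = "")
  orf_fwd <- fake_orf(paste0(rand_seq(250), frag, rand_seq(250)))
  core <- c(atp8 = atp8, cox1 = cmsscan:::gene_cds(350))
  h <- detect_chimera(orf_fwd, core)
  expect_equal(nrow(h), 1L)
  expect_equal(h$core_gene, "atp8")
  expect_true(abs(h$fragment_length - 175) <= 10)
  expect_gte(h$identity, 96)
  # same fragment planted in reverse complement
  orf_rev <- fake_orf(paste0(rand_seq(250), reverse_complement(frag),
                             rand_seq(250)))
  h2 <- detect_chimera(orf_rev, core)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$core_gene, "atp8")
  expect_equal(h2$strand, "-")
  expect_true(abs(h2$fragment_length - 175) <= 10)
})

test_that("genomic context finds the nearest gene across the circle", {
  set.seed(45)
  ann <- rbind(feature_table(1, "nad3", "CDS", 5000, 6200),
               feature_table(2, "ccmB", "CDS", 9000, 9900))
  orf <- list(orf_id = "o1", start = 4597L, end = 4897L, strand = "+")
  ctx <- genomic_context(orf, ann, 12000L)
  expect_equal(ctx$gene_name, "nad3")
  expect_equal(ctx$distance, 103L)
  expect_equal(ctx$position, "downstream")
  # overlap
  orf2 <- list(orf_id = "o2", start = 6100L, end = 6400L, strand = "+")
  expect_equal(genomic_context(orf2, ann, 12000L)$distance, 0L)
  # wrap-around: gene near origin, ORF near the end
  orf3 <- list(orf_id = "o3", start = 11800L, end = 11950L, strand = "+")
  ann3 <- feature_table(1, "atp9", "CDS", 30, 500)
  ctx3 <- genomic_context(orf3, ann3, 12000L)
  expect_equal(ctx3$distance, 80L)
  expect_equal(ctx3$position, "downstream")
  # no annotations
  expect_true(is.na(genomic_context(orf, NULL, 12000L)$gene_name))
})

test_that("origin assignment distinguishes donor, recombinant and novel", {
  set.seed(65)
  donor <- circular_genome(rand_seq(6000), id = "d")
  recip <- circular_genome(rand_seq(6000), id = "r")
  lifted <- fake_orf(substr(donor$sequence, 1001, 1600))
  expect_equal(assign_origin(lifted, donor, recip), "donor_identical")
  lifted_r <- fake_orf(substr(recip$sequence, 2001, 2600))
  expect_equal(assign_origin(lifted_r, donor, recip), "recipient_identical")
  half <- fake_orf(paste0(substr(donor$sequence, 3001, 3300),
                          substr(recip$sequence, 4001, 4300)))
  expect_equal(assign_origin(half, donor, recip), "recombinant")
  novel <- fake_orf(rand_seq(600))
  expect_equal(assign_origin(novel, donor, recip), "novel")
  # same genome on both sides can never be recombinant
  expect_false(assign_origin(lifted, donor, donor) == "recombinant")
})

test_that("candidate ranking enforces the evidence tiers", {
  expect_equal(nrow(rank_candidates(cmsscan:::empty_orf_table(),
                                    data.frame(orf_id = character(0),
                                               tm_count = integer(0)),
                                    list())), 0L)
  specific <- data.frame(orf_id = c("orf1", "orf2", "orf3"),
                         stringsAsFactors = FALSE)
  tm <- data.frame(orf_id = c("orf1", "orf2", "orf3"),
                   tm_count = c(2L, 0L, 1L))
  chim <- list(
    orf1 = data.frame(orf_id = "orf1", core_gene = "atp8",
                      fragment_length = 175L, identity = 98),
    orf2 = data.frame(orf_id = "orf2", core_gene = "cox1",
                      fragment_length = 133L, identity = 98),
    orf3 = cmsscan:::empty_chimera_table())
  rep <- rank_candidates(specific, tm, chim)
  expect_equal(rep$rank_tier[rep$orf_id == "orf1"], "candidate")
  expect_equal(rep$rank_tier[rep$orf_id == "orf2"], "supporting")  # no TM
  expect_equal(rep$rank_tier[rep$orf_id == "orf3"], "supporting")  # no chimera
  cand <- rep[rep$rank_tier == "candidate", ]
  expect_true(all(cand$tm_count >= 1L & cand$n_chimera >= 1L))
  # key mismatch is an error
  expect_error(rank_candidates(specific, tm[1:2, ], chim), "keyed")
})
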
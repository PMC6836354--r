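# A 12-nt cassette guard containing a stop codon in all six reading frames
# (it is its own reverse complement), so no ORF can extend across it.
STOPBLOCK <- "TTAATTAATTAA"

POLAR_AA <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H")
HYDRO_AA <- c("I", "L", "V", "F")
codons_for <- function(aas) {
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc %in% aas])
}

#' Default coding-SNP plan for the synthetic trio
#'
#' 26 substitutions over 12 shared genes: 10 synonymous (5 transitions, 5
#' transversions) and 16 non-synonymous (13 transitions, 3 transversions),
#' the composition observed between a rapeseed CMS mitogenome and its
#' maintainer.
#'
#' @return `data.frame` with columns `gene`, `effect`, `class`.
#' @export
default_snp_plan <- function() {
  plan <- rbind(
    c("rpl5",   "nonsynonymous", "transition"),
    c("atp1",   "synonymous",    "transversion"),
    c("atp1",   "nonsynonymous", "transition"),
    c("ccmFN1", "nonsynonymous", "transversion"),
    c("ccmFN1", "nonsynonymous", "transition"),
    c("cox1",   "synonymous",    "transition"),
    c("cox1",   "synonymous",    "transversion"),
    c("cox1",   "synonymous",    "transition"),
    c("cox1",   "synonymous",    "transversion"),
    c("nad4",   "nonsynonymous", "transition"),
    c("orfX",   "synonymous",    "transition"),
    c("orfX",   "nonsynonymous", "transition"),
    c("orfX",   "nonsynonymous", "transition"),
    c("orfX",   "nonsynonymous", "transition"),
    c("orfX",   "nonsynonymous", "transition"),
    c("orfX",   "nonsynonymous", "transition"),
    c("rpl2",   "nonsynonymous", "transition"),
    c("rpl2",   "nonsynonymous", "transition"),
    c("rpl2",   "nonsynonymous", "transversion"),
    c("ccmFN2", "nonsynonymous", "transversion"),
    c("rps7",   "synonymous",    "transition"),
    c("matR",   "nonsynonymous", "transition"),
    c("matR",   "nonsynonymous", "transition"),
    c("rps12",  "synonymous",    "transversion"),
    c("rps12",  "synonymous",    "transversion"),
    c("nad3",   "synonymous",    "transition"))
  data.frame(gene = plan[, 1], effect = plan[, 2], class = plan[, 3],
             stringsAsFactors = FALSE)
}

#' Default donor-specific ORF plan for the synthetic trio
#'
#' Sixteen donor-specific ORFs mirroring a published CMS-specific ORF
#' inventory: protein lengths, per-ORF transmembrane stretch counts, and
#' three chimeric ORFs (one carrying a 175 bp atp8 fragment, two carrying a
#' 133 bp cox1 fragment, each at ~98% identity). Two ORFs carry genomic
#' context constraints (distance to the nearest functional gene).
#'
#' @return `data.frame`, one row per planted ORF.
#' @export
default_orf_plan <- function() {
  df <- data.frame(
    name = c("orf108a", "orf133a", "orf110", "orf309", "orf257", "orf346",
             "orf101b", "orf130", "orf224", "orf133b", "orf106", "orf115a",
             "orf170", "orf394", "orf192", "orf131"),
    protein_length = c(108L, 133L, 110L, 309L, 257L, 346L, 101L, 130L, 224L,
                       133L, 106L, 115L, 170L, 394L, 192L, 131L),
    tm_count = c(1L, 0L, 1L, 3L, 6L, 3L, 0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L, 1L, 0L),
    chimera_gene = c(NA, NA, NA, "cox1", NA, "cox1", NA, NA, "atp8",
                     NA, NA, NA, NA, NA, NA, NA),
    fragment_length = c(NA, NA, NA, 133L, NA, 133L, NA, NA, 175L,
                        NA, NA, NA, NA, NA, NA, NA),
    fragment_identity = c(NA, NA, NA, 98, NA, 98, NA, NA, 98,
                          NA, NA, NA, NA, NA, NA, NA),
    strand = c("+", "+", "-", "+", "+", "+", "+", "+", "+",
               "+", "+", "+", "+", "+", "+", "-"),
    context_gene = c(NA, NA, NA, NA, NA, "nad3", NA, NA, "ccmB",
                     NA, NA, NA, NA, NA, NA, NA),
    context_distance = c(NA, NA, NA, NA, NA, 103L, NA, NA, 217L,
                         NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  df
}

#' Default repeat plan for the synthetic trio
#'
#' Four long repeats (9432, 7383, 2427, 1592 nt). In the CMS mosaic the
#' first three are inverted and the last direct; the 7383 and 2427 nt
#' repeats also exist (as direct repeats) in both parents, the other two
#' are donor-lineage only.
#'
#' @return `data.frame` with `name`, `length`, `orientation_cms`,
#'   `in_recipient`.
#' @export
default_repeat_plan <- function() {
  data.frame(name = c("R1", "R2", "R3", "R4"),
             length = c(9432L, 7383L, 2427L, 1592L),
             orientation_cms = c("inverted", "inverted", "inverted", "direct"),
             in_recipient = c(FALSE, TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic donor/recipient/cybrid trio
#'
#' Defaults emulate the study conditions of a rapeseed alloplasmic CMS
#' system at reduced genome scale: 20 shared genes, 26 coding SNPs (10
#' synonymous / 16 non-synonymous), one 33 bp in-frame insertion in the
#' second exon of rps3, four long repeats (9432/7383/2427/1592 nt), 16
#' donor-specific ORFs of which 3 are chimeric with transmembrane
#' stretches, one recipient-specific gene (cox2-2) retained by the cybrid,
#' and a ~93% donor fraction in the mosaic.
#'
#' @param seed Integer seed driving all randomness.
#' @param recipient_length Approximate recipient genome length (nt).
#' @param gene_codons Range of gene lengths in codons.
#' @param snp_plan See [default_snp_plan()].
#' @param indel_plan Named list of in-frame insertion lengths per gene.
#' @param repeat_plan See [default_repeat_plan()].
#' @param orf_plan See [default_orf_plan()].
#' @param recipient_specific Lengths of recipient-only intergenic segments
#'   that the cybrid retains (these create the recipient-derived mosaic
#'   blocks).
#' @param min_protein_length ORF screen floor used when scrubbing
#'   incidental ORFs out of donor-only material.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       recipient_length = 130000L,
                       gene_codons = c(300L, 460L),
                       snp_plan = default_snp_plan(),
                       indel_plan = list(rps3 = 33L),
                       repeat_plan = default_repeat_plan(),
                       orf_plan = default_orf_plan(),
                       recipient_specific = rep(2000L, 5),
                       min_protein_length = 101L) {
  stopifnot(recipient_length > 50000L, all(recipient_specific > 0))
  if (any(!is.na(orf_plan$fragment_length) &
            orf_plan$fragment_length >= 3L * orf_plan$protein_length)) {
    stop("chimeric fragment must be shorter than its ORF")
  }
  structure(list(seed = as.integer(seed), recipient_length = recipient_length,
                 gene_codons = gene_codons, snp_plan = snp_plan,
                 indel_plan = indel_plan, repeat_plan = repeat_plan,
                 orf_plan = orf_plan, recipient_specific = recipient_specific,
                 min_protein_length = min_protein_length),
            class = "sim_config")
}

## ---- sequence generators ---------------------------------------------

rand_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Intergenic-style sequence seeded with stop codons for all six frames at
# high density, so long incidental ORFs are essentially impossible.
stoprich_dna <- function(n, gc = 0.55) {
  stops <- c("TAA", "TAG", "TGA", "TTA", "CTA", "TCA")
  out <- character(0); tot <- 0L
  while (tot < n) {
    chunk <- rand_dna(sample(4:9, 1L), gc)
    motif <- sample(stops, 1L)
    out <- c(out, chunk, motif)
    tot <- tot + nchar(chunk) + 3L
  }
  substr(paste(out, collapse = ""), 1L, n)
}

# Stop-rich sequence verified to contain no ORF above the screen floor.
orf_free_dna <- function(n, min_protein_length, gc = 0.55, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- stoprich_dna(n, gc)
    g <- circular_genome(s, id = "tmp", circular = FALSE)
    if (nrow(find_orfs(g, min_protein_length)) == 0L) return(s)
  }
  stop("could not generate ORF-free segment of length ", n)
}

gene_cds <- function(n_codons) {
  body <- sample(codons_for(POLAR_AA), n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

# Filler codons for planted ORFs: mostly polar, with sparse Leu/Val/Ile
# "breaker" codons (xTA/GTA) whose 2nd/3rd positions seed stop codons in the
# shifted reading frames, so incidental overlapping ORFs terminate quickly.
# Isolated hydrophobic residues cannot push a 19-residue hydropathy window
# over the transmembrane threshold.
filler_codons <- function(n, breaker_prob = 0.22) {
  polar <- codons_for(POLAR_AA)
  breakers <- c("CTA", "GTA", "TTA", "ATA")
  pool <- c(polar, breakers)
  probs <- c(rep((1 - breaker_prob) / length(polar), length(polar)),
             rep(breaker_prob / length(breakers), length(breakers)))
  sample(pool, n, replace = TRUE, prob = probs)
}

## ---- SNP / indel planting --------------------------------------------

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# Plant one substitution of the requested effect/class into a CDS; returns
# the modified CDS and the record. Codons already used are skipped.
plant_snp <- function(cds, effect, class, used_codons, max_tries = 500L) {
  ncod <- nchar(cds) %/% 3L
  for (i in seq_len(max_tries)) {
    ci <- sample(2:(ncod - 1L), 1L)
    if (ci %in% used_codons) next
    off <- sample(1:3, 1L)
    pos <- (ci - 1L) * 3L + off
    ref <- substr(cds, pos, pos)
    alt <- if (class == "transition") transition_of[[ref]]
           else sample(transversions_of[[ref]], 1L)
    cod <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    alt_cod <- cod
    substr(alt_cod, off, off) <- alt
    if (alt_cod %in% STOP_CODONS) next
    eff <- if (translate_cds(cod) == translate_cds(alt_cod)) "synonymous" else "nonsynonymous"
    if (eff != effect) next
    out <- cds
    substr(out, pos, pos) <- alt
    return(list(cds = out, record = data.frame(
      cds_position = pos, codon_index = ci, recipient_nt = ref, donor_nt = alt,
      effect = effect, substitution_class = class, stringsAsFactors = FALSE)))
  }
  stop("could not plant a ", effect, " ", class, " substitution")
}

## ---- ORF construction -------------------------------------------------

# Build one planted ORF: polar backbone, `tm_count` hydrophobic stretches,
# optionally a core-gene fragment overwritten at ~target identity at a
# non-codon-aligned offset. Self-checks: translation, TM count, and no
# incidental ORF in the guarded cassette.
build_planted_orf <- function(plan, core_cds, min_protein_length,
                              max_tries = 60L) {
  P <- plan$protein_length
  tm_len <- 23L
  polar_cod <- codons_for(POLAR_AA)
  hydro_cod <- codons_for(HYDRO_AA)
  # reserve a polar region for the chimeric fragment (residues 3 onward),
  # then distribute the TM stretches over the remainder
  frag_res <- if (is.na(plan$chimera_gene)) 0L
              else (plan$fragment_length + 2L) %/% 3L + 2L
  tm_from <- 2L + frag_res + 5L
  avail <- P - 1L - tm_from
  if (plan$tm_count > 0L && avail < plan$tm_count * (tm_len + 5L)) {
    stop("ORF ", plan$name, " too short for its TM/chimera layout")
  }
  for (try in seq_len(max_tries)) {
    is_tm <- rep(FALSE, P)
    if (plan$tm_count > 0L) {
      gap <- max(5L, (avail - plan$tm_count * tm_len) %/% (plan$tm_count + 1L))
      pos <- tm_from + gap
      for (t in seq_len(plan$tm_count)) {
        is_tm[pos:(pos + tm_len - 1L)] <- TRUE
        pos <- pos + tm_len + gap
      }
    }
    cods <- character(P)
    cods[1] <- "ATG"
    cods[is_tm] <- sample(hydro_cod, sum(is_tm), replace = TRUE)
    rest <- which(!is_tm & seq_len(P) > 1L)
    cods[rest] <- filler_codons(length(rest))
    nt <- paste(c(cods, "TAA"), collapse = "")

    frag_rec <- NULL
    if (!is.na(plan$chimera_gene)) {
      flen <- plan$fragment_length
      src <- core_cds[[plan$chimera_gene]]
      fstart <- sample(seq_len(nchar(src) - flen + 1L), 1L)
      frag <- substr(src, fstart, fstart + flen - 1L)
      n_mut <- max(1L, round(flen * (1 - plan$fragment_identity / 100)))
      mpos <- sample(seq_len(flen), n_mut)
      for (m in mpos) {
        ref <- substr(frag, m, m)
        substr(frag, m, m) <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      }
      # overwrite into the reserved polar region, deliberately not
      # codon-aligned (the homology is nucleotide-level)
      ins <- 8L
      substr(nt, ins, ins + flen - 1L) <- frag
      # repair any in-frame stop created by the overwrite
      repaired <- TRUE
      for (rep_i in 1:20) {
        body_cods <- codons_of(nt)[2:P]
        bad <- which(body_cods %in% STOP_CODONS)
        if (length(bad) == 0L) break
        b <- bad[1] + 1L
        p <- (b - 1L) * 3L + 1L + (sample(0:2, 1L))
        ref <- substr(nt, p, p)
        for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
          cand <- nt
          substr(cand, p, p) <- alt
          cc <- codons_of(cand)[b]
          if (!cc %in% STOP_CODONS) { nt <- cand; break }
        }
        if (rep_i == 20L) repaired <- FALSE
      }
      if (!repaired) next
      frag_rec <- list(gene = plan$chimera_gene, orf_offset = ins - 1L,
                       length = flen, source_start = fstart - 1L)
    }
    if (!is.null(frag_rec)) {
      # the fragment must still align at (close to) its target identity
      # after stop repairs
      chk <- local_align(nt, core_cds[[plan$chimera_gene]])
      if (abs(chk$aligned_length - plan$fragment_length) > 8L ||
          chk$identity < plan$fragment_identity - 1.5) next
    }
    prot <- translate_cds(nt)
    if (substr(prot, nchar(prot), nchar(prot)) != "*") next
    body <- substr(prot, 1L, nchar(prot) - 1L)
    if (grepl("*", body, fixed = TRUE) || substr(body, 1, 1) != "M") next
    if (predict_tm(body)$count != plan$tm_count) next
    cassette <- paste0(STOPBLOCK,
                       if (plan$strand == "-") reverse_complement(nt) else nt,
                       STOPBLOCK)
    g <- circular_genome(cassette, id = "cassette", circular = FALSE)
    found <- find_orfs(g, min_protein_length)
    if (nrow(found) != 1L || found$protein_length != P) next
    return(list(nt = nt, cassette = cassette, protein = body,
                fragment = frag_rec))
  }
  stop("could not construct planted ORF ", plan$name)
}

## ---- trio assembly ----------------------------------------------------

#' Simulate a donor/recipient/cybrid trio of circular mitogenomes
#'
#' Builds three circular genomes with fully known planted structure: the
#' recipient carries the shared genes (plus a recipient-specific cox2-2 and
#' recipient-only intergenic segments); the donor carries the same genes
#' mutated per the SNP/indel plans, donor-specific ORFs in guarded
#' intergenic cassettes, and the planted long repeats; the cybrid (CMS)
#' genome is a mosaic carrying all donor-specific features, the donor
#' alleles of every variant gene, and the recipient-specific segments, with
#' two shared repeats flipped to inverted orientation. Every planted
#' feature is recorded in a truth table sufficient to score all pipeline
#' stages. The same seed reproduces byte-identical genomes.
#'
#' @param config A [sim_config()].
#' @return An object of class `cms_sim`: list with `genomes` (named list
#'   `donor`, `recipient`, `cms` of `circular_genome`), `truth` (list of
#'   data.frames: `orfs`, `snps`, `indels`, `repeats`, `blocks`,
#'   `expected`), and `config`.
#' @export
simulate_trio <- function(config = sim_config()) {
  with_seed(config$seed, simulate_trio_impl(config))
}

simulate_trio_impl <- function(config) {
  genes <- c("cox1", "rpl5", "atp1", "ccmFN1", "nad4", "orfX", "rpl2",
             "ccmFN2", "rps7", "matR", "rps3", "atp8", "cox2", "cox2-2",
             "nad1", "nad3", "rps12", "nad2", "cob", "ccmB")
  minus_genes <- c("atp8", "cob")
  two_exon <- "rps3"

  # recipient CDS per gene
  n_cod <- sample(seq(config$gene_codons[1], config$gene_codons[2]),
                  length(genes), replace = TRUE)
  names(n_cod) <- genes
  n_cod["cox2-2"] <- 130L
  rec_cds <- setNames(lapply(n_cod, gene_cds), genes)

  # donor alleles: SNPs and in-frame insertions
  don_cds <- rec_cds
  snp_records <- list()
  for (g in unique(config$snp_plan$gene)) {
    rows <- config$snp_plan[config$snp_plan$gene == g, , drop = FALSE]
    used <- integer(0)
    for (i in seq_len(nrow(rows))) {
      pl <- plant_snp(don_cds[[g]], rows$effect[i], rows$class[i], used)
      don_cds[[g]] <- pl$cds
      used <- c(used, pl$record$codon_index)
      pl$record$gene <- g
      snp_records[[length(snp_records) + 1L]] <- pl$record
    }
  }
  indel_records <- list()
  for (g in names(config$indel_plan)) {
    len <- config$indel_plan[[g]]
    if (len %% 3L != 0L) stop("indel plan lengths must be in-frame (multiples of 3)")
    ncodg <- nchar(don_cds[[g]]) %/% 3L
    at <- sample(seq(ncodg %/% 2L + 10L, ncodg - 10L), 1L)  # inside exon 2
    ins <- paste(sample(codons_for(POLAR_AA), len %/% 3L, replace = TRUE),
                 collapse = "")
    don_cds[[g]] <- paste0(substr(don_cds[[g]], 1L, (at - 1L) * 3L), ins,
                           substring(don_cds[[g]], (at - 1L) * 3L + 1L))
    indel_records[[length(indel_records) + 1L]] <- data.frame(
      gene = g, cds_position = (at - 1L) * 3L + 1L, length = len,
      in_frame = TRUE, aa_length = len %/% 3L, stringsAsFactors = FALSE)
  }

  # planted ORFs (fragments are cut from donor alleles)
  orf_plan <- config$orf_plan
  orfs <- lapply(seq_len(nrow(orf_plan)), function(i) {
    build_planted_orf(orf_plan[i, ], don_cds, config$min_protein_length)
  })
  names(orfs) <- orf_plan$name

  # repeat units (ORF-free) and recipient-specific segments
  rp <- config$repeat_plan
  units <- setNames(lapply(rp$length, orf_free_dna,
                           min_protein_length = config$min_protein_length),
                    rp$name)
  rspec <- lapply(config$recipient_specific, stoprich_dna)

  # intron for the two-exon gene
  intron <- stoprich_dna(200L)

  # ---- element list ----------------------------------------------------
  # spacer index -> inserts, in order (trailing-constrained inserts last)
  assign <- list(`2` = "orf108a", `3` = "R2a", `4` = "orf133a", `5` = "rspec1",
                 `6` = "orf110", `7` = "R1a", `8` = "orf309", `9` = "rspec2",
                 `10` = c("orf257", "R3a"), `11` = "orf101b",
                 `12` = c("orf130", "R4a"), `13` = "rspec3",
                 `14` = c("orf133b", "orf106"), `15` = "R1b",
                 `16` = "orf346", `17` = "orf115a",
                 `18` = c("rspec4", "R2b"), `19` = c("orf170", "R3b"),
                 `20` = "orf224",
                 `21` = c("orf394", "orf192", "orf131", "R4b", "rspec5"))

  n_inserts <- sum(lengths(assign))
  n_pads <- length(genes) + 1L + n_inserts
  fixed_gene_len <- sum(nchar(unlist(rec_cds))) + nchar(intron)
  rspec_len <- sum(vapply(rspec, nchar, integer(1)))
  rec_repeat_len <- 2L * sum(rp$length[rp$in_recipient])
  pad_budget <- config$recipient_length - fixed_gene_len - rspec_len - rec_repeat_len
  base_pad <- max(600L, pad_budget %/% n_pads)

  pad <- function(n = NULL) {
    if (is.null(n)) n <- round(base_pad * runif(1, 0.7, 1.3))
    s <- stoprich_dna(n)
    list(type = "pad", name = paste0("pad", pad_counter <<- pad_counter + 1L),
         rec = s, don = s, cms = "don")
  }
  pad_counter <- 0L

  elems <- list()
  add <- function(e) elems[[length(elems) + 1L]] <<- e

  element_for <- function(nm) {
    if (grepl("^orf", nm)) {
      return(list(type = "orf", name = nm, rec = NULL,
                  don = orfs[[nm]]$cassette, cms = "don"))
    }
    if (grepl("^rspec", nm)) {
      i <- as.integer(sub("rspec", "", nm))
      return(list(type = "rspec", name = nm, rec = rspec[[i]], don = NULL,
                  cms = "rec"))
    }
    # repeat copy Rka / Rkb
    base <- substr(nm, 1, 2); copy <- substr(nm, 3, 3)
    row <- rp[rp$name == base, ]
    unit <- units[[base]]
    # copy b is reverse-complemented wherever the plan says the pair is
    # inverted: donor-only inverted repeats (R1) are inverted in donor and
    # cms alike; repeats shared with the recipient (R2/R3) stay direct in
    # both parents and are flipped only in the cms mosaic
    don_content <- if (!row$in_recipient && copy == "b" &&
                         row$orientation_cms == "inverted")
      reverse_complement(unit) else unit
    cms_override <- NULL
    if (row$in_recipient && copy == "b" && row$orientation_cms == "inverted") {
      cms_override <- reverse_complement(unit)
    }
    list(type = "repeat", name = nm,
         rec = if (row$in_recipient) unit else NULL,
         don = don_content,
         cms = if (!is.null(cms_override)) "override" else "don",
         cms_content = cms_override)
  }

  for (gi in seq_along(genes)) {
    add(pad())
    for (nm in assign[[as.character(gi)]] %||% character(0)) {
      trailing <- !is.na(match(nm, orf_plan$name)) &&
        !is.na(orf_plan$context_distance[match(nm, orf_plan$name)])
      add(element_for(nm))
      if (trailing) {
        d <- orf_plan$context_distance[match(nm, orf_plan$name)]
        add(pad(d - nchar(STOPBLOCK)))
      } else {
        add(pad())
      }
    }
    g <- genes[gi]
    cds_rec <- rec_cds[[g]]; cds_don <- don_cds[[g]]
    if (g == two_exon) {
      e1 <- (nchar(cds_rec) %/% 6L) * 3L   # exon 1 length (in frame)
      rec_content <- paste0(substr(cds_rec, 1, e1), intron, substring(cds_rec, e1 + 1L))
      don_content <- paste0(substr(cds_don, 1, e1), intron, substring(cds_don, e1 + 1L))
      add(list(type = "gene", name = g, rec = rec_content, don = don_content,
               cms = "don", exon1 = e1))
    } else {
      strand <- if (g %in% minus_genes) "-" else "+"
      rec_content <- if (strand == "-") reverse_complement(cds_rec) else cds_rec
      don_content <- if (g == "cox2-2") NULL else
        if (strand == "-") reverse_complement(cds_don) else cds_don
      add(list(type = "gene", name = g, rec = rec_content, don = don_content,
               cms = if (g == "cox2-2") "rec" else "don", strand = strand))
    }
  }
  add(pad())
  for (nm in assign[["21"]]) { add(element_for(nm)); add(pad()) }

  # ---- repeat boundary guards ------------------------------------------
  # force the pad nucleotide flanking copy a to A and copy b to C on both
  # sides, so exact repeats cannot extend past the planted copies in any
  # genome or orientation
  set_edge <- function(s, side, ch) {
    if (side == "last") substr(s, nchar(s), nchar(s)) <- ch
    else substr(s, 1, 1) <- ch
    s
  }
  for (i in seq_along(elems)) {
    e <- elems[[i]]
    if (e$type != "repeat") next
    ch <- if (grepl("a$", e$name)) "A" else "C"
    for (fld in c("rec", "don")) {
      if (!is.null(elems[[i - 1L]][[fld]])) {
        elems[[i - 1L]][[fld]] <- set_edge(elems[[i - 1L]][[fld]], "last", ch)
      }
      if (!is.null(elems[[i + 1L]][[fld]])) {
        elems[[i + 1L]][[fld]] <- set_edge(elems[[i + 1L]][[fld]], "first", ch)
      }
    }
  }

  # ---- assemble genomes and truth --------------------------------------
  content_of <- function(e, line) {
    switch(line,
           rec = e$rec,
           don = e$don,
           cms = if (identical(e$cms, "override")) e$cms_content
                 else if (e$cms == "don") e$don else e$rec)
  }
  assemble <- function(line) {
    offs <- list(); pos <- 0L; parts <- character(0)
    for (e in elems) {
      s <- content_of(e, line)
      if (is.null(s)) next
      offs[[e$name]] <- c(pos, pos + nchar(s))
      parts <- c(parts, s)
      pos <- pos + nchar(s)
    }
    list(seq = paste(parts, collapse = ""), offs = offs)
  }
  rec_a <- assemble("rec"); don_a <- assemble("don"); cms_a <- assemble("cms")

  ann_for <- function(asm) {
    feats <- list(); fid <- 0L
    for (e in elems) {
      if (e$type != "gene") next
      iv <- asm$offs[[e$name]]
      if (is.null(iv)) next
      fid <- fid + 1L
      if (!is.null(e$exon1)) {
        # two exons around the intron
        total <- iv[2] - iv[1]
        feats[[fid]] <- feature_table(fid, e$name, "CDS",
                                      start = c(iv[1], iv[1] + e$exon1 + 200L),
                                      end = c(iv[1] + e$exon1, iv[2]),
                                      strand = "+")
      } else {
        feats[[fid]] <- feature_table(fid, e$name, "CDS", iv[1], iv[2],
                                      strand = e$strand)
      }
    }
    do.call(rbind, feats)
  }

  genomes <- list(
    donor = circular_genome(don_a$seq, id = "donor", circular = TRUE,
                            source = "synthetic", annotations = ann_for(don_a)),
    recipient = circular_genome(rec_a$seq, id = "recipient", circular = TRUE,
                                source = "synthetic", annotations = ann_for(rec_a)),
    cms = circular_genome(cms_a$seq, id = "cms", circular = TRUE,
                          source = "synthetic", annotations = ann_for(cms_a)))

  # truth: planted ORFs in cms coordinates
  orf_truth <- do.call(rbind, lapply(seq_len(nrow(orf_plan)), function(i) {
    nm <- orf_plan$name[i]
    iv <- cms_a$offs[[nm]]
    nt_len <- 3L * (orf_plan$protein_length[i] + 1L)
    start <- iv[1] + nchar(STOPBLOCK)
    fr <- orfs[[nm]]$fragment
    data.frame(orf = nm, start = start, end = start + nt_len,
               strand = orf_plan$strand[i], nt_length = nt_len,
               protein_length = orf_plan$protein_length[i],
               tm_count = orf_plan$tm_count[i],
               chimera_gene = if (is.null(fr)) NA_character_ else fr$gene,
               fragment_length = if (is.null(fr)) NA_integer_ else fr$length,
               origin = "donor_identical",
               context_gene = orf_plan$context_gene[i],
               context_distance = orf_plan$context_distance[i],
               stringsAsFactors = FALSE)
  }))

  snps <- do.call(rbind, snp_records)
  snps <- snps[, c("gene", "cds_position", "codon_index", "recipient_nt",
                   "donor_nt", "effect", "substitution_class")]
  indels <- do.call(rbind, indel_records)

  rep_truth <- do.call(rbind, lapply(rp$name, function(nm) {
    a <- cms_a$offs[[paste0(nm, "a")]]; b <- cms_a$offs[[paste0(nm, "b")]]
    data.frame(name = nm, length = rp$length[rp$name == nm],
               orientation_cms = rp$orientation_cms[rp$name == nm],
               pos_a = a[1], pos_b = b[1],
               in_recipient = rp$in_recipient[rp$name == nm],
               stringsAsFactors = FALSE)
  }))

  # recipient-derived mosaic blocks in the cms genome
  rec_names <- c(paste0("rspec", seq_along(rspec)), "cox2-2")
  blocks <- do.call(rbind, lapply(rec_names, function(nm) {
    iv <- cms_a$offs[[nm]]
    data.frame(name = nm, start = iv[1], end = iv[2], stringsAsFactors = FALSE)
  }))
  cms_len <- nchar(cms_a$seq)
  rec_bp <- sum(blocks$end - blocks$start)
  expected <- list(
    n_specific_orfs = nrow(orf_plan),
    n_candidates = sum(!is.na(orf_plan$chimera_gene)),
    n_tm_positive = sum(orf_plan$tm_count > 0L),
    n_synonymous = sum(snps$effect == "synonymous"),
    n_nonsynonymous = sum(snps$effect == "nonsynonymous"),
    indel_length = if (nrow(indels)) indels$length[1] else NA_integer_,
    repeat_lengths = sort(rp$length, decreasing = TRUE),
    donor_fraction = 1 - rec_bp / cms_len,
    n_recipient_blocks = nrow(blocks))

  structure(list(genomes = genomes,
                 truth = list(orfs = orf_truth, snps = snps, indels = indels,
                              repeats = rep_truth, blocks = blocks,
                              expected = expected),
                 config = config),
            class = "cms_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cms_sim <- function(x, ...) {
  cat("<cms_sim> synthetic organelle trio (seed", x$config$seed, ")\n")
  for (nm in names(x$genomes)) {
    cat(sprintf("  %-9s %s bp\n", nm, format(x$genomes[[nm]]$length, big.mark = ",")))
  }
  cat(sprintf("  planted: %d specific ORFs (%d chimeric), %d SNPs, %d repeats\n",
              nrow(x$truth$orfs), sum(!is.na(x$truth$orfs$chimera_gene)),
              nrow(x$truth$snps), nrow(x$truth$repeats)))
  invisible(x)
}

#' Write a synthetic trio to standard-format files
#'
#' Emits FASTA and GFF3 per genome plus tab-separated truth tables. The
#' pipeline consumes only the FASTA/GFF3 files; the truth tables exist for
#' scoring.
#'
#' @param sim A [simulate_trio()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(sim$genomes)) {
    g <- sim$genomes[[nm]]
    fa <- file.path(dir, paste0(nm, ".fasta"))
    write_genome(g, fa, "fasta")
    gff <- file.path(dir, paste0(nm, ".gff3"))
    write_gff3(g$annotations, g, gff)
    paths <- c(paths, setNames(c(fa, gff), paste0(nm, c(".fasta", ".gff3"))))
  }
  for (nm in c("orfs", "snps", "indels", "repeats", "blocks")) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    write.table(sim$truth[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, setNames(p, paste0("truth_", nm)))
  }
  invisible(paths)
}

#' Simulate a near-identical genome pair with planted SNPs and short indels
#'
#' Emulates a chloroplast-style comparison: the second genome is a copy of
#' the first carrying `n_snp` substitutions and `n_indel` insertions or
#' deletions of 1-`indel_max` bp, all separated by at least 80 bp.
#'
#' @param seed Integer seed.
#' @param length Genome length (nt).
#' @param n_snp,n_indel Numbers of planted substitutions / indel runs.
#' @param indel_max Maximum indel length (bp).
#' @param gc GC fraction of the backbone.
#' @return List with `a`, `b` (`circular_genome`), and `truth` (planted
#'   site table).
#' @export
simulate_diverged_pair <- function(seed = 1L, length = 60000L, n_snp = 60L,
                                   n_indel = 50L, indel_max = 5L, gc = 0.36) {
  with_seed(seed, {
    a_seq <- rand_dna(length, gc)
    n_var <- n_snp + n_indel
    # variant sites separated by >= 80 bp
    gaps <- 80L + sample(0:(2L * (length %/% n_var - 90L)), n_var, replace = TRUE)
    pos <- 1000L + cumsum(gaps)
    if (max(pos) > length - 1000L) {
      pos <- round(seq(1000L, length - 1000L, length.out = n_var))
    }
    kind <- sample(c(rep("snp", n_snp), rep("indel", n_indel)))
    truth <- data.frame(position = pos, kind = kind, length = 0L,
                        stringsAsFactors = FALSE)
    b_seq <- a_seq
    for (i in rev(seq_len(n_var))) {    # edit right-to-left
      p <- pos[i]
      if (kind[i] == "snp") {
        ref <- substr(b_seq, p, p)
        substr(b_seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        truth$length[i] <- 1L
      } else {
        len <- sample(seq_len(indel_max), 1L)
        truth$length[i] <- len
        if (runif(1) < 0.5) {  # deletion in b
          b_seq <- paste0(substr(b_seq, 1L, p - 1L), substring(b_seq, p + len))
        } else {               # insertion in b
          b_seq <- paste0(substr(b_seq, 1L, p - 1L), rand_dna(len, gc),
                          substring(b_seq, p))
        }
      }
    }
    list(a = circular_genome(a_seq, id = "cp_a", source = "synthetic"),
         b = circular_genome(b_seq, id = "cp_b", source = "synthetic"),
         truth = truth)
  })
}
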
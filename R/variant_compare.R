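#' Classify a nucleotide substitution as transition or transversion
#'
#' Purine<->purine (`A<->G`) and pyrimidine<->pyrimidine (`C<->T`) changes
#' are transitions; all purine<->pyrimidine changes are transversions.
#'
#' @param ref_nt,alt_nt Distinct nucleotides in `{A,C,G,T}`.
#' @return `"transition"` or `"transversion"`.
#' @export
classify_substitution <- function(ref_nt, alt_nt) {
  ref_nt <- toupper(ref_nt); alt_nt <- toupper(alt_nt)
  if (!all(c(ref_nt, alt_nt) %in% c("A", "C", "G", "T"))) {
    stop("nucleotides must be in {A,C,G,T}")
  }
  if (ref_nt == alt_nt) stop("identical nucleotides are not a variant")
  purine <- c("A", "G")
  if ((ref_nt %in% purine) == (alt_nt %in% purine)) "transition" else "transversion"
}

#' Compare two orthologous coding sequences
#'
#' The exon-joined coding sequences are globally aligned; every mismatch
#' column yields a SNP record with codon context taken from sequence `a`
#' (multi-hit codons are classified by joint codon translation), and every
#' gap run yields an indel record. Positions are 1-based in `a`'s CDS
#' coordinates.
#'
#' @param gene_name Gene label carried into the records.
#' @param cds_a,cds_b Coding-strand CDS sequences (length >= 3).
#' @param scheme A [scoring_scheme()].
#' @return List with `snps` (data.frame: `gene`, `cds_position`, `ref_nt`,
#'   `alt_nt`, `codon_index`, `ref_aa`, `alt_aa`, `effect`,
#'   `substitution_class`) and `indels` (data.frame: `gene`, `cds_position`,
#'   `length`, `in_frame`, `aa_length`).
#' @export
compare_cds <- function(gene_name, cds_a, cds_b, scheme = scoring_scheme()) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) < 3L || nchar(cds_b) < 3L) stop("CDS must be at least one codon")
  for (s in list(c(gene_name, cds_a), c(gene_name, cds_b))) {
    prot <- translate_cds(s[2])
    body <- substr(prot, 1L, nchar(prot) - 1L)
    if (grepl("*", body, fixed = TRUE)) {
      warning("internal stop codon in CDS of ", s[1], "; classification still emitted")
    }
  }
  al <- global_align(cds_a, cds_b, scheme)
  qa <- strsplit(al$aligned_query, "", fixed = TRUE)[[1]]
  qb <- strsplit(al$aligned_ref, "", fixed = TRUE)[[1]]
  apos <- cumsum(qa != "-")                # 1-based position in a per column

  snp_cols <- which(qa != "-" & qb != "-" & qa != qb)
  snps <- empty_snp_table()
  if (length(snp_cols)) {
    pos <- apos[snp_cols]
    cod_idx <- (pos - 1L) %/% 3L + 1L
    cods_a <- codons_of(cds_a)
    records <- lapply(seq_along(snp_cols), function(i) {
      ci <- cod_idx[i]
      ref_cod <- cods_a[ci]
      # apply every aligned substitution falling in this codon (joint translation)
      alt_cod <- strsplit(ref_cod, "")[[1]]
      in_codon <- which(cod_idx == ci)
      off <- pos[in_codon] - (ci - 1L) * 3L
      alt_cod[off] <- qb[snp_cols[in_codon]]
      alt_cod <- paste(alt_cod, collapse = "")
      ref_aa <- translate_cds(ref_cod); alt_aa <- translate_cds(alt_cod)
      data.frame(gene = gene_name, cds_position = pos[i],
                 ref_nt = qa[snp_cols[i]], alt_nt = qb[snp_cols[i]],
                 codon_index = ci, ref_aa = ref_aa, alt_aa = alt_aa,
                 effect = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
                 substitution_class = classify_substitution(qa[snp_cols[i]], qb[snp_cols[i]]),
                 stringsAsFactors = FALSE)
    })
    snps <- do.call(rbind, records)
  }

  indels <- empty_indel_table()
  is_gap <- qa == "-" | qb == "-"
  if (any(is_gap)) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    recs <- lapply(seq_len(nrow(runs)), function(i) {
      len <- runs[i, 2] - runs[i, 1] + 1L
      # position in a-coordinates of the first column of the run (for a gap
      # in a, the a-position of the next real character)
      p <- apos[runs[i, 1]]
      if (qa[runs[i, 1]] == "-") p <- p + 1L
      data.frame(gene = gene_name, cds_position = p, length = len,
                 in_frame = len %% 3L == 0L,
                 aa_length = if (len %% 3L == 0L) len %/% 3L else NA_integer_,
                 stringsAsFactors = FALSE)
    })
    indels <- do.call(rbind, recs)
  }
  list(snps = snps, indels = indels)
}

empty_snp_table <- function() {
  data.frame(gene = character(0), cds_position = integer(0),
             ref_nt = character(0), alt_nt = character(0),
             codon_index = integer(0), ref_aa = character(0),
             alt_aa = character(0), effect = character(0),
             substitution_class = character(0), stringsAsFactors = FALSE)
}

empty_indel_table <- function() {
  data.frame(gene = character(0), cds_position = integer(0),
             length = integer(0), in_frame = logical(0),
             aa_length = integer(0), stringsAsFactors = FALSE)
}

#' Whole-genome difference summary between two broadly homologous genomes
#'
#' Collinearity blocks are computed ([anchor_map()] + [chain_blocks()]) and
#' their alignment columns are tallied: substitution columns (SNPs), maximal
#' indel runs (gaps) with a length histogram, plus block coverage of `a` and
#' length-weighted identity.
#'
#' @param a,b `circular_genome` objects.
#' @param k Anchor k-mer size.
#' @param ... Passed to [chain_blocks()].
#' @return List: `snp_count`, `gap_count`, `gap_length_histogram` (bins
#'   `1-5` and `>5` bp), `coverage` (percent of `a` in blocks), `identity`
#'   (percent), `blocks`.
#' @export
summarize_genome_diff <- function(a, b, k = 31L, ...) {
  anchors <- anchor_map(a, b, k = k)
  ch <- chain_blocks(anchors, a, b, ...)
  if (nrow(ch$blocks) == 0L) {
    warning("no homologous blocks found between ", a$id, " and ", b$id)
    return(list(snp_count = 0L, gap_count = 0L,
                gap_length_histogram = c(`1-5` = 0L, `>5` = 0L),
                coverage = 0, identity = NA_real_, blocks = ch$blocks))
  }
  gl <- ch$gap_lengths
  list(snp_count = sum(ch$blocks$mismatches),
       gap_count = length(gl),
       gap_length_histogram = c(`1-5` = sum(gl >= 1 & gl <= 5), `>5` = sum(gl > 5)),
       coverage = ch$coverage,
       identity = ch$identity,
       blocks = ch$blocks)
}
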
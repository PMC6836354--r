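#' Detect chimeric fragments of core mitochondrial genes within an ORF
#'
#' Each core gene CDS is aligned locally against the ORF (both strands);
#' the best hit per gene is kept when it reaches `min_fragment` aligned
#' columns at `min_identity` percent. ORFs whose best hit covers at least
#' `copy_coverage` of the ORF at `copy_identity` percent are reclassified
#' as plain core-gene copies and yield no chimera hits.
#'
#' @param orf One row of a [find_orfs()] table.
#' @param core_genes Named character vector of core-gene CDS sequences
#'   (conventionally every annotated CDS of the maintainer mitogenome).
#' @param min_fragment Minimum aligned fragment length (nt).
#' @param min_identity Minimum fragment identity (percent).
#' @param copy_coverage,copy_identity Core-gene-copy exclusion thresholds.
#' @param scheme A [scoring_scheme()].
#' @return `data.frame` of hits: `orf_id`, `core_gene`, `fragment_length`,
#'   `identity`, `orf_start`, `orf_end`, `gene_start`, `gene_end` (0-based
#'   half-open within ORF / gene), `strand`. Attribute `core_copy` is TRUE
#'   when the ORF was excluded as a full copy.
#' @export
detect_chimera <- function(orf, core_genes, min_fragment = 100L,
                           min_identity = 90.0, copy_coverage = 0.80,
                           copy_identity = 95.0, scheme = scoring_scheme()) {
  if (length(core_genes) == 0L) stop("core gene set is empty")
  seq <- orf$nt_seq
  hits <- list()
  best_cov <- 0; best_cov_ident <- 0
  for (g in names(core_genes)) {
    gene_seq <- core_genes[[g]]
    h_fwd <- local_align(seq, gene_seq, scheme)
    h_rev <- local_align(seq, reverse_complement(gene_seq), scheme)
    strand <- if (h_rev$score > h_fwd$score) "-" else "+"
    h <- if (strand == "-") h_rev else h_fwd
    gene_iv <- h$ref_interval
    if (strand == "-") {
      gene_iv <- c(nchar(gene_seq) - h$ref_interval[2],
                   nchar(gene_seq) - h$ref_interval[1])
    }
    cov <- (h$query_interval[2] - h$query_interval[1]) / nchar(seq)
    if (cov > best_cov) { best_cov <- cov; best_cov_ident <- h$identity }
    if (h$aligned_length >= min_fragment && h$identity >= min_identity) {
      hits[[g]] <- data.frame(
        orf_id = orf$orf_id, core_gene = g,
        fragment_length = h$aligned_length,
        identity = round_half_up(h$identity, 2),
        orf_start = h$query_interval[1], orf_end = h$query_interval[2],
        gene_start = gene_iv[1], gene_end = gene_iv[2],
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  core_copy <- best_cov >= copy_coverage && best_cov_ident >= copy_identity
  out <- if (length(hits) == 0L || core_copy) empty_chimera_table()
         else do.call(rbind, hits)
  rownames(out) <- NULL
  attr(out, "core_copy") <- core_copy
  out
}

empty_chimera_table <- function() {
  data.frame(orf_id = character(0), core_gene = character(0),
             fragment_length = integer(0), identity = numeric(0),
             orf_start = integer(0), orf_end = integer(0),
             gene_start = integer(0), gene_end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Nearest annotated gene of an ORF on a circular genome
#'
#' Distance is the circular intergenic gap in base pairs (0 when the ORF
#' overlaps the gene). The relative position is reported from the ORF's
#' point of view on its own strand; ties break toward upstream.
#'
#' @param orf One row of a [find_orfs()] table.
#' @param annotations Feature table on the same genome (CDS/tRNA/rRNA).
#' @param genome_length Genome length (nt).
#' @return List `gene_name`, `distance`, `position` (`upstream` /
#'   `downstream` / `overlapping`), or `NULL`-free sentinel with
#'   `gene_name = NA` when there are no annotations.
#' @export
genomic_context <- function(orf, annotations, genome_length) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(list(gene_name = NA_character_, distance = NA_integer_,
                position = NA_character_))
  }
  L <- genome_length
  os <- orf$start %% L; oe <- (orf$end - 1L) %% L  # inclusive endpoints
  per_feat <- split(annotations, annotations$feature_id)
  best <- NULL
  for (seg in per_feat) {
    gs <- min(seg$start); ge <- max(seg$end) - 1L
    # circular gap from orf end to gene start and gene end to orf start
    fwd_gap <- (gs - oe - 1L) %% L        # gene begins after ORF ends
    rev_gap <- (os - ge - 1L) %% L        # gene ends before ORF starts
    dist <- min(fwd_gap, rev_gap)
    olap <- circ_overlap(os, oe, gs, ge, L)
    if (olap) { dist <- 0L; rel <- "overlapping" }
    else if (fwd_gap <= rev_gap) rel <- if (orf$strand == "+") "downstream" else "upstream"
    else rel <- if (orf$strand == "+") "upstream" else "downstream"
    cand <- list(gene_name = seg$gene_name[1], distance = as.integer(dist),
                 position = rel)
    if (is.null(best) || cand$distance < best$distance ||
        (cand$distance == best$distance && cand$position == "upstream" &&
         best$position != "upstream")) {
      best <- cand
    }
  }
  best
}

# Do inclusive arcs [a1,a2] and [b1,b2] overlap on a circle of size L?
circ_overlap <- function(a1, a2, b1, b2, L) {
  expand <- function(s, e) if (s <= e) list(c(s, e)) else list(c(s, L - 1L), c(0L, e))
  for (x in expand(a1, a2)) for (y in expand(b1, b2)) {
    if (x[1] <= y[2] && y[1] <= x[2]) return(TRUE)
  }
  FALSE
}

#' Assign the parental origin of an ORF in a cybrid genome
#'
#' Uses exact string search (both strands, doubled sequences for circular
#' molecules): `donor_identical` when a full-length perfect copy exists in
#' the donor and none in the recipient, `recipient_identical` symmetrically;
#' `recombinant` when the full length is only reconstructable as a donor
#' prefix plus recipient suffix (or vice versa); `novel` otherwise. An ORF
#' found verbatim in both parents cannot be attributed and is reported as
#' `recipient_identical` (the conservative call for a cybrid carrying the
#' recipient nucleus).
#'
#' @param orf One row of a [find_orfs()] table.
#' @param donor,recipient `circular_genome` objects.
#' @return Origin label (character scalar).
#' @export
assign_origin <- function(orf, donor, recipient) {
  seq <- orf$nt_seq
  dbl <- function(g) if (g$circular) paste0(g$sequence, g$sequence) else g$sequence
  Dd <- dbl(donor); Rr <- dbl(recipient)
  found <- function(s, g2) grepl(s, g2, fixed = TRUE) ||
    grepl(reverse_complement(s), g2, fixed = TRUE)
  in_d <- found(seq, Dd); in_r <- found(seq, Rr)
  if (in_d && !in_r) return("donor_identical")
  if (in_r && !in_d) return("recipient_identical")
  if (in_d && in_r) return("recipient_identical")
  # longest exact prefix/suffix present in each parent (binary search)
  n <- nchar(seq)
  max_prefix <- function(g2) bsearch(function(m) found(substr(seq, 1L, m), g2), n)
  max_suffix <- function(g2) bsearch(function(m) found(substr(seq, n - m + 1L, n), g2), n)
  if (max_prefix(Dd) + max_suffix(Rr) >= n) return("recombinant")
  if (max_prefix(Rr) + max_suffix(Dd) >= n) return("recombinant")
  "novel"
}

# Largest m in [0, n] with pred(m) TRUE; pred is monotone decreasing.
bsearch <- function(pred, n) {
  lo <- 0L; hi <- n
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (pred(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Combine screening evidence into ranked CMS candidate reports
#'
#' The candidate tier contains exactly the CMS-specific ORFs that carry at
#' least one predicted transmembrane segment and at least one chimeric
#' fragment of a core mitochondrial gene; specific ORFs with one line of
#' evidence are `supporting`, the rest `excluded`. Candidates are ordered
#' by chimera identity x fragment length, then transmembrane count,
#' descending.
#'
#' @param specific A [specific_orfs()] table.
#' @param tm A [predict_tm_orfs()] table for the same ORFs.
#' @param chimera Named list of [detect_chimera()] tables keyed by `orf_id`.
#' @param context Named list of [genomic_context()] results keyed by `orf_id`.
#' @param origin Named character vector of [assign_origin()] labels.
#' @return `data.frame` of candidate reports sorted candidate tier first.
#' @export
rank_candidates <- function(specific, tm, chimera, context = NULL, origin = NULL) {
  if (nrow(specific) == 0L) return(empty_candidate_table())
  if (!setequal(specific$orf_id, tm$orf_id) ||
      !all(specific$orf_id %in% names(chimera))) {
    stop("specific/tm/chimera inputs must be keyed by the same orf_ids")
  }
  rows <- lapply(seq_len(nrow(specific)), function(i) {
    id <- specific$orf_id[i]
    tmc <- tm$tm_count[match(id, tm$orf_id)]
    ch <- chimera[[id]]
    nch <- if (is.null(ch)) 0L else nrow(ch)
    ctx <- if (!is.null(context)) context[[id]] else NULL
    tier <- if (tmc >= 1L && nch >= 1L) "candidate"
            else if (tmc >= 1L || nch >= 1L) "supporting" else "excluded"
    sc <- if (nch) max(ch$identity * ch$fragment_length) else 0
    data.frame(
      orf_id = id, specific = TRUE, tm_count = tmc, n_chimera = nch,
      chimera_gene = if (nch) paste(ch$core_gene, collapse = ",") else NA_character_,
      fragment_length = if (nch) ch$fragment_length[which.max(ch$identity * ch$fragment_length)] else NA_integer_,
      fragment_identity = if (nch) max(ch$identity) else NA_real_,
      nearest_gene = if (!is.null(ctx)) ctx$gene_name else NA_character_,
      nearest_distance = if (!is.null(ctx)) ctx$distance else NA_integer_,
      nearest_position = if (!is.null(ctx)) ctx$position else NA_character_,
      origin = if (!is.null(origin)) unname(origin[id]) else NA_character_,
      rank_tier = tier, score = sc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tier_rank <- match(out$rank_tier, c("candidate", "supporting", "excluded"))
  out <- out[order(tier_rank, -out$score, -out$tm_count, out$orf_id), , drop = FALSE]
  out$score <- NULL
  rownames(out) <- NULL
  out
}

empty_candidate_table <- function() {
  data.frame(orf_id = character(0), specific = logical(0), tm_count = integer(0),
             n_chimera = integer(0), chimera_gene = character(0),
             fragment_length = integer(0), fragment_identity = numeric(0),
             nearest_gene = character(0), nearest_distance = integer(0),
             nearest_position = character(0), origin = character(0),
             rank_tier = character(0), stringsAsFactors = FALSE)
}
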
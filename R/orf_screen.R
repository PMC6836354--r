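#' Call open reading frames on a circular genome
#'
#' Both strands are scanned in all three frames under the standard genetic
#' code (plant mitochondria use the standard code). ORFs start at `ATG` and
#' end at the first in-frame stop; per (stop, frame) only the longest
#' ATG-initiated ORF is reported, so nested in-frame starts are suppressed.
#' Circular genomes are scanned on the doubled sequence and duplicate calls
#' landing entirely in the second copy are removed, so ORFs spanning the
#' origin are recovered. ORFs are named `orf<protein length>` with `a`, `b`,
#' ... suffixes on ties (in genome-position order).
#'
#' @param genome A `circular_genome`.
#' @param min_protein_length Minimum protein length in residues (the
#'   conventional "longer than 100 aa" screen corresponds to 101).
#' @return A `data.frame` with one row per ORF: `orf_id`, `genome_id`,
#'   `start`, `end` (0-based half-open on the forward strand; `end` may
#'   exceed the genome length when the ORF wraps the origin), `strand`,
#'   `nt_length` (including the stop codon), `protein`, `protein_length`,
#'   `nt_seq` (coding-strand sequence including the stop codon).
#' @export
find_orfs <- function(genome, min_protein_length = 101L) {
  L <- genome$length
  fwd <- if (genome$circular) paste0(genome$sequence, genome$sequence) else genome$sequence
  rev <- reverse_complement(fwd)
  hits <- rbind(scan_orf_frames(fwd, "+"), scan_orf_frames(rev, "-"))
  if (nrow(hits) == 0L) return(empty_orf_table())

  # map scanned coordinates (on fwd / rev string) to forward-strand footprint
  n2 <- nchar(fwd)
  fs <- ifelse(hits$strand == "+", hits$start, n2 - hits$end)
  fe <- ifelse(hits$strand == "+", hits$end, n2 - hits$start)
  keep <- fs < L & (fe - fs) <= L
  hits <- hits[keep, , drop = FALSE]; fs <- fs[keep]; fe <- fe[keep]
  # dedupe identical footprints (doubled-sequence copies)
  key <- paste(fs %% L, fe - fs, hits$strand)
  dup <- duplicated(key)
  hits <- hits[!dup, , drop = FALSE]; fs <- fs[!dup]; fe <- fe[!dup]

  nt_len <- fe - fs
  prot_len <- nt_len %/% 3L - 1L
  keep <- prot_len >= min_protein_length
  hits <- hits[keep, , drop = FALSE]; fs <- fs[keep]; fe <- fe[keep]
  nt_len <- nt_len[keep]; prot_len <- prot_len[keep]
  if (nrow(hits) == 0L) return(empty_orf_table())

  ord <- order(fs, fe, hits$strand)
  hits <- hits[ord, , drop = FALSE]; fs <- fs[ord]; fe <- fe[ord]
  nt_len <- nt_len[ord]; prot_len <- prot_len[ord]

  nt_seq <- vapply(seq_along(fs), function(i) {
    s <- circular_slice(genome, fs[i], fe[i])
    if (hits$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
  protein <- vapply(nt_seq, function(s) {
    p <- translate_cds(s)
    substr(p, 1L, nchar(p) - 1L)  # drop trailing stop
  }, character(1), USE.NAMES = FALSE)

  # orf<len> naming with tie suffixes in position order
  ids <- paste0("orf", prot_len)
  for (len in unique(prot_len[duplicated(prot_len)])) {
    idx <- which(prot_len == len)
    ids[idx] <- paste0("orf", len, letters[seq_along(idx)])
  }

  data.frame(orf_id = ids, genome_id = genome$id, start = fs, end = fe,
             strand = hits$strand, nt_length = nt_len, protein = protein,
             protein_length = prot_len, nt_seq = nt_seq,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_orf_table <- function() {
  data.frame(orf_id = character(0), genome_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             nt_length = integer(0), protein = character(0),
             protein_length = integer(0), nt_seq = character(0),
             stringsAsFactors = FALSE)
}

# Scan the three frames of one strand of `s`; returns 0-based half-open
# [start, end) on s (end includes the stop codon).
scan_orf_frames <- function(s, strand) {
  out <- list()
  n <- nchar(s)
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    starts <- seq.int(f + 1L, by = 3L, length.out = ncod)
    cods <- substring(s, starts, starts + 2L)
    is_stop <- cods %in% STOP_CODONS
    is_atg <- cods == "ATG"
    if (!any(is_stop) || !any(is_atg)) next
    # group codons by the number of stops strictly before them
    grp <- cumsum(c(0L, head(is_stop, -1L)))
    stop_idx <- which(is_stop)            # one stop terminates each group
    stop_grp <- grp[stop_idx]
    atg_idx <- which(is_atg)
    first_atg <- vapply(split(atg_idx, grp[atg_idx]), min, integer(1))
    g <- intersect(names(first_atg), as.character(stop_grp))
    if (length(g) == 0L) next
    a <- first_atg[g]
    st <- stop_idx[match(as.integer(g), stop_grp)]
    out[[length(out) + 1L]] <- data.frame(
      start = f + (a - 1L) * 3L,
      end = f + st * 3L,
      strand = strand)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

#' Decide whether an ORF is present in another genome
#'
#' The ORF nucleotide sequence is searched against both strands of the
#' (doubled, for circular molecules) target. An exact substring match short
#' circuits to coverage 1 / identity 100; otherwise shared 15-mers seed a
#' window that is aligned locally ([local_align()]). The verdict is
#' `present` iff `coverage >= coverage_min` and `identity >= identity_min`.
#' Identity is computed over aligned (non-gap) columns here, so that a
#' short indel (e.g. an in-frame insertion inside a shared gene) does not
#' mask an otherwise intact copy.
#'
#' @param orf One row of a [find_orfs()] table (or any list with `orf_id`
#'   and `nt_seq`).
#' @param target A `circular_genome`.
#' @param coverage_min Minimum fraction of the ORF covered by the best hit.
#' @param identity_min Minimum percent identity of the best hit.
#' @param scheme A [scoring_scheme()].
#' @return List: `orf_id`, `present_in`, `coverage`, `identity`, `verdict`.
#' @export
call_presence <- function(orf, target, coverage_min = 0.90, identity_min = 95.0,
                          scheme = scoring_scheme()) {
  seq <- orf$nt_seq
  tgt <- if (target$circular) paste0(target$sequence, target$sequence) else target$sequence
  res <- list(coverage = 0, identity = 0)
  for (s in c(seq, reverse_complement(seq))) {
    if (grepl(s, tgt, fixed = TRUE)) { res <- list(coverage = 1, identity = 100); break }
    hit <- seeded_local_hit(s, tgt, scheme)
    if (!is.null(hit)) {
      cov <- (hit$query_interval[2] - hit$query_interval[1]) / nchar(s)
      ident <- if (hit$matches + hit$mismatches > 0)
        100 * hit$matches / (hit$matches + hit$mismatches) else 0
      if (cov > res$coverage || (cov == res$coverage && ident > res$identity)) {
        res <- list(coverage = cov, identity = ident)
      }
    }
  }
  verdict <- if (res$coverage >= coverage_min && res$identity >= identity_min)
    "present" else "absent"
  list(orf_id = orf$orf_id, present_in = target$id,
       coverage = res$coverage, identity = res$identity, verdict = verdict)
}

# Best local alignment of `q` against a window of `t` seeded by shared
# 15-mers (full dynamic programming against a whole organelle genome is
# wasteful when a seed tells us where the homology lives).
seeded_local_hit <- function(q, t, scheme, k = 15L) {
  qk <- unique(kmers(q, k))
  if (length(qk) == 0L) return(NULL)
  pos <- integer(0)
  # locate seed positions of query kmers in the target
  hit <- which(!is.na(match(kmers(t, k), qk)))
  if (length(hit) == 0L) return(NULL)
  # cluster seed positions; align around the densest cluster
  hit <- sort(hit)
  brk <- c(0L, which(diff(hit) > nchar(q)), length(hit))
  sizes <- diff(brk)
  best <- which.max(sizes)
  win <- c(max(1L, hit[brk[best] + 1L] - nchar(q)),
           min(nchar(t), hit[brk[best + 1L]] + k + nchar(q)))
  local_align(q, substr(t, win[1], win[2]), scheme)
}

#' ORFs specific to a CMS genome relative to its maintainer
#'
#' Calls ORFs on the CMS genome and keeps those judged absent from the
#' maintainer by [call_presence()].
#'
#' @param cms,maintainer `circular_genome` objects.
#' @param min_protein_length Minimum protein length (residues).
#' @param coverage_min,identity_min Presence thresholds.
#' @param scheme A [scoring_scheme()].
#' @param orfs Optional precomputed [find_orfs()] table for `cms`.
#' @return The subset of the ORF table absent from the maintainer, in genome
#'   position order, with `coverage` and `identity` columns for the best
#'   maintainer hit.
#' @export
specific_orfs <- function(cms, maintainer, min_protein_length = 101L,
                          coverage_min = 0.90, identity_min = 95.0,
                          scheme = scoring_scheme(), orfs = NULL) {
  if (is.null(orfs)) orfs <- find_orfs(cms, min_protein_length)
  if (nrow(orfs) == 0L) return(cbind(orfs, coverage = numeric(0), identity = numeric(0)))
  calls <- lapply(seq_len(nrow(orfs)), function(i) {
    call_presence(orfs[i, ], maintainer, coverage_min, identity_min, scheme)
  })
  orfs$coverage <- vapply(calls, `[[`, numeric(1), "coverage")
  orfs$identity <- vapply(calls, `[[`, numeric(1), "identity")
  verdict <- vapply(calls, `[[`, character(1), "verdict")
  out <- orfs[verdict == "absent", , drop = FALSE]
  rownames(out) <- NULL
  out
}
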
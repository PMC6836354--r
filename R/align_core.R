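#' Alignment scoring scheme
#'
#' Defaults emulate BLASTN-style nucleotide scoring: match +2, mismatch -3,
#' gap open -5, gap extend -2. A gap run of length L costs
#' `gap_open + L * gap_extend` (both stored as non-positive numbers).
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open Penalty charged once per gap run (<= 0).
#' @param gap_extend Penalty charged per gap column (<= 0).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2) {
  if (match <= 0) stop("match reward must be positive")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0) {
    stop("mismatch and gap penalties must be <= 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

subst_matrix <- function(scheme, alphabet) {
  m <- matrix(scheme$mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- scheme$match
  if ("N" %in% alphabet) { m["N", ] <- 0; m[, "N"] <- 0 }
  m
}

aln_result <- function(aln, strand = "+") {
  pat <- as.character(Biostrings::alignedPattern(aln))
  alen <- nchar(pat)
  matches <- Biostrings::nmatch(aln)
  mism <- Biostrings::nmismatch(aln)
  list(score = Biostrings::score(aln),
       aligned_length = alen,
       matches = matches,
       mismatches = mism,
       gap_columns = alen - matches - mism,
       query_interval = c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
                          Biostrings::end(Biostrings::pattern(aln))),
       ref_interval = c(Biostrings::start(Biostrings::subject(aln)) - 1L,
                        Biostrings::end(Biostrings::subject(aln))),
       strand = strand,
       aligned_query = pat,
       aligned_ref = as.character(Biostrings::alignedSubject(aln)),
       identity = if (alen > 0) 100 * matches / alen else 0)
}

pa <- function(a, b, type, scheme, protein = FALSE) {
  if (protein) {
    alpha <- unique(c(strsplit(paste0(a, b), "")[[1]], "X"))
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = type,
      substitutionMatrix = subst_matrix(scheme, alpha),
      gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
      substitutionMatrix = subst_matrix(scheme, c("A", "C", "G", "T", "N")),
      gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  }
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' @param query,ref Nucleotide sequences (character scalars).
#' @param scheme A [scoring_scheme()].
#' @param protein Treat inputs as amino-acid sequences.
#' @return A list describing the best local alignment: `score`,
#'   `aligned_length`, `matches`, `mismatches`, `gap_columns`,
#'   `query_interval` / `ref_interval` (0-based half-open), `strand`,
#'   `identity` (percent of alignment columns matching), and the two aligned
#'   (gapped) strings.
#' @export
local_align <- function(query, ref, scheme = scoring_scheme(), protein = FALSE) {
  if (nchar(query) == 0L || nchar(ref) == 0L) stop("empty sequence")
  aln_result(pa(query, ref, "local", scheme, protein))
}

#' End-to-end global (Needleman-Wunsch) alignment with affine gaps
#'
#' @inheritParams local_align
#' @return Same structure as [local_align()] (intervals cover both sequences
#'   end to end).
#' @export
global_align <- function(query, ref, scheme = scoring_scheme(), protein = FALSE) {
  if (nchar(query) == 0L || nchar(ref) == 0L) stop("empty sequence")
  aln_result(pa(query, ref, "global", scheme, protein))
}

# Lengths of the gap runs in a gapped alignment string.
gap_runs <- function(gapped) {
  r <- rle(strsplit(gapped, "", fixed = TRUE)[[1]] == "-")
  r$lengths[r$values]
}

#' Percent identity and difference count between two sequences
#'
#' Sequences are globally aligned; identity is `matches / alignment columns`
#' (gap columns count as non-matching), rounded to one decimal. The
#' difference count is mismatch columns plus gap columns.
#'
#' @param a,b Sequences (character scalars).
#' @param level `"nucleotide"` or `"protein"`.
#' @param scheme A [scoring_scheme()].
#' @return List with `identity` (percent, 1 decimal) and `differences`.
#' @export
percent_identity <- function(a, b, level = c("nucleotide", "protein"),
                             scheme = scoring_scheme()) {
  level <- match.arg(level)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  al <- global_align(a, b, scheme, protein = level == "protein")
  list(identity = round_half_up(al$identity, 1),
       differences = al$mismatches + al$gap_columns)
}
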
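#' @importFrom stats filter setNames
#' @importFrom utils head tail write.table read.table
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Round half away from zero, matching how genome reports print percentages
# (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run a block with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(seq) == 0L) stop(what, " is empty", call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

# All k-mers of a string as a character vector; element i starts at 0-based i-1.
kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

codons_of <- function(seq) {
  n <- nchar(seq)
  nc <- n %/% 3L
  if (nc == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = nc)
  substring(seq, starts, starts + 2L)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Incomplete trailing codons are dropped; codons containing `N` translate to
#' `X`; stop codons translate to `*`.
#'
#' @param seq Nucleotide sequence (character scalar over A,C,G,T,N).
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq) {
  cods <- codons_of(toupper(seq))
  if (length(cods) == 0L) return("")
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
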
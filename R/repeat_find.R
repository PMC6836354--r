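#' Find long direct and inverted repeats in a genome
#'
#' Maximal exact repeated pairs are found by k-mer seeding (any exact repeat
#' of at least `min_repeat_length` nucleotides necessarily shares
#' `min_repeat_length - k + 1` k-mers, so none can be missed) and diagonal
#' run merging, on the sequence and its reverse complement. In `"near"`
#' mode, exact runs on the same diagonal separated by short gaps are chained
#' into diverged repeat pairs with an identity estimate.
#'
#' @param genome A `circular_genome` (treated linearly) or character sequence.
#' @param min_repeat_length Minimum repeat length (nt).
#' @param k Seed k-mer size.
#' @param mode `"exact"` (default) or `"near"`.
#' @param occ_cap Ignore k-mers occurring more than this many times.
#' @param near_gap Maximum gap chained in `"near"` mode.
#' @param min_identity Minimum identity (percent) kept in `"near"` mode.
#' @return A `data.frame` sorted by length descending: `length`, `pos_a`,
#'   `pos_b` (0-based starts, `pos_a < pos_b`), `orientation`
#'   (`direct`/`inverted`), `identity`.
#' @export
find_repeats <- function(genome, min_repeat_length = 500L, k = 31L,
                         mode = c("exact", "near"), occ_cap = 16L,
                         near_gap = 100L, min_identity = 98) {
  mode <- match.arg(mode)
  S <- seq_of(genome)
  L <- nchar(S)
  if (L < 2L * k) return(empty_repeat_table())
  sk <- kmers(S, k); rk <- kmers(reverse_complement(S), k)
  u <- unique(c(sk, rk))
  si <- match(sk, u); ri <- match(rk, u)

  # direct: pairs of positions of the same k-mer within S
  stab <- tabulate(si, nbins = length(u))
  dup <- which(stab[si] >= 2L & stab[si] <= occ_cap)
  dpairs <- list(q = integer(0), p = integer(0))
  if (length(dup)) {
    sp <- split(dup - 1L, si[dup])
    prs <- lapply(sp, function(p) {
      if (length(p) < 2L) return(NULL)
      cmb <- utils::combn(sort(p), 2L)
      list(q = cmb[1, ], p = cmb[2, ])
    })
    prs <- prs[!vapply(prs, is.null, logical(1))]
    dpairs <- list(q = unlist(lapply(prs, `[[`, "q"), use.names = FALSE),
                   p = unlist(lapply(prs, `[[`, "p"), use.names = FALSE))
  }
  direct <- merge_diag_runs(dpairs$q, dpairs$p, k)
  direct <- direct[direct$p_start != direct$q_start, , drop = FALSE]

  # inverted: matches between S and revcomp(S); in that coordinate pair the
  # second footprint starts at L - p2 - len on the forward strand
  rtab <- tabulate(ri, nbins = length(u))
  shared <- which(rtab[si] >= 1L & rtab[si] <= occ_cap & stab[si] <= occ_cap)
  ipairs <- list(q = integer(0), p = integer(0))
  if (length(shared)) {
    rp <- split(seq_along(ri) - 1L, ri)
    hits <- rp[as.character(si[shared])]
    nh <- lengths(hits)
    ipairs <- list(q = rep(shared - 1L, nh), p = unlist(hits, use.names = FALSE))
  }
  inv <- merge_diag_runs(ipairs$q, ipairs$p, k)
  if (nrow(inv)) {
    b_start <- L - inv$p_start - inv$len
    inv <- data.frame(q_start = pmin(inv$q_start, b_start),
                      p_start = pmax(inv$q_start, b_start), len = inv$len)
    inv <- inv[inv$q_start != inv$p_start, , drop = FALSE]
    inv <- unique(inv)
  }

  assemble <- function(df, orientation) {
    if (nrow(df) == 0L) return(empty_repeat_table())
    data.frame(length = df$len, pos_a = df$q_start, pos_b = df$p_start,
               orientation = orientation, identity = 100,
               stringsAsFactors = FALSE)
  }
  out <- rbind(assemble(direct, "direct"), assemble(inv, "inverted"))
  if (mode == "near" && nrow(out)) out <- chain_near_repeats(out, S, near_gap, min_identity)
  out <- out[out$length >= min_repeat_length, , drop = FALSE]
  out <- out[order(-out$length, out$pos_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_repeat_table <- function() {
  data.frame(length = integer(0), pos_a = integer(0), pos_b = integer(0),
             orientation = character(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

# Chain exact repeat runs on the same diagonal (direct: pos_b - pos_a
# constant; inverted: pos_a + pos_b + length constant) across small gaps.
chain_near_repeats <- function(rp, S, near_gap, min_identity) {
  rp$diag <- ifelse(rp$orientation == "direct",
                    rp$pos_b - rp$pos_a, rp$pos_a + rp$pos_b + rp$length)
  out <- list()
  for (key in unique(paste(rp$orientation, rp$diag))) {
    sub <- rp[paste(rp$orientation, rp$diag) == key, , drop = FALSE]
    sub <- sub[order(sub$pos_a), , drop = FALSE]
    cur <- sub[1, , drop = FALSE]; exact <- cur$length
    flush <- function(cur, exact) {
      cur$identity <- round_half_up(100 * exact / cur$length, 2)
      cur
    }
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        gap <- sub$pos_a[i] - (cur$pos_a + cur$length)
        if (gap >= 0 && gap <= near_gap) {
          cur$length <- sub$pos_a[i] + sub$length[i] - cur$pos_a
          if (cur$orientation == "direct") cur$pos_b <- cur$diag + cur$pos_a
          else cur$pos_b <- cur$diag - cur$pos_a - cur$length
          exact <- exact + sub$length[i]
        } else {
          out[[length(out) + 1L]] <- flush(cur, exact)
          cur <- sub[i, , drop = FALSE]; exact <- cur$length
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cur, exact)
  }
  out <- do.call(rbind, out)
  out <- out[out$identity >= min_identity, , drop = FALSE]
  out$diag <- NULL
  out
}

#' Predict subgenomic circles from a direct repeat
#'
#' Intramolecular recombination across the two copies of a direct repeat on
#' a circular molecule excises two smaller circles whose sizes sum to the
#' master-circle length; each retains one repeat copy.
#'
#' @param genome A circular `circular_genome`.
#' @param repeat_pair One row of a [find_repeats()] table (direct
#'   orientation).
#' @return List with `repeat_pair` and `circle_sizes` (two lengths summing
#'   to the genome length).
#' @export
predict_subgenomes <- function(genome, repeat_pair) {
  if (!isTRUE(genome$circular)) stop("subgenome prediction requires a circular genome")
  if (repeat_pair$orientation != "direct") {
    stop("recombination across an inverted repeat inverts the intervening segment; ",
         "subgenomic circles arise from direct repeats only")
  }
  d <- repeat_pair$pos_b - repeat_pair$pos_a
  list(repeat_pair = repeat_pair,
       circle_sizes = c(d, genome$length - d))
}
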
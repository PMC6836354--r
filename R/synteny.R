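# Merge k-mer match positions lying on one diagonal into maximal runs.
# `qpos`/`rpos` are 0-based match positions; consecutive positions on the
# same diagonal (rpos - qpos constant) collapse into one run of length
# run + k - 1.
merge_diag_runs <- function(qpos, rpos, k) {
  if (length(qpos) == 0L) {
    return(data.frame(q_start = integer(0), p_start = integer(0), len = integer(0)))
  }
  d <- rpos - qpos
  ord <- order(d, qpos)
  q <- qpos[ord]; dd <- d[ord]
  new_run <- c(TRUE, diff(q) != 1L | diff(dd) != 0L)
  grp <- cumsum(new_run)
  n <- tabulate(grp)
  first <- which(new_run)
  data.frame(q_start = q[first], p_start = rpos[ord][first],
             len = n + k - 1L)
}

seq_of <- function(x) if (inherits(x, "circular_genome")) x$sequence else toupper(x)

#' Map shared k-mer anchors between two genomes
#'
#' All matches of k-mers shared by query and reference are reported on both
#' strands, collapsed to maximal exact runs. K-mers occurring more than
#' `max_occ` times in either sequence are masked (they carry little
#' positional information but explode the match list); organelle repeat
#' copies are retained at the default.
#'
#' @param query,ref `circular_genome` objects or character sequences.
#' @param k K-mer size.
#' @param max_occ Occurrence cap per sequence.
#' @return A `data.frame` of anchors: `q_start`, `r_start` (0-based,
#'   forward-strand starts), `len`, `strand`, and `p2_start` (start in
#'   reverse-complement coordinates for `-` anchors; equals `r_start`
#'   for `+`).
#' @export
anchor_map <- function(query, ref, k = 31L, max_occ = 4L) {
  Q <- seq_of(query); R <- seq_of(ref)
  qk <- kmers(Q, k); rk <- kmers(R, k); rck <- kmers(reverse_complement(R), k)
  u <- unique(c(qk, rk, rck))
  qi <- match(qk, u); ri <- match(rk, u); rci <- match(rck, u)
  qtab <- tabulate(qi, nbins = length(u))

  pos_lists <- function(ids) {
    tab <- tabulate(ids, nbins = length(u))
    keep <- which(tab[ids] <= max_occ & qtab[ids] <= max_occ)
    sp <- split((keep - 1L), ids[keep])
    map <- vector("list", length(u))
    map[as.integer(names(sp))] <- sp
    map
  }
  expand <- function(map) {
    ok <- which(qtab[qi] <= max_occ)
    hits <- map[qi[ok]]
    nh <- lengths(hits)
    list(q = rep(ok - 1L, nh), p = unlist(hits, use.names = FALSE))
  }

  fw <- expand(pos_lists(ri))
  rv <- expand(pos_lists(rci))
  plus <- merge_diag_runs(fw$q, fw$p, k)
  minus <- merge_diag_runs(rv$q, rv$p, k)

  Lr <- nchar(R)
  out <- rbind(
    if (nrow(plus)) data.frame(q_start = plus$q_start, r_start = plus$p_start,
                               len = plus$len, strand = "+", p2_start = plus$p_start),
    if (nrow(minus)) data.frame(q_start = minus$q_start,
                                r_start = Lr - minus$p_start - minus$len,
                                len = minus$len, strand = "-",
                                p2_start = minus$p_start)
  )
  if (is.null(out)) out <- data.frame(q_start = integer(0), r_start = integer(0),
                                      len = integer(0), strand = character(0),
                                      p2_start = integer(0))
  out[order(out$q_start, out$r_start), , drop = FALSE]
}

#' Chain anchors into collinearity blocks
#'
#' Co-linear anchors on the same strand are chained when query and reference
#' gaps are at most `max_gap` and the diagonal drifts by at most `band`;
#' inter-anchor gaps are closed with global alignment so each block carries
#' match/mismatch/gap-column counts and an identity. Blocks shorter than
#' `min_block` are dropped, remaining blocks are made non-overlapping on the
#' query (longest first), and coverage is reported as the percentage of the
#' query inside blocks.
#'
#' @param anchors An [anchor_map()] table.
#' @param query,ref The sequences the anchors refer to.
#' @param max_gap Maximum inter-anchor gap (nt) within one chain.
#' @param min_block Minimum block length (nt) on the query.
#' @param band Maximum diagonal drift (nt) within one chain.
#' @param scheme A [scoring_scheme()] for gap closure.
#' @return List: `blocks` (data.frame with `q_start`, `q_end`, `r_start`,
#'   `r_end`, `strand`, `length`, `matches`, `mismatches`, `gap_columns`,
#'   `identity`), `coverage` (percent of query), `identity`
#'   (length-weighted percent), `gap_lengths` (all indel run lengths).
#' @export
chain_blocks <- function(anchors, query, ref, max_gap = 2000L, min_block = 500L,
                         band = 200L, scheme = scoring_scheme()) {
  Q <- seq_of(query); R <- seq_of(ref)
  Lr <- nchar(R); Lq <- nchar(Q)
  R2 <- list("+" = R, "-" = reverse_complement(R))

  empty_blocks <- data.frame(q_start = integer(0), q_end = integer(0),
                             r_start = integer(0), r_end = integer(0),
                             strand = character(0), length = integer(0),
                             matches = integer(0), mismatches = integer(0),
                             gap_columns = integer(0), identity = numeric(0))
  if (nrow(anchors) == 0L) {
    return(list(blocks = empty_blocks, coverage = 0, identity = NA_real_,
                gap_lengths = integer(0)))
  }

  blocks <- list(); all_gap_lengths <- integer(0)
  for (str in unique(anchors$strand)) {
    a <- anchors[anchors$strand == str, , drop = FALSE]
    a <- a[order(a$q_start, a$p2_start), , drop = FALSE]
    # greedy chaining in (q, p2) space; p2 increases with q on both strands
    chain_id <- integer(nrow(a))
    ends_q <- numeric(0); ends_p <- numeric(0); diags <- numeric(0)
    for (i in seq_len(nrow(a))) {
      q0 <- a$q_start[i]; p0 <- a$p2_start[i]
      dq <- q0 - ends_q; dp <- p0 - ends_p
      compat <- which(dq >= -31 & dq <= max_gap & dp >= -31 & dp <= max_gap &
                        abs((p0 - q0) - diags) <= band)
      if (length(compat)) {
        cid <- compat[which.max(ends_q[compat])]
      } else {
        cid <- length(ends_q) + 1L
        ends_q <- c(ends_q, -Inf); ends_p <- c(ends_p, -Inf); diags <- c(diags, p0 - q0)
      }
      chain_id[i] <- cid
      ends_q[cid] <- max(ends_q[cid], q0 + a$len[i])
      ends_p[cid] <- max(ends_p[cid], p0 + a$len[i])
      diags[cid] <- p0 - q0
    }
    for (cid in unique(chain_id)) {
      ch <- a[chain_id == cid, , drop = FALSE]
      st <- chain_stats(ch, Q, R2[[str]], scheme)
      if (is.null(st)) next
      r_int <- if (str == "+") c(st$p_start, st$p_end)
               else c(Lr - st$p_end, Lr - st$p_start)
      blocks[[length(blocks) + 1L]] <- data.frame(
        q_start = st$q_start, q_end = st$q_end,
        r_start = r_int[1], r_end = r_int[2], strand = str,
        length = st$q_end - st$q_start, matches = st$matches,
        mismatches = st$mismatches, gap_columns = st$gap_columns,
        identity = st$identity)
      all_gap_lengths <- c(all_gap_lengths, st$gap_lengths)
    }
  }
  if (length(blocks) == 0L) {
    return(list(blocks = empty_blocks, coverage = 0, identity = NA_real_,
                gap_lengths = integer(0)))
  }
  bl <- do.call(rbind, blocks)
  bl <- bl[bl$length >= min_block, , drop = FALSE]
  if (nrow(bl) == 0L) {
    return(list(blocks = empty_blocks, coverage = 0, identity = NA_real_,
                gap_lengths = all_gap_lengths))
  }
  # make blocks non-overlapping on the query, longest first
  bl <- bl[order(-bl$length), , drop = FALSE]
  kept <- list(); covered <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(bl))) {
    iv <- interval_subtract(c(bl$q_start[i], bl$q_end[i]), covered)
    if (nrow(iv) == 0L) next
    largest <- iv[which.max(iv[, 2] - iv[, 1]), ]
    frac <- (largest[2] - largest[1]) / bl$length[i]
    if (largest[2] - largest[1] < min_block) next
    b <- bl[i, , drop = FALSE]
    scale_cols <- c("matches", "mismatches", "gap_columns")
    b[scale_cols] <- lapply(b[scale_cols], function(v) round(v * frac))
    b$q_start <- largest[1]; b$q_end <- largest[2]
    b$length <- largest[2] - largest[1]
    kept[[length(kept) + 1L]] <- b
    covered <- rbind(covered, largest)
  }
  if (length(kept) == 0L) {
    return(list(blocks = empty_blocks, coverage = 0, identity = NA_real_,
                gap_lengths = all_gap_lengths))
  }
  bl <- do.call(rbind, kept)
  bl <- bl[order(bl$q_start), , drop = FALSE]
  rownames(bl) <- NULL
  tot <- bl$matches + bl$mismatches + bl$gap_columns
  list(blocks = bl,
       coverage = 100 * sum(bl$q_end - bl$q_start) / Lq,
       identity = 100 * sum(bl$matches) / sum(tot),
       gap_lengths = all_gap_lengths)
}

# Subtract covered intervals from [iv[1], iv[2]); returns remaining pieces.
interval_subtract <- function(iv, covered) {
  pieces <- matrix(iv, ncol = 2)
  if (nrow(covered)) {
    for (j in seq_len(nrow(covered))) {
      nxt <- matrix(numeric(0), ncol = 2)
      for (p in seq_len(nrow(pieces))) {
        a <- pieces[p, 1]; b <- pieces[p, 2]
        ca <- covered[j, 1]; cb <- covered[j, 2]
        if (cb <= a || ca >= b) { nxt <- rbind(nxt, c(a, b)); next }
        if (ca > a) nxt <- rbind(nxt, c(a, ca))
        if (cb < b) nxt <- rbind(nxt, c(cb, b))
      }
      pieces <- nxt
      if (nrow(pieces) == 0L) break
    }
  }
  pieces
}

# Alignment statistics for one chain of anchors (in (q, p2) coordinates).
chain_stats <- function(ch, Q, S2, scheme) {
  ch <- ch[order(ch$q_start), , drop = FALSE]
  # trim anchor overlaps on whichever side overlaps more (query or p2), so
  # that inter-anchor gaps reflect the net diagonal shift
  q0 <- ch$q_start; p0 <- ch$p2_start; len <- ch$len
  for (i in seq_along(q0)[-1]) {
    ov <- max((q0[i - 1] + len[i - 1]) - q0[i],
              (p0[i - 1] + len[i - 1]) - p0[i])
    if (ov > 0) { q0[i] <- q0[i] + ov; p0[i] <- p0[i] + ov; len[i] <- len[i] - ov }
  }
  keep <- len > 0
  q0 <- q0[keep]; p0 <- p0[keep]; len <- len[keep]
  if (length(q0) == 0L) return(NULL)
  matches <- sum(len); mismatches <- 0L; gap_cols <- 0L
  gap_lengths <- integer(0)
  if (length(q0) > 1L) {
    for (i in seq_along(q0)[-1]) {
      gq <- substr(Q, q0[i - 1] + len[i - 1] + 1L, q0[i])
      gp <- substr(S2, p0[i - 1] + len[i - 1] + 1L, p0[i])
      nq <- nchar(gq); np <- nchar(gp)
      if (nq == 0L && np == 0L) next
      if (nq == 0L || np == 0L) {
        gap_cols <- gap_cols + max(nq, np)
        gap_lengths <- c(gap_lengths, max(nq, np))
        next
      }
      al <- global_align(gq, gp, scheme)
      matches <- matches + al$matches
      mismatches <- mismatches + al$mismatches
      gap_cols <- gap_cols + al$gap_columns
      gap_lengths <- c(gap_lengths, gap_runs(al$aligned_query), gap_runs(al$aligned_ref))
    }
  }
  n <- length(q0)
  total <- matches + mismatches + gap_cols
  list(q_start = q0[1], q_end = q0[n] + len[n],
       p_start = p0[1], p_end = p0[n] + len[n],
       matches = matches, mismatches = mismatches, gap_columns = gap_cols,
       identity = 100 * matches / total, gap_lengths = gap_lengths)
}
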
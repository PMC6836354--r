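#' Pairwise p-distances for a set of sequences
#'
#' If all sequences have equal length they are treated as pre-aligned and
#' compared column-wise (columns gapped in both members of a pair are
#' ignored); otherwise each pair is globally aligned first. The distance is
#' the proportion of differing columns, gaps counting as differences.
#'
#' @param seqs Named character vector of at least three sequences.
#' @param level `"nucleotide"` or `"protein"`.
#' @param scheme A [scoring_scheme()] used when alignment is needed.
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pairwise_distances <- function(seqs, level = c("nucleotide", "protein"),
                               scheme = scoring_scheme()) {
  level <- match.arg(level)
  if (length(seqs) < 3L) stop("at least three sequences are required")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  n <- length(seqs)
  dm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  aligned <- length(unique(nchar(seqs))) == 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (aligned) {
        a <- strsplit(seqs[[i]], "")[[1]]; b <- strsplit(seqs[[j]], "")[[1]]
        keep <- !(a == "-" & b == "-")
        d <- sum(a[keep] != b[keep]) / sum(keep)
      } else {
        al <- global_align(seqs[[i]], seqs[[j]], scheme,
                           protein = level == "protein")
        d <- (al$mismatches + al$gap_columns) / al$aligned_length
      }
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (the
#' lowest-index pair wins). Negative branch-length estimates are clamped to
#' zero and flagged. The tree is returned as newick text with six-decimal
#' branch lengths, rooted at the final trifurcation (unrooted topology).
#'
#' @param dm Symmetric distance matrix with labelled rows/columns and zero
#'   diagonal, at least 3 taxa.
#' @return An object of class `nj_tree`: list with `newick`, `labels`,
#'   `negative_branches` (count clamped).
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (nrow(dm) < 3L) stop("neighbor joining requires at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must carry taxon labels")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(dm)
  nodes <- labels            # newick fragment per active node
  D <- dm
  clamped <- 0L
  fmt <- function(x) sprintf("%.6f", x)
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (Q[i, j] < best[1] - 1e-12) best <- c(Q[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { clamped <- clamped + 1L; bj <- bj + bi; bi <- 0 }
    if (bj < 0) { clamped <- clamped + 1L; bi <- bi + bj; bj <- 0 }
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(bi), nodes[j], fmt(bj))
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
    rownames(D2) <- colnames(D2) <- seq_len(nrow(D2))
    D <- D2
  }
  # resolve the final three nodes with the three-point formulas
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (b in c(b1, b2, b3)) if (b < 0) clamped <- clamped + 1L
  b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(b1),
                    nodes[2], fmt(b2), nodes[3], fmt(b3))
  structure(list(newick = newick, labels = labels,
                 negative_branches = clamped), class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("<nj_tree>", length(x$labels), "taxa\n")
  cat(x$newick, "\n")
  if (x$negative_branches > 0) {
    cat("note:", x$negative_branches, "negative branch estimate(s) clamped to 0\n")
  }
  invisible(x)
}
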
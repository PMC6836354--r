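# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Gotoh affine-gap dynamic programming, exhaustive over the full matrix.
# Gap run of length L costs open + L * ext (open, ext <= 0).
gotoh_score <- function(a, b, type = c("global", "local"),
                        match = 2, mism = -3, open = -5, ext = -2) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in (mis)match column
  E <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (consumes b)
  F <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (consumes a)
  M[1, 1] <- 0
  best_local <- 0
  for (j in seq_len(m)) E[1, j + 1] <- open + ext * j
  for (i in seq_len(n)) F[i + 1, 1] <- open + ext * i
  if (type == "local") { M[, 1] <- pmax(M[, 1], 0); M[1, ] <- pmax(M[1, ], 0) }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mism
      prev <- max(M[i, j], E[i, j], F[i, j])
      if (type == "local") prev <- max(prev, 0)
      M[i + 1, j + 1] <- prev + s
      E[i + 1, j + 1] <- max(E[i + 1, j] + ext, M[i + 1, j] + open + ext,
                             F[i + 1, j] + open + ext)
      F[i + 1, j + 1] <- max(F[i, j + 1] + ext, M[i, j + 1] + open + ext,
                             E[i, j + 1] + open + ext)
      if (type == "local") best_local <- max(best_local, M[i + 1, j + 1])
    }
  }
  if (type == "local") best_local
  else max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# Quadratic maximal-repeat scan: compares every diagonal of s against
# itself (direct) and against its reverse complement (inverted).
brute_repeats <- function(s, min_len) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  # direct: offset d >= 1, runs where ch[i] == ch[i+d]
  for (d in seq_len(n - min_len)) {
    eq <- ch[seq_len(n - d)] == ch[(1 + d):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      out[[length(out) + 1L]] <- data.frame(
        length = r$lengths[k], pos_a = starts[k] - 1L,
        pos_b = starts[k] - 1L + d, orientation = "direct")
    }
  }
  # inverted: s[a..a+len) == revcomp(s[b..b+len)) means s[i] == comp(s[j])
  # all along the anti-diagonal i + j = a + b + len - 1 (0-based)
  for (c2 in 0:(2L * n - 2L)) {
    i <- seq(max(0L, c2 - n + 1L), min(c2, n - 1L))
    j <- c2 - i
    eq <- ch[i + 1L] == unname(comp[ch[j + 1L]])
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      i0 <- i[starts[k]]; len <- r$lengths[k]
      pa <- i0                         # first footprint start
      pb <- c2 - i0 - len + 1L         # second footprint start
      if (pb <= pa) next               # count each pair once
      out[[length(out) + 1L]] <- data.frame(
        length = len, pos_a = pa, pos_b = pb, orientation = "inverted")
    }
  }
  if (!length(out)) return(data.frame(length = integer(0), pos_a = integer(0),
                                      pos_b = integer(0), orientation = character(0)))
  unique(do.call(rbind, out))
}

# Hash-join k-mer matcher (per-position matches, no run merging).
brute_anchors <- function(q, r, k) {
  qk <- substring(q, 1:(nchar(q) - k + 1), k:nchar(q))
  rk <- substring(r, 1:(nchar(r) - k + 1), k:nchar(r))
  idx <- new.env(hash = TRUE)
  for (i in seq_along(rk)) assign(rk[i], c(idx[[rk[i]]], i - 1L), envir = idx)
  out <- list()
  for (i in seq_along(qk)) {
    hits <- idx[[qk[i]]]
    if (!is.null(hits)) out[[length(out) + 1L]] <- data.frame(q = i - 1L, r = hits)
  }
  if (!length(out)) return(data.frame(q = integer(0), r = integer(0)))
  do.call(rbind, out)
}

# Random unrooted binary tree with positive branch lengths; returns the
# additive distance matrix and the ape tree for topology comparison.
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
  dm <- as.matrix(ape::cophenetic.phylo(tr))
  labs <- sort(rownames(dm))
  list(tree = tr, dm = dm[labs, labs])
}

same_topology <- function(nwk1, tree2) {
  t1 <- ape::unroot(ape::read.tree(text = nwk1))
  t2 <- ape::unroot(tree2)
  isTRUE(all.equal(ape::dist.topo(t1, t2)[[1]], 0))
}

# Expand merged anchor runs back to per-position k-mer matches.
expand_anchors <- function(anchors, k) {
  if (nrow(anchors) == 0L) return(data.frame(q = integer(0), r = integer(0)))
  out <- lapply(seq_len(nrow(anchors)), function(i) {
    nrun <- anchors$len[i] - k + 1L
    data.frame(q = anchors$q_start[i] + 0:(nrun - 1L),
               r = anchors$p2_start[i] + 0:(nrun - 1L))
  })
  do.call(rbind, out)
}
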
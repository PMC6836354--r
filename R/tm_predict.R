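# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Kyte-Doolittle hydropathy profile
#'
#' Centered moving average of per-residue Kyte-Doolittle scores; only full
#' windows are reported, so the profile covers residue centers
#' `(window+1)/2 ... n-(window-1)/2` (1-based). Unknown residues (`X`, `*`)
#' score 0.
#'
#' @param protein Amino-acid sequence (character scalar).
#' @param window Window size in residues (odd; 19 is the canonical choice
#'   for transmembrane detection).
#' @return Numeric vector of window means named by center residue position;
#'   empty (with a warning) if the protein is shorter than the window.
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < window) {
    warning("protein shorter than window; empty hydropathy profile")
    return(setNames(numeric(0), integer(0)))
  }
  sc <- unname(KD_SCALE[aa])
  sc[is.na(sc)] <- 0
  prof <- as.numeric(stats::filter(sc, rep(1 / window, window), sides = 2))
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  setNames(prof[centers], centers)
}

#' Predict transmembrane segments from hydropathy
#'
#' Maximal runs of profile values at or above `threshold` are taken as
#' membrane-spanning cores; runs separated by fewer than `merge_gap`
#' sub-threshold positions are merged (a single polar residue should not
#' split one helix), windows are expanded to residue intervals, and segments
#' shorter than `min_segment_length` residues are discarded.
#'
#' @param protein Amino-acid sequence.
#' @param threshold Window-average hydropathy cutoff (1.6 is the published
#'   canonical choice for transmembrane detection).
#' @param window Window size (residues).
#' @param min_segment_length Minimum segment length (residues).
#' @param merge_gap Runs separated by fewer than this many positions merge.
#' @return List with `segments` (two-column matrix of 0-based half-open
#'   residue intervals) and `count`.
#' @export
predict_tm <- function(protein, threshold = 1.6, window = 19L,
                       min_segment_length = 19L, merge_gap = 5L) {
  prof <- suppressWarnings(hydropathy_profile(protein, window))
  empty <- list(segments = matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))),
                count = 0L)
  if (length(prof) == 0L) return(empty)
  above <- prof >= threshold
  if (!any(above)) return(empty)
  centers <- as.integer(names(prof))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])  # indices into prof
  # merge runs separated by short sub-threshold gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap < merge_gap) merged[nrow(merged), 2] <- runs[i, 2]
      else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  half <- (window - 1L) %/% 2L
  seg <- cbind(start = centers[merged[, 1]] - half - 1L,   # 0-based
               end = centers[merged[, 2]] + half)
  seg <- seg[seg[, 2] - seg[, 1] >= min_segment_length, , drop = FALSE]
  list(segments = seg, count = nrow(seg))
}

#' Transmembrane prediction for a table of ORFs
#'
#' @param orfs A [find_orfs()] table.
#' @param ... Passed to [predict_tm()].
#' @return A `data.frame` with `orf_id`, `tm_count` and a `segments`
#'   list-column.
#' @export
predict_tm_orfs <- function(orfs, ...) {
  res <- lapply(orfs$protein, predict_tm, ...)
  data.frame(orf_id = orfs$orf_id,
             tm_count = vapply(res, `[[`, integer(1), "count"),
             segments = I(lapply(res, `[[`, "segments")),
             stringsAsFactors = FALSE)
}
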
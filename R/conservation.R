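# Vista-style sliding-window identity profiling of promoter alignments and
# conserved-block / proximal-boundary calling. Windows are anchored on the
# non-gap positions of a chosen reference row so that profile coordinates
# map directly onto the reference promoter.

#' Sliding-window percent identity along an alignment
#'
#' Windows of `window` reference (non-gap) positions, advanced by `step`.
#' A reference position counts as identical when every non-reference row
#' carries the same base in its column; a gap or an `N` in any row counts
#' as a mismatch. Identity = identical positions / `window`. Alignment
#' columns where the reference is gapped (insertions in other species) are
#' skipped entirely.
#'
#' @param aln Equal-width gapped `DNAStringSet` from [read_alignment()].
#' @param reference_id Name of the reference row.
#' @param window Window size in reference bp (default 20, the conventional
#'   Vista setting for short promoters).
#' @param step Step in reference bp (default 1, a smooth profile).
#' @return Object of class `conservation_profile`: a `data.frame` with
#'   columns `start`, `end` (0-based half-open reference coordinates) and
#'   `identity`, with attributes `reference_id`, `window`, `step` and
#'   `reference_length`.
#' @export
sliding_identity <- function(aln, reference_id, window = 20L, step = 1L) {
  window <- as.integer(window); step <- as.integer(step)
  if (!reference_id %in% names(aln))
    stop("reference_id '", reference_id, "' not found in alignment")
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  mat <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  ref_row <- which(names(aln) == reference_id)[1L]
  ref_cols <- which(mat[ref_row, ] != "-")
  ref_len <- length(ref_cols)
  if (window > ref_len)
    stop("window (", window, ") longer than ungapped reference (",
         ref_len, ")")
  ref_base <- mat[ref_row, ref_cols]
  others <- mat[-ref_row, ref_cols, drop = FALSE]
  ident_pos <- ref_base %in% c("A", "C", "G", "T") &
    colSums(others == rep(ref_base, each = nrow(others))) == nrow(others)
  starts <- seq.int(0L, ref_len - window, by = step)
  csum <- c(0L, cumsum(ident_pos))
  identity <- (csum[starts + window + 1L] - csum[starts + 1L]) / window
  out <- data.frame(start = starts, end = starts + window,
                    identity = identity)
  attr(out, "reference_id") <- reference_id
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "reference_length") <- ref_len
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Call conserved blocks from a conservation profile
#'
#' Maximal runs of consecutive windows with identity >= `threshold` are
#' merged into single reference intervals (union of the windows' spans);
#' `mean_identity` averages the qualifying windows of each run.
#'
#' @param profile A `conservation_profile`.
#' @param threshold Identity threshold in `[0,1]` (default 0.70).
#' @return `data.frame` with columns `start`, `end`, `mean_identity`,
#'   sorted and disjoint.
#' @export
call_blocks <- function(profile, threshold = 0.70) {
  if (nrow(profile) == 0) stop("empty conservation profile")
  hit <- profile$identity >= threshold
  if (!any(hit))
    return(data.frame(start = integer(0), end = integer(0),
                      mean_identity = numeric(0)))
  r <- rle(hit)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values)
  blk <- data.frame(
    start = profile$start[idx_start[runs]],
    end = profile$end[idx_end[runs]],
    sum_id = vapply(runs, function(i)
      sum(profile$identity[idx_start[i]:idx_end[i]]), numeric(1)),
    n_win = r$lengths[runs]
  )
  # with step < window, distinct runs can overlap in coordinates; merge
  # them so output intervals are disjoint
  merged <- blk[1, , drop = FALSE]
  if (nrow(blk) > 1) for (i in 2:nrow(blk)) {
    last <- nrow(merged)
    if (blk$start[i] < merged$end[last]) {
      merged$end[last] <- max(merged$end[last], blk$end[i])
      merged$sum_id[last] <- merged$sum_id[last] + blk$sum_id[i]
      merged$n_win[last] <- merged$n_win[last] + blk$n_win[i]
    } else {
      merged <- rbind(merged, blk[i, ])
    }
  }
  data.frame(start = merged$start, end = merged$end,
             mean_identity = merged$sum_id / merged$n_win)
}

#' Convert reference-coordinate blocks to distance upstream of the ATG
#'
#' Profile coordinates run 5' to 3' along the reference; promoter analyses
#' report positions as bp upstream of the translation start, which sits
#' immediately 3' of the promoter. Position 0 = first base 5' of the ATG.
#'
#' @param blocks Block `data.frame` in 5'->3' reference coordinates.
#' @param ref_length Ungapped reference length in bp.
#' @return Blocks with `start`/`end` in upstream-of-ATG coordinates,
#'   sorted by increasing (most-proximal-first) start.
#' @export
upstream_coords <- function(blocks, ref_length) {
  out <- data.frame(start = ref_length - blocks$end,
                    end = ref_length - blocks$start,
                    mean_identity = blocks$mean_identity)
  out[order(out$start), , drop = FALSE]
}

#' Call the proximal/distal promoter boundary from conserved blocks
#'
#' Blocks are given in upstream-of-ATG coordinates. The proximal cluster is
#' grown from the block closest to the start codon by absorbing successive
#' blocks separated by at most `max_gap` bp; the boundary is the 5' (distal)
#' edge of that cluster. Blocks beyond the first gap larger than `max_gap`
#' are left distal.
#'
#' @param blocks Block `data.frame` in upstream coordinates (see
#'   [upstream_coords()]).
#' @param max_gap Maximum within-cluster gap in bp (default 50, the scale
#'   separating the conserved core from its nearest outlying motifs).
#' @return List of class `boundary_call`: `found` (logical),
#'   `boundary_pos` (bp upstream of ATG, `NA` when not found),
#'   `blocks_proximal` and `max_gap`.
#' @export
call_boundary <- function(blocks, max_gap = 50L) {
  if (nrow(blocks) == 0)
    return(structure(list(found = FALSE, boundary_pos = NA_real_,
                          blocks_proximal = blocks, max_gap = max_gap),
                     class = "boundary_call"))
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  cluster_end <- blocks$end[1L]
  n_in <- 1L
  while (n_in < nrow(blocks) &&
         blocks$start[n_in + 1L] - cluster_end <= max_gap) {
    n_in <- n_in + 1L
    cluster_end <- max(cluster_end, blocks$end[n_in])
  }
  structure(list(found = TRUE, boundary_pos = cluster_end,
                 blocks_proximal = blocks[seq_len(n_in), , drop = FALSE],
                 max_gap = max_gap),
            class = "boundary_call")
}
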
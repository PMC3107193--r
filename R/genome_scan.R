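# Genome tiling and candidate-fragment selection. The screen that
# nominated robustness-conferring fragments subdivided a genome into 1 kb
# pieces, scored each for AT-enrichment and picked windows matching (or
# maximally departing from) the composition of known robustness-conferring
# distal promoters.

#' Tile contigs into fixed non-overlapping windows
#'
#' Windows are `[0,w), [w,2w), ...` per contig; a trailing partial window
#' shorter than `w` is dropped (scores on unequal lengths are not
#' comparable), so a contig shorter than the window yields no windows.
#' Windows never span contigs.
#'
#' @param contigs Named `DNAStringSet` (e.g. from [read_fasta()]).
#' @param window Window size in bp (default 1000; fragments of this size
#'   match the distal promoter pieces assayed experimentally).
#' @param step Optional step for a sliding scan (default `window`,
#'   i.e. disjoint tiling).
#' @return Interval `data.frame` (contig, start, end, name, score) with
#'   names `<contig>:<start>-<end>`.
#' @export
segment_genome <- function(contigs, window = 1000L, step = window) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2L) stop("window must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  pieces <- lapply(names(contigs), function(ctg) {
    len <- Biostrings::width(contigs[ctg])
    if (len < window) return(NULL)
    starts <- seq.int(0L, len - window, by = step)
    data.frame(contig = ctg, start = starts, end = starts + window,
               stringsAsFactors = FALSE)
  })
  iv <- do.call(rbind, c(pieces,
                         list(data.frame(contig = character(0),
                                         start = integer(0),
                                         end = integer(0)))))
  genomic_intervals(iv$contig, iv$start, iv$end,
                    name = sprintf("%s:%d-%d", iv$contig, iv$start, iv$end))
}

#' Score genome windows by composition
#'
#' For each interval: `at_score` (AA/TT dinucleotide class frequency) and
#' `gc_class_freq` (combined GC + CG class frequency, the classes depleted
#' in robustness-conferring sequences), via the composition module;
#' `nuc_score` (nucleosome-depletion fold-enrichment) when a trinucleotide
#' weight table is supplied. Windows with more than `max_n_frac` N are
#' excluded with a warning.
#'
#' @param contigs Named `DNAStringSet`.
#' @param intervals Interval `data.frame` from [segment_genome()].
#' @param trinuc_table Optional table from [read_trinuc_table()].
#' @param max_n_frac Maximum tolerated N fraction per window (default 0.5).
#' @return `data.frame`: contig, start, end, name, at_score, at_mono,
#'   gc_class_freq and (optionally) nuc_score.
#' @export
score_windows <- function(contigs, intervals, trinuc_table = NULL,
                          max_n_frac = 0.5) {
  seqs <- as.character(Biostrings::subseq(
    contigs[intervals$contig], start = intervals$start + 1L,
    end = intervals$end))
  n_frac <- vapply(seqs, function(s)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s),
    numeric(1))
  drop <- n_frac > max_n_frac
  if (any(drop)) {
    warning(sum(drop), " window(s) with >", max_n_frac * 100,
            "% N excluded: ", paste(utils::head(intervals$name[drop], 5),
                                    collapse = ", "))
    intervals <- intervals[!drop, , drop = FALSE]
    seqs <- seqs[!drop]
  }
  scores <- t(vapply(seqs, at_enrichment_score, numeric(2)))
  gc <- vapply(seqs, function(s) {
    f <- collapse_classes(count_kmers(s, 2L))$freqs
    unname(f["GC"] + f["CG"])
  }, numeric(1))
  out <- data.frame(contig = intervals$contig, start = intervals$start,
                    end = intervals$end, name = intervals$name,
                    at_score = unname(scores[, "aa_tt"]),
                    at_mono = unname(scores[, "at"]),
                    gc_class_freq = unname(gc),
                    stringsAsFactors = FALSE)
  if (!is.null(trinuc_table))
    out$nuc_score <- vapply(seqs, nucleosome_depletion_score, numeric(1),
                            table = trinuc_table)
  rownames(out) <- NULL
  out
}

#' Select candidate windows by composition match
#'
#' `mode = "enriched"` keeps windows whose `at_score` lies within
#' `rel_tolerance` relative distance of `reference_score`
#' (|score - ref| / ref <= tol) and ranks them by closeness — the rule used
#' to pick fragments "AT-enriched to an extent similar to" known distal
#' promoters. `mode = "depleted"` ranks all windows by ascending
#' `at_score` (most AT-poor first). Ties are broken by (contig, start) so
#' selection is deterministic.
#'
#' @param scores Output of [score_windows()].
#' @param reference_score Target AA/TT class frequency (enriched mode).
#' @param rel_tolerance Relative tolerance (default 0.1; "similar extent"
#'   is not quantified upstream, 10% is the package convention).
#' @param mode `"enriched"` or `"depleted"`.
#' @param top_n Number of candidates to return (default all qualifying).
#' @return Ranked subset of `scores`.
#' @export
select_candidates <- function(scores, reference_score = NULL,
                              rel_tolerance = 0.1,
                              mode = c("enriched", "depleted"),
                              top_n = Inf) {
  mode <- match.arg(mode)
  if (nrow(scores) == 0) stop("no windows to select from")
  if (mode == "enriched") {
    if (is.null(reference_score) || reference_score <= 0)
      stop("enriched mode needs a positive reference_score")
    if (rel_tolerance <= 0) stop("rel_tolerance must be > 0")
    dist <- abs(scores$at_score - reference_score) / reference_score
    keep <- scores[dist <= rel_tolerance, , drop = FALSE]
    keep_dist <- dist[dist <= rel_tolerance]
    if (nrow(keep) == 0) {
      warning("no window within tolerance ", rel_tolerance,
              " of reference score ", reference_score)
      return(keep)
    }
    ord <- order(keep_dist, keep$contig, keep$start)
  } else {
    keep <- scores
    ord <- order(keep$at_score, keep$contig, keep$start)
  }
  ranked <- keep[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  utils::head(ranked, top_n)
}

#' Write scored windows as BED6 (score column = at_score)
#' @param scores Output of [score_windows()].
#' @param path Output path.
#' @export
write_window_bed <- function(scores, path) {
  write_bed(genomic_intervals(scores$contig, scores$start, scores$end,
                              name = scores$name, score = scores$at_score),
            path)
}
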
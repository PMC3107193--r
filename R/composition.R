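# k-mer composition profiling and composition-derived scores.
#
# Dinucleotide (k=2) composition is the predictor of interest: sequences
# that confer robust reporter expression are AA/TT-enriched and GC/CG-
# depleted relative to the reporter vector backbone, and carry a
# trinucleotide signature of nucleosome depletion. k-mers are counted over
# overlapping windows at step 1; windows containing N are dropped so that
# frequencies are exact over observed bases.

#' Count overlapping k-mers in a sequence
#'
#' Windows advance by one base; any window containing `N` is skipped and
#' excluded from the total, so `total` equals the number of N-free length-k
#' windows.
#'
#' @param seq A character scalar, `DNAString` or single-element
#'   `DNAStringSet` over `{A,C,G,T,N}`.
#' @param k Word size, `k >= 1`.
#' @return An object of class `kmer_profile`: a list with `k`, `counts`
#'   (named integer vector over all 4^k words), `total` and
#'   `source_length`.
#' @export
count_kmers <- function(seq, k = 2L) {
  s <- as_seq_string(seq)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nchar(s) < k)
    stop("empty profile: sequence length ", nchar(s), " < k = ", k)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                 width = k, step = 1)
  # oligonucleotideFrequency bins only pure-ACGT words, so N-containing
  # windows fall out of the total automatically
  structure(list(k = k, counts = counts, total = sum(counts),
                 source_length = nchar(s)),
            class = "kmer_profile")
}

as_seq_string <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L) stop("expected a single sequence")
    seq <- seq[[1L]]
  }
  s <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", s)) {
    m <- regexpr("[^ACGTN]", s)
    stop("alphabet error: illegal character '", substr(s, m, m),
         "' at position ", m)
  }
  s
}

revcomp_str <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Strand-collapsed k-mer class labels
#'
#' Each k-mer is merged with its reverse complement into one class, labelled
#' `"XY/Y'X'"` with the alphabetically smaller member first (e.g. `AA/TT`);
#' reverse-complement palindromes such as `AT` form singleton classes. For
#' k = 2 this yields the 10 canonical dinucleotide classes.
#'
#' @param k Word size.
#' @return Named character vector mapping each k-mer to its class label.
#' @export
kmer_classes <- function(k = 2L) {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- revcomp_str(kmers)
  labels <- ifelse(kmers == rc, kmers,
                   paste(pmin(kmers, rc), pmax(kmers, rc), sep = "/"))
  stats::setNames(labels, kmers)
}

#' Collapse a k-mer profile into reverse-complement classes
#'
#' @param profile A `kmer_profile` from [count_kmers()] with k = 2 or 3.
#' @return An object of class `class_profile`: list with `k`, `counts`
#'   (per class), `freqs` (class count / total) and `total`.
#' @export
collapse_classes <- function(profile) {
  stopifnot(inherits(profile, "kmer_profile"))
  if (!profile$k %in% c(2L, 3L))
    stop("class collapsing is defined for k = 2 or 3")
  if (profile$total == 0L)
    stop("undefined frequencies: no N-free windows in sequence")
  cls <- kmer_classes(profile$k)
  counts <- tapply(profile$counts[names(cls)], cls, sum)
  counts <- counts[unique(unname(cls))]  # stable class order
  counts <- stats::setNames(as.numeric(counts), names(counts))
  structure(list(k = profile$k, counts = counts,
                 freqs = counts / profile$total, total = profile$total),
            class = "class_profile")
}

#' Baseline-relative class enrichment (log2)
#'
#' For each strand-collapsed class `c`,
#' `log2(f_target(c) / f_baseline(c))`. When any involved class count is
#' zero, `pseudocount` is added to every class count of both profiles
#' before frequencies are recomputed, which keeps all log-ratios finite and
#' preserves antisymmetry under swapping target and baseline. With
#' `pseudocount = 0`, classes at frequency zero in both profiles are
#' reported as 0.
#'
#' @param target,baseline `class_profile` objects with equal `k`.
#' @param pseudocount Nonnegative count added as described (default 0.5).
#' @return A `data.frame` with columns `class` and `log2_ratio`, carrying
#'   the pseudocount used as an attribute.
#' @export
enrichment <- function(target, baseline, pseudocount = 0.5) {
  stopifnot(inherits(target, "class_profile"),
            inherits(baseline, "class_profile"))
  if (target$k != baseline$k)
    stop("mismatched k: ", target$k, " vs ", baseline$k)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  ct <- target$counts; cb <- baseline$counts[names(ct)]
  if (pseudocount > 0 && (any(ct == 0) || any(cb == 0))) {
    ct <- ct + pseudocount
    cb <- cb + pseudocount
  }
  ft <- ct / sum(ct); fb <- cb / sum(cb)
  ratio <- log2(ft / fb)
  ratio[ft == 0 & fb == 0] <- 0
  out <- data.frame(class = names(ct), log2_ratio = unname(ratio),
                    stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' AT-enrichment score of a sequence
#'
#' Primary score (`aa_tt`) is the frequency of the AA/TT dinucleotide
#' class, the composition feature that tracks robustness-conferring
#' promoter fragments; the mononucleotide A+T fraction (`at`) is reported
#' alongside since "AT-enriched" is also used loosely. Both are invariant
#' under reverse complement.
#'
#' @param seq Sequence as for [count_kmers()]; length >= 2.
#' @return Named numeric vector `c(aa_tt = ..., at = ...)`.
#' @export
at_enrichment_score <- function(seq) {
  s <- as_seq_string(seq)
  cp <- collapse_classes(count_kmers(s, 2L))
  bases <- table(factor(strsplit(s, "")[[1]], levels = SEQ_ALPHABET))
  n_acgt <- sum(bases[c("A", "C", "G", "T")])
  if (n_acgt == 0) stop("undefined score: sequence is all N")
  c(aa_tt = unname(cp$freqs["AA/TT"]),
    at = unname((bases[["A"]] + bases[["T"]]) / n_acgt))
}

#' Read a trinucleotide weight table
#'
#' TSV with columns `trinucleotide`, `weight`, `background_freq`; must be
#' complete over all 64 trinucleotides, weights nonnegative and background
#' frequencies summing to 1. The weights encode preference for nucleosome-
#' depleted regions (membership flags or graded weights); such sets come
#' from external nucleosome-positioning studies and are therefore an input,
#' not a package constant.
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame` (see [trinuc_weight_table()]).
#' @export
read_trinuc_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  trinuc_weight_table(raw$trinucleotide, raw$weight, raw$background_freq)
}

#' Construct and validate a trinucleotide weight table
#' @param trinucleotide Character vector of all 64 trinucleotides.
#' @param weight Nonnegative weights (or 0/1 membership flags).
#' @param background_freq Background frequencies summing to 1.
#' @return `data.frame` with the three columns, ordered lexicographically.
#' @export
trinuc_weight_table <- function(trinucleotide, weight, background_freq) {
  all3 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)
  if (!setequal(trinucleotide, all3) || length(trinucleotide) != 64L)
    stop("weight table must cover all 64 trinucleotides exactly once")
  ord <- match(all3, trinucleotide)
  tab <- data.frame(trinucleotide = all3, weight = as.numeric(weight)[ord],
                    background_freq = as.numeric(background_freq)[ord],
                    stringsAsFactors = FALSE)
  if (any(tab$weight < 0)) stop("weights must be nonnegative")
  if (abs(sum(tab$background_freq) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  tab
}

#' Nucleosome-depletion fold-enrichment score
#'
#' Weighted trinucleotide frequency of the sequence relative to the same
#' weighting of the background:
#' `sum_t w(t) f_seq(t) / sum_t w(t) f_bg(t)`. A score of 1 means no
#' enrichment; robustness-conferring distal promoter fragments score around
#' 2 against genome-background tables.
#'
#' @param seq Sequence of length >= 3.
#' @param table Weight table from [read_trinuc_table()] or
#'   [trinuc_weight_table()].
#' @return Fold-enrichment (numeric scalar).
#' @export
nucleosome_depletion_score <- function(seq, table) {
  prof <- count_kmers(seq, 3L)
  if (prof$total == 0L) stop("undefined score: no N-free 3-mers")
  f_seq <- prof$counts[table$trinucleotide] / prof$total
  num <- sum(table$weight * f_seq)
  den <- sum(table$weight * table$background_freq)
  if (den == 0) stop("degenerate weight table: background weight mass is 0")
  unname(num / den)
}
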
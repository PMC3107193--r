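#' @importFrom Biostrings readBStringSet DNAStringSet reverseComplement
#'   oligonucleotideFrequency width
#' @importFrom stats sd var median ecdf rbeta rbinom rnorm runif ks.test
#'   wilcox.test ansari.test setNames
#' @importFrom utils read.delim write.table head
NULL

# All genomic coordinates in this package are 0-based half-open; an interval
# [start, end) has length end - start. Promoter positions are reported as
# distance upstream of the translation start (position 0 = first base 5' of
# the ATG).

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased on load and `U` is mapped to `T`; any character
#' outside `{A,C,G,T,N}` is rejected with an error naming the record and the
#' offending position (1-based within the sequence).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] whose names are the record ids
#'   (first whitespace-delimited token of each header). The full header is
#'   kept in the `description` metadata column.
#' @export
read_fasta <- function(path) {
  recs <- read_seqs(path, allow_gap = FALSE)
  out <- Biostrings::DNAStringSet(recs$seq)
  names(out) <- recs$id
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = recs$description)
  out
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but `-` is additionally permitted. All records must
#' have equal (aligned) length, there must be at least two of them, and each
#' must contain at least one non-gap character.
#'
#' @param path Path to an aligned FASTA file.
#' @return A `DNAStringSet` of equal-width gapped sequences.
#' @export
read_alignment <- function(path) {
  recs <- read_seqs(path, allow_gap = TRUE)
  if (length(recs$seq) < 2L)
    stop("alignment error: need >= 2 records, got ", length(recs$seq))
  lens <- nchar(recs$seq)
  if (length(unique(lens)) != 1L) {
    bad <- recs$id[lens != lens[1L]]
    stop("alignment error: ragged lengths; offending ids: ",
         paste(bad, collapse = ", "))
  }
  no_base <- vapply(recs$seq, function(s) !grepl("[ACGTN]", s), logical(1))
  if (any(no_base))
    stop("alignment error: records with no non-gap characters: ",
         paste(recs$id[no_base], collapse = ", "))
  out <- Biostrings::DNAStringSet(recs$seq)
  names(out) <- recs$id
  out
}

# shared FASTA reader + alphabet validation
read_seqs <- function(path, allow_gap = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("format error reading ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("format error: no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  legal <- if (allow_gap) "[^ACGTN-]" else "[^ACGTN]"
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop("format error: empty sequence for record '", ids[i], "'")
    m <- regexpr(legal, seqs[i])
    if (m > 0L)
      stop("alphabet error: illegal character '",
           substr(seqs[i], m, m), "' at position ", m,
           " in record '", ids[i], "'")
  }
  list(id = ids, description = headers, seq = unname(seqs))
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open. `name` and `score` are optional labels
#' carried into BED output.
#'
#' @param contig Character vector of contig names.
#' @param start,end Integer-like vectors, `0 <= start < end`.
#' @param name Optional character labels (default `"."`).
#' @param score Optional numeric scores (default `NA`).
#' @return A `data.frame` with columns contig, start, end, name, score.
#' @export
genomic_intervals <- function(contig, start, end, name = NULL, score = NULL) {
  n <- length(contig)
  if (is.null(name)) name <- rep(".", n)
  if (is.null(score)) score <- rep(NA_real_, n)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(start >= end))
    stop("invalid interval: require 0 <= start < end")
  data.frame(contig = as.character(contig), start = start, end = end,
             name = as.character(name), score = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' Standard 6-column BED (contig, start, end, name, score, strand), tab
#' separated, 0-based half-open. Strand is always `"."`; missing scores are
#' written as 0.
#'
#' @param intervals Interval data.frame as from [genomic_intervals()].
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) > 0 &&
      (any(intervals$start < 0) || any(intervals$start >= intervals$end)))
    stop("invalid interval: require 0 <= start < end")
  score <- ifelse(is.na(intervals$score), 0, intervals$score)
  lines <- if (nrow(intervals) == 0) character(0) else
    paste(intervals$contig, intervals$start, intervals$end,
          ifelse(is.na(intervals$name) | intervals$name == "", ".",
                 intervals$name),
          format(score, trim = TRUE, scientific = FALSE, digits = 15),
          ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file back into an interval table
#' @param path Path to a BED file written by [write_bed()].
#' @return Interval data.frame (contig, start, end, name, score).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0))[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6)) stop("format error: expected 6 BED columns")
  m <- do.call(rbind, parts)
  genomic_intervals(m[, 1], as.integer(m[, 2]), as.integer(m[, 3]),
                    m[, 4], as.numeric(m[, 5]))
}

N_D_NEURONS <- 19L

EXPR_COLUMNS <- c("strain", "temperature_c", "d_count", "dvb_expressed",
                  "intensity_d", "intensity_dvb")

#' Read a per-animal reporter-expression table
#'
#' The TSV must carry a header with columns `strain`, `temperature_c`,
#' `d_count`, `dvb_expressed`, `intensity_d`, `intensity_dvb`. Missing
#' values are `.` or empty. `d_count` is the number of GFP-positive D-type
#' neurons and must lie in 0..19 (the ventral nerve cord has 19 D-type
#' neurons); `dvb_expressed` flags visible GFP in the postanal neuron DVB.
#' Intensities are background-subtracted fluorescence in arbitrary units,
#' nonnegative or missing; animals with missing intensities remain valid for
#' count analyses.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` (one row per animal) with typed columns.
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = c(".", ""), check.names = FALSE)
  missing_cols <- setdiff(EXPR_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("parse error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop("parse error at line ", bad[1] + 1L, ": non-numeric value '",
           x[bad[1]], "' in column ", col)
    out
  }
  ds <- data.frame(
    strain        = raw$strain,
    temperature_c = parse_num(raw$temperature_c, "temperature_c"),
    d_count       = as.integer(parse_num(raw$d_count, "d_count")),
    dvb_expressed = parse_num(raw$dvb_expressed, "dvb_expressed") != 0,
    intensity_d   = parse_num(raw$intensity_d, "intensity_d"),
    intensity_dvb = parse_num(raw$intensity_dvb, "intensity_dvb"),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(ds$d_count) | ds$d_count < 0L | ds$d_count > N_D_NEURONS)
  if (length(bad))
    stop("domain error at line ", bad[1] + 1L, ": d_count must be in 0..",
         N_D_NEURONS, " (19 D-type neurons of the ventral nerve cord)")
  neg <- which(ds$intensity_d < 0 | ds$intensity_dvb < 0)
  if (length(neg))
    stop("domain error at line ", neg[1] + 1L, ": negative intensity")
  ds
}

#' Write a per-animal expression table as TSV
#'
#' Inverse of [read_expression_table()]; missing values are written as `.`.
#'
#' @param ds Expression data.frame.
#' @param path Output path.
#' @export
write_expression_table <- function(ds, path) {
  out <- ds[, EXPR_COLUMNS]
  out$dvb_expressed <- as.integer(out$dvb_expressed)
  for (col in EXPR_COLUMNS) {
    v <- out[[col]]
    v <- if (is.numeric(v)) format(v, trim = TRUE, scientific = FALSE,
                                   digits = 15) else as.character(v)
    v[is.na(out[[col]])] <- "."
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
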
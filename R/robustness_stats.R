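# Robustness statistics for reporter-expression datasets.
#
# Robustness is read out two ways: (i) consistency of the number of
# GFP-positive D-type neurons across individuals (count histograms,
# Wilcoxon rank-sum comparisons) and (ii) dispersion of expression levels
# — DVB/D intensity ratios (Ansari-Bradley scale test) and the scatter of
# (log D, log DVB) points about their group centroid (two-sample
# Kolmogorov-Smirnov on centroid distances). Intensities are analysed on a
# log10 scale; the KS distance statistic is invariant to the log base.

group_subset <- function(ds, strain, temperature) {
  sel <- ds[ds$strain == strain & ds$temperature_c == temperature, ,
            drop = FALSE]
  if (nrow(sel) == 0)
    stop("empty group: strain '", strain, "' at ", temperature, " degrees C")
  sel
}

#' Drop animals with no visible GFP anywhere
#'
#' Animals expressing GFP in no D-type neuron and not in DVB are assumed to
#' have lost the transgene and are excluded upstream of count analyses.
#'
#' @param ds Expression data.frame.
#' @return Filtered data.frame.
#' @export
drop_no_gfp <- function(ds) {
  ds[!(ds$d_count == 0L & !ds$dvb_expressed), , drop = FALSE]
}

#' Distribution of GFP-positive D-neuron counts within a group
#'
#' @param ds Expression data.frame (pre-filtered with [drop_no_gfp()] if
#'   transgene-loss animals may be present).
#' @param strain,temperature Group key.
#' @return Object of class `count_distribution`: list with `percentages`
#'   (named numeric over observed d_count values, summing to 100), `n` and
#'   `group_key`.
#' @export
count_distribution <- function(ds, strain, temperature) {
  g <- group_subset(ds, strain, temperature)
  tab <- table(g$d_count)
  pct <- stats::setNames(100 * as.numeric(tab) / nrow(g), names(tab))
  structure(list(percentages = pct,
                 n = nrow(g),
                 group_key = c(strain = strain,
                               temperature_c = temperature)),
            class = "count_distribution")
}

new_test_result <- function(test_name, statistic, p_value, n1, n2) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2),
            class = "robustness_test")
}

#' @export
print.robustness_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Compare cell-count consistency between two groups
#'
#' Two-sided Wilcoxon rank-sum with mid-rank tie handling. The exact null
#' distribution is used when `n1 + n2 <= 20` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param a,b Integer vectors of d_count values.
#' @return A `robustness_test` (test_name `"wilcoxon_rank_sum"`).
#' @export
compare_counts <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("degenerate data: all values identical across both samples")
    return(new_test_result("wilcoxon_rank_sum",
                           statistic = length(a) * length(b) / 2,
                           p_value = 1, length(a), length(b)))
  }
  exact <- (length(a) + length(b) <= 20L) && !any(duplicated(c(a, b)))
  ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  new_test_result("wilcoxon_rank_sum", ht$statistic, ht$p.value,
                  length(a), length(b))
}

#' Per-animal DVB/D intensity ratios for a group
#'
#' Animals without visible DVB fluorescence, or with a missing or zero
#' intensity, are excluded (they carry no ratio information).
#'
#' @param ds Expression data.frame.
#' @param strain,temperature Group key.
#' @return `data.frame` with columns `ratio` (intensity_dvb / intensity_d)
#'   and `log10_ratio`; the number of excluded animals is attached as
#'   attribute `n_excluded`.
#' @export
ratio_distribution <- function(ds, strain, temperature) {
  g <- group_subset(ds, strain, temperature)
  keep <- g$dvb_expressed & !is.na(g$intensity_d) & !is.na(g$intensity_dvb) &
    g$intensity_d > 0 & g$intensity_dvb > 0
  if (!any(keep))
    stop("no animals with DVB fluorescence in group '", strain, "'/",
         temperature)
  r <- g$intensity_dvb[keep] / g$intensity_d[keep]
  out <- data.frame(ratio = r, log10_ratio = log10(r))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Compare dispersion of two ratio distributions (Ansari-Bradley)
#'
#' Intended for log ratios (e.g. the `log10_ratio` column of
#' [ratio_distribution()]). Each sample is median-centred first, so only
#' scale — not location — is compared. Exact null distribution for small
#' samples without ties, normal approximation otherwise.
#'
#' @param a,b Numeric vectors (log ratios).
#' @param align_medians Subtract each sample's median first (default TRUE).
#' @return A `robustness_test` (test_name `"ansari_bradley"`).
#' @export
compare_dispersion <- function(a, b, align_medians = TRUE) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (align_medians) {
    a <- a - stats::median(a)
    b <- b - stats::median(b)
  }
  if (isTRUE(stats::var(c(a, b)) == 0) || isTRUE(stats::var(a) == 0) ||
      isTRUE(stats::var(b) == 0)) {
    warning("degenerate data: constant sample(s)")
    return(new_test_result("ansari_bradley", NA_real_, 1,
                           length(a), length(b)))
  }
  exact <- (length(a) + length(b) <= 50L) && !any(duplicated(c(a, b)))
  if (exact) {
    ht <- stats::ansari.test(a, b, alternative = "two.sided", exact = TRUE)
    return(new_test_result("ansari_bradley", ht$statistic, ht$p.value,
                           length(a), length(b)))
  }
  # Normal approximation from the conditional moments of the midrank
  # Ansari-Bradley scores. (stats::ansari.test leaves the mean un-tie-
  # corrected, which breaks exact symmetry under sample swap for unequal
  # n; the conditional moments restore it.)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  s <- pmin(r, N + 1 - r)
  ab <- sum(s[seq_len(n1)])
  S <- sum(s)
  e <- n1 * S / N
  v <- n1 * n2 * (N * sum(s^2) - S^2) / (N^2 * (N - 1))
  z <- (ab - e) / sqrt(v)
  p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  new_test_result("ansari_bradley", ab, p, n1, n2)
}

#' Centroid-distance scatter of log intensities for a group
#'
#' Each retained animal contributes a point
#' `(log intensity_d, log intensity_dvb)`; the group centroid is the
#' componentwise mean and each animal's scatter is its Euclidean distance
#' from the centroid. DVB-negative and zero/missing-intensity animals are
#' excluded as in [ratio_distribution()].
#'
#' @param ds Expression data.frame.
#' @param strain,temperature Group key.
#' @param log_base Log base for intensities (default 10; the downstream KS
#'   comparison is invariant to this choice).
#' @return Object of class `scatter_result`: `group_key`, `centroid`,
#'   `distances`, `n`, `n_excluded_no_dvb`.
#' @export
scatter_distances <- function(ds, strain, temperature, log_base = 10) {
  g <- group_subset(ds, strain, temperature)
  keep <- g$dvb_expressed & !is.na(g$intensity_d) & !is.na(g$intensity_dvb) &
    g$intensity_d > 0 & g$intensity_dvb > 0
  if (sum(keep) < 3L)
    stop("fewer than 3 animals retained for group '", strain, "'/",
         temperature, "; centroid unstable")
  x <- log(g$intensity_d[keep], base = log_base)
  y <- log(g$intensity_dvb[keep], base = log_base)
  centroid <- c(mean(x), mean(y))
  structure(list(group_key = c(strain = strain,
                               temperature_c = temperature),
                 centroid = centroid,
                 distances = sqrt((x - centroid[1])^2 + (y - centroid[2])^2),
                 n = sum(keep),
                 n_excluded_no_dvb = sum(!keep)),
            class = "scatter_result")
}

#' Compare two scatter-distance distributions (two-sample KS)
#'
#' @param r1,r2 `scatter_result` objects (or numeric distance vectors).
#' @return A `robustness_test` (test_name `"kolmogorov_smirnov"`); the
#'   statistic is the ECDF supremum distance D in `[0,1]`.
#' @export
compare_scatter <- function(r1, r2) {
  d1 <- if (inherits(r1, "scatter_result")) r1$distances else r1
  d2 <- if (inherits(r2, "scatter_result")) r2$distances else r2
  if (length(d1) == 0 || length(d2) == 0)
    stop("both distance lists must be non-empty")
  ht <- suppressWarnings(stats::ks.test(d1, d2, alternative = "two.sided"))
  new_test_result("kolmogorov_smirnov", ht$statistic, ht$p.value,
                  length(d1), length(d2))
}

#' Benjamini-Hochberg adjustment for a set of test results
#'
#' Off by default everywhere (raw p-values are reported, matching standard
#' practice for these small test families); provided for users who run
#' many pairwise comparisons.
#'
#' @param results List of `robustness_test` objects.
#' @return The list with an added `p_adjusted` element per test.
#' @export
adjust_bh <- function(results) {
  p <- vapply(results, function(r) r$p_value, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  Map(function(r, q) { r$p_adjusted <- q; r }, results, padj)
}
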
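# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the stats:: calls the package wraps) so that
# equivalence tests are two-route checks.

oracle_kmers <- function(s, k) {
  s <- toupper(s)
  counts <- integer(0)
  total <- 0L
  if (nchar(s) >= k) {
    for (i in 1:(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      total <- total + 1L
      counts[w] <- if (w %in% names(counts)) counts[[w]] + 1L else 1L
    }
  }
  list(counts = counts, total = total)
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_at <- function(s) {
  o <- oracle_kmers(s, 2)
  aa <- if ("AA" %in% names(o$counts)) o$counts[["AA"]] else 0
  tt <- if ("TT" %in% names(o$counts)) o$counts[["TT"]] else 0
  (aa + tt) / o$total
}

# per-window column scan over reference non-gap positions
oracle_identity <- function(seqs, ref_idx, window, step = 1) {
  rows <- strsplit(toupper(seqs), "")
  ref <- rows[[ref_idx]]
  cols <- which(ref != "-")
  n <- length(cols)
  starts <- seq(0, n - window, by = step)
  vapply(starts, function(s0) {
    hits <- 0
    for (j in (s0 + 1):(s0 + window)) {
      col <- cols[j]
      b <- ref[col]
      if (!b %in% c("A", "C", "G", "T")) next
      ok <- TRUE
      for (r in seq_along(rows)[-ref_idx])
        if (rows[[r]][col] != b) { ok <- FALSE; break }
      if (ok) hits <- hits + 1
    }
    hits / window
  }, numeric(1))
}

oracle_select_enriched <- function(scores, ref, tol) {
  d <- abs(scores$at_score - ref) / ref
  keep <- scores[d <= tol, , drop = FALSE]
  keep$dist <- d[d <= tol]
  keep[order(keep$dist, keep$contig, keep$start), , drop = FALSE]
}

oracle_count_pct <- function(counts) {
  vals <- sort(unique(counts))
  setNames(vapply(vals, function(v) 100 * sum(counts == v) / length(counts),
                  numeric(1)), as.character(vals))
}

oracle_scatter <- function(log_d, log_dvb) {
  cx <- sum(log_d) / length(log_d)
  cy <- sum(log_dvb) / length(log_dvb)
  sqrt((log_d - cx)^2 + (log_dvb - cy)^2)
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_wilcox_exact_p <- function(a, b) {
  pooled <- c(a, b)
  ranks <- rank(pooled)
  n1 <- length(a)
  obs <- sum(ranks[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  sums <- apply(splits, 2, function(ix) sum(ranks[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Ansari-Bradley scores: rank from both ends of the pooled sorted sample
oracle_ab_statistic <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  r <- rank(pooled)
  scores <- pmin(r, N + 1 - r)
  sum(scores[seq_along(a)])
}

oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}

random_seq <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}
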
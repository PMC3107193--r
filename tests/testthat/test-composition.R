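test_that("count_kmers counts overlapping windows and drops N windows", {
  p <- count_kmers("AAAA", 2)
  expect_equal(unname(p$counts[["AA"]]), 3L)
  expect_equal(p$total, 3L)

  p <- count_kmers("ACNGT", 2)
  expect_equal(p$total, 2L)
  expect_equal(unname(p$counts[c("AC", "GT")]), c(1L, 1L))

  expect_error(count_kmers("A", 2), "empty profile")
})

test_that("count_kmers matches a brute-force window scan", {
  set.seed(101)
  for (i in 1:30) {
    s <- random_seq(sample(20:200, 1), p_n = 0.05)
    k <- sample(1:3, 1)
    if (nchar(s) < k) next
    o <- oracle_kmers(s, k)
    p <- count_kmers(s, k)
    expect_equal(p$total, o$total)
    for (w in names(o$counts))
      expect_equal(unname(p$counts[[w]]), unname(o$counts[[w]]))
    expect_equal(sum(p$counts), p$total)
  }
})

test_that("class collapsing merges reverse complements into 10 classes", {
  cp <- collapse_classes(count_kmers("ATATAT", 2))
  expect_equal(length(cp$freqs), 10L)
  expect_equal(unname(cp$freqs[c("AT", "TA", "AA/TT")]), c(0.6, 0.4, 0))

  cp <- collapse_classes(count_kmers(strrep("A", 100), 2))
  expect_equal(unname(cp$freqs[["AA/TT"]]), 1.0)

  expect_error(collapse_classes(count_kmers("NNNN", 2)),
               "undefined frequencies")
})

test_that("class frequencies sum to 1 and are strand-invariant", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_seq(sample(10:100, 1))
    for (k in 2:3) {
      cp <- collapse_classes(count_kmers(s, k))
      expect_equal(sum(cp$freqs), 1, tolerance = 1e-9)
      cp_rc <- collapse_classes(count_kmers(oracle_revcomp(s), k))
      expect_equal(cp$freqs, cp_rc$freqs)
    }
  }
})

fake_class_profile <- function(counts) {
  structure(list(k = 2L, counts = counts, freqs = counts / sum(counts),
                 total = sum(counts)), class = "class_profile")
}

test_that("enrichment is zero at identity, log2 on ratios, antisymmetric", {
  cls <- unique(unname(kmer_classes(2)))
  base <- setNames(rep(10, 10), cls)

  t1 <- fake_class_profile(base)
  e <- enrichment(t1, t1, pseudocount = 0)
  expect_equal(e$log2_ratio, rep(0, 10))

  # AA/TT at 0.30 vs 0.15 with all classes occupied, pseudocount unused
  ct <- setNames(c(30, rep(70 / 9, 9)), cls)
  cb <- setNames(c(15, rep(85 / 9, 9)), cls)
  e <- enrichment(fake_class_profile(ct), fake_class_profile(cb),
                  pseudocount = 0)
  expect_equal(e$log2_ratio[e$class == "AA/TT"], 1.0)

  set.seed(33)
  for (i in 1:20) {
    a <- fake_class_profile(setNames(rpois(10, 5), cls))       # zeros likely
    b <- fake_class_profile(setNames(rpois(10, 5) + 1, cls))
    if (a$total == 0) next
    e_ab <- enrichment(a, b, 0.5)
    e_ba <- enrichment(b, a, 0.5)
    expect_equal(e_ab$log2_ratio, -e_ba$log2_ratio, tolerance = 1e-12)
    expect_true(all(is.finite(e_ab$log2_ratio)))
  }

  expect_error(
    enrichment(fake_class_profile(base),
               structure(list(k = 3L, counts = 1, freqs = 1, total = 1),
                         class = "class_profile")),
    "mismatched k")
})

test_that("at_enrichment_score is the AA/TT class frequency", {
  expect_equal(at_enrichment_score(strrep("A", 50))[["aa_tt"]], 1.0)
  expect_equal(at_enrichment_score(strrep("G", 50))[["aa_tt"]], 0.0)
  expect_error(at_enrichment_score("NNNN"), "all N|undefined")

  set.seed(5)
  for (i in 1:30) {
    s <- random_seq(1000, p_n = 0.02)
    sc <- at_enrichment_score(s)
    expect_equal(sc[["aa_tt"]], oracle_at(s))
    expect_equal(at_enrichment_score(oracle_revcomp(s))[["aa_tt"]],
                 sc[["aa_tt"]])
  }
})

test_that("nucleosome-depletion score is a weighted fold-enrichment", {
  tri <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3)
  uniform <- trinuc_weight_table(tri, rep(1, 64), rep(1 / 64, 64))
  set.seed(9)
  expect_equal(nucleosome_depletion_score(random_seq(500), uniform), 1.0)

  indicator <- trinuc_weight_table(tri, as.numeric(tri %in% c("AAA", "TTT")),
                                   rep(1 / 64, 64))
  expect_equal(nucleosome_depletion_score(strrep("A", 100), indicator), 32)

  member <- read_trinuc_table(fixture_trinuc_path())
  for (i in 1:20) {
    s <- random_seq(300)
    o <- oracle_kmers(s, 3)
    f <- setNames(rep(0, 64), tri)
    f[names(o$counts)] <- unlist(o$counts) / o$total
    expected <- sum(member$weight * f[member$trinucleotide]) /
      sum(member$weight * member$background_freq)
    expect_equal(nucleosome_depletion_score(s, member), expected)
  }

  degenerate <- trinuc_weight_table(tri, as.numeric(tri == "AAA"),
                                    c(0, rep(1 / 63, 63)))
  expect_error(nucleosome_depletion_score("ACGTACGT", degenerate),
               "degenerate")
})

test_that("trinucleotide weight tables are validated", {
  tri <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3)
  expect_error(trinuc_weight_table(tri[-1], rep(1, 63), rep(1 / 63, 63)),
               "64 trinucleotides")
  expect_error(trinuc_weight_table(tri, c(-1, rep(1, 63)), rep(1 / 64, 64)),
               "nonnegative")
  expect_error(trinuc_weight_table(tri, rep(1, 64), rep(1 / 60, 64)),
               "sum to 1")
})
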
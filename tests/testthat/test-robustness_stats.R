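test_that("count distributions are percentage histograms", {
  cd <- count_distribution(make_ds(rep(19, 200)), "FL", 20)
  expect_equal(cd$percentages, c("19" = 100))
  expect_equal(cd$n, 200L)

  cd <- count_distribution(make_ds(c(rep(19, 50), rep(18, 50))), "FL", 20)
  expect_equal(sort(cd$percentages), sort(c("18" = 50, "19" = 50)))

  expect_error(count_distribution(make_ds(1), "nope", 20), "empty group")

  set.seed(21)
  for (i in 1:20) {
    x <- sample(0:19, sample(20:200, 1), replace = TRUE)
    cd <- count_distribution(make_ds(x), "FL", 20)
    expect_equal(cd$percentages, oracle_count_pct(x))
    expect_equal(sum(cd$percentages), 100, tolerance = 1e-6)
  }
})

test_that("drop_no_gfp removes only fully GFP-negative animals", {
  ds <- make_ds(c(0, 0, 5), dvb = c(FALSE, TRUE, FALSE))
  kept <- drop_no_gfp(ds)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$d_count, c(0L, 5L))
})

test_that("compare_counts: exact small-sample p, null behavior, degeneracy", {
  r <- compare_counts(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p_value, oracle_wilcox_exact_p(c(1, 2), c(3, 4)))

  set.seed(8)
  x <- sample(10:19, 30, replace = TRUE)
  r <- compare_counts(x, x)
  expect_gte(r$p_value, 0.99)

  expect_warning(r <- compare_counts(rep(19, 50), rep(19, 50)),
                 "degenerate")
  expect_equal(r$p_value, 1)
})

test_that("compare_counts matches enumeration on small untied samples", {
  set.seed(31)
  for (i in 1:15) {
    vals <- sample(1:100, sample(6:10, 1))
    n1 <- sample(2:(length(vals) - 2), 1)
    a <- vals[1:n1]; b <- vals[-(1:n1)]
    expect_equal(compare_counts(a, b)$p_value,
                 oracle_wilcox_exact_p(a, b), tolerance = 1e-9)
  }
})

test_that("ratio distributions apply DVB exclusions", {
  ds <- make_ds(rep(19, 4), dvb = c(TRUE, TRUE, FALSE, TRUE),
                int_d = c(1000, 1000, 1000, 500),
                int_dvb = c(1000, 2000, 3000, NA))
  rd <- ratio_distribution(ds, "FL", 20)
  expect_equal(rd$ratio, c(1, 2))
  expect_equal(rd$log10_ratio, log10(c(1, 2)))
  expect_equal(attr(rd, "n_excluded"), 2L)

  ds$dvb_expressed <- FALSE
  expect_error(ratio_distribution(ds, "FL", 20), "no animals")

  set.seed(12)
  ds <- gen_expression(expr_preset("fragile_proximal", n_animals = 100),
                       "PR", seed = 5)
  rd <- ratio_distribution(ds, "PR", 20)
  keep <- ds$dvb_expressed & !is.na(ds$intensity_dvb)
  expect_equal(rd$ratio, ds$intensity_dvb[keep] / ds$intensity_d[keep])
})

test_that("compare_dispersion is an Ansari-Bradley scale test", {
  set.seed(4)
  x <- rnorm(20)
  r <- compare_dispersion(x, x)
  expect_gte(r$p_value, 0.99)

  expect_warning(r <- compare_dispersion(rep(1, 5), rep(2, 5)), "degenerate")
  expect_equal(r$p_value, 1)

  # statistic equals hand-computed AB rank scores (median-aligned input)
  a <- c(-0.3, 0.05, 0.4); b <- c(-1.1, 0.02, 1.3)
  r <- compare_dispersion(a, b, align_medians = FALSE)
  expect_equal(unname(r$statistic), oracle_ab_statistic(a, b))
})

test_that("scatter distances are centroid Euclidean norms in log space", {
  ds <- make_ds(rep(19, 4), int_d = c(1, 100, 1, 100),
                int_dvb = c(1, 1, 100, 100))
  sc <- scatter_distances(ds, "FL", 20)
  expect_equal(sc$centroid, c(1, 1))
  expect_equal(sc$distances, rep(sqrt(2), 4))

  ds <- make_ds(rep(19, 5), int_d = 1000, int_dvb = 500)
  sc <- scatter_distances(ds, "FL", 20)
  expect_equal(sc$distances, rep(0, 5))

  expect_error(scatter_distances(make_ds(rep(19, 2)), "FL", 20),
               "fewer than 3")

  set.seed(66)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    ds <- make_ds(rep(19, n), int_d = 10^rnorm(n, 3, 0.3),
                  int_dvb = 10^rnorm(n, 3, 0.3))
    sc <- scatter_distances(ds, "FL", 20)
    expect_equal(sc$distances,
                 oracle_scatter(log10(ds$intensity_d),
                                log10(ds$intensity_dvb)))
  }
})

test_that("KS comparison of scatter: identity, disjoint supports, oracle", {
  set.seed(9)
  ds <- make_ds(rep(19, 20), int_d = 10^rnorm(20, 3, 0.2),
                int_dvb = 10^rnorm(20, 3, 0.2))
  sc <- scatter_distances(ds, "FL", 20)
  r <- compare_scatter(sc, sc)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  r <- compare_scatter(c(0, 0, 0), c(1, 1, 1))
  expect_equal(unname(r$statistic), 1)

  for (i in 1:20) {
    x <- abs(rnorm(50, sd = 0.1)); y <- abs(rnorm(50, sd = 0.3))
    r <- compare_scatter(x, y)
    expect_equal(unname(r$statistic), oracle_ks_D(x, y))
  }
})

test_that("tests are two-sided symmetric with p in [0,1]", {
  set.seed(14)
  for (i in 1:10) {
    a <- sample(0:19, 30, replace = TRUE)
    b <- sample(5:19, 40, replace = TRUE)
    x <- rnorm(25, sd = 0.2); y <- rnorm(35, sd = 0.4)
    for (pair in list(list(compare_counts(a, b), compare_counts(b, a)),
                      list(compare_dispersion(x, y),
                           compare_dispersion(y, x)),
                      list(compare_scatter(abs(x), abs(y)),
                           compare_scatter(abs(y), abs(x))))) {
      expect_equal(pair[[1]]$p_value, pair[[2]]$p_value, tolerance = 1e-9)
      expect_gte(pair[[1]]$p_value, 0)
      expect_lte(pair[[1]]$p_value, 1)
    }
  }
})

test_that("scatter scales with log base; KS statistic is base-invariant", {
  set.seed(19)
  ds <- make_ds(rep(19, 30), int_d = 10^rnorm(30, 3, 0.3),
                int_dvb = 10^rnorm(30, 3, 0.3))
  s10 <- scatter_distances(ds, "FL", 20, log_base = 10)
  s2 <- scatter_distances(ds, "FL", 20, log_base = 2)
  expect_equal(s2$distances, s10$distances * log(10) / log(2),
               tolerance = 1e-12)

  ds2 <- make_ds(rep(19, 30), int_d = 10^rnorm(30, 3, 0.5),
                 int_dvb = 10^rnorm(30, 3, 0.5))
  t10 <- scatter_distances(ds2, "FL", 20, log_base = 10)
  t2 <- scatter_distances(ds2, "FL", 20, log_base = 2)
  expect_equal(compare_scatter(s10, t10)$statistic,
               compare_scatter(s2, t2)$statistic)
})

test_that("higher intensity noise increases mean scatter distance", {
  wins <- 0L
  for (seed in 1:10) {
    lo <- expr_sim_params(n_animals = 100, sigma_d = 0.1, sigma_r = 0.1)
    hi <- expr_sim_params(n_animals = 100, sigma_d = 0.4, sigma_r = 0.4)
    d_lo <- scatter_distances(gen_expression(lo, "L", seed), "L", 20)
    d_hi <- scatter_distances(gen_expression(hi, "H", seed + 1000), "H", 20)
    wins <- wins + (mean(d_hi$distances) > mean(d_lo$distances))
  }
  expect_gte(wins, 9L)
})

test_that("BH adjustment preserves raw p-values and adds adjusted ones", {
  set.seed(2)
  res <- list(compare_counts(sample(0:19, 30, TRUE), sample(0:19, 30, TRUE)),
              compare_counts(rep(10, 30), rep(15, 30)))
  adj <- adjust_bh(res)
  expect_equal(vapply(adj, `[[`, 1, "p_value"),
               vapply(res, `[[`, 1, "p_value"))
  expect_true(all(vapply(adj, `[[`, 1, "p_adjusted") >=
                    vapply(adj, `[[`, 1, "p_value") - 1e-12))
})
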
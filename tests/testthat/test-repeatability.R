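test_that("compound_rsd is the sample RSD in percent", {
  expect_equal(compound_rsd(c(10, 10, 10)), 0)
  expect_equal(compound_rsd(c(8, 10, 12)), 20)
  expect_equal(compound_rsd(c(8, 10, NA, 12)), 20)   # missing ignored
  expect_true(is.na(compound_rsd(c(-5, 0, 5))))       # non-positive mean
  expect_true(is.na(compound_rsd(c(3))))
})

test_that("below-threshold cells count strictly and render the printed style", {
  vals_below <- list(c(100, 100, 100))                 # RSD 0
  vals_above <- list(c(50, 100, 150))                  # RSD 50
  vals_exact <- list(c(85, 100, 115))                  # RSD exactly 15
  cells <- tibble::tibble(
    compound = sprintf("lc%02d", 1:27),
    class = "amino acids", measurement_type = "LC", condition = "c1",
    values = c(rep(vals_below, 22), rep(vals_above, 4), vals_exact)
  )
  s <- summarize_repeatability(fake_qc(cells))
  expect_equal(s$rsd$rsd_pct[s$rsd$compound == "lc27"], 15)
  expect_equal(s$below_threshold$n_below, 22L)         # 15.0 is not below
  expect_equal(s$below_threshold$n_detected, 27L)
  expect_equal(s$below_threshold$label, "22/27 (81%)")

  # one fewer above-threshold compound gives the 23/27 (85%) cell
  cells$values[23] <- vals_below
  s2 <- summarize_repeatability(fake_qc(cells))
  expect_equal(s2$below_threshold$label, "23/27 (85%)")
})

test_that("summary is a pure function of the QC result", {
  qc <- read_toy_qc()
  expect_equal(summarize_repeatability(qc), summarize_repeatability(qc))
})

test_that("conditions are ranked lowest-first with averaged ties and ignored missing", {
  d <- tibble::tibble(compound = "m",
                      condition = sprintf("c%d", 1:6),
                      rsd_pct = c(19, 22, 13, 25, 9, 10))
  expect_equal(rank_conditions(d)$rank, c(4, 5, 3, 6, 1, 2))

  d2 <- tibble::tibble(compound = "m", condition = c("a", "b", "c"),
                       rsd_pct = c(5, 5, 10))
  expect_equal(rank_conditions(d2)$rank, c(1.5, 1.5, 3))

  d3 <- tibble::tibble(compound = "m", condition = c("a", "b", "c"),
                       rsd_pct = c(7, NA, 9))
  r3 <- rank_conditions(d3)
  expect_equal(r3$condition, c("a", "c"))
  expect_equal(r3$rank, c(1, 2))

  # worst-rank category variant assigns missing cells the bottom category
  r3w <- rank_conditions(d3, missing = "worst_rank")
  expect_equal(setNames(r3w$rank, r3w$condition),
               c(a = 1, b = 3, c = 2))

  # compounds missing everywhere are excluded
  d4 <- dplyr::bind_rows(d3, tibble::tibble(
    compound = "gone", condition = c("a", "b", "c"), rsd_pct = NA_real_))
  expect_false("gone" %in% rank_conditions(d4)$compound)
})

test_that("Kruskal-Wallis H matches the closed form and base R", {
  kw0 <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)

  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 32 / 7, tolerance = 1e-12)

  # cross-check against the independent base-R implementation, with ties
  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:6, 18, replace = TRUE)
    g <- rep(c("a", "b", "c"), each = 6)
    ours <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact enumeration p agrees with the brute-force permutation oracle", {
  set.seed(11)
  instances <- list(
    list(c(1, 2), c(3, 4), c(5, 6)),
    list(c(1, 5, 2), c(4, 4), c(9, 2, 7)),
    list(c(2, 2, 2), c(5, 1), c(3, 3)),          # heavy ties
    list(runif(3), runif(2), runif(3)),
    list(rnorm(4), rnorm(4))
  )
  for (groups in instances) {
    p_pkg <- kruskal_wallis(groups, p_method = "exact")$p.value
    p_oracle <- kw_perm_oracle_p(groups)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }
})

test_that("ranking then testing is invariant under strictly monotone transforms", {
  set.seed(9)
  d <- tidyr::expand_grid(compound = sprintf("m%02d", 1:15),
                          condition = c("a", "b", "c", "d"))
  d$rsd_pct <- runif(nrow(d), 5, 60)
  h1 <- kruskal_wallis(rank_conditions(d)$rank,
                       rank_conditions(d)$condition)$statistic
  d2 <- dplyr::mutate(d, rsd_pct = exp(rsd_pct / 10))
  r2 <- rank_conditions(d2)
  h2 <- kruskal_wallis(r2$rank, r2$condition)$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("Tukey-Kramer on ranks reduces to the rank-sum comparison for k = 2", {
  set.seed(12)
  for (i in 1:10) {
    x <- c(rnorm(6), rnorm(7, mean = runif(1, 0, 2)))
    g <- rep(c("a", "b"), c(6, 7))
    tk <- tukey_kramer(x, g)
    kw <- kruskal_wallis(x, g)
    expect_equal(tk$pairs$p.value, kw$p.value, tolerance = 1e-5)
  }
  # identical groups: zero difference, not significant
  tk0 <- tukey_kramer(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(tk0$pairs$mean_rank_diff, 0)
  expect_false(tk0$pairs$significant)
})

test_that("H is non-negative, p lies in [0, 1] over random instances", {
  set.seed(2)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    groups <- replicate(k, sample(1:8, sample(3:8, 1), replace = TRUE),
                        simplify = FALSE)
    kw <- kruskal_wallis(groups)
    expect_gte(kw$statistic, 0)
    expect_gte(kw$p.value, 0)
    expect_lte(kw$p.value, 1)
  }
})

test_that("a strongly shifted condition is called out by the post-hoc test", {
  set.seed(33)
  hits <- 0L
  n_runs <- 50L
  for (i in seq_len(n_runs)) {
    d <- tidyr::expand_grid(compound = sprintf("m%02d", 1:30),
                            condition = c("c1", "c2", "c3"))
    d$rsd_pct <- runif(nrow(d), 5, 15) +
      ifelse(d$condition == "c3", 100, 0)
    cc <- compare_conditions(d, alpha = 0.05)
    pp <- tidy(cc)
    c3_pairs <- pp$significant[pp$group1 == "c3" | pp$group2 == "c3"]
    if (all(c3_pairs)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("compare_conditions runs on a real summary and reports coherently", {
  qc <- read_toy_qc()
  s <- summarize_repeatability(qc)
  cc <- compare_conditions(s)
  g <- glance(cc)
  expect_gte(g$statistic, 0)
  expect_true(g$p.value >= 0 && g$p.value <= 1)
  expect_equal(nrow(tidy(cc)), choose(3, 2))
  # raw-value variant is also available
  cc_raw <- compare_conditions(s, rank_based = FALSE)
  expect_s3_class(cc_raw$kw, "kw_test")
})
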
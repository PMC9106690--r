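test_that("LOD combines the blank-median rule with the noise floor", {
  cfg <- qc_config()
  lod1 <- compute_lod(tibble::tibble(compound = "x",
                                     value = c(5000, 6000, 7000)), cfg)
  expect_equal(lod1$lod, 20000)        # 3 * 6000 < floor
  expect_equal(lod1$source, "floor")

  lod2 <- compute_lod(tibble::tibble(compound = "x",
                                     value = c(10000, 20000, 30000)), cfg)
  expect_equal(lod2$lod, 60000)        # blank-derived branch
  expect_equal(lod2$source, "blank")

  lod3 <- compute_lod(tibble::tibble(compound = "x", value = c(0, 0, 0)), cfg)
  expect_equal(lod3$lod, 20000)

  lod4 <- compute_lod(tibble::tibble(compound = "x", value = NA_real_), cfg)
  expect_equal(lod4$lod, 20000)
  expect_equal(lod4$source, "floor_only")
})

test_that("the LOD boundary is strict: values must exceed the LOD", {
  d <- make_qc_tbl("c1", 1:3, "x", c(20000, 20001, 25000))
  d$lod <- NA_real_
  out <- apply_lod_filter(d, tibble::tibble(compound = "x", lod = 20000))
  expect_equal(out$status, c("lod", "retained", "retained"))
  expect_error(apply_lod_filter(d, tibble::tibble(compound = "y", lod = 1)),
               "no LOD")
})

test_that("the detection rule keeps 3/5 and 3/4 but drops 2/5", {
  cfg <- qc_config()
  d35 <- make_qc_tbl("c1", 1:5, "x", c(1, 1, 1, NA, NA))
  d35$status[4:5] <- "lod"
  expect_equal(sum(detection_filter(d35, cfg)$status == "retained"), 3)

  d25 <- make_qc_tbl("c1", 1:5, "x", c(1, 1, NA, NA, NA))
  d25$status[3:5] <- "lod"
  out25 <- detection_filter(d25, cfg)
  expect_equal(sum(out25$status == "retained"), 0)
  expect_equal(sum(out25$status == "detection_60pct"), 2)

  # an outlier-removed replicate leaves the denominator: 3 of 4 is valid
  d34 <- make_qc_tbl("c1", 1:5, "x", c(1, 1, 1, NA, 9))
  d34$status[4] <- "lod"
  d34$status[5] <- "outlier_mad"
  expect_equal(sum(detection_filter(d34, cfg)$status == "retained"), 3)
})

test_that("internal-standard normalization divides by the mapped standard", {
  d <- make_qc_tbl("c1", 1:3, "x", c(40000, NA, 30000))
  d$status[2] <- "missing"
  istd <- tibble::tibble(sample_id = sprintf("S_c1_R%d", 1:3),
                         istd = "IS", value = c(20000, 20000, NA))
  out <- normalize_to_istd(d, istd)
  expect_equal(out$value_norm[1], 2)
  expect_true(is.na(out$value_norm[2]))
  expect_equal(out$status[2], "missing")         # missing stays missing
  expect_equal(out$status[3], "istd_missing")    # absent standard

  # halving the standard in one injection doubles that injection's value
  istd2 <- istd
  istd2$value <- c(20000, 20000, 10000)
  out2 <- normalize_to_istd(make_qc_tbl("c1", 1:3, "x", rep(30000, 3)), istd2)
  expect_equal(out2$value_norm[3] / out2$value_norm[1], 2)
})

test_that("MAD outlier bounds flag and remove the extreme replicate", {
  d <- make_qc_tbl("c1", 1:5, "x", c(100, 101, 99, 100, 250))
  scan <- detect_sample_outliers(d, qc_config())
  f <- scan$flags
  expect_equal(f$center[1], 100)
  expect_equal(f$mad[1], 1)
  expect_equal(f$lower[1], 97.5)
  expect_equal(f$upper[1], 102.5)
  expect_equal(f$replicate[f$flagged], 5L)
  expect_true(f$removed[f$replicate == 5])
  expect_equal(unique(scan$data$status[scan$data$replicate == 5]),
               "outlier_mad")
})

test_that("equal replicate sums collapse the bounds without flagging anything", {
  d <- make_qc_tbl("c1", 1:5, "x", rep(7, 5))
  scan <- detect_sample_outliers(d, qc_config())
  expect_equal(scan$flags$mad, rep(0, 5))
  expect_false(any(scan$flags$flagged))
})

test_that("outlier removal is capped so 4 of 5 replicates always remain", {
  d <- make_qc_tbl("c1", 1:5, "x", c(100, 100, 100, 200, 300))
  scan <- detect_sample_outliers(d, qc_config())
  f <- scan$flags
  expect_equal(sort(f$replicate[f$flagged]), c(4L, 5L))
  expect_equal(f$replicate[f$removed], 5L)   # only the most extreme
  expect_equal(sum(scan$data$status == "retained"), 4)
})

test_that("conditions with fewer than 3 replicates are skipped with a note", {
  d <- make_qc_tbl("c1", 1:2, "x", c(1, 100))
  scan <- detect_sample_outliers(d, qc_config())
  expect_equal(nrow(scan$flags), 0)
  expect_equal(scan$skipped$condition, "c1")
  expect_match(scan$skipped$note, "skipped")
})

test_that("sparse cells are discarded at the 3-value boundary", {
  cfg <- qc_config()
  d3 <- make_qc_tbl("c1", 1:3, "x", c(1, 2, 3))
  expect_equal(sum(discard_sparse(d3, cfg)$status == "retained"), 3)

  d2 <- make_qc_tbl("c1", 1:3, "x", c(1, 2, NA))
  d2$status[3] <- "lod"
  out <- discard_sparse(d2, cfg)
  expect_equal(sum(out$status == "retained"), 0)
  expect_equal(sum(out$status == "sparse_lt3"), 2)
})

test_that("the full cascade reproduces the hand-derived toy-plate truth", {
  qc <- read_toy_qc()
  g <- glance(qc)
  expect_equal(g$n_values_in, 130)
  expect_equal(g$n_retained, 92)
  expect_equal(g$n_rejected, 38)
  expect_equal(g$n_outlier_injections, 1)

  # retained replicate counts per compound x condition, derived by hand
  counts <- dplyr::count(tidy(qc), compound, condition)
  key <- setNames(counts$n, paste(counts$compound, counts$condition))
  expected <- c(
    "Ala A" = 5, "Ala B" = 5, "Ala C" = 3,
    "Gly A" = 4, "Gly B" = 5,
    "Ser B" = 5, "Ser C" = 3,
    "Leu B" = 5, "Leu C" = 3,
    "PC 01 A" = 4, "PC 01 B" = 5, "PC 01 C" = 3,
    "PC 02 A" = 4, "PC 02 B" = 5, "PC 02 C" = 3,
    "PC 03 A" = 3, "PC 03 B" = 5, "PC 03 C" = 3,
    "PC 04 B" = 5, "PC 04 C" = 3,
    "SM 01 A" = 4, "SM 01 B" = 4, "SM 01 C" = 3
  )
  expect_equal(length(key), length(expected))
  expect_equal(key[names(expected)], expected)
  # Val fails the LOD everywhere; Ser/Leu/PC 04 fail in A; Gly is sparse in C
  expect_false("Val" %in% counts$compound)

  audit <- dplyr::count(qc_audit(qc), rule)
  expect_equal(setNames(audit$n, audit$rule),
               c(detection_60pct = 4L, istd_missing = 1L, lod = 26L,
                 outlier_mad = 5L, sparse_lt3 = 2L))

  # the planted whole-sample outlier: condition A replicate 5, FIA block only
  fl <- qc$outlier_flags[qc$outlier_flags$flagged, ]
  expect_equal(nrow(fl), 1)
  expect_equal(fl$condition, "A")
  expect_equal(fl$measurement_type, "FIA")
  expect_equal(fl$replicate, 5L)

  # Leu's blank-derived LOD (3 x 20000) beats the floor
  expect_equal(qc$lods$lod[qc$lods$compound == "Leu"], 60000)
  expect_equal(qc$lods$lod[qc$lods$compound == "Ala"], 20000)

  # hand-computed RSDs of retained normalized values
  s <- summarize_repeatability(qc)
  rsd <- setNames(s$rsd$rsd_pct, paste(s$rsd$compound, s$rsd$condition))
  expect_equal(rsd[["Ala A"]], 15.72637, tolerance = 1e-6)
  expect_equal(rsd[["Gly A"]], 19.86146, tolerance = 1e-6)
  expect_equal(rsd[["PC 01 B"]], 24.84520, tolerance = 1e-6)
  expect_equal(rsd[["SM 01 B"]], 0)
})

test_that("a clean generous plate retains every compound in every condition", {
  sim <- simulate_plate(scenario_config(
    panel = small_panel(), conditions = c("c1", "c2", "c3"),
    true_mean = 5e5, cv = 0.08, seed = 21
  ))
  qc <- run_qc(sim$plate)
  expect_equal(glance(qc)$n_cells_detected, 10 * 3)
  expect_equal(glance(qc)$n_compounds_detected, 10)
})

test_that("outlier detection is invariant to a global internal-standard rescale", {
  panel <- load_panel(toy_panel_path())
  plate <- read_plate(toy_plate_path(), panel)
  plate2 <- plate
  plate2$istd$value <- plate2$istd$value * 3.7
  qc1 <- run_qc(plate)
  qc2 <- run_qc(plate2)
  expect_equal(qc1$outlier_flags$flagged, qc2$outlier_flags$flagged)
  expect_equal(qc1$outlier_flags$removed, qc2$outlier_flags$removed)
  expect_equal(dplyr::select(tidy(qc1), -value_norm),
               dplyr::select(tidy(qc2), -value_norm))
})

test_that("retained plus rejected always equals the non-missing input", {
  for (seed in 1:5) {
    sim <- simulate_plate(scenario_config(
      panel = small_panel(), conditions = c("c1", "c2"),
      true_mean = tibble::tibble(compound = small_panel()$compound,
                                 true_mean = exp(runif(10, log(1e4),
                                                       log(1e6)))),
      cv = 0.25, seed = seed
    ))
    g <- glance(run_qc(sim$plate))
    expect_equal(g$n_retained + g$n_rejected, g$n_values_in)
  }
})

test_that("a sensitivity drop pushes near-threshold compounds below the LOD", {
  # one compound just above the floor: present at full sensitivity, filtered
  # out when the instrument response drops 40%
  cfg1 <- scenario_config(panel = small_panel(1, 0), conditions = "c1",
                          true_mean = 30000, cv = 0.05, sensitivity = 1,
                          seed = 3)
  cfg2 <- scenario_config(panel = small_panel(1, 0), conditions = "c1",
                          true_mean = 30000, cv = 0.05, sensitivity = 0.6,
                          seed = 3)
  qc1 <- run_qc(simulate_plate(cfg1)$plate)
  qc2 <- run_qc(simulate_plate(cfg2)$plate)
  expect_equal(glance(qc1)$n_compounds_detected, 1)
  expect_equal(glance(qc2)$n_compounds_detected, 0)
})
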
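test_that("ppm deviation follows the signed reference convention", {
  ## worked confirmation-table cases
  expect_equal(round(ppm_deviation(166.0866, 166.08627), 1), 2.0)
  expect_equal(round(ppm_deviation(134.0447, 134.0447), 1), 0.0)
  expect_equal(ppm_deviation(100.0, 100.0005), -5.0)
  expect_error(ppm_deviation(0, 100), "mass_ref")
})

test_that("internal-standard QC passes on noise-free tables and reports omissions", {
  db <- generate_compound_db(10, seed = 1)
  truth <- generate_ground_truth(db, solvents = "s", seed = 2,
                                 n_contaminants = 3)
  inst <- instrument_profile("Z", mass_sigma_ppm = 0, rt_sigma = 0,
                             detection_prob = 1)
  des <- study_design(solvents = "s", instruments = list(Z = inst),
                      n_injections = 3, seed = 3, intensity_sdlog = 0)
  tabs <- simulate_feature_tables(des, db, truth)
  qc <- qc_internal_standards(c(tabs$samples, tabs$blanks))
  expect_true(qc$pass)
  expect_equal(qc$per_standard$delta_ppm, rep(0, 12))
  expect_equal(qc$per_standard$rt_sd, rep(0, 12))
  expect_length(qc$missing, 0)

  ## drop one standard from every table -> listed as missing, not fatal
  drop_name <- internal_standard_set()$name[5]
  tabs2 <- lapply(tabs$samples, function(tb)
    tb[tb$source_id != paste0("standard:", drop_name), ])
  qc2 <- qc_internal_standards(tabs2)
  expect_true(drop_name %in% qc2$missing)
  expect_true(qc2$pass)
})

test_that("QC stays within tolerance at realistic mass noise (Monte-Carlo)", {
  db <- generate_compound_db(5, seed = 1)
  truth <- generate_ground_truth(db, solvents = "s", seed = 2,
                                 n_contaminants = 0)
  inst <- instrument_profile("N", mass_sigma_ppm = 2, rt_sigma = 0.05,
                             detection_prob = 1)
  for (seed in 1:20) {
    des <- study_design(solvents = "s", instruments = list(N = inst),
                        n_injections = 3, seed = seed)
    tabs <- simulate_feature_tables(des, db, truth)
    qc <- qc_internal_standards(c(tabs$samples, tabs$blanks))
    expect_true(qc$pass)
    expect_true(mean(abs(qc$per_standard$delta_ppm)) <= 5)
  }
})

test_that("consensus requires support from every injection", {
  tol <- tolerances()
  base <- data.frame(feature_id = "a", mz = 200.0, rt = 10, intensity = 1000,
                     sample = "S", injection = 1L, instrument = "B",
                     stringsAsFactors = FALSE)
  t1 <- base
  t2 <- transform(base, injection = 2L)
  t3 <- transform(base, injection = 3L, mz = 250)  # different feature
  cf <- consensus_features(list(t1, t2, t3), tol)
  expect_equal(nrow(cf), 0)

  ## identical triplicates reproduce the input coordinates exactly
  t3b <- transform(base, injection = 3L)
  cf2 <- consensus_features(list(t1, t2, t3b), tol)
  expect_equal(nrow(cf2), 1)
  expect_equal(cf2$mz, 200.0)
  expect_equal(cf2$rt, 10)
  expect_equal(cf2$n_injections_found, 3L)
  expect_equal(cf2$intensities[[1]], rep(1000, 3))
})

test_that("consensus discards sub-threshold intensities and validates inputs", {
  tol <- tolerances(noise_threshold = 500)
  t1 <- make_features(200, 10, "HILIC", intensity = 100)
  t1$injection <- 1L
  t2 <- transform(t1, injection = 2L)
  expect_equal(nrow(consensus_features(list(t1, t2), tol)), 0)
  t2$sample <- "other"
  expect_error(consensus_features(list(t1, t2)), "one \\(sample, instrument\\)")
})

test_that("greedy consensus matches the exhaustive grouping oracle on random tables", {
  tol <- tolerances()
  for (seed in 1:200) {
    tabs <- random_injection_tables(seed)
    got <- consensus_features(tabs, tol)
    want <- consensus_oracle(tabs, tol)
    got <- got[order(got$mz), ]
    expect_equal(got$mz, want$mz, tolerance = 1e-12)
    expect_equal(got$rt, want$rt, tolerance = 1e-12)
    expect_equal(got$intensity, want$intensity, tolerance = 1e-12)
    ## construction audit: every consensus feature is supported by one
    ## feature per injection within tolerance of its coordinates
    for (i in seq_len(nrow(got))) {
      for (tb in tabs) {
        d <- abs(ppm_deviation(got$mz[i], tb$mz)) <= 2 * tol$ppm_tol &
          abs(tb$rt - got$rt[i]) <= 2 * tol$rt_tol
        expect_true(any(d))
      }
    }
  }
})

test_that("blank subtraction removes coordinate matches, is idempotent, matches oracle", {
  tol <- tolerances()
  feats <- make_features(c(200, 300, 400), c(10, 20, 30), "x")
  empty_blank <- feats[0, ]
  expect_equal(blank_subtract(feats, empty_blank, tol)$mz, feats$mz)

  blank <- data.frame(feature_id = "b1", mz = 300, rt = 20, intensity = 50,
                      sample = "blank", injection = 1L, instrument = "B")
  out <- blank_subtract(feats, blank, tol)
  expect_equal(out$mz, c(200, 400))
  expect_equal(attr(out, "removed")$mz, 300)
  ## idempotence
  out2 <- blank_subtract(out, blank, tol)
  expect_equal(out2$mz, out$mz)

  for (seed in 1:100) {
    tabs <- random_injection_tables(seed, n_clusters = 15, n_inj = 1)
    f <- tabs[[1]]
    b <- random_injection_tables(seed + 1000, n_clusters = 10, n_inj = 1)[[1]]
    expect_equal(blank_subtract(f, b, tol)$mz,
                 blank_subtract_oracle(f, b, tol)$mz)
  }
})

test_that("ratio-mode blank subtraction spares features above the scaled blank", {
  tol <- tolerances(blank_factor = 1)
  feats <- make_features(200, 10, "x", intensity = 1e5)
  blank <- data.frame(feature_id = "b", mz = 200, rt = 10, intensity = 10,
                      sample = "blank", injection = 1L, instrument = "B")
  expect_equal(nrow(blank_subtract(feats, blank, tol, mode = "coordinate")), 0)
  expect_equal(nrow(blank_subtract(feats, blank, tol, mode = "ratio")), 1)
})

test_that("blank subtraction on the synthetic study removes contaminants only", {
  db <- generate_compound_db(15, seed = 4)
  truth <- generate_ground_truth(db, solvents = "s", seed = 5,
                                 n_contaminants = 8)
  inst <- instrument_profile("Z", mass_sigma_ppm = 0, rt_sigma = 0,
                             detection_prob = 1)
  des <- study_design(solvents = "s", instruments = list(Z = inst),
                      n_injections = 3, seed = 6, intensity_sdlog = 0)
  tabs <- simulate_feature_tables(des, db, truth)
  cf <- consensus_features(tabs$samples, tolerances())
  out <- blank_subtract(cf, tabs$blanks[[1]], tolerances())
  kept_src <- out$source_id
  expect_false(any(grepl("^contaminant:", kept_src)))
  expect_setequal(kept_src[grepl("^compound:", kept_src)],
                  paste0("compound:", db$compound_id))
  removed <- attr(out, "removed")$source_id
  expect_true(all(grepl("^contaminant:|^standard:", removed)))
})

test_that("15-min partition respects window, boundary and completeness", {
  f <- make_features(c(100, 110, 120, 130, 140),
                     c(4.9, 7.6, 15.0, 33.9, 34.2), "x")
  parts <- partition_by_column(f, tolerances())
  expect_equal(parts$hilic$rt, 7.6)           # 4.9 outside the window
  expect_equal(parts$rplc$rt, c(15.0, 33.9))  # boundary goes to RPLC
  expect_true(all(parts$hilic$column == "HILIC"))
  expect_true(all(parts$rplc$column == "RPLC"))
  ## completeness and disjointness over random features
  withr::with_seed(99, {
    g <- make_features(runif(200, 100, 500), runif(200, 0, 40), "x")
  })
  p <- partition_by_column(g, tolerances())
  in_window <- g$rt >= 5 & g$rt <= 34
  expect_equal(sort(c(p$hilic$feature_id, p$rplc$feature_id)),
               sort(g$feature_id[in_window]))
  expect_length(intersect(p$hilic$feature_id, p$rplc$feature_id), 0)
  expect_false(is.unsorted(p$hilic$rt))
  expect_false(is.unsorted(p$rplc$rt))
})

test_that("confirmation-table standards split 16 HILIC / 26 RPLC at 15 min", {
  std <- lemna_confirmation_standards()
  f <- data.frame(feature_id = std$name, rt = std$rt_standard)
  parts <- partition_by_column(f, tolerances())
  expect_equal(nrow(parts$hilic), 16)
  expect_equal(nrow(parts$rplc), 26)
})
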
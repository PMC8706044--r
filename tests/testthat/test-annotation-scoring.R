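test_that("mass screening scores and bounds the ppm window correctly", {
  db <- make_db(mass = c(200, 300, 400), logd = c(-1, 1, 2),
                families = list("Lemnaceae", "Lemnaceae", "Fabaceae"))
  cfg <- scoring_config()
  ## exact adduct mass -> subscore 1
  f <- list(feature_id = "F1", mz = db$adduct_mass[1], rt = 10, column = "HILIC")
  h <- mass_screen(f, db, cfg)
  expect_equal(h$compound_id, "C001")
  expect_equal(h$mass_subscore, 1.0)
  ## at the window edge -> still a candidate, subscore -> 0
  f2 <- list(feature_id = "F2", mz = db$adduct_mass[2] * (1 - 4.9999e-6),
             rt = 20, column = "RPLC")
  h2 <- mass_screen(f2, db, cfg)
  expect_equal(h2$compound_id, "C002")
  expect_equal(h2$mass_subscore, 0, tolerance = 1e-3)
  ## just outside -> no candidate
  f3 <- list(feature_id = "F3", mz = db$adduct_mass[2] * (1 - 5.0001e-6), rt = 20)
  expect_equal(nrow(mass_screen(f3, db, cfg)), 0)
})

test_that("mass screening equals the brute-force oracle on random databases", {
  for (seed in 1:25) {
    db <- generate_compound_db(200, seed = seed)
    withr::with_seed(seed + 500, {
      target <- sample(200, 1)
      mz <- db$adduct_mass[target] * (1 + runif(1, -6e-6, 6e-6))
    })
    h <- mass_screen(list(feature_id = "F", mz = mz, rt = 10), db,
                     scoring_config())
    want <- mass_screen_oracle(mz, db, 5)
    expect_setequal(h$compound_id, want$compound_id)
    expect_equal(h$mass_subscore[order(h$compound_id)],
                 want$mass_subscore[order(want$compound_id)],
                 tolerance = 1e-12)
  }
})

test_that("MS/MS sub-score counts matched fragments with one peak per fragment", {
  cfg <- scoring_config()
  cmp <- list(fragments = c(124, 96, 80, 78))
  exact <- data.frame(mz = c(124, 96, 80, 78), intensity = rep(1000, 4))
  expect_equal(as.numeric(msms_subscore(exact, cmp, cfg)), 1.0)
  disjoint <- data.frame(mz = c(300, 350), intensity = c(1000, 1000))
  expect_equal(as.numeric(msms_subscore(disjoint, cmp, cfg)), 0.0)
  ## peaks below the intensity threshold are ignored
  weak <- data.frame(mz = c(124, 96), intensity = c(10, 1000))
  s <- msms_subscore(weak, cmp, cfg)
  expect_equal(as.numeric(s), 0.25)
  expect_equal(attr(s, "n_matched"), 1L)
  ## one spectrum peak cannot match two fragments
  close_frags <- list(fragments = c(100.00, 100.04))
  one_peak <- data.frame(mz = 100.01, intensity = 1000)
  expect_equal(as.numeric(msms_subscore(one_peak, close_frags, cfg)), 0.5)
  ## compound without fragments -> absent, not zero
  s_na <- msms_subscore(exact, list(fragments = numeric(0)), cfg)
  expect_true(is.na(s_na))
  expect_equal(attr(s_na, "flag"), "no_fragments")
})

test_that("composite weights follow the column regime and flag the unique best hit", {
  cfg <- scoring_config()
  db <- make_db(mass = c(200, 200.0002), logd = c(-1, -1),
                families = list("Lemnaceae", "Lemnaceae"))
  f <- list(feature_id = "F1", mz = db$adduct_mass[1], rt = 8, column = "HILIC")
  h <- mass_screen(f, db, cfg)
  h$msms_subscore <- c(1, 1)
  h <- composite_and_flag(h, cfg, "HILIC")
  expect_equal(h$composite[h$compound_id == "C001"], 100.0)
  expect_equal(sum(h$look_at), 1L)
  expect_equal(h$compound_id[h$look_at], "C001")  # smaller |ppm| wins

  ## RPLC weighting with an absent MS/MS contributes zero
  h2 <- mass_screen(list(feature_id = "F2", mz = db$adduct_mass[1], rt = 20,
                         column = "RPLC"), db[1, ], cfg)
  h2$rti_subscore <- 0.5
  h2 <- composite_and_flag(h2, cfg, "RPLC")
  expect_equal(h2$composite, 100 * (1 / 3 + 0.5 / 3), tolerance = 1e-9)

  ## renormalizing mode drops the absent sub-score instead
  cfg_r <- scoring_config(absent_subscore = "renormalize")
  h3 <- mass_screen(list(feature_id = "F3", mz = db$adduct_mass[1], rt = 20,
                         column = "RPLC"), db[1, ], cfg_r)
  h3$rti_subscore <- 0.5
  h3 <- composite_and_flag(h3, cfg_r, "RPLC")
  expect_equal(h3$composite, 100 * (1 + 0.5) / 2, tolerance = 1e-9)
})

test_that("the flagged hit equals the argmax found by enumeration on random hit sets", {
  cfg <- scoring_config()
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(2:10, 1)
      db <- make_db(mass = 300 + runif(n, -0.001, 0.001),
                    logd = runif(n, -3, 3),
                    families = replicate(n, "Lemnaceae", simplify = FALSE))
      f <- list(feature_id = "F", mz = 300 + PROTON_MASS, rt = 20,
                column = "RPLC")
      h <- mass_screen(f, db, cfg)
      h$rti_subscore <- runif(nrow(h))
      h$msms_subscore <- runif(nrow(h))
    })
    h <- composite_and_flag(h, cfg, "RPLC")
    w <- c(1, 1, 1) / 3
    comp <- 100 * (w[1] * h$mass_subscore + w[2] * h$rti_subscore +
                     w[3] * h$msms_subscore)
    best <- which(comp == max(comp))
    if (length(best) > 1) best <- best[order(abs(h$ppm[best]),
                                             h$compound_id[best])][1]
    expect_equal(which(h$look_at), best)
    expect_equal(h$composite, comp, tolerance = 1e-9)
  }
})

test_that("composite is bounded and monotone in each sub-score", {
  cfg <- scoring_config()
  db <- make_db(300, 1, list("Lemnaceae"))
  base <- mass_screen(list(feature_id = "F", mz = db$adduct_mass, rt = 20,
                           column = "RPLC"), db, cfg)
  grid <- expand.grid(rti = c(0, 0.5, 1), msms = c(0, 0.5, 1))
  comps <- mapply(function(r, m) {
    h <- base; h$rti_subscore <- r; h$msms_subscore <- m
    composite_and_flag(h, cfg, "RPLC")$composite
  }, grid$rti, grid$msms)
  expect_true(all(comps >= 0 & comps <= 100))
  ## monotone in rti at fixed msms and vice versa
  m <- matrix(comps, 3, 3)
  expect_true(all(diff(m[, 1]) > 0) && all(diff(m[1, ]) > 0))
})

test_that("LogD sign filter keeps hydrophilic HILIC and lipophilic RPLC hits", {
  db <- make_db(mass = c(200, 210, 220), logd = c(-2.1, 0.5, 0),
                families = replicate(3, "Lemnaceae", simplify = FALSE))
  cfg <- scoring_config()
  mk <- function(i, col) {
    h <- mass_screen(list(feature_id = paste0("F", i), mz = db$adduct_mass[i],
                          rt = 10, column = col), db[i, ], cfg)
    h
  }
  h <- rbind(mk(1, "HILIC"), mk(2, "HILIC"), mk(3, "HILIC"))
  h <- logd_sign_filter(h)
  expect_true(is.na(h$eliminated_by[1]))            # logd -2.1 retained
  expect_equal(h$eliminated_by[2], "logd_filter")   # logd +0.5 eliminated
  expect_true(is.na(h$eliminated_by[3]))            # boundary logd 0 retained
  ## RPLC: the complement
  h2 <- rbind(mk(1, "RPLC"), mk(2, "RPLC"), mk(3, "RPLC"))
  h2 <- logd_sign_filter(h2)
  expect_equal(h2$eliminated_by[1], "logd_filter")
  expect_true(is.na(h2$eliminated_by[2]))
  expect_equal(h2$eliminated_by[3], "logd_filter")  # logd 0 fails RPLC
})

test_that("chemotaxonomy filter retains allowed families and commutes with the LogD filter", {
  db <- make_db(mass = c(200, 210), logd = c(-1, -1),
                families = list("Lemnaceae", "Fabaceae"))
  cfg <- scoring_config()
  h <- do.call(rbind, lapply(1:2, function(i)
    mass_screen(list(feature_id = paste0("F", i), mz = db$adduct_mass[i],
                     rt = 10, column = "HILIC"), db[i, ], cfg)))
  hc <- chemotaxonomy_filter(h, "Lemnaceae")
  expect_true(is.na(hc$eliminated_by[1]))
  expect_equal(hc$eliminated_by[2], "chemotaxonomy")
  ## allowing every family is the identity
  h_all <- chemotaxonomy_filter(h, c("Lemnaceae", "Fabaceae"))
  expect_true(all(is.na(h_all$eliminated_by)))

  ## commutation: survivor set identical in either filter order
  withr::with_seed(7, {
    n <- 40
    dbr <- make_db(mass = 200 + seq_len(n) * 10, logd = runif(n, -3, 3),
                   families = lapply(runif(n) < 0.5, function(x)
                     if (x) "Lemnaceae" else "Fabaceae"))
    cols <- sample(c("HILIC", "RPLC"), n, replace = TRUE)
  })
  hr <- do.call(rbind, lapply(seq_len(n), function(i)
    mass_screen(list(feature_id = paste0("F", i), mz = dbr$adduct_mass[i],
                     rt = 10, column = cols[i]),
                dbr[i, ], cfg)))
  a <- chemotaxonomy_filter(logd_sign_filter(hr), "Lemnaceae")
  b <- logd_sign_filter(chemotaxonomy_filter(hr, "Lemnaceae"))
  expect_equal(is.na(a$eliminated_by), is.na(b$eliminated_by))
})

test_that("successive elimination recovers the noise-free truth with monotone stage counts", {
  cfg <- scoring_config()
  db <- generate_compound_db(20, family_pool = "Lemnaceae", seed = 40)
  truth <- generate_ground_truth(db, solvents = "s", seed = 41,
                                 n_contaminants = 0)
  inst <- instrument_profile("Z", mass_sigma_ppm = 0, rt_sigma = 0,
                             detection_prob = 1, has_msms = TRUE)
  des <- study_design(solvents = "s", instruments = list(Z = inst),
                      n_injections = 3, seed = 42, intensity_sdlog = 0)
  tabs <- simulate_feature_tables(des, db, truth)
  cf <- consensus_features(tabs$samples, tolerances())
  cf <- blank_subtract(cf, tabs$blanks[[1]], tolerances())
  parts <- partition_by_column(cf, tolerances())
  feats <- rbind(parts$hilic, parts$rplc)

  rplc <- db$logd_ph7 >= 0
  cal <- fit_calibration(data.frame(rt = truth$compounds$true_rt[rplc],
                                    logd_ph7 = db$logd_ph7[rplc]))
  spectra <- list()
  cmp_of <- sub("^compound:", "", feats$source_id)
  for (i in seq_len(nrow(feats)))
    spectra[[feats$feature_id[i]]] <-
      simulate_msms(db[db$compound_id == cmp_of[i], ], noise_peaks = 5,
                    seed = 50 + i)

  res <- successive_elimination(feats, db, cfg, calibration = cal,
                                spectra = spectra,
                                allowed_families = "Lemnaceae")
  ## every ground-truth compound survives
  expect_setequal(res$survivors$compound_id, db$compound_id)
  ## noise-free: perfect sub-scores for the generating compound
  own <- res$hits[res$hits$compound_id == cmp_of[match(res$hits$feature_id,
                                                       feats$feature_id)], ]
  expect_true(all(own$mass_subscore == 1))
  expect_true(all(own$msms_subscore == 1))
  ## stage counts monotone non-increasing per column
  for (col in unique(res$audit$column)) {
    n <- res$audit$n_hits[res$audit$column == col]
    expect_true(all(diff(n) <= 0))
  }
  ## audit equals an independent recount from the tagged hit list
  la <- res$hits[res$hits$look_at, ]
  recount <- c(nrow(res$hits), nrow(la),
               sum(is.na(la$eliminated_by) |
                     la$eliminated_by == "chemotaxonomy"),
               sum(is.na(la$eliminated_by)))
  by_col <- stats::aggregate(n_hits ~ stage, data = res$audit, sum)
  expect_equal(by_col$n_hits[match(c("candidates", "look_at", "logd_filter",
                                     "chemotaxonomy"), by_col$stage)],
               recount)
})

test_that("family decoys are eliminated exactly at the chemotaxonomy stage", {
  res <- run_study(study_config(seed = 3, n_compounds = 20, n_decoys = 40))
  hits <- res$screening$hits
  decoy <- hits[grepl("^D", hits$compound_id), ]
  expect_gt(nrow(decoy), 0)
  expect_true(all(decoy$eliminated_by == "chemotaxonomy"))
  expect_false(any(grepl("^D", res$screening$survivors$compound_id)))
  ## survivor precision is 100% after chemotaxonomy
  expect_true(all(grepl("^C", res$screening$survivors$compound_id)))
})

test_that("look-at recovery on the default study exceeds 90% of truth compounds", {
  res <- run_study(study_config(seed = 1))
  expect_gte(res$manifest$recovery_rate, 0.9)
})

test_that("missing calibration degrades RPLC scoring with a warning", {
  db <- make_db(300, 1, list("Lemnaceae"))
  f <- make_features(db$adduct_mass, 20, "RPLC")
  expect_warning(res <- successive_elimination(f, db, scoring_config()),
                 "degrades")
  expect_true(is.na(res$hits$rti_subscore[1]))
  ## degraded weighting: mass-only hit scores 50 (mass 1/2, MS/MS absent)
  expect_equal(res$hits$composite[1], 50)
})
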
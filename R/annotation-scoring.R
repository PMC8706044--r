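#' Scoring configuration for hidden-target screening
#'
#' HILIC-regime candidates are scored from mass screening and MS/MS, each
#' weighted 50%; RPLC-regime candidates from mass screening, RTI screening
#' and MS/MS, each weighted one third. A sub-score that is unavailable at
#' nonzero weight (e.g. no MS/MS on a single-TOF instrument) contributes 0
#' under `absent_subscore = "zero"` (the conservative default) or is
#' dropped with the remaining weights renormalized under `"renormalize"`.
#'
#' @param ppm_window mass-screening window, ppm.
#' @param msms_mz_tol fragment matching tolerance, Da (50 mDa default).
#' @param msms_intensity_threshold minimum MS/MS peak intensity, counts.
#' @param rti_scale LogD difference at which the RTI sub-score reaches 0.
#' @param absent_subscore `"zero"` or `"renormalize"`.
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(ppm_window = 5, msms_mz_tol = 0.05,
                           msms_intensity_threshold = 50, rti_scale = 2,
                           absent_subscore = c("zero", "renormalize")) {
  check(ppm_window > 0 && msms_mz_tol > 0 && rti_scale > 0,
        "windows and scales must be positive")
  structure(list(ppm_window = ppm_window, msms_mz_tol = msms_mz_tol,
                 msms_intensity_threshold = msms_intensity_threshold,
                 rti_scale = rti_scale,
                 absent_subscore = match.arg(absent_subscore)),
            class = "scoring_config")
}

#' Sub-score weights per column regime
#'
#' @param column `"HILIC"` (mass 1/2, MS/MS 1/2) or `"RPLC"` (mass 1/3,
#'   RTI 1/3, MS/MS 1/3).
#' @param has_calibration if `FALSE`, the RPLC RTI term is unavailable and
#'   scoring degrades to the HILIC weighting (mass + MS/MS at 1/2 each).
#' @return named numeric weights summing to 1.
#' @export
mode_weights <- function(column, has_calibration = TRUE) {
  if (column == "HILIC" || !has_calibration)
    c(mass = 0.5, rti = 0, msms = 0.5)
  else
    c(mass = 1 / 3, rti = 1 / 3, msms = 1 / 3)
}

#' Mass screening of one feature against the compound database
#'
#' Candidates are database compounds whose \[M+H\]+ adduct mass lies within
#' `ppm_window` of the feature m/z; the mass sub-score falls linearly from
#' 1 at 0 ppm to 0 at the window edge (the edge itself is still a
#' candidate).
#'
#' @param feature one-row data.frame (or list) with `feature_id`, `mz`,
#'   `rt`, and optionally `column`.
#' @param db compound database.
#' @param cfg [scoring_config()].
#' @return data.frame of candidate hits, one row per matching compound,
#'   with `ppm`, `mass_subscore`, compound annotation columns and empty
#'   sub-score/flag slots to be filled by later stages.
#' @export
mass_screen <- function(feature, db, cfg = scoring_config()) {
  check(nrow(db) >= 1, "db must be non-empty")
  ppm <- ppm_deviation(db$adduct_mass, feature$mz)
  idx <- which(abs(ppm) <= cfg$ppm_window)
  hits <- data.frame(
    feature_id = rep(feature$feature_id, length(idx)),
    mz = rep(feature$mz, length(idx)),
    rt = rep(feature$rt, length(idx)),
    column = rep(if (!is.null(feature$column)) feature$column else NA_character_,
                 length(idx)),
    compound_id = db$compound_id[idx],
    name = db$name[idx],
    logd_ph7 = db$logd_ph7[idx],
    ppm = ppm[idx],
    mass_subscore = 1 - abs(ppm[idx]) / cfg$ppm_window,
    rti_subscore = rep(NA_real_, length(idx)),
    msms_subscore = rep(NA_real_, length(idx)),
    n_frag_matched = rep(NA_integer_, length(idx)),
    n_frag_total = vapply(db$fragments[idx], length, 1L),
    composite = rep(NA_real_, length(idx)),
    look_at = rep(FALSE, length(idx)),
    eliminated_by = rep(NA_character_, length(idx)),
    stringsAsFactors = FALSE
  )
  hits$families <- I(db$families[idx])
  hits$fragments <- I(db$fragments[idx])
  rownames(hits) <- NULL
  hits
}

#' MS/MS fragment-match sub-score
#'
#' Spectrum peaks below the intensity threshold are discarded; each
#' surviving peak may match at most one database fragment, assigned by
#' closest m/z within `msms_mz_tol`. The score is the fraction of the
#' compound's characteristic fragments matched. A compound without
#' fragments yields `NA` (sub-score absent, flagged), not 0.
#'
#' @param spectrum data.frame with `mz`, `intensity` (or `NULL`).
#' @param compound one-row database slice or list with `fragments`.
#' @param cfg [scoring_config()].
#' @return score in \[0, 1\] with attributes `n_matched`, `n_total`;
#'   `NA` when the compound has no fragments or `spectrum` is `NULL`.
#' @export
msms_subscore <- function(spectrum, compound, cfg = scoring_config()) {
  frags <- if (is.data.frame(compound)) compound$fragments[[1]] else compound$fragments
  if (length(frags) == 0)
    return(structure(NA_real_, n_matched = NA_integer_, n_total = 0L,
                     flag = "no_fragments"))
  if (is.null(spectrum))
    return(structure(NA_real_, n_matched = NA_integer_,
                     n_total = length(frags), flag = "no_spectrum"))
  peaks <- spectrum[spectrum$intensity >= cfg$msms_intensity_threshold, ,
                    drop = FALSE]
  if (nrow(peaks) == 0)
    return(structure(0, n_matched = 0L, n_total = length(frags)))
  ## all (peak, fragment) pairs within tolerance, matched greedily by
  ## ascending m/z distance; each peak and each fragment used at most once
  d <- abs(outer(peaks$mz, frags, "-"))
  pairs <- which(d <= cfg$msms_mz_tol, arr.ind = TRUE)
  n_matched <- 0L
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    used_peak <- rep(FALSE, nrow(peaks))
    used_frag <- rep(FALSE, length(frags))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_peak[i] && !used_frag[j]) {
        used_peak[i] <- TRUE
        used_frag[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  structure(n_matched / length(frags), n_matched = n_matched,
            n_total = length(frags))
}

#' Composite score and "look at" flag for one feature's candidate hits
#'
#' The composite is `100 * sum(weight_i * subscore_i)` over the regime's
#' weights; an absent sub-score at nonzero weight contributes 0 (or the
#' weights renormalize, per the configuration). Exactly one hit per
#' feature — the maximal composite, ties broken by smaller |ppm| then
#' lexicographic compound id — receives `look_at = TRUE`.
#'
#' @param hits candidate hits for a single feature ([mass_screen()] rows
#'   with `rti_subscore`/`msms_subscore` filled where available).
#' @param cfg [scoring_config()].
#' @param column `"HILIC"` or `"RPLC"`.
#' @param has_calibration whether an RTI calibration is available (RPLC).
#' @return `hits` with `composite` (percent) and `look_at` filled.
#' @export
composite_and_flag <- function(hits, cfg = scoring_config(), column,
                               has_calibration = TRUE) {
  if (nrow(hits) == 0) return(hits)
  check(length(unique(hits$feature_id)) == 1,
        "composite_and_flag expects hits of a single feature")
  w <- mode_weights(column, has_calibration)
  sub <- cbind(mass = hits$mass_subscore, rti = hits$rti_subscore,
               msms = hits$msms_subscore)
  if (cfg$absent_subscore == "renormalize") {
    comp <- vapply(seq_len(nrow(sub)), function(i) {
      avail <- !is.na(sub[i, ]) & w > 0
      if (!any(avail)) return(0)
      sum(w[avail] * sub[i, avail]) / sum(w[avail])
    }, 1)
  } else {
    sub[is.na(sub)] <- 0
    comp <- as.numeric(sub %*% w)
  }
  hits$composite <- 100 * comp
  hits$look_at <- FALSE
  best <- order(-hits$composite, abs(hits$ppm), hits$compound_id)[1]
  hits$look_at[best] <- TRUE
  hits
}

#' LogD sign filter
#'
#' HILIC-regime candidates must be hydrophilic: hits with database
#' LogD(pH 7) > 0 are eliminated (LogD = 0 is retained). RPLC-regime
#' candidates must be lipophilic: hits with LogD <= 0 are eliminated.
#' Elimination is recorded as a tag (`eliminated_by = "logd_filter"`), not
#' a deletion, so per-stage audits can recount.
#'
#' @param hits candidate hits with a `column` column (or supply `column`).
#' @param column optional regime overriding `hits$column`.
#' @return `hits` with `eliminated_by` set on failing rows.
#' @export
logd_sign_filter <- function(hits, column = NULL) {
  if (nrow(hits) == 0) return(hits)
  col <- if (!is.null(column)) rep(column, nrow(hits)) else hits$column
  bad <- ifelse(col == "HILIC", hits$logd_ph7 > 0, hits$logd_ph7 <= 0)
  hits$eliminated_by[bad & is.na(hits$eliminated_by)] <- "logd_filter"
  hits
}

#' Chemotaxonomy filter
#'
#' A hit is retained iff its compound's family set intersects the allowed
#' families (default Lemnaceae); other hits are tagged
#' `eliminated_by = "chemotaxonomy"`.
#'
#' @param hits candidate hits carrying a `families` list column.
#' @param allowed_families non-empty character vector.
#' @return `hits` with `eliminated_by` set on failing rows.
#' @export
chemotaxonomy_filter <- function(hits, allowed_families = "Lemnaceae") {
  check(length(allowed_families) >= 1, "allowed_families must be non-empty")
  if (nrow(hits) == 0) return(hits)
  ok <- vapply(hits$families, function(f)
    length(intersect(f, allowed_families)) > 0, TRUE)
  hits$eliminated_by[!ok & is.na(hits$eliminated_by)] <- "chemotaxonomy"
  hits
}

#' Successive-elimination screening of a consensus feature set
#'
#' The hidden-target pipeline per column regime: mass screening against the
#' database, RTI sub-scoring (RPLC only, when a calibration is supplied),
#' MS/MS sub-scoring (where spectra are available), composite scoring with
#' one "look at" hit per feature, then the LogD-sign and chemotaxonomy
#' filters applied as tags. Survivors are the look-at hits passing both
#' filters; all hits are returned for audit, along with per-stage counts.
#'
#' @param features consensus features with a `column` assignment (e.g. the
#'   concatenated output of [partition_by_column()]).
#' @param db compound database.
#' @param cfg [scoring_config()].
#' @param calibration optional [fit_calibration()] model; if `NULL`, RPLC
#'   scoring degrades to mass + MS/MS with a warning.
#' @param spectra optional named list of MS/MS spectra keyed by
#'   `feature_id`.
#' @param allowed_families chemotaxonomy filter families.
#' @return list of class `screening_result`: `hits` (all candidate hits
#'   with tags), `survivors`, `audit` (per column and stage counts).
#' @export
successive_elimination <- function(features, db, cfg = scoring_config(),
                                   calibration = NULL, spectra = NULL,
                                   allowed_families = "Lemnaceae") {
  check(nrow(db) >= 1, "db must be non-empty")
  has_cal <- !is.null(calibration)
  if (!has_cal && any(features$column == "RPLC"))
    warning("no RTI calibration: RPLC scoring degrades to mass + MS/MS")

  all_hits <- list()
  for (i in seq_len(nrow(features))) {
    feat <- features[i, , drop = FALSE]
    hits <- mass_screen(feat, db, cfg)
    if (nrow(hits) == 0) next
    if (feat$column == "RPLC" && has_cal) {
      pred <- predict_logd(calibration, feat$rt)
      hits$rti_subscore <- rti_subscore(pred, hits$logd_ph7, cfg$rti_scale)
    }
    spec <- if (!is.null(spectra)) spectra[[feat$feature_id]] else NULL
    if (!is.null(spec)) {
      for (k in seq_len(nrow(hits))) {
        s <- msms_subscore(spec, list(fragments = hits$fragments[[k]]), cfg)
        hits$msms_subscore[k] <- as.numeric(s)
        hits$n_frag_matched[k] <- attr(s, "n_matched")
      }
    }
    hits <- composite_and_flag(hits, cfg, feat$column, has_cal)
    all_hits[[length(all_hits) + 1]] <- hits
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    mass_screen(list(feature_id = "none", mz = -1, rt = 0), db, cfg)[0, ]
  rownames(hits) <- NULL

  hits <- logd_sign_filter(hits)
  hits <- chemotaxonomy_filter(hits, allowed_families)

  audit <- do.call(rbind, lapply(c("HILIC", "RPLC"), function(col) {
    h <- hits[hits$column == col, , drop = FALSE]
    la <- h[h$look_at, , drop = FALSE]
    data.frame(
      column = col,
      stage = c("candidates", "look_at", "logd_filter", "chemotaxonomy"),
      n_hits = c(nrow(h),
                 nrow(la),
                 sum(is.na(la$eliminated_by) |
                       la$eliminated_by == "chemotaxonomy"),
                 sum(is.na(la$eliminated_by))),
      stringsAsFactors = FALSE
    )
  }))
  survivors <- hits[hits$look_at & is.na(hits$eliminated_by), , drop = FALSE]
  structure(list(hits = hits, survivors = survivors, audit = audit),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Successive-elimination screening\n")
  print(x$audit, row.names = FALSE)
  cat(sprintf("%d surviving candidate hit(s)\n", nrow(x$survivors)))
  invisible(x)
}

#' Export a hit list as delimited text
#'
#' Columns: feature_id, compound_id, sub-scores, composite, look_at,
#' eliminated_by.
#'
#' @param hits hit data.frame (e.g. `screening_result$hits`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hit_list <- function(hits, path) {
  out <- hits[, c("feature_id", "compound_id", "name", "column", "ppm",
                  "mass_subscore", "rti_subscore", "msms_subscore",
                  "composite", "look_at", "eliminated_by")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
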
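#' Signed relative mass deviation in ppm
#'
#' `(mass_ref - mass_obs) / mass_ref * 1e6`: positive when the observed
#' mass reads low relative to the reference.
#'
#' @param mass_ref reference mass, Da (> 0).
#' @param mass_obs observed mass, Da.
#' @return signed deviation in ppm.
#' @export
ppm_deviation <- function(mass_ref, mass_obs) {
  check(all(mass_ref > 0), "mass_ref must be > 0")
  (mass_ref - mass_obs) / mass_ref * 1e6
}

#' Matching and filtering tolerances
#'
#' Defaults follow QTOF practice on the polarity-extended coupling: 5 ppm
#' mass tolerance, 0.3 min retention tolerance, a 5-34 min retention
#' window, a noise threshold of 50 counts, and a blank subtraction factor
#' of 1. The `"wide"` preset mirrors the looser single-TOF vendor settings
#' (10 ppm, 3 min, 1000-count peak filter).
#'
#' @param ppm_tol mass tolerance, ppm.
#' @param rt_tol retention-time tolerance, minutes.
#' @param rt_window retention window (min, max) in minutes.
#' @param noise_threshold minimum feature intensity, counts.
#' @param blank_factor blank subtraction multiplication factor.
#' @param preset `"default"` or `"wide"`.
#' @return list of class `tolerances`.
#' @export
tolerances <- function(ppm_tol = 5, rt_tol = 0.3, rt_window = c(5, 34),
                       noise_threshold = 50, blank_factor = 1,
                       preset = c("default", "wide")) {
  preset <- match.arg(preset)
  if (preset == "wide") {
    ppm_tol <- 10; rt_tol <- 3; noise_threshold <- 1000
  }
  check(ppm_tol > 0 && rt_tol > 0 && noise_threshold > 0 && blank_factor > 0,
        "all tolerances must be positive")
  check(rt_window[2] > rt_window[1], "rt_window must be increasing")
  structure(list(ppm_tol = ppm_tol, rt_tol = rt_tol, rt_window = rt_window,
                 noise_threshold = noise_threshold,
                 blank_factor = blank_factor),
            class = "tolerances")
}

#' Quality control against the spiked internal standards
#'
#' For every internal standard and every table, the nearest feature within
#' ten times the working tolerances is taken as the standard's observation.
#' Reported per standard: the mean observed m/z, its signed ppm deviation
#' from the expected mass, and the retention-time standard deviation across
#' all runs. A standard found in at most half of the tables is flagged
#' missing (not fatal). The overall pass flag is true iff every
#' sufficiently-observed standard has |dppm| <= `ppm_tol` and RT SD <=
#' `rt_tol`.
#'
#' @param tables list of feature tables (samples and blanks).
#' @param standards [internal_standard_set()]-style data.frame.
#' @param tol [tolerances()].
#' @return list of class `qc_report`: `per_standard` data.frame, `pass`,
#'   `missing` (names found in <= 50% of tables).
#' @export
qc_internal_standards <- function(tables, standards = internal_standard_set(),
                                  tol = tolerances()) {
  check(length(tables) >= 1, "at least one table required")
  obs <- lapply(seq_len(nrow(standards)), function(i) {
    mz0 <- standards$expected_mz[i]
    rt0 <- standards$expected_rt[i]
    hits <- lapply(tables, function(tb) {
      dppm <- abs(ppm_deviation(mz0, tb$mz))
      drt <- abs(tb$rt - rt0)
      cand <- which(dppm <= 10 * tol$ppm_tol & drt <= 10 * tol$rt_tol)
      if (length(cand) == 0) return(NULL)
      best <- cand[which.min(dppm[cand])]
      c(mz = tb$mz[best], rt = tb$rt[best])
    })
    hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
    n_found <- if (is.null(hits)) 0L else nrow(hits)
    data.frame(
      name = standards$name[i],
      n_found = n_found,
      n_tables = length(tables),
      mean_mz = if (n_found > 0) mean(hits[, "mz"]) else NA_real_,
      delta_ppm = if (n_found > 0)
        ppm_deviation(mz0, mean(hits[, "mz"])) else NA_real_,
      rt_sd = if (n_found > 1) stats::sd(hits[, "rt"])
              else if (n_found == 1) 0 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  per_standard <- do.call(rbind, obs)
  per_standard$missing <- per_standard$n_found <= 0.5 * per_standard$n_tables
  found <- per_standard[!per_standard$missing, , drop = FALSE]
  pass <- nrow(found) > 0 &&
    all(abs(found$delta_ppm) <= tol$ppm_tol) &&
    all(found$rt_sd <= tol$rt_tol)
  structure(list(per_standard = per_standard, pass = pass,
                 missing = per_standard$name[per_standard$missing]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Internal-standard QC: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  df <- x$per_standard
  df$delta_ppm <- round(df$delta_ppm, 2)
  df$rt_sd <- round(df$rt_sd, 3)
  print(df, row.names = FALSE)
  if (length(x$missing))
    cat("Missing standards:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Triplicate consensus alignment
#'
#' Aligns the injections of one (sample, instrument) pair. Features below
#' the noise threshold are discarded; the remainder are grouped greedily,
#' seeding each group with the most intense unused feature (ties broken by
#' ascending m/z). A group is accepted iff every injection contributes a
#' feature within `ppm_tol` and `rt_tol` of the seed (the closest in m/z
#' per injection); consensus m/z and RT are unweighted means over the
#' members. A seed without full replicate support is consumed without
#' producing output.
#'
#' @param injection_tables list of >= 2 feature tables from the same
#'   (sample, instrument), one per injection.
#' @param tol [tolerances()].
#' @return data.frame of consensus features: `feature_id`, `mz`, `rt`,
#'   `intensity` (mean), `intensities` (list column, by injection),
#'   `n_injections_found`, `sample`, `instrument`, `source_id` (seed
#'   provenance if present in the inputs).
#' @export
consensus_features <- function(injection_tables, tol = tolerances()) {
  check(length(injection_tables) >= 2, "need >= 2 injection tables")
  samp <- unique(unlist(lapply(injection_tables, function(t) unique(t$sample))))
  inst <- unique(unlist(lapply(injection_tables, function(t) unique(t$instrument))))
  check(length(samp) == 1 && length(inst) == 1,
        "all tables must come from one (sample, instrument)")
  n_inj <- length(injection_tables)

  all_f <- do.call(rbind, lapply(seq_along(injection_tables), function(j) {
    tb <- injection_tables[[j]]
    tb$.inj <- rep(j, nrow(tb))
    tb[, intersect(c("feature_id", "mz", "rt", "intensity", "source_id", ".inj"),
                   names(tb)), drop = FALSE]
  }))
  all_f <- all_f[all_f$intensity >= tol$noise_threshold, , drop = FALSE]
  has_src <- !is.null(all_f$source_id)

  ord <- order(-all_f$intensity, all_f$mz)
  all_f <- all_f[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(all_f))
  out <- list()
  for (s in seq_len(nrow(all_f))) {
    if (used[s]) next
    seed_mz <- all_f$mz[s]
    seed_rt <- all_f$rt[s]
    in_tol <- !used &
      abs(ppm_deviation(seed_mz, all_f$mz)) <= tol$ppm_tol &
      abs(all_f$rt - seed_rt) <= tol$rt_tol
    members <- integer(n_inj)
    ok <- TRUE
    for (j in seq_len(n_inj)) {
      if (j == all_f$.inj[s]) { members[j] <- s; next }
      cand <- which(in_tol & all_f$.inj == j)
      if (length(cand) == 0) { ok <- FALSE; break }
      d_mz <- abs(all_f$mz[cand] - seed_mz)
      d_rt <- abs(all_f$rt[cand] - seed_rt)
      members[j] <- cand[order(d_mz, d_rt)[1]]
    }
    used[s] <- TRUE
    if (!ok) next
    used[members] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      mz = mean(all_f$mz[members]),
      rt = mean(all_f$rt[members]),
      intensity = mean(all_f$intensity[members]),
      n_injections_found = n_inj,
      sample = samp, instrument = inst,
      source_id = if (has_src) all_f$source_id[s] else NA_character_,
      stringsAsFactors = FALSE
    )
    attr(out[[length(out)]], "intens") <- all_f$intensity[members]
  }
  if (length(out) == 0) {
    res <- data.frame(feature_id = character(), mz = numeric(), rt = numeric(),
                      intensity = numeric(), n_injections_found = integer(),
                      sample = character(), instrument = character(),
                      source_id = character(), stringsAsFactors = FALSE)
    res$intensities <- I(list())
    return(res)
  }
  intens <- lapply(out, attr, "intens")
  res <- do.call(rbind, out)
  res$intensities <- I(intens)
  res <- res[order(-res$intensity), , drop = FALSE]
  res$feature_id <- sprintf("CF_%s_%s_%04d", gsub("[^A-Za-z0-9]", "", samp),
                            inst, seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("feature_id", "mz", "rt", "intensity", "intensities",
          "n_injections_found", "sample", "instrument", "source_id")]
}

#' Blank subtraction
#'
#' Removes a consensus feature when a blank feature from the matching
#' solvent lies within `ppm_tol` and `rt_tol`. In `"coordinate"` mode
#' (`blank_factor = 1` semantics) the coordinate match alone removes the
#' feature; in `"ratio"` mode removal additionally requires
#' `blank intensity * blank_factor >= feature intensity`.
#'
#' @param features consensus feature data.frame.
#' @param blank blank feature table.
#' @param tol [tolerances()].
#' @param mode `"coordinate"` or `"ratio"`.
#' @return surviving features; removed rows are attached as attribute
#'   `"removed"` for audit.
#' @export
blank_subtract <- function(features, blank, tol = tolerances(),
                           mode = c("coordinate", "ratio")) {
  mode <- match.arg(mode)
  if (nrow(features) == 0 || nrow(blank) == 0) {
    attr(features, "removed") <- features[0, , drop = FALSE]
    return(features)
  }
  drop <- vapply(seq_len(nrow(features)), function(i) {
    dppm <- abs(ppm_deviation(features$mz[i], blank$mz))
    drt <- abs(blank$rt - features$rt[i])
    hit <- dppm <= tol$ppm_tol & drt <= tol$rt_tol
    if (mode == "ratio")
      hit <- hit & (blank$intensity * tol$blank_factor >= features$intensity[i])
    any(hit)
  }, TRUE)
  out <- features[!drop, , drop = FALSE]
  attr(out, "removed") <- features[drop, , drop = FALSE]
  out
}

#' Partition features at the 15-min HILIC/RPLC boundary
#'
#' The retention window (default 5-34 min, inclusive) is applied first;
#' features with RT < 15 min are assigned to the HILIC regime, RT >= 15 min
#' to the RPLC regime (the boundary itself goes to RPLC by convention).
#' Both lists are RT-sorted.
#'
#' @param features data.frame with an `rt` column.
#' @param tol [tolerances()] supplying the retention window.
#' @param boundary partition boundary in minutes.
#' @return list with `hilic` and `rplc` data.frames, each with a `column`
#'   label added.
#' @export
partition_by_column <- function(features, tol = tolerances(), boundary = 15) {
  keep <- features$rt >= tol$rt_window[1] & features$rt <= tol$rt_window[2]
  f <- features[keep, , drop = FALSE]
  hilic <- f[f$rt < boundary, , drop = FALSE]
  rplc <- f[f$rt >= boundary, , drop = FALSE]
  hilic <- hilic[order(hilic$rt), , drop = FALSE]
  rplc <- rplc[order(rplc$rt), , drop = FALSE]
  if (nrow(hilic)) hilic$column <- "HILIC"
  else hilic$column <- character(0)
  if (nrow(rplc)) rplc$column <- "RPLC"
  else rplc$column <- character(0)
  rownames(hilic) <- rownames(rplc) <- NULL
  list(hilic = hilic, rplc = rplc)
}
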
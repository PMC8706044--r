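#' Configuration of a synthetic screening study
#'
#' Bundles every tunable of the end-to-end workflow. The defaults define
#' the reference study used throughout the package's tests: 50 ground-truth
#' Lemnaceae compounds plus 100 decoy database entries that share a truth
#' compound's mass and LogD but belong to foreign families, three
#' extraction solvents, two instruments (TOF without MS/MS, QTOF with), and
#' triplicate injections.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_compounds ground-truth compounds.
#' @param n_decoys decoy database entries (family decoys).
#' @param truth_families families of the ground-truth compounds.
#' @param decoy_families families assigned to decoys (must not intersect
#'   `allowed_families`).
#' @param allowed_families chemotaxonomy filter.
#' @param solvents extraction solvents.
#' @param instruments list of [instrument_profile()]s.
#' @param n_injections injections per extract.
#' @param n_contaminants blank contaminant features.
#' @param tol [tolerances()].
#' @param scoring [scoring_config()].
#' @param id_rt_tol,id_ppm_tol,min_frag_overlap level-1 confirmation
#'   thresholds.
#' @param opls list: `n_predictive`, `n_orthogonal`, `scaling`,
#'   `log_transform`, `folds`, `pcorr_max`.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         n_compounds = 50L,
                         n_decoys = 100L,
                         truth_families = "Lemnaceae",
                         decoy_families = c("Fabaceae", "Asteraceae"),
                         allowed_families = "Lemnaceae",
                         solvents = c("100% MeOH", "50% MeOH", "100% H2O"),
                         instruments = default_instruments(),
                         n_injections = 3L,
                         n_contaminants = 25L,
                         tol = tolerances(),
                         scoring = scoring_config(),
                         id_rt_tol = 0.5, id_ppm_tol = 5,
                         min_frag_overlap = 1L,
                         opls = list(n_predictive = 1, n_orthogonal = 1,
                                     scaling = "uv", log_transform = TRUE,
                                     folds = 7, pcorr_max = 0.1)) {
  check(length(intersect(decoy_families, allowed_families)) == 0,
        "decoy families must not intersect the allowed families")
  structure(as.list(environment()), class = "study_config")
}

#' Simulate a complete synthetic study
#'
#' Generates the ground-truth compound database, the decoy-augmented
#' screening database, ground-truth abundances and contaminants, all
#' per-injection feature tables and blanks, per-compound MS/MS spectra for
#' the MS/MS-capable instruments, the RPLC calibration-standard mixture
#' (true retention times of the lipophilic truth compounds) and the
#' reference-standard list used for level-1 confirmation.
#'
#' Decoys cycle through the truth compounds, inheriting mass and
#' LogD exactly but with their own fragment lists and families outside the
#' chemotaxonomy filter, so they survive mass screening and the LogD-sign
#' filter and must be removed by chemotaxonomy alone.
#'
#' @param config a [study_config()].
#' @return list of class `synthetic_study`.
#' @export
simulate_study <- function(config = study_config()) {
  check(inherits(config, "study_config"), "config must be a study_config")
  seed <- as.integer(config$seed)

  db_truth <- generate_compound_db(config$n_compounds,
                                   family_pool = config$truth_families,
                                   seed = seed)
  decoys <- if (config$n_decoys > 0) {
    withr::with_seed(seed + 11L, {
      tmpl <- ((seq_len(config$n_decoys) - 1) %% nrow(db_truth)) + 1
      n_frag <- sample(2:8, config$n_decoys, replace = TRUE)
      d <- data.frame(
        compound_id = sprintf("D%04d", seq_len(config$n_decoys)),
        name = sprintf("decoy_%04d", seq_len(config$n_decoys)),
        monoisotopic_mass = db_truth$monoisotopic_mass[tmpl],
        adduct_mass = db_truth$adduct_mass[tmpl],
        logd_ph7 = db_truth$logd_ph7[tmpl],
        literature_tag = "synthetic-decoy",
        stringsAsFactors = FALSE
      )
      d$families <- I(lapply(seq_len(config$n_decoys), function(i)
        sample(config$decoy_families, 1)))
      d$fragments <- I(lapply(seq_len(config$n_decoys), function(i)
        sort(stats::runif(n_frag[i], 50, d$adduct_mass[i] - 1),
             decreasing = TRUE)))
      d
    })
  } else db_truth[0, ]

  truth <- generate_ground_truth(db_truth, solvents = config$solvents,
                                 seed = seed + 1L,
                                 n_contaminants = config$n_contaminants)
  design <- study_design(solvents = config$solvents,
                         instruments = config$instruments,
                         n_injections = config$n_injections,
                         seed = seed + 2L)
  tables <- simulate_feature_tables(design, db_truth, truth)

  spectra_by_compound <- lapply(seq_len(nrow(db_truth)), function(i)
    simulate_msms(db_truth[i, ], noise_peaks = 10, seed = seed + 100L + i))
  names(spectra_by_compound) <- db_truth$compound_id

  rplc <- truth$compounds$logd_ph7 >= 0
  calibration_standards <- data.frame(
    name = db_truth$name[rplc],
    rt = truth$compounds$true_rt[rplc],
    logd_ph7 = db_truth$logd_ph7[rplc],
    stringsAsFactors = FALSE
  )
  reference_standards <- data.frame(
    name = db_truth$name,
    compound_id = db_truth$compound_id,
    rt = truth$compounds$true_rt,
    mz = db_truth$adduct_mass,
    stringsAsFactors = FALSE
  )
  reference_standards$fragments <- I(db_truth$fragments)

  structure(list(config = config, db_truth = db_truth, decoys = decoys,
                 db_screen = rbind(db_truth, decoys), truth = truth,
                 design = design, tables = tables,
                 spectra_by_compound = spectra_by_compound,
                 calibration_standards = calibration_standards,
                 reference_standards = reference_standards),
            class = "synthetic_study")
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Feature tables and blanks as the canonical CSV dialect (with the
#' ground-truth provenance column retained), the screening database as CSV
#' and JSON, calibration standards as CSV, spectra as MSP and MGF, and the
#' ground truth as CSV.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$tables$samples))
    write_feature_table(study$tables$samples[[nm]],
                        file.path(dir, paste0("sample_", gsub("[^A-Za-z0-9]", "_", nm), ".csv")),
                        keep_provenance = TRUE)
  for (nm in names(study$tables$blanks))
    write_feature_table(study$tables$blanks[[nm]],
                        file.path(dir, paste0("blank_", gsub("[^A-Za-z0-9]", "_", nm), ".csv")),
                        keep_provenance = TRUE)
  write_compound_db(study$db_screen, file.path(dir, "compound_db.csv"))
  write_compound_db(study$db_screen, file.path(dir, "compound_db.json"),
                    format = "json")
  write_calibration_standards(study$calibration_standards,
                              file.path(dir, "calibration_standards.csv"))
  precursors <- stats::setNames(study$db_truth$adduct_mass,
                                study$db_truth$compound_id)
  write_msp(study$spectra_by_compound, file.path(dir, "spectra.msp"),
            precursors = precursors)
  write_mgf(study$spectra_by_compound, file.path(dir, "spectra.mgf"),
            precursors = precursors)
  gt <- merge(study$truth$abundance, study$truth$compounds, by = "compound_id")
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

## internal: provenance -> compound id ("compound:C0001" -> "C0001")
source_compound <- function(source_id) {
  ifelse(grepl("^compound:", source_id),
         sub("^compound:", "", source_id), NA_character_)
}

#' Align consensus features across samples into a sample x feature matrix
#'
#' Consensus features from different (solvent, instrument) samples are
#' grouped greedily by descending intensity within the matching
#' tolerances; each group becomes one matrix column (named `mz@rt`), each
#' (sample, injection) one row, with 0 where a sample lacks the feature.
#'
#' @param consensus_list named list of consensus feature data.frames (one
#'   per sample), as returned by [consensus_features()].
#' @param tol [tolerances()].
#' @return list: `X` (matrix), `meta` (row metadata: sample, instrument,
#'   injection), `features` (column metadata: mz, rt).
#' @export
build_data_matrix <- function(consensus_list, tol = tolerances()) {
  pooled <- do.call(rbind, lapply(names(consensus_list), function(k) {
    cf <- consensus_list[[k]]
    if (nrow(cf) == 0) return(NULL)
    data.frame(key = k, idx = seq_len(nrow(cf)), mz = cf$mz, rt = cf$rt,
               intensity = cf$intensity, stringsAsFactors = FALSE)
  }))
  check(!is.null(pooled) && nrow(pooled) > 0, "no consensus features to align")
  ord <- order(-pooled$intensity, pooled$mz)
  pooled <- pooled[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(pooled))
  groups <- list()
  for (s in seq_len(nrow(pooled))) {
    if (used[s]) next
    in_tol <- !used &
      abs(ppm_deviation(pooled$mz[s], pooled$mz)) <= tol$ppm_tol &
      abs(pooled$rt - pooled$rt[s]) <= tol$rt_tol
    members <- integer(0)
    for (k in names(consensus_list)) {
      cand <- which(in_tol & pooled$key == k)
      if (length(cand) == 0) next
      members <- c(members, cand[which.min(abs(pooled$mz[cand] - pooled$mz[s]))])
    }
    used[members] <- TRUE
    used[s] <- TRUE
    groups[[length(groups) + 1]] <- members
  }
  g_mz <- vapply(groups, function(m) mean(pooled$mz[m]), 1)
  g_rt <- vapply(groups, function(m) mean(pooled$rt[m]), 1)

  n_inj <- max(vapply(consensus_list, function(cf)
    if (nrow(cf)) length(cf$intensities[[1]]) else 0L, 1L))
  meta <- do.call(rbind, lapply(names(consensus_list), function(k) {
    cf <- consensus_list[[k]]
    data.frame(key = k,
               sample = if (nrow(cf)) cf$sample[1] else NA_character_,
               instrument = if (nrow(cf)) cf$instrument[1] else NA_character_,
               injection = seq_len(n_inj), stringsAsFactors = FALSE)
  }))
  X <- matrix(0, nrow(meta), length(groups))
  for (g in seq_along(groups)) {
    for (m in groups[[g]]) {
      cf <- consensus_list[[pooled$key[m]]]
      intens <- cf$intensities[[pooled$idx[m]]]
      rows <- which(meta$key == pooled$key[m])
      X[rows, g] <- intens[meta$injection[rows]]
    }
  }
  colnames(X) <- sprintf("%.4f@%.2f", g_mz, g_rt)
  list(X = X, meta = meta, features = data.frame(mz = g_mz, rt = g_rt))
}

#' Run the end-to-end screening workflow on a synthetic study
#'
#' Stages, in order: internal-standard QC over all tables; triplicate
#' consensus alignment per (solvent, instrument); blank subtraction;
#' retention-window filtering and the 15-min HILIC/RPLC partition; RT-LogD
#' calibration from the standard mixture; successive-elimination screening
#' of the MS/MS-capable instrument's features against the decoy-augmented
#' database; reference-standard confirmation into identification levels;
#' and OPLS-DA of the sample x feature matrix with instrument as class,
#' with S-plot selection of features common to both instruments.
#'
#' @param config a [study_config()].
#' @param study optionally, a pre-simulated [simulate_study()] result
#'   (its config takes precedence).
#' @return list of class `study_result`: `manifest` (per-stage counts, QC
#'   flag, recovery metrics — all computed, deterministic given the seed),
#'   `qc`, `consensus`, `screening`, `identifications`, `deviation_report`,
#'   `calibration`, `opls` (model, q2, splot, common features), `study`.
#' @export
run_study <- function(config = study_config(), study = NULL) {
  if (is.null(study)) study <- simulate_study(config)
  config <- study$config
  tol <- config$tol

  ## --- QC ------------------------------------------------------------
  qc <- qc_internal_standards(c(study$tables$samples, study$tables$blanks),
                              internal_standard_set(), tol)

  ## --- consensus + blank subtraction ---------------------------------
  inst_labels <- vapply(config$instruments, function(i) i$label, "")
  consensus <- list()
  for (solvent in config$solvents) {
    for (lab in inst_labels) {
      keys <- paste(solvent, lab, seq_len(config$n_injections), sep = "|")
      cf <- consensus_features(study$tables$samples[keys], tol)
      blank <- study$tables$blanks[[paste(solvent, lab, sep = "|")]]
      cf <- blank_subtract(cf, blank, tol)
      consensus[[paste(solvent, lab, sep = "|")]] <- cf
    }
  }

  ## --- calibration ---------------------------------------------------
  calibration <- fit_calibration(study$calibration_standards)

  ## --- screening (MS/MS-capable instrument) --------------------------
  msms_labs <- inst_labels[vapply(config$instruments,
                                  function(i) isTRUE(i$has_msms), TRUE)]
  screen_lab <- if (length(msms_labs)) msms_labs[1] else inst_labels[1]
  feats <- do.call(rbind, lapply(config$solvents, function(sv) {
    cf <- consensus[[paste(sv, screen_lab, sep = "|")]]
    part <- partition_by_column(cf, tol)
    rbind(part$hilic, part$rplc)
  }))
  spectra <- list()
  cmp <- source_compound(feats$source_id)
  for (i in which(!is.na(cmp))) {
    sp <- study$spectra_by_compound[[cmp[i]]]
    if (!is.null(sp)) spectra[[feats$feature_id[i]]] <- sp
  }
  screening <- successive_elimination(feats, study$db_screen, config$scoring,
                                      calibration = calibration,
                                      spectra = spectra,
                                      allowed_families = config$allowed_families)

  ## --- recovery bookkeeping ------------------------------------------
  truth_ids <- study$db_truth$compound_id
  surv <- screening$survivors
  surv_src <- source_compound(feats$source_id[match(surv$feature_id,
                                                    feats$feature_id)])
  recovered <- intersect(truth_ids,
                         surv$compound_id[!is.na(surv_src) &
                                            surv$compound_id == surv_src])
  decoy_hits <- screening$hits[grepl("^D", screening$hits$compound_id), ,
                               drop = FALSE]
  decoy_chemo_rate <- if (nrow(decoy_hits) > 0)
    mean(!is.na(decoy_hits$eliminated_by) &
           decoy_hits$eliminated_by == "chemotaxonomy") else NA_real_

  ## --- identification -------------------------------------------------
  ids <- list()
  for (cid in recovered) {
    rows <- surv[surv$compound_id == cid & !is.na(surv_src) & surv_src == cid, ,
                 drop = FALSE]
    best <- rows[which.max(rows$composite), , drop = FALSE]
    std <- study$reference_standards[study$reference_standards$compound_id == cid, ,
                                     drop = FALSE]
    spec <- spectra[[best$feature_id]]
    ids[[cid]] <- confirm_with_standard(best, std,
                                        rt_tol = config$id_rt_tol,
                                        ppm_tol = config$id_ppm_tol,
                                        min_frag_overlap = config$min_frag_overlap,
                                        spectrum = spec, cfg = config$scoring)
  }
  levels_assigned <- vapply(ids, function(r) r$level, 1L)
  deviation_report <- deviation_table(unname(ids))

  ## --- OPLS-DA --------------------------------------------------------
  op <- config$opls
  opls_res <- tryCatch({
    dm <- build_data_matrix(consensus, tol)
    keep <- !is.na(dm$meta$sample)
    dm$X <- dm$X[keep, , drop = FALSE]
    dm$meta <- dm$meta[keep, , drop = FALSE]
    ## instrument contrast when two instruments are present, solvent otherwise
    opls_classes <- if (length(unique(dm$meta$instrument)) >= 2)
      dm$meta$instrument else dm$meta$sample
    model <- suppressWarnings(
      fit_opls_da(dm$X, opls_classes,
                  n_predictive = op$n_predictive,
                  n_orthogonal = op$n_orthogonal,
                  scaling = op$scaling, log_transform = op$log_transform))
    q2 <- suppressWarnings(
      cross_validated_q2(dm$X, opls_classes, folds = op$folds,
                         seed = config$seed,
                         n_predictive = op$n_predictive,
                         n_orthogonal = op$n_orthogonal,
                         scaling = op$scaling,
                         log_transform = op$log_transform))
    splot <- s_plot(model)
    common <- select_common_features(splot, pcorr_max = op$pcorr_max)
    list(model = model, q2 = as.numeric(q2), splot = splot,
         common = common, matrix = dm)
  }, error = function(e) {
    warning(sprintf("OPLS-DA stage skipped: %s", conditionMessage(e)))
    list(model = NULL, q2 = NA_real_, splot = NULL, common = NULL,
         matrix = NULL, error = conditionMessage(e))
  })

  manifest <- list(
    seed = config$seed,
    qc_pass = qc$pass,
    n_tables = length(study$tables$samples) + length(study$tables$blanks),
    consensus_counts = vapply(consensus, nrow, 1L),
    screening_audit = screening$audit,
    n_truth = length(truth_ids),
    n_recovered = length(recovered),
    recovery_rate = length(recovered) / length(truth_ids),
    n_decoy_hits = nrow(decoy_hits),
    decoy_chemotaxonomy_elimination_rate = decoy_chemo_rate,
    n_level1 = sum(levels_assigned == 1L),
    level1_rate = sum(levels_assigned == 1L) / length(truth_ids),
    opls = list(
      r2x_cum = if (!is.null(opls_res$model)) opls_res$model$r2x_cum else NA_real_,
      r2y_cum = if (!is.null(opls_res$model)) opls_res$model$r2y_cum else NA_real_,
      q2_cum = opls_res$q2),
    n_common_features = if (!is.null(opls_res$common))
      nrow(opls_res$common) else 0L
  )

  structure(list(manifest = manifest, qc = qc, consensus = consensus,
                 calibration = calibration, screening = screening,
                 identifications = ids, deviation_report = deviation_report,
                 opls = opls_res,
                 study = study),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  m <- x$manifest
  cat("polarity-extended screening study\n")
  cat(sprintf("  QC pass: %s\n", m$qc_pass))
  cat(sprintf("  truth compounds recovered: %d / %d (%.0f%%)\n",
              m$n_recovered, m$n_truth, 100 * m$recovery_rate))
  cat(sprintf("  level-1 identifications: %d (%.0f%%)\n",
              m$n_level1, 100 * m$level1_rate))
  cat(sprintf("  OPLS-DA: R2Y(cum) = %.3f, Q2(cum) = %.3f\n",
              m$opls$r2y_cum, m$opls$q2_cum))
  invisible(x)
}
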
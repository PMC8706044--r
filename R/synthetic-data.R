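#' Generate a synthetic plant-metabolite compound database
#'
#' Emulates a chemotaxonomy-annotated compound database (name, neutral
#' monoisotopic mass, LogD at pH 7, plant family membership, characteristic
#' fragment m/z list) at small scale. LogD values are drawn from a bimodal
#' mixture: a hydrophilic component with strictly negative LogD (compounds
#' that elute from the HILIC column) and a lipophilic component with
#' positive LogD (RPLC-eluting compounds).
#'
#' @param n_compounds number of database records (>= 1).
#' @param family_pool character vector of plant family names to sample
#'   memberships from.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param p_polar mixing weight of the hydrophilic (LogD < 0) component.
#' @param mass_range neutral monoisotopic mass range in Da.
#' @param n_fragments_range range of characteristic fragments per compound.
#'
#' @return A data.frame with one row per compound: `compound_id`, `name`,
#'   `monoisotopic_mass` (neutral, Da), `adduct_mass` (\[M+H\]+, Da),
#'   `logd_ph7`, `families` (list column), `fragments` (list column of
#'   fragment m/z below the adduct mass), `literature_tag`.
#' @export
generate_compound_db <- function(n_compounds,
                                 family_pool = c("Lemnaceae", "Poaceae",
                                                 "Brassicaceae", "Nymphaeaceae"),
                                 seed = 1L,
                                 p_polar = 0.5,
                                 mass_range = c(100, 600),
                                 n_fragments_range = c(2L, 8L)) {
  check(is.numeric(n_compounds) && length(n_compounds) == 1 && n_compounds >= 1,
        "n_compounds must be a single number >= 1")
  check(length(family_pool) >= 1, "family_pool must be non-empty")
  check(p_polar >= 0 && p_polar <= 1, "p_polar must be in [0, 1]")
  n <- as.integer(n_compounds)

  withr::with_seed(as.integer(seed), {
    polar <- stats::runif(n) < p_polar
    logd <- numeric(n)
    ## hydrophilic mode strictly below 0, lipophilic mode strictly above
    logd[polar]  <- rtruncnorm(sum(polar), mean = -2, sd = 0.9,
                               lower = -5, upper = -0.05)
    logd[!polar] <- rtruncnorm(sum(!polar), mean = 2, sd = 0.9,
                               lower = 0.05, upper = 4.6)
    mono <- stats::runif(n, mass_range[1], mass_range[2])
    adduct <- mono + PROTON_MASS

    n_frag <- sample(seq(n_fragments_range[1], n_fragments_range[2]),
                     n, replace = TRUE)
    fragments <- lapply(seq_len(n), function(i) {
      sort(stats::runif(n_frag[i], 50, adduct[i] - 1), decreasing = TRUE)
    })
    n_fam <- sample(1:2, n, replace = TRUE, prob = c(0.8, 0.2))
    n_fam <- pmin(n_fam, length(family_pool))
    families <- lapply(seq_len(n), function(i) {
      sort(sample(family_pool, n_fam[i]))
    })

    db <- data.frame(
      compound_id = sprintf("C%04d", seq_len(n)),
      name = sprintf("compound_%04d", seq_len(n)),
      monoisotopic_mass = mono,
      adduct_mass = adduct,
      logd_ph7 = logd,
      literature_tag = "synthetic",
      stringsAsFactors = FALSE
    )
    db$families <- I(families)
    db$fragments <- I(fragments)
    db
  })
}

#' Deterministic retention model for the polarity-extended separation
#'
#' Maps LogD(pH 7) to a nominal retention time on the serial RPLC-HILIC
#' coupling. Hydrophilic compounds (LogD < 0) elute from the HILIC column in
#' the 5-15 min window; compounds with LogD >= 0 elute from the RPLC column
#' from 15 min on, via a linear map `rt = 15 + 4 * logd` (capped at 34 min)
#' that is exactly invertible in the noise-free case, so a retention-time
#' calibration fitted to noise-free standards recovers LogD exactly.
#'
#' The HILIC branch uses a bounded logistic map into \[5, 15) purely to give
#' a monotone nominal value; HILIC retention carries no calibration
#' information in this workflow (only the LogD sign is used there).
#'
#' @param logd_ph7 numeric vector of LogD(pH 7) values.
#' @return retention times in minutes.
#' @export
elution_model <- function(logd_ph7) {
  rt <- ifelse(logd_ph7 < 0,
               5 + 10 * stats::plogis(logd_ph7 + 2.5),
               pmin(34, 15 + 4 * logd_ph7))
  unname(rt)
}

#' Inverse of the RPLC branch of [elution_model()]
#'
#' @param rt retention time in minutes (>= 15).
#' @return LogD(pH 7).
#' @export
elution_model_inverse_rplc <- function(rt) (rt - 15) / 4

#' The spiked internal-standard mixture
#'
#' Twelve substances spiked into every sample and blank at 5 uM each, used
#' to monitor mass accuracy and retention-time stability across all runs.
#' The nominal \[M+H\]+ masses and retention times are fixed synthetic
#' coordinates spanning both column regimes.
#'
#' @return data.frame with `name`, `expected_mz` (Da), `expected_rt` (min),
#'   `concentration_uM`.
#' @export
internal_standard_set <- function() {
  data.frame(
    name = c("6-amino-1,3-dimethyl-5-(formylamino)uracil",
             "2,4-diamino-6-(hydroxymethyl)pteridine",
             "vidarabine", "famotidine", "etilefrine", "sotalol",
             "carbetamide", "monuron", "chlortoluron", "metobromuron",
             "chlorbromuron", "metconazole"),
    expected_mz = c(199.0831, 193.0832, 268.1040, 338.0528, 182.1176,
                    273.1267, 237.1234, 199.0633, 213.0789, 259.0077,
                    292.9687, 320.1524),
    expected_rt = c(6.2, 7.1, 8.4, 9.8, 11.3, 13.0,
                    17.5, 19.9, 22.4, 24.8, 27.3, 30.6),
    concentration_uM = 5,
    stringsAsFactors = FALSE
  )
}

#' Instrument noise/sensitivity profile
#'
#' @param label instrument label (e.g. "A", "B").
#' @param mass_sigma_ppm Gaussian m/z error, ppm.
#' @param rt_sigma Gaussian retention-time error, minutes.
#' @param detection_prob per-injection probability that a compound present
#'   in a sample yields a feature.
#' @param intensity_scale multiplicative sensitivity factor.
#' @param has_msms whether the instrument acquires MS/MS spectra.
#' @return a list of class `instrument_profile`.
#' @export
instrument_profile <- function(label, mass_sigma_ppm = 2, rt_sigma = 0.05,
                               detection_prob = 0.9, intensity_scale = 1,
                               has_msms = FALSE) {
  check(detection_prob >= 0 && detection_prob <= 1,
        "detection_prob must be in [0, 1]")
  structure(list(label = label, mass_sigma_ppm = mass_sigma_ppm,
                 rt_sigma = rt_sigma, detection_prob = detection_prob,
                 intensity_scale = intensity_scale, has_msms = has_msms),
            class = "instrument_profile")
}

#' Default two-instrument setup
#'
#' Instrument "A" is an older TOF without MS/MS and lower sensitivity;
#' instrument "B" is a newer QTOF with MS/MS and higher sensitivity
#' (per-injection detection probabilities 0.85 and 0.95).
#'
#' @return named list of two [instrument_profile()] objects.
#' @export
default_instruments <- function() {
  list(
    A = instrument_profile("A", mass_sigma_ppm = 2.0, rt_sigma = 0.05,
                           detection_prob = 0.85, intensity_scale = 0.6,
                           has_msms = FALSE),
    B = instrument_profile("B", mass_sigma_ppm = 1.5, rt_sigma = 0.05,
                           detection_prob = 0.95, intensity_scale = 1.0,
                           has_msms = TRUE)
  )
}

#' Study design for the synthetic extraction/injection layout
#'
#' @param solvents extraction solvents.
#' @param instruments list of [instrument_profile()] objects.
#' @param n_injections technical injections per extract (>= 1).
#' @param seed integer seed.
#' @param intensity_sdlog log-scale SD of per-injection intensity jitter.
#' @return list of class `study_design`.
#' @export
study_design <- function(solvents = c("100% MeOH", "50% MeOH", "100% H2O"),
                         instruments = default_instruments(),
                         n_injections = 3L,
                         seed = 1L,
                         intensity_sdlog = 0.15) {
  check(n_injections >= 1, "n_injections must be >= 1")
  check(length(solvents) >= 1, "at least one solvent required")
  structure(list(solvents = solvents, instruments = instruments,
                 n_injections = as.integer(n_injections),
                 seed = as.integer(seed),
                 intensity_sdlog = intensity_sdlog),
            class = "study_design")
}

#' Ground-truth sample composition for a synthetic study
#'
#' Every database compound is present in every extract, with log-normal
#' abundances whose log-mean differs by solvent (extraction efficiency).
#' True retention times come from [elution_model()] for RPLC compounds
#' (LogD >= 0); HILIC compounds get a uniform RT in \[5, 15) since HILIC
#' retention carries no calibration information here. A set of contaminant
#' features (present in blanks and samples alike) is also drawn.
#'
#' @param db compound database from [generate_compound_db()].
#' @param solvents character vector of extract labels.
#' @param seed integer seed.
#' @param n_contaminants number of blank contaminant features.
#' @param base_meanlog log abundance level of the first solvent.
#' @param solvent_shift successive decrease in meanlog per solvent.
#' @param sdlog log-scale SD of compound abundances.
#' @return list of class `ground_truth` with elements `compounds`
#'   (compound_id, true_rt, logd_ph7, adduct_mass), `abundance` (long
#'   data.frame solvent x compound), `contaminants`.
#' @export
generate_ground_truth <- function(db,
                                  solvents = c("100% MeOH", "50% MeOH", "100% H2O"),
                                  seed = 1L,
                                  n_contaminants = 25L,
                                  base_meanlog = log(5e4),
                                  solvent_shift = 0.5,
                                  sdlog = 0.8) {
  check(nrow(db) >= 1, "db must be non-empty")
  withr::with_seed(as.integer(seed), {
    n <- nrow(db)
    true_rt <- ifelse(db$logd_ph7 < 0,
                      stats::runif(n, 5, 15 - 1e-9),
                      elution_model(db$logd_ph7))
    compounds <- data.frame(compound_id = db$compound_id,
                            true_rt = true_rt,
                            logd_ph7 = db$logd_ph7,
                            adduct_mass = db$adduct_mass,
                            stringsAsFactors = FALSE)
    ab <- expand.grid(solvent = solvents, compound_id = db$compound_id,
                      stringsAsFactors = FALSE)
    meanlog <- base_meanlog - solvent_shift * (match(ab$solvent, solvents) - 1)
    ab$abundance <- stats::rlnorm(nrow(ab), meanlog = meanlog, sdlog = sdlog)
    contaminants <- data.frame(
      contaminant_id = sprintf("X%03d", seq_len(n_contaminants)),
      mz = stats::runif(n_contaminants, 100, 600) + PROTON_MASS,
      rt = stats::runif(n_contaminants, 5, 34),
      abundance = stats::rlnorm(n_contaminants, meanlog = base_meanlog - 1,
                                sdlog = 0.6),
      stringsAsFactors = FALSE
    )
    structure(list(compounds = compounds, abundance = ab,
                   contaminants = contaminants, solvents = solvents),
              class = "ground_truth")
  })
}

## internal: one feature-table row block for a set of sources
feature_block <- function(mz, rt, intensity, source_id, sample, injection,
                          instrument) {
  n <- length(mz)
  if (n == 0) {
    return(data.frame(feature_id = character(), mz = numeric(),
                      rt = numeric(), intensity = numeric(),
                      sample = character(), injection = integer(),
                      instrument = character(), source_id = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(feature_id = character(n), mz = mz, rt = rt,
             intensity = intensity, sample = sample,
             injection = as.integer(injection), instrument = instrument,
             source_id = source_id, stringsAsFactors = FALSE)
}

#' Simulate per-injection feature tables and blanks
#'
#' For each (solvent, instrument, injection), every ground-truth compound
#' appears with probability `detection_prob`, with m/z perturbed by Gaussian
#' ppm noise and RT by Gaussian `rt_sigma` noise; intensities are the true
#' abundances scaled by instrument sensitivity with log-normal injection
#' jitter. Blank contaminants appear in both the blank table and the sample
#' tables of the same solvent; the internal-standard mixture is spiked into
#' every table. One blank table is generated per (solvent, instrument).
#'
#' @param design a [study_design()].
#' @param db compound database.
#' @param truth a [generate_ground_truth()] result for the same db.
#' @return list with `samples` (named list of per-injection feature tables,
#'   keys `solvent|instrument|injection`) and `blanks` (named list, keys
#'   `solvent|instrument`). Tables carry a `source_id` provenance column
#'   (`compound:<id>`, `contaminant:<id>`, `standard:<name>`) used only for
#'   ground-truth bookkeeping; the on-disk writer drops it by default.
#' @export
simulate_feature_tables <- function(design, db, truth) {
  check(inherits(design, "study_design"), "design must be a study_design")
  check(nrow(db) >= 1, "db must be non-empty")
  standards <- internal_standard_set()
  std_abund <- 5e4

  withr::with_seed(design$seed, {
    samples <- list()
    blanks <- list()
    for (solvent in design$solvents) {
      ab <- truth$abundance[truth$abundance$solvent == solvent, ]
      ab <- ab[match(truth$compounds$compound_id, ab$compound_id), ]
      for (inst in design$instruments) {
        ppm_sd <- inst$mass_sigma_ppm
        ## blank: all contaminants + standards, instrument noise
        ct <- truth$contaminants
        bl <- rbind(
          feature_block(
            ct$mz * (1 + stats::rnorm(nrow(ct), 0, ppm_sd) * 1e-6),
            ct$rt + stats::rnorm(nrow(ct), 0, inst$rt_sigma),
            ct$abundance * inst$intensity_scale,
            paste0("contaminant:", ct$contaminant_id),
            paste0("blank_", solvent), 1L, inst$label),
          feature_block(
            standards$expected_mz *
              (1 + stats::rnorm(nrow(standards), 0, ppm_sd) * 1e-6),
            standards$expected_rt +
              stats::rnorm(nrow(standards), 0, inst$rt_sigma),
            std_abund * inst$intensity_scale,
            paste0("standard:", standards$name),
            paste0("blank_", solvent), 1L, inst$label)
        )
        bl$feature_id <- sprintf("B_%s_%s_%04d", solvent, inst$label,
                                 seq_len(nrow(bl)))
        blanks[[paste(solvent, inst$label, sep = "|")]] <- bl

        for (inj in seq_len(design$n_injections)) {
          detected <- stats::runif(nrow(truth$compounds)) < inst$detection_prob
          tc <- truth$compounds[detected, , drop = FALSE]
          tab <- ab$abundance[detected]
          jitter <- stats::rlnorm(sum(detected), 0, design$intensity_sdlog)
          blocks <- list(
            feature_block(
              tc$adduct_mass *
                (1 + stats::rnorm(nrow(tc), 0, ppm_sd) * 1e-6),
              tc$true_rt + stats::rnorm(nrow(tc), 0, inst$rt_sigma),
              tab * inst$intensity_scale * jitter,
              paste0("compound:", tc$compound_id),
              solvent, inj, inst$label),
            feature_block(
              ct$mz * (1 + stats::rnorm(nrow(ct), 0, ppm_sd) * 1e-6),
              ct$rt + stats::rnorm(nrow(ct), 0, inst$rt_sigma),
              ct$abundance * inst$intensity_scale,
              paste0("contaminant:", ct$contaminant_id),
              solvent, inj, inst$label),
            feature_block(
              standards$expected_mz *
                (1 + stats::rnorm(nrow(standards), 0, ppm_sd) * 1e-6),
              standards$expected_rt +
                stats::rnorm(nrow(standards), 0, inst$rt_sigma),
              std_abund * inst$intensity_scale,
              paste0("standard:", standards$name),
              solvent, inj, inst$label)
          )
          tabl <- do.call(rbind, blocks)
          tabl$feature_id <- sprintf("F_%s_%s_i%d_%04d", solvent, inst$label,
                                     inj, seq_len(nrow(tabl)))
          samples[[paste(solvent, inst$label, inj, sep = "|")]] <- tabl
        }
      }
    }
    list(samples = samples, blanks = blanks)
  })
}

#' Simulate an MS/MS spectrum for a database compound
#'
#' All characteristic fragments appear with intensities above the default
#' peak-intensity threshold; noise peaks are drawn uniformly below the
#' precursor adduct mass with intensities below the threshold.
#'
#' @param compound one-row slice of a compound database (or a list with
#'   `adduct_mass` and `fragments`).
#' @param noise_peaks number of noise peaks to add.
#' @param seed integer seed.
#' @param fragment_intensity_range intensity range of true fragment peaks.
#' @param noise_intensity_range intensity range of noise peaks.
#' @return data.frame with `mz`, `intensity`, sorted by m/z.
#' @export
simulate_msms <- function(compound, noise_peaks = 10L, seed = 1L,
                          fragment_intensity_range = c(200, 1000),
                          noise_intensity_range = c(5, 45)) {
  frags <- if (is.data.frame(compound)) compound$fragments[[1]] else compound$fragments
  precursor <- if (is.data.frame(compound)) compound$adduct_mass[1] else compound$adduct_mass
  check(length(frags) >= 1, "compound has no fragments")
  withr::with_seed(as.integer(seed), {
    spec <- data.frame(
      mz = c(frags, if (noise_peaks > 0) stats::runif(noise_peaks, 50, precursor)),
      intensity = c(stats::runif(length(frags),
                                 fragment_intensity_range[1],
                                 fragment_intensity_range[2]),
                    if (noise_peaks > 0)
                      stats::runif(noise_peaks, noise_intensity_range[1],
                                   noise_intensity_range[2]))
    )
    spec[order(spec$mz), , drop = FALSE]
  })
}
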
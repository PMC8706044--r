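#' Write / read a feature table
#'
#' The on-disk dialect is CSV with header
#' `feature_id,mz,rt_min,intensity,sample,injection,instrument`. The
#' in-memory `rt` column is written as `rt_min`; extra bookkeeping columns
#' (e.g. ground-truth `source_id`) are dropped unless `keep_provenance`.
#'
#' @param x feature table data.frame.
#' @param path output file.
#' @param keep_provenance keep the `source_id` column if present.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, keep_provenance = FALSE) {
  out <- data.frame(feature_id = x$feature_id, mz = x$mz, rt_min = x$rt,
                    intensity = x$intensity, sample = x$sample,
                    injection = x$injection, instrument = x$instrument,
                    stringsAsFactors = FALSE)
  if (keep_provenance && !is.null(x$source_id)) out$source_id <- x$source_id
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(x)[names(x) == "rt_min"] <- "rt"
  x
}

#' Write / read a compound database
#'
#' CSV dialect:
#' `compound_id,name,monoisotopic_mass,logd_ph7,families,fragments` with
#' `families` and `fragments` ';'-separated. A structured JSON twin can be
#' written with `format = "json"`.
#'
#' @param db compound database data.frame.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_compound_db <- function(db, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    recs <- lapply(seq_len(nrow(db)), function(i) {
      list(compound_id = db$compound_id[i], name = db$name[i],
           monoisotopic_mass = db$monoisotopic_mass[i],
           logd_ph7 = db$logd_ph7[i],
           families = as.list(db$families[[i]]),
           fragments = as.list(db$fragments[[i]]),
           literature_tag = db$literature_tag[i])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    out <- data.frame(compound_id = db$compound_id, name = db$name,
                      monoisotopic_mass = db$monoisotopic_mass,
                      logd_ph7 = db$logd_ph7,
                      families = vapply(db$families, paste, "", collapse = ";"),
                      fragments = vapply(db$fragments, function(f)
                        paste(format(f, digits = 10, trim = TRUE),
                              collapse = ";"), ""),
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_compound_db
#' @export
read_compound_db <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  db <- data.frame(compound_id = x$compound_id, name = x$name,
                   monoisotopic_mass = x$monoisotopic_mass,
                   adduct_mass = x$monoisotopic_mass + PROTON_MASS,
                   logd_ph7 = x$logd_ph7,
                   literature_tag = "file",
                   stringsAsFactors = FALSE)
  db$families <- I(strsplit(x$families, ";", fixed = TRUE))
  db$fragments <- I(lapply(strsplit(x$fragments, ";", fixed = TRUE), as.numeric))
  db
}

#' Write / read a calibration-standard mixture table
#'
#' CSV dialect: `name,rt_min,logd_ph7`.
#'
#' @param standards data.frame with `name`, `rt`, `logd_ph7`.
#' @param path file path.
#' @return `path` / a data.frame with `name`, `rt`, `logd_ph7`.
#' @export
write_calibration_standards <- function(standards, path) {
  utils::write.csv(data.frame(name = standards$name, rt_min = standards$rt,
                              logd_ph7 = standards$logd_ph7),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_standards
#' @export
read_calibration_standards <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(name = x$name, rt = x$rt_min, logd_ph7 = x$logd_ph7,
             stringsAsFactors = FALSE)
}

#' Write spectra in MSP or MGF format
#'
#' @param spectra named list of spectra (data.frames with `mz`,
#'   `intensity`); names become entry titles.
#' @param path output file.
#' @param precursors optional named numeric vector of precursor m/z.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path, precursors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(spectra)) {
    sp <- spectra[[nm]]
    writeLines(sprintf("NAME: %s", nm), con)
    if (!is.null(precursors) && nm %in% names(precursors))
      writeLines(sprintf("PRECURSORMZ: %.5f", precursors[[nm]]), con)
    writeLines(sprintf("Num Peaks: %d", nrow(sp)), con)
    writeLines(sprintf("%.5f %.1f", sp$mz, sp$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_msp
#' @export
write_mgf <- function(spectra, path, precursors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(spectra)) {
    sp <- spectra[[nm]]
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", nm), con)
    if (!is.null(precursors) && nm %in% names(precursors))
      writeLines(sprintf("PEPMASS=%.5f", precursors[[nm]]), con)
    writeLines(sprintf("%.5f %.1f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read spectra from an MSP file written by [write_msp()]
#'
#' @param path MSP file path.
#' @return named list of data.frames with `mz`, `intensity`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^NAME:", lines[i])) {
      nm <- sub("^NAME:\\s*", "", lines[i])
      while (!grepl("^Num Peaks:", lines[i])) i <- i + 1
      n <- as.integer(sub("^Num Peaks:\\s*", "", lines[i]))
      peaks <- if (n > 0) {
        do.call(rbind, lapply(lines[(i + 1):(i + n)], function(l) {
          as.numeric(strsplit(trimws(l), "\\s+")[[1]])
        }))
      } else matrix(numeric(), 0, 2)
      out[[nm]] <- data.frame(mz = peaks[, 1], intensity = peaks[, 2])
      i <- i + n + 1
    } else i <- i + 1
  }
  out
}

#' Curated reference-standard confirmation table for Lemna minor
#'
#' Loads the shipped table of 42 Lemna minor compounds confirmed by
#' reference-standard injection on the polarity-extended RPLC-HILIC
#' coupling: standard and measured retention times (min) and ion masses
#' (Da), characteristic MS/MS fragments, and whether the compound was also
#' detected on the single-TOF system. The serine row carries a `mass_note`
#' flagging an inconsistent printed measured mass; it is excluded from mass
#' recomputation when `drop_flagged_mass = TRUE`.
#'
#' @param drop_flagged_mass drop rows whose `mass_note` flags the printed
#'   measured mass as inconsistent.
#' @return data.frame with `name`, `rt_standard`, `rt_measured`,
#'   `mass_standard`, `mass_measured`, `fragments`, `system_a`, `mass_note`.
#' @export
lemna_confirmation_standards <- function(drop_flagged_mass = FALSE) {
  path <- system.file("extdata", "lemna_confirmation_standards.csv",
                      package = "polarscreen", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (drop_flagged_mass) x <- x[is.na(x$mass_note) | x$mass_note == "", ]
  x
}
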
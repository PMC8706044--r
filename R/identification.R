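#' Confirm a screened candidate against an injected reference standard
#'
#' A level-2 annotated hit is promoted to identification level 1 iff the
#' standard and the measured feature agree within `rt_tol` minutes and
#' `ppm_tol` ppm and at least `min_frag_overlap` characteristic fragments
#' of the standard are matched. Deviations are recorded signed as
#' standard minus measured. The defaults (0.5 min, 5 ppm, 1 fragment)
#' reflect typical replicate RT stability on this coupling; a permissive
#' preset of `rt_tol = 1` accommodates the larger deviations seen for some
#' validated glycosides.
#'
#' @param hit one surviving candidate hit (row of
#'   `screening_result$survivors`), carrying `mz`, `rt`, `name`,
#'   `compound_id` and, if MS/MS was scored, `n_frag_matched`.
#' @param std reference-standard result: list or one-row data.frame with
#'   `name`, `rt` (min), `mz` (Da), `fragments` (numeric vector or list
#'   column).
#' @param rt_tol maximum |RT deviation| for level 1, minutes.
#' @param ppm_tol maximum |mass deviation| for level 1, ppm.
#' @param min_frag_overlap minimum matched fragments for level 1.
#' @param spectrum optional measured MS/MS spectrum of the feature, used to
#'   (re)count fragment matches against the standard's fragment list.
#' @param cfg [scoring_config()] supplying the fragment-match tolerance.
#' @return list of class `identification_record`: `name`, `compound_id`,
#'   `level`, `delta_rt`, `delta_ppm`, `fragments_matched`,
#'   `fragments_total`, `chemotaxonomy_ok`, `column`, plus the standard and
#'   measured coordinates.
#' @export
confirm_with_standard <- function(hit, std, rt_tol = 0.5, ppm_tol = 5,
                                  min_frag_overlap = 1, spectrum = NULL,
                                  cfg = scoring_config()) {
  std_name <- if (is.data.frame(std)) std$name[1] else std$name
  hit_name <- if (is.data.frame(hit)) hit$name[1] else hit$name
  check(identical(std_name, hit_name),
        sprintf("standard '%s' does not correspond to candidate '%s'",
                std_name, hit_name))
  std_rt <- if (is.data.frame(std)) std$rt[1] else std$rt
  std_mz <- if (is.data.frame(std)) std$mz[1] else std$mz
  std_frags <- if (is.data.frame(std)) std$fragments[[1]] else std$fragments
  hit_rt <- if (is.data.frame(hit)) hit$rt[1] else hit$rt
  hit_mz <- if (is.data.frame(hit)) hit$mz[1] else hit$mz

  delta_rt <- std_rt - hit_rt
  delta_ppm <- ppm_deviation(std_mz, hit_mz)

  if (!is.null(spectrum)) {
    s <- msms_subscore(spectrum, list(fragments = std_frags), cfg)
    frag_matched <- attr(s, "n_matched")
  } else {
    frag_matched <- if (is.data.frame(hit)) hit$n_frag_matched[1] else
      hit$n_frag_matched
    if (is.null(frag_matched)) frag_matched <- NA_integer_
  }
  level <- if (!is.na(delta_rt) && abs(delta_rt) <= rt_tol &&
               abs(delta_ppm) <= ppm_tol &&
               !is.na(frag_matched) && frag_matched >= min_frag_overlap) 1L else 2L

  structure(list(
    name = hit_name,
    compound_id = if (is.data.frame(hit)) hit$compound_id[1] else hit$compound_id,
    level = level,
    delta_rt = delta_rt,
    delta_ppm = delta_ppm,
    fragments_matched = frag_matched,
    fragments_total = length(std_frags),
    chemotaxonomy_ok = TRUE,
    column = if (is.data.frame(hit)) hit$column[1] else hit$column,
    rt_standard = std_rt, rt_measured = hit_rt,
    mass_standard = std_mz, mass_measured = hit_mz
  ), class = "identification_record")
}

#' Assign an identification confidence level (1-5)
#'
#' Five-level scheme: 1 = confirmed by a reference standard; 2 = retention
#' behavior, accurate mass, fragmentation and chemotaxonomy all present;
#' 3 = accurate mass plus fragments compared across laboratories; 4 =
#' molecular formula or fragments only; 5 = mass recognition without
#' further information. A standard confirmation without an accurate mass is
#' contradictory and errors.
#'
#' @param evidence list of flags: `has_mass`, `has_rt`, `has_fragments`,
#'   `has_chemotaxonomy`, `cross_lab` (missing flags default to `FALSE`).
#' @param has_standard confirmed by reference-standard injection.
#' @param has_fragments overrides `evidence$has_fragments` if given.
#' @param has_formula molecular formula assigned.
#' @return integer level in 1-5.
#' @export
assign_level <- function(evidence = list(), has_standard = FALSE,
                         has_fragments = NULL, has_formula = FALSE) {
  get_flag <- function(nm) isTRUE(evidence[[nm]])
  has_mass <- get_flag("has_mass")
  has_rt <- get_flag("has_rt")
  has_chemo <- get_flag("has_chemotaxonomy")
  cross_lab <- get_flag("cross_lab")
  frags <- if (!is.null(has_fragments)) isTRUE(has_fragments)
           else get_flag("has_fragments")
  if (has_standard) {
    check(has_mass, "contradictory evidence: standard confirmation without accurate mass")
    return(1L)
  }
  if (has_mass && has_rt && frags && has_chemo) return(2L)
  if (has_mass && frags && cross_lab) return(3L)
  if (has_formula || frags) return(4L)
  if (has_mass) return(5L)
  stop("no usable evidence", call. = FALSE)
}

#' Deviation report for confirmed compounds
#'
#' Builds the standard-vs-measured report: retention times of the standard
#' (S) and the measured feature (M) with their signed deviation (S - M),
#' the corresponding ion masses with the signed ppm deviation, and the
#' fragment list. Rows are sorted by the standard retention time;
#' deviations are rounded to one decimal place.
#'
#' @param records either a list of [confirm_with_standard()] records or a
#'   data.frame with columns `name`, `rt_standard`, `rt_measured`,
#'   `mass_standard`, `mass_measured` (and optionally `fragments`).
#' @return data.frame: `name`, `rt_standard`, `rt_measured`, `delta_rt`,
#'   `mass_standard`, `mass_measured`, `delta_ppm`, `fragments`.
#' @export
deviation_table <- function(records) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records) == 0)
      return(data.frame(name = character(), rt_standard = numeric(),
                        rt_measured = numeric(), delta_rt = numeric(),
                        mass_standard = numeric(), mass_measured = numeric(),
                        delta_ppm = numeric(), fragments = character(),
                        stringsAsFactors = FALSE))
    df <- do.call(rbind, lapply(records, function(r)
      data.frame(name = r$name, rt_standard = r$rt_standard,
                 rt_measured = r$rt_measured,
                 mass_standard = r$mass_standard,
                 mass_measured = r$mass_measured,
                 fragments = NA_character_, stringsAsFactors = FALSE)))
  }
  if (nrow(df) == 0)
    return(data.frame(name = character(), rt_standard = numeric(),
                      rt_measured = numeric(), delta_rt = numeric(),
                      mass_standard = numeric(), mass_measured = numeric(),
                      delta_ppm = numeric(), fragments = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    name = df$name,
    rt_standard = df$rt_standard,
    rt_measured = df$rt_measured,
    delta_rt = round(df$rt_standard - df$rt_measured, 1),
    mass_standard = df$mass_standard,
    mass_measured = df$mass_measured,
    delta_ppm = round(ppm_deviation(df$mass_standard, df$mass_measured), 1),
    fragments = if (!is.null(df$fragments)) df$fragments else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rt_standard), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a deviation report as Markdown
#'
#' @param report a [deviation_table()] result.
#' @return character vector of Markdown lines.
#' @export
deviation_table_markdown <- function(report) {
  hdr <- c("| Compound | RT (S) | RT (M) | dRT | Mass (S) | Mass (M) | dppm |",
           "|---|---|---|---|---|---|---|")
  rows <- sprintf("| %s | %.1f | %.1f | %.1f | %.4f | %.4f | %.1f |",
                  report$name, report$rt_standard, report$rt_measured,
                  report$delta_rt, report$mass_standard,
                  report$mass_measured, report$delta_ppm)
  c(hdr, rows)
}
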
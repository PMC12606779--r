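#' Floored short-fragment excess of one draw
#'
#' The short assay (80 bp amplicon) counts every cfDNA template longer than
#' 80 bp, the mid assay (105 bp amplicon) every template longer than 105 bp,
#' so their difference estimates the 80-105 bp short-fragment excess that is
#' enriched in tumor-derived cfDNA. Negative differences are measurement
#' noise (the >80 bp class contains the >105 bp class) and are floored at 0.
#'
#' @param sm Numeric vector, >80 bp concentration (copies/mL plasma).
#' @param mm Numeric vector, >105 bp concentration, same units.
#' @return `pmax(sm - mm, 0)`, same length as the inputs.
#' @examples
#' compute_frag(c(5, 2), c(3, 3)) # 2, 0
#' @export
compute_frag <- function(sm, mm) {
  if (any(sm < 0, na.rm = TRUE) || any(mm < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative (upstream quantification contract)")
  }
  pmax(sm - mm, 0)
}

#' Derive the fragmentomic model variables from a profile table
#'
#' Computes, per patient, `Frag1 = max(SM1 - MM1, 0)`,
#' `Frag2 = max(SM2 - MM2, 0)`, `FragDiff = Frag2 - Frag1` and
#' `MMDiff = MM2 - MM1`. Only the per-draw excesses are floored; the two
#' between-draw differences keep their sign (the mid-marker change is used
#' as a signed noise-cleanup covariate in the candidate models).
#'
#' @param profiles Data frame with columns `SM1`, `MM1`, `SM2`, `MM2`
#'   (copies/mL plasma). Identifier and other columns are passed through.
#' @return A tibble: the input columns plus `Frag1`, `Frag2`, `FragDiff`,
#'   `MMDiff`.
#' @examples
#' derive_features(tibble::tibble(
#'   patient_id = "P1", SM1 = 10, MM1 = 4, SM2 = 20, MM2 = 6
#' ))
#' @export
derive_features <- function(profiles) {
  need <- c("SM1", "MM1", "SM2", "MM2")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    abort(paste0("profile table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  profiles |>
    as_tibble() |>
    mutate(
      Frag1 = compute_frag(.data$SM1, .data$MM1),
      Frag2 = compute_frag(.data$SM2, .data$MM2),
      FragDiff = .data$Frag2 - .data$Frag1,
      MMDiff = .data$MM2 - .data$MM1
    )
}

#' Progression-score change relative to healthy controls
#'
#' Difference between a subject's Progression Score and the mean score of a
#' healthy reference cohort. Positive values indicate a progression-like
#' elevation relative to healthy controls; values near zero indicate minimal
#' assay impact.
#'
#' @param ps Numeric vector of Progression Scores in \[0, 100\].
#' @param healthy_mean_ps Scalar mean PS of the healthy cohort, in \[0, 100\].
#' @return `ps - healthy_mean_ps`.
#' @export
compute_ps_change <- function(ps, healthy_mean_ps) {
  if (any(ps < 0 | ps > 100, na.rm = TRUE)) abort("ps must lie in [0, 100]")
  if (length(healthy_mean_ps) != 1 || is.na(healthy_mean_ps) ||
      healthy_mean_ps < 0 || healthy_mean_ps > 100) {
    abort("healthy_mean_ps must be a single value in [0, 100]")
  }
  ps - healthy_mean_ps
}
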
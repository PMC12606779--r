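#' @name qc_gating
#' @title Eligibility and run-quality gating
#'
#' @description
#' Each `check_*()` function evaluates one stated eligibility or run-quality
#' rule and returns a verdict table with columns `subject`, `rule`, `passed`,
#' `detail` — one row per evaluated subject and rule. [apply_exclusions()]
#' combines verdict tables into an analyzable cohort plus an exclusion table.
#'
#' Rules and their boundaries:
#' * transit: a draw received strictly more than `max_hours` (120 h) after
#'   collection fails; exactly 120 h passes.
#' * draw window: the second draw must fall 12-21 days (inclusive) after the
#'   first treatment.
#' * scan window: the assessment scan must fall 9-12 weeks (inclusive) after
#'   the first blood draw's collection.
#' * IPC shift: a sample whose mean internal-positive-control Ct departs from
#'   the run median by more than `max_shift_ct` is flagged as inhibited; an
#'   IPC that never amplified is total inhibition and fails outright.
#' * SVA concordance: the 265 bp SVA amplicon is quantified by both
#'   multiplexes from the same extract; a relative difference above
#'   `max_rel_diff` flags an experimental error.
NULL

hours_between <- function(from, to) as.numeric(difftime(to, from, units = "hours"))
days_between <- function(from, to) as.numeric(difftime(to, from, units = "days"))

#' Transit-time gate for blood draws
#'
#' @param manifest Manifest tibble (see [read_manifest()]) with timestamp
#'   columns `collected_at_1`, `received_at_1`, `collected_at_2`,
#'   `received_at_2`.
#' @param max_hours Maximum allowed collection-to-receipt transit, in hours.
#'   The boundary passes; strictly greater fails.
#' @return Verdict tibble, one row per patient and draw
#'   (rules `transit_time_draw1`, `transit_time_draw2`).
#' @export
check_transit_time <- function(manifest, max_hours = 120) {
  one_draw <- function(draw) {
    collected <- manifest[[paste0("collected_at_", draw)]]
    received <- manifest[[paste0("received_at_", draw)]]
    hrs <- hours_between(collected, received)
    indeterminate <- is.na(hrs)
    new_verdict(
      subject = manifest$patient_id,
      rule = paste0("transit_time_draw", draw),
      passed = !indeterminate & hrs <= max_hours,
      detail = dplyr::case_when(
        indeterminate ~ "indeterminate: missing timestamp",
        hrs <= max_hours ~ sprintf("transit %.1f h", hrs),
        TRUE ~ sprintf("transit %.1f h exceeds %g h", hrs, max_hours)
      )
    )
  }
  bind_rows(one_draw(1), one_draw(2))
}

#' Post-treatment draw-window gate
#'
#' The second draw must be collected between `min_days` and `max_days`
#' (inclusive) after the first treatment, and after the treatment itself.
#'
#' @inheritParams check_transit_time
#' @param min_days,max_days Inclusive window bounds in days.
#' @return Verdict tibble with rule `draw_window`.
#' @export
check_draw_window <- function(manifest, min_days = 12, max_days = 21) {
  d <- days_between(manifest$treatment_date, manifest$collected_at_2)
  indeterminate <- is.na(d)
  new_verdict(
    subject = manifest$patient_id,
    rule = "draw_window",
    passed = !indeterminate & d >= min_days & d <= max_days,
    detail = dplyr::case_when(
      indeterminate ~ "indeterminate: missing treatment or draw-2 date",
      d < 0 ~ "pre-treatment draw",
      d >= min_days & d <= max_days ~ sprintf("draw 2 at %.1f days", d),
      TRUE ~ sprintf("draw 2 at %.1f days outside [%g, %g]", d, min_days, max_days)
    )
  )
}

#' Assessment-scan window gate
#'
#' @inheritParams check_transit_time
#' @param min_weeks,max_weeks Inclusive window (weeks) between the first
#'   blood draw and the assessment scan.
#' @return Verdict tibble with rule `scan_window`.
#' @export
check_scan_window <- function(manifest, min_weeks = 9, max_weeks = 12) {
  w <- days_between(manifest$collected_at_1, manifest$assessment_scan_date) / 7
  indeterminate <- is.na(w)
  new_verdict(
    subject = manifest$patient_id,
    rule = "scan_window",
    passed = !indeterminate & w >= min_weeks & w <= max_weeks,
    detail = dplyr::case_when(
      indeterminate ~ "indeterminate: missing assessment scan date",
      w >= min_weeks & w <= max_weeks ~ sprintf("scan at %.1f weeks", w),
      TRUE ~ sprintf("scan at %.1f weeks outside [%g, %g]", w, min_weeks, max_weeks)
    )
  )
}

#' Internal-positive-control inhibition check
#'
#' Every reaction is spiked with the same synthetic IPC template, so within a
#' run all samples should report a comparable IPC Ct. A per-sample mean IPC
#' Ct more than `max_shift_ct` above or below the run median indicates PCR
#' inhibition (1 Ct is roughly a 2-fold amplification deficit); an IPC with
#' no amplification at all is total inhibition.
#'
#' @param plate Plate tibble (see [read_plate()]); only `IPC172` rows are
#'   used. Grouped by `run_id` when that column is present.
#' @param max_shift_ct Allowed absolute deviation from the run median (Ct).
#' @return Verdict tibble, one row per sample (rule `ipc_shift`).
#' @export
check_ipc_shift <- function(plate, max_shift_ct = 1.0) {
  ipc <- plate |> filter(.data$target == "IPC172")
  if (nrow(ipc) == 0) abort("no IPC wells in run: cannot assess inhibition")
  if (!"run_id" %in% names(ipc)) ipc$run_id <- "run1"
  per_sample <- ipc |>
    group_by(.data$run_id, .data$sample_id) |>
    summarise(mean_ct = mean(.data$ct, na.rm = TRUE), .groups = "drop_last") |>
    mutate(mean_ct = ifelse(is.nan(.data$mean_ct), NA_real_, .data$mean_ct))
  if (nrow(per_sample) < 2) {
    abort("need at least 2 samples with IPC wells to assess inhibition shift")
  }
  per_sample |>
    mutate(run_median = median(.data$mean_ct, na.rm = TRUE)) |>
    ungroup() |>
    mutate(
      shift = .data$mean_ct - .data$run_median,
      verdict = pmap(
        list(.data$sample_id, .data$mean_ct, .data$shift),
        function(sid, mct, sh) {
          if (is.na(mct)) {
            new_verdict(sid, "ipc_shift", FALSE, "total inhibition: IPC did not amplify")
          } else if (abs(sh) > max_shift_ct) {
            new_verdict(sid, "ipc_shift", FALSE,
                        sprintf("IPC shift %+.2f Ct exceeds %g Ct", sh, max_shift_ct))
          } else {
            new_verdict(sid, "ipc_shift", TRUE, sprintf("IPC shift %+.2f Ct", sh))
          }
        }
      )
    ) |>
    pull(.data$verdict) |>
    list_rbind()
}

#' Cross-multiplex SVA concordance check
#'
#' The 265 bp SVA amplicon is carried by both multiplexes, so the two
#' quantities for the same extract should agree; a large relative difference
#' (symmetric-mean denominator) flags an experimental error such as a
#' pipetting fault.
#'
#' @param q_mpx1,q_mpx2 SVA quantities from multiplex 1 and 2 (same units).
#' @param subject Subject identifier(s) for the verdict rows.
#' @param max_rel_diff Maximum allowed `|q1 - q2| / mean(q1, q2)`.
#' @return Verdict tibble with rule `sva_concordance`.
#' @export
check_sva_concordance <- function(q_mpx1, q_mpx2, subject = seq_along(q_mpx1),
                                  max_rel_diff = 0.30) {
  rel <- abs(q_mpx1 - q_mpx2) / ((q_mpx1 + q_mpx2) / 2)
  indeterminate <- is.na(q_mpx1) | is.na(q_mpx2) | q_mpx1 <= 0 | q_mpx2 <= 0
  new_verdict(
    subject = subject,
    rule = "sva_concordance",
    passed = !indeterminate & rel <= max_rel_diff,
    detail = dplyr::case_when(
      indeterminate ~ "indeterminate: missing or non-positive SVA quantity",
      rel <= max_rel_diff ~ sprintf("relative difference %.3f", rel),
      TRUE ~ sprintf("relative difference %.3f exceeds %g", rel, max_rel_diff)
    )
  )
}

#' Clinical-history exclusions recorded in the manifest
#'
#' Secondary malignancy, active autoimmune treatment and recent DVT/PE/sepsis
#' are enrollment exclusions that the assay cannot diagnose; they arrive as
#' boolean manifest columns and are turned into verdicts here. Absent columns
#' are treated as all-pass.
#'
#' @inheritParams check_transit_time
#' @return Verdict tibble (possibly zero rows).
#' @export
check_clinical_flags <- function(manifest) {
  flags <- c("secondary_malignancy", "autoimmune_treatment", "recent_dvt_pe_sepsis")
  present <- intersect(flags, names(manifest))
  if (!length(present)) return(new_verdict(character(), character(), logical()))
  purrr::map(present, function(fl) {
    val <- isTRUE_vec(manifest[[fl]])
    new_verdict(
      subject = manifest$patient_id,
      rule = fl,
      passed = !val,
      detail = ifelse(val, paste0("manifest flag ", fl), "")
    )
  }) |> list_rbind()
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Apply gating verdicts to a cohort
#'
#' A patient is excluded iff any rule verdict for them failed (indeterminate
#' verdicts count as failures and carry their reason). The analyzable and
#' excluded sets partition the input cohort.
#'
#' @param manifest Manifest tibble, one row per patient.
#' @param verdicts Verdict tibble whose `subject` values are patient ids
#'   (bind several `check_*()` outputs together).
#' @return A list with `analyzable` (manifest subset) and `exclusions`
#'   (tibble `patient_id`, `rule`, `detail`, one row per failed rule).
#' @export
apply_exclusions <- function(manifest, verdicts) {
  failed <- verdicts |>
    filter(!.data$passed, .data$subject %in% manifest$patient_id) |>
    transmute(patient_id = .data$subject, rule = .data$rule, detail = .data$detail)
  keep <- !manifest$patient_id %in% failed$patient_id
  list(
    analyzable = manifest[keep, , drop = FALSE],
    exclusions = failed
  )
}
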
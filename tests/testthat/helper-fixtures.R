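# Shared fixtures, all built in code at test time.

# Default synthetic cohort joined to its outcome, ready for modeling.
cohort_features <- function(seed, scenario = ps_scenario()) {
  co <- generate_cohort(scenario, seed = seed)
  derive_features(co$profiles) |>
    dplyr::left_join(
      dplyr::select(co$manifest, patient_id, progressed),
      by = "patient_id"
    )
}

# Minimal valid manifest: n patients, draw 2 at `draw2_days`, transit
# `transit_hours`, scan at `scan_weeks` after draw 1. Times are POSIXct UTC.
toy_manifest <- function(n = 3, transit_hours = 48, draw2_days = 15,
                         scan_weeks = 10, change_pct = 10) {
  t0 <- as.POSIXct("2024-03-01 09:00:00", tz = "UTC")
  vec <- function(x) rep_len(x, n)
  collected_1 <- rep(t0 - 36 * 3600, n)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    cancer_type = "breast",
    collected_at_1 = collected_1,
    received_at_1 = collected_1 + vec(transit_hours) * 3600,
    collected_at_2 = t0 + vec(draw2_days) * 86400,
    received_at_2 = t0 + vec(draw2_days) * 86400 + 48 * 3600,
    plasma_volume_uL = 500,
    treatment_date = rep(t0, n),
    baseline_scan_date = rep(t0 - 5 * 86400, n),
    assessment_scan_date = collected_1 + vec(scan_weeks) * 7 * 86400,
    sum_diameter_change_pct = vec(change_pct),
    progressed = vec(change_pct) >= 20
  )
}

# Tiny plate: triplicate wells for one target/sample.
toy_plate_rows <- function(sample_id = "P001-D1", patient_id = "P001",
                           draw_index = 1L, multiplex = 1L,
                           target = "SHORT80", cts = c(30, 30.1, 30.2),
                           dye = NULL) {
  if (is.null(dye)) {
    dye <- c(SHORT80 = "FAM", SHORT105 = "FAM", SVA265 = "Cy5", IPC172 = "HEX")[[target]]
  }
  tibble::tibble(
    well = sprintf("W%02d", seq_along(cts)),
    run_id = "R1",
    sample_id = sample_id, patient_id = patient_id,
    draw_index = draw_index, extraction = 1L,
    multiplex = multiplex, target = target, dye = dye,
    replicate = seq_along(cts), ct = cts
  )
}

# Exact-doubling curve used in closed-form quantification checks.
exact_curve <- function(intercept = 38, target = "SHORT80") {
  structure(
    list(target = target, slope = -1 / log10(2), intercept = intercept,
         r2 = 1, efficiency = 1, n = 12L),
    class = "standard_curve"
  )
}

# Brute-force AUC over all case-control pairs (independent oracle).
pair_counting_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  cases <- scores[labels]
  controls <- scores[!labels]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}
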
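#' Read a cohort manifest CSV
#'
#' The manifest is the per-patient exchange table: identifiers, draw
#' timestamps, treatment and scan dates, plasma volume, the imaging outcome
#' (percent change of the sum of target-lesion diameters) and the clinical
#' exclusion flags. Timestamps are ISO-8601 (date-only values are taken at
#' midnight UTC). A `progressed` column is derived from
#' `sum_diameter_change_pct >= 20` (boundary inclusive); a missing change
#' leaves the outcome missing, which is allowed at scoring time but not for
#' fitting or calibration.
#'
#' Rows that fail a type check (unparseable timestamp or number, receipt
#' before collection, draw 2 before draw 1) are kept and reported in a
#' warning — never silently dropped.
#'
#' @param path CSV file with a header row.
#' @return Manifest tibble, one row per patient.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("patient_id", "collected_at_1", "received_at_1",
                "collected_at_2", "received_at_2", "treatment_date",
                "baseline_scan_date", "assessment_scan_date")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("manifest is missing required column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- unique(raw$patient_id[duplicated(raw$patient_id)])
  if (length(dup)) {
    abort(paste0("duplicate patient_id in manifest: ", paste(dup, collapse = ", ")))
  }

  problems <- character()
  parse_col <- function(x, col, fn) {
    out <- fn(x)
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      problems <<- c(problems, sprintf("column %s, row(s) %s unparseable",
                                       col, paste(bad, collapse = ",")))
    }
    out
  }
  ts_cols <- c(required[-1])
  out <- raw
  for (cc in ts_cols) out[[cc]] <- parse_col(raw[[cc]], cc, parse_timestamp)
  out$plasma_volume_uL <- if ("plasma_volume_uL" %in% names(raw)) {
    parse_col(raw$plasma_volume_uL, "plasma_volume_uL", function(x) suppressWarnings(as.numeric(x)))
  } else {
    500
  }
  out$sum_diameter_change_pct <- if ("sum_diameter_change_pct" %in% names(raw)) {
    parse_col(raw$sum_diameter_change_pct, "sum_diameter_change_pct",
              function(x) suppressWarnings(as.numeric(x)))
  } else {
    NA_real_
  }
  if (!"cancer_type" %in% names(out)) out$cancer_type <- "other"
  for (fl in c("secondary_malignancy", "autoimmune_treatment", "recent_dvt_pe_sepsis")) {
    out[[fl]] <- if (fl %in% names(raw)) {
      parse_col(raw[[fl]], fl, function(x) as.logical(toupper(x)))
    } else {
      FALSE
    }
  }
  out$progressed <- out$sum_diameter_change_pct >= 20

  bad_order <- which(!is.na(out$collected_at_1) & !is.na(out$collected_at_2) &
                       out$collected_at_2 <= out$collected_at_1)
  if (length(bad_order)) {
    problems <- c(problems, sprintf("row(s) %s: draw 2 does not follow draw 1",
                                    paste(bad_order, collapse = ",")))
  }
  for (d in 1:2) {
    cc <- out[[paste0("collected_at_", d)]]
    rr <- out[[paste0("received_at_", d)]]
    bad <- which(!is.na(cc) & !is.na(rr) & rr < cc)
    if (length(bad)) {
      problems <- c(problems, sprintf("row(s) %s: draw %d received before collection",
                                      paste(bad, collapse = ","), d))
    }
  }
  if (length(problems)) {
    warn(paste0("manifest type-check problems (rows kept):\n  ",
                paste(problems, collapse = "\n  ")))
  }
  as_tibble(out)
}

parse_timestamp <- function(x) {
  out <- suppressWarnings(readr::parse_datetime(x))
  date_only <- is.na(out) & !is.na(x)
  if (any(date_only)) {
    d <- suppressWarnings(readr::parse_date(x[date_only]))
    out[date_only] <- as.POSIXct(d, tz = "UTC")
  }
  attr(out, "problems") <- NULL
  out
}

#' Read a qPCR plate export CSV
#'
#' Expects instrument-style columns `well`, `sample_id`, `multiplex`,
#' `target`, `dye`, `replicate`, `ct` (extras such as `run_id`,
#' `patient_id`, `draw_index`, `extraction` are kept; `patient_id` and
#' `draw_index` are reconstructed from `sample_id` of the form
#' `"<patient>-D<draw>"` when absent). `"Undetermined"` and empty Ct fields
#' are parsed as missing — a well that never crossed threshold, not a zero.
#' Dye-target pairing is validated (FAM reports the short amplicons, Cy5 the
#' SVA amplicon, HEX the IPC); mismatched rows are flagged `qc_ok = FALSE`
#' and collected into the `qc_errors` attribute (see
#' [plate_qc_errors()]).
#'
#' @param path CSV file.
#' @return Plate tibble.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) abort(paste0("plate file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("well", "sample_id", "multiplex", "target", "dye", "replicate", "ct")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("plate is missing required column(s): ", paste(miss, collapse = ", ")))
  }
  out <- raw
  out$multiplex <- as.integer(raw$multiplex)
  out$replicate <- as.integer(raw$replicate)
  ct_chr <- trimws(raw$ct)
  ct_chr[ct_chr %in% c("", "Undetermined", "undetermined", "NA")] <- NA
  out$ct <- suppressWarnings(as.numeric(ct_chr))
  if ("extraction" %in% names(raw)) out$extraction <- as.integer(raw$extraction)
  if ("draw_index" %in% names(raw)) out$draw_index <- as.integer(raw$draw_index)
  if (!"patient_id" %in% names(out) || !"draw_index" %in% names(out)) {
    m <- regmatches(out$sample_id, regexec("^(.*)-D([12])(-E[0-9]+)?$", out$sample_id))
    if (!"patient_id" %in% names(out)) {
      out$patient_id <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, character(1))
    }
    if (!"draw_index" %in% names(out)) {
      out$draw_index <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_, integer(1))
    }
  }

  expected_dye <- ps_dye_for_target(out$target)
  mismatch <- !is.na(expected_dye) & out$dye != expected_dye
  out$qc_ok <- !mismatch
  out <- as_tibble(out)
  qc_errors <- new_verdict(
    subject = out$well[mismatch],
    rule = "dye_target_pairing",
    passed = FALSE,
    detail = sprintf("target %s reported with dye %s (expected %s)",
                     out$target[mismatch], out$dye[mismatch], expected_dye[mismatch])
  )
  attr(out, "qc_errors") <- qc_errors
  out
}

#' @rdname read_plate
#' @param plate A plate tibble from [read_plate()].
#' @export
plate_qc_errors <- function(plate) {
  err <- attr(plate, "qc_errors")
  if (is.null(err)) new_verdict(character(), character(), logical()) else err
}

#' Run the full Progression Score pipeline
#'
#' Chains every stage — cohort acquisition (synthetic or from files),
#' eligibility gating, optional plate quantification with run QC,
#' fragmentomic feature derivation, six-model evaluation and selection,
#' bootstrap expected-PPV cut-point calibration, scoring, calls and
#' performance. Deterministic given the inputs and `seed`. Any stage's hard
#' error aborts with the stage name.
#'
#' @param config A list (or path to a JSON file) with entries:
#'   * `scenario`: a [ps_scenario()] or a list of its arguments (used when
#'     no `manifest_path` is given);
#'   * `seed`: integer, drives every random stage;
#'   * `simulate_plates`: logical; route the synthetic cohort through
#'     simulated plates, standard-curve fitting and run QC instead of using
#'     concentrations directly (default `FALSE`);
#'   * `manifest_path`, `profiles_path`, `plate_path`,
#'     `standard_points_path`: CSV inputs for a recorded cohort;
#'   * `B`, `min_ppv`, `thresholds`: calibration tunables (defaults 1000,
#'     0.99, 0:100);
#'   * `parsimony_on_flag`: model-selection behavior (default `TRUE`);
#'   * `max_transit_hours`, `ipc_max_shift_ct`, `sva_max_rel_diff`: gating
#'     tunables;
#'   * `out_dir`: when set, result CSV/JSON files and a run log are written
#'     there.
#' @return A `ps_run` list: `manifest`, `exclusions`, `features`,
#'   `model_table`, `best` (selected row), `calibration`, `cutpoint`,
#'   `calls`, `performance`, `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(
      scenario = ps_scenario(), seed = 1L, simulate_plates = FALSE,
      manifest_path = NULL, profiles_path = NULL, plate_path = NULL,
      standard_points_path = NULL,
      B = 1000, min_ppv = 0.99, thresholds = 0:100,
      parsimony_on_flag = TRUE,
      max_transit_hours = 120, ipc_max_shift_ct = 1.0, sva_max_rel_diff = 0.30,
      out_dir = NULL
    ),
    config
  )
  if (!inherits(cfg$scenario, "ps_scenario")) {
    cfg$scenario <- do.call(ps_scenario, as.list(cfg$scenario))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # --- acquire -------------------------------------------------------------
  truth <- NULL
  plate <- NULL
  acquired <- stage("acquire", {
    if (!is.null(cfg$manifest_path)) {
      manifest <- read_manifest(cfg$manifest_path)
      profiles <- if (!is.null(cfg$profiles_path)) {
        readr::read_csv(cfg$profiles_path, show_col_types = FALSE, progress = FALSE)
      } else {
        NULL
      }
      if (!is.null(cfg$plate_path)) plate <- read_plate(cfg$plate_path)
      list(manifest = manifest, profiles = profiles)
    } else {
      cohort <- generate_cohort(cfg$scenario, seed = cfg$seed)
      truth <- cohort$truth
      if (isTRUE(cfg$simulate_plates)) {
        plate <- simulate_plate(cohort$profiles, default_standard_curves(),
                                 cfg$scenario, inhibited = cohort$truth$inhibited)
        list(manifest = cohort$manifest, profiles = NULL)
      } else {
        list(manifest = cohort$manifest, profiles = cohort$profiles)
      }
    }
  })
  manifest <- acquired$manifest
  if (nrow(manifest) == 0) abort("no analyzable patients: empty cohort")

  # --- gate ----------------------------------------------------------------
  gated <- stage("qc_gating", {
    verdicts <- bind_rows(
      check_transit_time(manifest, max_hours = cfg$max_transit_hours),
      check_draw_window(manifest),
      check_scan_window(manifest),
      check_clinical_flags(manifest)
    )
    apply_exclusions(manifest, verdicts)
  })
  analyzable <- gated$analyzable
  exclusions <- gated$exclusions
  if (nrow(analyzable) == 0) abort("no analyzable patients: all excluded by gating")

  # --- quantify ------------------------------------------------------------
  profiles <- stage("qpcr_quant", {
    if (!is.null(plate)) {
      curves <- if (!is.null(cfg$standard_points_path)) {
        pts <- readr::read_csv(cfg$standard_points_path, show_col_types = FALSE,
                               progress = FALSE)
        split(pts, pts$target) |> lapply(fit_standard_curve)
      } else {
        # synthetic route: fit curves from a simulated dilution series
        lapply(default_standard_curves(), function(cu) {
          fit_standard_curve(simulate_standard_points(cu, ct_noise_sd = cfg$scenario$ct_noise_sd))
        })
      }
      ipc <- check_ipc_shift(plate, max_shift_ct = cfg$ipc_max_shift_ct)
      sva <- sva_quantities(plate, curves)
      svav <- check_sva_concordance(sva$q_mpx1, sva$q_mpx2, subject = sva$sample_id,
                                    max_rel_diff = cfg$sva_max_rel_diff)
      run_fail <- bind_rows(ipc, svav) |> filter(!.data$passed)
      fail_pid <- unique(sub("-D[12]$", "", run_fail$subject))
      exclusions <- bind_rows(
        exclusions,
        run_fail |> transmute(patient_id = sub("-D[12]$", "", .data$subject),
                              rule = .data$rule, detail = .data$detail)
      )
      analyzable <- analyzable |> filter(!.data$patient_id %in% fail_pid)
      ok_plate <- plate |>
        filter(.data$patient_id %in% analyzable$patient_id)
      if ("qc_ok" %in% names(ok_plate)) ok_plate <- ok_plate |> filter(.data$qc_ok)
      build_profiles(ok_plate, curves,
                     plasma_uL = cfg$scenario$plasma_volume_uL,
                     eluate_uL = cfg$scenario$eluate_uL,
                     reaction_template_uL = cfg$scenario$reaction_template_uL)
    } else {
      acquired$profiles |> filter(.data$patient_id %in% analyzable$patient_id)
    }
  })
  quant_fail <- grepl("unquantifiable", profiles$flags %||% "")
  if (any(quant_fail)) {
    exclusions <- bind_rows(
      exclusions,
      tibble(patient_id = profiles$patient_id[quant_fail],
             rule = "unquantifiable", detail = "missing target in a draw")
    )
    profiles <- profiles[!quant_fail, , drop = FALSE]
  }
  if (nrow(profiles) == 0) abort("no analyzable patients: none quantifiable")

  # --- features ------------------------------------------------------------
  features <- stage("fragment_features", {
    derive_features(profiles) |>
      left_join(analyzable |> select("patient_id", "progressed"), by = "patient_id")
  })

  # --- model ---------------------------------------------------------------
  fitted <- features |> filter(!is.na(.data$progressed))
  if (nrow(fitted) == 0) abort("no analyzable patients: no outcomes for fitting")
  model_table <- stage("progression_model", evaluate_models(fitted))
  best <- stage("progression_model",
                select_best(model_table, parsimony_on_flag = cfg$parsimony_on_flag))
  best_fit <- best$fit[[1]]

  # --- calibrate -----------------------------------------------------------
  calibration <- stage("calibration", {
    bootstrap_expected_ppv(
      fitted, predictors = best_fit$predictors,
      B = cfg$B, thresholds = cfg$thresholds,
      seed = (cfg$seed %% 1000003L) + 1L
    )
  })
  cutpoint <- stage("calibration", select_cutpoint(calibration, min_ppv = cfg$min_ppv))
  calibration$min_ppv <- cfg$min_ppv
  calibration$selected_cutpoint <- cutpoint

  # --- score ---------------------------------------------------------------
  calls <- stage("score", {
    features |>
      mutate(
        ps = predict(best_fit, newdata = features, type = "ps"),
        call = classify_ps(.data$ps, cutpoint)
      ) |>
      select("patient_id", "ps", "call", "progressed")
  })
  performance <- stage("score", {
    suppressWarnings(assay_performance(calls$call, calls$progressed))
  })

  run <- structure(
    list(
      manifest = manifest, analyzable = analyzable, exclusions = exclusions,
      profiles = profiles, features = features,
      model_table = model_table |> select(-"fit"), best = best,
      fit = best_fit, calibration = calibration, cutpoint = cutpoint,
      calls = calls, performance = performance, truth = truth,
      config = cfg,
      log = list(
        package_version = as.character(packageVersion("fragps")),
        r_version = as.character(getRversion()),
        seed = cfg$seed,
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
        n_input = nrow(manifest), n_analyzable = nrow(profiles),
        selected_model = best$model, cutpoint = cutpoint
      )
    ),
    class = "ps_run"
  )
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ps_run <- function(x, ...) {
  cat(sprintf(
    paste0("Progression Score run: %d patients (%d analyzable, %d exclusion rows)\n",
           "  selected model: %s (training AUC %.3f)\n",
           "  cut-point: %g (expected PPV target %g); %d progression call(s)\n"),
    nrow(x$manifest), nrow(x$profiles), nrow(x$exclusions),
    x$best$model, x$best$auc,
    x$cutpoint, x$calibration$min_ppv, sum(x$calls$call == "progression")
  ))
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Emits the exchange files of a run: `features.csv`, `model_table.csv`,
#' `calls.csv`, `performance.csv`, `exclusions.csv`, `calibration.json`
#' (curve + cut-point + seed) and `run_log.json` (versions, seed, sizes).
#'
#' @param run A `ps_run` from [run_pipeline()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$features, file.path(out_dir, "features.csv"))
  readr::write_csv(run$model_table, file.path(out_dir, "model_table.csv"))
  readr::write_csv(run$calls, file.path(out_dir, "calls.csv"))
  readr::write_csv(run$performance, file.path(out_dir, "performance.csv"))
  readr::write_csv(run$exclusions, file.path(out_dir, "exclusions.csv"))
  cal <- run$calibration
  jsonlite::write_json(
    list(curve = cal$curve, B = cal$B, seed = cal$seed, model = cal$model,
         min_ppv = cal$min_ppv, selected_cutpoint = cal$selected_cutpoint),
    file.path(out_dir, "calibration.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(run$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
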
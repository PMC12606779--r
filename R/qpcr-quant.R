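#' Fit a qPCR standard curve
#'
#' Least-squares fit of the universal log-linear qPCR calibration
#' `Ct = slope * log10(quantity) + intercept` to dilution-series points.
#' Amplification efficiency is `10^(-1/slope) - 1`; a perfectly doubling
#' reaction has slope -3.3219 and efficiency 1.
#'
#' @param points Data frame with columns `quantity` (known template copies,
#'   > 0) and `ct`; a `target` column, if present, is recorded on the curve.
#' @param min_r2 Minimum acceptable r-squared; a lower fit is kept but
#'   flagged with a warning (conventional acceptance is 0.98).
#' @return An object of class `standard_curve` with fields `target`,
#'   `slope`, `intercept`, `r2`, `efficiency`, `n`.
#' @examples
#' pts <- tibble::tibble(quantity = 10^(1:4), ct = 38 - 3.3219 * (1:4))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points, min_r2 = 0.98) {
  if (!all(c("quantity", "ct") %in% names(points))) {
    abort("standard-curve points need columns 'quantity' and 'ct'")
  }
  points <- points[!is.na(points$ct), , drop = FALSE]
  if (any(points$quantity <= 0)) abort("standard quantities must be > 0")
  if (length(unique(points$quantity)) < 3) {
    abort("need at least 3 distinct standard quantities to fit a curve")
  }
  fit <- lm(ct ~ log10(quantity), data = points)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("inverted curve: Ct must decrease with template quantity")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((points$ct - mean(points$ct))^2)
  if (r2 < min_r2) {
    warn(sprintf("standard curve r2 = %.4f below minimum %.2f", r2, min_r2))
  }
  structure(
    list(
      target = if ("target" %in% names(points)) as.character(points$target[1]) else NA_character_,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r2 = r2,
      efficiency = 10^(-1 / slope) - 1,
      n = nrow(points)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve%s: Ct = %.4f * log10(q) + %.3f  (eff %.1f%%, r2 %.4f, n = %d)\n",
    if (is.na(x$target)) "" else paste0(" [", x$target, "]"),
    x$slope, x$intercept, 100 * x$efficiency, x$r2, x$n
  ))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    target = x$target, slope = x$slope, intercept = x$intercept,
    r2 = x$r2, efficiency = x$efficiency, n = x$n
  )
}

#' Aggregate triplicate Ct values
#'
#' Mean of the non-missing replicate Cts with replicate-quality flags:
#' `high-scatter` when the non-missing range exceeds `max_range` Ct,
#' `dropout` when at least one replicate failed to amplify, and
#' `no-amplification` (with a missing mean) when none did.
#'
#' @param cts Numeric vector of 1-3 replicate Cts; `NA` marks a well that
#'   never crossed threshold.
#' @param max_range Replicate scatter bound in Ct.
#' @return One-row tibble with `mean_ct` and `flags`
#'   (semicolon-separated, `""` when clean).
#' @export
aggregate_replicates <- function(cts, max_range = 0.5) {
  if (length(cts) < 1 || length(cts) > 3) abort("expected 1-3 replicate Ct values")
  ok <- !is.na(cts)
  flags <- character()
  if (!any(ok)) {
    return(tibble(mean_ct = NA_real_, flags = "no-amplification"))
  }
  if (any(!ok)) flags <- c(flags, "dropout")
  if (sum(ok) > 1 && diff(range(cts[ok])) > max_range) flags <- c(flags, "high-scatter")
  tibble(mean_ct = mean(cts[ok]), flags = paste(flags, collapse = ";"))
}

#' Absolute quantity from a Ct and a standard curve
#'
#' Inverts the calibration: `q = 10^((ct - intercept) / slope)`, strictly
#' decreasing in Ct for any valid (negative-slope) curve. A missing Ct means
#' no amplification within the cycle count and maps to quantity 0.
#'
#' @param ct Numeric vector of (mean) Ct values.
#' @param curve A [fit_standard_curve()] object.
#' @return Template quantities in the reaction, same units as the standards.
#' @export
quantify_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- 10^((ct - curve$intercept) / curve$slope)
  q[is.na(ct)] <- 0
  q
}

#' Convert a per-reaction quantity to plasma concentration
#'
#' A reaction receives `reaction_template_uL` of an eluate of `eluate_uL`
#' extracted from `plasma_uL` of plasma, so
#' `copies/mL plasma = q * (eluate_uL / reaction_template_uL) / (plasma_uL / 1000)`.
#' Defaults follow the assay protocol: 2 uL template from a 60 uL eluate of
#' 500 uL plasma, i.e. 1 copy/reaction = 60 copies/mL.
#'
#' @param q_reaction Copies per reaction.
#' @param reaction_template_uL,eluate_uL,plasma_uL Volumes, all > 0.
#' @return Copies per mL plasma.
#' @export
to_plasma_concentration <- function(q_reaction, reaction_template_uL = 2,
                                    eluate_uL = 60, plasma_uL = 500) {
  if (any(c(reaction_template_uL, eluate_uL, plasma_uL) <= 0)) {
    abort("all volumes must be positive")
  }
  q_reaction * (eluate_uL / reaction_template_uL) / (plasma_uL / 1000)
}

#' Quantify a plate into per-patient fragment profiles
#'
#' Runs the full quantification path for the two informative targets:
#' replicate aggregation, curve inversion, unit conversion, and averaging of
#' duplicate extractions at the concentration level. The >80 bp
#' concentration (SM) comes from the multiplex-1 80 bp amplicon, the >105 bp
#' concentration (MM) from the multiplex-2 105 bp amplicon, each per draw.
#'
#' @param plate Plate tibble with columns `patient_id`, `draw_index`,
#'   `extraction`, `multiplex`, `target`, `replicate`, `ct` (see
#'   [read_plate()] / [simulate_plate()]).
#' @param curves Named list of `standard_curve` objects with entries
#'   `SHORT80` and `SHORT105` (run-matched).
#' @param plasma_uL Plasma input volume per extraction.
#' @param eluate_uL,reaction_template_uL Protocol volumes, see
#'   [to_plasma_concentration()].
#' @return Tibble `patient_id`, `SM1`, `MM1`, `SM2`, `MM2`, `flags`.
#'   Patients lacking an informative target in either draw get `NA`
#'   concentrations and the flag `unquantifiable`; drop them before
#'   modeling.
#' @export
build_profiles <- function(plate, curves, plasma_uL = 500, eluate_uL = 60,
                           reaction_template_uL = 2) {
  need <- c("patient_id", "draw_index", "multiplex", "target", "replicate", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss)) abort(paste0("plate is missing column(s): ", paste(miss, collapse = ", ")))
  if (!"extraction" %in% names(plate)) plate$extraction <- 1L
  for (tg in c("SHORT80", "SHORT105")) {
    if (!inherits(curves[[tg]], "standard_curve")) {
      abort(paste0("curves must contain a standard_curve for ", tg))
    }
  }

  informative <- plate |>
    filter((.data$target == "SHORT80" & .data$multiplex == 1) |
             (.data$target == "SHORT105" & .data$multiplex == 2))

  conc <- informative |>
    group_by(.data$patient_id, .data$draw_index, .data$extraction, .data$target) |>
    summarise(agg = list(aggregate_replicates(.data$ct)), .groups = "drop") |>
    tidyr::unnest("agg") |>
    mutate(
      quantity = purrr::map2_dbl(
        .data$mean_ct, .data$target,
        function(ct, tg) quantify_ct(ct, curves[[tg]])
      ),
      conc = to_plasma_concentration(
        .data$quantity,
        reaction_template_uL = reaction_template_uL,
        eluate_uL = eluate_uL, plasma_uL = plasma_uL
      )
    ) |>
    # duplicate extractions averaged at the concentration level
    group_by(.data$patient_id, .data$draw_index, .data$target) |>
    summarise(
      conc = mean(.data$conc),
      flags = paste(unique(.data$flags[.data$flags != ""]), collapse = ";"),
      n_extractions = dplyr::n(),
      .groups = "drop"
    )

  wide <- conc |>
    mutate(var = paste0(
      ifelse(.data$target == "SHORT80", "SM", "MM"), .data$draw_index
    )) |>
    select("patient_id", "var", "conc") |>
    tidyr::pivot_wider(names_from = "var", values_from = "conc")

  flag_tbl <- conc |>
    group_by(.data$patient_id) |>
    summarise(
      flags = paste(unique(.data$flags[.data$flags != ""]), collapse = ";"),
      .groups = "drop"
    )

  out <- wide |> left_join(flag_tbl, by = "patient_id")
  for (v in c("SM1", "MM1", "SM2", "MM2")) {
    if (!v %in% names(out)) out[[v]] <- NA_real_
  }
  incomplete <- is.na(out$SM1) | is.na(out$MM1) | is.na(out$SM2) | is.na(out$MM2)
  out$flags[incomplete] <- vapply(out$flags[incomplete], function(f) {
    paste(c(if (nzchar(f)) f, "unquantifiable"), collapse = ";")
  }, character(1))
  out[incomplete, c("SM1", "MM1", "SM2", "MM2")] <- NA_real_
  out |> select("patient_id", "SM1", "MM1", "SM2", "MM2", "flags")
}

#' Per-sample SVA quantities across the two multiplexes
#'
#' Aggregates the SVA wells of each multiplex per patient/draw and quantifies
#' them with the SVA curve, yielding the pair used by
#' [check_sva_concordance()].
#'
#' @inheritParams build_profiles
#' @return Tibble `patient_id`, `draw_index`, `sample_id`, `q_mpx1`, `q_mpx2`.
#' @export
sva_quantities <- function(plate, curves) {
  if (!inherits(curves[["SVA265"]], "standard_curve")) {
    abort("curves must contain a standard_curve for SVA265")
  }
  plate |>
    filter(.data$target == "SVA265") |>
    group_by(.data$patient_id, .data$draw_index, .data$multiplex) |>
    summarise(mean_ct = mean(.data$ct, na.rm = TRUE), .groups = "drop") |>
    mutate(
      mean_ct = ifelse(is.nan(.data$mean_ct), NA_real_, .data$mean_ct),
      q = quantify_ct(.data$mean_ct, curves[["SVA265"]])
    ) |>
    select(-"mean_ct") |>
    tidyr::pivot_wider(
      names_from = "multiplex", values_from = "q", names_prefix = "q_mpx"
    ) |>
    mutate(sample_id = paste0(.data$patient_id, "-D", .data$draw_index))
}
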
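#' Scenario configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of the generator. Concentrations are
#' copies per mL plasma and are drawn log-normally (cfDNA concentrations are
#' positive and right-skewed). The defaults describe the study regime the
#' pipeline is meant for: a cohort of 128 stage IV patients with roughly 16%
#' imaging-confirmed progression, a short-fragment excess that jumps in
#' progressors between the baseline and the 12-21 day post-treatment draw,
#' and low-rate pre-analytical artifacts (white-blood-cell lysis spikes, PCR
#' inhibition, non-cancer cfDNA elevation events).
#'
#' @param n_patients Cohort size.
#' @param prevalence Progression probability per patient.
#' @param mm_meanlog,mm_sdlog Log-normal parameters of the baseline >105 bp
#'   concentration MM1 (copies/mL).
#' @param frag_meanlog,frag_sdlog Log-normal parameters of the baseline
#'   short-fragment excess Frag1 = SM1 - MM1.
#' @param frag_noise_sdlog Draw-to-draw multiplicative noise (sd of log) on
#'   the short-fragment excess of non-progressing disease.
#' @param effect_meanlog,effect_sdlog Log-normal parameters of the additive
#'   progression effect on the draw-2 short-fragment excess (copies/mL).
#'   The wide default spread makes some progressors nearly silent at the
#'   second draw, so discrimination is strong but imperfect — a monitored
#'   cohort calls a fraction of true progressors, it does not separate
#'   perfectly.
#' @param mm_drift_sdlog Multiplicative drift (sd of log) of the >105 bp
#'   concentration between draws.
#' @param lysis_rate Per-draw probability of a white-blood-cell lysis event;
#'   the event adds the same genomic-DNA quantity to the >80 bp and >105 bp
#'   classes of that draw, inflating raw concentrations by a factor drawn
#'   from `lysis_fold_range` while leaving the fragmentomic difference
#'   unchanged.
#' @param lysis_fold_range Length-2 range of the raw fold-inflation.
#' @param inhibitor_rate Per-sample probability of PCR inhibition on the
#'   plate; `inhibitor_ct_shift` is added to every target's Ct including the
#'   internal positive control.
#' @param inhibitor_ct_shift Ct shift of an inhibited sample.
#' @param noncancer_event_rate Probability of a non-cancer cfDNA elevation
#'   event (acute inflammation, infarction, infection ...) between the
#'   draws. Such events release predominantly mononucleosomal (~166 bp)
#'   DNA, which amplifies in both the >80 bp and >105 bp assays, so the
#'   event adds a common spike to both classes of draw 2 — raising total
#'   cfDNA by about `noncancer_fold` — of which only `noncancer_short_frac`
#'   is sub-105 bp and lands in the short class alone.
#' @param noncancer_fold Raw cfDNA elevation factor of such an event.
#' @param noncancer_short_frac Sub-105 bp fraction of the event DNA.
#' @param ct_noise_sd Per-well replicate Ct noise (sd).
#' @param ipc_copies_per_reaction Spiked IPC template per reaction.
#' @param sva_fraction Long-fragment (265 bp amplifiable) concentration as a
#'   fraction of the >105 bp concentration, used for the SVA wells.
#' @param plasma_volume_uL,eluate_uL,reaction_template_uL Protocol volumes.
#' @param transit_violation_rate,draw_window_violation_rate,scan_window_violation_rate
#'   Fractions of patients generated to violate the corresponding
#'   eligibility gate (0 by default; raise them to exercise the gating).
#' @return A validated list of class `ps_scenario`.
#' @export
ps_scenario <- function(n_patients = 128,
                        prevalence = 20 / 128,
                        mm_meanlog = log(2000), mm_sdlog = 0.7,
                        frag_meanlog = log(250), frag_sdlog = 0.8,
                        frag_noise_sdlog = 0.25,
                        effect_meanlog = log(600), effect_sdlog = 1.3,
                        mm_drift_sdlog = 0.15,
                        lysis_rate = 0.03, lysis_fold_range = c(2, 10),
                        inhibitor_rate = 0.02, inhibitor_ct_shift = 2.5,
                        noncancer_event_rate = 0.02, noncancer_fold = 3,
                        noncancer_short_frac = 0.05,
                        ct_noise_sd = 0.15,
                        ipc_copies_per_reaction = 1000,
                        sva_fraction = 0.6,
                        plasma_volume_uL = 500, eluate_uL = 60,
                        reaction_template_uL = 2,
                        transit_violation_rate = 0,
                        draw_window_violation_rate = 0,
                        scan_window_violation_rate = 0) {
  sc <- as.list(environment())
  rates <- c(
    sc$prevalence, sc$lysis_rate, sc$inhibitor_rate, sc$noncancer_event_rate,
    sc$transit_violation_rate, sc$draw_window_violation_rate,
    sc$scan_window_violation_rate
  )
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (sc$n_patients < 2) abort("n_patients must be at least 2")
  sds <- c(sc$mm_sdlog, sc$frag_sdlog, sc$frag_noise_sdlog, sc$effect_sdlog,
           sc$mm_drift_sdlog, sc$ct_noise_sd)
  if (any(sds < 0)) abort("standard deviations must be non-negative")
  if (length(sc$lysis_fold_range) != 2 || any(sc$lysis_fold_range < 1) ||
      diff(sc$lysis_fold_range) < 0) {
    abort("lysis_fold_range must be an ascending pair of factors >= 1")
  }
  structure(sc, class = "ps_scenario")
}

#' Reference standard curves for the four qPCR targets
#'
#' Perfect-efficiency calibration curves (slope -3.3219, i.e. exact doubling
#' per cycle) with target-specific intercepts, used both to simulate plates
#' and as the truth for standard-point simulation.
#'
#' @return Named list of `standard_curve` objects
#'   (`SHORT80`, `SHORT105`, `SVA265`, `IPC172`).
#' @export
default_standard_curves <- function() {
  make <- function(target, intercept) {
    structure(
      list(target = target, slope = -1 / log10(2), # -3.3219, doubling per cycle
           intercept = intercept, r2 = 1,
           efficiency = 1, n = NA_integer_),
      class = "standard_curve"
    )
  }
  list(
    SHORT80 = make("SHORT80", 38),
    SHORT105 = make("SHORT105", 38),
    SVA265 = make("SVA265", 37),
    IPC172 = make("IPC172", 38)
  )
}

#' Simulate a dilution series for standard-curve fitting
#'
#' @param curve True `standard_curve` generating the points.
#' @param quantities Standard template quantities (copies/reaction).
#' @param n_reps Replicates per level.
#' @param ct_noise_sd Per-well Ct noise.
#' @return Tibble `target`, `quantity`, `ct` ready for
#'   [fit_standard_curve()].
#' @export
simulate_standard_points <- function(curve, quantities = 10^(1:5), n_reps = 3,
                                     ct_noise_sd = 0.15) {
  q <- rep(quantities, each = n_reps)
  tibble(
    target = curve$target,
    quantity = q,
    ct = curve$intercept + curve$slope * log10(q) + rnorm(length(q), 0, ct_noise_sd)
  )
}

#' Generate a synthetic monitored cohort
#'
#' Draws a complete cohort under a [ps_scenario()]: imaging outcome,
#' pre-artifact fragment concentrations at both draws, pre-analytical
#' artifact events, and eligibility-consistent timestamps. Progression acts
#' as an additive jump on the draw-2 short-fragment excess; lysis adds one
#' common genomic-DNA quantity to both size classes of the affected draw
#' (inflating raw concentrations but not their difference); a non-cancer
#' elevation event adds mononucleosome-dominated DNA to draw 2, raising both
#' classes with only a small short-only tail.
#'
#' @param scenario A [ps_scenario()].
#' @param seed Integer seed; the same scenario and seed reproduce the cohort
#'   exactly.
#' @return List of three tibbles: `manifest` (what the lab/CRO would ship),
#'   `profiles` (observed concentrations, artifacts included) and `truth`
#'   (pre-artifact concentrations and artifact flags — the recovery oracle,
#'   never an input to the pipeline).
#' @export
generate_cohort <- function(scenario = ps_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "ps_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_patients
  pid <- sprintf("P%04d", seq_len(n))

  progressed <- runif(n) < scenario$prevalence
  MM1 <- rlnorm(n, scenario$mm_meanlog, scenario$mm_sdlog)
  Frag1 <- rlnorm(n, scenario$frag_meanlog, scenario$frag_sdlog)
  SM1 <- MM1 + Frag1
  effect <- ifelse(progressed,
                   rlnorm(n, scenario$effect_meanlog, scenario$effect_sdlog), 0)
  Frag2 <- Frag1 * exp(rnorm(n, 0, scenario$frag_noise_sdlog)) + effect
  MM2 <- MM1 * exp(rnorm(n, 0, scenario$mm_drift_sdlog))

  noncancer <- runif(n) < scenario$noncancer_event_rate
  # event DNA is ~166 bp: a common additive spike to both size classes,
  # with only a small sub-105 bp tail perturbing the short-fragment excess
  spike <- ifelse(noncancer, (scenario$noncancer_fold - 1) * (MM2 + Frag2), 0)
  MM2 <- MM2 + spike * (1 - scenario$noncancer_short_frac)
  Frag2 <- Frag2 + spike * scenario$noncancer_short_frac
  SM2 <- MM2 + Frag2

  truth <- tibble(
    patient_id = pid, progressed = progressed, effect = effect,
    SM1 = SM1, MM1 = MM1, SM2 = SM2, MM2 = MM2,
    noncancer_event = noncancer
  )

  # observed concentrations: add lysis spikes per draw
  lysis1 <- runif(n) < scenario$lysis_rate
  lysis2 <- runif(n) < scenario$lysis_rate
  fold1 <- runif(n, scenario$lysis_fold_range[1], scenario$lysis_fold_range[2])
  fold2 <- runif(n, scenario$lysis_fold_range[1], scenario$lysis_fold_range[2])
  g1 <- ifelse(lysis1, SM1 * (fold1 - 1), 0)
  g2 <- ifelse(lysis2, SM2 * (fold2 - 1), 0)
  profiles <- tibble(
    patient_id = pid,
    SM1 = SM1 + g1, MM1 = MM1 + g1,
    SM2 = SM2 + g2, MM2 = MM2 + g2,
    flags = ""
  )
  truth$lysis_draw1 <- lysis1
  truth$lysis_draw2 <- lysis2
  truth$inhibited <- runif(n) < scenario$inhibitor_rate

  manifest <- synth_manifest(pid, progressed, scenario)
  list(manifest = manifest, profiles = profiles, truth = truth)
}

synth_manifest <- function(pid, progressed, scenario) {
  n <- length(pid)
  base <- as.POSIXct("2024-03-01 09:00:00", tz = "UTC")
  treatment <- base + ((seq_len(n) - 1) %% 45) * 86400
  collected_1 <- treatment - runif(n, 24, 47) * 3600
  transit1 <- runif(n, 24, 96)
  viol_t <- runif(n) < scenario$transit_violation_rate
  transit1[viol_t] <- runif(sum(viol_t), 121, 200)
  received_1 <- collected_1 + transit1 * 3600

  draw2_days <- runif(n, 12, 21)
  viol_d <- runif(n) < scenario$draw_window_violation_rate
  draw2_days[viol_d] <- runif(sum(viol_d), 22, 35)
  collected_2 <- treatment + draw2_days * 86400
  received_2 <- collected_2 + runif(n, 24, 96) * 3600

  scan_days <- runif(n, 9 * 7, 12 * 7)
  viol_s <- runif(n) < scenario$scan_window_violation_rate
  scan_days[viol_s] <- runif(sum(viol_s), 13 * 7, 16 * 7)

  tibble(
    patient_id = pid,
    cancer_type = sample(c("breast", "colorectal", "lung"), n, replace = TRUE),
    collected_at_1 = collected_1, received_at_1 = received_1,
    collected_at_2 = collected_2, received_at_2 = received_2,
    plasma_volume_uL = scenario$plasma_volume_uL,
    treatment_date = treatment,
    baseline_scan_date = treatment - runif(n, 3, 10) * 86400,
    assessment_scan_date = collected_1 + scan_days * 86400,
    sum_diameter_change_pct = ifelse(progressed, runif(n, 20, 80), runif(n, -30, 19.5)),
    progressed = progressed,
    secondary_malignancy = FALSE,
    autoimmune_treatment = FALSE,
    recent_dvt_pe_sepsis = FALSE
  )
}

#' Simulate qPCR plates from fragment profiles
#'
#' Emits triplicate wells for both multiplexes (multiplex 1: 80 bp ALU +
#' 265 bp SVA + IPC; multiplex 2: 105 bp ALU + 265 bp SVA + IPC) and
#' `n_extractions` duplicate extractions per draw. Per-reaction template
#' quantities follow the protocol volumes; each well's Ct is the calibration
#' curve evaluated at that quantity plus Gaussian noise, plus the inhibition
#' shift for inhibited samples (on every target including the IPC). A Ct
#' beyond 40 cycles is emitted as missing.
#'
#' @param profiles Profile tibble (`patient_id`, `SM1`, `MM1`, `SM2`,
#'   `MM2`).
#' @param curves Named list of `standard_curve`s, see
#'   [default_standard_curves()].
#' @param scenario A [ps_scenario()] (noise, volumes, IPC copies).
#' @param inhibited Logical per patient; defaults to all `FALSE` (inhibition
#'   sampling belongs to [generate_cohort()]'s truth table).
#' @param n_extractions Duplicate extractions per draw.
#' @param run_id Run label carried on every well.
#' @param max_cycles Cycle count beyond which no Ct is reported.
#' @return Plate tibble with columns `well`, `run_id`, `sample_id`,
#'   `patient_id`, `draw_index`, `extraction`, `multiplex`, `target`, `dye`,
#'   `replicate`, `ct`.
#' @export
simulate_plate <- function(profiles, curves, scenario = ps_scenario(),
                           inhibited = NULL, n_extractions = 2,
                           run_id = "R1", max_cycles = 40) {
  stopifnot(inherits(scenario, "ps_scenario"))
  if (is.null(inhibited)) inhibited <- rep(FALSE, nrow(profiles))
  if (length(inhibited) != nrow(profiles)) {
    abort("inhibited must have one entry per profile row")
  }

  long <- profiles |>
    mutate(.inhibited = inhibited) |>
    tidyr::pivot_longer(
      cols = c("SM1", "MM1", "SM2", "MM2"),
      names_to = c("class", "draw_index"),
      names_pattern = "(SM|MM)([12])",
      values_to = "conc"
    ) |>
    mutate(draw_index = as.integer(.data$draw_index)) |>
    tidyr::pivot_wider(names_from = "class", values_from = "conc") |>
    mutate(SVA = scenario$sva_fraction * .data$MM)

  grid <- long |>
    tidyr::crossing(
      extraction = seq_len(n_extractions),
      multiplex = 1:2,
      replicate = 1:3
    ) |>
    tidyr::crossing(slot = c("short", "long", "ipc")) |>
    mutate(
      target = dplyr::case_when(
        .data$slot == "short" & .data$multiplex == 1 ~ "SHORT80",
        .data$slot == "short" & .data$multiplex == 2 ~ "SHORT105",
        .data$slot == "long" ~ "SVA265",
        TRUE ~ "IPC172"
      ),
      conc = dplyr::case_when(
        .data$target == "SHORT80" ~ .data$SM,
        .data$target == "SHORT105" ~ .data$MM,
        .data$target == "SVA265" ~ .data$SVA,
        TRUE ~ NA_real_
      ),
      q = ifelse(
        .data$target == "IPC172",
        scenario$ipc_copies_per_reaction,
        .data$conc * (scenario$plasma_volume_uL / 1000) / scenario$eluate_uL *
          scenario$reaction_template_uL
      )
    )

  ct_hat <- purrr::map2_dbl(grid$q, grid$target, function(q, tg) {
    if (is.na(q) || q <= 0) return(NA_real_)
    curves[[tg]]$intercept + curves[[tg]]$slope * log10(q)
  })
  ct <- ct_hat + rnorm(nrow(grid), 0, scenario$ct_noise_sd) +
    ifelse(grid$.inhibited, scenario$inhibitor_ct_shift, 0)
  ct[is.na(ct_hat) | ct > max_cycles] <- NA_real_

  grid |>
    mutate(
      ct = ct,
      dye = ps_dye_for_target(.data$target),
      sample_id = paste0(.data$patient_id, "-D", .data$draw_index),
      run_id = run_id,
      well = sprintf("W%05d", dplyr::row_number())
    ) |>
    select("well", "run_id", "sample_id", "patient_id", "draw_index",
           "extraction", "multiplex", "target", "dye", "replicate", "ct")
}

#' Generate the non-cancer interference panel
#'
#' Emulates a specificity panel: adults sampled shortly after a qualifying
#' acute health event (default sizes: stroke 3, asthma hospitalization 2,
#' COPD exacerbation 3, diabetic ketoacidosis 3, severe IBD 4, myocardial
#' infarction 2, severe rheumatoid arthritis 5, severe seizure 3, viral
#' infection 5) plus nine healthy volunteers. Conditions elevate total cfDNA
#' at the second draw by a condition-specific factor. With
#' `elevation = "proportional"` (default) the event DNA is
#' mononucleosome-dominated and is counted by both the >80 bp and >105 bp
#' amplicons, so both measured classes inflate together (with only the
#' scenario's small sub-105 bp tail landing in the short class alone) and
#' the fragmentomic difference cancels. With `elevation = "short_only"` the
#' same quantity lands entirely in the >80 bp class, mimicking a
#' progression-like short-fragment gain.
#'
#' @param scenario A [ps_scenario()] (baseline concentration parameters).
#' @param conditions Tibble `condition`, `n`, `fold` overriding the default
#'   panel layout.
#' @param elevation How the event shows up in the draw-2 size classes.
#' @param seed Integer seed.
#' @return Tibble `subject_id`, `condition`, `fold`, `SM1`, `MM1`, `SM2`,
#'   `MM2`; score it with the cancer-trained model and compare via
#'   [compute_ps_change()].
#' @export
generate_noncancer_panel <- function(scenario = ps_scenario(),
                                     conditions = NULL,
                                     elevation = c("proportional", "short_only"),
                                     seed = NULL) {
  elevation <- match.arg(elevation)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conditions)) {
    conditions <- tibble(
      condition = c("healthy", "stroke", "asthma_hospitalization",
                    "copd_exacerbation", "diabetic_ketoacidosis", "ibd_severe",
                    "myocardial_infarction", "ra_severe", "seizure_severe",
                    "viral_infection"),
      n = c(9L, 3L, 2L, 3L, 3L, 4L, 2L, 5L, 3L, 5L),
      fold = c(1, 4, 1.5, 3, 2, 2, 4, 3, 2, 1.5)
    )
  }
  subj <- conditions |> tidyr::uncount(.data$n, .id = "k")
  m <- nrow(subj)
  MM1 <- rlnorm(m, scenario$mm_meanlog, scenario$mm_sdlog)
  Frag1 <- rlnorm(m, scenario$frag_meanlog, scenario$frag_sdlog)
  Frag2 <- Frag1 * exp(rnorm(m, 0, scenario$frag_noise_sdlog))
  MM2 <- MM1 * exp(rnorm(m, 0, scenario$mm_drift_sdlog))
  spike <- (subj$fold - 1) * (MM2 + Frag2) # event DNA raising total cfDNA
  if (elevation == "proportional") {
    # counted by both amplicons: both classes rise, the excess barely moves
    MM2 <- MM2 + spike * (1 - scenario$noncancer_short_frac)
    Frag2 <- Frag2 + spike * scenario$noncancer_short_frac
  } else {
    # the same quantity confined to the >80 bp class
    Frag2 <- Frag2 + spike
  }
  tibble(
    subject_id = sprintf("N%03d", seq_len(m)),
    condition = subj$condition,
    fold = subj$fold,
    SM1 = MM1 + Frag1, MM1 = MM1,
    SM2 = MM2 + Frag2, MM2 = MM2
  )
}
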
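test_that("scenario validation rejects impossible configurations", {
  expect_s3_class(ps_scenario(), "ps_scenario")
  expect_error(ps_scenario(prevalence = 1.2), "rates")
  expect_error(ps_scenario(n_patients = 1), "at least 2")
  expect_error(ps_scenario(mm_sdlog = -1), "non-negative")
  expect_error(ps_scenario(lysis_fold_range = c(10, 2)), "ascending")
})

test_that("the generator is seed-deterministic and hits the target prevalence", {
  a <- generate_cohort(ps_scenario(), seed = 5)
  b <- generate_cohort(ps_scenario(), seed = 5)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$profiles, generate_cohort(ps_scenario(), seed = 6)$profiles))

  # pooled prevalence across many cohorts sits inside the binomial 95% band
  set.seed(1000)
  n_rep <- 250
  hits <- vapply(seq_len(n_rep), function(s) {
    sum(generate_cohort(ps_scenario(n_patients = 128), seed = 1000 + s)$truth$progressed)
  }, numeric(1))
  p <- 20 / 128
  total <- n_rep * 128
  band <- qbinom(c(0.025, 0.975), total, p) / total
  expect_gt(mean(hits) / 128, band[1])
  expect_lt(mean(hits) / 128, band[2])
})

test_that("timestamps honor every eligibility gate by default and violate on demand", {
  co <- generate_cohort(ps_scenario(n_patients = 40), seed = 8)
  v <- dplyr::bind_rows(
    check_transit_time(co$manifest),
    check_draw_window(co$manifest),
    check_scan_window(co$manifest)
  )
  expect_true(all(v$passed))

  viol <- generate_cohort(
    ps_scenario(n_patients = 60, transit_violation_rate = 0.5,
                draw_window_violation_rate = 0.5, scan_window_violation_rate = 0.5),
    seed = 9
  )
  expect_gt(sum(!check_transit_time(viol$manifest)$passed), 0)
  expect_gt(sum(!check_draw_window(viol$manifest)$passed), 0)
  expect_gt(sum(!check_scan_window(viol$manifest)$passed), 0)
})

test_that("lysis inflates raw short-marker levels but not the fragment difference", {
  sc <- ps_scenario(n_patients = 200, lysis_rate = 1, prevalence = 0,
                    noncancer_event_rate = 0)
  co <- generate_cohort(sc, seed = 10)
  fold <- co$profiles$SM1 / co$truth$SM1
  expect_gt(mean(fold), 2) # raw >80 bp grossly inflated
  obs <- derive_features(co$profiles)
  true <- derive_features(co$truth)
  # the short-fragment excess is untouched by the common spike
  expect_equal(obs$Frag1, true$Frag1, tolerance = 1e-9)
  expect_equal(obs$FragDiff, true$FragDiff, tolerance = 1e-9)
})

test_that("a null progression effect yields chance-level discrimination", {
  sc <- ps_scenario(n_patients = 300, effect_meanlog = -Inf, lysis_rate = 0,
                    noncancer_event_rate = 0)
  co <- generate_cohort(sc, seed = 11)
  feats <- derive_features(co$profiles)
  feats$progressed <- co$truth$progressed
  fit <- suppressWarnings(fit_logistic(feats, c("MMDiff", "FragDiff")))
  expect_lt(abs(fit$training_auc - 0.5), 0.12)
})

test_that("an inhibited sample is caught by the IPC shift rule", {
  profiles <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:6),
    SM1 = 2400, MM1 = 1800, SM2 = 2600, MM2 = 1900
  )
  sc <- ps_scenario(inhibitor_ct_shift = 2.5, ct_noise_sd = 0.05)
  set.seed(12)
  plate <- simulate_plate(profiles, default_standard_curves(), sc,
                          inhibited = c(TRUE, rep(FALSE, 5)))
  v <- check_ipc_shift(plate)
  failed <- unique(sub("-D[12]$", "", v$subject[!v$passed]))
  expect_equal(failed, "P001")
})

test_that("quantities below the 40-cycle detection floor drop out", {
  profiles <- tibble::tibble(patient_id = "P001", SM1 = 0.05, MM1 = 0.01,
                             SM2 = 2400, MM2 = 1800)
  plate <- simulate_plate(profiles, default_standard_curves(),
                          ps_scenario(ct_noise_sd = 0), n_extractions = 1)
  d1_short <- dplyr::filter(plate, target == "SHORT80", draw_index == 1)
  expect_true(all(is.na(d1_short$ct)))
})

test_that("large cohorts recover the direction and scale of the configured effect", {
  sc <- ps_scenario(n_patients = 4000, prevalence = 0.3, lysis_rate = 0,
                    noncancer_event_rate = 0)
  co <- generate_cohort(sc, seed = 14)
  feats <- derive_features(co$profiles)
  feats$progressed <- co$truth$progressed
  fit <- suppressWarnings(fit_logistic(feats, "FragDiff"))
  expect_gt(fit$coefficients["FragDiff"], 0) # progression raises FragDiff
  expect_gt(fit$training_auc, 0.85)
  # progressor FragDiff centers near the configured median effect
  med_shift <- median(feats$FragDiff[feats$progressed]) -
    median(feats$FragDiff[!feats$progressed])
  expect_gt(med_shift, exp(sc$effect_meanlog) * 0.5)
  expect_lt(med_shift, exp(sc$effect_meanlog) * 2)
})

test_that("the default scenario can express the high-AUC study regime", {
  feats <- cohort_features(seed = 7)
  fit <- suppressWarnings(fit_logistic(feats, c("MMDiff", "FragDiff")))
  expect_gt(fit$training_auc, 0.9)
})

test_that("the interference panel reproduces the fragmentomic cancellation", {
  sc <- ps_scenario()
  feats <- cohort_features(seed = 15)
  fit <- suppressWarnings(fit_logistic(feats, c("MMDiff", "FragDiff")))

  ps_of <- function(panel) {
    predict(fit, newdata = derive_features(panel), type = "ps")
  }
  healthy <- generate_noncancer_panel(
    sc, conditions = tibble::tibble(condition = "healthy", n = 40L, fold = 1),
    seed = 16
  )
  healthy_mean <- mean(ps_of(healthy))
  expect_lt(abs(mean(compute_ps_change(ps_of(healthy), healthy_mean))), 1e-9)

  set.seed(17)
  prop <- generate_noncancer_panel(
    sc, conditions = tibble::tibble(condition = "mi", n = 40L, fold = 4),
    elevation = "proportional", seed = 17
  )
  set.seed(17)
  short <- generate_noncancer_panel(
    sc, conditions = tibble::tibble(condition = "mi", n = 40L, fold = 4),
    elevation = "short_only", seed = 17
  )
  ps_prop <- mean(compute_ps_change(ps_of(prop), healthy_mean))
  ps_short <- mean(compute_ps_change(ps_of(short), healthy_mean))
  # a short-only elevation mimics progression far more than a proportional one
  expect_gt(ps_short, 20)
  expect_lt(ps_prop, ps_short / 2)

  # default panel layout matches the published sizes
  panel <- generate_noncancer_panel(sc, seed = 18)
  sizes <- table(panel$condition)
  expect_equal(unname(sizes[["healthy"]]), 9)
  expect_equal(unname(sizes[["stroke"]]), 3)
  expect_equal(unname(sizes[["viral_infection"]]), 5)
  expect_equal(nrow(panel), 39)
})
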
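#' Progression Score from a model probability
#'
#' The Progression Score is the selected model's predicted progression
#' probability on a 0-100 scale, rounded to one decimal — a reporting scale
#' in the spirit of multigene recurrence scores.
#'
#' @param p Probabilities in \[0, 1\].
#' @return Scores in \[0, 100\], one decimal.
#' @export
ps_from_prob <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  round(100 * p, 1)
}

#' Bootstrap expected-PPV curve over candidate cut-points
#'
#' Estimates, for every candidate threshold, the positive predictive value
#' a progression call made at that threshold can be expected to achieve.
#' Each bootstrap iteration resamples the cohort with replacement, refits
#' the model on the resample (so model-coefficient uncertainty propagates
#' into the estimate), scores the resampled patients, and computes
#' `PPV_b(t) = TP / (TP + FP)` at every threshold; thresholds at which an
#' iteration makes no call contribute nothing at that threshold. The curve
#' reports the mean over defined iterations.
#'
#' @param data Feature table (predictors + outcome), the training cohort.
#' @param predictors Predictor column names of the selected model.
#' @param outcome Outcome column name.
#' @param B Number of bootstrap iterations.
#' @param thresholds Ascending candidate PS cut-points (default 0..100).
#' @param seed Integer seed making the curve reproducible.
#' @param refit Refit the model per resample (default). `FALSE` rescores
#'   with the full-cohort fit, propagating sampling but not model
#'   uncertainty.
#' @return A `ps_calibration` object: `curve` (tibble `threshold`,
#'   `expected_ppv`, `n_defined`), plus `B`, `seed`, `refit`, `model`, and
#'   `n` fields. Feed to [select_cutpoint()].
#' @export
bootstrap_expected_ppv <- function(data, predictors, outcome = "progressed",
                                   B = 1000, thresholds = 0:100, seed = NULL,
                                   refit = TRUE) {
  if (B < 1) abort("B must be at least 1")
  if (is.unsorted(thresholds)) abort("thresholds must be ascending")
  y <- as.logical(data[[outcome]])
  if (length(unique(y)) < 2) abort("degenerate outcome: need both classes")
  n <- nrow(data)
  if (!is.null(seed)) set.seed(seed)
  full_fit <- if (!refit) suppressWarnings(fit_logistic(data, predictors, outcome))
  nt <- length(thresholds)
  ppv_sum <- numeric(nt)
  ppv_n <- integer(nt)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (length(unique(yb)) < 2 && refit) next # unfittable resample
    boot <- data[idx, , drop = FALSE]
    fit_b <- if (refit) {
      tryCatch(suppressWarnings(fit_logistic(boot, predictors, outcome)),
               error = function(e) NULL)
    } else {
      full_fit
    }
    if (is.null(fit_b)) next
    ps_b <- ps_from_prob(predict(fit_b, newdata = boot, type = "prob"))
    # counts of calls / true calls at every threshold at once
    calls <- outer(ps_b, thresholds, ">=")
    n_call <- colSums(calls)
    n_tp <- colSums(calls & yb)
    defined <- n_call > 0
    ppv_sum[defined] <- ppv_sum[defined] + n_tp[defined] / n_call[defined]
    ppv_n[defined] <- ppv_n[defined] + 1L
  }
  structure(
    list(
      curve = tibble(
        threshold = thresholds,
        expected_ppv = ifelse(ppv_n > 0, ppv_sum / pmax(ppv_n, 1), NA_real_),
        n_defined = ppv_n
      ),
      B = B, seed = seed, refit = refit,
      model = paste(predictors, collapse = " + "),
      predictors = predictors, outcome = outcome, n = n,
      min_ppv = NA_real_, selected_cutpoint = NA_real_
    ),
    class = "ps_calibration"
  )
}

#' @export
print.ps_calibration <- function(x, ...) {
  cat(sprintf(
    "Bootstrap expected-PPV calibration (%s): B = %d, n = %d, %d thresholds%s\n",
    x$model, x$B, x$n, nrow(x$curve),
    if (is.na(x$selected_cutpoint)) "" else
      sprintf(", cut-point %g (PPV target %g)", x$selected_cutpoint, x$min_ppv)
  ))
  invisible(x)
}

#' @rdname bootstrap_expected_ppv
#' @param x A `ps_calibration`.
#' @param ... Unused.
#' @return `tidy()`: the expected-PPV curve as a tibble.
#' @method tidy ps_calibration
#' @export
tidy.ps_calibration <- function(x, ...) x$curve

#' Select the PS cut-point meeting an expected-PPV target
#'
#' Returns the smallest candidate threshold whose bootstrap expected PPV
#' meets `min_ppv` and stays at or above it at every larger threshold with a
#' defined estimate — the stability condition guards against isolated
#' upward blips in a curve that later dips back below target.
#'
#' @param calib A [bootstrap_expected_ppv()] object.
#' @param min_ppv Required expected PPV (fraction).
#' @return The selected cut-point (numeric scalar). Errors with the best
#'   achievable stable PPV when no threshold qualifies.
#' @export
select_cutpoint <- function(calib, min_ppv = 0.99) {
  stopifnot(inherits(calib, "ps_calibration"))
  cv <- calib$curve
  defined <- !is.na(cv$expected_ppv)
  if (!any(defined)) abort("calibration curve has no defined expected PPV")
  # running minimum over defined values from the right = worst PPV at >= t
  suffix_min <- rep(NA_real_, nrow(cv))
  running <- Inf
  for (i in rev(seq_len(nrow(cv)))) {
    if (defined[i]) running <- min(running, cv$expected_ppv[i])
    suffix_min[i] <- running
  }
  ok <- defined & suffix_min >= min_ppv
  if (!any(ok)) {
    abort(sprintf(
      "cannot meet PPV target %.3f: best achievable stable expected PPV is %.4f",
      min_ppv, max(suffix_min[defined])
    ))
  }
  cv$threshold[which(ok)[1]]
}

#' Classify Progression Scores against a cut-point
#'
#' @param ps Scores in \[0, 100\].
#' @param cutpoint Calibrated cut-point in \[0, 100\]; a score at the
#'   boundary calls progression.
#' @return Character vector: `"progression"` / `"likely non-progression"`.
#' @export
classify_ps <- function(ps, cutpoint) {
  if (any(ps < 0 | ps > 100, na.rm = TRUE)) abort("ps must lie in [0, 100]")
  if (cutpoint < 0 || cutpoint > 100) abort("cutpoint must lie in [0, 100]")
  ifelse(ps >= cutpoint, "progression", "likely non-progression")
}

#' Contingency performance of progression calls
#'
#' Cross-tabulates calls against the imaging outcome and reports the 2x2
#' counts with positive and negative predictive values. Patients with a
#' missing outcome are excluded with a warning (their count is reported in
#' the `n_missing_outcome` column). An undefined predictive value (no calls
#' in that margin) is `NA`.
#'
#' @param calls Character vector from [classify_ps()] (or logical,
#'   `TRUE` = progression call).
#' @param outcomes Logical imaging outcome (`TRUE` = progressed); may
#'   contain `NA`.
#' @return One-row tibble: `n_called`, `n_not_called`, `tp`, `fp`, `fn`,
#'   `tn`, `ppv`, `npv`, `n_missing_outcome`.
#' @export
assay_performance <- function(calls, outcomes) {
  if (is.character(calls)) calls <- calls == "progression"
  calls <- as.logical(calls)
  outcomes <- as.logical(outcomes)
  if (length(calls) != length(outcomes)) abort("calls and outcomes differ in length")
  n_missing <- sum(is.na(outcomes))
  if (n_missing > 0) {
    warn(sprintf("%d patient(s) without a known outcome excluded from performance", n_missing))
    keep <- !is.na(outcomes)
    calls <- calls[keep]
    outcomes <- outcomes[keep]
  }
  tp <- sum(calls & outcomes)
  fp <- sum(calls & !outcomes)
  fn <- sum(!calls & outcomes)
  tn <- sum(!calls & !outcomes)
  tibble(
    n_called = tp + fp, n_not_called = fn + tn,
    tp = tp, fp = fp, fn = fn, tn = tn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    n_missing_outcome = n_missing
  )
}
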
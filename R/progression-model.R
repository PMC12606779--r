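#' The six pre-defined candidate models
#'
#' The candidate set is fixed in advance on biological grounds (change in
#' short-fragment excess tracks change in tumor burden; baseline burden and
#' the signed mid-marker change may add information), avoiding data-driven
#' feature selection in a small cohort. Order is the canonical table order
#' and is used as the final tie-break in [select_best()].
#'
#' @return Tibble with columns `model` (label) and `predictors` (list of
#'   character vectors).
#' @export
ps_model_specs <- function() {
  specs <- list(
    c("FragDiff"),
    c("Frag1", "FragDiff"),
    c("SM1", "FragDiff"),
    c("MMDiff", "FragDiff"),
    c("Frag1", "MMDiff", "FragDiff"),
    c("SM1", "MMDiff", "FragDiff")
  )
  tibble(
    model = vapply(specs, paste, character(1), collapse = " + "),
    predictors = specs
  )
}

#' Fit one logistic progression model
#'
#' Maximum-likelihood logistic regression of the progression outcome on the
#' given fragmentomic predictors (Fisher-scoring IRLS, convergence tolerance
#' 1e-8, at most 100 iterations), with Wald per-coefficient tests, a
#' likelihood-ratio test of the whole model against intercept-only, and the
#' training ROC AUC of the fitted probabilities. Quasi-complete separation
#' (fitted probabilities numerically 0/1 or exploding coefficients) is
#' flagged on the result, not treated as a failure.
#'
#' @param data Data frame holding the predictors and the outcome column.
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the logical/0-1 outcome column.
#' @return A `ps_fit` object; see [tidy.ps_fit()] and [glance.ps_fit()].
#' @export
fit_logistic <- function(data, predictors, outcome = "progressed") {
  miss <- setdiff(c(predictors, outcome), names(data))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  y <- as.logical(data[[outcome]])
  if (anyNA(y) || anyNA(data[predictors])) {
    abort("missing outcome or predictor values: gate and drop before fitting")
  }
  if (length(unique(y)) < 2) {
    abort("degenerate outcome: need at least one case and one control")
  }
  f <- stats::as.formula(paste(
    "outcome__ ~", paste(predictors, collapse = " + ")
  ))
  df <- data[, predictors, drop = FALSE]
  df$outcome__ <- y
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = df, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  separation <- sep_warned || !fit$converged || any(abs(coef(fit)[-1]) > 15)
  sm <- summary(fit)$coefficients
  lrt_stat <- fit$null.deviance - fit$deviance
  lrt_df <- length(predictors)
  scores <- unname(predict(fit, type = "response"))
  structure(
    list(
      model = paste(predictors, collapse = " + "),
      predictors = predictors,
      outcome = outcome,
      glm = fit,
      coefficients = coef(fit),
      p_values = sm[, "Pr(>|z|)"],
      z_values = sm[, "z value"],
      std_errors = sm[, "Std. Error"],
      p_value = pchisq(lrt_stat, df = lrt_df, lower.tail = FALSE),
      training_auc = roc_auc(scores, y),
      fitted_probabilities = scores,
      labels = y,
      separation = separation,
      n = length(y)
    ),
    class = "ps_fit"
  )
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic progression model: %s\n  n = %d, training AUC = %.3f, LRT p = %.3g%s\n",
    x$model, x$n, x$training_auc, x$p_value,
    if (x$separation) " [quasi-complete separation flagged]" else ""
  ))
  invisible(x)
}

#' Tidy a fitted progression model
#'
#' @param x A `ps_fit`.
#' @param ... Unused.
#' @return Tibble of coefficients: `term`, `estimate`, `std_error`,
#'   `statistic` (Wald z), `p_value`.
#' @method tidy ps_fit
#' @export
tidy.ps_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$std_errors),
    statistic = unname(x$z_values),
    p_value = unname(x$p_values)
  )
}

#' @rdname tidy.ps_fit
#' @return `glance()`: one-row tibble of model-level summaries.
#' @method glance ps_fit
#' @export
glance.ps_fit <- function(x, ...) {
  tibble(
    model = x$model,
    n = x$n,
    training_auc = x$training_auc,
    p_value = x$p_value,
    separation = x$separation,
    deviance = x$glm$deviance,
    aic = x$glm$aic
  )
}

#' Predict probabilities / Progression Scores for new data
#'
#' @param object A `ps_fit`.
#' @param newdata Data frame with the model's predictor columns.
#' @param type `"prob"` for raw probabilities, `"ps"` for the 0-100 score.
#' @param ... Unused.
#' @export
predict.ps_fit <- function(object, newdata, type = c("prob", "ps"), ...) {
  type <- match.arg(type)
  p <- unname(predict(object$glm, newdata = newdata, type = "response"))
  if (type == "ps") ps_from_prob(p) else p
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney form of the area under the empirical ROC curve: the
#' probability that a random case outscores a random control, with ties
#' counting one half (midranks). Identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores Numeric predictions, higher = more case-like.
#' @param labels Logical (or 0/1) outcome, `TRUE` = case.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) abort("scores and labels must be complete")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and summarize all six candidate models
#'
#' Fits every row of [ps_model_specs()], computes each model's training AUC
#' and likelihood-ratio p-value, applies a Bonferroni multiplier equal to
#' the (pre-defined) number of models, and annotates models whose added
#' predictors beyond `FragDiff` are not statistically significant by Wald
#' test at `alpha`. Single-row failures are recorded, not propagated.
#'
#' @param data Feature table with predictor columns and the outcome.
#' @param outcome Outcome column name.
#' @param specs Model table, defaults to the six pre-defined models.
#' @param alpha Wald significance level for the note column.
#' @return Tibble: `model`, `n_predictors`, `auc`, `p_value`,
#'   `p_bonferroni`, `separation`, `note`, `fit` (list of `ps_fit`/NULL).
#' @export
evaluate_models <- function(data, outcome = "progressed",
                            specs = ps_model_specs(), alpha = 0.05) {
  m <- nrow(specs)
  rows <- purrr::map(seq_len(m), function(i) {
    preds <- specs$predictors[[i]]
    fit <- tryCatch(fit_logistic(data, preds, outcome = outcome), error = identity)
    if (inherits(fit, "error")) {
      return(tibble(
        model = specs$model[i], n_predictors = length(preds),
        auc = NA_real_, p_value = NA_real_, p_bonferroni = NA_real_,
        separation = NA, note = paste0("fit failed: ", conditionMessage(fit)),
        fit = list(NULL)
      ))
    }
    added <- setdiff(preds, "FragDiff")
    ns <- added[fit$p_values[added] >= alpha]
    note <- if (length(ns)) {
      paste0(paste(ns, collapse = " and "),
             if (length(ns) > 1) " are" else " is",
             " not statistically significant.")
    } else {
      ""
    }
    tibble(
      model = specs$model[i], n_predictors = length(preds),
      auc = fit$training_auc, p_value = fit$p_value,
      p_bonferroni = pmin(1, m * fit$p_value),
      separation = fit$separation, note = note, fit = list(fit)
    )
  })
  list_rbind(rows)
}

#' Select the preferred model from an evaluation table
#'
#' Base rule: highest training AUC; ties broken by fewer predictors, then
#' table order. With `parsimony_on_flag = TRUE` (default), models whose note
#' flags a non-significant added predictor are set aside before taking the
#' argmax (unless every candidate is flagged), so a leaner model whose extra
#' term earns nothing is preferred even when the flagged model's AUC is
#' marginally higher.
#'
#' @param table Output of [evaluate_models()].
#' @param parsimony_on_flag Disfavor models with non-significant added
#'   predictors outright (`TRUE`) or only on exact AUC ties (`FALSE`).
#' @return The selected row of `table` (one-row tibble, `fit` included).
#' @export
select_best <- function(table, parsimony_on_flag = TRUE) {
  ok <- table |> filter(!is.na(.data$auc))
  if (nrow(ok) == 0) abort("no successfully fitted model to select from")
  ok <- ok |> mutate(.order = seq_len(dplyr::n()), flagged = nzchar(.data$note))
  pool <- ok
  if (parsimony_on_flag && any(!ok$flagged)) pool <- ok |> filter(!.data$flagged)
  best <- pool |>
    arrange(desc(.data$auc), .data$n_predictors, .data$.order)
  if (!parsimony_on_flag) {
    # flagged models lose only exact AUC ties against unflagged ones
    top_auc <- best$auc[1]
    tied <- best |> filter(.data$auc == top_auc)
    if (any(!tied$flagged)) {
      best <- bind_rows(tied |> filter(!.data$flagged), tied |> filter(.data$flagged))
    }
  }
  best |> slice(1) |> select(-".order", -"flagged")
}

#' Leave-one-out cross-validated AUC
#'
#' Each patient is held out in turn, the model is refitted on the remaining
#' n-1 patients, and the held-out patient's probability is predicted; the n
#' pooled held-out probabilities are scored once against the outcomes. A
#' fold whose training set loses one outcome class entirely cannot be fitted
#' and predicts the training prevalence instead (counted in the
#' `n_flagged_folds` attribute). The fold structure is per patient, so row
#' order does not affect the result.
#'
#' @inheritParams fit_logistic
#' @return The pooled held-out AUC, with attributes `predictions` (numeric,
#'   input order) and `n_flagged_folds`.
#' @export
loocv_auc <- function(data, predictors, outcome = "progressed") {
  y <- as.logical(data[[outcome]])
  n <- nrow(data)
  if (n < 3) abort("need at least 3 patients for leave-one-out cross-validation")
  if (length(unique(y)) < 2) abort("degenerate outcome: need both classes")
  preds <- numeric(n)
  flagged <- 0L
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (length(unique(as.logical(train[[outcome]]))) < 2) {
      preds[i] <- mean(as.logical(train[[outcome]]))
      flagged <- flagged + 1L
      next
    }
    fit <- suppressWarnings(fit_logistic(train, predictors, outcome = outcome))
    preds[i] <- predict(fit, newdata = data[i, , drop = FALSE], type = "prob")
  }
  out <- roc_auc(preds, y)
  attr(out, "predictions") <- preds
  attr(out, "n_flagged_folds") <- flagged
  out
}
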
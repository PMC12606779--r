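test_that("rank AUC matches hand counts and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(2, 6), c(1, 0, 1, 0, 0, 1)), 0.5) # all tied
  expect_equal(roc_auc(c(2, 2, 3), c(TRUE, FALSE, TRUE)), 0.75) # one tied pair counts half
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("rank AUC equals exhaustive pair counting on every small dataset", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(1:5, n, replace = TRUE) # coarse grid to force ties
    expect_equal(roc_auc(scores, labels), pair_counting_auc(scores, labels))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(44)
  scores <- rnorm(80)
  labels <- runif(80) < plogis(scores)
  if (length(unique(labels)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(labels), predictor = scores,
      levels = c(0, 1), direction = "<", quiet = TRUE
    )))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("logistic fit matches the 2x2 closed-form log-odds", {
  # binary predictor: coefficient = log((a/b) / (c/d)) from the 2x2 table
  x <- rep(c(1, 1, 0, 0), times = c(30, 12, 9, 41)) # a=30 b=12 c=9 d=41
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(30, 12, 9, 41))
  fit <- fit_logistic(tibble::tibble(x = x, progressed = y), "x")
  expect_equal(unname(fit$coefficients["x"]),
               log((30 / 12) / (9 / 41)), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               log(9 / 41), tolerance = 1e-6)
})

test_that("logistic fit recovers known parameters and nulls", {
  set.seed(7)
  x <- rnorm(2000)
  y <- runif(2000) < plogis(-1 + 2 * x)
  fit <- fit_logistic(tibble::tibble(x = x, progressed = y), "x")
  expect_lt(abs(fit$coefficients["(Intercept)"] - (-1)), 0.2)
  expect_lt(abs(fit$coefficients["x"] - 2), 0.2)
  expect_false(fit$separation)

  # a predictor independent of the labels earns no significance
  set.seed(8)
  z <- rnorm(200)
  y2 <- runif(200) < 0.3
  fit2 <- fit_logistic(tibble::tibble(z = z, progressed = y2), "z")
  expect_gt(fit2$p_values["z"], 0.05)

  expect_error(
    fit_logistic(tibble::tibble(x = 1:5, progressed = rep(TRUE, 5)), "x"),
    "degenerate outcome"
  )
})

test_that("coefficient bias is small over repeated simulated cohorts", {
  set.seed(9)
  est <- replicate(200, {
    x <- rnorm(2000)
    y <- runif(2000) < plogis(-1 + 2 * x)
    suppressWarnings(fit_logistic(tibble::tibble(x = x, progressed = y), "x"))$coefficients
  })
  expect_lt(abs(mean(est["(Intercept)", ]) - (-1)) / 1, 0.05)
  expect_lt(abs(mean(est["x", ]) - 2) / 2, 0.05)
})

test_that("quasi-complete separation is flagged, not fatal", {
  d <- tibble::tibble(x = c(1:5, 11:15),
                      progressed = rep(c(FALSE, TRUE), each = 5))
  fit <- fit_logistic(d, "x")
  expect_true(fit$separation)
  expect_equal(fit$training_auc, 1)
})

test_that("all six pre-defined models are evaluated with Bonferroni x6", {
  feats <- cohort_features(seed = 3)
  tab <- evaluate_models(feats)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$model, ps_model_specs()$model)
  ok <- !is.na(tab$p_value)
  expect_equal(tab$p_bonferroni[ok], pmin(1, 6 * tab$p_value[ok]))
  # the short-fragment change carries the signal in this cohort
  expect_gt(max(tab$auc, na.rm = TRUE), 0.85)
  # errors in one row do not abort the others
  feats_bad <- dplyr::mutate(feats, SM1 = NA_real_)
  tab2 <- evaluate_models(feats_bad)
  expect_equal(nrow(tab2), 6)
  expect_true(any(grepl("fit failed", tab2$note)))
  expect_true(any(!is.na(tab2$auc)))
})

test_that("adding the mid-marker change rarely lowers, and on average raises, training AUC", {
  # the richer nested model maximizes likelihood, not AUC, so AUC dominance
  # is an empirical regularity of the signal regime rather than a theorem;
  # assert it in aggregate over cohorts
  deltas <- vapply(1:12, function(s) {
    feats <- cohort_features(seed = s)
    tab <- evaluate_models(feats)
    tab$auc[tab$model == "MMDiff + FragDiff"] - tab$auc[tab$model == "FragDiff"]
  }, numeric(1))
  expect_gte(mean(deltas >= 0), 0.7)
  expect_gt(mean(deltas), -0.001)
})

test_that("model selection prefers parsimony when the extra term earns nothing", {
  tab <- tibble::tibble(
    model = ps_model_specs()$model,
    n_predictors = c(1, 2, 2, 2, 3, 3),
    auc = c(0.802, 0.847, 0.910, 0.934, 0.936, 0.934),
    p_value = rep(1e-4, 6), p_bonferroni = rep(6e-4, 6),
    separation = FALSE,
    note = c("", "", "", "", "Frag1 is not statistically significant.",
             "SM1 is not statistically significant."),
    fit = vector("list", 6)
  )
  # default: flagged three-predictor models set aside, argmax of the rest
  expect_equal(select_best(tab)$model, "MMDiff + FragDiff")
  # literal argmax keeps the 0.936 model
  expect_equal(select_best(tab, parsimony_on_flag = FALSE)$model,
               "Frag1 + MMDiff + FragDiff")
  # exact ties break toward fewer predictors, then table order
  tied <- dplyr::mutate(tab, auc = 0.9, note = "")
  expect_equal(select_best(tied)$model, "FragDiff")
  # single fitted model selects itself
  expect_equal(select_best(tab[4, ])$model, "MMDiff + FragDiff")
  expect_error(select_best(dplyr::mutate(tab, auc = NA_real_)), "no successfully")
})

test_that("LOOCV matches a hand-rolled leave-one-out loop on a small fixture", {
  d <- tibble::tibble(
    x = c(0.1, 0.9, 0.4, 1.2, 0.3, 1.0),
    progressed = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  manual <- vapply(seq_len(nrow(d)), function(i) {
    g <- suppressWarnings(glm(progressed ~ x, data = d[-i, ], family = binomial(),
                              control = glm.control(epsilon = 1e-8, maxit = 100)))
    unname(predict(g, newdata = d[i, ], type = "response"))
  }, numeric(1))
  got <- loocv_auc(d, "x")
  expect_equal(as.numeric(got), roc_auc(manual, d$progressed))
  expect_equal(attr(got, "predictions"), manual, tolerance = 1e-8)
})

test_that("LOOCV is invariant to patient order and honest under a null", {
  feats <- cohort_features(seed = 6)
  a1 <- loocv_auc(feats, c("MMDiff", "FragDiff"))
  set.seed(10)
  perm <- sample(nrow(feats))
  a2 <- loocv_auc(feats[perm, ], c("MMDiff", "FragDiff"))
  expect_equal(as.numeric(a1), as.numeric(a2), tolerance = 1e-12)

  # pure-noise predictors: pooled LOOCV is pessimistic, never optimistic.
  # (Holding out a case lowers its own training prevalence, anti-ranking
  # the held-out predictions, so the null expectation sits below 0.5.)
  nulls <- vapply(1:10, function(s) {
    set.seed(100 + s)
    null_d <- tibble::tibble(x = rnorm(200), progressed = rep(c(TRUE, FALSE), 100))
    as.numeric(suppressWarnings(loocv_auc(null_d, "x")))
  }, numeric(1))
  expect_lt(mean(nulls), 0.55)
  expect_gt(mean(nulls), 0.2)
})

test_that("cross-validated AUC does not exceed training AUC on signal cohorts", {
  # optimism is a property in expectation; compare averages over replicates
  set.seed(13)
  diffs <- replicate(25, {
    d <- tibble::tibble(x = rnorm(60), progressed = runif(60) < plogis(1.5 * x))
    if (length(unique(d$progressed)) < 2) return(NA_real_)
    fit <- suppressWarnings(fit_logistic(d, "x"))
    fit$training_auc - as.numeric(suppressWarnings(loocv_auc(d, "x")))
  })
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})
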
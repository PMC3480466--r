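feat <- function(v, thigh) data.frame(median_v = v, median_thigh = thigh)

test_that("decision tree follows the printed split rules and boundaries", {
  th <- default_thresholds()
  expect_equal(classify_window(feat(0.30, 0.9), th), "lying")
  expect_equal(classify_window(feat(0.95, 0.80), th), "sitting")
  expect_equal(classify_window(feat(0.95, 0.05), th), "upright")
  # strict inequalities: boundary values fall to upright / standing
  expect_equal(classify_window(feat(0.66, 0.9), th), "sitting")
  expect_equal(classify_window(feat(0.66, 0.5), th), "upright")
  # magnitude rule is mounting-polarity free
  expect_equal(classify_window(feat(-0.30, 0.9), th), "lying")
  expect_equal(classify_window(feat(-0.95, -0.80), th), "sitting")
})

test_that("a pinned vertical sign convention is available", {
  th <- default_thresholds(vertical_sign = -1)
  # upright reads -1 g on the vertical axis under this convention
  expect_equal(classify_window(feat(-0.95, 0.05), th), "upright")
  expect_equal(classify_window(feat(-0.30, 0.05), th), "lying")
  expect_equal(classify_window(feat(0.95, 0.05), th), "lying")
})

test_that("the three classes partition every finite feature vector", {
  set.seed(41)
  f <- feat(runif(500, -2, 2), runif(500, -2, 2))
  lab <- classify_windows(f)$posture
  expect_false(anyNA(lab))
  expect_true(all(lab %in% c("lying", "sitting", "upright")))
})

test_that("classification depends only on gravity medians, never SD/activity", {
  f <- cbind(feat(c(0.3, 0.95), c(0.9, 0.9)),
             sd_v = c(0, 0), activity = c(0, 0))
  a <- classify_windows(f)$posture
  f$sd_v <- c(5, 5); f$activity <- c(3, 3)
  expect_equal(classify_windows(f)$posture, a)
})

sep_features <- function(n_per = 40, seed = 5) {
  set.seed(seed)
  data.frame(
    median_v = c(runif(n_per, -0.2, 0.2),        # lying
                 runif(n_per, 0.9, 1.05),        # sitting
                 runif(n_per, 0.9, 1.05)),       # upright
    median_thigh = c(runif(n_per, 0, 1),
                     runif(n_per, 0.8, 1.0),
                     runif(n_per, 0, 0.1)))
}
sep_labels <- function(n_per = 40) rep(c("lying", "sitting", "upright"), each = n_per)

test_that("fit_thresholds recovers separable classes perfectly", {
  f <- sep_features()
  for (seed in 1:5) {
    fit <- fit_thresholds(f, sep_labels(), folds = 10, seed = seed)
    expect_equal(fit$cv_accuracy, 1.0)
    expect_gt(fit$thresholds$vertical_g, 0.2)   # inside the empirical gap
    expect_lt(fit$thresholds$vertical_g, 0.9)
    expect_gt(fit$thresholds$thigh_g, 0.1)
    expect_lt(fit$thresholds$thigh_g, 0.8)
  }
})

test_that("fitting matches an exhaustive midpoint-search oracle under label noise", {
  f <- sep_features(60)
  lab <- sep_labels(60)
  set.seed(99)
  flip <- sample(length(lab), round(0.05 * length(lab)))
  lab[flip] <- sample(c("lying", "sitting", "upright"), length(flip), replace = TRUE)

  fit <- fit_thresholds(f, lab, folds = 10, seed = 7)
  expect_gt(fit$cv_accuracy, 0.9)

  # oracle: enumerate every midpoint for each split, maximizing accuracy of
  # the same hierarchical rule
  acc_of <- function(vg, tg) {
    lying <- abs(f$median_v) < vg
    sitting <- !lying & abs(f$median_thigh) > tg
    pred <- ifelse(lying, "lying", ifelse(sitting, "sitting", "upright"))
    mean(pred == lab)
  }
  vm <- sort(unique(abs(f$median_v)))
  v_cand <- (vm[-1] + vm[-length(vm)]) / 2
  best_v <- v_cand[which.max(vapply(v_cand, function(vg)
    mean((abs(f$median_v) < vg) == (lab == "lying")), numeric(1)))]
  tm <- sort(unique(abs(f$median_thigh[lab != "lying" & abs(f$median_v) >= best_v])))
  t_cand <- (tm[-1] + tm[-length(tm)]) / 2
  oracle_acc <- max(vapply(t_cand, function(tg) acc_of(best_v, tg), numeric(1)))
  fitted_acc <- acc_of(fit$thresholds$vertical_g, fit$thresholds$thigh_g)
  expect_gte(fitted_acc + 1e-9, oracle_acc)
})

test_that("fit_thresholds degenerate and error cases", {
  f <- sep_features(4)  # n = 12
  expect_silent(fit <- fit_thresholds(f[1:10, ], sep_labels(4)[1:10],
                                      folds = 10, seed = 1))
  expect_true(is.finite(fit$cv_accuracy))
  expect_error(fit_thresholds(f, rep("lying", 12), folds = 3), "two classes")
  expect_error(fit_thresholds(f, sep_labels(4), folds = 13), "folds")
  # deterministic given seed
  a <- fit_thresholds(f, sep_labels(4), folds = 3, seed = 5)
  b <- fit_thresholds(f, sep_labels(4), folds = 3, seed = 5)
  expect_identical(a, b)
})

test_that("classify_recording gates on the clock night window", {
  rec <- const_recording(0, -1, 0, 0.1, seconds = 3600,
                         start_time = "2026-01-01 23:00:00")
  w <- classify_recording(rec)
  expect_equal(nrow(w), 720)
  expect_true(all(w$posture == "lying"))

  # recording entirely outside 20:00-10:00 -> empty with a warning
  day <- const_recording(0, -1, 0, 0.1, seconds = 600,
                         start_time = "2026-01-01 12:00:00")
  expect_warning(wd <- classify_recording(day), "night window")
  expect_equal(nrow(wd), 0)

  # only the portion after 20:00 is kept when the recording straddles it
  strad <- const_recording(0, -1, 0, 0.1, seconds = 3600,
                           start_time = "2026-01-01 19:30:00")
  ws <- classify_recording(strad)
  expect_equal(nrow(ws), 360)
  expect_equal(min(ws$start_s), 1800)
})
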
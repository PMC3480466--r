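#' Hierarchical posture decision tree
#'
#' Two binary splits on window gravity medians classify each window as
#' `lying`, `sitting` or `upright` (standing/walking):
#' 1. *lying* when the torso is far from upright, i.e. the vertical-axis
#'    gravity median is small in magnitude: `|median_v| < vertical_g`
#'    (strict; default 0.66 g);
#' 2. otherwise *sitting* when the thigh antero-posterior gravity median is
#'    large: `|median_thigh| > thigh_g` (strict; default 0.5 g), else
#'    *upright*.
#'
#' The rule uses magnitudes so it is independent of sensor mounting
#' polarity; set `vertical_sign` in the thresholds to the value (+1/-1) the
#' vertical channel reads when upright to pin a signed convention
#' (`lying iff vertical_sign * median_v < vertical_g`). Boundary
#' values fall to upright / standing by the strict inequalities.
#' Classification uses window medians only (the gravity component), never
#' SD or activity.
#'
#' @param features a `window_features` data.frame (or any data.frame with
#'   `median_v` and `median_thigh` columns).
#' @param thresholds a [default_thresholds] object.
#' @return `classify_windows`: the input with a `posture` factor column
#'   (levels lying/sitting/upright). `classify_window`: a single label.
#' @export
classify_windows <- function(features, thresholds = default_thresholds()) {
  v <- features$median_v
  th <- features$median_thigh
  if (is.null(v) || is.null(th)) stop("features must have median_v and median_thigh")
  # magnitude rule by default (mounting-polarity free); with a pinned sign s,
  # upright reads v ~ s * 1 g and lying is s * v < vertical_g
  lying <- if (thresholds$vertical_sign == 0) abs(v) < thresholds$vertical_g
           else thresholds$vertical_sign * v < thresholds$vertical_g
  sitting <- !lying & abs(th) > thresholds$thigh_g
  lab <- ifelse(lying, "lying", ifelse(sitting, "sitting", "upright"))
  features$posture <- factor(lab, levels = posture_levels())
  features
}

posture_levels <- function() c("lying", "sitting", "upright")

#' @rdname classify_windows
#' @export
classify_window <- function(features, thresholds = default_thresholds()) {
  as.character(classify_windows(as.data.frame(features), thresholds)$posture[1])
}

#' Classify a full recording over the night window
#'
#' Computes [window_features] and classifies every window whose start falls
#' inside the configured clock night window (default 20:00-10:00, spanning
#' midnight). Windows outside the night window are discarded.
#'
#' @inheritParams classify_windows
#' @param rec an [accel_recording].
#' @param window_s,step_s passed to [window_features].
#' @return classified `window_features` restricted to the night window; a
#'   warning and zero rows when the recording does not overlap it.
#' @export
classify_recording <- function(rec, thresholds = default_thresholds(),
                               window_s = 5, step_s = window_s) {
  wf <- window_features(rec, window_s, step_s)
  keep <- in_night_window(clock_seconds(rec$start_time) + wf$start_s,
                          thresholds$night_start, thresholds$night_end)
  out <- classify_windows(wf[keep, , drop = FALSE], thresholds)
  if (nrow(out) == 0L)
    warning("recording does not overlap the night window ",
            thresholds$night_start, "-", thresholds$night_end)
  attributes(out)[c("window_s", "step_s", "sampling_rate", "start_time")] <-
    attributes(wf)[c("window_s", "step_s", "sampling_rate", "start_time")]
  rownames(out) <- NULL
  out
}

#' Fit the tree thresholds by 10-fold cross-validation
#'
#' Given labeled calibration windows, both split constants are refit by
#' exhaustive midpoint search (decision-stump style): candidate thresholds
#' are midpoints between consecutive sorted unique feature magnitudes, the
#' candidate maximizing training accuracy wins (ties resolved toward the
#' widest inter-point gap). Held-out accuracy is estimated by k-fold
#' cross-validation with seeded fold shuffling; the returned thresholds are
#' refit on all data.
#'
#' @param features data.frame with `median_v`, `median_thigh` columns.
#' @param labels character/factor of true coarse labels
#'   (lying/sitting/upright), one per row of `features`.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param thresholds baseline threshold set; only `vertical_g` and `thigh_g`
#'   are refit, all other constants are carried through.
#' @return list with `thresholds` (a `sleep_thresholds`) and `cv_accuracy`
#'   (mean held-out fraction correct).
#' @export
fit_thresholds <- function(features, labels, folds = 10, seed = 1,
                           thresholds = default_thresholds()) {
  labels <- as.character(labels)
  n <- length(labels)
  if (nrow(features) != n) stop("features and labels length mismatch")
  if (!all(labels %in% posture_levels()))
    stop("labels must be in {lying, sitting, upright}")
  if (length(unique(labels)) < 2L)
    stop("calibration data must contain at least two classes")
  if (folds > n) stop("more folds than labeled windows")
  if (folds < 2L) stop("need at least 2 folds")

  fold_id <- local_seed(seed, sample(rep_len(seq_len(folds), n)))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit <- fit_stumps(features[tr, , drop = FALSE], labels[tr], thresholds)
    pred <- predict_tree(features[!tr, , drop = FALSE], fit)
    acc[k] <- mean(pred == labels[!tr])
  }
  full <- fit_stumps(features, labels, thresholds)
  th <- thresholds
  th$vertical_g <- full["vertical_g"]
  th$thigh_g <- full["thigh_g"]
  list(thresholds = th, cv_accuracy = mean(acc))
}

# Exhaustive midpoint search for the two split constants.
fit_stumps <- function(features, labels, thresholds) {
  vmag <- abs(features$median_v)
  v_thr <- best_split(vmag, labels == "lying", below_is_positive = TRUE,
                      fallback = thresholds$vertical_g)
  nl <- labels != "lying"
  if (any(nl) && length(unique(labels[nl])) > 1L) {
    t_thr <- best_split(abs(features$median_thigh[nl]), labels[nl] == "sitting",
                        below_is_positive = FALSE, fallback = thresholds$thigh_g)
  } else t_thr <- thresholds$thigh_g
  c(vertical_g = v_thr, thigh_g = t_thr)
}

# One decision stump: positive class is (x < t) or (x > t).
best_split <- function(x, positive, below_is_positive, fallback) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(fallback)
  cand <- (u[-1] + u[-length(u)]) / 2
  gap <- u[-1] - u[-length(u)]
  acc <- vapply(cand, function(t) {
    pred <- if (below_is_positive) x < t else x > t
    mean(pred == positive)
  }, numeric(1))
  best <- which(acc == max(acc))
  cand[best[which.max(gap[best])]]
}

predict_tree <- function(features, fit) {
  lying <- abs(features$median_v) < fit["vertical_g"]
  sitting <- !lying & abs(features$median_thigh) > fit["thigh_g"]
  ifelse(lying, "lying", ifelse(sitting, "sitting", "upright"))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
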
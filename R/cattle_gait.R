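# Locomotion scoring for dairy cattle from side-view pose keypoints: per-frame
# gait features, back-silhouette straightness, rolling windows, a pluggable
# window classifier, and clip-level aggregation on the 1 (normal) to
# 5 (severely lame) locomotion-score scale.

#' Names of the 8 windowed locomotion features
#'
#' Step sizes and hoof-elbow shifts are normalised by body length (withers-pin
#' distance); head position by the mean vertical hoof-elbow extent of the four
#' legs. Body length itself acts only as the normaliser.
#'
#' @export
GAIT_FEATURES <- c("right_step", "left_step", "head_position",
                   "fr_shift", "fl_shift", "br_shift", "bl_shift",
                   "back_straightness")

#' Extract per-frame gait features from a cattle pose
#'
#' Computes, in the side-view image frame:
#' * `body_length` — Euclidean withers-pin distance (pixels);
#' * `right_step`, `left_step` — horizontal front-to-back hoof distance of the
#'   right / left leg pair, over body length;
#' * `fr/fl/br/bl_shift` — signed horizontal elbow-minus-hoof offset per leg,
#'   over body length, multiplied by the walking direction sign so left-going
#'   and right-going walks yield identical features;
#' * `head_position` — height of the head above the ground line (mean hoof y)
#'   divided by the mean vertical hoof-to-elbow extent of the four legs;
#' * `back_straightness` — from `edge` via [back_straightness_score()] when a
#'   back silhouette is supplied, else `NA`.
#'
#' Any feature depending on a keypoint whose confidence falls below
#' `conf_floor` is marked `NA` (missing), to be bridged later by
#' [build_windows()].
#'
#' @param pose [cattle_pose()] object.
#' @param walking_direction_sign +1 (walking towards +x) or -1.
#' @param edge optional [back_edge()] for this frame.
#' @param conf_floor minimal keypoint confidence (default 0.3).
#' @param lambda straightness decay constant, see [back_straightness_score()].
#' @return object of class `gait_features`: named numeric with `body_length`
#'   plus the eight [GAIT_FEATURES].
#' @export
extract_gait_features <- function(pose, walking_direction_sign = 1,
                                  edge = NULL, conf_floor = 0.3,
                                  lambda = 0.05) {
  stopifnot(inherits(pose, "cattle_pose"))
  if (!walking_direction_sign %in% c(-1, 1)) {
    stop("walking_direction_sign must be +1 or -1", call. = FALSE)
  }
  ok <- function(name) keypoint_conf(pose, name) >= conf_floor
  xy <- function(name) keypoint_xy(pose, name)

  if (!ok("withers") || !ok("pin")) {
    stop("degenerate pose: withers or pin below confidence floor", call. = FALSE)
  }
  L <- sqrt(sum((xy("withers") - xy("pin"))^2))
  if (L <= 1e-9) stop("degenerate pose: body length ~ 0", call. = FALSE)

  step <- function(front, back) {
    if (!ok(front) || !ok(back)) return(NA_real_)
    unname(abs(xy(front)[1] - xy(back)[1]) / L)
  }
  shift <- function(elbow, hoof) {
    if (!ok(elbow) || !ok(hoof)) return(NA_real_)
    unname(walking_direction_sign * (xy(elbow)[1] - xy(hoof)[1]) / L)
  }

  hooves <- c("fr_hoof", "fl_hoof", "br_hoof", "bl_hoof")
  elbows <- c("fr_elbow", "fl_elbow", "br_elbow", "bl_elbow")
  head_position <- NA_real_
  if (ok("head") && all(vapply(c(hooves, elbows), ok, TRUE))) {
    ground_y <- mean(vapply(hooves, function(h) xy(h)[2], 1))
    leg_height <- mean(abs(
      vapply(hooves, function(h) xy(h)[2], 1) -
        vapply(elbows, function(e) xy(e)[2], 1)))
    if (leg_height > 1e-9) {
      head_position <- (ground_y - xy("head")[2]) / leg_height
    }
  }

  bs <- if (is.null(edge)) NA_real_ else back_straightness_score(edge, lambda)

  structure(c(body_length = unname(L),
              right_step = step("fr_hoof", "br_hoof"),
              left_step = step("fl_hoof", "bl_hoof"),
              head_position = unname(head_position),
              fr_shift = shift("fr_elbow", "fr_hoof"),
              fl_shift = shift("fl_elbow", "fl_hoof"),
              br_shift = shift("br_elbow", "br_hoof"),
              bl_shift = shift("bl_elbow", "bl_hoof"),
              back_straightness = bs),
            class = "gait_features")
}

#' Back straightness score from the silhouette edge
#'
#' Fits the total-least-squares line to the back-edge points, takes the RMS of
#' the perpendicular residuals, normalises by body length and maps through
#' `exp(-err / (lambda * body_length))`: 1 for a perfectly straight back,
#' approaching 0 for a pronounced arch. Invariant to rigid motion and to
#' uniform scaling of points and reference length together.
#'
#' @param edge [back_edge()] object.
#' @param lambda decay constant (fraction of body length at which the score
#'   drops by 1/e; default 0.05).
#' @return score in (0, 1\].
#' @export
back_straightness_score <- function(edge, lambda = 0.05) {
  stopifnot(inherits(edge, "back_edge"))
  pts <- edge$points
  ctr <- colMeans(pts)
  centred <- sweep(pts, 2, ctr)
  sc <- crossprod(centred)            # 2x2 scatter matrix
  ev <- eigen(sc, symmetric = TRUE)$values
  err <- sqrt(max(ev[2], 0) / nrow(pts))  # RMS perpendicular residual
  exp(-err / (lambda * edge$body_length_ref))
}

#' Infer the walking direction sign from a pose sequence
#'
#' Sign of the net withers x displacement over the clip: +1 when the cow
#' walks towards +x (image right), -1 otherwise.
#'
#' @param poses list of [cattle_pose()] objects.
#' @return +1 or -1.
#' @export
walking_direction <- function(poses) {
  xs <- vapply(poses, function(p) keypoint_xy(p, "withers")[1], 1)
  if (xs[length(xs)] >= xs[1]) 1 else -1
}

#' Per-frame gait feature table for a clip
#'
#' Runs [extract_gait_features()] over a pose stream (direction inferred from
#' the withers track), joining per-frame back edges when provided.
#'
#' @param poses list of [cattle_pose()] objects.
#' @param edges optional list of [back_edge()] objects parallel to `poses`.
#' @param conf_floor,lambda passed through.
#' @return data.frame with `frame_index`, `body_length` and the eight
#'   [GAIT_FEATURES] columns.
#' @export
gait_feature_table <- function(poses, edges = NULL, conf_floor = 0.3,
                               lambda = 0.05) {
  sgn <- walking_direction(poses)
  rows <- lapply(seq_along(poses), function(i) {
    fv <- extract_gait_features(poses[[i]], sgn,
                                edge = if (is.null(edges)) NULL else edges[[i]],
                                conf_floor = conf_floor, lambda = lambda)
    c(frame_index = poses[[i]]$frame_index, unclass(fv))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Assemble rolling windows over the 8-feature signal
#'
#' Missing values are linearly interpolated per feature over interior gaps of
#' at most `max_gap` frames; longer gaps (and missing leading/trailing runs)
#' split the sequence, and windows are formed within each contiguous segment:
#' starts at the segment head, `stride` apart, `floor((N - window)/stride) + 1`
#' windows in a segment of N frames (0 when N < window, with a warning).
#'
#' @param features N x 8 matrix or data.frame of the [GAIT_FEATURES] columns
#'   (may contain `NA`).
#' @param window window length in frames (>= 2; default 20, i.e. 1 s at the
#'   20 fps clip rate).
#' @param stride window step in frames (>= 1; default 5).
#' @param max_gap longest missing run bridged by interpolation (default 3).
#' @return list of `locomotion_window` objects (`features` matrix,
#'   `start_frame` 0-based).
#' @export
build_windows <- function(features, window = 20, stride = 5, max_gap = 3) {
  if (window < 2) stop("window must be >= 2 frames", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1 frame", call. = FALSE)
  m <- as.matrix(as.data.frame(features)[, GAIT_FEATURES, drop = FALSE])
  n <- nrow(m)
  m <- apply(m, 2, interpolate_gaps, max_gap = max_gap)
  m <- matrix(m, nrow = n, dimnames = list(NULL, GAIT_FEATURES))
  good <- stats::complete.cases(m)
  segs <- contiguous_runs(which(good))
  out <- list()
  for (seg in segs) {
    N <- length(seg)
    if (N < window) next
    starts <- seq(1, N - window + 1, by = stride)
    for (s in starts) {
      idx <- seg[s:(s + window - 1)]
      out[[length(out) + 1]] <- structure(
        list(features = m[idx, , drop = FALSE], start_frame = idx[1] - 1L),
        class = "locomotion_window")
    }
  }
  if (!length(out)) warning("sequence too short or too gappy: 0 windows")
  out
}

# linear interpolation of interior NA runs up to max_gap frames
interpolate_gaps <- function(v, max_gap) {
  if (!anyNA(v) || all(is.na(v))) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    i0 <- starts[k] - 1; i1 <- ends[k] + 1
    if (i0 < 1 || i1 > length(v)) next   # leading/trailing runs stay missing
    idx <- starts[k]:ends[k]
    v[idx] <- v[i0] + (v[i1] - v[i0]) * (idx - i0) / (i1 - i0)
  }
  v
}

contiguous_runs <- function(idx) {
  if (!length(idx)) return(list())
  breaks <- c(0, which(diff(idx) > 1), length(idx))
  lapply(seq_len(length(breaks) - 1),
         function(k) idx[(breaks[k] + 1):breaks[k + 1]])
}

pool_window <- function(w) {
  f <- w$features
  stats_per <- function(col) {
    c(mean = mean(col), sd = stats::sd(col), min = min(col), max = max(col),
      mad1 = mean(abs(diff(col))))
  }
  as.numeric(apply(f, 2, stats_per))
}

#' Train the locomotion-score window classifier
#'
#' Reference classifier for the pluggable sequence-scoring slot: each window
#' is pooled into per-feature summary statistics (mean, sd, min, max, mean
#' absolute first difference) and a multinomial log-linear model is fitted
#' over the observed score classes. Deterministic for a fixed seed.
#'
#' @param windows list of `locomotion_window` objects.
#' @param labels integer locomotion scores in 1..5, one per window.
#' @param seed RNG seed for the fit.
#' @return object of class `sequence_classifier`.
#' @export
train_sequence_classifier <- function(windows, labels, seed = 1) {
  if (length(windows) != length(labels)) {
    stop("one label per window required", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > 5)) stop("labels must be in 1..5", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("degenerate training set: fewer than 2 distinct labels", call. = FALSE)
  }
  X <- t(vapply(windows, pool_window, numeric(5 * length(GAIT_FEATURES))))
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Xs <- scale(X, center = mu, scale = sdev)
  df <- as.data.frame(Xs)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$y <- factor(labels, levels = sort(unique(labels)))
  set.seed(seed)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 400,
                        decay = 1e-4, MaxNWts = 5000)
  structure(list(fit = fit, center = mu, scale = sdev,
                 levels = as.integer(levels(df$y)), seed = seed),
            class = "sequence_classifier")
}

#' Score windows with a trained classifier
#'
#' Emits a continuous score per window: the probability-weighted expectation
#' over the trained score classes, so the clip-level mean is well defined.
#'
#' @param clf [train_sequence_classifier()] result.
#' @param windows list of `locomotion_window` objects.
#' @return numeric vector of scores in `[1, 5]`.
#' @export
predict_window_scores <- function(clf, windows) {
  stopifnot(inherits(clf, "sequence_classifier"))
  X <- t(vapply(windows, pool_window, numeric(5 * length(GAIT_FEATURES))))
  Xs <- scale(X, center = clf$center, scale = clf$scale)
  df <- as.data.frame(Xs)
  names(df) <- paste0("f", seq_len(ncol(df)))
  p <- stats::predict(clf$fit, newdata = df, type = "probs")
  if (is.null(dim(p))) {
    p <- if (length(clf$levels) == 2) cbind(1 - p, p) else matrix(p, nrow = 1)
  }
  scores <- as.numeric(p %*% clf$levels)
  pmin(pmax(scores, 1), 5)
}

#' Hard class prediction per window
#'
#' @param clf [train_sequence_classifier()] result.
#' @param windows list of `locomotion_window` objects.
#' @return integer class per window.
#' @export
predict_window_class <- function(clf, windows) {
  X <- t(vapply(windows, pool_window, numeric(5 * length(GAIT_FEATURES))))
  Xs <- scale(X, center = clf$center, scale = clf$scale)
  df <- as.data.frame(Xs)
  names(df) <- paste0("f", seq_len(ncol(df)))
  as.integer(as.character(stats::predict(clf$fit, newdata = df, type = "class")))
}

#' Aggregate window scores into a clip-level locomotion score
#'
#' The clip score is the unrounded arithmetic mean of the window scores.
#'
#' @param window_scores numeric vector of window scores in `[1, 5]`.
#' @return object of class `clip_score` with `window_scores` and `clip_score`.
#' @export
score_clip <- function(window_scores) {
  if (!length(window_scores)) {
    stop("no windows: cannot score an empty clip", call. = FALSE)
  }
  if (any(window_scores < 1 | window_scores > 5)) {
    stop("window scores must lie in [1, 5]", call. = FALSE)
  }
  structure(list(window_scores = as.numeric(window_scores),
                 clip_score = mean(window_scores)),
            class = "clip_score")
}

#' @export
print.clip_score <- function(x, ...) {
  cat(sprintf("clip locomotion score %.3f over %d window(s)\n",
              x$clip_score, length(x$window_scores)))
  invisible(x)
}
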
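test_that("gait features follow their defining formulas", {
  p <- make_pose(0)
  fv <- extract_gait_features(p)
  # body length is the withers-pin distance
  expect_equal(unname(fv["body_length"]), 300)
  # hooves directly below elbows -> all four shifts are zero
  expect_equal(unname(fv[c("fr_shift", "fl_shift", "br_shift", "bl_shift")]),
               rep(0, 4))
  # step sizes are horizontal hoof distances over body length
  expect_equal(unname(fv["right_step"]), abs(130 - 330) / 300)
  expect_equal(unname(fv["left_step"]), abs(145 - 345) / 300)
  # head at y=75; ground at 260; leg height 80
  expect_equal(unname(fv["head_position"]), (260 - 75) / 80)

  # forced example: right step 0.8 at body length 100
  kp <- p$keypoints
  kp$x[kp$name == "withers"] <- 0; kp$y[kp$name == "withers"] <- 100
  kp$x[kp$name == "pin"] <- 100;   kp$y[kp$name == "pin"] <- 100
  kp$x[kp$name == "fr_hoof"] <- 120
  kp$x[kp$name == "br_hoof"] <- 40
  fv2 <- extract_gait_features(cattle_pose(0, kp))
  expect_equal(unname(fv2["body_length"]), 100)
  expect_equal(unname(fv2["right_step"]), 0.8)
})

test_that("gait features are translation invariant and scale as specified", {
  p0 <- make_pose(0)
  p1 <- make_pose(0, dx = 37.5, dy = -12.25)
  f0 <- unclass(extract_gait_features(p0))
  f1 <- unclass(extract_gait_features(p1))
  expect_equal(f1, f0, tolerance = 1e-12)

  p2 <- make_pose(0, scale = 2.5)
  f2 <- unclass(extract_gait_features(p2))
  expect_equal(f2["body_length"], 2.5 * f0["body_length"])
  nrm <- setdiff(GAIT_FEATURES, "back_straightness")
  expect_equal(f2[nrm], f0[nrm], tolerance = 1e-12)
})

test_that("low-confidence keypoints mark features missing; degenerate poses error", {
  p <- make_pose(0)
  kp <- p$keypoints
  kp$confidence[kp$name == "fr_hoof"] <- 0.1
  fv <- extract_gait_features(cattle_pose(0, kp))
  expect_true(is.na(fv["right_step"]))
  expect_true(is.na(fv["fr_shift"]))
  expect_true(is.na(fv["head_position"]))
  expect_false(is.na(fv["left_step"]))

  kp2 <- p$keypoints
  kp2$confidence[kp2$name == "pin"] <- 0.05
  expect_error(extract_gait_features(cattle_pose(0, kp2)), "degenerate")

  kp3 <- p$keypoints
  kp3$x[kp3$name == "pin"] <- kp3$x[kp3$name == "withers"]
  kp3$y[kp3$name == "pin"] <- kp3$y[kp3$name == "withers"]
  expect_error(extract_gait_features(cattle_pose(0, kp3)), "body length")
})

test_that("back straightness is 1 for collinear edges and decreases with sagitta", {
  # perfectly straight back, arbitrary orientation
  pts <- cbind(seq(0, 300, length.out = 11), seq(0, 150, length.out = 11))
  expect_equal(back_straightness_score(back_edge(pts, 300)), 1.0)

  # strictly decreasing across a sagitta grid 0..0.5 body lengths
  sag <- seq(0, 0.5, by = 0.05) * 300
  scores <- vapply(sag, function(s) back_straightness_score(arc_edge(s)), 1)
  expect_equal(scores[1], 1.0)
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("back straightness is invariant to rigid motion and uniform scaling", {
  e <- arc_edge(30)
  s0 <- back_straightness_score(e)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- back_edge(sweep(e$points %*% t(R), 2, c(55, -20), `+`),
                     e$body_length_ref)
  expect_equal(back_straightness_score(moved), s0, tolerance = 1e-12)
  scaled <- back_edge(e$points * 3, e$body_length_ref * 3)
  expect_equal(back_straightness_score(scaled), s0, tolerance = 1e-12)
  expect_error(back_edge(cbind(1:3, 1:3), 100), "5")
})

test_that("window count follows floor((N - window)/stride) + 1 on a grid", {
  mkfeat <- function(n) {
    m <- matrix(rnorm(n * 8), n, 8)
    colnames(m) <- GAIT_FEATURES
    m
  }
  expect_length(build_windows(mkfeat(100), 20, 5), 17)
  expect_length(suppressWarnings(build_windows(mkfeat(10), 20, 5)), 0)
  expect_length(build_windows(mkfeat(25), 20, 1), 6)
  set.seed(3)
  for (i in 1:20) {
    N <- sample(2:120, 1); w <- sample(2:40, 1); s <- sample(1:10, 1)
    expected <- if (N >= w) floor((N - w) / s) + 1 else 0
    got <- suppressWarnings(build_windows(mkfeat(N), w, s))
    expect_length(got, expected)
    if (expected > 0) {
      expect_equal(vapply(got, function(x) x$start_frame, 1L),
                   as.integer(seq(0, by = s, length.out = expected)))
    }
  }
})

test_that("short missing runs are interpolated; long gaps split the sequence", {
  m <- matrix(1, 40, 8, dimnames = list(NULL, GAIT_FEATURES))
  m[, 1] <- seq_len(40)
  m[10:11, 1] <- NA               # 2-frame gap: bridged linearly
  w <- build_windows(m, 10, 10, max_gap = 3)
  expect_length(w, 4)
  expect_equal(unname(w[[1]]$features[10, 1]), 10)  # interpolated value

  m2 <- matrix(1, 40, 8, dimnames = list(NULL, GAIT_FEATURES))
  m2[18:23, ] <- NA               # 6-frame gap: splits into 17 + 17 frames
  w2 <- build_windows(m2, 10, 5, max_gap = 3)
  starts <- vapply(w2, function(x) x$start_frame, 1L)
  expect_equal(starts, c(0L, 5L, 23L, 28L))
})

test_that("classifier separates well-separated synthetic gait classes", {
  train <- list(); labels <- integer(0)
  for (l in c(1, 4)) for (clip in 1:10) {
    g <- gen_gait_sequence(gait_script(l, n_frames = 45, noise_px = 1,
                                       seed = 100 * l + clip))
    ft <- gait_feature_table(g$poses, g$edges)
    w <- build_windows(ft[, GAIT_FEATURES], 20, 5)
    train <- c(train, w); labels <- c(labels, rep(l, length(w)))
  }
  clf <- train_sequence_classifier(train, labels, seed = 5)
  test_w <- list(); test_l <- integer(0)
  for (l in c(1, 4)) for (clip in 1:5) {
    g <- gen_gait_sequence(gait_script(l, n_frames = 45, noise_px = 1,
                                       seed = 9000 + 10 * l + clip))
    ft <- gait_feature_table(g$poses, g$edges)
    w <- build_windows(ft[, GAIT_FEATURES], 20, 5)
    test_w <- c(test_w, w); test_l <- c(test_l, rep(l, length(w)))
  }
  acc <- mean(predict_window_class(clf, test_w) == test_l)
  expect_gt(acc, 0.9)

  # determinism: same data and seed give identical predictions
  clf2 <- train_sequence_classifier(train, labels, seed = 5)
  expect_identical(predict_window_scores(clf, test_w),
                   predict_window_scores(clf2, test_w))

  expect_error(train_sequence_classifier(train, rep(2L, length(train)), 1),
               "degenerate")
})

test_that("clip score is the unrounded mean of window scores", {
  cs <- score_clip(c(2, 2, 3))
  expect_equal(cs$clip_score, 7 / 3)
  expect_equal(score_clip(4)$clip_score, 4.0)
  expect_error(score_clip(numeric(0)), "no windows")
})

test_that("walking direction sign makes mirrored walks give identical features", {
  g <- gen_gait_sequence(gait_script(2, n_frames = 30, noise_px = 0))
  # add forward drift so the direction sign is inferred from real motion
  moving <- lapply(g$poses, function(p) {
    kp <- p$keypoints
    kp$x <- kp$x + 3 * p$frame_index
    cattle_pose(p$frame_index, kp)
  })
  ft <- gait_feature_table(moving, g$edges)
  # mirror every pose about x = 0 (cow now walks the other way)
  mirrored <- lapply(moving, function(p) {
    kp <- p$keypoints
    kp$x <- -kp$x
    cattle_pose(p$frame_index, kp)
  })
  ftm <- gait_feature_table(mirrored, g$edges)
  expect_equal(ftm, ft, tolerance = 1e-12)
})
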
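test_that("track centroids map to pen centimetres with out-of-pen flagging", {
  sq <- rbind(c(0, 0), c(580, 0), c(580, 380), c(0, 380))
  tr <- compute_world_transform(sq)
  track <- list(
    track_frame(0, 1, c(280, 180, 300, 200), c(290, 190), "standing"),
    track_frame(1, 1, c(640, 180, 660, 200), c(650, 190), "standing"))
  w <- track_to_world(track, tr)
  expect_equal(c(w$x_cm[1], w$y_cm[1]), c(290, 190))
  expect_false(w$out_of_pen[1])
  expect_true(w$out_of_pen[2])   # 650 > 580 + 20 margin
})

test_that("distance accrues only while standing and gates glitch speeds", {
  # stationary standing pig
  xy <- matrix(rep(c(100, 100), 100), ncol = 2, byrow = TRUE)
  expect_equal(as.numeric(distance_traveled(xy, rep("standing", 100), 15)), 0)

  # straight 100 cm walk while standing
  xy2 <- cbind(seq(0, 100, length.out = 51), 0)
  d2 <- distance_traveled(xy2, rep("standing", 51), 15)
  expect_equal(as.numeric(d2), 100)
  expect_equal(attr(d2, "dropped_steps"), 0L)

  # same walk but lying throughout -> no distance
  expect_equal(as.numeric(distance_traveled(xy2, rep("lying", 51), 15)), 0)

  # posture transition frames do not count
  xy3 <- cbind(c(0, 10, 20, 30), 0)
  d3 <- distance_traveled(xy3, c("standing", "standing", "lying", "standing"), 1)
  expect_equal(as.numeric(d3), 10)

  # a 100 cm teleport at 15 fps implies 1500 cm/s -> dropped and tallied
  xy4 <- cbind(c(0, 1, 101, 102), 0)
  d4 <- distance_traveled(xy4, rep("standing", 4), 15)
  expect_equal(as.numeric(d4), 2)
  expect_equal(attr(d4, "dropped_steps"), 1L)

  expect_error(distance_traveled(xy2, rep("standing", 3), 15), "equal length")
})

test_that("distance is additive over splits and rotation invariant", {
  set.seed(9)
  xy <- cbind(cumsum(rnorm(60)), cumsum(rnorm(60)))
  post <- rep("standing", 60)
  whole <- as.numeric(distance_traveled(xy, post, 15))
  parts <- as.numeric(distance_traveled(xy[1:30, ], post[1:30], 15)) +
    as.numeric(distance_traveled(xy[30:60, ], post[30:60], 15))
  expect_equal(whole, parts, tolerance = 1e-9)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(as.numeric(distance_traveled(xy %*% t(R), post, 15)), whole,
               tolerance = 1e-9)
})

test_that("posture budget partitions the tracked time exactly", {
  expect_equal(posture_budget(rep("standing", 150), 15),
               c(standing_s = 10, lying_s = 0))
  alt <- rep(c("standing", "lying"), 50)
  expect_equal(posture_budget(alt, 10), c(standing_s = 5, lying_s = 5))
  expect_equal(posture_budget(character(0), 15),
               c(standing_s = 0, lying_s = 0))
  post <- c(rep("standing", 37), rep("lying", 13))
  pb <- posture_budget(post, 15)
  expect_equal(sum(pb), 50 / 15)
})

test_that("bounding-box contact uses the min-area overlap fraction", {
  a <- c(0, 0, 10, 10)
  r <- detect_contact(a, a)
  expect_true(r$contact)
  expect_equal(r$overlap_fraction, 1.0)

  r2 <- detect_contact(a, c(20, 20, 30, 30))
  expect_false(r2$contact)
  expect_equal(r2$overlap_fraction, 0)

  r3 <- detect_contact(a, c(5, 0, 15, 10))
  expect_equal(r3$overlap_fraction, 0.5)
  expect_true(r3$contact)

  # symmetric, bounded, threshold respected
  set.seed(5)
  for (i in 1:50) {
    b1 <- c(sort(runif(2, 0, 20)), sort(runif(2, 0, 20)))[c(1, 3, 2, 4)]
    b2 <- c(sort(runif(2, 0, 20)), sort(runif(2, 0, 20)))[c(1, 3, 2, 4)]
    f12 <- detect_contact(b1, b2)
    f21 <- detect_contact(b2, b1)
    expect_equal(f12$overlap_fraction, f21$overlap_fraction)
    expect_identical(f12$contact, f21$contact)
    expect_true(f12$overlap_fraction >= 0 && f12$overlap_fraction <= 1)
  }
  expect_error(detect_contact(c(0, 0, 0, 10), a), "zero-area")
})

test_that("interaction confirmation ORs motion, posture change and SSIM", {
  img <- matrix(runif(400, 0, 255), 20, 20)
  # identical crops, no motion, no posture change -> not confirmed (SSIM = 1)
  expect_false(confirm_interaction(img, img, centroid_step_cm = c(0, 0),
                                   posture_changed = c(FALSE, FALSE)))
  # motion above the gate confirms regardless of SSIM
  expect_true(confirm_interaction(img, img, centroid_step_cm = c(5, 0),
                                  posture_changed = c(FALSE, FALSE)))
  # posture change alone confirms
  expect_true(confirm_interaction(img, img, centroid_step_cm = c(0, 0),
                                  posture_changed = c(TRUE, FALSE)))
  # appearance change (scrambled crop) confirms through SSIM
  img2 <- matrix(runif(400, 0, 255), 20, 20)
  expect_true(confirm_interaction(img, img2, centroid_step_cm = c(0, 0),
                                  posture_changed = c(FALSE, FALSE)))
  expect_error(confirm_interaction(img, img[1:10, ], 0, FALSE), "shape")
})

test_that("fine interaction labels follow the part-pair taxonomy", {
  mk <- function(...) list(...)
  body_a <- rect_poly(0, 0, 100, 40)
  # mouth over tail only
  r <- classify_fine_interaction(
    mk(body = body_a, mouth = rect_poly(90, 10, 110, 30)),
    mk(body = rect_poly(120, 0, 220, 40), tail = rect_poly(105, 10, 125, 30)))
  expect_equal(r$fine_label, "mouth_to_tail")
  expect_equal(r$actor, "a")
  # body-body only
  r2 <- classify_fine_interaction(
    mk(body = body_a), mk(body = rect_poly(80, 0, 180, 40)))
  expect_equal(r2$fine_label, "body_contact")
  expect_true(is.na(r2$actor))
  # nothing above min_iou
  r3 <- classify_fine_interaction(
    mk(body = body_a), mk(body = rect_poly(500, 0, 600, 40)))
  expect_equal(r3$fine_label, "unclassified")
  # ear-ear maps to head_to_head
  r4 <- classify_fine_interaction(
    mk(body = rect_poly(0, 0, 10, 10), left_ear = rect_poly(10, 0, 20, 10)),
    mk(body = rect_poly(30, 0, 40, 10), right_ear = rect_poly(12, 0, 22, 10)))
  expect_equal(r4$fine_label, "head_to_head")
  expect_error(classify_fine_interaction(mk(mouth = body_a), mk(body = body_a)),
               "body")
})

test_that("selected part pair equals the brute-force max-IoU pair on random scenes", {
  set.seed(11)
  parts_of <- function() {
    n <- sample(2:5, 1)
    nm <- c("body", sample(c("mouth", "left_ear", "right_ear", "tail"), n - 1))
    out <- lapply(seq_len(n), function(i) {
      x0 <- runif(1, 0, 60); y0 <- runif(1, 0, 60)
      rect_poly(x0, y0, x0 + runif(1, 5, 40), y0 + runif(1, 5, 40))
    })
    names(out) <- nm
    out
  }
  for (s in 1:200) {
    pa <- parts_of(); pb <- parts_of()
    got <- classify_fine_interaction(pa, pb)
    # independent route: closed-form rectangle IoU over all cross pairs
    best <- list(v = -1, pa = NA, pb = NA)
    for (na in names(pa)) for (nb in names(pb)) {
      v <- rect_iou(pa[[na]], pb[[nb]])
      if (v > best$v) best <- list(v = v, pa = na, pb = nb)
    }
    if (best$v < 0.02 - 1e-6) {
      expect_equal(got$fine_label, "unclassified")
    } else if (best$v >= 0.02 + 1e-6) {
      expect_equal(got$iou, best$v, tolerance = 1e-9)
      expect_equal(got$pair, c(best$pa, best$pb))
    }
  }
})

test_that("enrichment interactions use overlap, plus movement for the ball", {
  hay <- rect_poly(0, 0, 50, 50)
  pig_on <- rect_poly(40, 40, 140, 80)
  pig_off <- rect_poly(60, 60, 160, 100)
  expect_true(detect_enrichment_interaction(pig_on, "hay", hay))
  expect_false(detect_enrichment_interaction(pig_off, "pole", hay))
  # ball: no overlap but it moved 10 cm -> interaction
  expect_true(detect_enrichment_interaction(pig_off, "ball", hay,
                                            ball_step_cm = 10))
  expect_false(detect_enrichment_interaction(pig_off, "ball", hay,
                                             ball_step_cm = 1))
  expect_error(detect_enrichment_interaction(pig_on, "wheel", hay), "wheel")
})

test_that("occlusion relabeling restores scripted identities", {
  oc <- gen_occlusion_scenario()
  fixed <- reassign_after_occlusion(oc$tracks, oc$transform)
  got <- unlist(lapply(fixed, function(fr) vapply(fr, function(t) t$track_id, 1L)))
  expect_equal(unname(got), oc$truth_ids$true_id)

  # no disappearances -> stream unchanged
  sc <- gen_pen_scene(pen_script(3, 2))
  same <- reassign_after_occlusion(sc$tracks, sc$transform)
  ids0 <- unlist(lapply(sc$tracks, function(fr) vapply(fr, function(t) t$track_id, 1L)))
  ids1 <- unlist(lapply(same, function(fr) vapply(fr, function(t) t$track_id, 1L)))
  expect_equal(ids1, ids0)

  # a reappearance beyond the gate keeps its new identity
  oc2 <- gen_occlusion_scenario()
  far <- reassign_after_occlusion(oc2$tracks, oc2$transform, gate_cm = 1)
  got2 <- unlist(lapply(far, function(fr) vapply(fr, function(t) t$track_id, 1L)))
  expect_true(any(got2 %in% c(3L, 4L)))
})

test_that("scripted pen scenes are recovered exactly under zero noise", {
  pen <- synthetic_pen()
  sc <- gen_pen_scene(pen_script(4, 20, events = list(
    list(time_s = 2, duration_s = 2, kind = "mouth_to_tail", participants = c(1, 2)),
    list(time_s = 7, duration_s = 2, kind = "head_to_head", participants = c(3, 4)),
    list(time_s = 12, duration_s = 3, kind = "body_contact", participants = c(1, 3)),
    list(time_s = 17, duration_s = 2, kind = "hay", participants = 2))), pen)
  ev <- detect_interactions(sc$tracks, pen, sc$transform)
  truth <- sc$truth[order(sc$truth$start_frame), ]
  expect_equal(nrow(ev), nrow(truth))
  expect_equal(ev$start_frame, truth$start_frame)
  expect_equal(ev$end_frame, truth$end_frame)
  expect_equal(ev$a, truth$a)
  expect_equal(ev$b, truth$b)
  expect_equal(ev$fine_label, truth$fine_label)
  expect_true(all(ev$confirmed))
})

test_that("hourly interaction minutes conserve event totals", {
  pen <- synthetic_pen()
  sc <- gen_pen_scene(pen_script(2, 4, events = list(
    list(time_s = 1, duration_s = 2, kind = "body_contact", participants = c(1, 2)))),
    pen)
  ev <- detect_interactions(sc$tracks, pen, sc$transform)
  summ <- activity_summary(sc$tracks, sc$transform)
  rep <- build_activity_report(ev, summ, fps = 15)
  # one confirmed event of 30 frames at 15 fps -> 2 s = 1/30 min per pig
  expect_equal(unname(rowSums(rep$interaction_minutes)),
               rep(30 / 15 / 60, 2))
  # time budget partitions the scene for every pig
  expect_equal(summ$standing_s + summ$lying_s, rep(4, 2))

  # random event sets: binned minutes equal per-event totals
  set.seed(31)
  ev2 <- data.frame(
    start_frame = sort(sample(0:200000, 10)), kind = "animal_animal",
    a = "1", b = "2", fine_label = "body_contact", confirmed = TRUE)
  ev2$end_frame <- ev2$start_frame + sample(10:5000, 10)
  ev2$n_frames <- ev2$end_frame - ev2$start_frame + 1
  rep2 <- build_activity_report(ev2, data.frame(animal = c("1", "2"),
                                                standing_s = 0, lying_s = 0,
                                                distance_cm = 0), fps = 15)
  expect_equal(unname(rowSums(rep2$interaction_minutes)),
               rep(sum(ev2$n_frames) / 15 / 60, 2), tolerance = 1e-9)
})

test_that("a spanning event of 900 frames at 15 fps books exactly one minute", {
  ev <- data.frame(start_frame = 0, end_frame = 899, kind = "animal_animal",
                   a = "1", b = "2", fine_label = "body_contact",
                   confirmed = TRUE, n_frames = 900)
  summ <- data.frame(animal = c("1", "2"), standing_s = 60, lying_s = 0,
                     distance_cm = 0)
  rep <- build_activity_report(ev, summ, fps = 15)
  expect_equal(unname(rowSums(rep$interaction_minutes)), c(1, 1))
  # no events -> all-zero matrix
  rep0 <- build_activity_report(ev[0, ], summ, fps = 15)
  expect_true(all(rep0$interaction_minutes == 0))
})

test_that("SSIM-based confirmation works end to end on rendered crops", {
  pen <- synthetic_pen()
  sc <- gen_pen_scene(pen_script(2, 4, events = list(
    list(time_s = 1, duration_s = 2, kind = "body_contact",
         participants = c(1, 2)))), pen, render_crops = TRUE)
  ev <- detect_interactions(sc$tracks, pen, sc$transform, crops = sc$crops)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$fine_label, "body_contact")
  expect_true(ev$confirmed)
})
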
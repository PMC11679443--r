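# Seeded synthetic-fixture generators. Every input the analysis modules
# consume can be produced here with controllable ground truth: gait keypoint
# sequences across lameness levels, embedding clusters for open-set
# identification, scripted pen scenes with a ground-truth interaction log,
# and colour-tag observations. All generators are pure functions of
# (script, seed).

#' Gait generation script
#'
#' @param lameness_level integer 1 (normal) .. 5 (severely lame).
#' @param n_frames clip length in frames (default 120, i.e. 6 s at 20 fps).
#' @param fps frame rate (default 20, the side-camera clip rate).
#' @param noise_px Gaussian pixel noise added to every keypoint and edge
#'   point (default 1).
#' @param seed RNG seed.
#' @return object of class `gait_script`.
#' @export
gait_script <- function(lameness_level, n_frames = 120, fps = 20,
                        noise_px = 1, seed = 1) {
  lameness_level <- as.integer(lameness_level)
  if (lameness_level < 1 || lameness_level > 5) {
    stop("lameness_level must be in 1..5", call. = FALSE)
  }
  if (noise_px < 0) stop("noise_px must be >= 0", call. = FALSE)
  structure(list(lameness_level = lameness_level, n_frames = n_frames,
                 fps = fps, noise_px = noise_px, seed = seed),
            class = "gait_script")
}

#' Generate a synthetic side-view gait sequence
#'
#' Sinusoidal leg kinematics in which three lameness signatures each grow
#' monotonically with the lameness level: step asymmetry (the right leg pair's
#' swing amplitude grows while the left pair's shrinks), vertical head-bob
#' amplitude, and back-arch sagitta (zero at level 1, 10% of body length at
#' level 5). Gaussian pixel noise is added on top; the draw is deterministic
#' per seed.
#'
#' @param script [gait_script()] object.
#' @return list with `poses` (list of [cattle_pose()]), `edges` (list of
#'   [back_edge()]), `true_level`, `fps`.
#' @export
gen_gait_sequence <- function(script) {
  stopifnot(inherits(script, "gait_script"))
  lvl <- script$lameness_level
  set.seed(script$seed)
  L <- 300                       # body length, px
  base <- list(
    head = c(40, 75), withers = c(100, 100), pin = c(400, 100),
    fr_elbow = c(130, 180), fl_elbow = c(145, 180),
    br_elbow = c(330, 180), bl_elbow = c(345, 180),
    # extra slots filling the 16-point format
    nose = c(20, 85), neck = c(75, 90), back_mid = c(250, 95),
    tail_base = c(420, 110), belly = c(250, 170)
  )
  A0 <- 40
  A_right <- A0 * (1 + 0.12 * (lvl - 1))
  A_left  <- A0 * (1 - 0.06 * (lvl - 1))
  bob <- 3 * (lvl - 1)
  sagitta <- 0.025 * (lvl - 1) * L / 3   # level 5 -> 0.033 L
  omega <- 2 * pi * 1.2 / script$fps     # 1.2 strides per second

  poses <- vector("list", script$n_frames)
  edges <- vector("list", script$n_frames)
  for (t in seq_len(script$n_frames)) {
    s <- sin(omega * (t - 1))
    kp <- base
    kp$head[2] <- base$head[2] + bob * sin(omega * (t - 1) + 0.5)
    kp$fr_hoof <- c(base$fr_elbow[1] + A_right * s, 260)
    kp$bl_hoof <- c(base$bl_elbow[1] + A_left * s, 260)
    kp$fl_hoof <- c(base$fl_elbow[1] - A_left * s, 260)
    kp$br_hoof <- c(base$br_elbow[1] - A_right * s, 260)
    m <- do.call(rbind, kp)
    if (script$noise_px > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, script$noise_px), nrow(m))
    }
    poses[[t]] <- cattle_pose(t - 1L, data.frame(
      name = rownames(m), x = m[, 1], y = m[, 2], confidence = 1))

    u <- seq(0, 1, length.out = 21)
    ex <- base$withers[1] + u * (base$pin[1] - base$withers[1])
    ey <- base$withers[2] - sagitta * 4 * u * (1 - u)
    if (script$noise_px > 0) {
      ex <- ex + stats::rnorm(21, 0, script$noise_px)
      ey <- ey + stats::rnorm(21, 0, script$noise_px)
    }
    edges[[t]] <- back_edge(cbind(ex, ey), L)
  }
  list(poses = poses, edges = edges, true_level = lvl, fps = script$fps)
}

#' Generate Gaussian embedding clusters for identification tests
#'
#' Places `k_ids` centroids with pairwise distance at least `separation`
#' (rejection sampling in a cube, deterministic per seed) and draws isotropic
#' Gaussian encodings around each.
#'
#' @param k_ids number of animals.
#' @param per_id encodings per animal.
#' @param sigma within-cluster standard deviation per coordinate.
#' @param separation minimal inter-centroid Euclidean distance (> 0).
#' @param dim latent dimension (default 3, the coat-pattern latent space).
#' @param seed RNG seed.
#' @return list with `points` (matrix), `ids` (character vector), `centroids`
#'   (matrix with id rownames).
#' @export
gen_embedding_clusters <- function(k_ids, per_id, sigma, separation,
                                   dim = 3, seed = 1) {
  if (separation <= 0) stop("separation must be positive", call. = FALSE)
  set.seed(seed)
  side <- separation * max(2, ceiling(k_ids^(1 / dim)) + 1)
  centroids <- matrix(NA_real_, 0, dim)
  tries <- 0
  while (nrow(centroids) < k_ids) {
    cand <- stats::runif(dim, 0, side)
    ok <- !nrow(centroids) ||
      min(sqrt(rowSums(sweep(centroids, 2, cand)^2))) >= separation
    if (ok) centroids <- rbind(centroids, cand)
    tries <- tries + 1
    if (tries > 10000 * k_ids) stop("could not place centroids", call. = FALSE)
  }
  ids <- sprintf("cow%02d", seq_len(k_ids))
  rownames(centroids) <- ids
  points <- do.call(rbind, lapply(seq_len(k_ids), function(i) {
    sweep(matrix(stats::rnorm(per_id * dim, 0, sigma), per_id, dim), 2,
          centroids[i, ], `+`)
  }))
  list(points = points, ids = rep(ids, each = per_id), centroids = centroids)
}

#' Generate noisy colour-tag observations around roster templates
#'
#' @param roster list of [animal_template()] entries.
#' @param sigma_lab Gaussian noise s.d. per CIELAB component.
#' @param n number of draws (templates cycled).
#' @param seed RNG seed.
#' @return data.frame with `true_id`, `L`, `a`, `b`, `symbol`.
#' @export
gen_color_observations <- function(roster, sigma_lab, n, seed = 1) {
  if (!length(roster)) stop("roster is empty", call. = FALSE)
  set.seed(seed)
  idx <- rep_len(seq_along(roster), n)
  rows <- lapply(idx, function(i) {
    t <- roster[[i]]
    lab <- t$lab + stats::rnorm(3, 0, sigma_lab)
    lab[1] <- min(max(lab[1], 0), 100)
    data.frame(true_id = t$animal_id, L = lab[1], a = lab[2], b = lab[3],
               symbol = if (is.null(t$symbol)) NA_character_ else t$symbol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pen scene script
#'
#' @param n_pigs number of pigs (1..6).
#' @param duration_s scene length in seconds.
#' @param fps frame rate (default 15, the pen camera rate).
#' @param events list of scripted events; each a list with `time_s`,
#'   `duration_s`, `kind` (a fine interaction label for pig-pig events, or an
#'   enrichment name), and `participants` (two track ids, or one for
#'   enrichment).
#' @param seed RNG seed.
#' @return object of class `pen_script`.
#' @export
pen_script <- function(n_pigs, duration_s, fps = 15, events = list(),
                       seed = 1) {
  if (n_pigs < 1 || n_pigs > 6) stop("n_pigs must be 1..6", call. = FALSE)
  for (e in events) {
    if (e$time_s < 0 || e$time_s + e$duration_s > duration_s) {
      stop("event outside scene duration", call. = FALSE)
    }
    if (!e$kind %in% c(setdiff(FINE_LABELS, "unclassified"), ENRICHMENT_NAMES)) {
      stop(sprintf("unknown event kind '%s'", e$kind), call. = FALSE)
    }
  }
  structure(list(n_pigs = n_pigs, duration_s = duration_s, fps = fps,
                 events = events, seed = seed),
            class = "pen_script")
}

#' A ready-made synthetic pen configuration
#'
#' Mildly trapezoidal pen corners in a small synthetic camera frame, with
#' enrichment polygons placed along the pen edges (away from the pigs' rest
#' positions) and an optional colour roster.
#'
#' @param img_w,img_h synthetic camera frame size in pixels.
#' @param world_dims pen dimensions in cm (default 580 x 380).
#' @param enrichment_names which enrichment objects to place.
#' @param roster optional list of [animal_template()] entries.
#' @return [pen_config()] object with an attached `world_transform` attribute
#'   and `enrichment_world` attribute (world-cm rectangles).
#' @export
synthetic_pen <- function(img_w = 160, img_h = 120, world_dims = c(580, 380),
                          enrichment_names = c("hay", "ball"),
                          roster = list()) {
  corners <- rbind(c(10, 6), c(img_w - 10, 8), c(img_w - 5, img_h - 8),
                   c(6, img_h - 10))
  tr <- compute_world_transform(corners, world_dims)
  slots <- list(feeder = c(60, 40), drinker = c(180, 40), hay = c(300, 40),
                pole = c(420, 40), ball = c(520, 60))
  enr_world <- list()
  enr_px <- list()
  for (nm in enrichment_names) {
    ctr <- slots[[nm]]
    rect <- rbind(ctr + c(-35, -25), ctr + c(35, -25),
                  ctr + c(35, 25), ctr + c(-35, 25))
    enr_world[[nm]] <- rect
    enr_px[[nm]] <- apply_transform(tr, rect, inverse = TRUE)
  }
  pen <- pen_config(corners, world_dims, enrichment = enr_px, roster = roster)
  attr(pen, "world_transform") <- tr
  attr(pen, "enrichment_world") <- enr_world
  pen
}

# pig part polygons in the local frame (cm): facing +u, centered on the body
PIG_LOCAL_PARTS <- list(
  body      = rbind(c(-50, -20), c(50, -20), c(50, 20), c(-50, 20)),
  mouth     = rbind(c(40, -8), c(58, -8), c(58, 8), c(40, 8)),
  left_ear  = rbind(c(30, -22), c(45, -22), c(45, -10), c(30, -10)),
  right_ear = rbind(c(30, 10), c(45, 10), c(45, 22), c(30, 22)),
  tail      = rbind(c(-58, -8), c(-40, -8), c(-40, 8), c(-58, 8))
)

# relative placement of pig b (in a's local frame) realising each fine label:
# offsets chosen so the intended part pair carries the maximal IoU while the
# bounding boxes still overlap by more than the contact threshold
PLACEMENTS <- list(
  mouth_to_tail = list(offset = c(95, 0),   heading = 0),
  head_to_head  = list(offset = c(102, 0),  heading = 180),
  mouth_to_body = list(offset = c(65, 0),   heading = 90),
  mouth_to_ear  = list(offset = c(92, 20),  heading = 180),
  body_contact  = list(offset = c(-30, 36), heading = 0)
)

rotate2 <- function(pts, deg) {
  th <- deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  pts %*% t(R)
}

pig_world_parts <- function(center, heading_deg) {
  lapply(PIG_LOCAL_PARTS, function(p) {
    sweep(rotate2(p, heading_deg), 2, center, `+`)
  })
}

#' Generate a scripted pen scene with ground truth
#'
#' Pigs rest at fixed, well-separated world positions (standing, stationary).
#' During a scripted pig-pig event the second participant is placed against
#' the first in the geometric arrangement realising the requested fine label,
#' and the pair jitters laterally by 1.5 cm per frame (3 cm inter-frame
#' steps, enough to confirm the interaction by motion); during an enrichment
#' event the participant is placed on the enrichment object. Everything is
#' projected to pixels through the pen homography. The ground-truth event log
#' is a first-class output, so tests never re-derive truth from the data.
#'
#' @param script [pen_script()] object.
#' @param pen [synthetic_pen()] configuration.
#' @param render_crops if TRUE also return per-frame grayscale images
#'   (textured pig rectangles on a flat background) for SSIM confirmation.
#' @return list with `tracks` (grouped track stream), `truth` (data.frame of
#'   scripted events: `start_frame`, `end_frame`, `kind`, `a`, `b`,
#'   `fine_label`), `crops` (named list of matrices or NULL), `transform`.
#' @export
gen_pen_scene <- function(script, pen = synthetic_pen(),
                          render_crops = FALSE) {
  stopifnot(inherits(script, "pen_script"))
  set.seed(script$seed)
  tr <- attr(pen, "world_transform")
  if (is.null(tr)) tr <- compute_world_transform(pen$corners_px, pen$world_dims)
  enr_world <- attr(pen, "enrichment_world")
  n_frames <- round(script$duration_s * script$fps)
  bases <- pig_base_positions(script$n_pigs)

  truth <- list()
  spans <- lapply(script$events, function(e) {
    f0 <- floor(e$time_s * script$fps)
    f1 <- floor((e$time_s + e$duration_s) * script$fps) - 1
    c(f0, f1)
  })
  for (k in seq_along(script$events)) {
    e <- script$events[[k]]
    is_pig <- e$kind %in% FINE_LABELS
    truth[[k]] <- data.frame(
      start_frame = spans[[k]][1], end_frame = spans[[k]][2],
      kind = if (is_pig) "animal_animal" else "enrichment",
      a = as.character(min(as.integer(e$participants))),
      b = if (is_pig) as.character(max(as.integer(e$participants))) else e$kind,
      fine_label = if (is_pig) e$kind else NA_character_,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(start_frame = integer(0), end_frame = integer(0),
               kind = character(0), a = character(0), b = character(0),
               fine_label = character(0))

  frames <- list()
  crops <- if (render_crops) vector("list", n_frames) else NULL
  img_dim <- c(120, 160)  # rows (y), cols (x) of the synthetic camera frame
  for (f in seq_len(n_frames) - 1L) {
    centers <- bases
    headings <- rep(0, script$n_pigs)
    jitter <- c(0, ifelse(f %% 2 == 0, 1.5, -1.5))
    for (k in seq_along(script$events)) {
      e <- script$events[[k]]
      if (f < spans[[k]][1] || f > spans[[k]][2]) next
      if (e$kind %in% FINE_LABELS) {
        a <- as.integer(e$participants[1]); b <- as.integer(e$participants[2])
        pl <- PLACEMENTS[[e$kind]]
        centers[a, ] <- bases[a, ] + jitter
        centers[b, ] <- bases[a, ] + pl$offset + jitter
        headings[b] <- pl$heading
      } else {
        p <- as.integer(e$participants[1])
        centers[p, ] <- colMeans(enr_world[[e$kind]])
      }
    }
    frame <- lapply(seq_len(script$n_pigs), function(i) {
      parts_w <- pig_world_parts(centers[i, ], headings[i])
      parts_px <- lapply(parts_w, function(p) apply_transform(tr, p, inverse = TRUE))
      allv <- do.call(rbind, parts_px)
      bbox <- c(min(allv[, 1]), min(allv[, 2]), max(allv[, 1]), max(allv[, 2]))
      cent <- apply_transform(tr, matrix(centers[i, ], ncol = 2), inverse = TRUE)
      track_frame(f, i, bbox, as.numeric(cent), "standing", parts_px)
    })
    frames[[length(frames) + 1]] <- frame
    if (render_crops) {
      crops[[f + 1]] <- render_frame(frame, img_dim)
      names(crops)[f + 1] <- as.character(f)
    }
  }
  grouped <- group_track_frames(unlist(frames, recursive = FALSE),
                                fps = script$fps)
  list(tracks = grouped, truth = truth, crops = crops, transform = tr)
}

# rest positions spaced so that a scripted contact placement (which can put
# the second participant up to ~215 cm beyond the first's base) never grazes
# a third pig's bounding box
pig_base_positions <- function(n_pigs) {
  xs <- c(80, 380); ys <- c(90, 190, 290)
  g <- as.matrix(expand.grid(xs, ys))
  unname(g[seq_len(n_pigs), , drop = FALSE])
}

# flat background + per-pig textured rectangle over its bbox; texture is
# anchored to the pig (moves with it) so SSIM drops when the pig moves
render_frame <- function(frame, img_dim) {
  img <- matrix(30, img_dim[1], img_dim[2])
  for (tf in frame) {
    b <- tf$bbox
    rows <- max(1, floor(b[2]) + 1):min(img_dim[1], ceiling(b[4]) + 1)
    cols <- max(1, floor(b[1]) + 1):min(img_dim[2], ceiling(b[3]) + 1)
    # texture phase is tied to the (sub-pixel) centroid, so even small
    # scripted motion decorrelates the pattern and depresses local SSIM
    ph <- 7 * tf$centroid
    rr <- outer(rows - b[2], cols - b[1], function(y, x) {
      120 + 20 * tf$track_id + 60 * sin(x * 1.9 + ph[1]) * cos(y * 1.7 + ph[2])
    })
    img[rows, cols] <- rr
  }
  pmin(pmax(img, 0), 255)
}

#' Add Gaussian pixel jitter to a grouped track stream
#'
#' Perturbs every part-polygon vertex with isotropic Gaussian pixel noise,
#' recomputes bounding boxes from the jittered parts, and jitters centroids
#' (clamped inside the new bbox). Emulates detector/segmentation noise on an
#' otherwise clean scripted scene.
#'
#' @param grouped grouped track stream.
#' @param sigma_px noise standard deviation in pixels.
#' @param seed RNG seed.
#' @return jittered grouped stream (same structure and attributes).
#' @export
jitter_tracks <- function(grouped, sigma_px, seed = 1) {
  set.seed(seed)
  out <- grouped
  for (g in seq_along(grouped)) {
    frame <- grouped[[g]]
    for (i in seq_along(frame)) {
      tf <- frame[[i]]
      if (!is.null(tf$parts)) {
        tf$parts <- lapply(tf$parts, function(p) {
          p + matrix(stats::rnorm(length(p), 0, sigma_px), nrow(p))
        })
        allv <- do.call(rbind, tf$parts)
        tf$bbox <- c(min(allv[, 1]), min(allv[, 2]),
                     max(allv[, 1]), max(allv[, 2]))
      } else {
        tf$bbox <- tf$bbox + stats::rnorm(4, 0, sigma_px) *
          c(-1, -1, 1, 1) * abs(stats::rnorm(4, 1, 0.2))
        tf$bbox <- c(pmin(tf$bbox[1:2], tf$bbox[3:4] - 1),
                     pmax(tf$bbox[3:4], tf$bbox[1:2] + 1))
      }
      cent <- tf$centroid + stats::rnorm(2, 0, sigma_px)
      tf$centroid <- pmin(pmax(cent, tf$bbox[1:2]), tf$bbox[3:4])
      frame[[i]] <- track_frame(tf$frame_index, tf$track_id, tf$bbox,
                                tf$centroid, tf$posture, tf$parts)
    }
    out[[g]] <- frame
  }
  out
}

#' Generate a scripted occlusion scenario for identity recovery
#'
#' Two pigs approach each other; during a short occlusion both tracks drop
#' out, and the tracker re-emits them under fresh ids with their positions
#' crossed. Ground truth is the original identity of every emitted frame.
#'
#' @param fps frame rate (default 15).
#' @param seed RNG seed (jitter-free scenario; kept for interface symmetry).
#' @return list with `tracks` (grouped stream), `truth_ids` (data.frame of
#'   `frame_index`, `emitted_id`, `true_id`), `transform`.
#' @export
gen_occlusion_scenario <- function(fps = 15, seed = 1) {
  pen <- synthetic_pen(enrichment_names = character(0))
  tr <- attr(pen, "world_transform")
  path1 <- cbind(seq(100, 400, length.out = 100), 200)  # walks +x
  path2 <- cbind(seq(400, 100, length.out = 100), 220)  # walks -x
  frames <- list(); truth <- list()
  for (f in 0:99) {
    occluded <- f >= 48 & f <= 52
    if (occluded) next
    mk <- function(id, pos, true_id) {
      bbox <- c(pos[1] - 55, pos[2] - 25, pos[1] + 55, pos[2] + 25)
      bpx <- apply_transform(tr, rbind(bbox[1:2], bbox[3:4]), inverse = TRUE)
      cpx <- apply_transform(tr, matrix(pos, ncol = 2), inverse = TRUE)
      truth[[length(truth) + 1]] <<- data.frame(
        frame_index = f, emitted_id = id, true_id = true_id)
      track_frame(f, id,
                  c(min(bpx[, 1]), min(bpx[, 2]), max(bpx[, 1]), max(bpx[, 2])),
                  as.numeric(cpx), "standing")
    }
    if (f < 48) {
      frames[[length(frames) + 1]] <- mk(1L, path1[f + 1, ], 1L)
      frames[[length(frames) + 1]] <- mk(2L, path2[f + 1, ], 2L)
    } else {
      # tracker re-emits with fresh ids, crossed: id 3 continues pig 2's
      # path, id 4 continues pig 1's
      frames[[length(frames) + 1]] <- mk(3L, path2[f + 1, ], 2L)
      frames[[length(frames) + 1]] <- mk(4L, path1[f + 1, ], 1L)
    }
  }
  list(tracks = group_track_frames(frames, fps = fps),
       truth_ids = do.call(rbind, truth), transform = tr)
}
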
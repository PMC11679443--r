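# Pen-level pig behaviour analytics: pixel tracks -> world coordinates,
# posture/time budgets, standing travel distance, identity recovery after
# occlusions, and rule-based detection of animal-animal and
# animal-enrichment interactions.

FINE_LABELS <- c("mouth_to_tail", "mouth_to_ear", "mouth_to_body",
                 "head_to_head", "body_contact", "unclassified")

#' Map one pig's track to world (cm) coordinates
#'
#' Applies the pen homography to each frame's centroid. Points falling
#' outside the pen rectangle by more than `margin` cm are flagged (tracker
#' glitches or mis-configured corners).
#'
#' @param track list of [track_frame()] objects for one animal.
#' @param transform [compute_world_transform()] result.
#' @param margin out-of-pen tolerance in cm (default 20).
#' @return data.frame with `frame_index`, `x_cm`, `y_cm`, `out_of_pen`.
#' @export
track_to_world <- function(track, transform, margin = 20) {
  stopifnot(inherits(transform, "world_transform"))
  cent <- t(vapply(track, function(tf) tf$centroid, numeric(2)))
  w <- apply_transform(transform, cent)
  L <- transform$world_dims[1]; W <- transform$world_dims[2]
  out <- w[, 1] < -margin | w[, 1] > L + margin |
    w[, 2] < -margin | w[, 2] > W + margin
  data.frame(frame_index = vapply(track, function(tf) tf$frame_index, 1L),
             x_cm = w[, 1], y_cm = w[, 2], out_of_pen = out)
}

#' Distance traveled by a standing pig
#'
#' Sums Euclidean steps between consecutive frames in which the pig is
#' standing in both frames (lying pigs accumulate no distance). Steps whose
#' implied speed exceeds `max_speed_cm_s` are dropped as tracker glitches and
#' tallied in the `dropped_steps` attribute.
#'
#' @param world_xy n x 2 matrix (or data.frame with `x_cm`, `y_cm`) of world
#'   positions in cm.
#' @param postures character vector of `"standing"`/`"lying"`, length n.
#' @param fps frame rate in Hz.
#' @param max_speed_cm_s speed gate (default 300 cm/s).
#' @return scalar distance in cm, with attribute `dropped_steps`.
#' @export
distance_traveled <- function(world_xy, postures, fps, max_speed_cm_s = 300) {
  if (is.data.frame(world_xy)) world_xy <- as.matrix(world_xy[, c("x_cm", "y_cm")])
  n <- nrow(world_xy)
  if (n != length(postures)) {
    stop("world_xy and postures must have equal length", call. = FALSE)
  }
  if (n < 2) return(structure(0, dropped_steps = 0L))
  steps <- sqrt(rowSums((world_xy[-1, , drop = FALSE] -
                           world_xy[-n, , drop = FALSE])^2))
  both_standing <- postures[-1] == "standing" & postures[-n] == "standing"
  speed_ok <- steps * fps <= max_speed_cm_s
  keep <- both_standing & speed_ok
  structure(sum(steps[keep]),
            dropped_steps = sum(both_standing & !speed_ok))
}

#' Standing / lying time budget
#'
#' @param postures character vector of per-frame postures.
#' @param fps frame rate in Hz (> 0).
#' @return named numeric `(standing_s, lying_s)`; sums to `length(postures)/fps`.
#' @export
posture_budget <- function(postures, fps) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  c(standing_s = sum(postures == "standing") / fps,
    lying_s = sum(postures == "lying") / fps)
}

#' Recover identities after tracker occlusions
#'
#' Maintains a short world-coordinate history per track. When a track id
#' disappears and a previously unseen id appears within `gate_cm` of the lost
#' id's last position inside `history_len` frames, the new id is relabeled to
#' the lost one; simultaneous candidates are resolved by greedy
#' minimal-total-distance matching.
#'
#' @param grouped grouped track stream (see [read_track_stream()]).
#' @param transform pen [compute_world_transform()] result.
#' @param history_len how many frames a lost id stays eligible (default 45,
#'   i.e. 3 s at 15 fps).
#' @param gate_cm maximal reappearance distance in cm (default 60).
#' @return relabeled grouped stream (same structure and attributes).
#' @export
reassign_after_occlusion <- function(grouped, transform, history_len = 45,
                                     gate_cm = 60) {
  mapping <- list()            # raw id (chr) -> canonical id (int)
  last_pos <- list()           # canonical id (chr) -> c(x_cm, y_cm)
  last_frame <- list()         # canonical id (chr) -> frame index
  out <- grouped
  for (g in seq_along(grouped)) {
    frame <- grouped[[g]]
    fidx <- frame[[1]]$frame_index
    raw_ids <- vapply(frame, function(tf) tf$track_id, 1L)
    wpos <- apply_transform(transform,
                            t(vapply(frame, function(tf) tf$centroid, numeric(2))))
    canon <- vapply(as.character(raw_ids),
                    function(r) mapping[[r]] %||% NA_integer_, 1L)
    fresh <- which(is.na(canon) & !as.character(raw_ids) %in% names(mapping))

    if (length(fresh)) {
      present <- stats::na.omit(canon)
      lost <- names(last_pos)[!as.integer(names(last_pos)) %in% present &
                                fidx - unlist(last_frame[names(last_pos)]) <= history_len]
      # all candidate (new, lost) pairs within the gate, greedy by distance
      cand <- expand.grid(fi = fresh, lid = lost, stringsAsFactors = FALSE)
      if (nrow(cand)) {
        cand$d <- mapply(function(fi, lid) {
          sqrt(sum((wpos[fi, ] - last_pos[[lid]])^2))
        }, cand$fi, cand$lid)
        cand <- cand[cand$d <= gate_cm, , drop = FALSE]
        cand <- cand[order(cand$d), , drop = FALSE]
        used_f <- integer(0); used_l <- character(0)
        for (k in seq_len(nrow(cand))) {
          fi <- cand$fi[k]; lid <- cand$lid[k]
          if (fi %in% used_f || lid %in% used_l) next
          mapping[[as.character(raw_ids[fi])]] <- as.integer(lid)
          canon[fi] <- as.integer(lid)
          used_f <- c(used_f, fi); used_l <- c(used_l, lid)
        }
      }
      # unmatched genuinely new tracks keep their own id
      for (fi in fresh) {
        if (is.na(canon[fi])) {
          mapping[[as.character(raw_ids[fi])]] <- raw_ids[fi]
          canon[fi] <- raw_ids[fi]
        }
      }
    }

    for (i in seq_along(frame)) {
      frame[[i]]$track_id <- canon[i]
      last_pos[[as.character(canon[i])]] <- wpos[i, ]
      last_frame[[as.character(canon[i])]] <- fidx
    }
    out[[g]] <- frame
  }
  out
}

#' Bounding-box contact test
#'
#' Overlap fraction is the intersection area over the smaller box's area (so
#' a small head inside a large pig's box still registers); contact when the
#' fraction reaches the threshold. Symmetric in its arguments.
#'
#' @param bbox_a,bbox_b length-4 `(x_min, y_min, x_max, y_max)`.
#' @param overlap_frac_threshold contact threshold (default 0.10).
#' @return list with logical `contact` and `overlap_fraction`.
#' @export
detect_contact <- function(bbox_a, bbox_b, overlap_frac_threshold = 0.10) {
  area <- function(b) (b[3] - b[1]) * (b[4] - b[2])
  if (area(bbox_a) <= 0 || area(bbox_b) <= 0) {
    stop("zero-area bounding box", call. = FALSE)
  }
  iw <- max(0, min(bbox_a[3], bbox_b[3]) - max(bbox_a[1], bbox_b[1]))
  ih <- max(0, min(bbox_a[4], bbox_b[4]) - max(bbox_a[2], bbox_b[2]))
  frac <- (iw * ih) / min(area(bbox_a), area(bbox_b))
  list(contact = frac >= overlap_frac_threshold, overlap_fraction = frac)
}

#' Confirm a bounding-box contact as a real interaction
#'
#' A contact counts as an interaction if there is any evidence of activity:
#' either animal moved more than `move_gate_cm` since the previous frame, OR
#' either animal changed posture, OR the grayscale appearance of the contact
#' region changed (SSIM between the previous and current union-bbox crops
#' below `ssim_threshold`). With no crops supplied the SSIM term is skipped.
#'
#' @param prev_crop,cur_crop grayscale matrices over the union bbox (same
#'   shape), or `NULL` to skip the SSIM term.
#' @param centroid_step_cm numeric vector: each animal's centroid step (cm).
#' @param posture_changed logical vector: each animal's posture change flag.
#' @param ssim_threshold SSIM below this confirms (default 0.90).
#' @param move_gate_cm movement gate in cm (default 2.0).
#' @return logical: interaction confirmed.
#' @export
confirm_interaction <- function(prev_crop = NULL, cur_crop = NULL,
                                centroid_step_cm = 0, posture_changed = FALSE,
                                ssim_threshold = 0.90, move_gate_cm = 2.0) {
  if (any(centroid_step_cm > move_gate_cm, na.rm = TRUE)) return(TRUE)
  if (any(posture_changed, na.rm = TRUE)) return(TRUE)
  if (!is.null(prev_crop) && !is.null(cur_crop)) {
    if (!all(dim(as.matrix(prev_crop)) == dim(as.matrix(cur_crop)))) {
      stop("crop shape mismatch", call. = FALSE)
    }
    return(ssim(prev_crop, cur_crop) < ssim_threshold)
  }
  FALSE
}

# unordered part-pair -> fine interaction label
pair_label <- function(pa, pb) {
  simplify <- function(p) if (p %in% c("left_ear", "right_ear")) "ear" else p
  a <- simplify(pa); b <- simplify(pb)
  pair <- sort(c(a, b))
  if (identical(pair, c("mouth", "tail"))) return("mouth_to_tail")
  if (identical(pair, c("ear", "mouth"))) return("mouth_to_ear")
  if (identical(pair, c("body", "mouth"))) return("mouth_to_body")
  if (all(pair %in% c("mouth", "ear"))) return("head_to_head")
  "body_contact"  # body-body and any remaining torso-adjacent combination
}

#' Classify the fine-grained type of an animal-animal interaction
#'
#' Computes the IoU of every cross pair of body-part polygons between the two
#' animals, selects the maximal-IoU pair above `min_iou`, and maps the pair to
#' a label: mouth-tail, mouth-ear, mouth-body, head-to-head (mouth/ear vs
#' mouth/ear), otherwise generic body contact; nothing above `min_iou` is
#' `unclassified`. The label is symmetric in the participants; when the mouth
#' in the selected pair belongs to exactly one animal, that animal is
#' recorded as the actor.
#'
#' @param parts_a,parts_b named lists of part polygons (must include `body`).
#' @param min_iou minimal IoU for a pair to count (default 0.02).
#' @return list with `fine_label`, `iou`, `pair` (part names a, b), `actor`
#'   (`"a"`, `"b"` or `NA`).
#' @export
classify_fine_interaction <- function(parts_a, parts_b, min_iou = 0.02) {
  if (is.null(parts_a$body) || is.null(parts_b$body)) {
    stop("both animals need a body polygon", call. = FALSE)
  }
  best <- list(iou = -1, pa = NA_character_, pb = NA_character_)
  for (pa in names(parts_a)) {
    for (pb in names(parts_b)) {
      v <- polygon_iou(parts_a[[pa]], parts_b[[pb]])
      if (v > best$iou) best <- list(iou = v, pa = pa, pb = pb)
    }
  }
  if (best$iou < min_iou) {
    return(list(fine_label = "unclassified", iou = best$iou,
                pair = c(NA_character_, NA_character_), actor = NA_character_))
  }
  actor <- NA_character_
  if (xor(best$pa == "mouth", best$pb == "mouth")) {
    actor <- if (best$pa == "mouth") "a" else "b"
  }
  list(fine_label = pair_label(best$pa, best$pb), iou = best$iou,
       pair = c(best$pa, best$pb), actor = actor)
}

#' Detect an animal-enrichment interaction
#'
#' Any polygon overlap between the animal and the enrichment mask counts; the
#' ball additionally counts as interacted-with when it moved more than
#' `ball_move_gate_cm` since the previous frame (a pig can kick it without
#' remaining in contact).
#'
#' @param animal_poly animal mask polygon (n x 2 matrix).
#' @param enrichment_name one of feeder, drinker, hay, pole, ball.
#' @param enrichment_poly enrichment mask polygon.
#' @param ball_step_cm ball displacement since previous frame (ball only).
#' @param ball_move_gate_cm movement gate in cm (default 3.0).
#' @return logical.
#' @export
detect_enrichment_interaction <- function(animal_poly, enrichment_name,
                                          enrichment_poly,
                                          ball_step_cm = NULL,
                                          ball_move_gate_cm = 3.0) {
  if (!enrichment_name %in% ENRICHMENT_NAMES) {
    stop(sprintf("unknown enrichment name '%s'", enrichment_name), call. = FALSE)
  }
  overlap <- polygon_intersection_area(animal_poly, enrichment_poly) > 0
  if (enrichment_name == "ball" && !is.null(ball_step_cm)) {
    return(overlap || ball_step_cm > ball_move_gate_cm)
  }
  overlap
}

#' Detect and assemble interaction events over a grouped track stream
#'
#' Per consecutive frame pair: every pig pair in bounding-box contact is
#' tested for confirmation (motion / posture change / SSIM on the union-bbox
#' crop when full-frame grayscale images are supplied), and its fine label is
#' classified from part polygons when present; every pig is tested against
#' every enrichment polygon. Confirmed contact frames of the same pair are
#' merged into events, bridging gaps up to `bridge_gap_s`.
#'
#' @param grouped grouped track stream.
#' @param pen [pen_config()] (enrichment polygons).
#' @param transform pen homography.
#' @param crops optional named list (by frame index) of full-frame grayscale
#'   matrices for SSIM confirmation; `NULL` skips the SSIM term.
#' @param fps frame rate (default from stream attribute, else 15).
#' @param overlap_frac_threshold,min_iou,ssim_threshold,move_gate_cm rule
#'   thresholds (see the per-rule functions).
#' @param bridge_gap_s gaps up to this many seconds merge into one event.
#' @return data.frame of events: `start_frame`, `end_frame`, `kind`
#'   (`animal_animal`/`enrichment`), `a`, `b`, `fine_label`, `confirmed`,
#'   `n_frames`.
#' @export
detect_interactions <- function(grouped, pen, transform, crops = NULL,
                                fps = attr(grouped, "fps") %||% 15,
                                overlap_frac_threshold = 0.10,
                                min_iou = 0.02, ssim_threshold = 0.90,
                                move_gate_cm = 2.0, bridge_gap_s = 1.0) {
  hits <- list()  # per frame: records of (key, kind, a, b, label, confirmed)
  prev_state <- NULL
  for (g in seq_along(grouped)) {
    frame <- grouped[[g]]
    fidx <- frame[[1]]$frame_index
    ids <- vapply(frame, function(tf) tf$track_id, 1L)
    wpos <- apply_transform(transform,
                            t(vapply(frame, function(tf) tf$centroid, numeric(2))))
    state <- list(ids = ids, wpos = wpos,
                  postures = vapply(frame, function(tf) tf$posture, ""),
                  frame = frame, fidx = fidx)

    if (length(frame) >= 2) {
      for (i in seq_len(length(frame) - 1)) {
        for (j in (i + 1):length(frame)) {
          ct <- detect_contact(frame[[i]]$bbox, frame[[j]]$bbox,
                               overlap_frac_threshold)
          if (!ct$contact) next
          conf <- confirm_pair(state, prev_state, i, j, crops,
                               ssim_threshold, move_gate_cm)
          lab <- "unclassified"
          if (!is.null(frame[[i]]$parts) && !is.null(frame[[j]]$parts)) {
            lab <- classify_fine_interaction(frame[[i]]$parts, frame[[j]]$parts,
                                             min_iou)$fine_label
          }
          a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
          hits[[length(hits) + 1]] <- data.frame(
            frame = fidx, kind = "animal_animal",
            a = as.character(a), b = as.character(b),
            fine_label = lab, confirmed = conf)
        }
      }
    }
    for (i in seq_along(frame)) {
      for (en in names(pen$enrichment)) {
        poly <- frame[[i]]$parts$body
        if (is.null(poly)) poly <- bbox_to_polygon(frame[[i]]$bbox)
        if (detect_enrichment_interaction(poly, en, pen$enrichment[[en]])) {
          hits[[length(hits) + 1]] <- data.frame(
            frame = fidx, kind = "enrichment",
            a = as.character(ids[i]), b = en,
            fine_label = NA_character_, confirmed = TRUE)
        }
      }
    }
    prev_state <- state
  }
  assemble_events(hits, fps, bridge_gap_s)
}

bbox_to_polygon <- function(b) {
  rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]), c(b[1], b[4]))
}

confirm_pair <- function(state, prev_state, i, j, crops, ssim_threshold,
                         move_gate_cm) {
  if (is.null(prev_state)) return(FALSE)
  step_of <- function(idx) {
    p <- match(state$ids[idx], prev_state$ids)
    if (is.na(p)) return(NA_real_)
    sqrt(sum((state$wpos[idx, ] - prev_state$wpos[p, ])^2))
  }
  posture_change_of <- function(idx) {
    p <- match(state$ids[idx], prev_state$ids)
    if (is.na(p)) return(FALSE)
    state$postures[idx] != prev_state$postures[p]
  }
  steps <- c(step_of(i), step_of(j))
  pch <- c(posture_change_of(i), posture_change_of(j))
  pc <- cc <- NULL
  if (!is.null(crops)) {
    prv <- crops[[as.character(prev_state$fidx)]]
    cur <- crops[[as.character(state$fidx)]]
    if (!is.null(prv) && !is.null(cur)) {
      ub <- union_bbox(state$frame[[i]]$bbox, state$frame[[j]]$bbox, dim(cur))
      if (!is.null(ub)) {
        pc <- prv[ub$rows, ub$cols, drop = FALSE]
        cc <- cur[ub$rows, ub$cols, drop = FALSE]
        if (any(dim(pc) < 7)) pc <- cc <- NULL  # smaller than the SSIM window
      }
    }
  }
  confirm_interaction(pc, cc, centroid_step_cm = steps, posture_changed = pch,
                      ssim_threshold = ssim_threshold,
                      move_gate_cm = move_gate_cm)
}

union_bbox <- function(ba, bb, img_dim) {
  x0 <- floor(min(ba[1], bb[1])); x1 <- ceiling(max(ba[3], bb[3]))
  y0 <- floor(min(ba[2], bb[2])); y1 <- ceiling(max(ba[4], bb[4]))
  rows <- max(1, y0 + 1):min(img_dim[1], y1 + 1)
  cols <- max(1, x0 + 1):min(img_dim[2], x1 + 1)
  if (length(rows) < 2 || length(cols) < 2) return(NULL)
  list(rows = rows, cols = cols)
}

modal <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

assemble_events <- function(hits, fps, bridge_gap_s) {
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      kind = character(0), a = character(0), b = character(0),
                      fine_label = character(0), confirmed = logical(0),
                      n_frames = integer(0))
  if (!length(hits)) return(empty)
  df <- do.call(rbind, hits)
  df <- df[df$confirmed | df$kind == "enrichment", , drop = FALSE]
  if (!nrow(df)) return(empty)
  key <- paste(df$kind, df$a, df$b, sep = "|")
  gap <- max(1L, as.integer(round(bridge_gap_s * fps)))
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$frame), ]
    brk <- c(0, which(diff(sub$frame) > gap), nrow(sub))
    for (s in seq_len(length(brk) - 1)) {
      seg <- sub[(brk[s] + 1):brk[s + 1], , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        start_frame = min(seg$frame), end_frame = max(seg$frame),
        kind = seg$kind[1], a = seg$a[1], b = seg$b[1],
        fine_label = modal(seg$fine_label),
        confirmed = any(seg$confirmed),
        n_frames = nrow(seg))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start_frame, res$a, res$b), , drop = FALSE]
}

#' Per-animal activity summary from a grouped track stream
#'
#' Computes each animal's posture budget and standing travel distance.
#'
#' @param grouped grouped track stream.
#' @param transform pen homography.
#' @param fps frame rate.
#' @return data.frame: `animal`, `standing_s`, `lying_s`, `distance_cm`.
#' @export
activity_summary <- function(grouped, transform,
                             fps = attr(grouped, "fps") %||% 15) {
  all_tf <- unlist(grouped, recursive = FALSE)
  ids <- sort(unique(vapply(all_tf, function(tf) tf$track_id, 1L)))
  rows <- lapply(ids, function(id) {
    track <- Filter(function(tf) tf$track_id == id, all_tf)
    track <- track[order(vapply(track, function(tf) tf$frame_index, 1L))]
    w <- track_to_world(track, transform)
    postures <- vapply(track, function(tf) tf$posture, "")
    pb <- posture_budget(postures, fps)
    d <- distance_traveled(as.matrix(w[, c("x_cm", "y_cm")]), postures, fps)
    data.frame(animal = as.character(id), standing_s = pb[["standing_s"]],
               lying_s = pb[["lying_s"]], distance_cm = as.numeric(d))
  })
  do.call(rbind, rows)
}

#' Build the hourly activity report
#'
#' Distributes each confirmed event's frames into wall-clock hour bins (both
#' participants of an animal-animal event accrue the time) and joins the
#' per-animal budgets and distances. Totals are conserved across bins.
#'
#' @param events event data.frame from [detect_interactions()].
#' @param summary per-animal summary from [activity_summary()].
#' @param fps frame rate.
#' @param bin_hours bin width in hours (default 1).
#' @return object of class `activity_report`: list with `per_animal`
#'   (data.frame) and `interaction_minutes` (animals x bins matrix).
#' @export
build_activity_report <- function(events, summary, fps, bin_hours = 1) {
  animals <- summary$animal
  frames_per_bin <- fps * 3600 * bin_hours
  max_frame <- if (nrow(events)) max(events$end_frame) else 0
  n_bins <- max(1, ceiling((max_frame + 1) / frames_per_bin))
  mat <- matrix(0, nrow = length(animals), ncol = n_bins,
                dimnames = list(animals, paste0("h", seq_len(n_bins) - 1)))
  if (nrow(events)) {
    for (e in seq_len(nrow(events))) {
      if (!events$confirmed[e]) next
      parts <- if (events$kind[e] == "animal_animal") {
        c(events$a[e], events$b[e])
      } else {
        events$a[e]
      }
      frames <- events$start_frame[e]:events$end_frame[e]
      bins <- floor(frames / frames_per_bin) + 1
      tab <- table(bins)
      for (p in intersect(parts, animals)) {
        for (bn in names(tab)) {
          mat[p, as.integer(bn)] <- mat[p, as.integer(bn)] +
            as.integer(tab[[bn]]) / fps / 60
        }
      }
    }
  }
  structure(list(per_animal = summary, interaction_minutes = mat),
            class = "activity_report")
}

#' @export
print.activity_report <- function(x, ...) {
  cat("activity_report for", nrow(x$per_animal), "animal(s)\n")
  print(x$per_animal, row.names = FALSE)
  cat("interaction minutes per hour bin:\n")
  print(round(x$interaction_minutes, 3))
  invisible(x)
}
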
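# Stream readers and writers. Native interchange format is JSON Lines (one
# record per line, append-friendly for edge acquisition); COCO-keypoints JSON
# is accepted for pose import. Writers emit a canonical key order so that
# write(read(x)) reproduces a canonical file byte-for-byte.

read_json_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop(sprintf("parse error at line %d of %s: %s", i, path,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }
  recs
}

split_meta <- function(recs) {
  is_meta <- vapply(recs, function(r) !is.null(r$meta), TRUE)
  meta <- if (any(is_meta)) recs[[which(is_meta)[1]]]$meta else NULL
  list(meta = meta, records = recs[!is_meta])
}

#' Read a cattle pose stream
#'
#' Reads per-frame 16-slot keypoint records, either from the native JSON Lines
#' format (one object per line with `frame_index` and a `keypoints` map of
#' `name: [x, y, confidence]`; an optional `{"meta": {"fps": ...}}` line
#' carries the frame rate) or from COCO-keypoints JSON (visibility flags
#' 0/1/2 are mapped to confidences 0/0.5/1; keypoint names come from the
#' category definition).
#'
#' @param path file path.
#' @param format `"jsonl"` (native) or `"coco_json"`.
#' @return list of [cattle_pose()] objects sorted by frame index, with an
#'   `fps` attribute (default 20, the side-camera clip rate).
#' @export
read_pose_stream <- function(path, format = c("jsonl", "coco_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  poses <- if (format == "jsonl") read_pose_jsonl(path) else read_pose_coco(path)
  ord <- order(vapply(poses, function(p) p$frame_index, 1L))
  structure(poses[ord], fps = attr(poses, "fps") %||% 20)
}

read_pose_jsonl <- function(path) {
  parts <- split_meta(read_json_lines(path))
  poses <- lapply(seq_along(parts$records), function(i) {
    r <- parts$records[[i]]
    if (is.null(r$frame_index) || is.null(r$keypoints)) {
      stop(sprintf("parse error at record %d: need frame_index and keypoints", i),
           call. = FALSE)
    }
    kp <- r$keypoints
    df <- data.frame(
      name = names(kp),
      x = vapply(kp, function(v) as.numeric(v[1]), 1),
      y = vapply(kp, function(v) as.numeric(v[2]), 1),
      confidence = vapply(kp, function(v) as.numeric(v[3]), 1),
      stringsAsFactors = FALSE
    )
    tryCatch(cattle_pose(r$frame_index, df), error = function(e) {
      stop(sprintf("record %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  })
  attr(poses, "fps") <- parts$meta$fps %||% 20
  poses
}

read_pose_coco <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$categories) || is.null(doc$annotations)) {
    stop("COCO file needs categories and annotations", call. = FALSE)
  }
  kp_names <- unlist(doc$categories[[1]]$keypoints)
  lapply(seq_along(doc$annotations), function(i) {
    ann <- doc$annotations[[i]]
    k <- unlist(ann$keypoints)
    if (length(k) != 3 * length(kp_names)) {
      stop(sprintf("annotation %d: keypoint triplet count mismatch", i),
           call. = FALSE)
    }
    m <- matrix(k, ncol = 3, byrow = TRUE)
    df <- data.frame(name = kp_names, x = m[, 1], y = m[, 2],
                     confidence = m[, 3] / 2, stringsAsFactors = FALSE)
    tryCatch(cattle_pose(ann$image_id, df), error = function(e) {
      stop(sprintf("annotation %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  })
}

#' Write a cattle pose stream as canonical JSON Lines
#'
#' @param poses list of [cattle_pose()] objects.
#' @param path output path.
#' @param fps frame rate written to the metadata line.
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(poses, path, fps = attr(poses, "fps") %||% 20) {
  lines <- c(
    jsonlite::toJSON(list(meta = list(fps = fps)), auto_unbox = TRUE, digits = NA),
    vapply(poses, function(p) {
      kp <- p$keypoints
      ord <- order(match(kp$name, REQUIRED_KEYPOINTS), kp$name)
      kp <- kp[ord, ]
      kl <- lapply(seq_len(nrow(kp)), function(i) c(kp$x[i], kp$y[i], kp$confidence[i]))
      names(kl) <- kp$name
      as.character(jsonlite::toJSON(
        list(frame_index = p$frame_index, keypoints = kl),
        auto_unbox = TRUE, digits = NA))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a pig track stream (JSON Lines), grouped by frame
#'
#' One `track_frame` record per line with `frame_index`, `track_id`, `bbox`,
#' `centroid`, `posture` and optional `parts` polygons. Records are grouped by
#' frame and sorted; gaps in a track's frame coverage are reported as
#' warnings (tracker dropouts).
#'
#' @param path file path.
#' @return list (one element per frame, sorted) of lists of [track_frame()]
#'   objects, with attributes `fps` (default 15, the pen camera rate) and
#'   `frame_indices`.
#' @export
read_track_stream <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  parts <- split_meta(read_json_lines(path))
  if (!length(parts$records)) {
    warning("empty track stream: ", path)
    return(structure(list(), fps = parts$meta$fps %||% 15,
                     frame_indices = integer(0)))
  }
  frames <- lapply(seq_along(parts$records), function(i) {
    r <- parts$records[[i]]
    parts_poly <- NULL
    if (!is.null(r$parts)) {
      parts_poly <- lapply(r$parts, function(p) {
        if (is.matrix(p)) p else matrix(unlist(p), ncol = 2, byrow = TRUE)
      })
    }
    tryCatch(
      track_frame(r$frame_index, r$track_id, unlist(r$bbox),
                  unlist(r$centroid), r$posture, parts_poly),
      error = function(e) {
        stop(sprintf("record %d: %s", i, conditionMessage(e)), call. = FALSE)
      }
    )
  })
  group_track_frames(frames, fps = parts$meta$fps %||% 15)
}

group_track_frames <- function(frames, fps = 15) {
  fidx <- vapply(frames, function(f) f$frame_index, 1L)
  tids <- vapply(frames, function(f) f$track_id, 1L)
  for (id in unique(tids)) {
    fr <- sort(fidx[tids == id])
    gaps <- diff(fr)
    if (any(gaps > 1)) {
      warning(sprintf("track %d has %d gap(s) in frame coverage", id,
                      sum(gaps > 1)))
    }
  }
  ufr <- sort(unique(fidx))
  grouped <- lapply(ufr, function(f) frames[fidx == f])
  names(grouped) <- as.character(ufr)
  structure(grouped, fps = fps, frame_indices = ufr)
}

#' Write a pig track stream as canonical JSON Lines
#'
#' @param grouped grouped track stream as returned by [read_track_stream()].
#' @param path output path.
#' @param fps frame rate written to the metadata line.
#' @return `path`, invisibly.
#' @export
write_track_stream <- function(grouped, path, fps = attr(grouped, "fps") %||% 15) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(list(meta = list(fps = fps)),
                                           auto_unbox = TRUE, digits = NA)), con)
  for (frame in grouped) {
    for (tf in frame) {
      rec <- list(frame_index = tf$frame_index, track_id = tf$track_id,
                  bbox = tf$bbox, centroid = tf$centroid, posture = tf$posture)
      if (!is.null(tf$parts)) {
        rec$parts <- lapply(tf$parts, function(p) {
          lapply(seq_len(nrow(p)), function(i) p[i, ])
        })
      }
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                               digits = NA)), con)
    }
  }
  invisible(path)
}

#' Load a pen configuration from YAML or JSON
#'
#' Validates corner geometry, applies the default 580 x 380 cm world
#' dimensions when omitted, and converts roster RGB colours to CIELAB.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return [pen_config()] object.
#' @export
load_pen_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("pen config must be YAML or JSON", call. = FALSE)
  }
  if (is.null(doc$corners_px)) stop("pen config needs corners_px", call. = FALSE)
  corners <- matrix(unlist(doc$corners_px), ncol = 2, byrow = !is.matrix(doc$corners_px))
  if (is.matrix(doc$corners_px)) corners <- doc$corners_px
  roster <- lapply(doc$roster %||% list(), function(r) {
    animal_template(r$id, lab = r$lab, rgb = r$rgb, symbol = r$symbol)
  })
  enrichment <- lapply(doc$enrichment %||% list(), function(p) {
    matrix(unlist(p), ncol = 2, byrow = TRUE)
  })
  pen_config(
    corners_px = corners,
    world_dims = unlist(doc$world_dims) %||% c(580, 380),
    enrichment = enrichment,
    roster = roster,
    fps = doc$fps %||% 15
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
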
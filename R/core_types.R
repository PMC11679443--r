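# Domain types shared by the cattle and pig pipelines. These are light S3
# records with strict constructors: every stream reader funnels through them,
# so schema violations surface at parse time, not deep in an analysis.

#' Required cattle keypoint names
#'
#' The eleven anatomical keypoints every pose record must carry: head,
#' withers, pin bone, and the elbow and hoof of each leg (fr/fl/br/bl =
#' front-right, front-left, back-right, back-left). The pose format carries 16
#' slots; the remaining five are free alias slots bound via
#' `extra_keypoints`, so any upstream 16-point ordering can be mapped in.
#'
#' @export
REQUIRED_KEYPOINTS <- c(
  "head", "withers", "pin",
  "fr_elbow", "fl_elbow", "br_elbow", "bl_elbow",
  "fr_hoof", "fl_hoof", "br_hoof", "bl_hoof"
)

N_KEYPOINT_SLOTS <- 16L

POSTURE_LEVELS <- c("standing", "lying")
PART_NAMES <- c("mouth", "left_ear", "right_ear", "body", "tail")
ENRICHMENT_NAMES <- c("feeder", "drinker", "hay", "pole", "ball")
SYMBOL_LEVELS <- c("triangle", "circle", "line", "cross")

#' Construct a single-frame cattle pose
#'
#' @param frame_index non-negative integer frame number.
#' @param keypoints data.frame with columns `name`, `x`, `y`, `confidence`;
#'   must contain all of [REQUIRED_KEYPOINTS] and at most 16 rows in total.
#' @return object of class `cattle_pose`.
#' @export
cattle_pose <- function(frame_index, keypoints) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0) {
    stop("frame_index must be a non-negative integer", call. = FALSE)
  }
  keypoints <- as.data.frame(keypoints, stringsAsFactors = FALSE)
  needed <- c("name", "x", "y", "confidence")
  if (!all(needed %in% names(keypoints))) {
    stop("keypoints need columns name, x, y, confidence", call. = FALSE)
  }
  keypoints <- keypoints[, needed]
  missing_kp <- setdiff(REQUIRED_KEYPOINTS, keypoints$name)
  if (length(missing_kp)) {
    stop(sprintf("pose schema error: missing required keypoint(s): %s",
                 paste(missing_kp, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(keypoints$name)) {
    stop("duplicate keypoint names", call. = FALSE)
  }
  if (nrow(keypoints) > N_KEYPOINT_SLOTS) {
    stop(sprintf("at most %d keypoint slots allowed", N_KEYPOINT_SLOTS),
         call. = FALSE)
  }
  if (any(!is.finite(keypoints$x)) || any(!is.finite(keypoints$y))) {
    stop("keypoint coordinates must be finite", call. = FALSE)
  }
  if (any(keypoints$confidence < 0 | keypoints$confidence > 1)) {
    stop("keypoint confidences must lie in [0, 1]", call. = FALSE)
  }
  structure(list(frame_index = frame_index, keypoints = keypoints),
            class = "cattle_pose")
}

keypoint_xy <- function(pose, name) {
  i <- match(name, pose$keypoints$name)
  c(x = pose$keypoints$x[i], y = pose$keypoints$y[i])
}

keypoint_conf <- function(pose, name) {
  pose$keypoints$confidence[match(name, pose$keypoints$name)]
}

#' Construct a single pig track frame
#'
#' One pig's tracked state in one frame: bounding box, centroid, binary
#' posture, and optionally the segmented body-part polygons.
#'
#' @param frame_index integer frame number.
#' @param track_id integer tracker identity.
#' @param bbox length-4 numeric `(x_min, y_min, x_max, y_max)` in pixels.
#' @param centroid length-2 numeric `(x, y)`; must lie inside `bbox`.
#' @param posture `"standing"` or `"lying"`.
#' @param parts optional named list of polygons (n x 2 matrices); names drawn
#'   from mouth, left_ear, right_ear, body, tail.
#' @return object of class `track_frame`.
#' @export
track_frame <- function(frame_index, track_id, bbox, centroid, posture,
                        parts = NULL) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[1] >= bbox[3] || bbox[2] >= bbox[4]) {
    stop("bbox must be (x_min, y_min, x_max, y_max) with positive extent",
         call. = FALSE)
  }
  centroid <- as.numeric(centroid)
  if (centroid[1] < bbox[1] || centroid[1] > bbox[3] ||
      centroid[2] < bbox[2] || centroid[2] > bbox[4]) {
    stop("centroid must lie inside bbox", call. = FALSE)
  }
  if (!posture %in% POSTURE_LEVELS) {
    stop(sprintf("posture schema error: '%s' is not one of %s", posture,
                 paste(POSTURE_LEVELS, collapse = "/")), call. = FALSE)
  }
  if (!is.null(parts)) {
    bad <- setdiff(names(parts), PART_NAMES)
    if (length(bad)) {
      stop(sprintf("unknown body part(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    parts <- lapply(parts, as_polygon)
  }
  structure(list(frame_index = as.integer(frame_index),
                 track_id = as.integer(track_id),
                 bbox = bbox, centroid = centroid,
                 posture = posture, parts = parts),
            class = "track_frame")
}

#' Construct an animal colour/symbol template
#'
#' Roster entry for colour-based pig identification: a reference CIELAB tag
#' colour and, for livestock-mark identification, the painted symbol class.
#'
#' @param animal_id character identifier.
#' @param lab length-3 numeric `(L, a, b)`; give either this or `rgb`.
#' @param rgb length-3 numeric sRGB channels on `[0, 255]`, converted on load.
#' @param symbol optional one of triangle, circle, line, cross.
#' @return object of class `animal_template`.
#' @export
animal_template <- function(animal_id, lab = NULL, rgb = NULL, symbol = NULL) {
  if (is.null(lab) && is.null(rgb)) {
    stop("animal template needs either a lab or an rgb colour", call. = FALSE)
  }
  if (is.null(lab)) lab <- unclass(rgb_to_lab(rgb))
  lab <- as.numeric(lab)
  if (length(lab) != 3 || any(!is.finite(lab)) || lab[1] < 0 || lab[1] > 100) {
    stop("lab colour must be finite with L in [0, 100]", call. = FALSE)
  }
  if (!is.null(symbol) && !symbol %in% SYMBOL_LEVELS) {
    stop(sprintf("unknown symbol '%s'", symbol), call. = FALSE)
  }
  structure(list(animal_id = as.character(animal_id),
                 lab = c(L = lab[1], a = lab[2], b = lab[3]),
                 symbol = symbol),
            class = "animal_template")
}

#' Construct a pen configuration
#'
#' @param corners_px 4x2 matrix of pen corner pixels, clockwise in the image
#'   starting from the corner mapped to the world origin.
#' @param world_dims `(length_cm, width_cm)`, default the 580 x 380 cm pen.
#' @param enrichment named list of polygons; names drawn from feeder, drinker,
#'   hay, pole, ball.
#' @param roster list of [animal_template()] entries.
#' @param fps acquisition frame rate (Hz), default 15.
#' @return object of class `pen_config`.
#' @export
pen_config <- function(corners_px, world_dims = c(580, 380),
                       enrichment = list(), roster = list(), fps = 15) {
  corners_px <- as_polygon(corners_px)
  if (nrow(corners_px) != 4) stop("pen needs exactly 4 corners", call. = FALSE)
  if (any_three_collinear(corners_px)) {
    stop("pen config error: three corners are collinear", call. = FALSE)
  }
  world_dims <- as.numeric(world_dims)
  if (length(world_dims) != 2 || any(world_dims <= 0)) {
    stop("world_dims must be two positive lengths in cm", call. = FALSE)
  }
  bad <- setdiff(names(enrichment), ENRICHMENT_NAMES)
  if (length(bad)) {
    stop(sprintf("pen config error: unknown enrichment name(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  enrichment <- lapply(enrichment, as_polygon)
  if (length(roster) && !all(vapply(roster, inherits, TRUE, "animal_template"))) {
    stop("roster must be a list of animal_template objects", call. = FALSE)
  }
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  structure(list(corners_px = corners_px,
                 world_dims = c(length_cm = world_dims[1],
                                width_cm = world_dims[2]),
                 enrichment = enrichment, roster = roster, fps = fps),
            class = "pen_config")
}

#' Construct a back-silhouette edge
#'
#' Ordered contour points along the cow's back between withers and pin,
#' together with the body length used to make the straightness score
#' scale-free.
#'
#' @param points n x 2 matrix (n >= 5) of pixel points along the back edge.
#' @param body_length_ref reference body length in pixels (> 0).
#' @return object of class `back_edge`.
#' @export
back_edge <- function(points, body_length_ref) {
  points <- as_polygon(points)
  if (nrow(points) < 5) {
    stop("insufficient edge: at least 5 back-edge points required", call. = FALSE)
  }
  if (!is.finite(body_length_ref) || body_length_ref <= 0) {
    stop("body_length_ref must be positive", call. = FALSE)
  }
  structure(list(points = points, body_length_ref = as.numeric(body_length_ref)),
            class = "back_edge")
}

#' Clamp an arbitrary snapshot-scorer into the 1-5 band
#'
#' Body condition scoring plugs in as an arbitrary callable mapping a cropped
#' top-down image reference to a scalar; this wrapper enforces the 1 (emaciated)
#' to 5 (obese) output contract.
#'
#' @param fun function taking one argument (an image reference) and returning
#'   a numeric scalar.
#' @return function with outputs clamped to `[1, 5]`.
#' @export
snapshot_scorer <- function(fun) {
  stopifnot(is.function(fun))
  function(crop) {
    v <- as.numeric(fun(crop))
    if (length(v) != 1 || !is.finite(v)) {
      stop("snapshot scorer must return a finite scalar", call. = FALSE)
    }
    min(max(v, 1), 5)
  }
}

#' @export
print.cattle_pose <- function(x, ...) {
  cat("cattle_pose: frame", x$frame_index, "with", nrow(x$keypoints),
      "keypoints\n")
  invisible(x)
}

#' @export
print.pen_config <- function(x, ...) {
  cat("pen_config:", x$world_dims[1], "x", x$world_dims[2], "cm,",
      length(x$enrichment), "enrichment object(s),",
      length(x$roster), "roster entries,", x$fps, "fps\n")
  invisible(x)
}
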
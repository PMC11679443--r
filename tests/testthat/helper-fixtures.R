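# shared fixture builders (everything generated in code; no stored data)

# a straight standing pose with every hoof directly below its elbow
make_pose <- function(frame_index = 0, dx = 0, dy = 0, scale = 1, conf = 1) {
  kp <- rbind(
    head = c(40, 75), withers = c(100, 100), pin = c(400, 100),
    fr_elbow = c(130, 180), fl_elbow = c(145, 180),
    br_elbow = c(330, 180), bl_elbow = c(345, 180),
    fr_hoof = c(130, 260), fl_hoof = c(145, 260),
    br_hoof = c(330, 260), bl_hoof = c(345, 260)
  )
  kp <- kp * scale
  kp[, 1] <- kp[, 1] + dx
  kp[, 2] <- kp[, 2] + dy
  cattle_pose(frame_index, data.frame(
    name = rownames(kp), x = kp[, 1], y = kp[, 2], confidence = conf))
}

rect_poly <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# exact IoU of two axis-aligned rectangles (closed form, independent of the
# package's polygon clipping)
rect_iou <- function(a, b) {
  ax <- range(a[, 1]); ay <- range(a[, 2])
  bx <- range(b[, 1]); by <- range(b[, 2])
  iw <- max(0, min(ax[2], bx[2]) - max(ax[1], bx[1]))
  ih <- max(0, min(ay[2], by[2]) - max(ay[1], by[1]))
  inter <- iw * ih
  union <- diff(ax) * diff(ay) + diff(bx) * diff(by) - inter
  if (union <= 0) 0 else inter / union
}

random_quad <- function() {
  # convex-ish quadrilateral: perturbed rectangle, retried until valid
  repeat {
    q <- rbind(c(0, 0), c(100, 0), c(100, 80), c(0, 80)) +
      matrix(stats::runif(8, -18, 18), 4, 2)
    ok <- tryCatch({
      compute_world_transform(q)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(q)
  }
}

# circular-arc back edge with given sagitta over a fixed chord
arc_edge <- function(sagitta, chord = 300, n = 25) {
  if (sagitta == 0) {
    return(back_edge(cbind(seq(0, chord, length.out = n), 0), chord))
  }
  R <- (chord^2 / 4 + sagitta^2) / (2 * sagitta)
  half <- asin((chord / 2) / R)
  th <- seq(-half, half, length.out = n)
  back_edge(cbind(R * sin(th) + chord / 2, R * (1 - cos(th)) - sagitta), chord)
}

default_roster <- function() {
  list(
    animal_template("p1", rgb = c(220, 40, 40), symbol = "circle"),
    animal_template("p2", rgb = c(40, 80, 220), symbol = "triangle"),
    animal_template("p3", rgb = c(40, 180, 60), symbol = "cross"),
    animal_template("p4", rgb = c(240, 220, 40), symbol = "line")
  )
}
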
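# Colour-based pig identification: mean tag colour -> CIELAB -> CIEDE2000
# match against the user-defined roster (ear-tag colour alone, or livestock
# mark symbol + colour).

#' Construct a CIELAB colour
#'
#' @param L lightness in \[0, 100\].
#' @param a,b opponent channels (red-green / yellow-blue), unbounded.
#' @return object of class `lab_color`.
#' @export
lab_color <- function(L, a, b) {
  v <- c(L = as.numeric(L), a = as.numeric(a), b = as.numeric(b))
  if (any(!is.finite(v))) stop("lab components must be finite", call. = FALSE)
  if (v[1] < 0 || v[1] > 100) stop("L must lie in [0, 100]", call. = FALSE)
  structure(v, class = "lab_color")
}

#' Mean RGB colour over a polygonal region
#'
#' Channel-wise arithmetic mean over the pixels whose centers fall inside the
#' polygon (pixel `[r, c]` has center `(x = c - 1, y = r - 1)`).
#'
#' @param img H x W x 3 numeric array, channels on \[0, 255\].
#' @param polygon n x 2 matrix of (x, y) pixel vertices.
#' @return named numeric `(R, G, B)`.
#' @export
mean_rgb <- function(img, polygon) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  polygon <- as_polygon(polygon)
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  c0 <- max(1, floor(xr[1]) + 1); c1 <- min(dim(img)[2], ceiling(xr[2]) + 1)
  r0 <- max(1, floor(yr[1]) + 1); r1 <- min(dim(img)[1], ceiling(yr[2]) + 1)
  if (c0 > c1 || r0 > r1) stop("empty mask: polygon selects no pixels", call. = FALSE)
  cols <- c0:c1; rows <- r0:r1
  sel_r <- integer(0); sel_c <- integer(0)
  for (r in rows) for (cc in cols) {
    if (point_in_polygon(c(cc - 1, r - 1), polygon)) {
      sel_r <- c(sel_r, r); sel_c <- c(sel_c, cc)
    }
  }
  if (!length(sel_r)) stop("empty mask: polygon selects no pixels", call. = FALSE)
  idx <- cbind(sel_r, sel_c)
  c(R = mean(img[, , 1][idx]), G = mean(img[, , 2][idx]), B = mean(img[, , 3][idx]))
}

#' Convert an sRGB colour to CIELAB
#'
#' IEC 61966-2-1 sRGB decoding, D65 reference white, CIE 1976 L*a*b*.
#'
#' @param rgb length-3 numeric, channels on \[0, 255\].
#' @return [lab_color()] object.
#' @export
rgb_to_lab <- function(rgb) {
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3 || any(!is.finite(rgb)) || any(rgb < 0 | rgb > 255)) {
    stop("rgb channels must lie in [0, 255]", call. = FALSE)
  }
  s <- rgb / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  white <- c(0.95047, 1.00000, 1.08883)  # D65
  t <- xyz / white
  f <- ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  # the white point lands at L = 100 + ~1e-13; clamp numerical overshoot
  lab_color(L = min(max(116 * f[2] - 16, 0), 100),
            a = 500 * (f[1] - f[2]),
            b = 200 * (f[2] - f[3]))
}

#' CIEDE2000 colour difference
#'
#' Full CIEDE2000 formula: G chroma correction, transformed hue angles, the
#' SL/SC/SH weighting functions and the RT hue-rotation term, with
#' parametric factors kL, kC, kH (all 1 by default).
#'
#' @param c1,c2 [lab_color()] objects or length-3 `(L, a, b)` numerics.
#' @param kL,kC,kH parametric weighting factors.
#' @return non-negative Delta E00 scalar.
#' @export
ciede2000 <- function(c1, c2, kL = 1, kC = 1, kH = 1) {
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  L1 <- c1[1]; a1 <- c1[2]; b1 <- c1[3]
  L2 <- c2[1]; a2 <- c2[2]; b2 <- c2[3]

  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)

  h1p <- if (C1p == 0) 0 else (atan2(b1, a1p) * 180 / pi) %% 360
  h2p <- if (C2p == 0) 0 else (atan2(b2, a2p) * 180 / pi) %% 360

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0 else {
    d <- h2p - h1p
    if (d > 180) d <- d - 360
    if (d < -180) d <- d + 360
    d
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p else {
    d <- abs(h1p - h2p); s <- h1p + h2p
    if (d <= 180) s / 2
    else if (s < 360) (s + 360) / 2
    else (s - 360) / 2
  }

  T <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

#' Match an observed colour (and optional symbol) against the roster
#'
#' Restricts candidates to roster entries carrying the observed symbol when
#' one is given (livestock-mark mode), then assigns the template with minimal
#' CIEDE2000 distance, rejecting when even the best match exceeds the
#' threshold. Exact ties resolve to the lexicographically smallest id.
#'
#' @param observed [lab_color()] or `(L, a, b)` numeric.
#' @param roster list of [animal_template()] entries.
#' @param symbol optional observed symbol class.
#' @param reject_threshold maximal acceptable Delta E00 (default 25).
#' @return list with `animal_id` (`NA` when unidentified), `delta_e`, and
#'   logical `identified`.
#' @export
match_template <- function(observed, roster, symbol = NULL,
                           reject_threshold = 25) {
  if (!length(roster)) stop("roster is empty", call. = FALSE)
  if (!is.null(symbol)) {
    has_sym <- vapply(roster, function(t) !is.null(t$symbol), TRUE)
    if (!any(has_sym)) {
      stop("config error: symbol given but no roster entry carries symbols",
           call. = FALSE)
    }
    roster <- Filter(function(t) identical(t$symbol, symbol), roster)
    if (!length(roster)) {
      return(list(animal_id = NA_character_, delta_e = Inf, identified = FALSE))
    }
  }
  ids <- vapply(roster, function(t) t$animal_id, "")
  de <- vapply(roster, function(t) ciede2000(observed, t$lab), 1)
  ord <- order(de, ids)  # ties -> smallest id
  best <- ord[1]
  if (de[best] <= reject_threshold) {
    list(animal_id = ids[best], delta_e = de[best], identified = TRUE)
  } else {
    list(animal_id = NA_character_, delta_e = de[best], identified = FALSE)
  }
}
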
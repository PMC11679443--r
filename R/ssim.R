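# Structural similarity index between two grayscale patches, used to confirm
# that something actually changed inside a contact region between consecutive
# frames.

gaussian_kernel <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid-mode 2D filtering by summed kernel shifts (images here are small crops)
filter2_valid <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  oh <- nrow(img) - kh + 1; ow <- ncol(img) - kw + 1
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      out <- out + kernel[i, j] * img[i:(i + oh - 1), j:(j + ow - 1)]
    }
  }
  out
}

#' Structural similarity index (SSIM) of two grayscale images
#'
#' Gaussian-weighted local statistics (default 7x7 window, sigma 1.5) with the
#' standard stabilising constants C1 = (0.01 L)^2, C2 = (0.03 L)^2; returns the
#' mean of the local SSIM map. Values near 1 indicate an unchanged scene.
#'
#' @param img1,img2 numeric matrices of identical dimension (grayscale
#'   intensities on `[0, dynamic_range]`).
#' @param window odd window size in pixels.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param dynamic_range intensity range L (255 for 8-bit images).
#' @return scalar mean SSIM in \[-1, 1\].
#' @export
ssim <- function(img1, img2, window = 7, sigma = 1.5, dynamic_range = 255) {
  img1 <- as.matrix(img1); img2 <- as.matrix(img2)
  if (!all(dim(img1) == dim(img2))) {
    stop("SSIM inputs must have identical dimensions", call. = FALSE)
  }
  if (any(dim(img1) < window)) {
    stop(sprintf("images smaller than the %dx%d SSIM window", window, window),
         call. = FALSE)
  }
  k <- gaussian_kernel(window, sigma)
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu1 <- filter2_valid(img1, k)
  mu2 <- filter2_valid(img2, k)
  s11 <- filter2_valid(img1 * img1, k) - mu1^2
  s22 <- filter2_valid(img2 * img2, k) - mu2^2
  s12 <- filter2_valid(img1 * img2, k) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mean(map)
}
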
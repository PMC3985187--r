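# Synthetic filament textures standing in for cortical-microtubule images:
# anti-aliased line segments whose axial orientations are drawn from a
# wrapped-normal distribution on the doubled angle, so the 2D nematic order
# parameter S = |E exp(2 i theta)| is controlled exactly
# (S = exp(-sigma^2 / 2) on the doubled angle => sigma = sqrt(-2 log S)).

#' Specification of a synthetic filament image
#'
#' @param width,height image size in pixels.
#' @param n_filaments number of line segments.
#' @param order_parameter_S target 2D nematic order parameter in [0, 1]
#'   (0 = isotropic, 1 = perfectly aligned).
#' @param mean_angle mean orientation (degrees from +x toward +y).
#' @param filament_width Gaussian cross-profile width of a drawn filament
#'   (pixels).
#' @param noise_sd additive Gaussian intensity noise, as a fraction of the
#'   dynamic range.
#' @param filament_length segment length in pixels (default 0.8 of the
#'   smaller image side).
#' @param bit_depth 8 or 16; output intensities are quantized to this range.
#' @param seed integer RNG seed.
#' @return a `filament_image_spec`.
#' @export
filament_image_spec <- function(width = 256L, height = 256L,
                                n_filaments = 300L, order_parameter_S = 0.7,
                                mean_angle = 0, filament_width = 1.5,
                                noise_sd = 0, filament_length = NULL,
                                bit_depth = 8L, seed = 1L) {
  if (order_parameter_S < 0 || order_parameter_S > 1)
    stop("order_parameter_S must lie in [0, 1]")
  stopifnot(width >= 16L, height >= 16L, n_filaments >= 1L,
            filament_width > 0, noise_sd >= 0, bit_depth %in% c(8L, 16L))
  if (is.null(filament_length)) filament_length <- 0.8 * min(width, height)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_filaments = as.integer(n_filaments),
                 order_parameter_S = order_parameter_S,
                 mean_angle = mean_angle, filament_width = filament_width,
                 noise_sd = noise_sd, filament_length = filament_length,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "filament_image_spec")
}

#' Draw a synthetic filament image with known nematic order
#'
#' @param spec a [filament_image_spec()].
#' @return a `filament_image` list: `image` (height x width matrix, 0 to
#'   2^bit_depth - 1), `angles` (ground-truth orientations, degrees in
#'   [0, 180)), `spec`.
#' @export
make_filament_image <- function(spec) {
  stopifnot(inherits(spec, "filament_image_spec"))
  with_seed(spec$seed, {
    n <- spec$n_filaments
    S <- spec$order_parameter_S
    if (S >= 1) {
      th2 <- rep(2 * spec$mean_angle * pi / 180, n)
    } else if (S <= 0) {
      th2 <- runif(n, 0, 2 * pi)
    } else {
      sig <- sqrt(-2 * log(S))
      th2 <- 2 * spec$mean_angle * pi / 180 + sig * rnorm(n)
    }
    theta <- (th2 / 2) %% pi
    w <- spec$width; h <- spec$height
    cx <- runif(n, 1, w); cy <- runif(n, 1, h)
    len <- spec$filament_length * runif(n, 0.8, 1.2)
    img <- matrix(0, h, w)
    sg <- spec$filament_width / 2
    reach <- ceiling(3 * sg)
    for (i in seq_len(n)) {
      dx <- cos(theta[i]); dy <- sin(theta[i])
      a <- c(cx[i] - dx * len[i] / 2, cy[i] - dy * len[i] / 2)
      b <- c(cx[i] + dx * len[i] / 2, cy[i] + dy * len[i] / 2)
      x0 <- max(1L, floor(min(a[1L], b[1L]) - reach))
      x1 <- min(w, ceiling(max(a[1L], b[1L]) + reach))
      y0 <- max(1L, floor(min(a[2L], b[2L]) - reach))
      y1 <- min(h, ceiling(max(a[2L], b[2L]) + reach))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      px <- rep(xs, each = length(ys)); py <- rep(ys, length(xs))
      d <- dist_point_segment(px, py, a, b)
      add <- exp(-d^2 / (2 * sg^2))
      img[cbind(py, px)] <- img[cbind(py, px)] + add
    }
    img <- img / max(img, 1e-12)
    if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
    maxv <- 2^spec$bit_depth - 1
    img <- round(pmin(pmax(img, 0), 1) * maxv)
    structure(list(image = img, angles = theta * 180 / pi, spec = spec),
              class = "filament_image")
  })
}
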
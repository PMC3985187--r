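# Nematic / texture-tensor quantification of filament alignment in
# grayscale images. Local orientation comes from Gaussian-derivative
# gradients (the direction along the filaments is perpendicular to the
# intensity gradient), weighted by squared gradient magnitude; the
# second-moment tensor of those axial orientations gives the two score
# conventions: score_v1 in [0,1] from the orientation tensor itself, and the
# modified convention score_v2 = 2 * score_v1 in [0,2] (the eigenvalue
# difference of the traceless nematic tensor over the unit trace).
#
# Image convention: matrices are indexed [row = y, col = x]; angles are
# measured in degrees from the +x axis toward +y, modulo 180 (orientations
# are axial).

#' Polygonal region of interest
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates.
#' @param label region label.
#' @param exclude_wall_band erode the region inward to drop the bright
#'   anticlinal-wall signal at the cell outline?
#' @param band_px erosion width in pixels.
#' @return a `roi_polygon`.
#' @export
roi_polygon <- function(vertices, label = "roi", exclude_wall_band = FALSE,
                        band_px = 3L) {
  vertices <- as_ring(vertices)
  if (!is_simple_polygon(vertices)) stop("ROI polygon must be simple")
  structure(list(vertices = vertices, label = label,
                 exclude_wall_band = isTRUE(exclude_wall_band),
                 band_px = as.integer(band_px)),
            class = "roi_polygon")
}

gaussian_kernel <- function(sigma, deriv = FALSE) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv) -x / sigma^2 * g else g
}

# separable convolution with edge replication; k applied along the given dim
conv1 <- function(img, k, along = c("x", "y")) {
  along <- match.arg(along)
  r <- (length(k) - 1L) / 2
  out <- matrix(0, nrow(img), ncol(img))
  n <- if (along == "x") ncol(img) else nrow(img)
  for (t in seq_along(k)) {
    off <- t - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[t] * (if (along == "x") img[, idx, drop = FALSE]
                         else img[idx, , drop = FALSE])
  }
  out
}

roi_mask <- function(img, roi) {
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(roi)) return(matrix(TRUE, ny, nx))
  px <- rep(seq_len(nx), each = ny)
  py <- rep(seq_len(ny), nx)
  m <- matrix(points_in_polygon(px, py, roi$vertices), ny, nx)
  if (roi$exclude_wall_band && roi$band_px > 0L) {
    for (k in seq_len(roi$band_px)) {
      shr <- m
      shr[-1, ] <- shr[-1, ] & m[-ny, ]
      shr[-ny, ] <- shr[-ny, ] & m[-1, ]
      shr[, -1] <- shr[, -1] & m[, -nx]
      shr[, -nx] <- shr[, -nx] & m[, -1]
      m <- shr
    }
  }
  m
}

#' Orientation texture tensor of an image region
#'
#' @param image numeric matrix (grayscale, row = y).
#' @param roi a [roi_polygon()] or `NULL` for the whole image.
#' @param sigma Gaussian derivative scale (pixels).
#' @param min_pixels minimum region size.
#' @return a `nematic_tensor`: `tensor` (2 x 2 orientation second moments),
#'   `weight` (sum of gradient-energy weights), `n_pixels`, `degenerate`
#'   (flat region), `mean_orientation` (degrees in [0, 180), `NA` when the
#'   score is below the degeneracy tolerance).
#' @export
texture_tensor <- function(image, roi = NULL, sigma = 1.5, min_pixels = 100L) {
  image <- as.matrix(image)
  storage.mode(image) <- "double"
  mask <- roi_mask(image, roi)
  if (sum(mask) < min_pixels)
    stop("ROI smaller than min_pixels (", min_pixels, ")")
  g <- gaussian_kernel(sigma)
  dg <- gaussian_kernel(sigma, deriv = TRUE)
  gx <- conv1(conv1(image, dg, "x"), g, "y")
  gy <- conv1(conv1(image, g, "x"), dg, "y")
  # keep clear of the mask edge so wall/border gradients don't leak in
  r <- (length(g) - 1L) / 2
  core <- mask
  for (k in seq_len(r)) {
    ny <- nrow(core); nx <- ncol(core)
    shr <- core
    shr[-1, ] <- shr[-1, ] & core[-ny, ]
    shr[-ny, ] <- shr[-ny, ] & core[-1, ]
    shr[, -1] <- shr[, -1] & core[, -nx]
    shr[, -nx] <- shr[, -nx] & core[, -1]
    core <- shr
  }
  if (sum(core) >= min_pixels) mask <- core
  gx <- gx[mask]; gy <- gy[mask]
  w <- gx^2 + gy^2
  sw <- sum(w)
  scale2 <- max(image[mask])^2 + 1e-300
  if (sw <= 1e-12 * scale2 * sum(mask)) {
    return(structure(list(tensor = diag(2) / 2, weight = 0,
                          n_pixels = sum(mask), degenerate = TRUE,
                          mean_orientation = NA_real_),
                     class = "nematic_tensor"))
  }
  # filament axis n = (-gy, gx)/|g|; tensor = sum w n n' / sum w
  Txx <- sum(gy^2)   / sw
  Tyy <- sum(gx^2)   / sw
  Txy <- sum(-gx * gy) / sw
  tensor <- matrix(c(Txx, Txy, Txy, Tyy), 2L, 2L)
  ang <- 0.5 * atan2(2 * Txy, Txx - Tyy) * 180 / pi
  ang <- ang %% 180
  sc <- anisotropy_score(tensor)
  structure(list(tensor = tensor, weight = sw, n_pixels = sum(mask),
                 degenerate = FALSE,
                 mean_orientation = if (sc$score_v1 > 1e-3) ang else NA_real_),
            class = "nematic_tensor")
}

#' Anisotropy scores from an orientation tensor
#'
#' `score_v1 = (lambda1 - lambda2) / (lambda1 + lambda2)` of the orientation
#' second-moment tensor (0 = isotropic, 1 = perfectly aligned);
#' `score_v2 = 2 * score_v1` is the modified convention whose upper bound is
#' 2 (eigenvalue difference of the traceless nematic tensor `2T - I` over
#' the unit trace of `T`).
#'
#' @param tensor a 2 x 2 orientation tensor or a [texture_tensor()] result.
#' @return list: `score_v1`, `score_v2`, `degenerate`.
#' @export
anisotropy_score <- function(tensor) {
  deg <- FALSE
  if (inherits(tensor, "nematic_tensor")) {
    deg <- tensor$degenerate
    tensor <- tensor$tensor
  }
  tr <- tensor[1L, 1L] + tensor[2L, 2L]
  if (deg || tr <= 1e-300)
    return(list(score_v1 = 0, score_v2 = 0, degenerate = TRUE))
  dd <- sqrt(((tensor[1L, 1L] - tensor[2L, 2L]) / 2)^2 + tensor[1L, 2L]^2)
  v1 <- 2 * dd / tr
  list(score_v1 = v1, score_v2 = 2 * v1, degenerate = FALSE)
}

#' Orientation tensor from an explicit angle list
#'
#' Oracle-style helper: the second-moment tensor of axial angles (degrees),
#' optionally weighted. `anisotropy_score()` of this equals the 2D nematic
#' order parameter `S = |mean(exp(2 i theta))|` for unit weights.
#'
#' @param angles_deg orientation angles in degrees.
#' @param weights optional weights.
#' @return 2 x 2 tensor.
#' @export
nematic_from_angles <- function(angles_deg, weights = NULL) {
  th <- angles_deg * pi / 180
  if (is.null(weights)) weights <- rep(1, length(th))
  w <- weights / sum(weights)
  n1 <- cos(th); n2 <- sin(th)
  matrix(c(sum(w * n1 * n1), sum(w * n1 * n2),
           sum(w * n1 * n2), sum(w * n2 * n2)), 2L, 2L)
}

#' Empirical 2D nematic order parameter of an angle list
#' @param angles_deg angles in degrees.
#' @return `|mean(exp(2 i theta))|` in [0, 1].
#' @export
order_parameter <- function(angles_deg) {
  th <- angles_deg * pi / 90 # 2 theta in radians
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Score many cells (ROIs) across timepoints
#'
#' @param images a single matrix, or a list of matrices (one per timepoint).
#' @param rois list of [roi_polygon()] with unique labels.
#' @param timepoints optional timepoint labels (default seq_along(images)).
#' @param ... passed to [texture_tensor()].
#' @return long-format data.frame: `cell`, `time`, `score_v1`, `score_v2`,
#'   `orientation`, `n_pixels`; rows sorted by cell label then time. ROIs
#'   that fail (e.g. out of bounds at a timepoint) give NA rows.
#' @export
score_cells <- function(images, rois, timepoints = NULL, ...) {
  if (is.matrix(images)) images <- list(images)
  if (is.null(timepoints)) timepoints <- seq_along(images)
  stopifnot(length(timepoints) == length(images))
  if (inherits(rois, "roi_polygon")) rois <- list(rois)
  labs <- vapply(rois, function(r) r$label, "")
  rows <- list()
  for (ti in seq_along(images)) {
    for (ri in seq_along(rois)) {
      res <- tryCatch({
        tt <- texture_tensor(images[[ti]], rois[[ri]], ...)
        sc <- anisotropy_score(tt)
        data.frame(cell = labs[ri], time = timepoints[ti],
                   score_v1 = sc$score_v1, score_v2 = sc$score_v2,
                   orientation = tt$mean_orientation,
                   n_pixels = tt$n_pixels)
      }, error = function(e) {
        message("score_cells: ", labs[ri], " @ ", timepoints[ti], ": ",
                conditionMessage(e))
        data.frame(cell = labs[ri], time = timepoints[ti],
                   score_v1 = NA_real_, score_v2 = NA_real_,
                   orientation = NA_real_, n_pixels = NA_integer_)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cell, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
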
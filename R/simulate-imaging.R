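#' Rotated two-dimensional Gaussian
#'
#' The model fitted to every fluorescent focus:
#' \deqn{f(x,y) = b + A e^{-(a\Delta x^2 + 2c\,\Delta x \Delta y + d\Delta y^2)}}
#' with \eqn{a = \cos^2\theta/(2\sigma_x^2) + \sin^2\theta/(2\sigma_y^2)},
#' \eqn{c = -\sin 2\theta/(4\sigma_x^2) + \sin 2\theta/(4\sigma_y^2)} and
#' \eqn{d = \sin^2\theta/(2\sigma_x^2) + \cos^2\theta/(2\sigma_y^2)}.
#' `x` is the column coordinate and `y` the row coordinate, in pixels, with
#' the origin at the top-left of the image.
#'
#' @param x,y coordinates (px), recycled against each other.
#' @param b baseline; A amplitude; x0,y0 center (px); sx,sy axis standard
#'   deviations (px); theta rotation in radians.
#' @param A,x0,y0,sx,sy,theta see above.
#' @return numeric vector of intensities.
#' @export
gaussian2d <- function(x, y, b, A, x0, y0, sx, sy, theta) {
  a <- cos(theta)^2 / (2 * sx^2) + sin(theta)^2 / (2 * sy^2)
  cc <- -sin(2 * theta) / (4 * sx^2) + sin(2 * theta) / (4 * sy^2)
  d <- sin(theta)^2 / (2 * sx^2) + cos(theta)^2 / (2 * sy^2)
  dx <- x - x0; dy <- y - y0
  b + A * exp(-(a * dx^2 + 2 * cc * dx * dy + d * dy^2))
}

# internal: render one slice (rows x cols) given puncta/spots on that slice
.render_slice <- function(nrow_px, ncol_px, baseline, puncta, spots,
                          spot_amp, spot_sigma) {
  xs <- matrix(rep(seq_len(ncol_px), each = nrow_px), nrow_px, ncol_px)
  ys <- matrix(rep(seq_len(nrow_px), ncol_px), nrow_px, ncol_px)
  img <- matrix(baseline, nrow_px, ncol_px)
  if (!is.null(puncta) && nrow(puncta))
    for (i in seq_len(nrow(puncta)))
      img <- img + gaussian2d(xs, ys, 0, puncta$A[i], puncta$x0[i],
                              puncta$y0[i], puncta$sx[i], puncta$sy[i],
                              puncta$theta[i])
  if (!is.null(spots) && nrow(spots))
    for (i in seq_len(nrow(spots)))
      img <- img + gaussian2d(xs, ys, 0, spot_amp, spots$x[i], spots$y[i],
                              spot_sigma, spot_sigma, 0)
  img
}

#' Simulate a multi-slice fluorescence image stack with known truth
#'
#' Renders circular cells, rotated-Gaussian puncta (G bodies) and
#' diffraction-limited mRNA spots into a `rows x cols x slices` stack, then
#' optionally corrupts it with Poisson shot noise and Gaussian read noise.
#' A noiseless evaluation of the stack at a punctum center on its slice
#' equals `baseline + A` of the truth record.
#'
#' @param dim integer triple `(rows, cols, slices)`.
#' @param cells `data.frame(cell_id, cx, cy, r)` of circular cell outlines
#'   (px); may be `NULL`.
#' @param puncta `data.frame(x0, y0, slice, A, sx, sy, theta)`; `sx`, `sy`
#'   must be positive and `A` non-negative, centers inside the image.
#' @param spots `data.frame(x, y, z)` of mRNA positions; may be `NULL`.
#' @param baseline image-wide baseline intensity `b` (A.U.).
#' @param noise_sd Gaussian read-noise sd (A.U.); 0 for noiseless.
#' @param poisson logical, add Poisson shot noise on the rendered intensity.
#' @param pixel_size physical pixel size in micrometers (default 0.13).
#' @param spot_amp,spot_sigma amplitude (A.U.) and sd (px) of rendered
#'   mRNA spots.
#' @param seed integer seed; noise is reproducible given the seed.
#' @return a list of class `image_truth` with `stack` (3D array),
#'   `cell_labels` (integer label matrix), `puncta`, `spots`, `baseline`,
#'   `pixel_size`.
#' @export
simulate_image_stack <- function(dim = c(128L, 128L, 5L), cells = NULL,
                                 puncta = NULL, spots = NULL,
                                 baseline = 100, noise_sd = 0,
                                 poisson = FALSE, pixel_size = 0.13,
                                 spot_amp = 600, spot_sigma = 0.8,
                                 seed = 1L) {
  stopifnot(length(dim) == 3, pixel_size > 0)
  if (!is.null(puncta) && nrow(puncta)) {
    if (any(puncta$sx <= 0) || any(puncta$sy <= 0))
      .fail("punctum sigma must be positive")
    if (any(puncta$A < 0)) .fail("punctum amplitude must be non-negative")
    if (any(puncta$x0 < 1 | puncta$x0 > dim[2] |
              puncta$y0 < 1 | puncta$y0 > dim[1]))
      .fail("punctum centers must lie inside the image bounds")
  }
  .with_seed(seed)
  stack <- array(0, dim)
  for (z in seq_len(dim[3])) {
    pz <- if (!is.null(puncta)) puncta[puncta$slice == z, , drop = FALSE]
    sz <- if (!is.null(spots)) spots[spots$z == z, , drop = FALSE]
    stack[, , z] <- .render_slice(dim[1], dim[2], baseline, pz, sz,
                                  spot_amp, spot_sigma)
  }
  if (poisson) stack[] <- stats::rpois(length(stack), pmax(stack, 0))
  if (noise_sd > 0) stack[] <- stack + stats::rnorm(length(stack), 0, noise_sd)
  labels <- matrix(0L, dim[1], dim[2])
  if (!is.null(cells) && nrow(cells)) {
    xs <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
    ys <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1], dim[2])
    for (i in seq_len(nrow(cells))) {
      inside <- (xs - cells$cx[i])^2 + (ys - cells$cy[i])^2 <= cells$r[i]^2
      labels[inside] <- i
    }
  }
  structure(list(stack = stack, cell_labels = labels, puncta = puncta,
                 spots = spots, baseline = baseline,
                 pixel_size = pixel_size),
            class = "image_truth")
}
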
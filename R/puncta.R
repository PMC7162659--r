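#' Detect local maxima in a projection image
#'
#' Returns strict 8-neighborhood local maxima that exceed the image
#' baseline (median) by at least `prominence`. Detections closer together
#' than `min_dist` are merged, keeping the brighter one. The default
#' prominence is 5x a robust noise estimate (median absolute deviation of
#' the pixel-to-pixel differences). For wide, bright foci whose shot noise
#' rides on a smooth profile, set `smooth_sigma` to pre-blur the image so
#' each focus contributes a single maximum; positions are still reported
#' on the original pixel grid.
#'
#' @param image numeric matrix (rows x cols).
#' @param prominence required height above baseline (A.U.); `NULL` for the
#'   MAD-based default (computed before smoothing).
#' @param min_dist merge radius in px.
#' @param smooth_sigma Gaussian pre-blur sd in px (0 = none).
#' @return `data.frame` with `x` (col), `y` (row), `value`.
#' @export
detect_maxima <- function(image, prominence = NULL, min_dist = 5,
                          smooth_sigma = 0) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) .fail("image smaller than the 3x3 patch")
  if (is.null(prominence))
    prominence <- 5 * stats::mad(diff(as.numeric(image))) / sqrt(2)
  if (smooth_sigma > 0)
    image <- as.matrix(EBImage::gblur(EBImage::Image(image),
                                      sigma = smooth_sigma))
  baseline <- stats::median(image)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- image
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    is_max <- is_max & (image > nb)
  }
  is_max <- is_max & (image >= baseline + prominence)
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x = numeric(), y = numeric(), value = numeric()))
  det <- data.frame(x = idx[, 2], y = idx[, 1],
                    value = image[idx])
  det <- det[order(-det$value), , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    d <- sqrt((det$x - det$x[i])^2 + (det$y - det$y[i])^2)
    keep[d < min_dist & seq_len(nrow(det)) > i] <- FALSE
  }
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Extract a square patch around a focus
#'
#' Side in pixels = `round(side_um / pixel_size)` (4.9 um at 0.13 um/px
#' gives a 38 px square). Patches hitting the image border are clipped and
#' flagged.
#'
#' @param image numeric matrix.
#' @param center `c(x, y)` center in px (col, row).
#' @param side_um patch side in micrometers (default 4.9).
#' @param pixel_size pixel size in micrometers (> 0).
#' @return list: `patch` (matrix), `x_offset`, `y_offset` (0-based offsets
#'   of the patch within the image), `clipped` (logical), `side_px`.
#' @export
extract_patch <- function(image, center, side_um = 4.9, pixel_size = 0.13) {
  stopifnot(pixel_size > 0)
  cx <- round(center[1]); cy <- round(center[2])
  if (cx < 1 || cx > ncol(image) || cy < 1 || cy > nrow(image))
    .fail("patch center (%s, %s) outside the image", center[1], center[2])
  side <- max(1L, as.integer(round(side_um / pixel_size)))
  half_lo <- (side - 1L) %/% 2L
  x1 <- cx - half_lo; x2 <- x1 + side - 1L
  y1 <- cy - half_lo; y2 <- y1 + side - 1L
  clipped <- x1 < 1 || y1 < 1 || x2 > ncol(image) || y2 > nrow(image)
  x1c <- max(1L, x1); x2c <- min(ncol(image), x2)
  y1c <- max(1L, y1); y2c <- min(nrow(image), y2)
  list(patch = image[y1c:y2c, x1c:x2c, drop = FALSE],
       x_offset = x1c - 1L, y_offset = y1c - 1L,
       clipped = clipped, side_px = side)
}

#' Subtract average background measured in three boxes
#'
#' The background is the mean intensity over the supplied boxes; the
#' corrected image is floored at zero.
#'
#' @param image numeric matrix.
#' @param boxes list of boxes, each `c(x1, y1, x2, y2)` in px (inclusive).
#' @return list: `image` (corrected), `background`.
#' @export
subtract_background <- function(image, boxes) {
  stopifnot(length(boxes) >= 1)
  vals <- numeric(0)
  covered <- matrix(FALSE, nrow(image), ncol(image))
  overlap <- FALSE
  for (b in boxes) {
    if (b[1] < 1 || b[2] < 1 || b[3] > ncol(image) || b[4] > nrow(image))
      .fail("background box outside the image")
    sel <- covered[b[2]:b[4], b[1]:b[3]]
    if (any(sel)) overlap <- TRUE
    covered[b[2]:b[4], b[1]:b[3]] <- TRUE
    vals <- c(vals, as.numeric(image[b[2]:b[4], b[1]:b[3]]))
  }
  if (overlap) warning("background boxes overlap")
  bg <- mean(vals)
  list(image = pmax(image - bg, 0), background = bg)
}

#' Fit a rotated 2D Gaussian to a focus patch
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of [gaussian2d()].
#' Initialization: baseline = patch border median, amplitude = max -
#' baseline, center = centroid of the top-decile pixels, sigma = side/6,
#' theta = 0; bounds keep sigma in `[0.5, side]` px and the amplitude
#' non-negative. `theta` is reported modulo pi; near-circular fits
#' (|sx - sy|/sx < 1%) get theta = 0 and a `circular` flag.
#'
#' @param patch numeric matrix, at least 5x5 px.
#' @param pixel_size optional pixel size (um) to also report sigma in um.
#' @return list of class `punctum_fit`: `b`, `A`, `x0`, `y0` (px within
#'   the patch), `sx`, `sy` (px), `sx_um`, `sy_um`, `theta`, `residual`
#'   (norm), `converged`, `circular`.
#' @export
fit_gaussian2d <- function(patch, pixel_size = NA_real_) {
  nr <- nrow(patch); nc <- ncol(patch)
  if (nr < 5 || nc < 5) .fail("patch must be at least 5x5 px")
  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), nc)
  z <- as.numeric(patch)
  border <- c(patch[1, ], patch[nr, ], patch[, 1], patch[, nc])
  b0 <- stats::median(border)
  A0 <- max(z) - b0
  top <- z >= stats::quantile(z, 0.9)
  x00 <- sum(xs[top] * z[top]) / sum(z[top])
  y00 <- sum(ys[top] * z[top]) / sum(z[top])
  side <- max(nr, nc)
  # moment-based shape start: intensity covariance of the background-
  # subtracted patch gives sigma and the principal-axis angle
  w <- pmax(z - b0, 0)
  sw <- sum(w)
  sx0 <- side / 6; sy0 <- side / 6; th0 <- 0
  if (sw > 0) {
    mx <- sum(w * xs) / sw; my <- sum(w * ys) / sw
    cxx <- sum(w * (xs - mx)^2) / sw
    cyy <- sum(w * (ys - my)^2) / sw
    cxy <- sum(w * (xs - mx) * (ys - my)) / sw
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
    if (all(ev$values > 0)) {
      sx0 <- sqrt(ev$values[1]); sy0 <- sqrt(ev$values[2])
      th0 <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    }
  }
  sx0 <- min(max(sx0, 0.6), side); sy0 <- min(max(sy0, 0.6), side)
  lower <- c(-Inf, 0, 1 - side, 1 - side, 0.5, 0.5, -pi)
  upper <- c(Inf, Inf, nc + side, nr + side, side, side, pi)
  resid_fun <- function(p)
    z - gaussian2d(xs, ys, p[1], p[2], p[3], p[4], p[5], p[6], p[7])
  wrap <- function(t) ((t + pi) %% (2 * pi)) - pi
  # the moment start can sit in a shallow local valley for some rotation
  # angles; try the axis-swapped and axis-aligned starts too
  starts <- list(
    c(b = b0, A = max(A0, 1e-6), x0 = x00, y0 = y00,
      sx = sx0, sy = sy0, theta = th0),
    c(b = b0, A = max(A0, 1e-6), x0 = x00, y0 = y00,
      sx = sy0, sy = sx0, theta = wrap(th0 + pi / 2)),
    c(b = b0, A = max(A0, 1e-6), x0 = x00, y0 = y00,
      sx = sx0, sy = sy0, theta = 0))
  best <- NULL
  for (par0 in starts) {
    fit <- try(minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                                  fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance <= 1e-16 * sum(z^2)) break
  }
  if (is.null(best)) {
    p <- starts[[1]]; converged <- FALSE
    resid <- sqrt(sum(resid_fun(p)^2))
  } else {
    p <- best$par
    converged <- best$info %in% 1:4
    resid <- sqrt(best$deviance)
  }
  sx <- p[5]; sy <- p[6]; theta <- p[7] %% pi
  circular <- abs(sx - sy) / max(sx, 1e-12) < 0.01
  if (circular) theta <- 0
  structure(list(b = unname(p[1]), A = unname(p[2]), x0 = unname(p[3]),
                 y0 = unname(p[4]), sx = unname(sx), sy = unname(sy),
                 sx_um = unname(sx * pixel_size),
                 sy_um = unname(sy * pixel_size),
                 theta = unname(theta), residual = resid,
                 converged = converged, circular = circular),
            class = "punctum_fit")
}

#' Classify cells by puncta count
#'
#' Maps per-cell counts of accepted detections to `{none = 0, single = 1,
#' multiple >= 2}` and reports fractions per category. Detections outside
#' every cell mask are counted separately, not assigned.
#'
#' @param cell_labels integer label matrix (0 = background).
#' @param detections `data.frame` with `x`, `y` columns (px).
#' @param warn_min_cells warn when fewer cells than this are scored
#'   (default 100, the per-replicate floor used when scoring G bodies).
#' @return list: `per_cell` (data.frame cell, count, label), `fractions`
#'   (named: single, multiple, none), `n_outside`.
#' @export
classify_cells <- function(cell_labels, detections, warn_min_cells = 100L) {
  n_cells <- max(cell_labels)
  if (n_cells < warn_min_cells)
    warning(sprintf("only %d cells scored (< %d per replicate)",
                    n_cells, warn_min_cells))
  counts <- integer(n_cells)
  n_outside <- 0L
  for (i in seq_len(nrow(detections))) {
    r <- round(detections$y[i]); c <- round(detections$x[i])
    lab <- if (r >= 1 && r <= nrow(cell_labels) &&
                 c >= 1 && c <= ncol(cell_labels)) cell_labels[r, c] else 0L
    if (lab == 0L) n_outside <- n_outside + 1L else
      counts[lab] <- counts[lab] + 1L
  }
  label <- ifelse(counts == 0L, "none", ifelse(counts == 1L, "single",
                                               "multiple"))
  fr <- c(single = mean(label == "single"),
          multiple = mean(label == "multiple"),
          none = mean(label == "none"))
  list(per_cell = data.frame(cell = seq_len(n_cells), count = counts,
                             label = label, stringsAsFactors = FALSE),
       fractions = fr, n_outside = n_outside)
}

#' Compare puncta-class fractions between conditions
#'
#' Two-sided unpaired Student t-tests (pooled variance, the form used for
#' replicate-level image quantifications; `pooled_var = FALSE` gives
#' Welch) with a Bonferroni correction over the requested comparisons
#' (`p_adj = min(1, m * p)`).
#'
#' @param fractions `data.frame` with `condition`, `replicate`, `fraction`.
#' @param comparisons list of `c(condition_a, condition_b)` pairs; default
#'   all pairs.
#' @param pooled_var pooled-variance (Student) t-test; `FALSE` for Welch.
#' @return `data.frame`: `condition_a`, `condition_b`, `t`, `p`, `p_adj`.
#' @export
compare_conditions <- function(fractions, comparisons = NULL,
                               pooled_var = TRUE) {
  conds <- unique(fractions$condition)
  if (is.null(comparisons))
    comparisons <- utils::combn(conds, 2, simplify = FALSE)
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(p) {
    a <- fractions$fraction[fractions$condition == p[1]]
    b <- fractions$fraction[fractions$condition == p[2]]
    if (length(a) < 2 || length(b) < 2)
      .fail("need >= 2 replicates per condition (%s vs %s)", p[1], p[2])
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      tt <- list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else tt <- stats::t.test(a, b, var.equal = pooled_var)
    data.frame(condition_a = p[1], condition_b = p[2],
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- pmin(1, m * out$p)
  out
}
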
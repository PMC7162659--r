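#' Correct a FRAP trace for background and acquisition photobleaching
#'
#' Background is subtracted from the bleached and control series; each
#' control is normalized to its own pre-bleach mean and the bleached
#' series is divided frame-wise by the mean of the normalized controls
#' (cancelling acquisition photobleaching exactly when controls and
#' granule bleach at the same rate). The trace is then rescaled so the
#' pre-bleach mean is 1 and the first post-bleach frame is 0.
#'
#' @param trace a [simulate_frap_trace()] object or a list with `times`,
#'   `raw`, `controls` (matrix with >= 3 columns), `background`,
#'   `bleach_index`.
#' @return the input list extended with `corrected` (photobleach-corrected,
#'   pre-bleach approximately 1), `normalized` (0-1 rescaled),
#'   `remaining_fraction` (first post-bleach / pre-bleach intensity after
#'   background subtraction, before rescaling).
#' @export
correct_trace <- function(trace) {
  ctrl <- trace$controls
  if (is.null(dim(ctrl)) || ncol(ctrl) < 3)
    .fail("need at least 3 unbleached control series")
  bi <- trace$bleach_index
  pre <- seq_len(bi - 1L)
  raw <- trace$raw - trace$background
  ctrl <- ctrl - trace$background
  ctrl_norm <- sweep(ctrl, 2, colMeans(ctrl[pre, , drop = FALSE]), "/")
  decay <- rowMeans(ctrl_norm)
  corrected <- raw / decay
  pre_val <- mean(corrected[pre])
  post0 <- corrected[bi]
  trace$corrected <- corrected / pre_val
  trace$remaining_fraction <- post0 / pre_val
  trace$normalized <- (corrected - post0) / (pre_val - post0)
  trace
}

#' Bleach-depth filter for FRAP traces
#'
#' Keeps a trace only when less than 40% of the granule fluorescence
#' remains in the first post-bleach frame (evaluated after background
#' subtraction and photobleach correction, before 0-1 rescaling). The
#' bound is strict: exactly 40% remaining is dropped.
#'
#' @param trace a [correct_trace()]'d trace.
#' @param max_remaining strict upper bound on the remaining fraction
#'   (default 0.40).
#' @return logical: keep the trace?
#' @export
filter_bleach_depth <- function(trace, max_remaining = 0.40) {
  if (is.null(trace$remaining_fraction))
    .fail("trace must be corrected first (correct_trace)")
  trace$remaining_fraction < max_remaining
}

#' Fit the exponential recovery model to a corrected FRAP trace
#'
#' Least-squares fit of `I(t) = A * (1 - exp(-tau * t))` to the normalized
#' post-bleach frames with `t <= t_max` (t measured from the first
#' post-bleach frame). The recovery half-time is `log(2) / tau`. Plasmid
#' experiments suffer late-trace photobleaching; use `t_max = 25` for
#' them.
#'
#' @param trace a [correct_trace()]'d trace with `normalized` values.
#' @param t_max fit window in minutes (default 40).
#' @return list of class `recovery_fit`: `A`, `tau`, `half_time`,
#'   `t_max`, `converged`, `flat` (amplitude indistinguishable from 0,
#'   tau unidentifiable).
#' @export
fit_recovery <- function(trace, t_max = 40) {
  bi <- trace$bleach_index
  t <- trace$times[bi:length(trace$times)] - trace$times[bi]
  y <- trace$normalized[bi:length(trace$times)]
  sel <- t <= t_max
  t <- t[sel]; y <- y[sel]
  if (length(t) < 5) .fail("need >= 5 post-bleach frames within t_max")
  a0 <- max(mean(y[t >= stats::quantile(t, 0.75)]), 0.01)
  t_half_guess <- t[which(y >= a0 / 2)[1]]
  tau0 <- if (is.na(t_half_guess) || t_half_guess <= 0) 0.1
          else log(2) / t_half_guess
  fit <- try(minpack.lm::nls.lm(
    par = c(A = a0, tau = tau0),
    lower = c(0, 1e-6), upper = c(1.5, Inf),
    fn = function(p) y - p[1] * (1 - exp(-p[2] * t)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    A <- a0; tau <- tau0; converged <- FALSE
  } else {
    A <- unname(fit$par[1]); tau <- unname(fit$par[2])
    converged <- fit$info %in% 1:4
  }
  flat <- A < 0.02   # no measurable recovery: tau is unidentifiable
  structure(list(A = A, tau = tau,
                 half_time = if (flat) NA_real_ else log(2) / tau,
                 t_max = t_max, converged = converged && !flat,
                 flat = flat),
            class = "recovery_fit")
}

#' Track a granule through a time series and extract its intensity
#'
#' Per frame, the measurement circle is re-centered on the brightest pixel
#' within `search_radius` of the previous center. The circle radius is
#' chosen once, on the bleach frame, as the radius in `radius_grid`
#' maximizing the fraction of signal bleached
#' (`1 - post/pre` circle intensity ratio).
#'
#' @param frames 3D array (rows x cols x frames).
#' @param initial_center `c(x, y)` px.
#' @param bleach_index first post-bleach frame.
#' @param radius_grid candidate radii in px.
#' @param search_radius tracking search radius in px.
#' @param min_peak minimum peak intensity to consider the track alive;
#'   losing the peak truncates the trace with a flag.
#' @return list: `centers` (n x 2), `intensity` (mean intensity within the
#'   circle per frame), `radius`, `lost` (logical), `n_tracked`.
#' @export
track_granule <- function(frames, initial_center, bleach_index,
                          radius_grid = 1:10, search_radius = 3,
                          min_peak = -Inf) {
  nf <- dim(frames)[3]
  nr <- dim(frames)[1]; nc <- dim(frames)[2]
  circ_mean <- function(img, cx, cy, r) {
    x1 <- max(1, floor(cx - r)); x2 <- min(nc, ceiling(cx + r))
    y1 <- max(1, floor(cy - r)); y2 <- min(nr, ceiling(cy + r))
    xs <- rep(x1:x2, each = y2 - y1 + 1); ys <- rep(y1:y2, x2 - x1 + 1)
    sel <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    mean(img[cbind(ys[sel], xs[sel])])
  }
  centers <- matrix(NA_real_, nf, 2)
  cx <- initial_center[1]; cy <- initial_center[2]
  lost <- FALSE; n_tracked <- 0L
  for (f in seq_len(nf)) {
    x1 <- max(1, round(cx - search_radius)); x2 <- min(nc, round(cx + search_radius))
    y1 <- max(1, round(cy - search_radius)); y2 <- min(nr, round(cy + search_radius))
    sub <- frames[y1:y2, x1:x2, f, drop = FALSE][, , 1]
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    if (max(sub) < min_peak) { lost <- TRUE; break }
    cy <- y1 + pk[1] - 1; cx <- x1 + pk[2] - 1
    centers[f, ] <- c(cx, cy)
    n_tracked <- f
  }
  # radius: maximize percent of signal bleached at the bleach frame
  pre_img <- frames[, , bleach_index - 1L]
  post_img <- frames[, , bleach_index]
  pc <- centers[bleach_index - 1L, ]; qc <- centers[bleach_index, ]
  frac_bleached <- vapply(radius_grid, function(r)
    1 - circ_mean(post_img, qc[1], qc[2], r) /
      circ_mean(pre_img, pc[1], pc[2], r), numeric(1))
  # inside a uniformly bleached granule the percent bleached is flat, then
  # falls once the circle swallows unbleached surround: take the largest
  # radius still within 2% of the maximum, capturing the whole granule
  near_max <- frac_bleached >= 0.98 * max(frac_bleached)
  radius <- max(radius_grid[near_max])
  intensity <- vapply(seq_len(n_tracked), function(f)
    circ_mean(frames[, , f], centers[f, 1], centers[f, 2], radius),
    numeric(1))
  list(centers = centers[seq_len(n_tracked), , drop = FALSE],
       intensity = intensity, radius = radius, lost = lost,
       n_tracked = n_tracked)
}
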
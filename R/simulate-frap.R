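#' Simulate a FRAP experiment (bleached granule + unbleached controls)
#'
#' The bleached granule follows the single-exponential recovery model
#' \eqn{I(t) = A(1 - e^{-\tau t})} in normalized units, embedded in raw
#' intensity units: pre-bleach plateau `i_pre`, a drop to
#' `i_pre * (1 - bleach_depth)` at the bleach frame, then recovery toward
#' `A_true` of the bleached fraction. Acquisition photobleaching multiplies
#' every series by `exp(-rate * frame)`, mirroring the correction by
#' unbleached control cells; a constant background offset is added to all
#' series.
#'
#' @param A_true recovery amplitude as a fraction of the bleached signal
#'   (0 < A_true <= 1; 0 is allowed and gives a flat post-bleach trace).
#' @param tau_true recovery rate per minute (> 0); half-time = ln(2)/tau.
#' @param bleach_depth fraction of granule fluorescence destroyed by the
#'   bleach pulse, in (0, 1].
#' @param acquisition_bleach_rate per-frame fractional loss from imaging
#'   (multiplicative exponential decay).
#' @param n_controls number of unbleached control cells (>= 3 for the
#'   correction step downstream).
#' @param noise_sd Gaussian noise sd in normalized units.
#' @param n_frames total frames; frames are `frame_interval` minutes apart.
#' @param pre_frames pre-bleach frames; the bleach happens between frame
#'   `pre_frames` and `pre_frames + 1`.
#' @param i_pre,background raw pre-bleach intensity and background (A.U.).
#' @param frame_interval minutes between frames.
#' @param seed integer seed.
#' @return a list of class `frap_trace` with `times` (min), `raw` (bleached
#'   series, A.U.), `controls` (matrix, one column per control),
#'   `background`, `bleach_index` (first post-bleach frame), and the truth
#'   parameters.
#' @export
simulate_frap_trace <- function(A_true = 0.3, tau_true = log(2) / 10,
                                bleach_depth = 0.8,
                                acquisition_bleach_rate = 0.01,
                                n_controls = 3L, noise_sd = 0.02,
                                n_frames = 41L, pre_frames = 5L,
                                i_pre = 1000, background = 50,
                                frame_interval = 1, seed = 1L) {
  if (bleach_depth <= 0 || bleach_depth > 1)
    .fail("bleach_depth must lie in (0, 1]")
  stopifnot(A_true >= 0, A_true <= 1, tau_true > 0, n_controls >= 1)
  .with_seed(seed)
  frames <- seq_len(n_frames)
  times <- (frames - 1) * frame_interval
  bleach_index <- pre_frames + 1L
  t_post <- times - times[bleach_index]        # 0 at first post-bleach frame
  decay <- exp(-acquisition_bleach_rate * (frames - 1))
  i_post0 <- i_pre * (1 - bleach_depth)
  model <- ifelse(frames < bleach_index, i_pre,
                  i_post0 + (i_pre - i_post0) * A_true *
                    (1 - exp(-tau_true * pmax(t_post, 0))))
  raw <- model * decay + background +
    stats::rnorm(n_frames, 0, noise_sd * i_pre)
  controls <- vapply(seq_len(n_controls), function(k)
    i_pre * decay + background + stats::rnorm(n_frames, 0, noise_sd * i_pre),
    numeric(n_frames))
  structure(list(times = times, raw = raw, controls = controls,
                 background = background, bleach_index = bleach_index,
                 A_true = A_true, tau_true = tau_true,
                 bleach_depth = bleach_depth,
                 acquisition_bleach_rate = acquisition_bleach_rate),
            class = "frap_trace")
}

#' Simulate a G-body growth-competition observation
#'
#' A mixed culture is seeded with a fraction `f_true` of G-body-forming
#' (GB+) cells and `1 - f_true` non-forming (GB-) cells. Scoring `n_cells`
#' per arm for the presence of a G body gives binomial counts with success
#' probabilities `pct_gb_plus/100`, `pct_gb_minus/100`, and, for the mix,
#' `f_true * pct_gb_plus/100 + (1 - f_true) * pct_gb_minus/100`.
#'
#' @param f_true true GB+ fraction of the mixed culture, in `[0, 1]`.
#' @param pct_gb_plus,pct_gb_minus percent of cells with G bodies in the
#'   pure GB+ and GB- cultures; must differ for identifiability.
#' @param n_cells cells scored per arm (>= 1).
#' @param seed integer seed.
#' @return a list of class `competition_obs` with `pct_mix`, `pct_gb_plus`,
#'   `pct_gb_minus` (observed percentages), the underlying counts and
#'   `n_cells`, and `f_true`.
#' @export
simulate_competition <- function(f_true = 0.5, pct_gb_plus = 90,
                                 pct_gb_minus = 10, n_cells = 1000L,
                                 seed = 1L) {
  stopifnot(f_true >= 0, f_true <= 1)
  if (n_cells < 1) .fail("n_cells must be at least 1")
  if (pct_gb_plus == pct_gb_minus)
    .fail("pct_gb_plus must differ from pct_gb_minus (non-identifiable)")
  .with_seed(seed)
  p_mix <- f_true * pct_gb_plus / 100 + (1 - f_true) * pct_gb_minus / 100
  k <- c(mix = stats::rbinom(1, n_cells, p_mix),
         plus = stats::rbinom(1, n_cells, pct_gb_plus / 100),
         minus = stats::rbinom(1, n_cells, pct_gb_minus / 100))
  structure(list(pct_mix = 100 * k[["mix"]] / n_cells,
                 pct_gb_plus = 100 * k[["plus"]] / n_cells,
                 pct_gb_minus = 100 * k[["minus"]] / n_cells,
                 counts = k, n_cells = n_cells, f_true = f_true),
            class = "competition_obs")
}
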
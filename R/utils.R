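#' Derive a per-stage seed from a single global seed
#'
#' Every stochastic stage of the pipeline draws its seed from one global seed
#' so that a whole run is reproducible end to end while stages stay
#' independent of each other (adding iterations to one stage never perturbs
#' another). The fan-out is a plain polynomial string hash of the stage name,
#' folded into the global seed modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage (e.g. `"parclip"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double-int range
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h + (as.double(seed) %% m) * 48271) %% (m - 1) + 1)
}

# internal: set seed only when one is supplied
.with_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# internal: stop with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# internal: check 0-based half-open interval columns
.check_intervals <- function(start, end, what = "interval") {
  if (any(start < 0)) .fail("%s: negative coordinates are not allowed", what)
  if (any(end <= start)) .fail("%s: end must exceed start (0-based half-open)", what)
  invisible(TRUE)
}

# internal: midpoint of a 0-based half-open interval, as a 0-based position
.midpoint <- function(start, end) floor((start + end - 1) / 2)
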
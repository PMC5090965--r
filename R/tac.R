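#' Time-activity curve (TAC) container
#'
#' A TAC is a tibble with one row per PET frame and columns
#' `frame_start_s`, `frame_duration_s` and `concentration_kBq_per_mL`.
#' Frames must be contiguous and non-overlapping; kinetic routines work on
#' frame mid-times expressed in minutes.
#'
#' @param frame_durations_s Numeric vector of frame durations in seconds.
#' @param concentration Numeric vector of frame-averaged radioactivity
#'   concentrations (kBq/mL), one per frame.
#' @param frame_start_s Optional frame start times (seconds). Defaults to the
#'   cumulative sum of the durations starting at 0.
#' @return A tibble of class `tac`.
#' @export
tac <- function(frame_durations_s, concentration,
                frame_start_s = NULL) {
  if (any(!is.finite(frame_durations_s)) || any(frame_durations_s <= 0))
    stop("all frame durations must be positive and finite")
  n <- length(frame_durations_s)
  if (length(concentration) != n)
    stop("concentration must have one value per frame")
  if (any(!is.finite(concentration)))
    stop("non-finite concentration values")
  if (is.null(frame_start_s))
    frame_start_s <- cumsum(c(0, frame_durations_s[-n]))
  if (length(frame_start_s) != n)
    stop("frame_start_s must have one value per frame")
  ends <- frame_start_s + frame_durations_s
  if (n > 1 && any(frame_start_s[-1] < ends[-n] - 1e-9))
    stop("frames overlap")
  out <- tibble::tibble(
    frame_start_s = as.numeric(frame_start_s),
    frame_duration_s = as.numeric(frame_durations_s),
    concentration_kBq_per_mL = as.numeric(concentration)
  )
  class(out) <- c("tac", class(out))
  out
}

#' Default dynamic frame schedule
#'
#' The 41-frame, 90-minute dynamic acquisition schedule used throughout:
#' 6 x 10 s, 6 x 30 s, 11 x 60 s, 15 x 180 s and 3 x 600 s (5400 s total).
#'
#' @return Numeric vector of 41 frame durations in seconds.
#' @export
frame_schedule_default <- function() {
  c(rep(10, 6), rep(30, 6), rep(60, 11), rep(180, 15), rep(600, 3))
}

#' Frame mid-times of a TAC in minutes
#' @param x A `tac` or any data frame with `frame_start_s`/`frame_duration_s`.
#' @return Numeric vector of mid-times (minutes).
#' @export
tac_mid_min <- function(x) {
  (x$frame_start_s + x$frame_duration_s / 2) / 60
}

# Fine time grid (minutes) covering a frame schedule, including every frame
# boundary so frame averages can be computed by exact trapezoidal pieces.
# dt_min is the nominal spacing; boundaries are merged in.
fine_grid_min <- function(frame_durations_s, dt_min = 0.1) {
  ends <- cumsum(frame_durations_s) / 60
  g <- sort(unique(c(seq(0, max(ends), by = dt_min), 0, ends,
                     cumsum(c(0, frame_durations_s[-length(frame_durations_s)])) / 60)))
  g
}

# Trapezoidal average of a curve sampled on grid t (minutes) over each frame.
# Grid must contain every frame boundary.
frame_average <- function(t, y, frame_durations_s) {
  starts <- cumsum(c(0, frame_durations_s[-length(frame_durations_s)])) / 60
  ends <- cumsum(frame_durations_s) / 60
  cum <- c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  idx <- function(v) {
    i <- findInterval(v, t)
    if (any(abs(t[i] - v) > 1e-9)) stop("frame boundary missing from grid")
    i
  }
  i0 <- idx(starts); i1 <- idx(ends)
  (cum[i1] - cum[i0]) / (ends - starts)
}

# Causal convolution of y (on grid t, minutes) with exp(-k * t), by an exact
# trapezoidal recursion that tolerates non-uniform spacing.
exp_conv <- function(t, y, k) {
  n <- length(t)
  out <- numeric(n)
  if (n < 2) return(out)
  dt <- diff(t)
  ek <- exp(-k * dt)
  for (i in 2:n) {
    out[i] <- out[i - 1] * ek[i - 1] +
      dt[i - 1] / 2 * (y[i - 1] * ek[i - 1] + y[i])
  }
  out
}

# Reconstruct a fine-grid curve from a measured TAC: linear interpolation of
# the frame values at mid-times, anchored at (0, 0), then a few conservative
# correction sweeps so the reconstruction's frame averages reproduce the
# measured frame values (the measurements are averages, not point samples).
tac_to_fine <- function(x, t, n_sweep = 50) {
  mids <- tac_mid_min(x)
  vals <- x$concentration_kBq_per_mL
  y <- stats::approx(c(0, mids), c(0, vals), xout = t, rule = 2)$y
  dur <- x$frame_duration_s
  for (s in seq_len(n_sweep)) {
    err <- vals - frame_average(t, y, dur)
    if (max(abs(err)) < 1e-12 * max(abs(vals))) break
    y <- y + stats::approx(c(0, mids), c(0, err), xout = t, rule = 2)$y
  }
  y
}
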
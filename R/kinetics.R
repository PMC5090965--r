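#' Fit the simplified reference tissue model by basis functions
#'
#' Standard basis-function SRTM: for each candidate `k2a` on a log-spaced
#' grid, the basis `Cref (x) exp(-k2a t)` is computed on a fine grid,
#' frame-averaged, and the two-parameter linear subproblem
#' `Ct = theta1 Cref + theta2 basis` is solved by least squares; the grid
#' minimum is then polished by golden-section search on `log(k2a)`.
#' Parameters follow from `R1 = theta1`, `k2 = theta2 + R1 k2a`,
#' `BP = k2/k2a - 1`, `k2' = k2/R1`.
#'
#' @param target,ref [tac()] objects sharing a frame schedule.
#' @param k2a_range Search range for `k2a` (1/min).
#' @param n_grid Number of log-spaced grid points.
#' @param dt_min Fine-grid spacing (minutes).
#' @return A list of class `kinetic_params`: `R1`, `k2`, `BP`, `k2a`,
#'   `k2prime`, `rss`, and `bp_clamped` (TRUE when a negative BP estimate was
#'   clamped to 0).
#' @export
fit_srtm <- function(target, ref, k2a_range = c(0.01, 1), n_grid = 64,
                     dt_min = 0.1) {
  dur <- target$frame_duration_s
  if (!isTRUE(all.equal(dur, ref$frame_duration_s)))
    stop("target and ref must share a frame schedule")
  y <- target$concentration_kBq_per_mL
  if (all(y == 0) || all(ref$concentration_kBq_per_mL == 0))
    stop("degenerate all-zero TAC")
  t <- fine_grid_min(dur, dt_min)
  cref_fine <- tac_to_fine(ref, t)
  # the R1 column is the measured reference itself; only the convolution
  # basis needs the fine-grid reconstruction
  cref_frames <- ref$concentration_kBq_per_mL

  rss_at <- function(k2a) {
    basis <- frame_average(t, exp_conv(t, cref_fine, k2a), dur)
    X <- cbind(cref_frames, basis)
    fit <- stats::lsfit(X, y, intercept = FALSE)
    list(rss = sum(fit$residuals^2), theta = fit$coefficients)
  }

  grid <- exp(seq(log(k2a_range[1]), log(k2a_range[2]), length.out = n_grid))
  rss <- vapply(grid, function(k) rss_at(k)$rss, numeric(1))
  i <- which.min(rss)
  lo <- log(grid[max(1, i - 1)]); hi <- log(grid[min(n_grid, i + 1)])
  # golden-section refinement on log(k2a)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- rss_at(exp(c1))$rss; f2 <- rss_at(exp(c2))$rss
  for (iter in 1:60) {
    if (b - a < 1e-8) break
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- rss_at(exp(c1))$rss
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- rss_at(exp(c2))$rss
    }
  }
  k2a <- exp((a + b) / 2)
  best <- rss_at(k2a)
  R1 <- unname(best$theta[1])
  k2 <- unname(best$theta[2]) + R1 * k2a
  BP <- k2 / k2a - 1
  clamped <- FALSE
  if (BP < 0) {
    warning("negative BP estimate clamped to 0")
    BP <- 0
    clamped <- TRUE
  }
  structure(list(R1 = R1, k2 = k2, BP = BP, k2a = k2a,
                 k2prime = k2 / R1, rss = best$rss, bp_clamped = clamped),
            class = "kinetic_params")
}

#' Estimate the reference efflux constant k2' from signal-rich regions
#'
#' Fits SRTM to each signal-rich TAC against the reference and pools the
#' per-region `k2/R1` values.
#'
#' @param ref Reference [tac()].
#' @param signal_rich A list of [tac()] objects (e.g. caudate and putamen).
#' @param pool `"median"` (default) or `"mean"`.
#' @param ... Passed to [fit_srtm()].
#' @return Pooled `k2'` (1/min).
#' @export
estimate_k2prime <- function(ref, signal_rich, pool = c("median", "mean"),
                             ...) {
  pool <- match.arg(pool)
  if (inherits(signal_rich, "tac")) signal_rich <- list(signal_rich)
  if (length(signal_rich) < 1) stop("need at least one signal-rich TAC")
  vals <- vapply(signal_rich, function(x) {
    fit <- tryCatch(fit_srtm(x, ref, ...), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$k2prime
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("all SRTM fits failed")
  if (pool == "median") stats::median(vals) else mean(vals)
}

#' Logan reference-tissue graphical analysis with fixed k2'
#'
#' Ordinary least squares of
#' `y(T) = int_0^T Ct / Ct(T)` on
#' `x(T) = (int_0^T Cref + Cref(T)/k2') / Ct(T)`
#' over frames with mid-time `>= t_star`; integrals by trapezoid on frame
#' mid-times with an implicit origin point. The slope is the distribution
#' volume ratio (DVR) and `BPnd = DVR - 1`.
#'
#' @param target,ref [tac()] objects on one frame schedule.
#' @param k2prime Fixed reference efflux constant (1/min, > 0).
#' @param t_star Start of the linear segment (minutes).
#' @return A list of class `logan_fit`: `dvr`, `bpnd`, `intercept`, `t_star`,
#'   `n_points`, `r_squared`.
#' @export
logan_ref_bpnd <- function(target, ref, k2prime, t_star = 30) {
  if (k2prime <= 0) stop("k2prime must be positive")
  mids <- tac_mid_min(target)
  ct <- target$concentration_kBq_per_mL
  cr <- ref$concentration_kBq_per_mL
  cumtrapz0 <- function(t, y) {
    tt <- c(0, t); yy <- c(0, y)
    cumsum(c(0, diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2))[-1]
  }
  ict <- cumtrapz0(mids, ct)
  icr <- cumtrapz0(mids, cr)
  use <- mids >= t_star
  drop0 <- use & ct == 0
  if (any(drop0)) {
    warning(sprintf("%d frame(s) with zero target activity dropped",
                    sum(drop0)))
    use <- use & ct != 0
  }
  if (sum(use) < 3) stop("fewer than 3 usable frames at or after t_star")
  x <- (icr[use] + cr[use] / k2prime) / ct[use]
  y <- ict[use] / ct[use]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(dvr = slope, bpnd = slope - 1,
                 intercept = unname(stats::coef(fit)[1]),
                 t_star = t_star, n_points = sum(use),
                 r_squared = summary(fit)$r.squared),
            class = "logan_fit")
}
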
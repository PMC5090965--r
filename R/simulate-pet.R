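#' Synthetic reference-region time-activity curve
#'
#' Generates a smooth, nonnegative reference TAC as a difference of two
#' exponentials, `C(t) = A (exp(-lambda_slow t) - exp(-lambda_fast t))`,
#' frame-averaged analytically over the acquisition schedule. This is the
#' generative stand-in for a measured cerebellar reference curve.
#'
#' @param amplitude Peak-scale amplitude `A` (kBq/mL); `amplitude = 0` gives an
#'   all-zero TAC.
#' @param lambda_fast,lambda_slow Exponential rates (1/min); must satisfy
#'   `lambda_fast > lambda_slow > 0`.
#' @param frame_durations_s Frame schedule (seconds);
#'   default [frame_schedule_default()].
#' @return A [tac()] with the analytic frame averages.
#' @export
simulate_reference_tac <- function(amplitude = 30,
                                   lambda_fast = 3,
                                   lambda_slow = 0.03,
                                   frame_durations_s = frame_schedule_default()) {
  if (!(lambda_fast > lambda_slow && lambda_slow > 0))
    stop("need lambda_fast > lambda_slow > 0")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  ends <- cumsum(frame_durations_s) / 60
  starts <- c(0, ends[-length(ends)])
  # analytic mean of exp(-l t) over [t0, t1]
  eavg <- function(l, t0, t1) (exp(-l * t0) - exp(-l * t1)) / (l * (t1 - t0))
  vals <- amplitude * (eavg(lambda_slow, starts, ends) -
                         eavg(lambda_fast, starts, ends))
  tac(frame_durations_s, vals)
}

# Closed-form reference curve as a function of time in minutes.
reference_curve_fun <- function(amplitude, lambda_fast, lambda_slow) {
  function(t) amplitude * (exp(-lambda_slow * t) - exp(-lambda_fast * t))
}

# Noiseless SRTM solution on a fine grid:
#   Ct(t) = R1 Cref(t) + (k2 - R1 k2a) [Cref (x) exp(-k2a t)](t),
# with k2a = k2 / (1 + BP).
srtm_curve <- function(t, cref, R1, k2, BP) {
  k2a <- k2 / (1 + BP)
  R1 * cref + (k2 - R1 * k2a) * exp_conv(t, cref, k2a)
}

#' Simulate a target-region TAC under the simplified reference tissue model
#'
#' Computes the noiseless SRTM solution
#' `Ct(t) = R1 Cref(t) + (k2 - R1 k2a) [Cref (x) exp(-k2a t)](t)` with
#' `k2a = k2/(1+BP)` on a fine grid (trapezoidal convolution), frame-averages
#' it, and optionally adds independent Gaussian noise whose per-frame standard
#' deviation scales as `noise_sd0 / sqrt(frame duration in minutes)` — the
#' usual count-statistics proxy for reconstructed PET frames.
#'
#' @param ref Reference input: either a [tac()] (interpolated at frame
#'   mid-times, anchored at the origin) or a function of time in minutes.
#' @param R1 Relative delivery `K1/K1'` (unitless, > 0).
#' @param k2 Target efflux rate (1/min, > 0).
#' @param BP Binding potential BPnd (unitless, >= 0).
#' @param frame_durations_s Frame schedule (seconds).
#' @param noise_sd0 Noise scale (kBq/mL per sqrt-minute); 0 for noiseless.
#' @param seed Integer seed; required when `noise_sd0 > 0`.
#' @param dt_min Fine-grid spacing in minutes.
#' @return A [tac()].
#' @export
simulate_target_tac <- function(ref, R1, k2, BP,
                                frame_durations_s = frame_schedule_default(),
                                noise_sd0 = 0, seed = NULL, dt_min = 0.1) {
  if (R1 <= 0 || k2 <= 0) stop("R1 and k2 must be positive")
  if (BP < 0) stop("BP must be nonnegative")
  t <- fine_grid_min(frame_durations_s, dt_min)
  cref <- if (is.function(ref)) ref(t) else tac_to_fine(ref, t)
  ct <- srtm_curve(t, cref, R1, k2, BP)
  vals <- frame_average(t, ct, frame_durations_s)
  if (noise_sd0 > 0) {
    if (is.null(seed)) stop("seed required for noisy simulation")
    sd <- noise_sd0 / sqrt(frame_durations_s / 60)
    vals <- withr::with_seed(seed, vals + stats::rnorm(length(vals), 0, sd))
  }
  tac(frame_durations_s, vals)
}

#' Simulate a 4D dynamic phantom image with labelled regions
#'
#' Every voxel of a region follows the noiseless SRTM time course implied by
#' that region's kinetic parameters; independent Gaussian frame noise
#' (scaled as in [simulate_target_tac()]) is added per voxel.
#'
#' @param shape Integer vector of length 3, the image grid.
#' @param roi_masks Named list of logical 3D arrays (same shape), pairwise
#'   disjoint. Voxels not covered by any mask stay zero.
#' @param kinetic_map Named list, one entry per mask, each a list with
#'   elements `R1`, `k2`, `BP`.
#' @param ref Reference input as in [simulate_target_tac()].
#' @param frame_durations_s Frame schedule (seconds).
#' @param noise_sd0 Per-voxel noise scale; 0 for noiseless.
#' @param seed Integer seed; required when `noise_sd0 > 0`.
#' @param voxel_size_mm Isotropic voxel edge (mm), recorded as an attribute
#'   and in NIfTI headers on write.
#' @return List with `image` (4D array, x-y-z-frame), `masks`, and
#'   `frame_durations_s`.
#' @export
simulate_dynamic_image <- function(shape, roi_masks, kinetic_map, ref,
                                   frame_durations_s = frame_schedule_default(),
                                   noise_sd0 = 0, seed = NULL,
                                   voxel_size_mm = 0.7) {
  stopifnot(length(shape) == 3)
  cover <- array(0L, shape)
  for (m in roi_masks) {
    if (!identical(dim(m), as.integer(shape))) stop("mask shape mismatch")
    cover <- cover + (m != 0)
  }
  if (any(cover > 1L)) stop("roi_masks overlap")
  if (!setequal(names(roi_masks), names(kinetic_map)))
    stop("kinetic_map must name exactly the masks")
  nf <- length(frame_durations_s)
  img <- array(0, c(shape, nf))
  nvox <- prod(shape)
  flat <- matrix(img, nvox, nf)
  for (nm in names(roi_masks)) {
    kp <- kinetic_map[[nm]]
    curve <- simulate_target_tac(ref, kp$R1, kp$k2, kp$BP,
                                 frame_durations_s)$concentration_kBq_per_mL
    idx <- which(roi_masks[[nm]] != 0)
    flat[idx, ] <- matrix(curve, length(idx), nf, byrow = TRUE)
  }
  if (noise_sd0 > 0) {
    if (is.null(seed)) stop("seed required for noisy simulation")
    sd <- noise_sd0 / sqrt(frame_durations_s / 60)
    flat <- withr::with_seed(seed, {
      flat + matrix(stats::rnorm(nvox * nf, 0, rep(sd, each = nvox)), nvox, nf)
    })
  }
  img <- array(flat, c(shape, nf))
  attr(img, "voxel_size_mm") <- voxel_size_mm
  list(image = img, masks = roi_masks, frame_durations_s = frame_durations_s)
}
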
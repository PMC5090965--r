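#' Voxelwise Logan BPnd parametric image
#'
#' Applies [logan_ref_bpnd()] with a fixed `k2'` to every voxel time course
#' inside a mask of a 4D dynamic image. Voxels outside the mask, and voxels
#' whose fit fails, carry `NA`.
#'
#' @param dynamic 4D array (x-y-z-frame) or the `image` element of
#'   [simulate_dynamic_image()].
#' @param ref Reference [tac()].
#' @param k2prime Fixed reference efflux constant (1/min).
#' @param mask Logical/0-1 3D array; voxels to fit.
#' @param t_star Start of the Logan linear segment (minutes).
#' @param frame_durations_s Frame schedule matching the 4th dimension.
#' @return 3D array of BPnd with attribute `n_failed` (count of in-mask
#'   voxels whose fit failed).
#' @export
parametric_bpnd_image <- function(dynamic, ref, k2prime, mask,
                                  t_star = 30,
                                  frame_durations_s = frame_schedule_default()) {
  d <- dim(dynamic)
  if (length(d) != 4) stop("dynamic must be 4D")
  if (!identical(dim(mask), d[1:3])) stop("mask grid mismatch")
  nf <- d[4]
  if (nf != length(frame_durations_s)) stop("frame schedule mismatch")
  flat <- matrix(dynamic, prod(d[1:3]), nf)
  idx <- which(mask != 0)
  out <- rep(NA_real_, prod(d[1:3]))
  n_failed <- 0L
  for (v in idx) {
    fit <- tryCatch(
      suppressWarnings(logan_ref_bpnd(tac(frame_durations_s, flat[v, ]),
                                      ref, k2prime, t_star)),
      error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L else out[v] <- fit$bpnd
  }
  out <- array(out, d[1:3])
  attr(out, "n_failed") <- n_failed
  out
}

#' ROI percent change between two parametric images
#'
#' Mean BPnd over a mask in pre- and post-injection images and the percent
#' change `100 (post - pre) / pre`.
#'
#' @param pre_img,post_img 3D BPnd arrays on one grid.
#' @param roi_mask Logical/0-1 3D array, nonempty.
#' @return A list of class `roi_change`: `pre_bpnd`, `post_bpnd`,
#'   `percent_change`.
#' @export
roi_percent_change <- function(pre_img, post_img, roi_mask) {
  if (!identical(dim(pre_img), dim(post_img)))
    stop("images must share a grid")
  idx <- which(roi_mask != 0)
  if (length(idx) == 0) stop("empty ROI mask")
  pre <- mean(pre_img[idx], na.rm = TRUE)
  post <- mean(post_img[idx], na.rm = TRUE)
  structure(list(pre_bpnd = pre, post_bpnd = post,
                 percent_change = 100 * (post - pre) / pre),
            class = "roi_change")
}

#' Two-sample t-test on per-animal percent changes
#'
#' Companion test comparing percent-change values between two receptor
#' conditions (classical pooled-variance t, `df = n1 + n2 - 2`), with a
#' Shapiro-Wilk normality check on each sample.
#'
#' @param changes1,changes2 Numeric vectors of per-animal percent changes.
#' @return A list: `t`, `df`, `p`, and `shapiro_p` (length 2).
#' @export
percent_change_ttest <- function(changes1, changes2) {
  fit <- stats::t.test(changes1, changes2, var.equal = TRUE)
  sw <- c(stats::shapiro.test(changes1)$p.value,
          stats::shapiro.test(changes2)$p.value)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, shapiro_p = sw)
}
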
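#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis
#' in millimetres, converted to voxels. Boundaries are handled by kernel
#' renormalization (the smoothed image is divided by the smoothed
#' all-ones volume), so a constant image is unchanged everywhere.
#'
#' @param image 3D array.
#' @param fwhm_mm Full width at half maximum (mm). Nonpositive values return
#'   the input unchanged with a warning.
#' @param voxel_size_mm Voxel edge lengths (mm), length 1 (isotropic) or 3.
#' @return Smoothed 3D array.
#' @export
gaussian_smooth <- function(image, fwhm_mm, voxel_size_mm = 0.7) {
  if (fwhm_mm <= 0) {
    warning("fwhm <= 0; returning input unchanged")
    return(image)
  }
  vs <- rep(voxel_size_mm, length.out = 3)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vs
  conv_axis <- function(arr, axis) {
    s <- sigma_vox[axis]
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), d[axis])
    n <- d[axis]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    aperm(array(out, d[perm]), order(perm))
  }
  sm <- image
  ones <- array(1, dim(image))
  for (ax in 1:3) {
    sm <- conv_axis(sm, ax)
    ones <- conv_axis(ones, ax)
  }
  sm / ones
}

#' Voxelwise GLM of BPnd against a behavioral score
#'
#' Per in-mask voxel, ordinary least squares of BPnd on the design
#' (intercept, behavioral score, and optionally the global-mean covariate),
#' returning the t-statistic map for the score coefficient with
#' `df = n - p`. Perfect fits (zero residual variance) are capped at
#' `t_cap` and flagged.
#'
#' @param images List of 3D arrays, or a 4D array with scans as the 4th
#'   dimension.
#' @param design A data frame with column `score` (one row per scan) and
#'   optionally `global_mean`. When `global_mean` is `"auto"` (passed via
#'   `global_mean = TRUE` below) it is computed as each scan's mean over the
#'   mask.
#' @param mask Logical/0-1 3D array.
#' @param global_mean Include the global-mean covariate: `TRUE` computes it
#'   from the mask, `FALSE` omits it (a 2-column design, `df = n - 2`), or a
#'   numeric vector supplies it directly.
#' @param t_cap Cap for infinite t values (default 1e6).
#' @return A list of class `voxel_glm`: `t_map` (3D, `NA` outside mask),
#'   `df`, `beta` (matrix p x voxels-in-mask), `mask`, `design_matrix`,
#'   `n_capped`.
#' @export
fit_voxel_glm <- function(images, design, mask, global_mean = TRUE,
                          t_cap = 1e6) {
  if (is.list(images)) {
    n <- length(images)
    Y <- t(vapply(images, function(im) as.numeric(im)[which(mask != 0)],
                  numeric(sum(mask != 0))))
  } else {
    d <- dim(images)
    n <- d[4]
    flat <- matrix(images, prod(d[1:3]), n)
    Y <- t(flat[which(mask != 0), , drop = FALSE])
  }
  score <- design$score
  if (length(score) != n) stop("design must have one row per scan")
  if (stats::sd(score) == 0) stop("score regressor is constant")
  X <- cbind(intercept = rep(1, n), score = score)
  if (isTRUE(global_mean)) {
    X <- cbind(X, global_mean = rowMeans(Y))
  } else if (is.numeric(global_mean)) {
    X <- cbind(X, global_mean = global_mean)
  }
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient design: collinear columns among ",
         paste(colnames(X), collapse = ", "))
  if (n < p + 1) stop("need at least p + 1 scans")
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi["score", "score"])
  tval <- beta["score", ] / se
  n_capped <- sum(!is.finite(tval) | abs(tval) > t_cap)
  tval[!is.finite(tval)] <- sign(beta["score", ][!is.finite(tval)]) * t_cap
  tval <- pmin(pmax(tval, -t_cap), t_cap)
  t_map <- array(NA_real_, dim(mask))
  t_map[which(mask != 0)] <- tval
  structure(list(t_map = t_map, df = df, beta = beta, mask = mask,
                 design_matrix = X, n_capped = n_capped),
            class = "voxel_glm")
}

#' Threshold a t-map and report clusters
#'
#' Two-sided voxel p-values from the t distribution; suprathreshold voxels
#' of the requested sign are grouped into connected components
#' (26-connectivity by default) and summarised.
#'
#' @param result A [fit_voxel_glm()] result.
#' @param p_thresh Uncorrected voxel p threshold (default 0.05).
#' @param sign `"both"`, `"positive"`, or `"negative"`.
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return A tibble: `cluster_id`, `n_voxels`, `peak_t`, `peak_x`, `peak_y`,
#'   `peak_z` (1-based voxel indices). Empty when nothing survives.
#' @export
threshold_and_cluster <- function(result, p_thresh = 0.05,
                                  sign = c("both", "positive", "negative"),
                                  connectivity = 26) {
  sign <- match.arg(sign)
  stopifnot(connectivity %in% c(6, 26))
  tm <- result$t_map
  pv <- 2 * stats::pt(-abs(tm), result$df)
  supra <- !is.na(tm) & pv < p_thresh
  if (sign == "positive") supra <- supra & tm > 0
  if (sign == "negative") supra <- supra & tm < 0
  idx <- which(supra)
  if (length(idx) == 0)
    return(tibble::tibble(cluster_id = integer(), n_voxels = integer(),
                          peak_t = numeric(), peak_x = integer(),
                          peak_y = integer(), peak_z = integer()))
  d <- dim(tm)
  coords <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  in_set <- array(0L, d)
  in_set[idx] <- seq_along(idx)
  labels <- integer(length(idx))
  cur <- 0L
  for (start in seq_along(idx)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      xyz <- coords[v, ]
      nb <- sweep(offs, 2, xyz, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      ids <- in_set[cbind(nb[, 1], nb[, 2], nb[, 3])]
      ids <- ids[ids != 0L]
      new <- ids[labels[ids] == 0L]
      if (length(new) > 0) {
        labels[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  rows <- lapply(seq_len(cur), function(cid) {
    members <- which(labels == cid)
    tv <- tm[idx[members]]
    pk <- members[which.max(abs(tv))]
    tibble::tibble(cluster_id = cid, n_voxels = length(members),
                   peak_t = tm[idx[pk]],
                   peak_x = coords[pk, 1], peak_y = coords[pk, 2],
                   peak_z = coords[pk, 3])
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$n_voxels), ]
}

#' Residualized, standardized scatter values for a peak voxel or ROI
#'
#' Partial-regression values: the BPnd values and the behavioral score are
#' each residualized on the remaining design columns (intercept and, when
#' present, the global-mean covariate) and z-scored. The OLS slope between
#' the returned pairs relates to the voxel GLM t-statistic for the score by
#' the partial-regression identity `t = r sqrt(df / (1 - r^2))`, where `r`
#' is the correlation of the residualized pairs.
#'
#' @param values Numeric vector of BPnd values per scan (peak voxel or ROI
#'   mean).
#' @param design Data frame with `score` and optionally `global_mean`.
#' @return A tibble: `bpnd_resid`, `score_resid` (both z-scored).
#' @export
residualized_scatter <- function(values, design) {
  n <- length(values)
  Z <- cbind(intercept = rep(1, n))
  if (!is.null(design$global_mean)) Z <- cbind(Z, design$global_mean)
  resid_on <- function(y) stats::lsfit(Z, y, intercept = FALSE)$residuals
  rv <- resid_on(values)
  rs <- resid_on(design$score)
  if (stats::sd(rv) == 0 || stats::sd(rs) == 0)
    stop("zero-variance residuals")
  tibble::tibble(bpnd_resid = as.numeric(scale(rv)),
                 score_resid = as.numeric(scale(rs)))
}
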
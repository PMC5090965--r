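test_that("Gaussian smoothing preserves constants and handles fwhm <= 0", {
  img <- array(3.7, c(8, 8, 6))
  sm <- gaussian_smooth(img, 2, voxel_size_mm = 0.7)
  expect_equal(sm, img, tolerance = 1e-12)
  expect_warning(out <- gaussian_smooth(img, 0), "unchanged")
  expect_identical(out, img)
})

test_that("smoothed delta matches the analytic Gaussian profile", {
  img <- array(0, c(25, 25, 25))
  img[13, 13, 13] <- 1
  vs <- 0.5
  sm <- gaussian_smooth(img, 2, voxel_size_mm = vs)
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  prof <- sm[, 13, 13]
  x <- (seq_len(25) - 13) * vs
  k1 <- dnorm(x, sd = sigma); k1 <- k1 / sum(k1)
  # separable kernel: central axis profile proportional to the 1D kernel
  expected <- k1 * sm[13, 13, 13] / max(k1)
  interior <- 9:17                    # kernel support fully inside the grid
  expect_lt(max(abs(prof[interior] - expected[interior])),
            0.01 * max(expected))
})

test_that("smoothing is linear", {
  withr::with_seed(2, {
    a <- array(rnorm(120), c(6, 5, 4))
    b <- array(rnorm(120), c(6, 5, 4))
    s <- function(x) gaussian_smooth(x, 1.5, 0.7)
    expect_equal(s(2 * a + 3 * b), 2 * s(a) + 3 * s(b), tolerance = 1e-12)
  })
})

make_stack <- function(n, shape, mask, signal = NULL, seed = 1) {
  withr::with_seed(seed, {
    score <- rnorm(n)
    imgs <- array(rnorm(prod(shape) * n), c(shape, n))
    if (!is.null(signal)) {
      for (i in seq_len(n)) imgs[, , , i] <- imgs[, , , i] + signal * score[i]
    }
    list(images = imgs, score = score)
  })
}

test_that("GLM degrees of freedom follow the design size", {
  shape <- c(6, 6, 4)
  mask <- array(TRUE, shape)
  st <- make_stack(20, shape, mask)
  r3 <- fit_voxel_glm(st$images, data.frame(score = st$score), mask,
                      global_mean = TRUE)
  expect_equal(r3$df, 17)
  r2 <- fit_voxel_glm(st$images, data.frame(score = st$score), mask,
                      global_mean = FALSE)
  expect_equal(r2$df, 18)
  expect_true(all(is.na(r3$t_map[!mask])))
  expect_error(fit_voxel_glm(st$images,
                             data.frame(score = rep(1, 20)), mask),
               "constant")
})

test_that("a perfect linear voxel is capped and flagged", {
  shape <- c(3, 3, 2)
  mask <- array(TRUE, shape)
  n <- 10
  score <- seq_len(n)
  imgs <- array(rnorm(prod(shape) * n, sd = 0.1), c(shape, n))
  for (i in seq_len(n)) imgs[1, 1, 1, i] <- 2 * score[i]
  r <- fit_voxel_glm(imgs, data.frame(score = score), mask,
                     global_mean = FALSE)
  expect_equal(r$t_map[1, 1, 1], 1e6)
  expect_gte(r$n_capped, 1)
})

test_that("rank-deficient designs are rejected with the column names", {
  shape <- c(3, 3, 2)
  mask <- array(TRUE, shape)
  st <- make_stack(10, shape, mask)
  expect_error(fit_voxel_glm(st$images, data.frame(score = st$score), mask,
                             global_mean = st$score),
               "collinear")
})

test_that("t statistics are invariant to affine rescaling of the covariate", {
  shape <- c(4, 4, 3)
  mask <- array(TRUE, shape)
  st <- make_stack(12, shape, mask, seed = 3)
  gm <- withr::with_seed(4, rnorm(12, 10, 1))
  a <- fit_voxel_glm(st$images, data.frame(score = st$score), mask,
                     global_mean = gm)
  b <- fit_voxel_glm(st$images, data.frame(score = st$score), mask,
                     global_mean = 5 * gm - 2)
  expect_equal(a$t_map, b$t_map, tolerance = 1e-9)
})

test_that("thresholding and clustering find a planted blob", {
  shape <- c(8, 8, 6)
  mask <- array(TRUE, shape)
  tm <- array(0, shape)
  tm[3:4, 3:4, 2:3] <- 6
  tm[3, 3, 2] <- 8                     # peak
  res <- structure(list(t_map = tm, df = 17, mask = mask),
                   class = "voxel_glm")
  tab <- threshold_and_cluster(res, 0.05, "positive")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_voxels, 8)
  expect_equal(tab$peak_t, 8)
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z), c(3, 3, 2))
  # sub-threshold map -> empty table
  res$t_map <- tm * 0.1
  expect_equal(nrow(threshold_and_cluster(res, 0.05)), 0)
})

test_that("corner-touching blobs merge under 26- but not 6-connectivity", {
  shape <- c(6, 6, 4)
  tm <- array(0, shape)
  tm[2:3, 2:3, 2] <- 7
  tm[4:5, 4:5, 3] <- 7                 # touches (3,3,2) only at a corner
  res <- structure(list(t_map = tm, df = 17), class = "voxel_glm")
  t26 <- threshold_and_cluster(res, 0.05, "positive", connectivity = 26)
  t6 <- threshold_and_cluster(res, 0.05, "positive", connectivity = 6)
  expect_equal(nrow(t26), 1)
  expect_equal(nrow(t6), 2)
  # cluster voxels are a subset of the suprathreshold set
  expect_equal(sum(t26$n_voxels), sum(tm != 0))
})

test_that("residualized scatter reproduces the GLM t at a voxel", {
  n <- 20
  withr::with_seed(6, {
    gm <- rnorm(n, 10, 1)
    score <- rnorm(n) + 0.3 * gm
    vals <- 0.4 * score + 0.2 * gm + rnorm(n)
  })
  shape <- c(2, 2, 1)
  mask <- array(TRUE, shape)
  imgs <- array(rnorm(prod(shape) * n), c(shape, n))
  imgs[1, 1, 1, ] <- vals
  glm <- fit_voxel_glm(imgs, data.frame(score = score), mask,
                       global_mean = gm)
  sc <- residualized_scatter(vals, data.frame(score = score,
                                              global_mean = gm))
  r <- cor(sc$bpnd_resid, sc$score_resid)
  t_from_r <- r * sqrt(glm$df / (1 - r^2))
  expect_equal(t_from_r, glm$t_map[1, 1, 1], tolerance = 1e-10)
  # no covariate: returns z-scored originals
  sc0 <- residualized_scatter(vals, data.frame(score = score))
  expect_equal(sc0$bpnd_resid, as.numeric(scale(vals)))
  expect_equal(sc0$score_resid, as.numeric(scale(score)))
})

test_that("orthogonal covariate leaves the score residuals proportional", {
  n <- 16
  score <- rep(c(-1, 1), 8)
  gm <- rep(c(1, 1, -1, -1), 4)        # orthogonal to score and intercept
  vals <- withr::with_seed(10, rnorm(n))
  sc <- residualized_scatter(vals, data.frame(score = score,
                                              global_mean = gm))
  expect_equal(sc$score_resid, as.numeric(scale(score)), tolerance = 1e-12)
})
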
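#' Recursive change-point detection on a binary learning record
#'
#' Within a segment, the candidate change point is the trial at which the
#' cumulative-correct record deviates most from the straight line joining
#' the segment endpoints. It is retained when a two-proportion test between
#' the two sub-segments rejects; retained points split the segment and the
#' search recurses on both halves.
#'
#' Because the candidate is selected as the maximal deviation, a raw test at
#' `alpha` would not control the false-alarm rate; by default the
#' two-proportion p-value is Bonferroni-corrected for the number of
#' candidate split points in the segment (a union bound on the maximal
#' statistic), which keeps the family-wise false-alarm rate on a stationary
#' sequence at or below `alpha`. `correction = "none"` gives the raw
#' per-point test.
#'
#' @param outcomes Binary vector (1 = correct) of length >= 2.
#' @param alpha Retention significance level (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param test `"binomial"` (Fisher's exact test, used for segments up to
#'   `exact_max` trials) or `"chisq"` (two-proportion chi-square). The
#'   default `"auto"` picks the exact test for small segments.
#' @param exact_max Segment size up to which the exact test is used.
#' @return Sorted integer vector of retained change points (a change point
#'   `t` means the process changed between trials `t` and `t + 1`); empty
#'   when none is retained.
#' @export
find_change_points <- function(outcomes, alpha = 0.05,
                               correction = c("bonferroni", "none"),
                               test = c("auto", "binomial", "chisq"),
                               exact_max = 200) {
  correction <- match.arg(correction)
  test <- match.arg(test)
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary (0/1)")
  n <- length(outcomes)
  if (n < 2) stop("need >= 2 trials")
  cum <- cumsum(outcomes)
  found <- integer(0)

  split_p <- function(x1, n1, x2, n2) {
    use_exact <- test == "binomial" ||
      (test == "auto" && (n1 + n2) <= exact_max)
    if (use_exact) {
      m <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2)
      stats::fisher.test(m)$p.value
    } else {
      suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2))$p.value)
    }
  }

  recurse <- function(a, b) {
    if (b - a < 1) return()
    s_a <- if (a > 1) cum[a - 1] else 0
    idx <- a:(b - 1)
    line <- s_a + (cum[b] - s_a) * (idx - (a - 1)) / (b - (a - 1))
    dev <- abs(cum[idx] - line)
    t <- idx[which.max(dev)]
    x1 <- cum[t] - s_a; n1 <- t - a + 1
    x2 <- cum[b] - cum[t]; n2 <- b - t
    p <- split_p(x1, n1, x2, n2)
    if (correction == "bonferroni") p <- min(1, p * length(idx))
    if (is.finite(p) && p < alpha) {
      found <<- c(found, t)
      recurse(a, t)
      recurse(t + 1, b)
    }
  }
  recurse(1, n)
  sort(found)
}

#' Segment a learning record into bias, chance and improvement stages
#'
#' The bias/perseveration stage runs from the first trial to the last trial
#' at which the running (cumulative from trial 1) correct ratio is
#' significantly below chance by a one-sided exact binomial test at
#' `alpha_bias`; it is empty when no trial qualifies. The improvement stage
#' starts after the last segment boundary (a change point, or the phase
#' start when none exists) whose following segment's correct rate is
#' significantly above chance (one-sided binomial at `alpha_improve`), and
#' runs to the final trial. The chance stage is the remainder between them.
#' The three intervals always partition trials `1..length(outcomes)`.
#'
#' @param outcomes Binary correct/incorrect vector, trials 1..criterion
#'   trial.
#' @param change_points Output of [find_change_points()] on `outcomes`.
#' @param alpha_bias Significance for the below-chance running ratio
#'   (default 0.01).
#' @param alpha_improve Significance for the above-chance segment test
#'   (default 0.05).
#' @return A list of class `stage_segmentation`: `bias_interval`,
#'   `chance_interval`, `improvement_interval` (each `c(first, last)` or
#'   `NULL`), and `change_points`.
#' @export
classify_stages <- function(outcomes, change_points, alpha_bias = 0.01,
                            alpha_improve = 0.05) {
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary (0/1)")
  n <- length(outcomes)
  cum <- cumsum(outcomes)
  t_all <- seq_len(n)
  # one-sided lower-tail exact binomial: P(X <= x) under p = 0.5
  p_below <- stats::pbinom(cum, t_all, 0.5)
  bias_end <- if (any(p_below < alpha_bias)) max(which(p_below < alpha_bias)) else 0L

  bounds <- c(0L, change_points)
  seg_ends <- c(change_points, n)
  improve_start <- NA_integer_
  for (i in rev(seq_along(bounds))) {
    a <- bounds[i] + 1L; b <- seg_ends[i]
    x <- cum[b] - (if (a > 1) cum[a - 1] else 0)
    p <- stats::pbinom(x - 1, b - a + 1L, 0.5, lower.tail = FALSE)
    if (p < alpha_improve) {
      improve_start <- a
      break
    }
  }
  if (is.na(improve_start)) improve_start <- n + 1L
  if (improve_start <= bias_end) improve_start <- bias_end + 1L

  iv <- function(a, b) if (a > b) NULL else c(a, b)
  seg <- structure(list(
    bias_interval = iv(1L, bias_end),
    chance_interval = iv(bias_end + 1L, improve_start - 1L),
    improvement_interval = iv(improve_start, n),
    change_points = change_points), class = "stage_segmentation")
  # coverage invariant: stages partition 1..n
  covered <- sum(vapply(seg[1:3], function(x)
    if (is.null(x)) 0L else x[2] - x[1] + 1L, integer(1)))
  if (covered != n) stop("stage intervals fail to cover the record")
  seg
}
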
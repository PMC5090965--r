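#' Parameters of the synthetic choice agent
#'
#' The generative behavioral model is a two-armed Q-learning agent with a
#' softmax decision rule. Per trial the chosen stimulus' value is updated
#' `Q <- (1 - alpha) Q + alpha R` with `R` in `{0, 1}`; the unchosen value is
#' untouched. The choice logit is
#' `beta (Q_A - Q_B)` plus additive terms for a left-side bias, repeating the
#' previously chosen stimulus, and repeating the previously touched side; a
#' lapse probability mixes in uniform random choice. An abort hazard models
#' a >= 15-minute response pause that terminates the session. Response times
#' are log-normal with median `rt_location` seconds and log-scale `rt_scale`.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Softmax inverse temperature, >= 0.
#' @param side_bias Additive preference for the left side (logit units).
#' @param stim_stickiness Additive bonus for repeating the previous stimulus
#'   choice (logit units).
#' @param side_stickiness Additive bonus for repeating the previous side
#'   (logit units).
#' @param lapse Probability of a uniform-random choice, in `[0, 1]`.
#' @param abort_hazard Per-trial probability of the session-ending pause,
#'   in `[0, 1]`.
#' @param rt_location Median response time (seconds, > 0).
#' @param rt_scale Log-normal scale of response times, >= 0.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.25, beta = 5, side_bias = 0.2,
                         stim_stickiness = 0.2, side_stickiness = 0.2,
                         lapse = 0.05, abort_hazard = 2e-4,
                         rt_location = 1.5, rt_scale = 0.4) {
  in01 <- function(x) is.finite(x) && x >= 0 && x <= 1
  if (!in01(alpha)) stop("alpha must be in [0, 1]")
  if (!in01(lapse)) stop("lapse must be in [0, 1]")
  if (!in01(abort_hazard)) stop("abort_hazard must be in [0, 1]")
  if (beta < 0) stop("beta must be nonnegative")
  if (rt_scale < 0) stop("rt_scale must be nonnegative")
  if (rt_location <= 0) stop("rt_location must be positive")
  structure(list(alpha = alpha, beta = beta, side_bias = side_bias,
                 stim_stickiness = stim_stickiness,
                 side_stickiness = side_stickiness, lapse = lapse,
                 abort_hazard = abort_hazard, rt_location = rt_location,
                 rt_scale = rt_scale),
            class = "agent_params")
}

#' Preset agent parameter sets for the study groups
#'
#' Pre-injection animals of all groups share one parameter set. Post
#' injection, the D2R-knockdown preset has a lower inverse temperature,
#' higher abort hazard, longer response times and a higher lapse rate; the
#' D1R-knockdown and control presets are unchanged from baseline.
#'
#' @param group One of `"control"`, `"d1r_kd"`, `"d2r_kd"`.
#' @param period `"pre"` or `"post"`.
#' @return An [agent_params()] object.
#' @export
agent_preset <- function(group = c("control", "d1r_kd", "d2r_kd"),
                         period = c("pre", "post")) {
  group <- match.arg(group)
  period <- match.arg(period)
  if (period == "post" && group == "d2r_kd")
    agent_params(beta = 3, lapse = 0.08, abort_hazard = 1.5e-3,
                 rt_location = 2.5)
  else
    agent_params()
}

# Counterbalanced left/right placement: the rewarded-map's first stimulus is
# on the left in exactly floor(n/2) trials (ceiling for the other), order
# shuffled. Returns a logical vector: TRUE when stimulus 1 is on the left.
counterbalanced_sides <- function(n) {
  sides <- rep(c(TRUE, FALSE), length.out = n)
  sample(sides)
}

#' Simulate one session of the two-choice discrimination task
#'
#' Runs the Q-learning/softmax agent for up to `n_trials` trials of a
#' criterion-style session. Left/right stimulus placement is pseudorandom and
#' counterbalanced within the session. An abort draw before any trial
#' truncates the session; the aborting trial is recorded as a marker row with
#' missing choice fields, `aborted_session = 1`, and a 900-second intertrial
#' gap.
#'
#' @param params An [agent_params()] object.
#' @param reward_map Named 0/1 vector over exactly two stimuli; 1 marks the
#'   rewarded stimulus.
#' @param n_trials Number of trials in a full session (>= 1).
#' @param q_init Named initial Q-values for the two stimuli (defaults 0.5).
#' @param seed Integer seed; identical seeds give identical records.
#' @return A tibble with one row per trial (columns `trial_index`,
#'   `left_stim`, `right_stim`, `chosen_stim`, `chosen_side`, `rewarded`,
#'   `response_time_s`, `aborted_session`, `intertrial_s`) and attributes
#'   `aborted` (logical) and `q_final` (named vector).
#' @export
simulate_agent_session <- function(params, reward_map, n_trials,
                                   q_init = NULL, seed = 1) {
  stopifnot(inherits(params, "agent_params"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  stims <- names(reward_map)
  if (length(stims) != 2 || is.null(stims) || anyNA(reward_map))
    stop("reward_map must cover exactly two named stimuli")
  if (is.null(q_init)) q_init <- stats::setNames(c(0.5, 0.5), stims)
  if (!setequal(names(q_init), stims)) stop("q_init must name both stimuli")
  q <- q_init[stims]

  withr::with_seed(seed, {
    s1_left <- counterbalanced_sides(n_trials)
    rows <- vector("list", n_trials)
    prev_stim <- NA_character_
    prev_side <- NA_character_
    aborted <- FALSE
    for (i in seq_len(n_trials)) {
      if (stats::runif(1) < params$abort_hazard) {
        rows[[i]] <- tibble::tibble(
          trial_index = i,
          left_stim = if (s1_left[i]) stims[1] else stims[2],
          right_stim = if (s1_left[i]) stims[2] else stims[1],
          chosen_stim = NA_character_, chosen_side = NA_character_,
          rewarded = NA_integer_, response_time_s = NA_real_,
          aborted_session = 1L, intertrial_s = 900)
        aborted <- TRUE
        rows <- rows[seq_len(i)]
        break
      }
      left <- if (s1_left[i]) stims[1] else stims[2]
      right <- if (s1_left[i]) stims[2] else stims[1]
      # logit of choosing stimulus 1 over stimulus 2
      du <- params$beta * (q[[stims[1]]] - q[[stims[2]]])
      du <- du + params$side_bias * (if (s1_left[i]) 1 else -1)
      if (!is.na(prev_stim))
        du <- du + params$stim_stickiness *
          (if (prev_stim == stims[1]) 1 else -1)
      if (!is.na(prev_side)) {
        side_of_s1 <- if (s1_left[i]) "left" else "right"
        du <- du + params$side_stickiness *
          (if (side_of_s1 == prev_side) 1 else -1)
      }
      p1 <- (1 - params$lapse) * stats::plogis(du) + params$lapse / 2
      choose1 <- stats::runif(1) < p1
      chosen <- if (choose1) stims[1] else stims[2]
      side <- if (chosen == left) "left" else "right"
      r <- as.integer(reward_map[[chosen]])
      q[[chosen]] <- (1 - params$alpha) * q[[chosen]] + params$alpha * r
      rt <- stats::rlnorm(1, meanlog = log(params$rt_location),
                          sdlog = params$rt_scale)
      rows[[i]] <- tibble::tibble(
        trial_index = i, left_stim = left, right_stim = right,
        chosen_stim = chosen, chosen_side = side, rewarded = r,
        response_time_s = rt, aborted_session = 0L,
        intertrial_s = if (r == 1) 3 else 5)
      prev_stim <- chosen
      prev_side <- side
    }
    out <- dplyr::bind_rows(rows)
    if (aborted) out$aborted_session <- 1L
    attr(out, "aborted") <- aborted
    attr(out, "q_final") <- q
    out
  })
}
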
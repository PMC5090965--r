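# compact constructor for hand-built single-phase logs
mklog <- function(chosen, rewarded, side = NULL, session = NULL,
                  left = NULL) {
  n <- length(chosen)
  if (is.null(session)) session <- rep(1L, n)
  if (is.null(side)) side <- rep("left", n)
  if (is.null(left)) left <- chosen   # chosen stimulus on its chosen side
  right <- ifelse(left == "A", "B", "A")
  ti <- stats::ave(seq_len(n), session, FUN = seq_along)
  tibble::tibble(
    animal_id = "X", group = "g", phase_label = "N1", task_kind = "novel",
    session_index = session, trial_index = as.integer(ti),
    left_stim = left, right_stim = right, chosen_stim = chosen,
    chosen_side = side, rewarded = as.integer(rewarded),
    response_time_s = 1, aborted_session = 0L, intertrial_s = 3)
}

test_that("errors to criterion counts through the criterion session", {
  all_correct <- mklog(rep("A", 100), rep(1, 100))
  expect_equal(as.integer(errors_to_criterion(all_correct)), 0)
  # session 1: 85/100, session 2: 92/100 -> 15 + 8 = 23
  s1 <- c(rep(1, 85), rep(0, 15))
  s2 <- c(rep(1, 92), rep(0, 8))
  log <- mklog(rep("A", 200), c(s1, s2), session = rep(1:2, each = 100))
  e <- errors_to_criterion(log)
  expect_equal(as.integer(e), 23)
  expect_true(attr(e, "attained"))
  expect_error(errors_to_criterion(log[0, ]), "empty")
})

test_that("non-attainment is flagged and totals all errors", {
  log <- mklog(rep("A", 100), rep(c(1, 0), 50))
  e <- errors_to_criterion(log)
  expect_equal(as.integer(e), 50)
  expect_false(attr(e, "attained"))
})

test_that("errors to criterion is invariant to stimulus relabeling", {
  log <- make_random_log(5, n_sessions = 2, session_size = 30)
  swapped <- log
  swap <- function(x) ifelse(x == "Pa", "Pb", "Pa")
  swapped$chosen_stim <- swap(log$chosen_stim)
  swapped$left_stim <- swap(log$left_stim)
  swapped$right_stim <- swap(log$right_stim)
  expect_equal(as.integer(errors_to_criterion(log, 0.9, 30)),
               as.integer(errors_to_criterion(swapped, 0.9, 30)))
})

test_that("win-stay enumeration on a constructed sequence", {
  # (reward,A),(A),(reward,A),(B): 2 qualifying pairs, 1 stay
  log <- mklog(c("A", "A", "A", "B"), c(1, 0, 1, 0))
  expect_equal(win_stay(log), 1 / 2)
  # an agent that always repeats a rewarded stimulus
  log2 <- mklog(rep("A", 10), rep(1, 10))
  expect_equal(win_stay(log2), 1)
})

test_that("undefined pair statistics return NA, not zero", {
  log <- mklog("A", 1)
  expect_true(is.na(win_stay(log)))
  expect_true(is.na(lose_shift(log)))
  expect_true(is.na(side_stickiness(log)))
  # all wins -> lose_shift undefined
  log2 <- mklog(c("A", "A"), c(1, 1))
  expect_true(is.na(lose_shift(log2)))
})

test_that("pairs never span session boundaries", {
  log <- mklog(c("A", "A"), c(1, 1), session = c(1L, 2L))
  expect_true(is.na(win_stay(log)))
})

test_that("side stickiness trivial cases", {
  alt <- mklog(rep("A", 10), rep(1, 10),
               side = rep(c("left", "right"), 5),
               left = rep(c("A", "B"), 5))
  expect_equal(side_stickiness(alt, "simple"), 0)
  always_left <- mklog(rep(c("A", "B"), 5), rep(c(1, 0), 5),
                       side = rep("left", 10),
                       left = rep(c("A", "B"), 5))
  expect_equal(side_stickiness(always_left, "simple"), 1)
})

test_that("behavioral statistics match brute-force enumeration on random logs", {
  for (seed in 1:50) {
    log <- make_random_log(seed, n_sessions = sample(1:3, 1),
                           session_size = 20)
    expect_equal(win_stay(log), oracle_win_stay(log))
    expect_equal(lose_shift(log), oracle_lose_shift(log))
    expect_equal(side_stickiness(log, "simple"), oracle_side_stick_simple(log))
    expect_equal(side_stickiness(log, "reward_associated"),
                 oracle_side_stick_reward(log))
    expect_equal(as.integer(errors_to_criterion(log, 0.9, 20)),
                 as.integer(oracle_errors_to_criterion(log, 0.9, 20)))
  }
})

test_that("random chooser has win-stay near one half", {
  log <- withr::with_seed(99, {
    ch <- sample(c("A", "B"), 10000, replace = TRUE)
    mklog(ch, as.integer(ch == "A"))
  })
  expect_lt(abs(win_stay(log) - 0.5), 3 * sqrt(0.25 / sum(log$rewarded)))
  # complement identity: win-stay + win-shift = 1 over rewarded-previous pairs
  prev_win <- log$rewarded[-nrow(log)] == 1
  win_shift <- mean((log$chosen_stim[-1] !=
                       log$chosen_stim[-nrow(log)])[prev_win])
  expect_equal(win_stay(log) + win_shift, 1)
})

test_that("response-time pools and Mann-Whitney behave as expected", {
  mkph <- function(labels, rt) {
    dplyr::bind_rows(lapply(labels, function(l) {
      x <- mklog(rep("A", 25), rep(1, 25))
      x$phase_label <- l
      x$response_time_s <- rt
      x
    }))
  }
  pre <- mkph(c(paste0("N", 7:10), paste0("R", 7:10)), 1:25)
  post <- mkph(c(paste0("N", 7:10), paste0("R", 7:10)), 26:50)
  r <- response_time_comparison(pre, post)
  expect_equal(unname(r$n), c(160, 160))
  ident <- response_time_comparison(pre, pre)
  expect_equal(unname(ident$U), 160 * 160 / 2)
  # U + U' = n1 n2
  r2 <- response_time_comparison(post, pre)
  expect_equal(unname(r$U) + unname(r2$U), 160 * 160)
})

test_that("tiny pools give the exact enumeration p-value", {
  mk1 <- function(rt) {
    x <- mklog(rep("A", length(rt)), rep(1, length(rt)))
    x$response_time_s <- rt
    x
  }
  r <- suppressWarnings(response_time_comparison(mk1(1:3), mk1(4:6)))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)
})

test_that("aborted sessions count and square root", {
  log <- make_random_log(3)
  expect_equal(count_aborted_sessions(log)$n, 0)
  log$aborted_session[log$session_index == 2] <- 1L
  expect_equal(count_aborted_sessions(log)$n, 1)
})

test_that("normalized locomotor activity ratio", {
  # constructed 6-day series (Mon-Sat): daily totals 100 pre, 200 post
  mkseries <- function(daily_total) {
    ts <- as.POSIXct(as.Date("2016-01-04"), tz = "UTC") +
      30 * (seq_len(6 * 2880) - 1)
    activity_series(ts, rep(daily_total / 2880, 6 * 2880))
  }
  pre <- mkseries(100)
  post <- mkseries(200)
  expect_equal(normalized_locomotor_activity(pre, pre, n_days = 3), 1.0)
  expect_equal(normalized_locomotor_activity(pre, post, n_days = 3), 2.0)
  zero <- mkseries(0)
  expect_true(is.na(normalized_locomotor_activity(zero, post, n_days = 3)))
})

test_that("summarize_behavior returns one row per animal-phase with stats", {
  d <- task_design(data.frame(
    label = c("N1", "R1"), task_kind = c("novel", "reversal"),
    stimulus_pair = 1, period = "pre"), trials_per_session = 50,
    max_sessions_per_phase = 10)
  log <- simulate_task_battery(d, agent_params(abort_hazard = 0),
                               agent_params(abort_hazard = 0), seed = 8)
  sm <- summarize_behavior(log, criterion = 0.9, session_size = 50)
  expect_equal(nrow(sm), 2)
  probs <- unlist(sm[, c("win_stay", "lose_shift", "side_stick_simple",
                         "side_stick_reward")])
  expect_true(all(probs >= 0 & probs <= 1, na.rm = TRUE))
  expect_equal(sm$sqrt_errors, sqrt(sm$errors_to_criterion))
  expect_equal(sm$bias_trials + sm$chance_trials + sm$improvement_trials,
               vapply(split(log, log$phase_label), function(tr)
                 sum(!is.na(tr$rewarded)), integer(1))[sm$phase_label],
               ignore_attr = TRUE)
})
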
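#' Errors to criterion for one phase
#'
#' Sessions are the unit of evaluation: the criterion is attained at the
#' first complete (non-aborted, full-length) session whose fraction of
#' rewarded trials is at least `criterion`. The return value counts every
#' unrewarded trial in all sessions up to and including the criterion
#' session. Aborted sessions contribute their completed trials. If no
#' session attains the criterion, the total error count is returned with
#' attribute `attained = FALSE`.
#'
#' @param trials Trial records of a single phase (must contain
#'   `session_index`, `rewarded`, and `aborted_session`).
#' @param criterion Fraction correct required (default 0.9).
#' @param session_size Trials in a full session (default 100).
#' @return Integer error count with attribute `attained`.
#' @export
errors_to_criterion <- function(trials, criterion = 0.9, session_size = 100) {
  if (nrow(trials) == 0) stop("empty phase")
  sess_ids <- sort(unique(trials$session_index))
  errors <- 0L
  for (s in sess_ids) {
    tr <- trials[trials$session_index == s, ]
    done <- tr[!is.na(tr$rewarded), ]
    errors <- errors + sum(done$rewarded == 0)
    complete <- nrow(done) == session_size && !any(tr$aborted_session == 1)
    if (complete && mean(done$rewarded) >= criterion) {
      attr(errors, "attained") <- TRUE
      return(errors)
    }
  }
  attr(errors, "attained") <- FALSE
  errors
}

#' Count aborted sessions
#'
#' A session counts as aborted when any of its rows carries
#' `aborted_session = 1` (a >= 15-minute response pause ended the day).
#'
#' @param trials Trial records (any number of animals' phases for one
#'   period); sessions identified by `phase_label` x `session_index` (and
#'   `animal_id` if present).
#' @return A list: `n` (count) and `sqrt_n` (its square-root transform, used
#'   for group statistics to stabilise variance).
#' @export
count_aborted_sessions <- function(trials) {
  if (nrow(trials) == 0) return(list(n = 0L, sqrt_n = 0))
  keys <- c("animal_id", "phase_label", "session_index")
  keys <- intersect(keys, names(trials))
  ab <- unique(trials[trials$aborted_session == 1, keys, drop = FALSE])
  list(n = nrow(ab), sqrt_n = sqrt(nrow(ab)))
}

# Consecutive-trial pairs within a session; never crosses session (or phase,
# or animal) boundaries. Abort marker rows (NA choices) break the chain.
consecutive_pairs <- function(trials) {
  keys <- intersect(c("animal_id", "phase_label", "session_index"),
                    names(trials))
  if (length(keys) > 0) {
    grp <- do.call(paste, c(trials[keys], sep = "\r"))
  } else grp <- rep("all", nrow(trials))
  ord <- order(grp, trials$trial_index)
  tr <- trials[ord, ]
  g <- grp[ord]
  n <- nrow(tr)
  if (n < 2) return(NULL)
  i <- seq_len(n - 1)
  ok <- g[i] == g[i + 1] &
    tr$trial_index[i + 1] == tr$trial_index[i] + 1 &
    !is.na(tr$chosen_stim[i]) & !is.na(tr$chosen_stim[i + 1])
  if (!any(ok)) return(NULL)
  list(prev = tr[i[ok], ], nxt = tr[i[ok] + 1, ])
}

#' Win-stay probability
#'
#' Among consecutive-trial pairs whose first trial was rewarded, the
#' probability that the same stimulus was chosen in the next trial. Pairs
#' spanning session boundaries are excluded.
#'
#' @param trials Trial records.
#' @return Probability, or `NA` when no qualifying pair exists.
#' @export
win_stay <- function(trials) {
  p <- consecutive_pairs(trials)
  if (is.null(p)) return(NA_real_)
  q <- p$prev$rewarded == 1
  if (!any(q)) return(NA_real_)
  mean(p$nxt$chosen_stim[q] == p$prev$chosen_stim[q])
}

#' Lose-shift probability
#'
#' Among consecutive-trial pairs whose first trial was unrewarded, the
#' probability that the other stimulus was chosen in the next trial.
#'
#' @inheritParams win_stay
#' @return Probability, or `NA` when no qualifying pair exists.
#' @export
lose_shift <- function(trials) {
  p <- consecutive_pairs(trials)
  if (is.null(p)) return(NA_real_)
  q <- p$prev$rewarded == 0
  if (!any(q)) return(NA_real_)
  mean(p$nxt$chosen_stim[q] != p$prev$chosen_stim[q])
}

#' Side-stickiness probabilities
#'
#' `mode = "simple"`: fraction of consecutive pairs in which the same side
#' (left or right) was touched twice. `mode = "reward_associated"`:
#' restricted to pairs in which repeating the previously touched side would
#' have been rewarded (the next trial's reward-mapped stimulus sat on that
#' side), the fraction actually repeating that side.
#'
#' @param trials Trial records.
#' @param mode `"simple"` or `"reward_associated"`.
#' @return Probability, or `NA` when no qualifying pair exists.
#' @export
side_stickiness <- function(trials, mode = c("simple", "reward_associated")) {
  mode <- match.arg(mode)
  p <- consecutive_pairs(trials)
  if (is.null(p)) return(NA_real_)
  if (mode == "simple")
    return(mean(p$nxt$chosen_side == p$prev$chosen_side))
  # rewarded stimulus of the next trial: the chosen one if rewarded, else
  # the other member of the presented pair
  correct_next <- ifelse(p$nxt$rewarded == 1, p$nxt$chosen_stim,
                         ifelse(p$nxt$chosen_stim == p$nxt$left_stim,
                                p$nxt$right_stim, p$nxt$left_stim))
  side_of_correct <- ifelse(correct_next == p$nxt$left_stim, "left", "right")
  q <- side_of_correct == p$prev$chosen_side
  if (!any(q)) return(NA_real_)
  mean(p$nxt$chosen_side[q] == p$prev$chosen_side[q])
}

#' Per-animal, per-phase behavioral summary
#'
#' Computes errors to criterion (and its square root), aborted-session
#' count, win-stay, lose-shift, both side-stickiness probabilities, and —
#' when `stages = TRUE` — the bias/chance/improvement stage trial counts
#' from change-point segmentation of the trials up to the criterion session.
#'
#' @param trial_log Trial-log tibble (schema of [simulate_task_battery()]).
#' @param criterion,session_size As in [errors_to_criterion()].
#' @param stages Compute stage segmentation per phase (default TRUE).
#' @param alpha Change-point retention significance (default 0.05).
#' @param alpha_bias Bias-stage significance (default 0.01).
#' @return A tibble with one row per animal x phase.
#' @export
summarize_behavior <- function(trial_log, criterion = 0.9,
                               session_size = 100, stages = TRUE,
                               alpha = 0.05, alpha_bias = 0.01) {
  split_keys <- interaction(trial_log$animal_id, trial_log$phase_label,
                            drop = TRUE)
  parts <- split(trial_log, split_keys)
  rows <- lapply(parts, function(tr) {
    tr <- tr[order(tr$session_index, tr$trial_index), ]
    etc <- errors_to_criterion(tr, criterion, session_size)
    done <- tr[!is.na(tr$rewarded), ]
    row <- tibble::tibble(
      animal_id = tr$animal_id[1], group = tr$group[1],
      phase_label = tr$phase_label[1], task_kind = tr$task_kind[1],
      n_sessions = length(unique(tr$session_index)),
      errors_to_criterion = as.integer(etc),
      attained = attr(etc, "attained"),
      sqrt_errors = sqrt(as.integer(etc)),
      aborted_sessions = count_aborted_sessions(tr)$n,
      win_stay = win_stay(tr), lose_shift = lose_shift(tr),
      side_stick_simple = side_stickiness(tr, "simple"),
      side_stick_reward = side_stickiness(tr, "reward_associated"))
    if (stages) {
      seg <- tryCatch({
        cp <- find_change_points(done$rewarded, alpha = alpha)
        classify_stages(done$rewarded, cp, alpha_bias = alpha_bias)
      }, error = function(e) NULL)
      len <- function(iv) if (is.null(iv)) 0L else iv[2] - iv[1] + 1L
      row$bias_trials <- if (is.null(seg)) NA_integer_ else len(seg$bias_interval)
      row$chance_trials <- if (is.null(seg)) NA_integer_ else len(seg$chance_interval)
      row$improvement_trials <- if (is.null(seg)) NA_integer_ else len(seg$improvement_interval)
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$animal_id, out$phase_label), ]
}

#' Response-time comparison on end-of-phase trial pools
#'
#' Pools the final `tail_n` completed trials of every phase in each period
#' and compares the pooled response times with a two-sided Mann-Whitney U
#' test (exact for small untied pools, normal approximation with tie
#' correction otherwise).
#'
#' @param pre_trials,post_trials Trial records; phases identified by
#'   `phase_label`.
#' @param tail_n Trials taken from the end of each phase (default 20). When
#'   a phase has fewer, all its trials are used with a warning.
#' @return A list: `U`, `p`, `medians`, `quartiles` (2 x 2), `n` (pool
#'   sizes).
#' @export
response_time_comparison <- function(pre_trials, post_trials, tail_n = 20) {
  pool <- function(trials) {
    parts <- split(trials, trials$phase_label)
    unlist(lapply(parts, function(tr) {
      tr <- tr[order(tr$session_index, tr$trial_index), ]
      rt <- tr$response_time_s[!is.na(tr$response_time_s)]
      if (length(rt) < tail_n)
        warning("phase with fewer than tail_n trials; using all")
      utils::tail(rt, tail_n)
    }), use.names = FALSE)
  }
  x <- pool(pre_trials); y <- pool(post_trials)
  wt <- stats::wilcox.test(x, y)
  list(U = unname(wt$statistic), p = wt$p.value,
       medians = c(pre = stats::median(x), post = stats::median(y)),
       quartiles = rbind(pre = stats::quantile(x, c(0.25, 0.75)),
                         post = stats::quantile(y, c(0.25, 0.75))),
       n = c(pre = length(x), post = length(y)))
}

#' Normalized locomotor activity ratio
#'
#' Daily activity summed over the first 3 complete weekdays of the
#' post-injection series divided by that over the last 3 complete weekdays
#' of the pre-injection series.
#'
#' @param pre_series,post_series Activity series (see [activity_series()]).
#' @param n_days Weekdays per period (default 3).
#' @return Ratio (post / pre), `NA` when the pre-period total is zero.
#' @export
normalized_locomotor_activity <- function(pre_series, post_series,
                                          n_days = 3) {
  daily <- function(series) {
    d <- as.Date(series$timestamp)
    full <- names(which(table(d) == 2880))
    full <- full[!weekdays(as.Date(full)) %in% c("Saturday", "Sunday")]
    if (length(full) < n_days) stop("need >= ", n_days, " complete weekdays")
    sums <- tapply(series$counts, d, sum)
    sums[full]
  }
  pre <- daily(pre_series); post <- daily(post_series)
  pre_sum <- sum(utils::tail(pre, n_days))
  post_sum <- sum(utils::head(post, n_days))
  if (pre_sum == 0) return(NA_real_)
  post_sum / pre_sum
}
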
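#' Task design for a discrimination/reversal battery
#'
#' @param phases A data frame with columns `label` (e.g. "N7"), `task_kind`
#'   (`"novel"` or `"reversal"`), `stimulus_pair` (integer id; a reversal
#'   phase inverts the reward map of the preceding novel phase with the same
#'   pair), and `period` (`"pre"` or `"post"`; post phases run with the
#'   post-injection agent parameters).
#' @param trials_per_session Trials in a full daily session (default 100).
#' @param criterion Fraction correct that ends a phase when attained in a
#'   complete session (default 0.90).
#' @param max_sessions_per_phase Safety cap on sessions per phase.
#' @return A list of class `task_design`.
#' @export
task_design <- function(phases, trials_per_session = 100, criterion = 0.9,
                        max_sessions_per_phase = 25) {
  phases <- tibble::as_tibble(phases)
  need <- c("label", "task_kind", "stimulus_pair", "period")
  if (!all(need %in% names(phases)))
    stop("phases must have columns ", paste(need, collapse = ", "))
  if (!(criterion > 0 && criterion <= 1)) stop("criterion must be in (0, 1]")
  if (!all(phases$task_kind %in% c("novel", "reversal")))
    stop("task_kind must be 'novel' or 'reversal'")
  for (i in which(phases$task_kind == "reversal")) {
    prior <- phases$task_kind[seq_len(i - 1)] == "novel" &
      phases$stimulus_pair[seq_len(i - 1)] == phases$stimulus_pair[i]
    if (!any(prior))
      stop("reversal phase '", phases$label[i],
           "' is not preceded by its novel phase")
  }
  structure(list(phases = phases, trials_per_session = trials_per_session,
                 criterion = criterion,
                 max_sessions_per_phase = max_sessions_per_phase),
            class = "task_design")
}

#' Preset battery design mirroring the study timeline
#'
#' Four novel:reversal pairs before the injection (N3:R3 to N6:R6) and four
#' after (N7:R7 to N10:R10). The post-injection block is the one entering the
#' three-way ANOVA (TASK x REPEAT within, GROUP between).
#'
#' @param period `"both"` (default), `"pre"`, or `"post"`.
#' @param ... Passed to [task_design()].
#' @return A [task_design()].
#' @export
task_design_preset <- function(period = c("both", "pre", "post"), ...) {
  period <- match.arg(period)
  block <- function(reps, per) {
    do.call(rbind, lapply(reps, function(k) {
      data.frame(label = c(paste0("N", k), paste0("R", k)),
                 task_kind = c("novel", "reversal"),
                 stimulus_pair = k, period = per)
    }))
  }
  ph <- rbind(if (period != "post") block(3:6, "pre"),
              if (period != "pre") block(7:10, "post"))
  task_design(ph, ...)
}

#' Simulate a full discrimination/reversal battery for one animal
#'
#' Each phase runs sessions until a complete (non-aborted) session reaches
#' the criterion fraction correct, or until the session cap. Q-values carry
#' over between a novel phase and its reversal (the reward map inverts);
#' novel phases introduce fresh stimuli initialised at 0.5. Post-injection
#' phases use `params_post`.
#'
#' @param design A [task_design()].
#' @param params_pre,params_post [agent_params()] for the two periods.
#' @param seed Integer seed.
#' @param animal_id,group Identifier columns copied into the log.
#' @return A trial-log tibble in the documented schema (columns `animal_id`,
#'   `group`, `phase_label`, `task_kind`, `session_index`, `trial_index`,
#'   `left_stim`, `right_stim`, `chosen_stim`, `chosen_side`, `rewarded`,
#'   `response_time_s`, `aborted_session`, `intertrial_s`).
#' @export
simulate_task_battery <- function(design, params_pre, params_post, seed = 1,
                                  animal_id = "A1", group = "control") {
  stopifnot(inherits(design, "task_design"))
  q_store <- list()
  out <- list()
  sess_counter <- 0L
  for (i in seq_len(nrow(design$phases))) {
    ph <- design$phases[i, ]
    stims <- paste0("P", ph$stimulus_pair, c("a", "b"))
    rmap <- if (ph$task_kind == "novel")
      stats::setNames(c(1L, 0L), stims) else stats::setNames(c(0L, 1L), stims)
    key <- as.character(ph$stimulus_pair)
    q <- q_store[[key]]
    if (is.null(q)) q <- stats::setNames(c(0.5, 0.5), stims)
    pars <- if (ph$period == "post") params_post else params_pre
    for (s in seq_len(design$max_sessions_per_phase)) {
      sess_counter <- sess_counter + 1L
      sess_seed <- (as.double(seed) * 100003 + sess_counter * 97) %% 2147483629
      sess <- simulate_agent_session(pars, rmap, design$trials_per_session,
                                     q_init = q, seed = as.integer(sess_seed))
      q <- attr(sess, "q_final")
      sess$session_index <- s
      sess$phase_label <- ph$label
      sess$task_kind <- ph$task_kind
      out[[length(out) + 1L]] <- sess
      done <- !attr(sess, "aborted") &&
        nrow(sess) == design$trials_per_session &&
        mean(sess$rewarded) >= design$criterion
      if (done) break
    }
    q_store[[key]] <- q
  }
  log <- dplyr::bind_rows(out)
  log$animal_id <- animal_id
  log$group <- group
  log[, c("animal_id", "group", "phase_label", "task_kind", "session_index",
          "trial_index", "left_stim", "right_stim", "chosen_stim",
          "chosen_side", "rewarded", "response_time_s", "aborted_session",
          "intertrial_s")]
}

#' Simulate the preset 5 + 5 + 4 cohort
#'
#' Five D1R-knockdown, five D2R-knockdown and four control animals, each run
#' through the battery with the group's pre/post parameter presets.
#'
#' @param design A [task_design()]; default [task_design_preset()].
#' @param seed Integer seed.
#' @param n_d1,n_d2,n_control Group sizes.
#' @return Combined trial-log tibble for all animals.
#' @export
simulate_cohort <- function(design = task_design_preset(), seed = 1,
                            n_d1 = 5, n_d2 = 5, n_control = 4) {
  groups <- c(rep("d1r_kd", n_d1), rep("d2r_kd", n_d2),
              rep("control", n_control))
  logs <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    simulate_task_battery(
      design,
      params_pre = agent_preset(g, "pre"),
      params_post = agent_preset(g, "post"),
      seed = (as.double(seed) * 7919 + i * 104729) %% 2147483629,
      animal_id = sprintf("M%02d", i), group = g)
  })
  dplyr::bind_rows(logs)
}
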
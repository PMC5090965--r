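# Brute-force oracles, written as direct scans over the records so they stay
# independent of the package's grouped/vectorized implementations.

oracle_errors_to_criterion <- function(trials, criterion = 0.9,
                                       session_size = 100) {
  errors <- 0
  for (s in sort(unique(trials$session_index))) {
    tr <- trials[trials$session_index == s, ]
    tr <- tr[order(tr$trial_index), ]
    done <- tr[!is.na(tr$rewarded), ]
    errors <- errors + sum(done$rewarded == 0)
    if (nrow(done) == session_size && all(tr$aborted_session == 0) &&
        sum(done$rewarded) / nrow(done) >= criterion)
      return(errors)
  }
  errors
}

# enumerate consecutive same-session pairs by explicit double loop
oracle_pairs <- function(trials) {
  trials <- trials[order(trials$session_index, trials$trial_index), ]
  out <- list()
  for (i in seq_len(nrow(trials) - 1)) {
    a <- trials[i, ]; b <- trials[i + 1, ]
    if (a$session_index == b$session_index &&
        b$trial_index == a$trial_index + 1 &&
        !is.na(a$chosen_stim) && !is.na(b$chosen_stim))
      out[[length(out) + 1]] <- list(a = a, b = b)
  }
  out
}

oracle_win_stay <- function(trials) {
  ps <- oracle_pairs(trials)
  num <- 0; den <- 0
  for (p in ps) if (p$a$rewarded == 1) {
    den <- den + 1
    if (p$b$chosen_stim == p$a$chosen_stim) num <- num + 1
  }
  if (den == 0) NA_real_ else num / den
}

oracle_lose_shift <- function(trials) {
  ps <- oracle_pairs(trials)
  num <- 0; den <- 0
  for (p in ps) if (p$a$rewarded == 0) {
    den <- den + 1
    if (p$b$chosen_stim != p$a$chosen_stim) num <- num + 1
  }
  if (den == 0) NA_real_ else num / den
}

oracle_side_stick_simple <- function(trials) {
  ps <- oracle_pairs(trials)
  if (length(ps) == 0) return(NA_real_)
  mean(vapply(ps, function(p) p$b$chosen_side == p$a$chosen_side, logical(1)))
}

oracle_side_stick_reward <- function(trials) {
  ps <- oracle_pairs(trials)
  num <- 0; den <- 0
  for (p in ps) {
    correct_b <- if (p$b$rewarded == 1) p$b$chosen_stim else
      setdiff(c(p$b$left_stim, p$b$right_stim), p$b$chosen_stim)
    side_correct <- if (correct_b == p$b$left_stim) "left" else "right"
    if (side_correct == p$a$chosen_side) {
      den <- den + 1
      if (p$b$chosen_side == p$a$chosen_side) num <- num + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

# random but schema-valid single-phase trial log (consistent reward map)
make_random_log <- function(seed, n_sessions = 3, session_size = 20) {
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_sessions)) {
      for (i in seq_len(session_size)) {
        s1_left <- runif(1) < 0.5
        chosen1 <- runif(1) < 0.6
        chosen <- if (chosen1) "Pa" else "Pb"
        rows[[length(rows) + 1]] <- tibble::tibble(
          animal_id = "T1", group = "control", phase_label = "N1",
          task_kind = "novel", session_index = s, trial_index = i,
          left_stim = if (s1_left) "Pa" else "Pb",
          right_stim = if (s1_left) "Pb" else "Pa",
          chosen_stim = chosen,
          chosen_side = if ((chosen == "Pa") == s1_left) "left" else "right",
          rewarded = as.integer(chosen == "Pa"),
          response_time_s = rlnorm(1, 0.5, 0.3),
          aborted_session = 0L, intertrial_s = 3)
      }
    }
    dplyr::bind_rows(rows)
  })
}

# split-plot ANOVA oracle: stratum projections + per-stratum sequential SS,
# computed from cell means rather than via aov()
oracle_mixed_anova <- function(d) {
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$task <- factor(d$task); d$rep_f <- factor(d[["repeat"]])
  t_l <- nlevels(d$task); r_l <- nlevels(d$rep_f)
  N <- nlevels(d$subject); g <- nlevels(d$group)
  grand <- mean(d$value)
  m_s <- tapply(d$value, d$subject, mean)
  sg <- unique(d[, c("subject", "group")])
  grp <- sg$group[match(levels(d$subject), as.character(sg$subject))]
  n_g <- table(grp)
  m_g <- tapply(m_s, grp, mean)
  ss_group <- t_l * r_l * sum(n_g * (m_g - grand)^2)
  ss_subj <- t_l * r_l * sum((m_s - m_g[grp])^2)

  # within-stratum components from cell means, subject-centered
  m_st <- tapply(d$value, list(d$subject, d$task), mean)
  m_sr <- tapply(d$value, list(d$subject, d$rep_f), mean)
  m_str <- tapply(d$value, list(d$subject, d$task, d$rep_f), mean)
  z_t <- sweep(m_st, 1, m_s)           # subject x task
  z_r <- sweep(m_sr, 1, m_s)
  seq_ss <- function(z, k_rep) {
    # z: subject x levels, rows sum to zero; k_rep observations per cell
    eff <- colMeans(z)                       # every subject weighted equally
    ss_main <- k_rep * N * sum(eff^2)
    cellm <- apply(z, 2, function(col) tapply(col, grp, mean))  # group x level
    inter <- sweep(cellm, 2, eff)
    ss_inter <- k_rep * sum(rep(as.numeric(n_g), ncol(z)) * inter^2)
    fitted <- matrix(eff, N, ncol(z), byrow = TRUE) +
      inter[match(as.character(grp), rownames(inter)), , drop = FALSE]
    ss_err <- k_rep * sum((z - fitted)^2)
    c(main = ss_main, inter = ss_inter, err = ss_err)
  }
  s_t <- seq_ss(z_t, r_l)
  s_r <- seq_ss(z_r, t_l)
  # task x rep stratum: three-way cell means centered on all lower terms
  z_tr <- m_str
  for (s in seq_len(N)) {
    z_tr[s, , ] <- m_str[s, , ] - outer(z_t[s, ], rep(1, r_l)) -
      outer(rep(1, t_l), z_r[s, ]) - m_s[s]
  }
  eff_tr <- apply(z_tr, c(2, 3), mean)
  ss_tr <- N * sum(eff_tr^2)
  cell_gtr <- array(0, c(g, t_l, r_l))
  for (gi in seq_len(g)) {
    cell_gtr[gi, , ] <- apply(z_tr[grp == levels(grp)[gi], , , drop = FALSE],
                              c(2, 3), mean)
  }
  inter_gtr <- sweep(cell_gtr, c(2, 3), eff_tr)
  ss_gtr <- sum(as.numeric(n_g) * apply(inter_gtr^2, 1, sum))
  fitted_tr <- array(0, dim(z_tr))
  for (s in seq_len(N)) {
    gi <- match(grp[s], levels(grp))
    fitted_tr[s, , ] <- eff_tr + inter_gtr[gi, , ]
  }
  ss_tr_err <- sum((z_tr - fitted_tr)^2)

  df <- list(group = c(g - 1, N - g),
             task = c(t_l - 1, (t_l - 1) * (N - g)),
             rep_f = c(r_l - 1, (r_l - 1) * (N - g)),
             group_task = c((g - 1) * (t_l - 1), (t_l - 1) * (N - g)),
             group_rep = c((g - 1) * (r_l - 1), (r_l - 1) * (N - g)),
             task_rep = c((t_l - 1) * (r_l - 1),
                          (t_l - 1) * (r_l - 1) * (N - g)),
             group_task_rep = c((g - 1) * (t_l - 1) * (r_l - 1),
                                (t_l - 1) * (r_l - 1) * (N - g)))
  ss <- list(group = ss_group, task = s_t[["main"]], rep_f = s_r[["main"]],
             group_task = s_t[["inter"]], group_rep = s_r[["inter"]],
             task_rep = ss_tr, group_task_rep = ss_gtr)
  err_ss <- list(group = ss_subj, task = s_t[["err"]], rep_f = s_r[["err"]],
                 group_task = s_t[["err"]], group_rep = s_r[["err"]],
                 task_rep = ss_tr_err, group_task_rep = ss_tr_err)
  out <- lapply(names(ss), function(nm) {
    ms <- ss[[nm]] / df[[nm]][1]
    mse <- err_ss[[nm]] / df[[nm]][2]
    Fv <- ms / mse
    tibble::tibble(effect = nm, df_num = df[[nm]][1], df_den = df[[nm]][2],
                   ss = ss[[nm]], F = Fv,
                   p = stats::pf(Fv, df[[nm]][1], df[[nm]][2],
                                 lower.tail = FALSE))
  })
  dplyr::bind_rows(out)
}

# random complete split-plot dataset
make_anova_data <- function(seed, g = 3, n_per = c(5, 5, 4), t_l = 2,
                            r_l = 4) {
  withr::with_seed(seed, {
    N <- sum(n_per)
    subj <- sprintf("S%02d", seq_len(N))
    grp <- rep(paste0("G", seq_len(g)), n_per)
    d <- expand.grid(subject = subj, task = paste0("T", seq_len(t_l)),
                     "repeat" = paste0("R", seq_len(r_l)),
                     stringsAsFactors = FALSE)
    d$group <- grp[match(d$subject, subj)]
    d$value <- rnorm(nrow(d)) + rnorm(N)[match(d$subject, subj)] +
      as.numeric(factor(d$group)) * 0.3
    d
  })
}
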
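#' Three-way mixed ANOVA (one between-, two within-subject factors)
#'
#' Split-plot ANOVA of the study design: GROUP is a between-subject factor;
#' TASK and REPEAT are within-subject factors crossed within every subject.
#' Between effects are tested against the subject-within-group mean square;
#' each within effect and its GROUP interaction against the corresponding
#' effect-by-subject-within-group mean square. For group sizes `n_g`
#' (total `N`), `t` task levels and `r` repeats the degrees of freedom are
#' GROUP `(g - 1, N - g)`, TASK `(t - 1, (t - 1)(N - g))`, REPEAT
#' `(r - 1, (r - 1)(N - g))`, and analogously for interactions.
#'
#' Computed via `stats::aov()` with `Error(subject/(task * repeat))` strata.
#' Levene's test (median-centered) on the subject means and Mauchly's
#' sphericity test for the REPEAT contrasts are reported alongside; Fisher's
#' LSD pairwise group comparisons use the subject-within-group mean square.
#'
#' @param data Data frame with columns `subject`, `group`, `task`,
#'   `repeat`, `value`; the within design must be complete (every subject
#'   measured in every task x repeat cell exactly once).
#' @return A list of class `mixed_anova`: `table` (tibble: effect, df_num,
#'   df_den, ss, ms, F, p), `lsd` (pairwise group comparisons), `levene_p`,
#'   `mauchly_p`, and the design sizes.
#' @export
mixed_anova <- function(data) {
  need <- c("subject", "group", "task", "repeat", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  d <- data.frame(subject = factor(data$subject),
                  group = factor(data$group),
                  task = factor(data$task),
                  rep_f = factor(data[["repeat"]]),
                  value = as.numeric(data$value))
  t_lev <- nlevels(d$task); r_lev <- nlevels(d$rep_f)
  N <- nlevels(d$subject); g <- nlevels(d$group)
  counts <- table(d$subject, d$task, d$rep_f)
  if (any(counts != 1))
    stop("within-subject design must be complete (one value per cell)")
  sg <- unique(d[, c("subject", "group")])
  if (nrow(sg) != N) stop("each subject must belong to exactly one group")

  fit <- stats::aov(value ~ group * task * rep_f +
                      Error(subject / (task * rep_f)), data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    res <- tab[trimws(rownames(tab)) == "Residuals", , drop = FALSE]
    eff <- tab[trimws(rownames(tab)) != "Residuals", , drop = FALSE]
    for (i in seq_len(nrow(eff))) {
      nm <- trimws(rownames(eff)[i])
      nm <- gsub("rep_f", "repeat", nm)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = toupper(gsub(":", " x ", nm)),
        df_num = eff[i, "Df"], df_den = res[1, "Df"],
        ss = eff[i, "Sum Sq"], ms = eff[i, "Mean Sq"],
        F = eff[i, "F value"], p = eff[i, "Pr(>F)"])
    }
  }
  table <- dplyr::bind_rows(rows)

  # subject-within-group mean square for the between stratum
  subj_means <- tapply(d$value, d$subject, mean)
  subj_group <- sg$group[match(names(subj_means), as.character(sg$subject))]
  ms_between <- table$ss[table$effect == "GROUP"] /
    table$df_num[table$effect == "GROUP"]
  mse_subj <- sum(tapply(seq_along(subj_means), subj_group, function(ix) {
    sum((subj_means[ix] - mean(subj_means[ix]))^2)
  })) * t_lev * r_lev / (N - g)
  lsd <- fisher_lsd(tapply(d$value, d$group, mean),
                    table(sg$group) * t_lev * r_lev, mse_subj, N - g)

  # Levene (median-centered) on subject means across groups
  z <- abs(subj_means - stats::ave(subj_means, subj_group,
                                   FUN = stats::median))
  levene_p <- stats::anova(stats::lm(z ~ subj_group))$`Pr(>F)`[1]

  # Mauchly for the REPEAT contrasts (needs >= 3 levels)
  mauchly_p <- NA_real_
  if (r_lev >= 3) {
    ord <- order(d$subject, d$task, d$rep_f)
    Y <- matrix(d$value[ord], nrow = N, byrow = TRUE)
    idata <- expand.grid(rep_f = factor(levels(d$rep_f)),
                         task = factor(levels(d$task)))
    idata <- idata[order(idata$task, idata$rep_f), c("task", "rep_f")]
    grp_of_row <- sg$group[match(levels(d$subject), as.character(sg$subject))]
    mlm <- stats::lm(Y ~ grp_of_row)
    mt <- tryCatch(
      stats::mauchly.test(mlm, M = ~ task + rep_f, X = ~ task, idata = idata),
      error = function(e) NULL)
    if (!is.null(mt)) mauchly_p <- mt$p.value
  }

  structure(list(table = table, lsd = lsd, levene_p = levene_p,
                 mauchly_p = mauchly_p,
                 design = c(groups = g, subjects = N, tasks = t_lev,
                            repeats = r_lev)),
            class = "mixed_anova")
}

# Fisher's LSD pairwise comparisons given cell means, per-mean observation
# counts, the error mean square and its df.
fisher_lsd <- function(means, n_per, mse, df) {
  labs <- names(means)
  combs <- utils::combn(seq_along(means), 2)
  rows <- apply(combs, 2, function(ix) {
    i <- ix[1]; j <- ix[2]
    se <- sqrt(mse * (1 / n_per[i] + 1 / n_per[j]))
    tval <- (means[i] - means[j]) / se
    tibble::tibble(contrast = paste(labs[i], "-", labs[j]),
                   diff = unname(means[i] - means[j]),
                   t = unname(tval), df = df,
                   p = 2 * stats::pt(-abs(unname(tval)), df))
  })
  dplyr::bind_rows(rows)
}

#' Paired pre/post t-test with normality check
#'
#' Paired t-test on within-animal differences (`df = n - 1`), with a
#' Shapiro-Wilk test on the differences.
#'
#' @param pre,post Equal-length numeric vectors (one value per animal).
#' @return A list: `t`, `df`, `p`, `shapiro_p`.
#' @export
paired_prepost_ttest <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be equal length")
  if (length(pre) < 2) stop("need n >= 2")
  fit <- stats::t.test(post, pre, paired = TRUE)
  dif <- post - pre
  sw <- if (stats::sd(dif) == 0) NA_real_ else stats::shapiro.test(dif)$p.value
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, shapiro_p = sw)
}

#' One-way group ANOVA with Fisher's LSD post hoc
#'
#' Across-group ANOVA (`df = (g - 1, N - g)`) with unadjusted pairwise LSD
#' comparisons using the residual mean square, and a Shapiro-Wilk test on
#' the residuals.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return A list: `F`, `df`, `p`, `lsd` (tibble), `shapiro_p`.
#' @export
oneway_group_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  fit <- stats::aov(values ~ g)
  tab <- stats::anova(fit)
  mse <- tab$`Mean Sq`[2]
  lsd <- fisher_lsd(tapply(values, g, mean), table(g), mse, tab$Df[2])
  res <- stats::residuals(fit)
  sw <- if (stats::sd(res) == 0) NA_real_ else stats::shapiro.test(res)$p.value
  list(F = tab$`F value`[1], df = c(tab$Df[1], tab$Df[2]),
       p = tab$`Pr(>F)`[1], lsd = lsd, shapiro_p = sw)
}
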
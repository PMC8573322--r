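# Regression chain: mixed-effect logistic regression of EV-consistent choice
# on task, mixed-effect linear regression of log decision time, and the
# pooled two-proportion z test used to compare per-task strategy
# distributions. Random intercepts for participant and item (gamble pair)
# throughout, with a flagged fixed-effects fallback for degenerate fits.

term_row <- function(term, b, se, stat, p, df = NA_real_,
                     crit = stats::qnorm(0.975)) {
  data.frame(term = term, estimate = b, se = se,
             ci_low = b - crit * se, ci_high = b + crit * se,
             statistic = stat, p_value = p, stringsAsFactors = FALSE)
}

#' Mixed-effect logistic regression of EV-consistent choice on task
#'
#' Fits `ev_consistent ~ task + (1 | participant) + (1 | item)` with task
#' dummy-coded (alternative-wise = 1, dimension-wise = 0) by Laplace GLMM. A
#' positive coefficient means the alternative-wise task raises the odds of
#' choosing the higher-EV option. On a singular or failed GLMM fit the model
#' degrades to plain logistic regression and the result is flagged.
#'
#' @param trials Trial table (`participant_id`, `task`, `pair_id`, `choice`).
#' @param pairs The `gamble_pairs` table.
#' @return List of class `"choice_model"` with `b`, `se`, `ci95`,
#'   `odds_ratio`, `or_ci95`, `statistic` (z), `p_value`, `model_label`,
#'   `degraded`, `terms` (per-term data frame) and the fitted `model`.
#' @export
fit_choice_model <- function(trials, pairs) {
  d <- trials_with_ev_consistency(trials, pairs)
  if (length(unique(d$task)) < 2L)
    stop("both tasks must be present", call. = FALSE)
  if (length(unique(d$participant_id)) < 2L ||
      length(unique(d$pair_id)) < 2L)
    stop("need at least 2 participants and 2 items", call. = FALSE)
  if (all(d$ev_consistent) || !any(d$ev_consistent))
    stop("EV-consistency is constant: complete separation, model undefined",
         call. = FALSE)
  d$task01 <- as.integer(d$task == "ALT")
  d$y <- as.integer(d$ev_consistent)

  degraded <- FALSE
  fit <- tryCatch(
    lme4::glmer(y ~ task01 + (1 | participant_id) + (1 | pair_id),
                data = d, family = stats::binomial()),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit)) {
    if (is.null(fit)) {
      degraded <- TRUE
      fit <- stats::glm(y ~ task01, data = d, family = stats::binomial())
    } else {
      degraded <- TRUE  # singular random effects: keep the GLMM, flag it
    }
  }
  cf <- stats::coef(summary(fit))
  b <- cf["task01", 1L]; se <- cf["task01", 2L]
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  crit <- stats::qnorm(0.975)
  structure(list(
    b = b, se = se, ci95 = c(b - crit * se, b + crit * se),
    odds_ratio = exp(b),
    or_ci95 = exp(c(b - crit * se, b + crit * se)),
    statistic = z, p_value = p,
    model_label = "ev_consistent ~ task + (1|participant) + (1|item), logit",
    degraded = degraded,
    terms = term_row("task", b, se, z, p),
    model = fit
  ), class = "choice_model")
}

#' @export
print.choice_model <- function(x, ...) {
  cat(sprintf(
    "<choice_model> task b = %.3f [%.3f, %.3f], OR = %.2f, z = %.2f, p = %.3g%s\n",
    x$b, x$ci95[1], x$ci95[2], x$odds_ratio, x$statistic, x$p_value,
    if (x$degraded) " (degraded fit)" else ""))
  invisible(x)
}

#' Mixed-effect linear regression of log decision time
#'
#' Fits `log(rt_s) ~ task + ev_diff + outcome_diff + (1 | participant) +
#' (1 | item)`, with task dummy-coded (alternative-wise = 1), `ev_diff` the
#' absolute expected-value difference and `outcome_diff` the absolute outcome
#' difference of the pair (both in yuan). t statistics and p values use
#' Satterthwaite degrees of freedom; on a failed or singular fit the model
#' degrades to ordinary least squares and is flagged.
#'
#' @param trials Trial table including positive `rt_s`.
#' @param pairs The `gamble_pairs` table.
#' @return List of class `"rt_model"` with a per-term data frame `terms`
#'   (`task`, `ev_diff`, `outcome_diff`: estimate, ci, t, p), `degraded`, and
#'   the fitted `model`.
#' @export
fit_rt_model <- function(trials, pairs) {
  if (!"rt_s" %in% names(trials))
    stop("trial table needs an 'rt_s' column", call. = FALSE)
  if (any(!is.finite(trials$rt_s) | trials$rt_s <= 0))
    stop("response times must be strictly positive", call. = FALSE)
  d <- trials_with_ev_consistency(trials, pairs)
  d$task01 <- as.integer(d$task == "ALT")
  d$log_rt <- log(d$rt_s)

  degraded <- FALSE
  fit <- tryCatch(
    lmerTest::lmer(log_rt ~ task01 + ev_diff + outcome_diff +
                     (1 | participant_id) + (1 | pair_id), data = d),
    error = function(e) NULL)
  if (is.null(fit)) {
    degraded <- TRUE
    fit <- stats::lm(log_rt ~ task01 + ev_diff + outcome_diff, data = d)
  } else if (lme4::isSingular(fit)) {
    degraded <- TRUE
  }
  cf <- stats::coef(summary(fit))
  pick <- c(task = "task01", ev_diff = "ev_diff",
            outcome_diff = "outcome_diff")
  rows <- lapply(names(pick), function(nm) {
    r <- cf[pick[[nm]], ]
    b <- r[["Estimate"]]; se <- r[["Std. Error"]]
    tstat <- b / se
    p <- if ("Pr(>|t|)" %in% colnames(cf)) r[["Pr(>|t|)"]] else
      2 * stats::pnorm(-abs(tstat))
    term_row(nm, b, se, tstat, p)
  })
  terms <- do.call(rbind, rows)
  structure(list(
    terms = terms,
    model_label = "log(rt) ~ task + |dEV| + |dOutcome| + (1|participant) + (1|item)",
    degraded = degraded, model = fit
  ), class = "rt_model")
}

#' @export
print.rt_model <- function(x, ...) {
  cat("<rt_model>", x$model_label,
      if (x$degraded) "(degraded fit)" else "", "\n")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Pooled two-proportion z test (one-tailed)
#'
#' Compares two classification proportions `k1/n1` and `k2/n2` with the
#' pooled-variance z statistic
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))`, `p = (k1+k2)/(n1+n2)`, and a
#' one-tailed p value `P(Z > z)`. Equal proportions give `z = 0`, `p = 0.5`.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return List with `z`, `p_one_tailed`, `p1`, `p2`.
#' @examples
#' compare_classification_proportions(49, 50, 44, 50)  # z ~ 1.96
#' @export
compare_classification_proportions <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1)
    stop("both groups must be non-empty", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (p1 == p2) 0 else (p1 - p2) / se
  list(z = z, p_one_tailed = stats::pnorm(z, lower.tail = FALSE),
       p1 = p1, p2 = p2)
}
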
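# Mediation of the task effect on EV-consistent choice through search
# direction (the SM index). Paths on the linear probability scale:
#   mediator model  sm ~ task            -> a
#   outcome model   y  ~ task + sm       -> c' (task), b (sm)
#   total model     y  ~ task            -> c
# Indirect effect ab = a * b; for the OLS engine the fitted total effect
# satisfies c = c' + ab as an algebraic identity. Uncertainty in ab comes
# from a participant-level (cluster) percentile bootstrap.

ols_coef <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  fit$coefficients
}

mediation_paths_fixed <- function(t01, sm, y) {
  X1 <- cbind(1, t01)
  X2 <- cbind(1, t01, sm)
  a <- ols_coef(sm, X1)[2L]
  cb <- ols_coef(y, X2)
  c_total <- ols_coef(y, X1)[2L]
  list(a = unname(a), b = unname(cb[3L]), c_prime = unname(cb[2L]),
       c_total = unname(c_total))
}

mediation_paths_mixed <- function(d) {
  m_med <- lmerTest::lmer(sm ~ task01 + (1 | participant_id) + (1 | pair_id),
                          data = d)
  m_out <- lmerTest::lmer(y ~ task01 + sm + (1 | participant_id) +
                            (1 | pair_id), data = d)
  m_tot <- lmerTest::lmer(y ~ task01 + (1 | participant_id) + (1 | pair_id),
                          data = d)
  list(a = unname(lme4::fixef(m_med)[["task01"]]),
       b = unname(lme4::fixef(m_out)[["sm"]]),
       c_prime = unname(lme4::fixef(m_out)[["task01"]]),
       c_total = unname(lme4::fixef(m_tot)[["task01"]]),
       models = list(mediator = m_med, outcome = m_out, total = m_tot))
}

#' Mediation analysis: task -> SM index -> EV-consistent choice
#'
#' Estimates the a (task to SM), b (SM to choice, task held), c' (direct) and
#' c (total) paths on the linear probability scale, with the task dummy-coded
#' (alternative-wise = 1). The indirect effect is `ab = a * b`. A 95\%
#' percentile confidence interval for `ab` is built by resampling
#' participants with replacement (`n_boot` cluster-bootstrap resamples, OLS
#' path refits within each resample); `n_boot = 0` returns point estimates
#' with the interval marked unavailable.
#'
#' @param data Data frame with columns `participant_id`, `pair_id`, `task`
#'   (`"ALT"`/`"DIM"`), `sm` (per-trial SM index; `NA` rows are dropped) and
#'   `ev_consistent` (logical or 0/1).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Optional integer seed for the bootstrap.
#' @param engine `"mixed"` fits the three path models with participant and
#'   item random intercepts (falling back to `"fixed"` with a flag when a fit
#'   fails); `"fixed"` uses OLS throughout, for which the decomposition
#'   `c = c' + ab` is exact.
#' @param conf_level Confidence level for the bootstrap interval.
#' @return List of class `"mediation_result"` with `a`, `b_path`, `c_total`,
#'   `c_prime`, `ab`, `ci95_ab`, `z_ab` (ab over its bootstrap SE), `n_boot`,
#'   `engine`, `degraded`, `n_participants`.
#' @export
mediation_analysis <- function(data, n_boot = 5000, seed = NULL,
                               engine = c("mixed", "fixed"),
                               conf_level = 0.95) {
  engine <- match.arg(engine)
  need <- c("participant_id", "pair_id", "task", "sm", "ev_consistent")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("mediation data is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- data[!is.na(data$sm), , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows with a non-missing SM", call. = FALSE)
  if (length(unique(d$task)) < 2L)
    stop("both tasks must be present", call. = FALSE)
  pids <- unique(d$participant_id)
  if (length(pids) < 3L)
    stop("insufficient clusters: mediation needs at least 3 participants",
         call. = FALSE)
  d$task01 <- as.integer(d$task == "ALT")
  d$y <- as.numeric(d$ev_consistent)

  degraded <- FALSE
  if (engine == "mixed") {
    paths <- tryCatch(mediation_paths_mixed(d), error = function(e) NULL)
    if (is.null(paths)) {
      degraded <- TRUE
      paths <- mediation_paths_fixed(d$task01, d$sm, d$y)
    }
  } else {
    paths <- mediation_paths_fixed(d$task01, d$sm, d$y)
  }
  ab <- paths$a * paths$b

  ci <- c(NA_real_, NA_real_)
  z_ab <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    idx_by_pid <- split(seq_len(nrow(d)), d$participant_id)
    t01 <- d$task01; smv <- d$sm; yv <- d$y
    ab_boot <- numeric(n_boot)
    np <- length(idx_by_pid)
    for (b in seq_len(n_boot)) {
      take <- sample.int(np, np, replace = TRUE)
      ix <- unlist(idx_by_pid[take], use.names = FALSE)
      pb <- mediation_paths_fixed(t01[ix], smv[ix], yv[ix])
      ab_boot[b] <- pb$a * pb$b
    }
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(ab_boot, c(alpha, 1 - alpha),
                                 na.rm = TRUE, type = 7))
    sdb <- stats::sd(ab_boot, na.rm = TRUE)
    if (is.finite(sdb) && sdb > 0) z_ab <- ab / sdb
  }

  structure(list(a = paths$a, b_path = paths$b, c_total = paths$c_total,
                 c_prime = paths$c_prime, ab = ab, ci95_ab = ci,
                 z_ab = z_ab, n_boot = as.integer(n_boot), engine = engine,
                 degraded = degraded, n_participants = length(pids)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<mediation> a = %.4f, b = %.4f, ab = %.4f",
           " [%s, %s], c' = %.4f, c = %.4f (%s engine, %d bootstrap draws)\n"),
    x$a, x$b_path, x$ab,
    ifelse(is.na(x$ci95_ab[1]), "NA", sprintf("%.4f", x$ci95_ab[1])),
    ifelse(is.na(x$ci95_ab[2]), "NA", sprintf("%.4f", x$ci95_ab[2])),
    x$c_prime, x$c_total, x$engine, x$n_boot))
  invisible(x)
}
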
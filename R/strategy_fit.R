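# Maximum-likelihood strategy classification. Each participant-by-task block
# of choices is fit by two candidate strategies (EV and maximax) under a
# softmax choice rule with sensitivity phi >= 0; goodness of fit is the
# deviance G^2 = -2 sum ln f_j(y), compared against the random-choice
# baseline 2 N ln 2.

#' Strategy valuations for a table of gamble pairs
#'
#' Computes the subjective valuation V of each option under a strategy:
#' `V = outcome * probability` for `"EV"`, `V = outcome` for `"MAXIMAX"`.
#'
#' @param pairs A `gamble_pairs` data frame (or anything accepted by the
#'   pair-table contract).
#' @param strategy `"EV"` or `"MAXIMAX"`.
#' @return A list with numeric vectors `v_a` and `v_b`.
#' @export
strategy_valuations <- function(pairs, strategy = c("EV", "MAXIMAX")) {
  strategy <- match.arg(strategy)
  d <- as_pair_frame(pairs)
  if (strategy == "EV")
    list(v_a = d$outcome_a * d$prob_a, v_b = d$outcome_b * d$prob_b)
  else
    list(v_a = as.numeric(d$outcome_a), v_b = as.numeric(d$outcome_b))
}

#' Softmax probability of choosing option A
#'
#' The softmax choice rule gives
#' \deqn{p(A,B) = \frac{e^{\varphi V(A)}}{e^{\varphi V(A)} + e^{\varphi V(B)}}}
#' computed in the overflow-safe single-logistic form
#' `plogis(phi * (v_a - v_b))`, so arguments as large as `phi * V = 990` are
#' handled without overflow. At `phi = 0` or equal valuations the probability
#' is exactly 0.5.
#'
#' @param v_a,v_b Numeric valuations of options A and B.
#' @param phi Non-negative choice-sensitivity parameter.
#' @return Probability of choosing A, in `[0, 1]`.
#' @export
choice_probability <- function(v_a, v_b, phi) {
  if (any(phi < 0)) stop("'phi' must be non-negative", call. = FALSE)
  stopifnot(all(is.finite(v_a)), all(is.finite(v_b)))
  stats::plogis(phi * (v_a - v_b))
}

# Signed valuation difference (chosen minus unchosen) per trial, for one
# strategy. trials: data frame with pair_id and choice ("A"/"B").
chosen_value_margin <- function(trials, pairs, strategy) {
  idx <- match(trials$pair_id, pairs$pair_id)
  if (anyNA(idx))
    stop("trials reference pair_id(s) absent from the pair table",
         call. = FALSE)
  v <- strategy_valuations(pairs[idx, , drop = FALSE], strategy)
  bad <- !trials$choice %in% c("A", "B")
  if (any(bad))
    stop("choice codes must be 'A' or 'B'", call. = FALSE)
  ifelse(trials$choice == "A", v$v_a - v$v_b, v$v_b - v$v_a)
}

#' Deviance of a strategy for a set of observed choices
#'
#' Computes \eqn{G^2 = -2 \sum_j \ln f_j(y)}, where \eqn{f_j(y)} is the
#' softmax probability the strategy assigns to the choice actually made on
#' trial j. Log-probabilities are evaluated directly on the log scale, so the
#' result is finite for any finite `phi`. At `phi = 0` every trial
#' contributes `ln 2` and `g_squared = 2 N ln 2`, the random-choice baseline.
#'
#' @param trials Data frame with columns `pair_id` and `choice` (`"A"`/`"B"`).
#' @param pairs The `gamble_pairs` table the trials refer to.
#' @param strategy `"EV"` or `"MAXIMAX"`.
#' @param phi Non-negative choice sensitivity.
#' @return Non-negative deviance.
#' @export
g_squared <- function(trials, pairs, strategy = c("EV", "MAXIMAX"), phi) {
  strategy <- match.arg(strategy)
  if (nrow(trials) < 1L) stop("at least one trial is required", call. = FALSE)
  if (length(phi) != 1L || !is.finite(phi) || phi < 0)
    stop("'phi' must be a single non-negative number", call. = FALSE)
  dv <- chosen_value_margin(trials, pairs, strategy)
  -2 * sum(stats::plogis(phi * dv, log.p = TRUE))
}

#' Random-choice baseline deviance
#'
#' @param n_trials Number of binary trials.
#' @return `2 * n_trials * ln 2`.
#' @export
baseline_g2 <- function(n_trials) 2 * n_trials * log(2)

#' Fit one strategy to a participant's choices by maximum likelihood
#'
#' Minimizes [g_squared()] over the sensitivity `phi` on `[0, phi_max]`,
#' using a 50-point log-spaced grid pre-scan followed by bounded
#' golden-section refinement around the grid minimum (the grid guards against
#' stalls on the flat region where the softmax has saturated). When the
#' deviance profile is flat (degenerate stimuli with identical valuations),
#' `phi_hat` is reported as 0 by the tie rule.
#'
#' @param trials Data frame with columns `pair_id` and `choice`.
#' @param pairs The `gamble_pairs` table.
#' @param strategy `"EV"` or `"MAXIMAX"`.
#' @param phi_max Upper search bound for phi (default 10; valuations are at
#'   most 99 yuan, and the softmax is numerically saturated well before
#'   `phi * dV` reaches that scale).
#' @param tol Convergence tolerance passed to [stats::optimize()].
#' @return A list of class `"strategy_fit"` with `strategy`, `phi_hat`, `g2`,
#'   `n_trials`.
#' @export
fit_strategy <- function(trials, pairs, strategy = c("EV", "MAXIMAX"),
                         phi_max = 10, tol = 1e-6) {
  strategy <- match.arg(strategy)
  if (nrow(trials) < 1L) stop("at least one trial is required", call. = FALSE)
  dv <- chosen_value_margin(trials, pairs, strategy)
  obj <- function(phi) -2 * sum(stats::plogis(phi * dv, log.p = TRUE))

  grid <- c(0, exp(seq(log(1e-3), log(phi_max), length.out = 49)))
  vals <- vapply(grid, obj, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  best_phi <- grid[k]; best_g2 <- vals[k]
  if (hi > lo) {
    opt <- stats::optimize(obj, interval = c(lo, hi), tol = tol)
    if (opt$objective < best_g2) {
      best_phi <- opt$minimum; best_g2 <- opt$objective
    }
  }
  # tie rule: a flat profile (or no improvement over phi = 0) reports phi = 0
  if (best_g2 >= vals[1] - 1e-9) {
    best_phi <- 0; best_g2 <- vals[1]
  }
  structure(list(strategy = strategy, phi_hat = best_phi, g2 = best_g2,
                 n_trials = nrow(trials)),
            class = "strategy_fit")
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat(sprintf("<strategy_fit> %s: phi_hat = %.4f, G2 = %.3f over %d trials\n",
              x$strategy, x$phi_hat, x$g2, x$n_trials))
  invisible(x)
}

#' Classify one participant-task block of choices
#'
#' Fits both candidate strategies and assigns the label of the better-fitting
#' (lower-G2) one. The participant is labelled `"GUESS_OR_OTHER"` when the
#' best fit is no better than the random-choice baseline `2 N ln 2` (within
#' `tol`), or when the two strategies tie exactly.
#'
#' @param trials Data frame with columns `pair_id`, `choice`, and optionally
#'   `participant_id` / `task` (echoed into the result when unique).
#' @param pairs The `gamble_pairs` table.
#' @param phi_max,tol_fit Passed to [fit_strategy()].
#' @param tol Numerical tolerance for the baseline and tie comparisons.
#' @return A list of class `"classification_result"` with `label`, `fits`
#'   (both [fit_strategy()] results), `baseline_g2`, `participant_id`, `task`.
#' @export
classify_participant <- function(trials, pairs, phi_max = 10,
                                 tol_fit = 1e-6, tol = 1e-9) {
  fit_ev <- fit_strategy(trials, pairs, "EV", phi_max, tol_fit)
  fit_mm <- fit_strategy(trials, pairs, "MAXIMAX", phi_max, tol_fit)
  base <- baseline_g2(nrow(trials))
  best <- if (fit_ev$g2 <= fit_mm$g2) fit_ev else fit_mm
  tie <- abs(fit_ev$g2 - fit_mm$g2) < tol
  label <- if (best$g2 >= base - tol || tie) "GUESS_OR_OTHER" else best$strategy
  one_or_na <- function(x) {
    u <- unique(as.character(x))
    if (length(u) == 1L) u else NA_character_
  }
  structure(list(
    participant_id = if ("participant_id" %in% names(trials))
      one_or_na(trials$participant_id) else NA_character_,
    task = if ("task" %in% names(trials)) one_or_na(trials$task)
      else NA_character_,
    label = label,
    fits = list(EV = fit_ev, MAXIMAX = fit_mm),
    baseline_g2 = base
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s / %s -> %s (G2 EV %.2f, maximax %.2f, baseline %.2f)\n",
              x$participant_id, x$task, x$label,
              x$fits$EV$g2, x$fits$MAXIMAX$g2, x$baseline_g2))
  invisible(x)
}

#' Classify every participant-by-task block of a trial table
#'
#' Classification is performed separately per task, mirroring how per-task
#' strategy distributions are reported.
#'
#' @param trials Trial table with columns `participant_id`, `task`,
#'   `pair_id`, `choice`.
#' @param pairs The `gamble_pairs` table.
#' @param ... Passed to [classify_participant()].
#' @return A data frame (one row per participant x task) with columns
#'   `participant_id`, `task`, `label`, `phi_hat_ev`, `g2_ev`,
#'   `phi_hat_maximax`, `g2_maximax`, `baseline_g2`.
#' @export
classify_participants <- function(trials, pairs, ...) {
  need <- c("participant_id", "task", "pair_id", "choice")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(trials$participant_id, trials$task, drop = TRUE,
                     lex.order = TRUE)
  blocks <- split(seq_len(nrow(trials)), key)
  rows <- lapply(blocks, function(ix) {
    cr <- classify_participant(trials[ix, , drop = FALSE], pairs, ...)
    data.frame(participant_id = cr$participant_id, task = cr$task,
               label = cr$label,
               phi_hat_ev = cr$fits$EV$phi_hat, g2_ev = cr$fits$EV$g2,
               phi_hat_maximax = cr$fits$MAXIMAX$phi_hat,
               g2_maximax = cr$fits$MAXIMAX$g2,
               baseline_g2 = cr$baseline_g2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Is a choice consistent with expected-value maximization?
#'
#' @param pair A `gamble_pairs` data frame (vectorized; recycled against
#'   `choice`) or a single [gamble_pair()].
#' @param choice Character vector of `"A"`/`"B"` choices.
#' @return Logical vector: `TRUE` where the chosen option has the strictly
#'   larger expected value. Raises an error if any pair has (numerically)
#'   equal expected values, since EV-consistency is undefined there.
#' @export
ev_consistent <- function(pair, choice) {
  d <- as_pair_frame(pair)
  dev <- d$outcome_a * d$prob_a - d$outcome_b * d$prob_b
  if (any(abs(dev) < 1e-12))
    stop("pair(s) with equal expected values: EV-consistency is undefined",
         call. = FALSE)
  if (!all(choice %in% c("A", "B")))
    stop("choice codes must be 'A' or 'B'", call. = FALSE)
  ifelse(choice == "A", dev > 0, dev < 0)
}

# Trial table augmented with the model covariates used downstream: the
# EV-consistency code, |EV_A - EV_B| and |x_A - x_B|.
#' Add EV-consistency coding and difference covariates to a trial table
#'
#' @param trials Trial table with `pair_id` and `choice`.
#' @param pairs The `gamble_pairs` table.
#' @return `trials` with added columns `ev_consistent` (logical), `ev_diff`
#'   and `outcome_diff` (absolute differences, yuan).
#' @export
trials_with_ev_consistency <- function(trials, pairs) {
  idx <- match(trials$pair_id, pairs$pair_id)
  if (anyNA(idx))
    stop("trials reference pair_id(s) absent from the pair table",
         call. = FALSE)
  p <- pairs[idx, , drop = FALSE]
  trials$ev_consistent <- ev_consistent(p, trials$choice)
  trials$ev_diff <- abs(p$outcome_a * p$prob_a - p$outcome_b * p$prob_b)
  trials$outcome_diff <- abs(p$outcome_a - p$outcome_b)
  trials
}
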
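# Gambles and gamble pairs: the stimulus space is simple binary gambles in
# which each option offers one nonzero gain (1-99 yuan) with one probability
# (1-98%, whole percents). Probabilities are stored as fractions throughout;
# the integer-percent form is an I/O rendering only.

#' Construct a single risky gamble
#'
#' A gamble is one nonzero monetary outcome (in yuan) paired with the
#' probability of receiving it. Outcomes are integers between 1 and 99;
#' probabilities are whole percents between 1\% and 98\%, stored as fractions.
#'
#' @param outcome Integer outcome in yuan, between 1 and 99.
#' @param probability Probability of the outcome as a fraction; `probability *
#'   100` must be a whole number between 1 and 98.
#' @return An object of class `"gamble"` with elements `outcome` and
#'   `probability`.
#' @examples
#' g <- gamble(50, 0.50)
#' ev_value(g)
#' @export
gamble <- function(outcome, probability) {
  if (length(outcome) != 1L || length(probability) != 1L)
    stop("'outcome' and 'probability' must be scalars", call. = FALSE)
  outcome <- as.numeric(outcome)
  probability <- as.numeric(probability)
  if (!is.finite(outcome) || abs(outcome - round(outcome)) > 1e-9 ||
      outcome < 1 || outcome > 99)
    stop("outcome must be a whole number of yuan between 1 and 99", call. = FALSE)
  pct <- probability * 100
  if (!is.finite(probability) || abs(pct - round(pct)) > 1e-6 ||
      round(pct) < 1 || round(pct) > 98)
    stop("probability must be a whole percent between 1% and 98%", call. = FALSE)
  structure(list(outcome = outcome, probability = probability),
            class = "gamble")
}

#' @export
print.gamble <- function(x, ...) {
  cat(sprintf("<gamble> %d yuan with probability %d%%\n",
              as.integer(x$outcome), as.integer(round(x$probability * 100))))
  invisible(x)
}

#' Expected value of a gamble
#'
#' For a gamble with a single nonzero outcome x occurring with probability p,
#' the expected value is x * p (in yuan).
#'
#' @param g A [gamble()] object, or a numeric vector of outcomes (in which
#'   case `probability` must be supplied).
#' @param probability Numeric vector of probabilities (fractions), used when
#'   `g` is numeric. Recycled against `g`.
#' @return Numeric expected value(s) in yuan.
#' @export
ev_value <- function(g, probability = NULL) {
  if (inherits(g, "gamble")) return(g$outcome * g$probability)
  if (is.null(probability))
    stop("'probability' is required when 'g' is not a gamble object",
         call. = FALSE)
  as.numeric(g) * as.numeric(probability)
}

#' Maximax valuation of a gamble
#'
#' The maximax heuristic values an option by its maximum outcome; for a
#' one-nonzero-outcome gamble this is simply the outcome, ignoring its
#' probability.
#'
#' @param g A [gamble()] object or a numeric vector of outcomes.
#' @return Numeric outcome(s) in yuan.
#' @export
maximax_value <- function(g) {
  if (inherits(g, "gamble")) return(g$outcome)
  as.numeric(g)
}

# Coerce the accepted pair representations to a plain data.frame with columns
# outcome_a, prob_a, outcome_b, prob_b (fractions).
as_pair_frame <- function(pair) {
  if (inherits(pair, "gamble_pair")) {
    return(data.frame(outcome_a = pair$option_a$outcome,
                      prob_a = pair$option_a$probability,
                      outcome_b = pair$option_b$outcome,
                      prob_b = pair$option_b$probability))
  }
  if (is.data.frame(pair)) {
    need <- c("outcome_a", "prob_a", "outcome_b", "prob_b")
    miss <- setdiff(need, names(pair))
    if (length(miss))
      stop("pair table is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    return(pair)
  }
  stop("'pair' must be a gamble_pair or a gamble-pair data frame",
       call. = FALSE)
}

#' Construct a pair of gambles
#'
#' A gamble pair presents two options, A and B. Valid stimuli have a
#' trade-off structure: one option offers the strictly larger outcome at the
#' strictly smaller probability (the riskier option), so that neither option
#' dominates the other.
#'
#' @param option_a,option_b [gamble()] objects.
#' @param pair_id Identifier for the pair.
#' @param min_ev_gap Minimum required absolute expected-value difference
#'   between the options, in yuan. Equal-EV pairs make EV-consistency coding
#'   ambiguous, so a positive floor is enforced by default.
#' @return An object of class `"gamble_pair"` with elements `pair_id`,
#'   `option_a`, `option_b` and `risky_on_top` (`TRUE` when option A is the
#'   riskier option, i.e. the larger-outcome / smaller-probability one).
#' @export
gamble_pair <- function(option_a, option_b, pair_id = "P001",
                        min_ev_gap = 0.5) {
  stopifnot(inherits(option_a, "gamble"), inherits(option_b, "gamble"))
  p <- list(pair_id = as.character(pair_id), option_a = option_a,
            option_b = option_b)
  class(p) <- "gamble_pair"
  if (option_a$outcome == option_b$outcome &&
      option_a$probability == option_b$probability)
    stop("the two options are identical: degenerate pair", call. = FALSE)
  if (is_dominated(p))
    stop("one option dominates the other (or the options are identical); ",
         "a valid pair needs a strict outcome/probability trade-off",
         call. = FALSE)
  dev <- ev_value(option_a) - ev_value(option_b)
  if (abs(dev) < min_ev_gap)
    stop(sprintf("expected values differ by %.3f yuan, below the %.3f floor",
                 abs(dev), min_ev_gap), call. = FALSE)
  p$risky_on_top <- option_a$outcome > option_b$outcome
  p
}

#' @export
print.gamble_pair <- function(x, ...) {
  cat(sprintf("<gamble_pair %s>\n  A: %d yuan @ %d%%  (EV %.2f)\n  B: %d yuan @ %d%%  (EV %.2f)\n",
              x$pair_id,
              as.integer(x$option_a$outcome),
              as.integer(round(x$option_a$probability * 100)),
              ev_value(x$option_a),
              as.integer(x$option_b$outcome),
              as.integer(round(x$option_b$probability * 100)),
              ev_value(x$option_b)))
  invisible(x)
}

#' Test whether one option of a pair dominates the other
#'
#' Option X dominates option Y when X is at least as good on both the outcome
#' and the probability and strictly better on at least one. Identical options
#' are not a dominance relation (no strict inequality) but are equally
#' degenerate as stimuli; they are rejected by [gamble_pair()] separately.
#'
#' @param pair A [gamble_pair()] or a data frame with columns `outcome_a`,
#'   `prob_a`, `outcome_b`, `prob_b` (one row per pair; vectorized).
#' @return Logical vector, `TRUE` where a dominance relation exists.
#' @export
is_dominated <- function(pair) {
  d <- as_pair_frame(pair)
  a_dom <- d$outcome_a >= d$outcome_b & d$prob_a >= d$prob_b &
    (d$outcome_a > d$outcome_b | d$prob_a > d$prob_b)
  b_dom <- d$outcome_b >= d$outcome_a & d$prob_b >= d$prob_a &
    (d$outcome_b > d$outcome_a | d$prob_b > d$prob_a)
  a_dom | b_dom
}

#' Generate a set of gamble pairs by rejection sampling
#'
#' Outcomes are drawn uniformly from 1-99 yuan and probabilities uniformly
#' from 1-98 whole percents, and a candidate pair is kept only if it satisfies
#' the stimulus constraints, so accepted pairs are exactly uniform on the
#' constrained set.
#'
#' Both modes require a strict trade-off (no dominance) and an expected-value
#' gap of at least `min_ev_gap`. In `"exp2"` mode pairs are additionally
#' constrained so that the maximax heuristic and the EV strategy predict
#' opposite choices: the option with the larger outcome has the strictly
#' smaller expected value.
#'
#' The riskier option (larger outcome, smaller probability) is placed in the
#' A (top) slot for exactly `ceiling(n/2)` of the pairs and in the B slot for
#' the rest, with the assignment of flags to pairs randomized.
#'
#' @param n Number of pairs to generate.
#' @param mode `"exp1"` (trade-off constraint only) or `"exp2"` (strategies
#'   additionally conflict on every pair).
#' @param seed Optional integer seed; when supplied the result is a pure
#'   function of `(n, mode, seed)`.
#' @param min_ev_gap Minimum absolute EV difference in yuan (default 0.5).
#' @param unique_pairs If `TRUE`, reject candidate pairs whose unordered
#'   option set duplicates an already-accepted pair.
#' @param max_attempts Rejection-sampling budget per pair; exceeding it
#'   signals infeasible constraints and raises an error.
#' @return A data frame of class `"gamble_pairs"` with columns `pair_id`,
#'   `outcome_a`, `prob_a`, `outcome_b`, `prob_b`, `risky_on_top`.
#'   Probabilities are fractions.
#' @examples
#' pairs <- generate_pairs(10, mode = "exp2", seed = 1)
#' all(!is_dominated(pairs))
#' @export
generate_pairs <- function(n, mode = c("exp1", "exp2"), seed = NULL,
                           min_ev_gap = 0.5, unique_pairs = FALSE,
                           max_attempts = 10000) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))

  seen <- character(0)
  out_x1 <- integer(n); out_p1 <- integer(n)
  out_x2 <- integer(n); out_p2 <- integer(n)
  for (i in seq_len(n)) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "pair %d: rejection sampling exceeded %d attempts; constraints look infeasible",
          i, max_attempts), call. = FALSE)
      x1 <- sample.int(99L, 1L); x2 <- sample.int(99L, 1L)
      p1 <- sample.int(98L, 1L); p2 <- sample.int(98L, 1L)
      # trade-off: larger outcome must carry the strictly smaller probability
      tradeoff <- (x1 > x2 && p1 < p2) || (x2 > x1 && p2 < p1)
      if (!tradeoff) next
      ev1 <- x1 * p1 / 100; ev2 <- x2 * p2 / 100
      if (abs(ev1 - ev2) < min_ev_gap) next
      if (mode == "exp2" && sign(x1 - x2) != -sign(ev1 - ev2)) next
      if (unique_pairs) {
        key <- paste(sort(c(paste(x1, p1), paste(x2, p2))), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
      }
      break
    }
    out_x1[i] <- x1; out_p1[i] <- p1; out_x2[i] <- x2; out_p2[i] <- p2
  }

  # counterbalance: risky option in the A slot for ceiling(n/2) pairs
  risky_on_top <- rep(FALSE, n)
  risky_on_top[sample.int(n, ceiling(n / 2))] <- TRUE
  risky_first <- out_x1 > out_x2
  swap <- risky_first != risky_on_top
  oa <- ifelse(swap, out_x2, out_x1); pa <- ifelse(swap, out_p2, out_p1)
  ob <- ifelse(swap, out_x1, out_x2); pb <- ifelse(swap, out_p1, out_p2)

  pairs <- data.frame(
    pair_id = sprintf("P%03d", seq_len(n)),
    outcome_a = as.integer(oa), prob_a = pa / 100,
    outcome_b = as.integer(ob), prob_b = pb / 100,
    risky_on_top = risky_on_top,
    stringsAsFactors = FALSE
  )
  class(pairs) <- c("gamble_pairs", "data.frame")
  pairs
}

# Internal invariant check used by readers and simulators.
validate_gamble_pairs <- function(pairs) {
  d <- as_pair_frame(pairs)
  ok_out <- function(x) all(is.finite(x) & x == round(x) & x >= 1 & x <= 99)
  ok_pr <- function(p) {
    pct <- p * 100
    all(is.finite(p) & abs(pct - round(pct)) < 1e-6 &
          round(pct) >= 1 & round(pct) <= 98)
  }
  if (!ok_out(d$outcome_a) || !ok_out(d$outcome_b))
    stop("outcomes must be whole yuan amounts in 1-99", call. = FALSE)
  if (!ok_pr(d$prob_a) || !ok_pr(d$prob_b))
    stop("probabilities must be whole percents in 1-98 (stored as fractions)",
         call. = FALSE)
  if (any(is_dominated(d)))
    stop("dominated (or degenerate) pairs present", call. = FALSE)
  invisible(TRUE)
}
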
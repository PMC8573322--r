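# Search-direction metrics from AOI-labelled fixations. The information
# board is 2 options x 2 dimensions, with AOI codes A_PROB, A_OUT, B_PROB,
# B_OUT. Transitions between distinct AOIs are tallied as alternative-wise
# (same option, different dimension), dimension-wise (same dimension,
# different option) or diagonal (both differ), and combined into the
# Bockenholt-Hynan search measure (SM) index.

AOI_CODES <- c("A_PROB", "A_OUT", "B_PROB", "B_OUT")
TASK_CODES <- c("ALT", "DIM")

#' Remove fixations shorter than a duration threshold
#'
#' Fixations with `duration_ms` strictly below `min_ms` are excluded;
#' fixations exactly at the threshold are kept and order is preserved.
#'
#' @param fixations Data frame with (at least) a `duration_ms` column.
#' @param min_ms Threshold in milliseconds (default 50).
#' @return The filtered data frame.
#' @export
filter_fixations <- function(fixations, min_ms = 50) {
  if (!"duration_ms" %in% names(fixations))
    stop("fixation table needs a 'duration_ms' column", call. = FALSE)
  fixations[fixations$duration_ms >= min_ms, , drop = FALSE]
}

#' Count AOI transitions in one fixation sequence
#'
#' Consecutive fixations on the same AOI are merged first (a re-fixation is
#' not a transition); each step between distinct AOIs then counts once, as
#' alternative-wise (`r_alt`), dimension-wise (`r_dim`) or diagonal
#' (`r_diag`, different option and different dimension). Diagonal moves count
#' toward the total `n_total` but toward neither directional tally.
#'
#' @param aoi Character vector of AOI codes in fixation order, or a data
#'   frame with an `aoi` column.
#' @return A list of class `"transition_counts"` with `n_total`, `r_alt`,
#'   `r_dim`, `r_diag`.
#' @examples
#' count_transitions(c("A_PROB", "A_OUT", "B_OUT", "B_PROB"))
#' @export
count_transitions <- function(aoi) {
  if (is.data.frame(aoi)) {
    if (!"aoi" %in% names(aoi))
      stop("fixation table needs an 'aoi' column", call. = FALSE)
    aoi <- aoi$aoi
  }
  aoi <- as.character(aoi)
  bad <- !aoi %in% AOI_CODES
  if (any(bad))
    stop("unknown AOI code(s): ", paste(unique(aoi[bad]), collapse = ", "),
         call. = FALSE)
  runs <- rle(aoi)$values
  if (length(runs) < 2L) {
    counts <- list(n_total = 0L, r_alt = 0L, r_dim = 0L, r_diag = 0L)
    return(structure(counts, class = "transition_counts"))
  }
  from <- runs[-length(runs)]
  to <- runs[-1L]
  same_opt <- substr(from, 1L, 1L) == substr(to, 1L, 1L)
  same_dim <- substring(from, 3L) == substring(to, 3L)
  structure(list(
    n_total = length(from),
    r_alt = sum(same_opt & !same_dim),
    r_dim = sum(!same_opt & same_dim),
    r_diag = sum(!same_opt & !same_dim)
  ), class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("<transition_counts> N = %d (alt %d, dim %d, diag %d)\n",
              x$n_total, x$r_alt, x$r_dim, x$r_diag))
  invisible(x)
}

#' Bockenholt-Hynan search measure (SM) index
#'
#' For an information board with `A` alternatives and `D` dimensions,
#' \deqn{SM = \sqrt{N}\,\frac{\frac{DA}{N}(r_a - r_d) - (D - A)}
#'   {\sqrt{A^2 (D-1) + D^2 (A-1)}}}
#' where N is the total number of transitions and r_a, r_d the counts of
#' alternative-wise and dimension-wise transitions. For the 2 x 2 board this
#' reduces to `sqrt(2) * (r_alt - r_dim) / sqrt(N)`. Positive values indicate
#' predominantly alternative-wise search, negative values predominantly
#' dimension-wise search.
#'
#' @param counts A [count_transitions()] result, or a list/data-frame row
#'   with fields `n_total`, `r_alt`, `r_dim`.
#' @param n_alternatives,n_dimensions Board shape (defaults 2 and 2).
#' @return The SM index (dimensionless).
#' @export
sm_index <- function(counts, n_alternatives = 2, n_dimensions = 2) {
  N <- counts$n_total
  if (is.null(N) || any(N < 1))
    stop("SM index is undefined for n_total < 1", call. = FALSE)
  A <- n_alternatives; D <- n_dimensions
  sqrt(N) * ((D * A / N) * (counts$r_alt - counts$r_dim) - (D - A)) /
    sqrt(A^2 * (D - 1) + D^2 * (A - 1))
}

# Validate minimal fixation-table schema used by sm_per_trial().
check_fixation_table <- function(fixations) {
  need <- c("participant_id", "task", "pair_id", "aoi", "duration_ms")
  miss <- setdiff(need, names(fixations))
  if (length(miss))
    stop("fixation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Per-trial SM index for a fixation table
#'
#' Applies the duration filter, merges same-AOI re-fixations, counts
#' transitions and computes the SM index for every
#' participant-task-trial cell. Trials that retain fewer than two
#' distinct-AOI fixations have no transitions and get a missing (`NA`) SM;
#' they are excluded from the participant means computed by
#' [sm_participant_means()].
#'
#' @param fixations Fixation table with columns `participant_id`, `task`,
#'   `pair_id`, `aoi`, `duration_ms` (and optionally `fixation_index`, used
#'   to order fixations within a trial).
#' @param min_ms Duration filter threshold in ms (default 50).
#' @return Data frame with one row per trial: `participant_id`, `task`,
#'   `pair_id`, `n_total`, `r_alt`, `r_dim`, `r_diag`, `sm`.
#' @export
sm_per_trial <- function(fixations, min_ms = 50) {
  check_fixation_table(fixations)
  f <- fixations
  if ("fixation_index" %in% names(f)) {
    f <- f[order(f$participant_id, f$task, f$pair_id, f$fixation_index), ,
           drop = FALSE]
  }
  f <- filter_fixations(f, min_ms)
  # trial identity of each fixation row
  trial_key <- paste(f$participant_id, f$task, f$pair_id, sep = "\r")
  n <- nrow(f)
  if (n == 0L) {
    return(data.frame(participant_id = character(0), task = character(0),
                      pair_id = character(0), n_total = integer(0),
                      r_alt = integer(0), r_dim = integer(0),
                      r_diag = integer(0), sm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  bad <- !f$aoi %in% AOI_CODES
  if (any(bad))
    stop("unknown AOI code(s): ", paste(unique(f$aoi[bad]), collapse = ", "),
         call. = FALSE)
  # merge consecutive same-AOI fixations within a trial
  new_trial <- c(TRUE, trial_key[-1L] != trial_key[-n])
  keep <- new_trial | c(TRUE, f$aoi[-1L] != f$aoi[-n])
  g <- f[keep, , drop = FALSE]
  gkey <- trial_key[keep]
  m <- nrow(g)
  # transitions: consecutive collapsed fixations within the same trial
  same_trial <- c(FALSE, gkey[-1L] == gkey[-m])
  from <- c("", g$aoi[-m])
  to <- g$aoi
  is_trans <- same_trial
  alt <- is_trans & substr(from, 1L, 1L) == substr(to, 1L, 1L)
  dim_ <- is_trans & !alt & substring(from, 3L) == substring(to, 3L)
  diag_ <- is_trans & !alt & !dim_

  fac <- factor(gkey, levels = unique(gkey))
  agg <- data.frame(
    n_total = as.integer(rowsum(as.integer(is_trans), fac)),
    r_alt = as.integer(rowsum(as.integer(alt), fac)),
    r_dim = as.integer(rowsum(as.integer(dim_), fac)),
    r_diag = as.integer(rowsum(as.integer(diag_), fac))
  )
  first_row <- g[!duplicated(fac), c("participant_id", "task", "pair_id"),
                 drop = FALSE]
  out <- cbind(first_row, agg)
  out$sm <- ifelse(out$n_total >= 1,
                   sqrt(pmax(out$n_total, 1)) *
                     (2 * 2 / pmax(out$n_total, 1)) *
                     (out$r_alt - out$r_dim) / sqrt(8),
                   NA_real_)
  rownames(out) <- NULL
  out
}

#' Participant-by-task mean SM
#'
#' @param trial_sm Output of [sm_per_trial()].
#' @return Data frame with `participant_id`, `task`, `mean_sm`, `n_trials`
#'   (trials with a non-missing SM).
#' @export
sm_participant_means <- function(trial_sm) {
  ok <- !is.na(trial_sm$sm)
  d <- trial_sm[ok, , drop = FALSE]
  out <- stats::aggregate(list(mean_sm = d$sm),
                          by = list(participant_id = d$participant_id,
                                    task = d$task),
                          FUN = mean)
  ns <- stats::aggregate(list(n_trials = d$sm),
                         by = list(participant_id = d$participant_id,
                                   task = d$task),
                         FUN = length)
  out <- merge(out, ns, by = c("participant_id", "task"), sort = TRUE)
  out$n_trials <- as.integer(out$n_trials)
  out
}
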
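# Readers/writers for the five tabular interchange formats. Plain
# comma-delimited UTF-8 with a single header row. Probabilities are integer
# percents on disk (columns prob_pct_a / prob_pct_b) and fractions in
# memory. Readers validate the schema and report the first offending row and
# column; unknown extra columns are preserved.

read_table_checked <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(label, " table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

fail_rows <- function(bad, label, column, what) {
  if (any(bad))
    stop(sprintf("%s table row %d, column '%s': %s", label,
                 which(bad)[1L], column, what), call. = FALSE)
}

check_numeric_col <- function(df, col, label, positive = FALSE) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  fail_rows(nrow(df) > 0 & is.na(x) & !is.na(df[[col]]), label, col,
            "non-numeric cell")
  fail_rows(is.na(x), label, col, "missing value")
  if (positive) fail_rows(x <= 0, label, col, "must be > 0")
  x
}

check_code_col <- function(df, col, label, codes) {
  x <- as.character(df[[col]])
  fail_rows(!x %in% codes, label, col,
            paste0("invalid code (expected one of ",
                   paste(codes, collapse = ", "), ")"))
  x
}

#' Write / read a gamble-pair table
#'
#' On disk: `pair_id, outcome_a, prob_pct_a, outcome_b, prob_pct_b,
#' risky_on_top`, with probabilities as integer percents. In memory
#' probabilities are fractions (`prob_a`, `prob_b`).
#'
#' @param pairs A `gamble_pairs` data frame.
#' @param path File path.
#' @return `write_gamble_table` returns `path` invisibly;
#'   `read_gamble_table` returns a validated `gamble_pairs` data frame.
#' @export
write_gamble_table <- function(pairs, path) {
  validate_gamble_pairs(pairs)
  out <- data.frame(pair_id = pairs$pair_id,
                    outcome_a = as.integer(pairs$outcome_a),
                    prob_pct_a = as.integer(round(pairs$prob_a * 100)),
                    outcome_b = as.integer(pairs$outcome_b),
                    prob_pct_b = as.integer(round(pairs$prob_b * 100)),
                    risky_on_top = pairs$risky_on_top,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(pairs),
                   c("pair_id", "outcome_a", "prob_a", "outcome_b",
                     "prob_b", "risky_on_top"))
  if (length(extra)) out <- cbind(out, pairs[, extra, drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gamble_table
#' @export
read_gamble_table <- function(path) {
  label <- "gamble"
  df <- read_table_checked(path, c("pair_id", "outcome_a", "prob_pct_a",
                                   "outcome_b", "prob_pct_b",
                                   "risky_on_top"), label)
  if (nrow(df) == 0L) {
    out <- data.frame(pair_id = character(0), outcome_a = integer(0),
                      prob_a = numeric(0), outcome_b = integer(0),
                      prob_b = numeric(0), risky_on_top = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("gamble_pairs", "data.frame")
    return(out)
  }
  oa <- check_numeric_col(df, "outcome_a", label)
  ob <- check_numeric_col(df, "outcome_b", label)
  pa <- check_numeric_col(df, "prob_pct_a", label)
  pb <- check_numeric_col(df, "prob_pct_b", label)
  fail_rows(pa != round(pa) | pa < 1 | pa > 98, label, "prob_pct_a",
            "must be a whole percent in 1-98")
  fail_rows(pb != round(pb) | pb < 1 | pb > 98, label, "prob_pct_b",
            "must be a whole percent in 1-98")
  rot <- df$risky_on_top
  if (is.character(rot)) rot <- toupper(rot) %in% c("TRUE", "T", "1")
  out <- data.frame(pair_id = as.character(df$pair_id),
                    outcome_a = as.integer(oa), prob_a = pa / 100,
                    outcome_b = as.integer(ob), prob_b = pb / 100,
                    risky_on_top = as.logical(rot),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("pair_id", "outcome_a", "prob_pct_a",
                                "outcome_b", "prob_pct_b", "risky_on_top"))
  if (length(extra)) out <- cbind(out, df[, extra, drop = FALSE])
  validate_gamble_pairs(out)
  class(out) <- c("gamble_pairs", "data.frame")
  out
}

#' Write / read a trial table
#'
#' Columns: `participant_id, task, pair_id, choice, rt_s, task_order`
#' (`task_order` optional on read).
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  label <- "trial"
  df <- read_table_checked(path, c("participant_id", "task", "pair_id",
                                   "choice", "rt_s"), label)
  if (nrow(df) == 0L) return(df)
  df$task <- check_code_col(df, "task", label, TASK_CODES)
  df$choice <- check_code_col(df, "choice", label, c("A", "B"))
  df$rt_s <- check_numeric_col(df, "rt_s", label, positive = TRUE)
  df$participant_id <- as.character(df$participant_id)
  df$pair_id <- as.character(df$pair_id)
  df
}

#' Write / read a fixation table
#'
#' Columns: `participant_id, task, pair_id, fixation_index, aoi,
#' duration_ms`, AOI codes among `A_PROB, A_OUT, B_PROB, B_OUT`.
#'
#' @param fixations Fixation data frame.
#' @param path File path.
#' @export
write_fixation_table <- function(fixations, path) {
  utils::write.csv(fixations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixation_table
#' @export
read_fixation_table <- function(path) {
  label <- "fixation"
  df <- read_table_checked(path, c("participant_id", "task", "pair_id",
                                   "fixation_index", "aoi", "duration_ms"),
                           label)
  if (nrow(df) == 0L) return(df)
  df$task <- check_code_col(df, "task", label, TASK_CODES)
  df$aoi <- check_code_col(df, "aoi", label, AOI_CODES)
  df$fixation_index <- check_numeric_col(df, "fixation_index", label)
  df$duration_ms <- check_numeric_col(df, "duration_ms", label,
                                      positive = TRUE)
  df$participant_id <- as.character(df$participant_id)
  df$pair_id <- as.character(df$pair_id)
  df
}

#' Write / read a per-trial SM table
#'
#' Columns: `participant_id, task, pair_id, n_total, r_alt, r_dim, r_diag,
#' sm` (missing SM written as empty).
#'
#' @param sm_table SM data frame, as produced by [sm_per_trial()].
#' @param path File path.
#' @export
write_sm_table <- function(sm_table, path) {
  utils::write.csv(sm_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sm_table
#' @export
read_sm_table <- function(path) {
  label <- "sm"
  df <- read_table_checked(path, c("participant_id", "task", "pair_id",
                                   "n_total", "r_alt", "r_dim", "r_diag",
                                   "sm"), label)
  if (nrow(df) == 0L) return(df)
  df$task <- check_code_col(df, "task", label, TASK_CODES)
  for (col in c("n_total", "r_alt", "r_dim", "r_diag"))
    df[[col]] <- as.integer(check_numeric_col(df, col, label))
  df$sm <- suppressWarnings(as.numeric(df$sm))
  df$participant_id <- as.character(df$participant_id)
  df$pair_id <- as.character(df$pair_id)
  df
}

#' Write / read a classification report
#'
#' Columns: `participant_id, task, label, phi_hat_ev, g2_ev,
#' phi_hat_maximax, g2_maximax, baseline_g2`.
#'
#' @param classification Data frame from [classify_participants()].
#' @param path File path.
#' @export
write_classification_table <- function(classification, path) {
  utils::write.csv(classification, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classification_table
#' @export
read_classification_table <- function(path) {
  label <- "classification"
  df <- read_table_checked(path, c("participant_id", "task", "label",
                                   "phi_hat_ev", "g2_ev", "phi_hat_maximax",
                                   "g2_maximax", "baseline_g2"), label)
  if (nrow(df) == 0L) return(df)
  df$task <- check_code_col(df, "task", label, TASK_CODES)
  df$label <- check_code_col(df, "label", label,
                             c("EV", "MAXIMAX", "GUESS_OR_OTHER"))
  for (col in c("phi_hat_ev", "g2_ev", "phi_hat_maximax", "g2_maximax",
                "baseline_g2"))
    df[[col]] <- check_numeric_col(df, col, label)
  df$participant_id <- as.character(df$participant_id)
  df
}
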
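# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Simulate choices for one agent on a pair set, directly from the softmax
# (no search coupling), and return a trial table usable by the fitters.
simulate_agent_trials <- function(pairs, strategy, phi,
                                  participant_id = "S001", task = "ALT") {
  v <- strategy_valuations(pairs, if (strategy == "GUESS") "EV" else strategy)
  p_a <- if (strategy == "GUESS") rep(0.5, nrow(pairs)) else
    choice_probability(v$v_a, v$v_b, phi)
  data.frame(participant_id = participant_id, task = task,
             pair_id = pairs$pair_id,
             choice = ifelse(runif(nrow(pairs)) < p_a, "A", "B"),
             stringsAsFactors = FALSE)
}

# Small two-task multi-participant trial table with independent softmax
# choices (per-task phi), for the regression models.
simulate_two_task_trials <- function(pairs, n_participants, phi_alt, phi_dim,
                                     strategy = "EV") {
  rows <- lapply(seq_len(n_participants), function(i) {
    id <- sprintf("S%03d", i)
    rbind(simulate_agent_trials(pairs, strategy, phi_alt, id, "ALT"),
          simulate_agent_trials(pairs, strategy, phi_dim, id, "DIM"))
  })
  out <- do.call(rbind, rows)
  out$rt_s <- exp(log(4) + 0.16 * (out$task == "ALT") + rnorm(nrow(out), 0, 0.3))
  out
}

# Independent brute-force transition counter: pairwise scan after an
# explicit merge loop, no shared code with count_transitions().
brute_force_counts <- function(aoi) {
  merged <- character(0)
  for (a in aoi) {
    if (length(merged) == 0L || merged[length(merged)] != a)
      merged <- c(merged, a)
  }
  n <- 0L; ra <- 0L; rd <- 0L; dg <- 0L
  if (length(merged) >= 2L) {
    for (i in 2:length(merged)) {
      f <- merged[i - 1L]; t <- merged[i]
      n <- n + 1L
      fo <- substr(f, 1, 1); to <- substr(t, 1, 1)
      fd <- sub("^[AB]_", "", f); td <- sub("^[AB]_", "", t)
      if (fo == to && fd != td) ra <- ra + 1L
      else if (fo != to && fd == td) rd <- rd + 1L
      else dg <- dg + 1L
    }
  }
  list(n_total = n, r_alt = ra, r_dim = rd, r_diag = dg)
}
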
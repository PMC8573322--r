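# Synthetic participants. Agents hold a decision strategy (EV, maximax, or
# guessing), a softmax sensitivity phi, per-task search biases governing a
# Markov walk over the four AOIs, and log-normal response-time parameters
# with a task effect and an EV-difference effect. The generator reproduces
# the statistical structure the downstream analysis assumes, so the whole
# pipeline is testable without any external data.

#' Specify a synthetic participant
#'
#' @param participant_id Identifier.
#' @param strategy `"EV"`, `"MAXIMAX"` or `"GUESS"`.
#' @param phi Softmax sensitivity (ignored for `"GUESS"` agents). Either a
#'   single non-negative number or a named vector `c(ALT = , DIM = )` for
#'   task-dependent sensitivity.
#' @param search_bias Named vector `c(ALT = , DIM = )` in `[0, 1]`: the
#'   probability that a fixation transition is alternative-wise (within
#'   option) rather than dimension-wise (within dimension), per task.
#' @param rt_params List with `baseline_log_s`, `task_effect_log_s`,
#'   `ev_slope_per_yuan`, `noise_sd_log_s` (log-seconds scale; see
#'   [simulate_rt()]).
#' @return An object of class `"agent_spec"`.
#' @export
agent_spec <- function(participant_id,
                       strategy = c("EV", "MAXIMAX", "GUESS"),
                       phi = 0.5,
                       search_bias = c(ALT = 0.9, DIM = 0.1),
                       rt_params = default_rt_params()) {
  strategy <- match.arg(strategy)
  if (any(!is.finite(phi)) || any(phi < 0))
    stop("'phi' must be non-negative", call. = FALSE)
  if (length(phi) > 1L && !all(TASK_CODES %in% names(phi)))
    stop("a task-dependent 'phi' must be named c(ALT = , DIM = )",
         call. = FALSE)
  if (!all(TASK_CODES %in% names(search_bias)))
    stop("'search_bias' must be named c(ALT = , DIM = )", call. = FALSE)
  if (any(search_bias < 0 | search_bias > 1))
    stop("'search_bias' entries must lie in [0, 1]", call. = FALSE)
  need <- c("baseline_log_s", "task_effect_log_s", "ev_slope_per_yuan",
            "noise_sd_log_s")
  miss <- setdiff(need, names(rt_params))
  if (length(miss))
    stop("rt_params is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (rt_params$noise_sd_log_s <= 0 && rt_params$noise_sd_log_s != 0)
    stop("noise_sd_log_s must be non-negative", call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 strategy = strategy, phi = phi,
                 search_bias = search_bias, rt_params = rt_params),
            class = "agent_spec")
}

#' Default response-time parameters
#'
#' Baseline median decision time of about 4.1 s in the dimension-wise task, a
#' +0.16 log-seconds effect of the alternative-wise task, a -0.006
#' log-seconds-per-yuan effect of the absolute EV difference, residual
#' log-normal noise with SD 0.35, and a between-participant baseline SD of
#' 0.15 log-seconds (used by [simulate_experiment()]; ignored by the
#' single-trial [simulate_rt()]).
#'
#' @return Named list of parameters.
#' @export
default_rt_params <- function() {
  list(baseline_log_s = log(4.1), task_effect_log_s = 0.16,
       ev_slope_per_yuan = 0.006, noise_sd_log_s = 0.35,
       participant_sd_log_s = 0.15)
}

agent_phi <- function(agent, task) {
  if (length(agent$phi) > 1L) unname(agent$phi[[task]]) else agent$phi
}

#' Simulate one choice from an agent on a gamble pair
#'
#' The choice is a Bernoulli draw with P(A) given by the softmax over the
#' agent's strategy valuations; `"GUESS"` agents choose A with probability
#' 0.5.
#'
#' @param agent An [agent_spec()].
#' @param pair A one-row `gamble_pairs` data frame or [gamble_pair()].
#' @param task Task code (`"ALT"`/`"DIM"`), used only to resolve a
#'   task-dependent `phi`.
#' @return `"A"` or `"B"`.
#' @export
simulate_choice <- function(agent, pair, task = "ALT") {
  p_a <- if (agent$strategy == "GUESS") 0.5 else {
    v <- strategy_valuations(as_pair_frame(pair), agent$strategy)
    choice_probability(v$v_a[1L], v$v_b[1L], agent_phi(agent, task))
  }
  if (stats::runif(1) < p_a) "A" else "B"
}

#' Simulate an AOI fixation sequence as a biased Markov walk
#'
#' Starting from a uniformly drawn AOI, each of `n_transitions` steps is
#' alternative-wise (stay within the current option, switch dimension) with
#' probability `bias_alt` under the `"ALT"` task or `bias_dim` under `"DIM"`,
#' and dimension-wise (stay within the dimension, switch option) otherwise.
#' Durations are drawn log-normal (median `exp(dur_meanlog)` ms) and, by
#' default, truncated below 60 ms so that the standard 50 ms fixation filter
#' is a no-op unless sub-50 ms fixations are injected deliberately by setting
#' `min_duration_ms` to 0.
#'
#' @param task `"ALT"` or `"DIM"`.
#' @param bias_alt,bias_dim Per-task alternative-wise transition
#'   probabilities in `[0, 1]`.
#' @param n_transitions Number of transitions (>= 1); the sequence has
#'   `n_transitions + 1` fixations.
#' @param dur_meanlog,dur_sdlog Log-normal duration parameters (ms scale);
#'   defaults give a 250 ms median with sigma_log 0.4.
#' @param min_duration_ms Lower truncation for durations (resampling);
#'   default 60 ms, set 0 to disable.
#' @return Data frame with columns `fixation_index`, `aoi`, `duration_ms`.
#' @export
simulate_fixations <- function(task = c("ALT", "DIM"), bias_alt = 0.9,
                               bias_dim = 0.1, n_transitions,
                               dur_meanlog = log(250), dur_sdlog = 0.4,
                               min_duration_ms = 60) {
  task <- match.arg(task)
  if (!is.numeric(n_transitions) || n_transitions < 1)
    stop("'n_transitions' must be >= 1", call. = FALSE)
  n_transitions <- as.integer(n_transitions)
  bias <- if (task == "ALT") bias_alt else bias_dim
  if (bias < 0 || bias > 1) stop("bias must lie in [0, 1]", call. = FALSE)
  n_fix <- n_transitions + 1L
  alt_move <- stats::runif(n_transitions) < bias
  opt0 <- sample(0:1, 1L)
  dim0 <- sample(0:1, 1L)
  # alternative-wise move toggles the dimension; dimension-wise toggles option
  dims <- (dim0 + cumsum(c(0L, as.integer(alt_move)))) %% 2L
  opts <- (opt0 + cumsum(c(0L, as.integer(!alt_move)))) %% 2L
  aoi <- paste0(c("A", "B")[opts + 1L], "_", c("PROB", "OUT")[dims + 1L])
  dur <- stats::rlnorm(n_fix, dur_meanlog, dur_sdlog)
  if (min_duration_ms > 0) {
    while (any(short <- dur < min_duration_ms))
      dur[short] <- stats::rlnorm(sum(short), dur_meanlog, dur_sdlog)
  }
  data.frame(fixation_index = seq_len(n_fix), aoi = aoi, duration_ms = dur,
             stringsAsFactors = FALSE)
}

#' Simulate a response time for one trial
#'
#' `rt = exp(baseline + task_effect * [task == "ALT"] - ev_slope * |dEV| +
#' Normal(0, noise_sd))` seconds: log-normal decision times with a task
#' effect and a (negative) effect of the absolute expected-value difference.
#'
#' @param agent An [agent_spec()] (supplies `rt_params`).
#' @param task `"ALT"` or `"DIM"`.
#' @param pair A one-row `gamble_pairs` data frame or [gamble_pair()].
#' @return Response time in seconds (strictly positive).
#' @export
simulate_rt <- function(agent, task = c("ALT", "DIM"), pair) {
  task <- match.arg(task)
  p <- as_pair_frame(pair)
  dev <- abs(p$outcome_a[1L] * p$prob_a[1L] - p$outcome_b[1L] * p$prob_b[1L])
  rp <- agent$rt_params
  mu <- rp$baseline_log_s + rp$task_effect_log_s * (task == "ALT") -
    rp$ev_slope_per_yuan * dev
  exp(mu + stats::rnorm(1L, 0, rp$noise_sd_log_s))
}

# Deterministic per-participant substream seed derived from the global seed.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629)
}

#' Simulate a full within-subject experiment
#'
#' Every participant completes both tasks on the same stimulus set, task
#' order counterbalanced across participants (odd-numbered participants do
#' the alternative-wise task first). Per trial, a fixation walk is drawn
#' first; the choice is then drawn conditional on the trial's realized
#' search direction when `coupling > 0` (see Details), and a response time is
#' drawn last.
#'
#' @details With coupling strength `kappa = coupling` and a trial whose
#' non-diagonal transitions have alternative-wise share `s`, an EV-strategy
#' agent values the options by the EV rule with probability
#' `1 - kappa * (1 - s)` and by the maximax rule otherwise; a maximax agent
#' uses the maximax rule with probability `1 - kappa * s`. This makes the
#' task -> search direction -> strategy -> choice chain generative: tasks
#' shift the search bias, the realized search direction shifts which rule
#' values the options, and the rule determines EV-consistency. `coupling = 0`
#' gives agents that follow their nominal strategy on every trial; `"GUESS"`
#' agents are unaffected.
#'
#' @param config A [pipeline_config()] (or a list accepted by it).
#' @return A list of class `"rc_experiment"` with elements `pairs`, `agents`
#'   (one row per participant), `trials` (participant_id, task, pair_id,
#'   choice, rt_s, task_order) and `fixations` (participant_id, task,
#'   pair_id, fixation_index, aoi, duration_ms).
#' @export
simulate_experiment <- function(config = pipeline_config()) {
  config <- as_pipeline_config(config)
  set.seed(config$seed)
  pairs <- generate_pairs(config$n_pairs, config$stimulus_mode,
                          min_ev_gap = config$min_ev_gap)

  n <- config$n_participants
  strategies <- sample(names(config$agent_mixture), n, replace = TRUE,
                       prob = config$agent_mixture)
  phis <- if (is.list(config$phi)) {
    stats::rlnorm(n, config$phi$meanlog, config$phi$sdlog)
  } else rep(list(config$phi), n)
  ids <- sprintf("S%03d", seq_len(n))
  task_order <- rep(c("ALT_first", "DIM_first"), length.out = n)

  vals_ev <- strategy_valuations(pairs, "EV")
  vals_mm <- strategy_valuations(pairs, "MAXIMAX")
  ev_gap <- abs(vals_ev$v_a - vals_ev$v_b)
  rp <- config$rt_params
  kappa <- config$coupling

  tr_pid <- list(); tr_task <- list(); tr_choice <- list(); tr_rt <- list()
  fx <- list()
  fi <- 0L
  part_sd <- if (is.null(rp$participant_sd_log_s)) 0 else
    rp$participant_sd_log_s
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    u_i <- stats::rnorm(1L, 0, part_sd)  # participant RT baseline shift
    agent_strategy <- strategies[i]
    phi_i <- if (is.list(config$phi)) phis[i][[1]] else config$phi
    tasks <- if (task_order[i] == "ALT_first") c("ALT", "DIM") else
      c("DIM", "ALT")
    for (task in tasks) {
      phi_t <- if (length(phi_i) > 1L) unname(phi_i[[task]]) else phi_i
      bias <- if (task == "ALT") config$bias_alt else config$bias_dim
      m <- nrow(pairs)
      nt <- stats::rpois(m, config$transitions_lambda) + 1L
      choices <- character(m)
      rts <- numeric(m)
      for (j in seq_len(m)) {
        f <- simulate_fixations(task, config$bias_alt, config$bias_dim,
                                nt[j], config$fixation_meanlog,
                                config$fixation_sdlog,
                                config$min_fixation_ms)
        cnt <- count_transitions(f$aoi)
        s_alt <- if ((cnt$r_alt + cnt$r_dim) > 0)
          cnt$r_alt / (cnt$r_alt + cnt$r_dim) else 0.5
        if (agent_strategy == "GUESS") {
          p_a <- 0.5
        } else {
          p_ev_rule <- if (agent_strategy == "EV") 1 - kappa * (1 - s_alt)
            else kappa * s_alt
          rule <- if (stats::runif(1) < p_ev_rule) "EV" else "MAXIMAX"
          v <- if (rule == "EV") vals_ev else vals_mm
          p_a <- choice_probability(v$v_a[j], v$v_b[j], phi_t)
        }
        choices[j] <- if (stats::runif(1) < p_a) "A" else "B"
        mu <- rp$baseline_log_s + u_i +
          rp$task_effect_log_s * (task == "ALT") -
          rp$ev_slope_per_yuan * ev_gap[j]
        rts[j] <- exp(mu + stats::rnorm(1L, 0, rp$noise_sd_log_s))
        fi <- fi + 1L
        f$participant_id <- ids[i]
        f$task <- task
        f$pair_id <- pairs$pair_id[j]
        fx[[fi]] <- f
      }
      tr_pid[[length(tr_pid) + 1L]] <- rep(ids[i], m)
      tr_task[[length(tr_task) + 1L]] <- rep(task, m)
      tr_choice[[length(tr_choice) + 1L]] <- choices
      tr_rt[[length(tr_rt) + 1L]] <- rts
    }
  }

  trials <- data.frame(
    participant_id = unlist(tr_pid),
    task = unlist(tr_task),
    pair_id = rep(pairs$pair_id, times = 2L * n),
    choice = unlist(tr_choice),
    rt_s = unlist(tr_rt),
    stringsAsFactors = FALSE
  )
  trials$task_order <- task_order[match(trials$participant_id, ids)]
  fixations <- do.call(rbind, fx)
  fixations <- fixations[, c("participant_id", "task", "pair_id",
                             "fixation_index", "aoi", "duration_ms")]
  rownames(fixations) <- NULL
  agents <- data.frame(
    participant_id = ids, strategy = strategies,
    phi = if (is.list(config$phi)) unlist(phis) else
      vapply(phis, function(x) if (length(x) > 1L) mean(x) else x,
             numeric(1)),
    task_order = task_order, stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, agents = agents, trials = trials,
                 fixations = fixations, config = config),
            class = "rc_experiment")
}

#' @export
print.rc_experiment <- function(x, ...) {
  cat(sprintf(
    "<rc_experiment> %d participants x 2 tasks x %d pairs (%s stimuli): %d trials, %d fixations\n",
    nrow(x$agents), nrow(x$pairs), x$config$stimulus_mode, nrow(x$trials),
    nrow(x$fixations)))
  invisible(x)
}
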
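# Pipeline driver: generate -> simulate -> classify -> smindex -> analyze ->
# mediate, fully deterministic given the config seed. Each stage logs a
# stage-tagged line to standard error; a stage failure is logged and the
# driver returns a partial result naming the failed stage.

#' Pipeline configuration
#'
#' Collects every knob of the simulation-and-analysis pipeline, with defaults
#' matching the study conditions the pipeline emulates: 50 participants, 60
#' strategy-conflict (`"exp2"`) gamble pairs, a within-subject two-task
#' design, strongly alternative-wise search under the ALT task (bias 0.9) and
#' strongly dimension-wise search under the DIM task (bias 0.1), and a
#' 5,000-resample mediation bootstrap.
#'
#' @param seed Integer seed; the whole run is a pure function of the config.
#' @param n_participants Number of synthetic participants.
#' @param n_pairs Number of gamble pairs.
#' @param stimulus_mode `"exp2"` (EV and maximax conflict on every pair) or
#'   `"exp1"`.
#' @param agent_mixture Named proportions over `EV`, `MAXIMAX`, `GUESS`;
#'   must sum to 1.
#' @param phi Softmax sensitivity: a single value, a named per-task vector
#'   `c(ALT = , DIM = )`, or `list(meanlog = , sdlog = )` for log-normal
#'   heterogeneity across participants.
#' @param coupling Search-to-strategy coupling strength in `[0, 1]` (see
#'   [simulate_experiment()]); 0 switches the mediation chain off.
#' @param bias_alt,bias_dim Alternative-wise transition probability under the
#'   ALT and DIM tasks.
#' @param rt_params Response-time parameters, see [default_rt_params()].
#' @param transitions_lambda Poisson mean for transitions per trial (the
#'   count used is `rpois(lambda) + 1`).
#' @param fixation_meanlog,fixation_sdlog Log-normal fixation-duration
#'   parameters (ms scale).
#' @param min_fixation_ms Lower truncation of simulated durations (default
#'   60 ms, so the 50 ms analysis filter is a no-op unless set below 50).
#' @param min_ev_gap Minimum |EV difference| of generated pairs, yuan.
#' @param n_boot Mediation bootstrap resamples.
#' @param mediation_engine `"mixed"` or `"fixed"`, see
#'   [mediation_analysis()].
#' @param output_dir Optional directory: when set, [run_pipeline()] writes
#'   all tables, a results file and a run manifest there.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_participants = 50L,
                            n_pairs = 60L,
                            stimulus_mode = c("exp2", "exp1"),
                            agent_mixture = c(EV = 0.9, MAXIMAX = 0.05,
                                              GUESS = 0.05),
                            phi = list(meanlog = log(0.5), sdlog = 0.3),
                            coupling = 0.3,
                            bias_alt = 0.9,
                            bias_dim = 0.1,
                            rt_params = default_rt_params(),
                            transitions_lambda = 8,
                            fixation_meanlog = log(250),
                            fixation_sdlog = 0.4,
                            min_fixation_ms = 60,
                            min_ev_gap = 0.5,
                            n_boot = 5000L,
                            mediation_engine = c("mixed", "fixed"),
                            output_dir = NULL) {
  stimulus_mode <- match.arg(stimulus_mode)
  mediation_engine <- match.arg(mediation_engine)
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("'seed' must be a single integer", call. = FALSE)
  for (nm in c("n_participants", "n_pairs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("'", nm, "' must be a positive integer", call. = FALSE)
  }
  if (abs(sum(agent_mixture) - 1) > 1e-9)
    stop("agent_mixture proportions must sum to 1", call. = FALSE)
  if (!all(names(agent_mixture) %in% c("EV", "MAXIMAX", "GUESS")) ||
      is.null(names(agent_mixture)))
    stop("agent_mixture must be named over EV / MAXIMAX / GUESS",
         call. = FALSE)
  if (any(agent_mixture < 0))
    stop("agent_mixture proportions must be non-negative", call. = FALSE)
  for (nm in c("coupling", "bias_alt", "bias_dim")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (is.list(phi)) {
    if (!all(c("meanlog", "sdlog") %in% names(phi)))
      stop("a distributional 'phi' must be list(meanlog = , sdlog = )",
           call. = FALSE)
  } else if (any(phi < 0)) {
    stop("'phi' must be non-negative", call. = FALSE)
  }
  if (n_boot < 0 || n_boot != round(n_boot))
    stop("'n_boot' must be a non-negative integer", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 n_pairs = as.integer(n_pairs),
                 stimulus_mode = stimulus_mode,
                 agent_mixture = agent_mixture, phi = phi,
                 coupling = coupling, bias_alt = bias_alt,
                 bias_dim = bias_dim, rt_params = rt_params,
                 transitions_lambda = transitions_lambda,
                 fixation_meanlog = fixation_meanlog,
                 fixation_sdlog = fixation_sdlog,
                 min_fixation_ms = min_fixation_ms,
                 min_ev_gap = min_ev_gap, n_boot = as.integer(n_boot),
                 mediation_engine = mediation_engine,
                 output_dir = output_dir),
            class = "pipeline_config")
}

as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.list(x)) return(do.call(pipeline_config, x))
  stop("'config' must be a pipeline_config or a named list", call. = FALSE)
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package", call. = FALSE)
  raw <- yaml::read_yaml(path)
  if ("agent_mixture" %in% names(raw))
    raw$agent_mixture <- unlist(raw$agent_mixture)
  if ("phi" %in% names(raw) && is.list(raw$phi) &&
      !all(c("meanlog", "sdlog") %in% names(raw$phi)))
    raw$phi <- unlist(raw$phi)
  if ("rt_params" %in% names(raw)) raw$rt_params <- as.list(raw$rt_params)
  do.call(pipeline_config, raw)
}

pipe_log <- function(stage, msg, quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' Executes generate, simulate, classify, smindex, analyze (choice and
#' decision-time models plus the per-task classification-proportion z test)
#' and mediate, in order. With `config$output_dir` set, all tables, a
#' machine-readable results file (`results.csv`: one record per model term)
#' and a run manifest (`manifest.txt`: config echo, seed, versions) are
#' written there. The run is fully deterministic given the config.
#'
#' A stage failure is logged to standard error and the driver returns the
#' results of the completed stages with `status = "partial"` and the failed
#' stage's name and error message.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return List of class `"pipeline_result"`: `config`, `status`
#'   (`"complete"` or `"partial"`), possibly `failed_stage` / `error`, and
#'   stage outputs `pairs`, `trials`, `fixations`, `agents`,
#'   `classification`, `class_test`, `sm_trials`, `sm_participants`,
#'   `choice_model`, `rt_model`, `mediation`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  config <- as_pipeline_config(config)
  res <- list(config = config, status = "complete")
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  run_stage <- function(stage, expr) {
    pipe_log(stage, "starting", quiet)
    tryCatch(list(ok = TRUE, value = expr),
             error = function(e) {
               message(sprintf("[%s] FAILED: %s", stage, conditionMessage(e)))
               list(ok = FALSE, error = conditionMessage(e))
             })
  }

  # generate + simulate (one seeded draw covers both)
  st <- run_stage("simulate", simulate_experiment(config))
  if (!st$ok) {
    res$status <- "partial"; res$failed_stage <- "simulate"
    res$error <- st$error
    return(structure(res, class = "pipeline_result"))
  }
  exp_data <- st$value
  res$pairs <- exp_data$pairs
  res$agents <- exp_data$agents
  res$trials <- exp_data$trials
  res$fixations <- exp_data$fixations
  pipe_log("simulate",
           sprintf("%d trials, %d fixations", nrow(res$trials),
                   nrow(res$fixations)), quiet)
  if (!is.null(outdir)) {
    write_gamble_table(res$pairs, file.path(outdir, "gambles.csv"))
    write_trial_table(res$trials, file.path(outdir, "trials.csv"))
    write_fixation_table(res$fixations, file.path(outdir, "fixations.csv"))
  }

  stages <- list(
    classify = function(res) {
      cls <- classify_participants(res$trials, res$pairs)
      k <- function(task) sum(cls$label == "EV" & cls$task == task)
      n <- function(task) sum(cls$task == task)
      res$classification <- cls
      res$class_test <- c(
        compare_classification_proportions(k("ALT"), n("ALT"),
                                           k("DIM"), n("DIM")),
        list(k_alt = k("ALT"), n_alt = n("ALT"),
             k_dim = k("DIM"), n_dim = n("DIM")))
      if (!is.null(res$config$output_dir))
        write_classification_table(cls, file.path(res$config$output_dir,
                                                  "classification.csv"))
      res
    },
    smindex = function(res) {
      res$sm_trials <- sm_per_trial(res$fixations)
      res$sm_participants <- sm_participant_means(res$sm_trials)
      if (!is.null(res$config$output_dir))
        write_sm_table(res$sm_trials,
                       file.path(res$config$output_dir, "sm_trials.csv"))
      res
    },
    analyze = function(res) {
      res$choice_model <- fit_choice_model(res$trials, res$pairs)
      res$rt_model <- fit_rt_model(res$trials, res$pairs)
      res
    },
    mediate = function(res) {
      d <- trials_with_ev_consistency(res$trials, res$pairs)
      key_d <- paste(d$participant_id, d$task, d$pair_id)
      key_s <- paste(res$sm_trials$participant_id, res$sm_trials$task,
                     res$sm_trials$pair_id)
      d$sm <- res$sm_trials$sm[match(key_d, key_s)]
      res$mediation <- mediation_analysis(
        d, n_boot = res$config$n_boot,
        seed = substream_seed(res$config$seed, 999983L),
        engine = res$config$mediation_engine)
      res
    }
  )
  for (stage in names(stages)) {
    st <- run_stage(stage, stages[[stage]](res))
    if (!st$ok) {
      res$status <- "partial"; res$failed_stage <- stage
      res$error <- st$error
      break
    }
    res <- st$value
    res$status <- "complete"
  }

  if (!is.null(outdir)) {
    write_results_files(res, outdir)
    write_manifest(res, file.path(outdir, "manifest.txt"))
  }
  structure(res, class = "pipeline_result")
}

# One record per model term: machine-readable results.
pipeline_results_table <- function(res) {
  rows <- list()
  add <- function(model, term, estimate, ci_low = NA, ci_high = NA,
                  statistic = NA, p = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, term = term, estimate = estimate, ci_low = ci_low,
      ci_high = ci_high, statistic = statistic, p = p,
      stringsAsFactors = FALSE)
  }
  if (!is.null(res$choice_model)) {
    cm <- res$choice_model
    add("choice_logistic", "task", cm$b, cm$ci95[1], cm$ci95[2],
        cm$statistic, cm$p_value)
    add("choice_logistic", "task_odds_ratio", cm$odds_ratio,
        cm$or_ci95[1], cm$or_ci95[2])
  }
  if (!is.null(res$rt_model)) {
    for (i in seq_len(nrow(res$rt_model$terms))) {
      r <- res$rt_model$terms[i, ]
      add("rt_linear", r$term, r$estimate, r$ci_low, r$ci_high,
          r$statistic, r$p_value)
    }
  }
  if (!is.null(res$class_test)) {
    ct <- res$class_test
    add("classification_z", "prop_ev_alt", ct$p1)
    add("classification_z", "prop_ev_dim", ct$p2)
    add("classification_z", "z", ct$z, statistic = ct$z,
        p = ct$p_one_tailed)
  }
  if (!is.null(res$mediation)) {
    md <- res$mediation
    add("mediation", "a", md$a)
    add("mediation", "b", md$b_path)
    add("mediation", "ab", md$ab, md$ci95_ab[1], md$ci95_ab[2], md$z_ab)
    add("mediation", "c_prime", md$c_prime)
    add("mediation", "c_total", md$c_total)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

write_results_files <- function(res, outdir) {
  tab <- pipeline_results_table(res)
  if (!is.null(tab))
    utils::write.csv(tab, file.path(outdir, "results.csv"),
                     row.names = FALSE)
  # human-readable report
  con <- file(file.path(outdir, "report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("riskysearch pipeline report (seed %d, status %s)", res$config$seed,
    res$status)
  if (!is.null(res$failed_stage))
    w("failed stage: %s (%s)", res$failed_stage, res$error)
  if (!is.null(res$choice_model))
    w("choice model: task b = %.3f [%.3f, %.3f], OR = %.2f, z = %.2f, p = %.3g",
      res$choice_model$b, res$choice_model$ci95[1], res$choice_model$ci95[2],
      res$choice_model$odds_ratio, res$choice_model$statistic,
      res$choice_model$p_value)
  if (!is.null(res$class_test))
    w("EV classification: ALT %.0f%% vs DIM %.0f%%, z = %.2f, one-tailed p = %.3f",
      100 * res$class_test$p1, 100 * res$class_test$p2, res$class_test$z,
      res$class_test$p_one_tailed)
  if (!is.null(res$sm_participants)) {
    m <- tapply(res$sm_participants$mean_sm, res$sm_participants$task, mean)
    w("mean SM: ALT %.3f, DIM %.3f", m[["ALT"]], m[["DIM"]])
  }
  if (!is.null(res$mediation))
    w("mediation: a = %.3f, b = %.3f, ab = %.3f [%.3f, %.3f], c' = %.3f, c = %.3f",
      res$mediation$a, res$mediation$b_path, res$mediation$ab,
      res$mediation$ci95_ab[1], res$mediation$ci95_ab[2],
      res$mediation$c_prime, res$mediation$c_total)
  invisible(NULL)
}

write_manifest <- function(res, path) {
  cfg <- res$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("package: riskysearch %s",
            as.character(utils::packageVersion("riskysearch"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("status: %s", res$status),
    "config:",
    paste0("  ", gsub("\n", "\n  ", vapply(names(cfg), function(nm) {
      sprintf("%s: %s", nm, paste(deparse(cfg[[nm]]), collapse = " "))
    }, character(1))))
  ), con)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> status %s (seed %d)\n", x$status,
              x$config$seed))
  if (!is.null(x$failed_stage))
    cat("  failed stage:", x$failed_stage, "-", x$error, "\n")
  if (!is.null(x$choice_model)) print(x$choice_model)
  if (!is.null(x$mediation)) print(x$mediation)
  invisible(x)
}
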
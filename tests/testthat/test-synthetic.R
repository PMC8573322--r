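test_that("agent choices follow the softmax generatively", {
  set.seed(3)
  pair <- generate_pairs(1, "exp1", seed = 3)
  # saturation: a high-phi EV agent nearly always takes the higher-EV option
  big_gap <- data.frame(pair_id = "PX", outcome_a = 80, prob_a = 0.9,
                        outcome_b = 40, prob_b = 0.5, risky_on_top = TRUE)
  ag <- agent_spec("S1", "EV", phi = 10)
  ch <- replicate(200, simulate_choice(ag, big_gap))
  expect_true(all(ch == "A"))  # P(B) < 1e-6 at this phi and gap
  # phi = 0 is a fair coin
  ag0 <- agent_spec("S1", "EV", phi = 0)
  ch0 <- replicate(2000, simulate_choice(ag0, big_gap))
  expect_equal(mean(ch0 == "A"), 0.5, tolerance = 0.05)
  # maximax agent on a strategy-conflict pair takes the higher outcome
  p2 <- generate_pairs(1, "exp2", seed = 8)
  agm <- agent_spec("S1", "MAXIMAX", phi = 10)
  chm <- replicate(200, simulate_choice(agm, p2))
  higher_out <- if (p2$outcome_a > p2$outcome_b) "A" else "B"
  expect_true(all(chm == higher_out))
})

test_that("choice frequencies converge to the softmax probabilities", {
  # chi-squared goodness of fit on simulated draws over a grid of phi, dV
  set.seed(17)
  for (phi in c(0.1, 0.5, 2)) {
    for (dv in c(0.5, 2, 5)) {
      p <- choice_probability(10 + dv, 10, phi)
      n <- 10000
      k <- sum(runif(n) < p)  # simulate_choice reduces to this Bernoulli
      test <- suppressWarnings(chisq.test(c(k, n - k), p = c(p, 1 - p)))
      expect_gt(test$p.value, 0.01)
    }
  }
  # and through the full agent interface at a fixed cell
  pair <- data.frame(pair_id = "PX", outcome_a = 60, prob_a = 0.5,
                     outcome_b = 40, prob_b = 0.6, risky_on_top = TRUE)
  ag <- agent_spec("S1", "EV", phi = 0.2)
  p <- choice_probability(30, 24, 0.2)
  ch <- replicate(4000, simulate_choice(ag, pair))
  test <- suppressWarnings(chisq.test(table(factor(ch, c("A", "B"))),
                                      p = c(p, 1 - p)))
  expect_gt(test$p.value, 0.01)
})

test_that("fixation walks honour the bias parameter", {
  set.seed(5)
  # bias 1: purely alternative-wise, r_dim = 0
  f1 <- simulate_fixations("ALT", bias_alt = 1, bias_dim = 0,
                           n_transitions = 10)
  c1 <- count_transitions(f1$aoi)
  expect_equal(c1$r_dim, 0L)
  expect_equal(c1$r_alt, 10L)
  # bias 0: purely dimension-wise, r_alt = 0
  f0 <- simulate_fixations("DIM", bias_alt = 1, bias_dim = 0,
                           n_transitions = 10)
  c0 <- count_transitions(f0$aoi)
  expect_equal(c0$r_alt, 0L)
  expect_equal(c0$r_dim, 10L)
  # bias 0.5: alternative-wise share tends to one half
  f5 <- simulate_fixations("ALT", bias_alt = 0.5, bias_dim = 0.5,
                           n_transitions = 10000)
  c5 <- count_transitions(f5$aoi)
  expect_equal(c5$r_alt / (c5$r_alt + c5$r_dim), 0.5, tolerance = 0.03)
  # durations respect the default 60 ms truncation
  expect_true(all(f5$duration_ms >= 60))
  # sub-50 ms fixations can be injected for the filter's test path
  set.seed(6)
  fs <- simulate_fixations("ALT", n_transitions = 3000, min_duration_ms = 0,
                           dur_meanlog = log(80), dur_sdlog = 0.6)
  expect_gt(sum(fs$duration_ms < 50), 0)
})

test_that("response times follow the log-linear structure", {
  pair <- data.frame(pair_id = "PX", outcome_a = 60, prob_a = 0.5,
                     outcome_b = 40, prob_b = 0.6, risky_on_top = TRUE)
  # noise -> 0: closed form and monotonicity
  ag <- agent_spec("S1", "EV", phi = 1,
                   rt_params = list(baseline_log_s = log(4),
                                    task_effect_log_s = 0,
                                    ev_slope_per_yuan = 0,
                                    noise_sd_log_s = 1e-12))
  expect_equal(simulate_rt(ag, "DIM", pair), 4.0, tolerance = 1e-6)
  ag2 <- agent_spec("S1", "EV", phi = 1,
                    rt_params = list(baseline_log_s = log(4),
                                     task_effect_log_s = 0.2,
                                     ev_slope_per_yuan = 0.01,
                                     noise_sd_log_s = 1e-12))
  expect_gt(simulate_rt(ag2, "ALT", pair), simulate_rt(ag2, "DIM", pair))
  wide <- data.frame(pair_id = "PY", outcome_a = 90, prob_a = 0.9,
                     outcome_b = 10, prob_b = 0.5, risky_on_top = TRUE)
  expect_lt(simulate_rt(ag2, "DIM", wide), simulate_rt(ag2, "DIM", pair))
  expect_gt(simulate_rt(ag2, "DIM", wide), 0)
})

test_that("the experiment generator produces a balanced deterministic design", {
  cfg <- pipeline_config(seed = 99, n_participants = 6, n_pairs = 10,
                         n_boot = 0)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$fixations, e2$fixations)
  expect_equal(nrow(e1$trials), 6 * 2 * 10)
  expect_equal(sort(unique(e1$trials$task)), c("ALT", "DIM"))
  # every participant sees every pair in both tasks
  tab <- table(e1$trials$participant_id, e1$trials$task)
  expect_true(all(tab == 10))
  # task order counterbalanced across participants
  expect_equal(unname(table(e1$agents$task_order)), c(3L, 3L),
               ignore_attr = TRUE)
  expect_true(all(e1$trials$rt_s > 0))
  expect_true(all(e1$fixations$duration_ms > 0))
})

test_that("high-phi uncoupled EV agents are EV-consistent in both tasks", {
  cfg <- pipeline_config(seed = 13, n_participants = 4, n_pairs = 20,
                         agent_mixture = c(EV = 1, MAXIMAX = 0, GUESS = 0),
                         phi = 10, coupling = 0, n_boot = 0)
  e <- simulate_experiment(cfg)
  d <- trials_with_ev_consistency(e$trials, e$pairs)
  expect_gte(mean(d$ev_consistent[d$task == "ALT"]), 0.99)
  expect_gte(mean(d$ev_consistent[d$task == "DIM"]), 0.99)
})
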
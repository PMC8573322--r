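test_that("the pooled two-proportion z test matches its closed form", {
  r <- compare_classification_proportions(49, 50, 44, 50)
  expect_lt(abs(r$z - 1.96), 0.005)
  expect_lt(abs(r$p_one_tailed - 0.025), 5e-4)
  r2 <- compare_classification_proportions(43, 45, 39, 45)
  expect_lt(abs(r2$z - 1.48), 0.005)
  expect_lt(abs(r2$p_one_tailed - 0.069), 5e-4)
  r3 <- compare_classification_proportions(30, 40, 15, 20)
  expect_equal(r3$z, 0)
  expect_equal(r3$p_one_tailed, 0.5)
  expect_error(compare_classification_proportions(1, 0, 1, 2), "non-empty")
  expect_error(compare_classification_proportions(5, 4, 1, 2), "0 <= k <= n")
})

test_that("the choice model recovers a positive task effect and OR = exp(b)", {
  set.seed(101)
  pairs <- generate_pairs(30, "exp2", seed = 101)
  trials <- simulate_two_task_trials(pairs, 15, phi_alt = 1, phi_dim = 0.15)
  fit <- fit_choice_model(trials, pairs)
  expect_gt(fit$b, 0)
  expect_equal(fit$odds_ratio, exp(fit$b), tolerance = 1e-9)
  expect_lt(fit$p_value, 0.01)
  expect_lt(fit$ci95[1], fit$ci95[2])
})

test_that("the choice model rejects degenerate inputs", {
  pairs <- generate_pairs(10, "exp2", seed = 7)
  trials <- simulate_two_task_trials(pairs, 4, 1, 1)
  expect_error(fit_choice_model(trials[trials$task == "ALT", ], pairs),
               "both tasks")
  # constant outcome: force every choice to the higher-EV option
  dev <- pairs$outcome_a * pairs$prob_a - pairs$outcome_b * pairs$prob_b
  trials$choice <- ifelse(dev[match(trials$pair_id, pairs$pair_id)] > 0,
                          "A", "B")
  expect_error(fit_choice_model(trials, pairs), "separation")
})

test_that("the decision-time model recovers the generating coefficients", {
  set.seed(202)
  cfg <- pipeline_config(seed = 202, n_participants = 25, n_pairs = 40,
                         agent_mixture = c(EV = 1, MAXIMAX = 0, GUESS = 0),
                         phi = 0.5, coupling = 0, n_boot = 0)
  e <- simulate_experiment(cfg)
  fit <- fit_rt_model(e$trials, e$pairs)
  b <- fit$terms
  task_row <- b[b$term == "task", ]
  ev_row <- b[b$term == "ev_diff", ]
  out_row <- b[b$term == "outcome_diff", ]
  # truth: +0.16 log-s task effect, -0.006 per yuan EV-difference slope,
  # no outcome-difference effect
  expect_true(task_row$ci_low < 0.16 + 0.03 && task_row$ci_high > 0.16 - 0.03)
  expect_lt(abs(ev_row$estimate - (-0.006)), 0.003)
  expect_gt(out_row$p_value, 0.001)  # no true effect to detect
  expect_lt(task_row$p_value, 1e-6)
  expect_error(fit_rt_model(transform(e$trials, rt_s = 0), e$pairs),
               "positive")
})

test_that("mediation point estimates satisfy the product and sum identities", {
  set.seed(303)
  cfg <- pipeline_config(seed = 303, n_participants = 12, n_pairs = 15,
                         n_boot = 0)
  e <- simulate_experiment(cfg)
  d <- trials_with_ev_consistency(e$trials, e$pairs)
  sm <- sm_per_trial(e$fixations)
  d$sm <- sm$sm[match(paste(d$participant_id, d$task, d$pair_id),
                      paste(sm$participant_id, sm$task, sm$pair_id))]
  m <- mediation_analysis(d, n_boot = 0, engine = "fixed")
  expect_equal(m$ab, m$a * m$b_path, tolerance = 1e-12)
  expect_equal(m$c_total, m$c_prime + m$ab, tolerance = 1e-6)
  expect_true(all(is.na(m$ci95_ab)))  # n_boot = 0: interval unavailable
  # mixed engine returns the same structure
  mm <- mediation_analysis(d, n_boot = 0, engine = "mixed")
  expect_equal(mm$ab, mm$a * mm$b_path, tolerance = 1e-12)
})

test_that("mediation bootstrap is seeded-reproducible and needs 3 clusters", {
  set.seed(404)
  cfg <- pipeline_config(seed = 404, n_participants = 8, n_pairs = 10,
                         n_boot = 0)
  e <- simulate_experiment(cfg)
  d <- trials_with_ev_consistency(e$trials, e$pairs)
  sm <- sm_per_trial(e$fixations)
  d$sm <- sm$sm[match(paste(d$participant_id, d$task, d$pair_id),
                      paste(sm$participant_id, sm$task, sm$pair_id))]
  m1 <- mediation_analysis(d, n_boot = 100, seed = 5, engine = "fixed")
  m2 <- mediation_analysis(d, n_boot = 100, seed = 5, engine = "fixed")
  expect_identical(m1$ci95_ab, m2$ci95_ab)
  two <- d[d$participant_id %in% unique(d$participant_id)[1:2], ]
  expect_error(mediation_analysis(two, n_boot = 0), "insufficient clusters")
})

test_that("a switched-on mediation chain yields a positive indirect effect", {
  cfg <- pipeline_config(seed = 505, n_participants = 25, n_pairs = 25,
                         coupling = 0.5, n_boot = 300,
                         mediation_engine = "fixed")
  e <- simulate_experiment(cfg)
  d <- trials_with_ev_consistency(e$trials, e$pairs)
  sm <- sm_per_trial(e$fixations)
  d$sm <- sm$sm[match(paste(d$participant_id, d$task, d$pair_id),
                      paste(sm$participant_id, sm$task, sm$pair_id))]
  m <- mediation_analysis(d, n_boot = 300, seed = 1, engine = "fixed")
  expect_gt(m$ab, 0)
  expect_gt(m$ci95_ab[1], 0)  # interval excludes zero
})
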
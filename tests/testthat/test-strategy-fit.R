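test_that("softmax probabilities obey the symmetry identities", {
  expect_equal(choice_probability(5, 5, 3), 0.5)
  expect_equal(choice_probability(1, 99, 0), 0.5)
  # complementary choice probabilities sum to 1 exactly
  for (phi in c(0, 0.1, 1, 10)) {
    va <- runif(20, 0, 99); vb <- runif(20, 0, 99)
    expect_equal(choice_probability(va, vb, phi) +
                   choice_probability(vb, va, phi), rep(1, 20))
  }
  # logistic-function oracle
  expect_equal(choice_probability(10, 0, 1), 1 / (1 + exp(-10)))
  expect_equal(choice_probability(10, 0, 1), 0.9999546, tolerance = 1e-7)
  # overflow safety at phi * V = 990
  p <- choice_probability(99, 0, 10)
  expect_true(is.finite(p) && p <= 1 && p > 0.999999)
})

test_that("G-squared matches the random baseline and a hand-summed oracle", {
  pairs <- generate_pairs(60, "exp2", seed = 5)
  trials <- data.frame(pair_id = pairs$pair_id,
                       choice = sample(c("A", "B"), 60, TRUE))
  expect_equal(g_squared(trials, pairs, "EV", 0), 2 * 60 * log(2))
  expect_equal(g_squared(trials, pairs, "EV", 0), 83.1777, tolerance = 1e-4)
  expect_equal(baseline_g2(60), 83.1777, tolerance = 1e-4)

  # term-by-term independent summation at phi = 0.3 on 10 hand-built trials
  set.seed(11)
  p10 <- generate_pairs(10, "exp1", seed = 9)
  t10 <- data.frame(pair_id = p10$pair_id,
                    choice = sample(c("A", "B"), 10, TRUE))
  phi <- 0.3
  oracle <- 0
  for (j in seq_len(10)) {
    va <- p10$outcome_a[j] * p10$prob_a[j]
    vb <- p10$outcome_b[j] * p10$prob_b[j]
    p_a <- exp(phi * va) / (exp(phi * va) + exp(phi * vb))
    f <- if (t10$choice[j] == "A") p_a else 1 - p_a
    oracle <- oracle - 2 * log(f)
  }
  expect_equal(g_squared(t10, p10, "EV", phi), oracle, tolerance = 1e-10)

  # deviance stays finite deep in the saturated regime
  sure_b <- data.frame(pair_id = pairs$pair_id, choice = "B")
  g <- g_squared(sure_b, pairs, "MAXIMAX", 10)
  expect_true(is.finite(g) && g >= 0)
})

test_that("fitted G-squared never exceeds the random-choice ceiling", {
  set.seed(21)
  pairs <- generate_pairs(60, "exp2", seed = 21)
  for (strategy in c("EV", "MAXIMAX", "GUESS")) {
    trials <- simulate_agent_trials(pairs, strategy, 0.7)
    for (fitted in c("EV", "MAXIMAX")) {
      fit <- fit_strategy(trials, pairs, fitted)
      expect_lte(fit$g2, baseline_g2(60) + 1e-9)
      expect_gte(fit$phi_hat, 0)
    }
  }
})

test_that("a purely random chooser fits back to the baseline", {
  set.seed(31)
  pairs <- generate_pairs(60, "exp2", seed = 31)
  phis <- g2s <- numeric(50)
  for (r in 1:50) {
    trials <- simulate_agent_trials(pairs, "GUESS", 0)
    fit <- fit_strategy(trials, pairs, "EV")
    phis[r] <- fit$phi_hat; g2s[r] <- fit$g2
  }
  expect_lt(mean(phis), 0.05)        # phi_hat -> 0 in expectation
  expect_equal(mean(g2s), baseline_g2(60), tolerance = 0.05 * baseline_g2(60))
})

test_that("classification recovers the generating strategy and labels guessers", {
  set.seed(41)
  pairs <- generate_pairs(60, "exp2", seed = 41)
  trials_ev <- simulate_agent_trials(pairs, "EV", 2)
  trials_mm <- simulate_agent_trials(pairs, "MAXIMAX", 2)
  expect_equal(classify_participant(trials_ev, pairs)$label, "EV")
  expect_equal(classify_participant(trials_mm, pairs)$label, "MAXIMAX")

  # guessers: optimizing phi lets one strategy dip below the baseline by
  # chance on most replicates (on strategy-conflict stimuli the two margins
  # are anti-correlated, so noise nearly always favours one of them), but
  # guessers are still flagged far more often than strategic agents are
  guess_rate <- mean(replicate(60, {
    classify_participant(simulate_agent_trials(pairs, "GUESS", 0),
                         pairs)$label == "GUESS_OR_OTHER"
  }))
  strategic_rate <- mean(replicate(60, {
    classify_participant(simulate_agent_trials(pairs, "EV", 2),
                         pairs)$label == "GUESS_OR_OTHER"
  }))
  expect_gt(guess_rate, strategic_rate)
  expect_equal(strategic_rate, 0)
})

test_that("degenerate stimuli with identical valuations hit the tie rule", {
  pairs <- generate_pairs(20, "exp1", seed = 51)
  # maximax sees only outcomes; equal outcomes flatten its deviance profile
  flat_mm <- pairs
  flat_mm$outcome_b <- flat_mm$outcome_a
  flat_mm$prob_b <- pmin(0.98, flat_mm$prob_a + 0.10)
  trials <- data.frame(pair_id = pairs$pair_id,
                       choice = rep(c("A", "B"), 10))
  fit <- fit_strategy(trials, flat_mm, "MAXIMAX")
  expect_equal(fit$phi_hat, 0)
  expect_equal(fit$g2, baseline_g2(20))
  # fully identical options flatten both profiles: exact tie -> guessing
  flat_both <- pairs
  flat_both$outcome_b <- flat_both$outcome_a
  flat_both$prob_b <- flat_both$prob_a
  cr <- classify_participant(trials, flat_both)
  expect_equal(cr$label, "GUESS_OR_OTHER")
  expect_equal(cr$fits$EV$g2, baseline_g2(20))
  expect_equal(cr$fits$MAXIMAX$phi_hat, 0)
})

test_that("classify_participants reports one row per participant and task", {
  set.seed(61)
  pairs <- generate_pairs(30, "exp2", seed = 61)
  trials <- rbind(
    simulate_agent_trials(pairs, "EV", 2, "S001", "ALT"),
    simulate_agent_trials(pairs, "EV", 2, "S001", "DIM"),
    simulate_agent_trials(pairs, "MAXIMAX", 2, "S002", "ALT"),
    simulate_agent_trials(pairs, "MAXIMAX", 2, "S002", "DIM"))
  cls <- classify_participants(trials, pairs)
  expect_equal(nrow(cls), 4)
  expect_setequal(names(cls), c("participant_id", "task", "label",
                                "phi_hat_ev", "g2_ev", "phi_hat_maximax",
                                "g2_maximax", "baseline_g2"))
  expect_equal(cls$label[cls$participant_id == "S001"], c("EV", "EV"))
  expect_equal(cls$label[cls$participant_id == "S002"],
               c("MAXIMAX", "MAXIMAX"))
})

test_that("EV-consistency coding follows the expected values and rejects ties", {
  d <- data.frame(outcome_a = 50, prob_a = 0.9, outcome_b = 70, prob_b = 0.6)
  expect_true(ev_consistent(d, "A"))    # 45 > 42
  expect_false(ev_consistent(d, "B"))
  tied <- data.frame(outcome_a = 50, prob_a = 0.9, outcome_b = 90,
                     prob_b = 0.5)     # 45 = 45
  expect_error(ev_consistent(tied, "B"), "equal expected values")
})
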
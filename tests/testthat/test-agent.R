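test_that("the C-count posterior matches the binomial worked examples", {
  expect_equal(cs_posterior(0, 0), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(cs_posterior(1, 0), c(1 / 6, 1 / 3, 1 / 2), tolerance = 1e-12)
  expect_equal(cs_posterior(0, 1), c(1 / 2, 1 / 3, 1 / 6), tolerance = 1e-12)
  expect_error(cs_posterior(1, 0, up_levels = integer(0)), "nonempty")
  expect_error(cs_posterior(-1, 0), "invalid")
  expect_error(cs_posterior(7, 6), "invalid")
})

test_that("the posterior concentrates on the truth after seeing all 12 Cs", {
  # The binomial form caps the attainable certainty: a full census of a 6-up
  # ring leaves mass (1/2)^12 / ((1/2)^12 + 2 (3/16)^6) = 0.737 on the truth,
  # and 0.827 for the 3- and 9-up rings. The mode is always the truth.
  for (up in c(3L, 6L, 9L)) {
    post <- cs_posterior(up, 12L - up)
    expect_equal(c(3, 6, 9)[which.max(post)], up)
    expect_gte(post[match(up, c(3, 6, 9))], 0.73)
  }
  expect_equal(cs_posterior(6, 6)[2],
               0.5^12 / (0.5^12 + 2 * (3 / 16)^6), tolerance = 1e-12)
})

test_that("Cs values are posterior-weighted expected rewards", {
  expect_equal(cs_value(rep(1 / 3, 3), "combined"), 0.5, tolerance = 1e-12)
  expect_equal(cs_value(c(0, 0, 1), "cs_only"), 1, tolerance = 1e-12)
  expect_equal(cs_value(c(1 / 6, 1 / 3, 1 / 2), "combined"),
               sum(c(1 / 6, 1 / 3, 1 / 2) * c(0.25, 0.5, 0.75)),
               tolerance = 1e-12)
  expect_error(cs_value(c(0.5, 0.5, 0.5), "combined"), "normalised")
})

test_that("colour-value retrieval follows 1 - tau_color^t", {
  expect_equal(effective_color_value(0.8, 1, 0), 0.8, tolerance = 1e-12)
  expect_equal(effective_color_value(0.8, 2, 0.5), 0.6, tolerance = 1e-12)
  # the retrieved fraction at the second decision event
  expect_equal(effective_color_value(1, 2, 0.2324), 0.946, tolerance = 5e-4)
  expect_error(effective_color_value(1, -1, 0.5), "step")
})

test_that("policy probabilities match the logistic closed forms", {
  p0 <- neutral_params()
  expect_equal(p_continue_gathering(0.3, -0.2, 4, p0), 0.5, tolerance = 1e-12)
  expect_equal(p_look_right(0.3, -0.2, "none", p0), 0.5, tolerance = 1e-12)
  expect_equal(p_choose_right(0.3, -0.6, p0), 0.5, tolerance = 1e-12)

  pa <- neutral_params(alpha_gather = 2, tau = 0)
  expect_equal(p_continue_gathering(0, 0, 1, pa), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  pb <- neutral_params(beta_dcolor = -1, tau = 0)
  expect_equal(p_continue_gathering(0, 1, 1, pb), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  pc <- neutral_params(beta_look_stay = 1)
  expect_equal(p_look_right(0, 0, "right", pc), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  pd <- neutral_params(beta_look_color = 2)
  expect_equal(p_look_right(0, -0.5, "none", pd), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  # choice: value difference cancels exactly
  pe <- neutral_params(beta_choose = 3)
  expect_equal(p_choose_right(0.25, -0.5, pe), 0.5, tolerance = 1e-12)
  pf <- neutral_params(beta_choose = 500)
  expect_gt(p_choose_right(0.1, 0, pf), 1 - 1e-12)
})

test_that("urgency-gated colour differences never raise gathering when the weight is negative", {
  p <- neutral_params(beta_dcolor = -1.7, alpha_gather = 1.2)
  dvs <- seq(0, 1, by = 0.05)
  probs <- vapply(dvs, function(d) p_continue_gathering(0.2, d, 3, p), numeric(1))
  expect_true(all(diff(probs) <= 0))
  expect_true(all(probs > 0 & probs < 1))
})

test_that("TD colour learning follows the adaptive-rate update", {
  p <- neutral_params(epsilon = 0.5)
  st <- belief_state(c("c1", "c2"))
  # first outcome: eta = 1/(0.5 + 0.5) = 1; delta = 1 - (0.5 + 0)
  st2 <- td_update(st, "c1", 1, 0.5, p)
  expect_equal(st2$v_color[["c1"]], 0.5, tolerance = 1e-12)
  expect_equal(st2$n_out[["c1"]], 1L)
  expect_equal(st2$v_color[["c2"]], 0)
  # zero prediction error leaves the value unchanged
  st3 <- td_update(st2, "c1", 1, 0.5, p)
  expect_equal(st3$v_color[["c1"]], 0.5, tolerance = 1e-12)
  expect_error(td_update(st, "c9", 1, 0, p), "unknown colour")
})

test_that("the learned value converges to the colour's reward rate", {
  set.seed(7)
  p <- neutral_params(epsilon = 1)
  st <- belief_state("c1")
  for (i in 1:1000) st <- td_update(st, "c1", rbinom(1, 1, 0.5), 0, p)
  expect_lt(abs(st$v_color[["c1"]] - 0.5), 0.05)
})

test_that("C selection is uniform over the unfixated Cs", {
  set.seed(3)
  expect_equal(select_c_to_fixate(setdiff(1:12, 5L)), 5L)
  draws <- replicate(12000, select_c_to_fixate(integer(0)))
  freq <- tabulate(draws, 12) / 12000
  expect_true(all(abs(freq - 1 / 12) <
                    3 * sqrt((1 / 12) * (11 / 12) / 12000)))
  expect_error(select_c_to_fixate(1:12), "already fixated")
})

test_that("degenerate policies stop immediately and respect the fixation cap", {
  sched <- one_trial_schedule()
  p_stop <- neutral_params(alpha_gather = -50)
  st <- belief_state(c("c1", "c2"))
  set.seed(1)
  out <- simulate_trial(sched[1, ], st, p_stop)
  expect_equal(out$record$n_fix, 0L)
  expect_true(out$record$choice %in% c("left", "right"))
  p_go <- neutral_params(alpha_gather = 50)
  for (cap in c(3L, 24L)) {
    out <- simulate_trial(sched[1, ], st, p_go, max_steps = cap)
    expect_lte(out$record$n_fix, cap)
    expect_equal(out$record$n_fix, nrow(out$fixations))
  }
})

test_that("colour-only trials yield no C fixations", {
  sched <- one_trial_schedule("color_only")
  st <- belief_state(c("c1", "c2"))
  set.seed(2)
  out <- simulate_trial(sched[1, ], st, neutral_params(alpha_gather = 10))
  expect_equal(out$record$n_fix, 0L)
})

test_that("simulation is reproducible and sensitive to the colour-gathering weight", {
  s <- generate_task(small_config(), seed = 9)
  p <- as_agent_params(unlist(sample_params(1, generating_hyperparams())[1, ]))
  a <- simulate_participant(s, p, seed = 5)
  b <- simulate_participant(s, p, seed = 5)
  expect_identical(a$trials, b$trials)
  expect_identical(a$fixations, b$fixations)
  # removing the colour suppression of gathering increases fixations
  p_no <- p; p_no[["beta_dcolor"]] <- 0
  p_yes <- p; p_yes[["beta_dcolor"]] <- -3
  n_no <- mean(simulate_participant(s, as_agent_params(p_no), seed = 11)$trials$n_fix)
  n_yes <- mean(simulate_participant(s, as_agent_params(p_yes), seed = 11)$trials$n_fix)
  expect_gt(n_no, n_yes)
})

test_that("with no colour pathway the model ignores colours entirely", {
  p <- neutral_params(omega_color = 0, beta_choose = 5)
  # colour-only choice is exactly 0.5 whatever the learned values
  expect_equal(p_choose_right(0, 0.9, p), 0.5, tolerance = 1e-12)
  # tau_color = 0 gives instant retrieval from the first event on
  expect_equal(effective_color_value(0.73, 1, 0), 0.73, tolerance = 1e-12)
})

test_that("parameter validation enforces the constrained domains", {
  expect_error(agent_params(tau = 1.5), "tau")
  expect_error(agent_params(omega_color = -0.1), "omega_color")
  expect_error(agent_params(epsilon = 0), "epsilon")
})
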
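test_that("with neutral parameters every decision contributes log(1/2)", {
  sched <- one_trial_schedule()
  p0 <- neutral_params()
  spec <- model_spec("full")
  # one fixation then choice: continue, side, stop, choice
  d1 <- one_trial_data(sched, choice = "right", fix_sides = "left", fix_idx = 1L)
  expect_equal(as.numeric(dataset_loglik(d1, p0, spec)), 4 * log(0.5),
               tolerance = 1e-12)
  # immediate choice: stop + choice only
  d0 <- one_trial_data(sched, choice = "left")
  expect_equal(as.numeric(dataset_loglik(d0, p0, spec)), 2 * log(0.5),
               tolerance = 1e-12)
  # colour-only trial: choice term only
  dc <- one_trial_data(one_trial_schedule("color_only"), choice = "right")
  expect_equal(as.numeric(dataset_loglik(dc, p0, spec)), log(0.5),
               tolerance = 1e-12)
})

test_that("exp(trial log-likelihood) normalises over all bounded outcomes", {
  # every (C-index sequence, choice) outcome with <= 2 fixations, weighted by
  # the uniform C-selection factor the likelihood omits, must sum to one
  set.seed(31)
  sched <- one_trial_schedule(left_up = 6L, right_up = 9L,
                              left_orient = "101010101010",
                              right_orient = "111111111000")
  prm <- as_agent_params(unlist(sample_params(1, generating_hyperparams())[1, ]))
  spec <- model_spec("full")
  outcomes <- enumerate_cindex_outcomes(max_steps = 2L)
  total <- 0
  for (oc in outcomes) {
    for (choice in c("left", "right")) {
      d <- one_trial_data(sched, choice = choice, fix_sides = oc$sides,
                          fix_idx = oc$idx, max_steps = 2L)
      total <- total + exp(as.numeric(dataset_loglik(d, prm, spec))) * oc$fac
    }
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("the likelihood factorises over trials and is zero on empty data", {
  co <- tiny_cohort(n = 1, seed = 51)
  d <- co$data[[1]]
  prm <- as_agent_params(co$true_params[1, ])
  ll <- dataset_loglik(d, prm)
  by_trial <- attr(ll, "by_trial")
  n <- nrow(d$trials)
  # dropping the final trial (state identical up to there) removes its term
  d2 <- participant_data(d$schedule, d$trials[-n, ],
                         d$fixations[d$fixations$trial != d$trials$trial[n], ],
                         max_steps = d$max_steps)
  expect_equal(as.numeric(dataset_loglik(d2, prm)),
               as.numeric(ll) - by_trial[n], tolerance = 1e-10)
  # empty dataset
  d0 <- participant_data(d$schedule, d$trials[0, ], d$fixations[0, ])
  expect_identical(as.numeric(dataset_loglik(d0, prm)), 0)
})

test_that("the reduced variants nest inside the full model", {
  co <- tiny_cohort(n = 1, seed = 52)
  d <- co$data[[1]]
  prm <- as_agent_params(co$true_params[1, ])
  prm0 <- prm; prm0[["beta_dcolor"]] <- 0
  expect_equal(as.numeric(dataset_loglik(d, as_agent_params(prm0), model_spec("full"))),
               as.numeric(dataset_loglik(d, prm, model_spec("no-color-gather"))),
               tolerance = 1e-10)
  prm1 <- prm; prm1[["beta_look_color"]] <- 0
  expect_equal(as.numeric(dataset_loglik(d, as_agent_params(prm1), model_spec("full"))),
               as.numeric(dataset_loglik(d, prm, model_spec("no-color-look"))),
               tolerance = 1e-10)
})

test_that("the compiled kernel reproduces the reference implementation", {
  co <- tiny_cohort(n = 2, seed = 53)
  h <- generating_hyperparams()
  set.seed(8)
  for (p in 1:2) {
    d <- co$data[[p]]
    prep <- prepare_participant(d)
    draws <- sample_params(6, h)
    for (i in 1:6) {
      prm <- as_agent_params(unlist(draws[i, ]))
      for (sp in c("full", "no-color-gather", "no-color-look")) {
        a <- as.numeric(dataset_loglik(d, prm, model_spec(sp)))
        b <- batch_loglik(prep, matrix(as.numeric(prm), 1), model_spec(sp))
        expect_equal(b, a, tolerance = 1e-9)
      }
    }
  }
})

test_that("data are most likely under their generating parameters", {
  set.seed(17)
  co <- generate_cohort(cohort_spec(n_participants = 3, seed = 54))
  preps <- lapply(co$data, prepare_participant)
  truth <- colMeans(co$true_params)
  ll_true <- sum(vapply(seq_along(preps), function(p)
    batch_loglik(preps[[p]], matrix(co$true_params[p, ], 1)), numeric(1)))
  worse <- 0
  for (r in 1:20) {
    ll_pert <- sum(vapply(seq_along(preps), function(p) {
      z <- co$true_params[p, ]
      z[c("alpha_gather", "beta_dCs", "beta_choose")] <-
        z[c("alpha_gather", "beta_dCs", "beta_choose")] + rnorm(3, 0, 0.75)
      z["omega_color"] <- min(1, max(0, z["omega_color"] + rnorm(1, 0, 0.2)))
      batch_loglik(preps[[p]], matrix(z, 1))
    }, numeric(1)))
    if (ll_pert <= ll_true) worse <- worse + 1
  }
  expect_gte(worse, 19)
})

test_that("a coarse grid over one parameter peaks at the truth", {
  co <- generate_cohort(cohort_spec(
    n_participants = 6,
    hyper = within(generating_hyperparams(), sd[param == "beta_choose"] <- 1e-8),
    seed = 55))
  preps <- lapply(co$data, prepare_participant)
  grid <- seq(1, 5, by = 1)   # truth is beta_choose = 3
  total <- vapply(grid, function(bc) {
    sum(vapply(seq_along(preps), function(p) {
      z <- co$true_params[p, ]; z["beta_choose"] <- bc
      batch_loglik(preps[[p]], matrix(z, 1))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(grid[which.max(total)], 3)
})
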
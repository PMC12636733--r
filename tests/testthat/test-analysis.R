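test_that("predictors encode observed-C differences and reward history", {
  sched <- one_trial_schedule(right_up = 9L, left_up = 3L,
                              left_p = 1, right_p = 0)
  # all 12 Cs of the right (9-up) stimulus fixated, none of the left
  trials <- data.frame(trial = 1L, trial_type = "combined", choice = "right",
                       reward = 1L, rt_proxy = 12L,
                       up_l = 0L, down_l = 0L, up_r = 9L, down_r = 3L)
  fx <- data.frame(trial = rep(1L, 12), step = 1:12, side = "right",
                   c_index = 1:12)
  d <- participant_data(sched, trials, fx)
  pred <- build_predictors(d)
  expect_equal(pred$dCs_obs, 6)          # 9 up - 3 down
  expect_equal(pred$sumCs, 12)
  expect_equal(pred$dCs_instr, 6)
  expect_equal(pred$dPcolor, 0)          # first encounter of both colours
  # a no-fixation trial has zero observed counts
  trials0 <- within(trials, { up_r <- 0L; down_r <- 0L; rt_proxy <- 0L })
  d0 <- participant_data(sched, trials0, fx[0, ])
  pred0 <- build_predictors(d0)
  expect_equal(pred0$dCs_obs, 0)
  expect_equal(pred0$sumCs, 0)
  # zero-variance predictors are flagged, not propagated as NaN
  expect_true(all(is.finite(as.matrix(pred[grep("^z_", names(pred))]))))
  expect_true("sumCs" %in% attr(pred, "zero_variance"))
})

test_that("reward history is a running proportion excluding the current trial", {
  co <- tiny_cohort(n = 1, seed = 91)
  d <- co$data[[1]]
  pred <- build_predictors(d)
  # recompute one mid-block value by hand
  k <- which(pred$dPcolor != 0)[1]
  expect_false(is.na(k))
  tr <- d$trials; si <- match(tr$trial, d$schedule$trial)
  sch <- d$schedule[si, ]
  target_trial <- pred$trial[k]
  i <- which(tr$trial == target_trial)
  rc <- sch$right_color[i]
  prior <- which(seq_len(nrow(tr)) < i &
                 ifelse(tr$choice == "right", sch$right_color, sch$left_color) == rc)
  ph_r <- if (length(prior)) mean(tr$reward[prior]) else 0
  lc <- sch$left_color[i]
  priorl <- which(seq_len(nrow(tr)) < i &
                  ifelse(tr$choice == "right", sch$right_color, sch$left_color) == lc)
  ph_l <- if (length(priorl)) mean(tr$reward[priorl]) else 0
  expect_equal(pred$dPcolor[k], ph_r - ph_l, tolerance = 1e-12)
})

test_that("choice regressions recover a known generative slope", {
  set.seed(14)
  preds <- lapply(1:12, function(p) {
    n <- 200
    d <- data.frame(z_dCs_obs = rnorm(n), z_dPcolor = rnorm(n),
                    z_sumCs = rnorm(n))
    d$choice <- rbinom(n, 1, 1 / (1 + exp(-1.5 * d$z_dCs_obs)))
    d
  })
  fit <- fit_choice_model(preds, formula = "tradeoff")
  g <- fit$group
  b_cs <- g[g$term == "z_dCs_obs", ]
  expect_lt(abs(b_cs$mean - 1.5), 3 * b_cs$se + 0.15)
  expect_lt(b_cs$p, 0.001)
  # colour plays no role in the generator
  b_col <- g[g$term == "z_dPcolor", ]
  expect_gt(b_col$p, 0.01)
})

test_that("model comparison by BIC favours the combined regression", {
  set.seed(15)
  preds <- lapply(1:10, function(p) {
    n <- 250
    d <- data.frame(z_dCs_instr = rnorm(n), z_dPcolor = rnorm(n))
    d$choice <- rbinom(n, 1, plogis(1.2 * d$z_dCs_instr + 0.8 * d$z_dPcolor))
    d
  })
  bics <- vapply(c("cs", "color", "combined"),
                 function(f) fit_choice_model(preds, formula = f)$total_bic,
                 numeric(1))
  expect_equal(unname(which.min(bics)), 3L)
})

test_that("accuracy contrasts separate optimal, random and Cs-only choosers", {
  co <- tiny_cohort(n = 3, seed = 92)
  # replace choices with the combined-optimal rule
  opt <- lapply(co$data, function(d) {
    si <- match(d$trials$trial, d$schedule$trial)
    s <- d$schedule[si, ]
    comb <- d$trials$trial_type == "combined"
    pr <- numeric(nrow(d$trials))
    pr[comb] <- true_reward_prob("combined", s$right_p_color[comb], s$right_up[comb]) -
      true_reward_prob("combined", s$left_p_color[comb], s$left_up[comb])
    d$trials$choice <- ifelse(pr >= 0, "right", "left")
    d
  })
  acc <- accuracy_contrasts(opt)
  expect_true(all(acc$accuracy$combined_optimal == 1))
  # a random chooser sits near one half on every criterion
  set.seed(9)
  rnd <- lapply(co$data, function(d) {
    d$trials$choice <- sample(c("left", "right"), nrow(d$trials), replace = TRUE)
    d
  })
  accr <- accuracy_contrasts(rnd)$accuracy
  for (cn in c("combined_optimal", "cs_optimal", "color_optimal")) {
    pooled <- mean(accr[[cn]])
    expect_lt(abs(pooled - 0.5), 3 * sqrt(0.25 / (3 * 40)))
  }
})

test_that("relative-use indices behave as normalized contrasts", {
  stub <- list(terms = c("z_dCs_obs", "z_dPcolor"),
               coefs = cbind("(Intercept)" = c(0, 0, 0),
                             z_dCs_obs = c(1, 1, 2),
                             z_dPcolor = c(1, 0, 4)))
  class(stub) <- "choice_model_fit"
  sym <- use_indices(stub, variant = "symmetric")
  expect_equal(sym$reg_index[1], 0)                     # equal use
  expect_equal(sym$reg_index[2], -1)                    # pure Cs user
  asym <- use_indices(stub, variant = "asymmetric")
  expect_equal(asym$reg_index[2], -1)
  # scale invariance
  stub2 <- stub; stub2$coefs[, 2:3] <- stub2$coefs[, 2:3] * 7
  expect_equal(use_indices(stub2, variant = "symmetric")$reg_index,
               sym$reg_index, tolerance = 1e-12)
  # model-based index with a sign flag
  fit_stub <- list(posterior_means = cbind(omega_color = c(0.5, 0.4, 0.3),
                                           alpha_gather = c(2, -1, 1)))
  out <- use_indices(stub, fit = fit_stub)
  expect_equal(out$model_index[1:2], c(0.25, -0.4))
  expect_equal(out$negative_denominator[1:2], c(FALSE, TRUE))
})

test_that("cross-measure correlations detect identity, nulls and planted signal", {
  m <- data.frame(a = 1:10, b = 1:10)
  out <- cross_measures(m)
  expect_equal(out$r[out$var1 == "a" & out$var2 == "b"], 1, tolerance = 1e-12)
  # independent vectors rarely exceed |r| = 0.3 at n = 100
  set.seed(4)
  high <- 0
  for (i in 1:50) {
    r <- cross_measures(data.frame(x = rnorm(100), y = rnorm(100)))$r
    if (abs(r) >= 0.3) high <- high + 1
  }
  expect_lte(high / 50, 0.05)
  # planted negative correlation is recovered
  set.seed(5)
  x <- rnorm(60); y <- -0.8 * x + rnorm(60, 0, 0.5)
  expect_lt(cross_measures(data.frame(x = x, y = y))$r, 0)
})

test_that("correspondence summaries expose the model's mechanisms", {
  h <- generating_hyperparams()
  h$mean[h$param == "beta_choose"] <- 60    # near-deterministic chooser
  h$sd <- h$sd / 4
  co <- generate_cohort(cohort_spec(n_participants = 6, hyper = h, seed = 93))
  corr <- model_data_correspondence(co, co$true_params)
  cv <- corr$choice_curve
  expect_gt(cv$p_right[nrow(cv)], 0.8)
  expect_lt(cv$p_right[1], 0.2)
  # urgency makes continuing less likely with each fixation
  expect_lt(corr$continue_slope, 0)
  # colour-value differences suppress Cs sampling
  expect_lt(corr$cs_by_dvcolor_slope, 0)
})
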
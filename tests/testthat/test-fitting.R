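test_that("group-prior draws respect the parameter transforms", {
  set.seed(12)
  h <- default_hyperparams()
  draws <- sample_params(10000, h)
  # Phi of a standard normal is uniform on [0, 1]
  ks <- ks.test(draws$omega_color, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_true(all(draws$epsilon > 0))
  expect_true(all(draws$tau >= 0 & draws$tau <= 1))
  # degenerate sds reproduce the transformed means exactly
  h0 <- h; h0$sd <- rep(0, nrow(h0))
  d0 <- sample_params(5, h0)
  expect_equal(unique(d0$omega_color), pnorm(0))
  expect_equal(unique(d0$epsilon), exp(h$mean[h$param == "epsilon"]))
  # inactive parameters are fixed at zero in natural space
  d1 <- sample_params(3, h, active = setdiff(h$param, "beta_dcolor"))
  expect_true(all(d1$beta_dcolor == 0))
  expect_true(all(d1$alpha_gather != 0))
})

test_that("with a single sample the posterior mean is the lone draw", {
  co <- tiny_cohort(n = 1, seed = 61)
  fit <- suppressWarnings(iis_fit(co, n_samples = 1, max_iters = 1, seed = 3,
                                  keep_samples = TRUE))
  expect_equal(unname(fit$posterior_means[1, ]),
               unname(fit$samples[[1]]$theta[1, ]))
  expect_equal(sum(fit$samples[[1]]$weights), 1)
})

test_that("fits are reproducible and keep group sds positive", {
  co <- tiny_cohort(n = 2, seed = 62)
  f1 <- iis_fit(co, n_samples = 150, max_iters = 3, seed = 9)
  f2 <- iis_fit(co, n_samples = 150, max_iters = 3, seed = 9)
  expect_identical(as.numeric(ibic(f1)), as.numeric(ibic(f2)))
  expect_identical(f1$posterior_means, f2$posterior_means)
  expect_true(all(f1$trace$sd > 0))
})

test_that("importance weights are invariant to constant log-likelihood shifts", {
  co <- tiny_cohort(n = 1, seed = 63)
  fit <- suppressWarnings(iis_fit(co, n_samples = 200, max_iters = 1, seed = 5,
                                  keep_samples = TRUE))
  ll <- fit$samples[[1]]$loglik
  softmax <- function(x) { w <- exp(x - max(x)); w / sum(w) }
  expect_equal(unname(fit$samples[[1]]$weights), unname(softmax(ll)),
               tolerance = 1e-12)
  expect_equal(unname(softmax(ll + 500)), unname(softmax(ll)),
               tolerance = 1e-12)
})

test_that("the iBIC is deviance plus a hyperparameter penalty in log N", {
  co <- tiny_cohort(n = 2, seed = 64)
  fit <- iis_fit(co, n_samples = 100, max_iters = 2, seed = 7)
  ib <- ibic(fit)
  expect_equal(as.numeric(ib),
               -2 * sum(fit$log_marginal) + fit$n_hyper * log(fit$n_decisions),
               tolerance = 1e-12)
  expect_equal(fit$n_hyper, 26L)
  # one extra free parameter (mean + sd) costs exactly 2 log N at equal fit
  stub <- fit; stub$n_hyper <- fit$n_hyper + 2L
  expect_equal(as.numeric(ibic(stub)) - as.numeric(ib),
               2 * log(fit$n_decisions), tolerance = 1e-12)
  # reduced variants have one parameter fewer
  fitr <- iis_fit(co, spec = model_spec("no-color-gather"), n_samples = 100,
                  max_iters = 2, seed = 7)
  expect_equal(fitr$n_hyper, 24L)
  expect_true(all(fitr$posterior_means[, "beta_dcolor"] == 0))
})

test_that("model comparison tables are ranked and reproducible", {
  co <- tiny_cohort(n = 2, seed = 65)
  one <- compare_models(co, specs = list("full"), n_samples = 80,
                        max_iters = 2, seed = 3)
  expect_equal(nrow(one), 1L)
  two <- compare_models(co, specs = list("full", "full"), n_samples = 80,
                        max_iters = 2, seed = 3)
  expect_equal(two$ibic[1], two$ibic[2], tolerance = 1e-12)
  expect_true(all(diff(two$ibic) >= 0))
})

test_that("fit objects expose the standard modelling methods", {
  co <- tiny_cohort(n = 2, seed = 66)
  fit <- suppressWarnings(iis_fit(co, n_samples = 100, max_iters = 2, seed = 2))
  expect_output(print(fit), "Hierarchical fit")
  s <- summary(fit)
  expect_true(all(c("param", "group_mean_natural") %in% names(s)))
  cg <- coef(fit)
  expect_named(cg, s$param)
  cp <- coef(fit, "participants")
  expect_equal(dim(cp), c(2L, 13L))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), sum(fit$log_marginal))
  expect_equal(attr(ll, "df"), 26L)
  sims <- simulate(fit, nsim = 1, seed = 4, schedule = co$data[[1]]$schedule)
  expect_length(sims[[1]], 2L)
  expect_s3_class(sims[[1]][[1]], "participant_sim")
})

test_that("a homogeneous cohort recovers its identifiable group quantities", {
  h <- generating_hyperparams()
  h$sd <- rep(0, nrow(h))
  co <- generate_cohort(cohort_spec(n_participants = 5, hyper = h, seed = 67))
  fit <- iis_fit(co, n_samples = 800, max_iters = 12, seed = 21)
  est <- setNames(fit$hyper$mean, fit$hyper$param)
  truth <- setNames(generating_hyperparams()$mean, generating_hyperparams()$param)
  for (nm in c("beta_dCs", "beta_dcolor", "beta_look_color", "beta_look_stay",
               "beta_choose")) {
    expect_lt(abs(est[[nm]] - truth[[nm]]), 0.6)
  }
  # the urgency triplet is a ridge: only the gather log-odds curve
  # alpha_gather + beta_time * (1 - tau^t) is well identified
  curve <- function(v, t) v[["alpha_gather"]] +
    v[["beta_time"]] * (1 - pnorm(v[["tau"]])^t)
  for (t in 1:4) expect_lt(abs(curve(est, t) - curve(truth, t)), 0.5)
  # colour weight on the natural scale
  expect_lt(abs(pnorm(est[["omega_color"]]) - pnorm(truth[["omega_color"]])), 0.25)
})
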
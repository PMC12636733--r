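#' Generating group-level hyperparameters for synthetic cohorts
#'
#' The default study conditions for simulated cohorts, in unconstrained space.
#' Signs and magnitudes follow the fitted-model account of the task: a
#' positive baseline tendency to gather (`alpha_gather`), stopping promoted by
#' large absolute value differences (`beta_dCs`, `beta_dcolor` negative — the
#' colour term is the trade-off mechanism) and by elapsed time (`beta_time`
#' negative), perseverant, value-guided looking, a positive choice inverse
#' temperature with partial colour weighting, and a retrieval rate
#' `tau_color` near 0.23 so that about 94.6% of the learned colour value is
#' available by the second decision event.
#'
#' @return Hyperparameter table as in [default_hyperparams()].
#' @export
generating_hyperparams <- function() {
  h <- default_hyperparams()
  means <- c(alpha_gather = 2.5, beta_dCs = -2.0, beta_dcolor = -2.0,
             beta_time = -1.0, tau = 0.0, alpha_look_right = 0.0,
             beta_look_color = 1.0, beta_look_Cs = 1.0, beta_look_stay = 0.5,
             beta_choose = 3.0, omega_color = 0.3,
             tau_color = stats::qnorm(0.2324), epsilon = 0.0)
  sds <- c(alpha_gather = 0.5, beta_dCs = 0.5, beta_dcolor = 0.5,
           beta_time = 0.5, tau = 0.5, alpha_look_right = 0.3,
           beta_look_color = 0.5, beta_look_Cs = 0.5, beta_look_stay = 0.3,
           beta_choose = 0.5, omega_color = 0.5, tau_color = 0.3,
           epsilon = 0.3)
  h$mean <- unname(means[h$param])
  h$sd <- unname(sds[h$param])
  h
}

#' Synthetic cohort specification
#'
#' @param n_participants Number of participants.
#' @param config A [task_config()].
#' @param hyper Generating hyperparameters ([generating_hyperparams()]).
#' @param iamap Screen geometry ([interest_area_map()]).
#' @param seed Master seed; everything downstream is derived from it.
#' @param max_steps Per-trial fixation cap.
#' @param jitter_sd Fixation-placement jitter sd in pixels (default
#'   radius / 4, clipped inside the acceptance radius so interest-area
#'   assignment is unambiguous by construction).
#' @param repeat_rate Probability of emitting a duplicate (repeat) fixation
#'   after each fixation, to exercise the repeat filter.
#' @param off_rate Probability of emitting an off-stimulus fixation after each
#'   fixation (stress mode).
#' @param degrade_fraction Fraction of participants assigned an eye-tracking
#'   validity below the 75% inclusion threshold.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 30L, config = task_config(),
                        hyper = generating_hyperparams(),
                        iamap = interest_area_map(), seed = 1L,
                        max_steps = 24L, jitter_sd = NULL,
                        repeat_rate = 0.05, off_rate = 0,
                        degrade_fraction = 0) {
  radius <- iamap$radius[1]
  if (is.null(jitter_sd)) jitter_sd <- radius / 4
  structure(list(n_participants = as.integer(n_participants), config = config,
                 hyper = hyper, iamap = iamap, seed = as.integer(seed),
                 max_steps = as.integer(max_steps), jitter_sd = jitter_sd,
                 repeat_rate = repeat_rate, off_rate = off_rate,
                 degrade_fraction = degrade_fraction),
            class = "cohort_spec")
}

jitter_point <- function(x, y, sd, radius) {
  repeat {
    dx <- stats::rnorm(1, 0, sd); dy <- stats::rnorm(1, 0, sd)
    if (sqrt(dx^2 + dy^2) < 0.95 * radius) return(c(x + dx, y + dy))
  }
}

# fixation report rows for one participant's simulation
emit_fixation_report <- function(sim, iamap, pid, jitter_sd, repeat_rate,
                                 off_rate) {
  fx <- sim$fixations
  key <- paste(iamap$side, iamap$c_index)
  radius <- iamap$radius[1]
  rows <- list()
  for (i in seq_len(nrow(fx))) {
    k <- match(paste(fx$side[i], fx$c_index[i]), key)
    pt <- jitter_point(iamap$x[k], iamap$y[k], jitter_sd, radius)
    t0 <- 1000 * fx$trial[i] + 250 * (fx$step[i] - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      participant = pid, trial = fx$trial[i], t_start = t0, duration = 200,
      x = pt[1], y = pt[2], stringsAsFactors = FALSE)
    if (repeat_rate > 0 && stats::runif(1) < repeat_rate) {
      pt2 <- jitter_point(iamap$x[k], iamap$y[k], jitter_sd, radius)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, trial = fx$trial[i], t_start = t0 + 100,
        duration = 80, x = pt2[1], y = pt2[2], stringsAsFactors = FALSE)
    }
    if (off_rate > 0 && stats::runif(1) < off_rate) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, trial = fx$trial[i], t_start = t0 + 150,
        duration = 60, x = 960 + stats::runif(1, -30, 30),
        y = 950 + stats::runif(1, -30, 30), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(participant = character(), trial = integer(),
                      t_start = numeric(), duration = numeric(),
                      x = numeric(), y = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic cohort
#'
#' Draws per-participant agent parameters from the generating group
#' distribution, builds each participant a schedule (colour counterbalancing
#' differs by participant seed), simulates behaviour, and emits a pixel-level
#' fixation report that reproduces the simulated fixations through the eye
#' parsing pipeline. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `data` (list of
#'   [participant_data()]), `sims`, `true_params` (matrix), `reports`
#'   (fixation-report data frames), `validity`, `iamap`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  P <- spec$n_participants
  set.seed(spec$seed)
  draws <- if (P > 0) sample_params(P, spec$hyper) else NULL
  valid_frac <- rep(1, P)
  if (spec$degrade_fraction > 0 && P > 0) {
    nbad <- round(spec$degrade_fraction * P)
    if (nbad > 0) {
      bad <- sample.int(P, nbad)
      valid_frac[bad] <- stats::runif(nbad, 0.3, 0.75)
    }
  }
  data <- sims <- reports <- vector("list", P)
  ids <- sprintf("p%02d", seq_len(P))
  for (p in seq_len(P)) {
    pseed <- spec$seed + 7919L * p
    sched <- generate_task(spec$config, seed = pseed)
    prm <- as_agent_params(unlist(draws[p, ]))
    sim <- simulate_participant(sched, prm, seed = pseed + 1L,
                                max_steps = spec$max_steps)
    # RNG stream continues from the simulation seed for report jitter
    reports[[p]] <- emit_fixation_report(sim, spec$iamap, ids[p],
                                         spec$jitter_sd, spec$repeat_rate,
                                         spec$off_rate)
    sims[[p]] <- sim
    data[[p]] <- as_participant_data(sim, sched, id = ids[p])
  }
  true_params <- if (P > 0) as.matrix(draws) else
    matrix(numeric(0), 0, length(PARAM_NAMES),
           dimnames = list(NULL, PARAM_NAMES))
  if (P > 0) rownames(true_params) <- ids
  structure(list(data = data, sims = sims, true_params = true_params,
                 reports = reports,
                 validity = data.frame(participant = ids,
                                       validity = valid_frac,
                                       stringsAsFactors = FALSE),
                 iamap = spec$iamap, spec = spec, ids = ids),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %s trials each\n",
              length(x$data),
              if (length(x$data)) nrow(x$data[[1]]$trials) else 0))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the file formats the parsing/analysis stages consume: per-participant
#' schedule and trial CSVs, a pooled fixation-report TSV, the interest-area
#' CSV, the validity CSV, and the ground-truth parameters as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(cohort$data)) {
    id <- cohort$ids[p]
    write_task_schedule(cohort$data[[p]]$schedule,
                        file.path(dir, sprintf("schedule_%s.csv", id)))
    utils::write.csv(cohort$data[[p]]$trials,
                     file.path(dir, sprintf("trials_%s.csv", id)),
                     row.names = FALSE)
  }
  write_fixation_report(do.call(rbind, cohort$reports),
                        file.path(dir, "fixation_report.tsv"))
  utils::write.csv(as.data.frame(cohort$iamap),
                   file.path(dir, "interest_areas.csv"), row.names = FALSE)
  utils::write.csv(cohort$validity, file.path(dir, "validity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(true_params = as.data.frame(cohort$true_params), seed = cohort$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Parameter-recovery harness
#'
#' Generates a cohort with known ground truth, fits it with [iis_fit()], and
#' tabulates recovery: per-parameter correlation between true and
#' posterior-mean values across participants, and the bias of the recovered
#' group means.
#'
#' @param spec A [cohort_spec()].
#' @param fit_spec The [model_spec()] to fit (default full).
#' @param ... Fitting settings passed to [iis_fit()].
#' @return List of class `recovery_report`: `report` (one row per free
#'   parameter), `fit`, `cohort`.
#' @export
recovery_harness <- function(spec = cohort_spec(),
                             fit_spec = model_spec("full"), ...) {
  cohort <- generate_cohort(spec)
  fit <- iis_fit(cohort, spec = fit_spec, ...)
  active <- fit$hyper$param[fit$hyper$active]
  rows <- lapply(active, function(nm) {
    tru <- cohort$true_params[, nm]
    est <- fit$posterior_means[, nm]
    r <- if (stats::sd(tru) > 0 && stats::sd(est) > 0) stats::cor(tru, est) else NA_real_
    k <- match(nm, fit$hyper$param)
    data.frame(param = nm,
               gen_mean_z = spec$hyper$mean[match(nm, spec$hyper$param)],
               recovered_mean_z = fit$hyper$mean[k],
               true_mean_natural = mean(tru),
               recovered_mean_natural = mean(est),
               correlation = r, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$bias_z <- report$recovered_mean_z - report$gen_mean_z
  structure(list(report = report, fit = fit, cohort = cohort),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (true vs posterior-mean, across participants)\n")
  print.data.frame(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}
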
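#' Model specification
#'
#' The full model uses learned colour information in both the
#' continue-gathering decision and the look-direction decision. The two
#' reduced variants each drop it from one of these (removing the corresponding
#' weight from the free parameters); colour always enters the choice rule via
#' `omega_color`.
#'
#' @param name `"full"`, `"no-color-gather"` (no colour term in the gather
#'   decision) or `"no-color-look"` (no colour term in the look decision).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("full", "no-color-gather", "no-color-look")) {
  name <- match.arg(name)
  gather <- name != "no-color-gather"
  look <- name != "no-color-look"
  active <- PARAM_NAMES
  if (!gather) active <- setdiff(active, "beta_dcolor")
  if (!look) active <- setdiff(active, "beta_look_color")
  structure(list(name = name,
                 include_color_in_gather = gather,
                 include_color_in_look = look,
                 active = active),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s': colour in gather = %s, colour in look = %s (%d free parameters)\n",
              x$name, x$include_color_in_gather, x$include_color_in_look,
              length(x$active)))
  invisible(x)
}

#' Participant data container
#'
#' Bundles a schedule with one participant's observed (or simulated) behaviour
#' for likelihood evaluation: per trial the fixation side/C sequence, the
#' choice and the reward.
#'
#' @param schedule A [generate_task()] schedule.
#' @param trials Data frame with columns `trial`, `trial_type`, `choice`
#'   (`"left"`/`"right"`), `reward` (0/1).
#' @param fixations Long data frame with columns `trial`, `step`, `side`,
#'   `c_index` (may have zero rows; immediate choices are allowed).
#' @param max_steps Per-trial fixation cap assumed by the generative process.
#' @param id Optional participant id.
#' @return An object of class `participant_data`.
#' @export
participant_data <- function(schedule, trials, fixations, max_steps = 24L,
                             id = NA_character_) {
  stopifnot(all(c("trial", "trial_type", "choice", "reward") %in% names(trials)))
  stopifnot(all(c("trial", "step", "side", "c_index") %in% names(fixations)))
  if (!all(trials$trial %in% schedule$trial)) stop_config("trials missing from schedule")
  structure(list(schedule = schedule, trials = trials,
                 fixations = fixations, max_steps = as.integer(max_steps),
                 id = id),
            class = "participant_data")
}

#' @export
print.participant_data <- function(x, ...) {
  cat(sprintf("Participant data: %d trials, %d fixations\n",
              nrow(x$trials), nrow(x$fixations)))
  invisible(x)
}

#' Coerce a simulated participant to a data container
#'
#' @param sim A [simulate_participant()] result.
#' @param schedule The schedule it was simulated on.
#' @param id Optional id.
#' @return A [participant_data()] object.
#' @export
as_participant_data <- function(sim, schedule, id = NA_character_) {
  participant_data(schedule, sim$trials, sim$fixations,
                   max_steps = sim$max_steps, id = id)
}

# gated effective colour difference for one decision family
.gate <- function(dv, on) if (on) dv else 0

#' Log-likelihood of one observed trial
#'
#' Sums, over the observed fixation sequence, the log-probabilities of each
#' continue decision and side decision, plus the stop decision and the choice,
#' then advances the learning state. Forced events (stop at the fixation cap
#' or with both rings exhausted; look towards the only non-exhausted side)
#' contribute zero. Which C within a side was fixated is uniform over the
#' unfixated Cs and parameter-free, so it is omitted. Each event probability
#' is floored at 1e-12 before taking the log.
#'
#' @param trial One schedule row.
#' @param record The corresponding row of the trials table.
#' @param fixations This trial's fixations, in step order.
#' @param state A [belief_state()].
#' @param params An [agent_params()] vector.
#' @param spec A [model_spec()].
#' @param up_levels,n_cs,max_steps Task structure.
#' @param td_cs `"believed"` uses the agent's posterior-based Cs value of the
#'   chosen stimulus in the TD prediction error; `"true"` uses the value
#'   implied by the true up-count.
#' @return List with `loglik` and the updated `state`.
#' @export
trial_loglik <- function(trial, record, fixations, state, params, spec,
                         up_levels = c(3L, 6L, 9L), n_cs = 12L,
                         max_steps = 24L, td_cs = c("believed", "true")) {
  td_cs <- match.arg(td_cs)
  tt <- record$trial_type
  has_color <- tt != "cs_only"
  has_cs <- tt != "color_only"
  ll <- 0

  vcl <- if (has_color) state$v_color[[trial$left_color]] else 0
  vcr <- if (has_color) state$v_color[[trial$right_color]] else 0
  dv_color_learned <- vcr - vcl

  up_l <- 0L; down_l <- 0L; up_r <- 0L; down_r <- 0L
  n_seen_l <- 0L; n_seen_r <- 0L
  last_side <- "none"
  v_l <- v_r <- 0

  if (has_cs) {
    ol <- orient_vec(trial$left_orient)
    or <- orient_vec(trial$right_orient)
    L <- nrow(fixations)
    for (j in seq_len(L + 1L) - 1L) {   # j = 0 .. L
      t_idx <- j + 1L
      v_l <- side_value(up_l, down_l, tt, up_levels, n_cs)
      v_r <- side_value(up_r, down_r, tt, up_levels, n_cs)
      dv_cs <- v_r - v_l
      dv_col_eff <- if (has_color) dv_color_learned * (1 - params[["tau_color"]]^t_idx) else 0
      exhausted <- n_seen_l >= n_cs && n_seen_r >= n_cs
      forced_stop <- j >= max_steps || exhausted
      if (j == L) {
        if (!forced_stop) {
          p_cont <- p_continue_gathering(dv_cs, .gate(dv_col_eff, spec$include_color_in_gather),
                                         t_idx, params)
          ll <- ll + max(log(1 - p_cont), .LOG_FLOOR)
        }
        break
      }
      if (forced_stop) stop_config("fixation recorded after forced stop")
      p_cont <- p_continue_gathering(dv_cs, .gate(dv_col_eff, spec$include_color_in_gather),
                                     t_idx, params)
      ll <- ll + max(log(p_cont), .LOG_FLOOR)
      side <- fixations$side[j + 1L]
      forced_side <- (n_seen_l >= n_cs) || (n_seen_r >= n_cs)
      if (!forced_side) {
        p_r <- p_look_right(dv_cs, .gate(dv_col_eff, spec$include_color_in_look),
                            last_side, params)
        p_side <- if (side == "right") p_r else 1 - p_r
        ll <- ll + max(log(p_side), .LOG_FLOOR)
      }
      ci <- fixations$c_index[j + 1L]
      if (ci < 1L || ci > n_cs) stop_config("fixated C index %d absent from schedule", ci)
      if (side == "left") {
        n_seen_l <- n_seen_l + 1L
        if (ol[ci] == 1L) up_l <- up_l + 1L else down_l <- down_l + 1L
      } else {
        n_seen_r <- n_seen_r + 1L
        if (or[ci] == 1L) up_r <- up_r + 1L else down_r <- down_r + 1L
      }
      last_side <- side
    }
    t_idx <- L + 1L
    dv_cs <- v_r - v_l
    dv_col_eff <- if (has_color) dv_color_learned * (1 - params[["tau_color"]]^t_idx) else 0
  } else {
    dv_cs <- 0
    dv_col_eff <- dv_color_learned * (1 - params[["tau_color"]])
  }

  p_right <- p_choose_right(dv_cs, if (has_color) dv_col_eff else 0, params)
  p_choice <- if (record$choice == "right") p_right else 1 - p_right
  ll <- ll + max(log(p_choice), .LOG_FLOOR)

  if (has_color) {
    chosen_color <- if (record$choice == "right") trial$right_color else trial$left_color
    v_cs_chosen <- 0
    if (has_cs) {
      if (td_cs == "believed") {
        v_cs_chosen <- if (record$choice == "right") v_r else v_l
      } else {
        true_up <- if (record$choice == "right") trial$right_up else trial$left_up
        lin <- cs_reward_prob(true_up, up_levels)
        v_cs_chosen <- 0.25 + 0.5 * lin
      }
    }
    state <- td_update(state, chosen_color, record$reward, v_cs_chosen, params)
  }
  list(loglik = ll, state = state)
}

#' Log-likelihood of a participant's dataset
#'
#' Folds [trial_loglik()] over trials in order with persistent learning state.
#' This is the reference R implementation; the importance-sampling fitter uses
#' an equivalent compiled kernel (cross-checked in the test suite).
#'
#' @param data A [participant_data()].
#' @param params An [agent_params()] vector.
#' @param spec A [model_spec()].
#' @param td_cs See [trial_loglik()].
#' @return Scalar log-likelihood (0 for an empty dataset), with per-trial
#'   contributions in attribute `"by_trial"`.
#' @export
dataset_loglik <- function(data, params, spec = model_spec("full"),
                           td_cs = c("believed", "true")) {
  td_cs <- match.arg(td_cs)
  cfg <- attr(data$schedule, "config") %||% task_config()
  colors <- unique(stats::na.omit(c(data$schedule$left_color, data$schedule$right_color)))
  state <- belief_state(colors)
  n <- nrow(data$trials)
  by_trial <- numeric(n)
  sched_idx <- match(data$trials$trial, data$schedule$trial)
  for (i in seq_len(n)) {
    tr <- data$schedule[sched_idx[i], , drop = FALSE]
    rec <- data$trials[i, , drop = FALSE]
    fx <- data$fixations[data$fixations$trial == rec$trial, , drop = FALSE]
    fx <- fx[order(fx$step), , drop = FALSE]
    out <- trial_loglik(tr, rec, fx, state, params, spec,
                        up_levels = cfg$up_levels, n_cs = cfg$n_cs_per_stimulus,
                        max_steps = data$max_steps, td_cs = td_cs)
    by_trial[i] <- out$loglik
    state <- out$state
  }
  total <- sum(by_trial)
  attr(total, "by_trial") <- by_trial
  total
}

#' Precompute likelihood inputs for fast evaluation
#'
#' Replays a participant's fixation record once to extract everything that
#' does not depend on the free parameters: the Cs value differences entering
#' each decision event, event time indices, perseverance codes, forced-event
#' flags and the per-trial colour/reward bookkeeping for the learning loop.
#' The result feeds the compiled likelihood kernel used by [iis_fit()].
#'
#' @param data A [participant_data()].
#' @param td_cs See [trial_loglik()].
#' @return A list of flat arrays (class `participant_prep`).
#' @export
prepare_participant <- function(data, td_cs = c("believed", "true")) {
  td_cs <- match.arg(td_cs)
  cfg <- attr(data$schedule, "config") %||% task_config()
  up_levels <- cfg$up_levels; n_cs <- cfg$n_cs_per_stimulus
  max_steps <- data$max_steps
  colors <- unique(stats::na.omit(c(data$schedule$left_color, data$schedule$right_color)))
  n <- nrow(data$trials)
  sched_idx <- match(data$trials$trial, data$schedule$trial)

  tt_code <- c(combined = 0L, cs_only = 1L, color_only = 2L)
  g_tr <- integer(0); g_t <- integer(0); g_dvcs <- numeric(0); g_y <- integer(0)
  l_tr <- integer(0); l_t <- integer(0); l_dvcs <- numeric(0)
  l_stay <- numeric(0); l_y <- integer(0)
  c_tr <- integer(n); c_t <- integer(n); c_dvcs <- numeric(n); c_y <- integer(n)
  trial_tt <- integer(n); cl <- integer(n); cr <- integer(n)
  chosen <- integer(n); reward <- numeric(n); vcs_chosen <- numeric(n)

  # value cache over (up, down) count pairs, per weight set
  val_cache <- function(type) {
    m <- matrix(NA_real_, n_cs + 1L, n_cs + 1L)
    for (u in 0:n_cs) for (d in 0:(n_cs - u)) {
      m[u + 1L, d + 1L] <- side_value(u, d, type, up_levels, n_cs)
    }
    m
  }
  vc_comb <- val_cache("combined"); vc_cs <- val_cache("cs_only")

  for (i in seq_len(n)) {
    tr <- data$schedule[sched_idx[i], , drop = FALSE]
    rec <- data$trials[i, , drop = FALSE]
    tt <- rec$trial_type
    trial_tt[i] <- tt_code[[tt]]
    has_color <- tt != "cs_only"; has_cs <- tt != "color_only"
    cl[i] <- if (has_color) match(tr$left_color, colors) else 0L
    cr[i] <- if (has_color) match(tr$right_color, colors) else 0L
    c_tr[i] <- i; c_y[i] <- as.integer(rec$choice == "right")
    reward[i] <- rec$reward
    chosen[i] <- if (has_color) { if (c_y[i] == 1L) cr[i] else cl[i] } else 0L

    if (!has_cs) {
      c_t[i] <- 1L; c_dvcs[i] <- 0; vcs_chosen[i] <- 0
      next
    }
    vc <- if (tt == "combined") vc_comb else vc_cs
    ol <- orient_vec(tr$left_orient); or <- orient_vec(tr$right_orient)
    fx <- data$fixations[data$fixations$trial == rec$trial, , drop = FALSE]
    fx <- fx[order(fx$step), , drop = FALSE]
    L <- nrow(fx)
    up_l <- 0L; down_l <- 0L; up_r <- 0L; down_r <- 0L
    n_l <- 0L; n_r <- 0L; last <- 0
    v_l <- v_r <- 0
    for (j in 0:L) {
      t_idx <- j + 1L
      v_l <- vc[up_l + 1L, down_l + 1L]; v_r <- vc[up_r + 1L, down_r + 1L]
      dv <- v_r - v_l
      forced_stop <- j >= max_steps || (n_l >= n_cs && n_r >= n_cs)
      if (j == L) {
        if (!forced_stop) {
          g_tr <- c(g_tr, i); g_t <- c(g_t, t_idx)
          g_dvcs <- c(g_dvcs, dv); g_y <- c(g_y, 0L)
        }
        break
      }
      g_tr <- c(g_tr, i); g_t <- c(g_t, t_idx)
      g_dvcs <- c(g_dvcs, dv); g_y <- c(g_y, 1L)
      side_right <- fx$side[j + 1L] == "right"
      if (!(n_l >= n_cs || n_r >= n_cs)) {
        l_tr <- c(l_tr, i); l_t <- c(l_t, t_idx); l_dvcs <- c(l_dvcs, dv)
        l_stay <- c(l_stay, last); l_y <- c(l_y, as.integer(side_right))
      }
      ci <- fx$c_index[j + 1L]
      if (side_right) {
        n_r <- n_r + 1L
        if (or[ci] == 1L) up_r <- up_r + 1L else down_r <- down_r + 1L
        last <- 1
      } else {
        n_l <- n_l + 1L
        if (ol[ci] == 1L) up_l <- up_l + 1L else down_l <- down_l + 1L
        last <- -1
      }
    }
    c_t[i] <- L + 1L
    c_dvcs[i] <- v_r - v_l
    if (has_color) {
      if (td_cs == "believed") {
        vcs_chosen[i] <- if (c_y[i] == 1L) v_r else v_l
      } else {
        true_up <- if (c_y[i] == 1L) tr$right_up else tr$left_up
        vcs_chosen[i] <- 0.25 + 0.5 * cs_reward_prob(true_up, up_levels)
      }
    }
  }

  structure(list(
    n_trials = n, n_colors = length(colors), colors = colors,
    trial_tt = trial_tt, cl = cl, cr = cr, chosen = chosen,
    reward = reward, vcs_chosen = vcs_chosen,
    g_tr = g_tr, g_t = g_t, g_dvcs = g_dvcs, g_y = g_y,
    l_tr = l_tr, l_t = l_t, l_dvcs = l_dvcs, l_stay = l_stay, l_y = l_y,
    c_tr = c_tr, c_t = c_t, c_dvcs = c_dvcs, c_y = c_y,
    t_max = max(1L, g_t, l_t, c_t),
    n_decisions = length(g_y) + length(l_y) + n
  ), class = "participant_prep")
}

#' Fast dataset log-likelihood for a batch of parameter vectors
#'
#' Evaluates the dataset log-likelihood of one participant for each row of a
#' parameter matrix, using the compiled kernel.
#'
#' @param prep A [prepare_participant()] result.
#' @param theta Numeric matrix, one row per parameter vector, columns in the
#'   canonical order (`gazetrade:::PARAM_NAMES`).
#' @param spec A [model_spec()].
#' @return Numeric vector of log-likelihoods, one per row of `theta`.
#' @export
batch_loglik <- function(prep, theta, spec = model_spec("full")) {
  stopifnot(inherits(prep, "participant_prep"))
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  stopifnot(ncol(theta) == length(PARAM_NAMES))
  participant_loglik_cpp(prep, theta,
                         spec$include_color_in_gather,
                         spec$include_color_in_look)
}

#' Replay learned colour values for given parameters
#'
#' Runs the across-trial learning loop once, returning each trial's
#' right-minus-left learned colour value difference and the per-colour value
#' trajectory. Useful for model-data correspondence summaries.
#'
#' @param prep A [prepare_participant()] result.
#' @param params An [agent_params()] vector.
#' @return Data frame with one row per trial: `dv_color_learned`, `v_left`,
#'   `v_right`.
#' @export
replay_color_values <- function(prep, params) {
  v <- numeric(prep$n_colors)
  eps <- params[["epsilon"]]
  dv <- vl <- vr <- numeric(prep$n_trials)
  nn <- integer(prep$n_colors)
  for (i in seq_len(prep$n_trials)) {
    vl[i] <- if (prep$cl[i] > 0L) v[prep$cl[i]] else 0
    vr[i] <- if (prep$cr[i] > 0L) v[prep$cr[i]] else 0
    dv[i] <- vr[i] - vl[i]
    ch <- prep$chosen[i]
    if (ch > 0L) {
      nn[ch] <- nn[ch] + 1L
      eta <- 1 / (eps + nn[ch] / 2)
      delta <- prep$reward[i] - (prep$vcs_chosen[i] + v[ch])
      v[ch] <- v[ch] + eta * delta
    }
  }
  data.frame(trial_index = seq_len(prep$n_trials),
             dv_color_learned = dv, v_left = vl, v_right = vr)
}
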
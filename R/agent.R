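#' @useDynLib gazetrade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical parameter order used throughout (R and C++ sides)
PARAM_NAMES <- c("alpha_gather", "beta_dCs", "beta_dcolor", "beta_time", "tau",
                 "alpha_look_right", "beta_look_color", "beta_look_Cs",
                 "beta_look_stay", "beta_choose", "omega_color", "tau_color",
                 "epsilon")

#' Agent parameters
#'
#' The 13 free parameters of the gather/look/choose agent. At each within-trial
#' decision event the agent first decides whether to continue gathering
#' perceptual information (a logistic in the absolute colour- and Cs-value
#' differences plus an urgency term), then, if gathering, which side to fixate
#' (a logistic in the signed value differences plus a perseverance term), and,
#' on stopping, which stimulus to choose (a logistic in
#' `dV_Cs + omega_color * dV_color`). Colour values are learned across trials
#' by temporal-difference updates with learning rate `1 / (epsilon + n/2)`,
#' and are retrieved within a trial at rate `1 - tau_color^t`.
#'
#' @param alpha_gather Baseline log-odds of continuing to gather.
#' @param beta_dCs Weight on `|dV_Cs|` in the gather decision.
#' @param beta_dcolor Weight on `|dV_color|` in the gather decision (negative
#'   values produce the learned/perceived trade-off).
#' @param beta_time Weight on the urgency term `1 - tau^t`.
#' @param tau Urgency growth rate, in \[0, 1\].
#' @param alpha_look_right Rightward looking bias.
#' @param beta_look_color,beta_look_Cs Weights on signed value differences in
#'   the look decision.
#' @param beta_look_stay Same-side perseverance weight (+1/-1 coding of the
#'   last fixated side; 0 at the first fixation of a trial).
#' @param beta_choose Choice inverse temperature.
#' @param omega_color Weight of colour value in the choice value, in \[0, 1\].
#' @param tau_color Colour-value retrieval rate, in \[0, 1\]; the fraction of
#'   the learned value available at decision event `t` is `1 - tau_color^t`.
#' @param epsilon Learning-rate offset, > 0.
#' @return Named numeric vector of class `agent_params`.
#' @export
agent_params <- function(alpha_gather = 1, beta_dCs = -2, beta_dcolor = -2,
                         beta_time = -1, tau = 0.5, alpha_look_right = 0,
                         beta_look_color = 1, beta_look_Cs = 1,
                         beta_look_stay = 0.5, beta_choose = 3,
                         omega_color = 0.6, tau_color = 0.2324, epsilon = 1) {
  p <- c(alpha_gather = alpha_gather, beta_dCs = beta_dCs,
         beta_dcolor = beta_dcolor, beta_time = beta_time, tau = tau,
         alpha_look_right = alpha_look_right, beta_look_color = beta_look_color,
         beta_look_Cs = beta_look_Cs, beta_look_stay = beta_look_stay,
         beta_choose = beta_choose, omega_color = omega_color,
         tau_color = tau_color, epsilon = epsilon)
  validate_agent_params(p)
  structure(p, class = "agent_params")
}

validate_agent_params <- function(p) {
  if (!all(PARAM_NAMES %in% names(p))) stop_config("missing agent parameters")
  if (any(!is.finite(p[PARAM_NAMES]))) stop_config("agent parameters must be finite")
  for (nm in c("tau", "tau_color", "omega_color")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop_config("%s must be in [0, 1]", nm)
  }
  if (p[["epsilon"]] <= 0) stop_config("epsilon must be > 0")
  invisible(p)
}

#' @rdname agent_params
#' @param x Named numeric vector (or one-row data frame) containing all 13
#'   parameters.
#' @export
as_agent_params <- function(x) {
  p <- as.numeric(x[PARAM_NAMES])
  names(p) <- PARAM_NAMES
  validate_agent_params(p)
  structure(p, class = "agent_params")
}

#' Posterior over the number of upward-facing Cs
#'
#' Binomial-likelihood posterior over the possible up-counts, with an implicit
#' uniform prior: `p(n)` is proportional to
#' `(n/n_cs)^observed_up * (1 - n/n_cs)^observed_down`.
#'
#' @param observed_up,observed_down Counts of upward/downward Cs fixated so far
#'   on one side this trial.
#' @param up_levels Candidate up-counts (default `c(3, 6, 9)`).
#' @param n_cs Ring size (default 12).
#' @return Probability vector over `up_levels`, summing to 1.
#' @export
cs_posterior <- function(observed_up, observed_down, up_levels = c(3L, 6L, 9L),
                         n_cs = 12L) {
  if (length(up_levels) == 0L) stop_config("up_levels must be nonempty")
  if (observed_up < 0 || observed_down < 0 ||
      observed_up + observed_down > n_cs) {
    stop_config("invalid observed counts")
  }
  q <- up_levels / n_cs
  w <- q^observed_up * (1 - q)^observed_down
  s <- sum(w)
  if (s <= 0) stop_config("posterior has zero mass for the observed counts")
  w / s
}

#' Value of a stimulus from its C-count posterior
#'
#' Expected reward contribution of the Cs: a posterior-weighted mean of the
#' per-level expected rewards. In combined trials a level's weight is the
#' marginal reward probability given that up-count (0.25/0.5/0.75 under the
#' defaults, the colour contribution averaging to 0.25); in Cs-only trials it
#' is the instructed probability itself (0/0.5/1).
#'
#' @param posterior Probability vector over `up_levels` (normalised).
#' @param trial_type `"combined"` or `"cs_only"`.
#' @param up_levels Candidate up-counts.
#' @return Scalar value.
#' @export
cs_value <- function(posterior, trial_type = c("combined", "cs_only"),
                     up_levels = c(3L, 6L, 9L)) {
  trial_type <- match.arg(trial_type)
  if (abs(sum(posterior) - 1) > 1e-8) stop_config("posterior must be normalised")
  lin <- cs_reward_prob(up_levels, up_levels)
  w <- if (trial_type == "combined") 0.25 + 0.5 * lin else lin
  sum(posterior * w)
}

#' Effective (retrieved) colour value
#'
#' The learned colour value is not available instantaneously: at decision event
#' `step` within a trial the agent uses `v_learned * (1 - tau_color^step)`.
#' With `tau_color = 0.2324` the retrieved fraction at the second event is
#' `1 - 0.2324^2 = 0.946`.
#'
#' @param v_learned Learned colour value.
#' @param step Decision-event index within the trial (>= 0).
#' @param tau_color Retrieval rate in \[0, 1\].
#' @return Effective value (vectorised over any argument).
#' @export
effective_color_value <- function(v_learned, step, tau_color) {
  if (any(step < 0)) stop_config("step must be >= 0")
  v_learned * (1 - tau_color^step)
}

#' Gather/look/choose policy probabilities
#'
#' The three within-trial decision rules. `p_continue_gathering` is a logistic
#' in the absolute value differences and the urgency term;
#' `p_look_right` in the signed differences plus perseverance;
#' `p_choose_right` in `beta_choose * (dv_cs + omega_color * dv_color)`
#' (colour-only trials have `dv_cs = 0`, Cs-only trials `dv_color = 0`).
#' All value-difference arguments are right minus left; colour differences are
#' the *effective* (retrieval-discounted) values.
#'
#' @param dv_cs Signed Cs value difference (right minus left).
#' @param dv_color Signed effective colour value difference.
#' @param step Decision-event index `t` (completed fixations + 1).
#' @param last_side `"left"`, `"right"` or `"none"` (first fixation).
#' @param params An [agent_params()] vector.
#' @return Probability (vectorised over the value arguments).
#' @export
p_continue_gathering <- function(dv_cs, dv_color, step, params) {
  logistic(params[["alpha_gather"]] +
           params[["beta_dCs"]] * abs(dv_cs) +
           params[["beta_dcolor"]] * abs(dv_color) +
           params[["beta_time"]] * (1 - params[["tau"]]^step))
}

#' @rdname p_continue_gathering
#' @export
p_look_right <- function(dv_cs, dv_color, last_side = "none", params) {
  stay <- c(left = -1, right = 1, none = 0)[[last_side]]
  logistic(params[["alpha_look_right"]] +
           params[["beta_look_color"]] * dv_color +
           params[["beta_look_Cs"]] * dv_cs +
           params[["beta_look_stay"]] * stay)
}

#' @rdname p_continue_gathering
#' @export
p_choose_right <- function(dv_cs, dv_color, params) {
  logistic(params[["beta_choose"]] *
             (dv_cs + params[["omega_color"]] * dv_color))
}

#' Across-trial belief state
#'
#' Holds the learned colour values and per-colour outcome counts carried from
#' trial to trial.
#'
#' @param colors Character vector of colour ids.
#' @return List with `v_color` (named numeric, initialised at 0) and `n_out`
#'   (named integer outcome counts).
#' @export
belief_state <- function(colors) {
  list(v_color = stats::setNames(numeric(length(colors)), colors),
       n_out = stats::setNames(integer(length(colors)), colors))
}

#' Temporal-difference update of a colour value
#'
#' After a rewarded or unrewarded choice of a coloured stimulus, the chosen
#' colour's value moves toward the prediction error
#' `delta = reward - (v_cs_chosen + v_color)` at rate
#' `eta = 1 / (epsilon + n/2)`, where `n` counts outcomes for that colour
#' including the current one (each outcome is only half attributable to the
#' colour). Only the chosen colour updates.
#'
#' @param state A [belief_state()].
#' @param chosen_color Colour id of the chosen stimulus.
#' @param reward Observed reward (0/1).
#' @param v_cs_chosen The Cs value of the chosen stimulus entering the
#'   prediction (the agent's believed value at choice time; 0 when no Cs).
#' @param params An [agent_params()] vector (uses `epsilon`).
#' @return Updated state.
#' @export
td_update <- function(state, chosen_color, reward, v_cs_chosen, params) {
  if (!chosen_color %in% names(state$v_color)) {
    stop_config("unknown colour id '%s'", chosen_color)
  }
  n <- state$n_out[[chosen_color]] + 1L
  state$n_out[[chosen_color]] <- n
  eta <- 1 / (params[["epsilon"]] + n / 2)
  delta <- reward - (v_cs_chosen + state$v_color[[chosen_color]])
  state$v_color[[chosen_color]] <- state$v_color[[chosen_color]] + eta * delta
  state
}

#' Pick a C to fixate on one side
#'
#' The policy chooses a side; the concrete C is drawn uniformly among that
#' side's not-yet-fixated Cs.
#'
#' @param fixated Integer vector of C indices already fixated on that side.
#' @param n_cs Ring size.
#' @return A single C index.
#' @export
select_c_to_fixate <- function(fixated, n_cs = 12L) {
  remaining <- setdiff(seq_len(n_cs), fixated)
  if (length(remaining) == 0L) stop_config("all Cs on this side already fixated")
  remaining[sample.int(length(remaining), 1L)]
}

orient_vec <- function(s) as.integer(strsplit(s, "")[[1]])

# within-trial evidence counts -> believed side value (param-free)
side_value <- function(up, down, trial_type, up_levels, n_cs) {
  cs_value(cs_posterior(up, down, up_levels, n_cs), trial_type, up_levels)
}

#' Simulate one trial of the gather/look/choose agent
#'
#' Runs the within-trial loop: at each decision event the agent draws
#' continue-vs-choose; while gathering it draws a side and fixates an unseen C
#' there; on stopping (or at `max_steps`, or with both rings exhausted) it
#' draws a choice and a Bernoulli reward, then applies the TD colour update.
#'
#' @param trial One row of a [generate_task()] schedule.
#' @param state A [belief_state()] carrying learning from earlier trials.
#' @param params An [agent_params()] vector.
#' @param up_levels,n_cs Task structure (defaults match [task_config()]).
#' @param max_steps Fixation cap per trial (default 24, both rings).
#' @return List with `record` (choice, reward, n_fix, rt_proxy, ...),
#'   `fixations` (data.frame: step, side, c_index, up) and the updated `state`.
#' @export
simulate_trial <- function(trial, state, params, up_levels = c(3L, 6L, 9L),
                           n_cs = 12L, max_steps = 24L) {
  tt <- trial$trial_type
  has_color <- tt != "cs_only"
  has_cs <- tt != "color_only"
  vcl <- if (has_color) state$v_color[[trial$left_color]] else 0
  vcr <- if (has_color) state$v_color[[trial$right_color]] else 0
  dv_color_learned <- vcr - vcl

  fix_side <- character(0); fix_idx <- integer(0); fix_up <- integer(0)
  up_l <- 0L; down_l <- 0L; up_r <- 0L; down_r <- 0L
  seen_l <- integer(0); seen_r <- integer(0)
  last_side <- "none"
  ol <- if (has_cs) orient_vec(trial$left_orient) else integer(0)
  or <- if (has_cs) orient_vec(trial$right_orient) else integer(0)

  s <- 0L
  if (has_cs) {
    repeat {
      t_idx <- s + 1L
      v_l <- side_value(up_l, down_l, tt, up_levels, n_cs)
      v_r <- side_value(up_r, down_r, tt, up_levels, n_cs)
      dv_cs <- v_r - v_l
      dv_col <- if (has_color) dv_color_learned * (1 - params[["tau_color"]]^t_idx) else 0
      exhausted <- length(seen_l) >= n_cs && length(seen_r) >= n_cs
      forced_stop <- s >= max_steps || exhausted
      if (forced_stop) break
      p_cont <- p_continue_gathering(dv_cs, dv_col, t_idx, params)
      if (stats::runif(1) >= p_cont) break
      # side
      if (length(seen_l) >= n_cs) {
        side <- "right"
      } else if (length(seen_r) >= n_cs) {
        side <- "left"
      } else {
        p_r <- p_look_right(dv_cs, dv_col, last_side, params)
        side <- if (stats::runif(1) < p_r) "right" else "left"
      }
      if (side == "left") {
        ci <- select_c_to_fixate(seen_l, n_cs)
        seen_l <- c(seen_l, ci)
        if (ol[ci] == 1L) up_l <- up_l + 1L else down_l <- down_l + 1L
        u <- ol[ci]
      } else {
        ci <- select_c_to_fixate(seen_r, n_cs)
        seen_r <- c(seen_r, ci)
        if (or[ci] == 1L) up_r <- up_r + 1L else down_r <- down_r + 1L
        u <- or[ci]
      }
      fix_side <- c(fix_side, side); fix_idx <- c(fix_idx, ci); fix_up <- c(fix_up, u)
      last_side <- side
      s <- s + 1L
    }
  }

  # choice at decision event t = s + 1
  t_idx <- s + 1L
  dv_col <- if (has_color) dv_color_learned * (1 - params[["tau_color"]]^t_idx) else 0
  if (has_cs) {
    v_l <- side_value(up_l, down_l, tt, up_levels, n_cs)
    v_r <- side_value(up_r, down_r, tt, up_levels, n_cs)
    dv_cs <- v_r - v_l
  } else {
    v_l <- v_r <- 0; dv_cs <- 0
  }
  p_right <- p_choose_right(dv_cs, dv_col, params)
  choice <- if (stats::runif(1) < p_right) "right" else "left"

  p_rew <- true_reward_prob(tt,
                            p_color = if (choice == "right") trial$right_p_color else trial$left_p_color,
                            up_count = if (choice == "right") trial$right_up else trial$left_up,
                            up_levels = up_levels)
  reward <- draw_reward(p_rew)

  chosen_color <- NA_character_
  v_cs_chosen <- 0
  if (has_color) {
    chosen_color <- if (choice == "right") trial$right_color else trial$left_color
    if (has_cs) v_cs_chosen <- if (choice == "right") v_r else v_l
    state <- td_update(state, chosen_color, reward, v_cs_chosen, params)
  }

  list(
    record = data.frame(
      trial = trial$trial, block = trial$block, trial_type = tt,
      choice = choice, reward = reward, n_fix = s, rt_proxy = s,
      chosen_color = chosen_color, v_cs_chosen = v_cs_chosen,
      dv_color_learned = dv_color_learned,
      up_l = up_l, down_l = down_l, up_r = up_r, down_r = down_r,
      stringsAsFactors = FALSE
    ),
    fixations = if (s > 0L) {
      data.frame(trial = trial$trial, step = seq_len(s), side = fix_side,
                 c_index = fix_idx, up = fix_up, stringsAsFactors = FALSE)
    } else {
      data.frame(trial = integer(), step = integer(), side = character(),
                 c_index = integer(), up = integer(), stringsAsFactors = FALSE)
    },
    state = state
  )
}

#' Simulate a participant over a full schedule
#'
#' Folds [simulate_trial()] over the schedule with persistent colour learning.
#' Deterministic given `seed`.
#'
#' @param schedule A [generate_task()] schedule.
#' @param params An [agent_params()] vector.
#' @param seed Integer seed.
#' @param max_steps Per-trial fixation cap.
#' @return An object of class `participant_sim`: list with `trials`
#'   (one row per trial), `fixations` (long format), `params`, `seed`.
#' @export
simulate_participant <- function(schedule, params, seed = 1L, max_steps = 24L) {
  cfg <- attr(schedule, "config") %||% task_config()
  set.seed(as.integer(seed))
  colors <- unique(stats::na.omit(c(schedule$left_color, schedule$right_color)))
  state <- belief_state(colors)
  recs <- vector("list", nrow(schedule))
  fixs <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    out <- simulate_trial(schedule[i, , drop = FALSE], state, params,
                          up_levels = cfg$up_levels,
                          n_cs = cfg$n_cs_per_stimulus, max_steps = max_steps)
    recs[[i]] <- out$record
    fixs[[i]] <- out$fixations
    state <- out$state
  }
  structure(list(
    trials = do.call(rbind, recs),
    fixations = do.call(rbind, fixs),
    params = params,
    state = state,
    seed = seed,
    max_steps = max_steps
  ), class = "participant_sim")
}

#' @export
print.participant_sim <- function(x, ...) {
  cat(sprintf("Simulated participant: %d trials, %d fixations, mean %.2f fixations/trial\n",
              nrow(x$trials), nrow(x$fixations), mean(x$trials$n_fix)))
  invisible(x)
}
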
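# shared fixtures: compact task design and hand-built single-trial data

# reduced design for fast tests: same structure, fewer trials
small_config <- function() {
  task_config(block_composition = list(
    c(combined = 12L, cs_only = 6L, color_only = 6L),
    c(combined = 12L, cs_only = 6L, color_only = 6L),
    c(combined = 30L, cs_only = 0L, color_only = 0L)
  ))
}

# neutral parameters: every linear weight zero -> all event probabilities 0.5
neutral_params <- function(...) {
  base <- list(alpha_gather = 0, beta_dCs = 0, beta_dcolor = 0, beta_time = 0,
               tau = 0.5, alpha_look_right = 0, beta_look_color = 0,
               beta_look_Cs = 0, beta_look_stay = 0, beta_choose = 0,
               omega_color = 0.5, tau_color = 0.5, epsilon = 1)
  do.call(agent_params, utils::modifyList(base, list(...)))
}

# a single-trial schedule with fully specified orientations
one_trial_schedule <- function(trial_type = "combined",
                               left_color = "c1", right_color = "c2",
                               left_p = 0, right_p = 1,
                               left_up = 3L, right_up = 9L,
                               left_orient = NULL, right_orient = NULL) {
  fixed_orient <- function(up) paste(c(rep("1", up), rep("0", 12 - up)),
                                     collapse = "")
  has_color <- trial_type != "cs_only"
  has_cs <- trial_type != "color_only"
  sched <- data.frame(
    block = 1L, trial = 1L, trial_type = trial_type, practice = FALSE,
    left_color = if (has_color) left_color else NA_character_,
    left_p_color = if (has_color) left_p else NA_real_,
    left_up = if (has_cs) left_up else NA_integer_,
    left_orient = if (has_cs) left_orient %||% fixed_orient(left_up) else NA_character_,
    right_color = if (has_color) right_color else NA_character_,
    right_p_color = if (has_color) right_p else NA_real_,
    right_up = if (has_cs) right_up else NA_integer_,
    right_orient = if (has_cs) right_orient %||% fixed_orient(right_up) else NA_character_,
    stringsAsFactors = FALSE
  )
  attr(sched, "config") <- task_config()
  class(sched) <- c("task_schedule", "data.frame")
  sched
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# participant_data for a single observed trial
one_trial_data <- function(sched, choice = "right", reward = 1L,
                           fix_sides = character(0), fix_idx = integer(0),
                           max_steps = 24L) {
  trials <- data.frame(trial = 1L, trial_type = sched$trial_type,
                       choice = choice, reward = reward,
                       stringsAsFactors = FALSE)
  fixations <- data.frame(trial = rep(1L, length(fix_sides)),
                          step = seq_along(fix_sides), side = fix_sides,
                          c_index = fix_idx, stringsAsFactors = FALSE)
  participant_data(sched, trials, fixations, max_steps = max_steps)
}

tiny_cohort <- function(n = 4L, seed = 101L, ...) {
  generate_cohort(cohort_spec(n_participants = n, config = small_config(),
                              seed = seed, ...))
}
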
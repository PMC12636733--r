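#' Task configuration
#'
#' Describes the two-armed bandit with compound stimuli: each option can carry a
#' coloured circle whose reward probability must be learned, and/or a ring of
#' `n_cs_per_stimulus` Landolt Cs whose reward probability is instructed to
#' scale linearly with the number of upward-facing Cs. The default design has
#' two learning blocks, each introducing three new colours with reward
#' probabilities \{0, 0.5, 1\} and interleaving 36 combined, 18 Cs-only and 18
#' colour-only trials, followed by a third block of 162 combined trials drawing
#' on all six colours.
#'
#' @param n_cs_per_stimulus Number of Landolt Cs per ring (default 12).
#' @param up_levels Possible counts of upward-facing Cs (default `c(3, 6, 9)`).
#' @param color_probs_per_block List of reward-probability sets, one per
#'   colour-introducing block (default two sets of `c(0, 0.5, 1)`).
#' @param block_composition List of per-block counts, each
#'   `c(combined =, cs_only =, color_only =)`.
#' @param choice_deadline Choice deadline in seconds (recorded; the generative
#'   model represents time pressure through its urgency term, not a clock).
#' @param reward_unit Payoff per rewarded trial.
#' @param allow_identical_pairs If `FALSE` (default), trials whose left and
#'   right stimuli are identical in every present component are resampled, so
#'   an accuracy criterion always has a better option or a colour/Cs tie only.
#' @param practice If `TRUE`, [generate_task()] prepends practice trials
#'   (block 0), excluded from analyses by default.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_cs_per_stimulus = 12L,
                        up_levels = c(3L, 6L, 9L),
                        color_probs_per_block = list(c(0, 0.5, 1), c(0, 0.5, 1)),
                        block_composition = list(
                          c(combined = 36L, cs_only = 18L, color_only = 18L),
                          c(combined = 36L, cs_only = 18L, color_only = 18L),
                          c(combined = 162L, cs_only = 0L, color_only = 0L)
                        ),
                        choice_deadline = 4,
                        reward_unit = 1,
                        allow_identical_pairs = FALSE,
                        practice = FALSE) {
  n_cs_per_stimulus <- as.integer(n_cs_per_stimulus)
  up_levels <- sort(as.integer(up_levels))
  if (n_cs_per_stimulus < 1L) stop_config("n_cs_per_stimulus must be positive")
  if (length(up_levels) < 1L || any(up_levels < 0L) ||
      any(up_levels > n_cs_per_stimulus)) {
    stop_config("up_levels must lie in [0, n_cs_per_stimulus]")
  }
  for (p in unlist(color_probs_per_block)) {
    if (!is.finite(p) || p < 0 || p > 1) stop_config("colour probabilities must be in [0, 1]")
  }
  for (bc in block_composition) {
    if (!all(c("combined", "cs_only", "color_only") %in% names(bc))) {
      stop_config("each block composition needs combined/cs_only/color_only counts")
    }
    if (any(bc < 0)) stop_config("block trial counts must be nonnegative")
  }
  structure(list(
    n_cs_per_stimulus = n_cs_per_stimulus,
    up_levels = up_levels,
    color_probs_per_block = color_probs_per_block,
    block_composition = block_composition,
    choice_deadline = choice_deadline,
    reward_unit = reward_unit,
    allow_identical_pairs = isTRUE(allow_identical_pairs),
    practice = isTRUE(practice)
  ), class = "task_config")
}

# Linear map from an up-count to the Cs reward probability: the smallest level
# predicts 0, the largest predicts 1 (3 -> 0, 6 -> 0.5, 9 -> 1 by default).
cs_reward_prob <- function(up_count, up_levels = c(3L, 6L, 9L)) {
  lo <- min(up_levels); hi <- max(up_levels)
  if (hi == lo) return(rep(0.5, length(up_count)))
  (up_count - lo) / (hi - lo)
}

#' True reward probability of a stimulus
#'
#' Combined stimuli predict reward by the additive, equally weighted rule
#' `(p_color + p_cs) / 2`, where `p_cs` maps the up-count linearly onto
#' \[0, 1\] (3 -> 0, 6 -> 0.5, 9 -> 1 under the defaults). Single-component
#' stimuli use the corresponding component alone.
#'
#' @param trial_type One of `"combined"`, `"cs_only"`, `"color_only"`.
#' @param p_color Reward probability of the colour (or `NA` for cs_only).
#' @param up_count Number of upward-facing Cs (or `NA` for color_only).
#' @param up_levels The possible up-counts (defines the linear map).
#' @return Reward probability in \[0, 1\]. Vectorised over `p_color`/`up_count`.
#' @export
true_reward_prob <- function(trial_type, p_color = NA_real_, up_count = NA_integer_,
                             up_levels = c(3L, 6L, 9L)) {
  trial_type <- match.arg(trial_type, c("combined", "cs_only", "color_only"))
  p_cs <- cs_reward_prob(up_count, up_levels)
  out <- switch(trial_type,
    combined = (p_color + p_cs) / 2,
    cs_only = p_cs,
    color_only = p_color
  )
  if (any(is.na(out))) stop_config("missing stimulus component for trial type '%s'", trial_type)
  out
}

#' Bernoulli reward draw
#'
#' @param p Reward probability (vectorised).
#' @return 0/1 integer vector of the same length.
#' @export
draw_reward <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop_config("reward probability must be in [0, 1]")
  as.integer(stats::runif(length(p)) < p)
}

orientation_string <- function(up_count, n_cs) {
  o <- integer(n_cs)
  o[sample.int(n_cs, up_count)] <- 1L
  paste(o, collapse = "")
}

# One stimulus side for a trial of the given type.
sample_stimulus <- function(trial_type, colors, color_probs, up_levels, n_cs) {
  color_id <- NA_character_; p_color <- NA_real_
  up <- NA_integer_; orient <- NA_character_
  if (trial_type != "cs_only") {
    k <- sample.int(length(colors), 1L)
    color_id <- colors[k]; p_color <- color_probs[k]
  }
  if (trial_type != "color_only") {
    up <- up_levels[sample.int(length(up_levels), 1L)]
    orient <- orientation_string(up, n_cs)
  }
  list(color_id = color_id, p_color = p_color, up = up, orient = orient)
}

#' Generate a task schedule
#'
#' Builds the full trial list for one participant: per-block trial-type counts
#' are exact, trial order within a block is randomised, and each stimulus is
#' sampled uniformly over the block's colour set and the up-count levels.
#' Colour-to-probability assignment is a per-participant random permutation
#' (counterbalancing), drawn from the same seed.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A `data.frame` of class `task_schedule` with one row per trial:
#'   `block`, `trial`, `trial_type`, and `left_`/`right_`-prefixed `color`,
#'   `p_color`, `up`, `orient` (orientation 0/1 string), plus `practice`.
#' @export
generate_task <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(as.integer(seed))
  n_color_blocks <- length(config$color_probs_per_block)
  # colour ids c1, c2, ... ; per-block sets of 3 (or however many probs given)
  sets <- vector("list", n_color_blocks)
  idx <- 0L
  for (b in seq_len(n_color_blocks)) {
    probs <- config$color_probs_per_block[[b]]
    ids <- paste0("c", idx + seq_along(probs))
    idx <- idx + length(probs)
    # counterbalancing: random colour-to-probability permutation per participant
    sets[[b]] <- list(ids = ids, probs = sample(probs))
  }
  all_ids <- unlist(lapply(sets, `[[`, "ids"))
  all_probs <- unlist(lapply(sets, `[[`, "probs"))

  blocks <- seq_along(config$block_composition)
  rows <- list()
  make_block <- function(b, comp, colors, probs, practice = FALSE) {
    types <- rep(c("combined", "cs_only", "color_only"),
                 times = c(comp[["combined"]], comp[["cs_only"]], comp[["color_only"]]))
    if (length(types) == 0L) return(NULL)
    types <- sample(types)
    out <- vector("list", length(types))
    for (i in seq_along(types)) {
      tt <- types[i]
      repeat {
        L <- sample_stimulus(tt, colors, probs, config$up_levels, config$n_cs_per_stimulus)
        R <- sample_stimulus(tt, colors, probs, config$up_levels, config$n_cs_per_stimulus)
        identical_pair <- identical(L$color_id, R$color_id) &&
          identical(L$up, R$up)
        if (config$allow_identical_pairs || !identical_pair) break
      }
      out[[i]] <- data.frame(
        block = b, trial = NA_integer_, trial_type = tt, practice = practice,
        left_color = L$color_id, left_p_color = L$p_color,
        left_up = L$up, left_orient = L$orient,
        right_color = R$color_id, right_p_color = R$p_color,
        right_up = R$up, right_orient = R$orient,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }

  if (config$practice) {
    comp <- c(combined = 10L, cs_only = 10L, color_only = 10L)
    rows[[length(rows) + 1L]] <-
      make_block(0L, comp, sets[[1L]]$ids, sets[[1L]]$probs, practice = TRUE)
  }
  for (b in blocks) {
    comp <- config$block_composition[[b]]
    if (b <= n_color_blocks) {
      colors <- sets[[b]]$ids; probs <- sets[[b]]$probs
    } else {
      colors <- all_ids; probs <- all_probs
    }
    rows[[length(rows) + 1L]] <- make_block(b, comp, colors, probs)
  }
  sched <- do.call(rbind, rows)
  if (is.null(sched)) {
    sched <- data.frame(block = integer(), trial = integer(),
                        trial_type = character(), practice = logical(),
                        left_color = character(), left_p_color = numeric(),
                        left_up = integer(), left_orient = character(),
                        right_color = character(), right_p_color = numeric(),
                        right_up = integer(), right_orient = character(),
                        stringsAsFactors = FALSE)
  }
  sched$trial <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  attr(sched, "config") <- config
  class(sched) <- c("task_schedule", "data.frame")
  sched
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("Task schedule: %d trials in %d block(s)\n",
              nrow(x), length(unique(x$block))))
  if (nrow(x)) {
    tab <- table(x$block, x$trial_type)
    print(tab)
  }
  invisible(x)
}

#' Write / read a task schedule as CSV
#'
#' Plain-CSV serialisation (one row per trial; orientations as 0/1 strings).
#'
#' @param schedule A `task_schedule`.
#' @param path File path.
#' @return `read_task_schedule` returns the schedule `data.frame`.
#' @export
write_task_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_task_schedule
#' @export
read_task_schedule <- function(path) {
  sched <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(left_orient = "character",
                                          right_orient = "character"))
  class(sched) <- c("task_schedule", "data.frame")
  sched
}
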
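# Brute-force enumeration oracle: chains the closed-form policy probabilities
# over every possible (side sequence, choice) outcome of one trial, summing
# over which C (upward or downward) each fixation lands on. Independent of
# trial_loglik / simulate_trial internals.
enumerate_side_outcomes <- function(sched, params, v_left = 0, v_right = 0,
                                    max_steps = 2L, up_levels = c(3L, 6L, 9L),
                                    n_cs = 12L) {
  tt <- sched$trial_type
  has_color <- tt != "cs_only"
  dv_col_learned <- if (has_color) v_right - v_left else 0
  up_tot_l <- sched$left_up; up_tot_r <- sched$right_up
  acc <- new.env(parent = emptyenv())
  add <- function(key, p) {
    assign(key, (if (exists(key, acc)) get(key, acc) else 0) + p, acc)
  }
  rec <- function(ul, dl, ur, dr, last, s, seq, prob) {
    t_idx <- s + 1L
    vl <- cs_value(cs_posterior(ul, dl, up_levels, n_cs), tt, up_levels)
    vr <- cs_value(cs_posterior(ur, dr, up_levels, n_cs), tt, up_levels)
    dv_cs <- vr - vl
    dv_col <- dv_col_learned * (1 - params[["tau_color"]]^t_idx)
    nl <- ul + dl; nr <- ur + dr
    forced <- s >= max_steps || (nl >= n_cs && nr >= n_cs)
    p_cont <- if (forced) 0 else p_continue_gathering(dv_cs, dv_col, t_idx, params)
    p_r <- p_choose_right(dv_cs, dv_col, params)
    add(paste0(seq, "|right"), prob * (1 - p_cont) * p_r)
    add(paste0(seq, "|left"), prob * (1 - p_cont) * (1 - p_r))
    if (p_cont > 0) {
      p_side_r <- if (nl >= n_cs) 1 else if (nr >= n_cs) 0 else
        p_look_right(dv_cs, dv_col, last, params)
      if (p_side_r < 1) {   # fixate left: branch on orientation of the C
        rem_up <- up_tot_l - ul; rem <- n_cs - nl
        p_up <- rem_up / rem
        base <- prob * p_cont * (1 - p_side_r)
        if (p_up > 0) rec(ul + 1L, dl, ur, dr, "left", s + 1L,
                          paste0(seq, "L"), base * p_up)
        if (p_up < 1) rec(ul, dl + 1L, ur, dr, "left", s + 1L,
                          paste0(seq, "L"), base * (1 - p_up))
      }
      if (p_side_r > 0) {
        rem_up <- up_tot_r - ur; rem <- n_cs - nr
        p_up <- rem_up / rem
        base <- prob * p_cont * p_side_r
        if (p_up > 0) rec(ul, dl, ur + 1L, dr, "right", s + 1L,
                          paste0(seq, "R"), base * p_up)
        if (p_up < 1) rec(ul, dl, ur, dr + 1L, "right", s + 1L,
                          paste0(seq, "R"), base * (1 - p_up))
      }
    }
  }
  rec(0L, 0L, 0L, 0L, "none", 0L, "", 1)
  out <- data.frame(outcome = ls(acc),
                    prob = vapply(ls(acc), get, numeric(1), envir = acc),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# all (c-index sequence, choice) outcomes up to max_steps fixations, each with
# the uniform C-selection factor; used to check that exp(trial_loglik) times
# the omitted constant sums to one
enumerate_cindex_outcomes <- function(max_steps = 2L, n_cs = 12L) {
  seqs <- list(list(sides = character(0), idx = integer(0), fac = 1))
  out <- list()
  for (s in seq_len(max_steps + 1L) - 1L) {
    for (sq in seqs) if (length(sq$sides) == s) out[[length(out) + 1L]] <- sq
    if (s == max_steps) break
    nxt <- list()
    for (sq in seqs) {
      if (length(sq$sides) != s) next
      for (side in c("left", "right")) {
        used <- sq$idx[sq$sides == side]
        remaining <- setdiff(seq_len(n_cs), used)
        for (ci in remaining) {
          nxt[[length(nxt) + 1L]] <- list(sides = c(sq$sides, side),
                                          idx = c(sq$idx, ci),
                                          fac = sq$fac / length(remaining))
        }
      }
    }
    seqs <- c(seqs, nxt)
  }
  out
}
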
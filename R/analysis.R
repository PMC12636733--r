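#' Build trial-level choice predictors
#'
#' For each combined trial, constructs the regression predictors: the
#' instructed up-count difference (`dCs_instr`, right minus left), the
#' observed-C difference `dCs_obs` (upward- minus downward-facing fixated Cs,
#' right minus left stimulus), the total number of fixated Cs (`sumCs`), the
#' colour reward-history difference `dPcolor` (proportion of rewarded choices
#' of each colour over *prior* trials; colours never chosen score 0), and an
#' RT measure (the fixation-step proxy for simulated data). All predictors
#' are z-scored within participant (`z_`-prefixed columns); zero-variance
#' predictors are flagged and left at zero.
#'
#' @param data A [participant_data()].
#' @param counts Optional per-trial gaze totals (`trial`, `up_l`, `down_l`,
#'   `up_r`, `down_r`), e.g. aggregated from [cumulative_counts()]. Defaults
#'   to the counts stored in `data$trials`. If absent entirely, observed
#'   counts fall back to the instructed ones (flagged).
#' @return Data frame, one row per combined trial, with attribute
#'   `"zero_variance"` naming degenerate predictors and `"fallback_instructed"`.
#' @export
build_predictors <- function(data, counts = NULL) {
  tr <- data$trials
  si <- match(tr$trial, data$schedule$trial)
  sch <- data$schedule[si, , drop = FALSE]

  # colour reward history up to but excluding the current trial
  colors <- unique(stats::na.omit(c(sch$left_color, sch$right_color)))
  nch <- stats::setNames(numeric(length(colors)), colors)
  nrew <- nch
  ph_left <- ph_right <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    lc <- sch$left_color[i]; rc <- sch$right_color[i]
    ph_left[i] <- if (!is.na(lc) && nch[[lc]] > 0) nrew[[lc]] / nch[[lc]] else 0
    ph_right[i] <- if (!is.na(rc) && nch[[rc]] > 0) nrew[[rc]] / nch[[rc]] else 0
    cc <- if (tr$choice[i] == "right") rc else lc
    if (!is.na(cc)) {
      nch[[cc]] <- nch[[cc]] + 1
      nrew[[cc]] <- nrew[[cc]] + tr$reward[i]
    }
  }

  fallback <- FALSE
  cnt_cols <- c("up_l", "down_l", "up_r", "down_r")
  if (is.null(counts)) {
    if (all(cnt_cols %in% names(tr))) {
      counts <- tr[, c("trial", cnt_cols)]
    } else {
      fallback <- TRUE
      counts <- data.frame(trial = tr$trial,
                           up_l = sch$left_up, down_l = 12 - sch$left_up,
                           up_r = sch$right_up, down_r = 12 - sch$right_up)
    }
  }
  ci <- match(tr$trial, counts$trial)

  keep <- tr$trial_type == "combined"
  out <- data.frame(
    trial = tr$trial[keep],
    choice = as.integer(tr$choice[keep] == "right"),
    dCs_instr = (sch$right_up - sch$left_up)[keep],
    dCs_obs = ((counts$up_r - counts$down_r) -
               (counts$up_l - counts$down_l))[ci][keep],
    sumCs = (counts$up_l + counts$down_l + counts$up_r + counts$down_r)[ci][keep],
    dPcolor = (ph_right - ph_left)[keep],
    rt = if ("rt" %in% names(tr)) tr$rt[keep] else tr$rt_proxy[keep],
    stringsAsFactors = FALSE
  )
  out$absdCs_obs <- abs(out$dCs_obs)
  zero_var <- character(0)
  for (v in c("dCs_instr", "dCs_obs", "sumCs", "dPcolor", "rt", "absdCs_obs")) {
    z <- zscore(out[[v]])
    if (isTRUE(attr(z, "zero_variance"))) zero_var <- c(zero_var, v)
    out[[paste0("z_", v)]] <- as.numeric(z)
  }
  attr(out, "zero_variance") <- zero_var
  attr(out, "fallback_instructed") <- fallback
  out
}

CHOICE_FORMULAS <- list(
  cs = c("z_dCs_instr"),
  color = c("z_dPcolor"),
  combined = c("z_dCs_instr", "z_dPcolor"),
  tradeoff = c("z_dCs_obs", "z_dPcolor", "z_dPcolor:z_sumCs"),
  tradeoff_evidence = c("z_dCs_obs", "z_dPcolor", "z_dPcolor:z_sumCs",
                        "z_dPcolor:z_absdCs_obs"),
  rt_moderation = c("z_dCs_obs", "z_dPcolor", "z_dPcolor:z_sumCs",
                    "z_dPcolor:z_rt")
)

design_matrix <- function(pred, terms) {
  X <- matrix(1, nrow(pred), length(terms) + 1L,
              dimnames = list(NULL, c("(Intercept)", terms)))
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    v <- rep(1, nrow(pred))
    for (p in parts) v <- v * pred[[p]]
    X[, tm] <- v
  }
  X
}

# Newton-Raphson logistic regression with optional ridge penalty
ridge_logistic <- function(X, y, lambda = 0, max_iter = 100) {
  b <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- logistic(eta)
    W <- p * (1 - p)
    g <- crossprod(X, y - p) - lambda * b
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    b <- b + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% b)
  se <- tryCatch(sqrt(diag(solve(crossprod(X, X * logistic(eta) *
                                             (1 - logistic(eta)))))),
                 error = function(e) rep(NA_real_, ncol(X)))
  ll <- sum(y * log_logistic(eta) + (1 - y) * log_logistic(-eta))
  list(coef = stats::setNames(b, colnames(X)), se = se, deviance = -2 * ll)
}

#' Per-participant choice regressions with group-level tests
#'
#' Fits the named logistic-regression formula separately per participant by
#' maximum likelihood and tests each coefficient against zero across
#' participants with a one-sample t-test — a two-stage approximation to a
#' mixed logistic model with full random slopes. Quasi-separated participants
#' are refit with a small ridge penalty and flagged.
#'
#' @param preds A list of [build_predictors()] tables (one per participant),
#'   or a single table.
#' @param formula One of `"cs"`, `"color"`, `"combined"`, `"tradeoff"`,
#'   `"tradeoff_evidence"`, `"rt_moderation"`.
#' @param min_trials Minimum usable trials per participant (default 30).
#' @param ridge Ridge penalty used on fallback (default 0.5).
#' @return Object of class `choice_model_fit`: per-participant coefficients,
#'   the group-level test table, and per-participant deviance and BIC.
#' @export
fit_choice_model <- function(preds, formula = "tradeoff", min_trials = 30L,
                             ridge = 0.5) {
  if (is.data.frame(preds)) preds <- list(preds)
  formula <- match.arg(formula, names(CHOICE_FORMULAS))
  terms <- CHOICE_FORMULAS[[formula]]
  coefs <- ses <- matrix(NA_real_, length(preds), length(terms) + 1L,
                         dimnames = list(NULL, c("(Intercept)", terms)))
  dev <- bic <- rep(NA_real_, length(preds))
  flagged <- logical(length(preds))
  for (p in seq_along(preds)) {
    d <- preds[[p]]
    if (nrow(d) < min_trials) next
    X <- design_matrix(d, terms)
    f <- ridge_logistic(X, d$choice, lambda = 0)
    if (any(!is.finite(f$coef)) || max(abs(f$coef)) > 15) {
      f <- ridge_logistic(X, d$choice, lambda = ridge)
      flagged[p] <- TRUE
    }
    coefs[p, ] <- f$coef
    ses[p, ] <- f$se
    dev[p] <- f$deviance
    bic[p] <- f$deviance + ncol(X) * log(nrow(d))
  }
  ok <- !is.na(coefs[, 1])
  group <- do.call(rbind, lapply(colnames(coefs), function(cn) {
    v <- coefs[ok, cn]
    tt <- if (sum(ok) >= 3 && stats::sd(v) > 0) stats::t.test(v) else NULL
    data.frame(term = cn, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(formula = formula, terms = terms, coefs = coefs, ses = ses,
                 group = group, deviance = dev, bic = bic,
                 total_bic = sum(bic[ok]), flagged = flagged,
                 n_fit = sum(ok)),
            class = "choice_model_fit")
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat(sprintf("Choice model '%s': %d participants fit (total BIC %.1f)\n",
              x$formula, x$n_fit, x$total_bic))
  print.data.frame(x$group, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Choice-accuracy contrasts
#'
#' On combined trials, computes each participant's tendency to choose the
#' stimulus favoured by (a) the total reward probability, (b) the up-count
#' alone, and (c) the colour probability alone — each over the trials where
#' that criterion is not tied — with paired t-tests of (a) against (b) and
#' (c) across participants.
#'
#' @param cohort A list of [participant_data()] (or [generate_cohort()]
#'   result).
#' @return List of class `accuracy_contrasts`: `accuracy` (per participant)
#'   and `tests`.
#' @export
accuracy_contrasts <- function(cohort) {
  cohort <- as_cohort(cohort)
  acc <- do.call(rbind, lapply(seq_along(cohort), function(p) {
    d <- cohort[[p]]
    tr <- d$trials[d$trials$trial_type == "combined", ]
    si <- match(tr$trial, d$schedule$trial)
    sch <- d$schedule[si, , drop = FALSE]
    p_tot_r <- true_reward_prob("combined", sch$right_p_color, sch$right_up)
    p_tot_l <- true_reward_prob("combined", sch$left_p_color, sch$left_up)
    right <- tr$choice == "right"
    rate <- function(crit_r, crit_l) {
      nt <- crit_r != crit_l
      if (!any(nt)) return(NA_real_)
      mean((right & crit_r > crit_l | !right & crit_l > crit_r)[nt])
    }
    data.frame(participant = p,
               combined_optimal = rate(p_tot_r, p_tot_l),
               cs_optimal = rate(sch$right_up, sch$left_up),
               color_optimal = rate(sch$right_p_color, sch$left_p_color))
  }))
  tests <- list(
    combined_vs_cs = stats::t.test(acc$combined_optimal, acc$cs_optimal,
                                   paired = TRUE),
    combined_vs_color = stats::t.test(acc$combined_optimal, acc$color_optimal,
                                      paired = TRUE)
  )
  structure(list(accuracy = acc, tests = tests), class = "accuracy_contrasts")
}

#' @export
print.accuracy_contrasts <- function(x, ...) {
  cat("Mean accuracies: ")
  cat(sprintf("combined %.3f, Cs %.3f, colour %.3f\n",
              mean(x$accuracy$combined_optimal, na.rm = TRUE),
              mean(x$accuracy$cs_optimal, na.rm = TRUE),
              mean(x$accuracy$color_optimal, na.rm = TRUE)))
  invisible(x)
}

#' Relative-use indices
#'
#' Per-participant summaries of reliance on learned (colour) versus perceived
#' (Cs) information: a regression-based index contrasting the colour and Cs
#' choice weights, and a model-based index `omega_color / alpha_gather` from
#' the hierarchical fit. The regression index has two reconstructions:
#' `"symmetric"` (default) divides by `|beta_Cs| + |beta_color|`;
#' `"asymmetric"` divides by `beta_Cs + |beta_color|`. Indices with a
#' near-zero denominator are returned as `NA` and counted.
#'
#' @param coefs A [fit_choice_model()] result whose terms include a Cs and a
#'   colour weight (e.g. formula `"combined"` or `"tradeoff"`).
#' @param fit Optional [iis_fit()] for the model-based index.
#' @param variant `"symmetric"` or `"asymmetric"`.
#' @return Data frame of class `use_index`: per participant `beta_Cs`,
#'   `beta_color`, `reg_index`, and (if `fit` given) `model_index` with a
#'   `negative_denominator` flag.
#' @export
use_indices <- function(coefs, fit = NULL,
                        variant = c("symmetric", "asymmetric")) {
  variant <- match.arg(variant)
  cs_term <- intersect(c("z_dCs_instr", "z_dCs_obs"), coefs$terms)[1]
  b_cs <- coefs$coefs[, cs_term]
  b_col <- coefs$coefs[, "z_dPcolor"]
  den <- if (variant == "symmetric") abs(b_cs) + abs(b_col) else b_cs + abs(b_col)
  idx <- ifelse(abs(den) < 1e-8, NA_real_, (b_col - b_cs) / den)
  out <- data.frame(participant = seq_along(b_cs), beta_Cs = b_cs,
                    beta_color = b_col, reg_index = idx)
  if (!is.null(fit)) {
    om <- fit$posterior_means[, "omega_color"]
    ag <- fit$posterior_means[, "alpha_gather"]
    out$model_index <- ifelse(abs(ag) < 1e-8, NA_real_, om / ag)
    out$negative_denominator <- ag < 0
  }
  attr(out, "n_undefined") <- sum(is.na(idx))
  attr(out, "variant") <- variant
  class(out) <- c("use_index", "data.frame")
  out
}

#' Cross-measure correlations
#'
#' Pearson correlations (with p-values) among per-participant measures —
#' e.g. regression weights, model parameters, use indices, session-1 vs
#' session-2 indices, or fixation/RT contrasts.
#'
#' @param measures Data frame, one row per participant, numeric columns.
#' @param pairs Optional 2-column character matrix of column pairs; default
#'   all pairs.
#' @return Data frame: `var1`, `var2`, `n`, `r`, `p`.
#' @export
cross_measures <- function(measures, pairs = NULL) {
  num <- names(measures)[vapply(measures, is.numeric, logical(1))]
  if (is.null(pairs)) {
    pairs <- t(utils::combn(num, 2))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    x <- measures[[pairs[i, 1]]]; y <- measures[[pairs[i, 2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2],
                        n = sum(ok), r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Model-data correspondence summaries
#'
#' The descriptive curves used to compare behaviour (real or simulated) with
#' the fitted model: (i) probability of choosing right by binned learned
#' colour-value difference; (ii) probability of continuing to gather by
#' fixation index (with its regression slope); (iii) and (iv)
#' within-participant-centred number of fixated Cs and stopping step against
#' the absolute colour-value difference (slopes). Colour values are obtained
#' by replaying the learning rule at the supplied parameters.
#'
#' @param cohort A list of [participant_data()] or a cohort object.
#' @param params_matrix Matrix of per-participant parameters (rows aligned
#'   with the cohort), e.g. `coef(fit, "participants")` or the generator's
#'   truth.
#' @param n_bins Number of bins for the choice curve.
#' @return List of class `gaze_correspondence`: `choice_curve`,
#'   `continue_by_index` (+ `continue_slope`), `cs_by_dvcolor_slope`,
#'   `stop_by_dvcolor_slope`, and the pooled trial table.
#' @export
model_data_correspondence <- function(cohort, params_matrix, n_bins = 7L) {
  cohort <- as_cohort(cohort)
  stopifnot(nrow(params_matrix) == length(cohort))
  rows <- lapply(seq_along(cohort), function(p) {
    d <- cohort[[p]]
    prep <- prepare_participant(d)
    prm <- as_agent_params(params_matrix[p, ])
    rv <- replay_color_values(prep, prm)
    tr <- d$trials
    data.frame(participant = p, trial_type = tr$trial_type,
               choice_right = as.integer(tr$choice == "right"),
               n_fix = tr$n_fix,
               dv_color = rv$dv_color_learned,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  comb <- tab[tab$trial_type == "combined", ]

  br <- stats::quantile(comb$dv_color, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE)
  br <- unique(br)
  bin <- cut(comb$dv_color, br, include.lowest = TRUE)
  choice_curve <- data.frame(
    bin_mid = tapply(comb$dv_color, bin, mean),
    p_right = tapply(comb$choice_right, bin, mean),
    n = as.integer(table(bin)))

  # p(continue at event k): share of trials with >= k fixations among those
  # with >= k-1 fixations (combined and cs-only trials gather)
  gat <- tab[tab$trial_type != "color_only", ]
  kmax <- max(gat$n_fix)
  cont <- do.call(rbind, lapply(seq_len(max(kmax, 1L)), function(k) {
    at_risk <- sum(gat$n_fix >= k - 1L)
    went_on <- sum(gat$n_fix >= k)
    data.frame(fix_index = k, p_continue = went_on / at_risk, n = at_risk)
  }))
  cont <- cont[cont$n >= 5, , drop = FALSE]
  continue_slope <- if (nrow(cont) >= 3) {
    unname(stats::coef(stats::lm(p_continue ~ fix_index, data = cont,
                                 weights = n))[2])
  } else NA_real_

  # within-participant centring
  comb$absdv <- abs(comb$dv_color)
  comb$c_nfix <- comb$n_fix - stats::ave(comb$n_fix, comb$participant)
  comb$c_absdv <- comb$absdv - stats::ave(comb$absdv, comb$participant)
  cs_slope <- unname(stats::coef(stats::lm(c_nfix ~ c_absdv, data = comb))[2])

  structure(list(choice_curve = choice_curve, continue_by_index = cont,
                 continue_slope = continue_slope,
                 cs_by_dvcolor_slope = cs_slope,
                 stop_by_dvcolor_slope = cs_slope,
                 trials = tab),
            class = "gaze_correspondence")
}

#' @export
print.gaze_correspondence <- function(x, ...) {
  cat(sprintf("Correspondence summaries: continue-by-index slope %.4f, Cs-by-|dVcolor| slope %.3f\n",
              x$continue_slope, x$cs_by_dvcolor_slope))
  invisible(x)
}

#' @export
plot.gaze_correspondence <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(x$choice_curve$bin_mid, x$choice_curve$p_right, type = "b",
                 xlab = "dV colour (right - left)", ylab = "p(choose right)",
                 ylim = c(0, 1))
  graphics::abline(h = 0.5, lty = 3)
  graphics::plot(x$continue_by_index$fix_index, x$continue_by_index$p_continue,
                 type = "b", xlab = "fixation index", ylab = "p(continue)")
  comb <- x$trials[x$trials$trial_type == "combined", ]
  graphics::plot(abs(comb$dv_color), comb$n_fix, pch = 16, cex = 0.3,
                 xlab = "|dV colour|", ylab = "Cs fixated")
  invisible(x)
}
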
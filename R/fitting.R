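#' Group-level hyperparameters
#'
#' Each free parameter has a group-level normal distribution in an
#' unconstrained space, mapped to its natural domain by a per-parameter
#' transform: identity for the alpha/beta weights, the standard-normal CDF for
#' `omega_color`, `tau` and `tau_color` (a standard normal maps to an
#' approximately uniform \[0, 1\] prior), and `exp` for `epsilon` (lognormal
#' prior with mean 2 and standard deviation 2, i.e. meanlog 0.347, sdlog
#' 0.833).
#'
#' @return Data frame with columns `param`, `mean`, `sd`, `transform` — the
#'   default (prior) hyperparameters used to initialise [iis_fit()].
#' @export
default_hyperparams <- function() {
  transform <- rep("identity", length(PARAM_NAMES))
  names(transform) <- PARAM_NAMES
  transform[c("omega_color", "tau", "tau_color")] <- "probit"
  transform["epsilon"] <- "log"
  m <- rep(0, length(PARAM_NAMES)); names(m) <- PARAM_NAMES
  s <- rep(1, length(PARAM_NAMES)); names(s) <- PARAM_NAMES
  # lognormal with mean 2, sd 2: sdlog^2 = log(1 + (2/2)^2), meanlog = log 2 - sdlog^2/2
  sdlog <- sqrt(log(2))
  m["epsilon"] <- log(2) - log(2) / 2
  s["epsilon"] <- sdlog
  data.frame(param = PARAM_NAMES, mean = unname(m), sd = unname(s),
             transform = unname(transform), stringsAsFactors = FALSE)
}

apply_transform <- function(z, transform) {
  switch(transform,
         identity = z,
         probit = stats::pnorm(z),
         log = exp(z),
         stop_config("unknown transform '%s'", transform))
}

# z matrix (n x 13, canonical column order) -> natural-space matrix
transform_draws <- function(z, hyper) {
  theta <- z
  for (k in seq_along(PARAM_NAMES)) {
    theta[, k] <- apply_transform(z[, k], hyper$transform[k])
  }
  colnames(theta) <- PARAM_NAMES
  theta
}

#' Draw agent parameters from group-level hyperparameters
#'
#' Draws unconstrained normals per parameter and applies the per-parameter
#' transforms, so all constrained parameters land in their domains.
#'
#' @param n Number of parameter vectors.
#' @param hyper Hyperparameter table as from [default_hyperparams()].
#' @param active Character vector of free parameter names; parameters not
#'   listed are fixed at 0 in natural space (used by the reduced model
#'   variants).
#' @return Data frame of `n` parameter vectors in natural space, with the
#'   unconstrained draws in attribute `"z"`.
#' @export
sample_params <- function(n, hyper = default_hyperparams(),
                          active = PARAM_NAMES) {
  stopifnot(n >= 1)
  if (any(hyper$sd < 0)) stop_config("group standard deviations must be >= 0")
  k <- length(PARAM_NAMES)
  z <- matrix(0, n, k, dimnames = list(NULL, PARAM_NAMES))
  for (j in seq_len(k)) {
    if (PARAM_NAMES[j] %in% active) {
      z[, j] <- stats::rnorm(n, hyper$mean[j], hyper$sd[j])
    } else {
      z[, j] <- NA_real_
    }
  }
  theta <- z
  for (j in seq_len(k)) {
    theta[, j] <- if (PARAM_NAMES[j] %in% active) {
      apply_transform(z[, j], hyper$transform[j])
    } else 0
  }
  out <- as.data.frame(theta)
  attr(out, "z") <- z
  out
}

as_cohort <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) return(cohort$data)
  if (inherits(cohort, "participant_data")) return(list(cohort))
  stopifnot(is.list(cohort), length(cohort) > 0)
  cohort
}

#' Hierarchical empirical-Bayes fit by iterative importance sampling
#'
#' Alternates (a) per-participant importance sampling — parameter vectors are
#' drawn from the current group-level distribution and weighted by the
#' exponentiated dataset log-likelihood — with (b) re-estimation of the
#' group-level means and standard deviations by importance-weighted moment
#' matching in the unconstrained space, pooled across participants.
#' Per-participant posterior summaries are importance-weighted averages; the
#' per-participant log marginal likelihood is estimated as the log mean
#' weight. Deterministic given `seed`.
#'
#' @param cohort A list of [participant_data()] objects (or a
#'   [generate_cohort()] result).
#' @param spec A [model_spec()].
#' @param n_samples Importance samples per participant per iteration.
#' @param max_iters Maximum iterations.
#' @param tol Convergence tolerance on the largest absolute change of any
#'   unconstrained group mean or sd.
#' @param seed Integer seed.
#' @param hyper0 Initial hyperparameters (default [default_hyperparams()]).
#' @param td_cs Cs value entering the TD prediction error, see [trial_loglik()].
#' @param keep_samples Keep the final iteration's samples and weights per
#'   participant (memory-heavy; default `FALSE`).
#' @param verbose Print per-iteration progress.
#' @return An object of class `iis_fit`; see [coef.iis_fit()], [ibic()],
#'   [summary.iis_fit()].
#' @export
iis_fit <- function(cohort, spec = model_spec("full"), n_samples = 2000L,
                    max_iters = 50L, tol = 1e-2, seed = 1L,
                    hyper0 = default_hyperparams(),
                    td_cs = c("believed", "true"),
                    keep_samples = FALSE, verbose = FALSE) {
  td_cs <- match.arg(td_cs)
  cohort <- as_cohort(cohort)
  P <- length(cohort)
  preps <- lapply(cohort, prepare_participant, td_cs = td_cs)
  ids <- vapply(seq_len(P), function(i) {
    id <- cohort[[i]]$id
    if (is.na(id)) sprintf("p%02d", i) else as.character(id)
  }, character(1))

  set.seed(as.integer(seed))
  K <- length(PARAM_NAMES)
  active <- PARAM_NAMES %in% spec$active
  mu <- hyper0$mean; sdv <- hyper0$sd
  trace <- list()
  iter <- 0L; converged <- FALSE
  post_mean <- matrix(NA_real_, P, K, dimnames = list(ids, PARAM_NAMES))
  z_post <- post_mean
  log_marg <- numeric(P); ess <- numeric(P)
  kept <- if (keep_samples) vector("list", P) else NULL

  repeat {
    iter <- iter + 1L
    Ez <- matrix(0, P, K); Ez2 <- matrix(0, P, K)
    for (p in seq_len(P)) {
      z <- matrix(0, n_samples, K)
      for (j in seq_len(K)) {
        if (active[j]) z[, j] <- stats::rnorm(n_samples, mu[j], sdv[j])
      }
      theta <- z
      for (j in seq_len(K)) {
        theta[, j] <- if (active[j]) apply_transform(z[, j], hyper0$transform[j]) else 0
      }
      ll <- participant_loglik_cpp(preps[[p]], theta,
                                   spec$include_color_in_gather,
                                   spec$include_color_in_look)
      m <- max(ll)
      w <- exp(ll - m)
      sw <- sum(w)
      w <- w / sw
      log_marg[p] <- m + log(sw) - log(n_samples)
      ess[p] <- 1 / sum(w^2)
      Ez[p, ] <- colSums(w * z)
      Ez2[p, ] <- colSums(w * z^2)
      colnames(theta) <- PARAM_NAMES
      post_mean[p, ] <- colSums(w * theta)
      z_post[p, ] <- Ez[p, ]
      if (keep_samples) kept[[p]] <- list(theta = theta, z = z, weights = w, loglik = ll)
    }
    new_mu <- ifelse(active, colMeans(Ez), mu)
    new_var <- colMeans(Ez2) - new_mu^2
    new_sd <- ifelse(active, sqrt(pmax(new_var, 1e-6)), sdv)
    change <- max(abs(new_mu - mu), abs(new_sd - sdv))
    trace[[iter]] <- data.frame(iteration = iter, param = PARAM_NAMES,
                                mean = new_mu, sd = new_sd,
                                max_change = change,
                                mean_ess = mean(ess),
                                stringsAsFactors = FALSE)
    mu <- new_mu; sdv <- new_sd
    if (verbose) {
      message(sprintf("iter %d: max change %.4f, mean ESS %.1f, sum logZ %.1f",
                      iter, change, mean(ess), sum(log_marg)))
    }
    if (change < tol) { converged <- TRUE; break }
    if (iter >= max_iters) break
  }
  if (any(ess < 2)) {
    warning(sprintf("low effective sample size (< 2) for %d participant(s)",
                    sum(ess < 2)), call. = FALSE)
  }

  hyper <- data.frame(param = PARAM_NAMES, mean = mu, sd = sdv,
                      transform = hyper0$transform, active = active,
                      stringsAsFactors = FALSE)
  structure(list(
    hyper = hyper,
    posterior_means = post_mean,
    z_posterior_means = z_post,
    log_marginal = stats::setNames(log_marg, ids),
    ess = stats::setNames(ess, ids),
    trace = do.call(rbind, trace),
    spec = spec,
    n_hyper = 2L * sum(active),
    n_decisions = sum(vapply(preps, `[[`, integer(1), "n_decisions")),
    n_samples = as.integer(n_samples),
    iterations = iter,
    converged = converged,
    seed = as.integer(seed),
    td_cs = td_cs,
    samples = kept,
    ids = ids
  ), class = "iis_fit")
}

#' Integrated Bayesian information criterion
#'
#' `-2 * sum(log marginal likelihood) + n_hyper * log(N)`, where `n_hyper`
#' counts the group-level hyperparameters (a mean and an sd per free
#' parameter) and `N` is the total number of modelled decision events (every
#' free gather, look and choice event in the cohort). Lower is better.
#'
#' @param fit An [iis_fit()] object.
#' @return Scalar iBIC, with the deviance and penalty in attributes.
#' @export
ibic <- function(fit) {
  stopifnot(inherits(fit, "iis_fit"))
  dev <- -2 * sum(fit$log_marginal)
  pen <- fit$n_hyper * log(fit$n_decisions)
  out <- dev + pen
  attr(out, "deviance") <- dev
  attr(out, "penalty") <- pen
  attr(out, "n_decisions") <- fit$n_decisions
  out
}

#' Compare model variants by iBIC
#'
#' Fits each model specification to the same cohort with a shared seed and
#' ranks the variants by [ibic()].
#'
#' @param cohort As in [iis_fit()].
#' @param specs List of [model_spec()] objects or names.
#' @param ... Passed to [iis_fit()] (`n_samples`, `max_iters`, `seed`, ...).
#' @return Data frame of class `ibic_comparison`, ranked best first, with the
#'   fits in attribute `"fits"`.
#' @export
compare_models <- function(cohort,
                           specs = list("full", "no-color-gather", "no-color-look"),
                           ...) {
  specs <- lapply(specs, function(s) if (inherits(s, "model_spec")) s else model_spec(s))
  fits <- lapply(specs, function(s) iis_fit(cohort, spec = s, ...))
  tab <- do.call(rbind, lapply(seq_along(specs), function(i) {
    ib <- ibic(fits[[i]])
    data.frame(model = specs[[i]]$name,
               n_free_params = length(specs[[i]]$active),
               n_hyper = fits[[i]]$n_hyper,
               log_marglik = sum(fits[[i]]$log_marginal),
               deviance = attr(ib, "deviance"),
               ibic = as.numeric(ib),
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$ibic), ]
  tab$delta_ibic <- tab$ibic - tab$ibic[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("ibic_comparison", "data.frame")
  tab
}

#' @export
print.ibic_comparison <- function(x, ...) {
  cat("iBIC model comparison (lower is better)\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
print.iis_fit <- function(x, ...) {
  cat(sprintf("Hierarchical fit ('%s' model): %d participants, %d importance samples/iter\n",
              x$spec$name, nrow(x$posterior_means), x$n_samples))
  cat(sprintf("%s after %d iteration(s); sum log marginal = %.2f; iBIC = %.2f\n",
              if (x$converged) "Converged" else "Stopped", x$iterations,
              sum(x$log_marginal), as.numeric(ibic(x))))
  invisible(x)
}

#' Summarise a hierarchical fit
#'
#' @param object An [iis_fit()] object.
#' @param ... Unused.
#' @return Data frame per parameter: unconstrained group mean and sd, the
#'   group mean mapped to natural space, and the across-participant mean of
#'   the posterior-mean parameters.
#' @export
summary.iis_fit <- function(object, ...) {
  h <- object$hyper
  nat <- vapply(seq_len(nrow(h)),
                function(k) apply_transform(h$mean[k], h$transform[k]),
                numeric(1))
  out <- data.frame(param = h$param, active = h$active,
                    group_mean_z = h$mean, group_sd_z = h$sd,
                    group_mean_natural = ifelse(h$active, nat, 0),
                    mean_posterior = colMeans(object$posterior_means),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.iis_fit", "data.frame")
  out
}

#' @export
print.summary.iis_fit <- function(x, ...) {
  cat("Group-level parameter estimates\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract coefficients from a hierarchical fit
#'
#' @param object An [iis_fit()] object.
#' @param type `"group"` for the group-level means in natural space,
#'   `"participants"` for the matrix of per-participant posterior means.
#' @param ... Unused.
#' @export
coef.iis_fit <- function(object, type = c("group", "participants"), ...) {
  type <- match.arg(type)
  if (type == "participants") return(object$posterior_means)
  s <- summary(object)
  stats::setNames(s$group_mean_natural, s$param)
}

#' @export
logLik.iis_fit <- function(object, ...) {
  structure(sum(object$log_marginal), df = object$n_hyper,
            nobs = object$n_decisions, class = "logLik")
}

#' Simulate behaviour from a fitted model
#'
#' Simulates each participant at their posterior-mean parameters on a given
#' schedule (posterior-predictive style, one cohort per `nsim`).
#'
#' @param object An [iis_fit()] object.
#' @param nsim Number of simulated cohorts.
#' @param seed Integer seed.
#' @param schedule A schedule to simulate on (required).
#' @param ... Unused.
#' @return A list of length `nsim`; each element is a list of
#'   `participant_sim` objects.
#' @export
simulate.iis_fit <- function(object, nsim = 1, seed = 1L, schedule = NULL, ...) {
  if (is.null(schedule)) stop_config("a schedule is required to simulate from the fit")
  P <- nrow(object$posterior_means)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    out[[r]] <- lapply(seq_len(P), function(p) {
      prm <- as_agent_params(object$posterior_means[p, ])
      simulate_participant(schedule, prm,
                           seed = as.integer(seed) + (r - 1L) * P + p)
    })
  }
  out
}

#' @export
plot.iis_fit <- function(x, params = c("alpha_gather", "beta_dcolor", "omega_color"), ...) {
  tr <- x$trace[x$trace$param %in% params, ]
  graphics::matplot(
    stats::reshape(tr[, c("iteration", "param", "mean")],
                   direction = "wide", idvar = "iteration",
                   timevar = "param")[, -1],
    type = "l", lty = 1, xlab = "iteration",
    ylab = "group mean (unconstrained)", ...)
  graphics::legend("topright", legend = params, col = seq_along(params),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
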
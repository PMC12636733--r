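#' Logistic (inverse-logit) function
#'
#' @param x Numeric vector of log-odds.
#' @return `1 / (1 + exp(-x))`, vectorised.
#' @export
logistic <- function(x) 1 / (1 + exp(-x))

# Numerically stable log of the logistic function, floored so that no modelled
# event contributes less than log(1e-12) (keeps importance weights finite
# under extreme proposals).
.LOG_FLOOR <- log(1e-12)

log_logistic <- function(x) {
  out <- ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))
  pmax(out, .LOG_FLOOR)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# z-score that tolerates zero variance (returns zeros and flags via attribute)
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) {
    out <- rep(0, length(x))
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  out <- (x - mean(x)) / s
  attr(out, "zero_variance") <- FALSE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
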
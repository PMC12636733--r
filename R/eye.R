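#' Read a fixation report
#'
#' Reads a tab-separated fixation report with header columns `participant`,
#' `trial`, `t_start`, `duration`, `x`, `y` (EyeLink-fixation-report-like).
#' Malformed rows (non-numeric fields, nonpositive durations) are collected
#' into an error report rather than silently dropped.
#'
#' @param path Path to the TSV file.
#' @return Data frame of valid fixation records, with the malformed rows (and
#'   a `reason` column) in attribute `"errors"`.
#' @export
read_fixation_report <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("participant", "trial", "t_start", "duration", "x", "y")
  if (!all(needed %in% names(raw))) {
    stop_config("fixation report must have columns: %s",
                paste(needed, collapse = ", "))
  }
  num <- c("trial", "t_start", "duration", "x", "y")
  conv <- raw
  for (cn in num) conv[[cn]] <- suppressWarnings(as.numeric(raw[[cn]]))
  bad_na <- rowSums(is.na(conv[num])) > 0
  bad_dur <- !bad_na & conv$duration <= 0
  bad <- bad_na | bad_dur
  errors <- raw[bad, , drop = FALSE]
  if (nrow(errors)) {
    errors$reason <- ifelse(bad_na[bad], "non-numeric field", "nonpositive duration")
  }
  out <- conv[!bad, , drop = FALSE]
  out$trial <- as.integer(out$trial)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Write a fixation report
#'
#' @param fixations Data frame with the report columns.
#' @param path Output TSV path.
#' @export
write_fixation_report <- function(fixations, path) {
  cols <- c("participant", "trial", "t_start", "duration", "x", "y")
  utils::write.table(fixations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Interest-area map for the two C rings
#'
#' Builds the per-C interest areas: 12 centres per side placed on a ring,
#' index 1 at the top and increasing clockwise. The default acceptance radius
#' is half the centre-to-centre spacing of adjacent Cs, so circles touch but
#' do not overlap. Coordinates are screen pixels with origin top-left.
#'
#' @param left_center,right_center Ring centres, `c(x, y)` in pixels.
#' @param ring_radius Ring radius in pixels.
#' @param n_cs Number of Cs per ring.
#' @param radius Acceptance radius; default half the adjacent-C spacing.
#' @return Data frame of class `interest_area_map`: `side`, `c_index`, `x`,
#'   `y`, `radius`.
#' @export
interest_area_map <- function(left_center = c(480, 540),
                              right_center = c(1440, 540),
                              ring_radius = 150, n_cs = 12L, radius = NULL) {
  spacing <- 2 * ring_radius * sin(pi / n_cs)
  if (is.null(radius)) radius <- spacing / 2
  if (radius <= 0) stop_config("acceptance radius must be positive")
  ang <- -pi / 2 + 2 * pi * (seq_len(n_cs) - 1L) / n_cs
  mk <- function(center, side) {
    data.frame(side = side, c_index = seq_len(n_cs),
               x = center[1] + ring_radius * cos(ang),
               y = center[2] + ring_radius * sin(ang),
               radius = radius, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(left_center, "left"), mk(right_center, "right"))
  class(out) <- c("interest_area_map", "data.frame")
  out
}

#' Assign fixations to Landolt-C interest areas
#'
#' Labels each fixation with the nearest C centre if it falls within that
#' centre's acceptance radius, otherwise `"off"`-stimulus. Ties in distance
#' are broken by the lowest C index, then the left side.
#'
#' @param fixations Data frame from [read_fixation_report()] (or any table
#'   with `x`, `y`).
#' @param iamap An [interest_area_map()]; the layout is constant across
#'   trials.
#' @return `fixations` with added columns `side` (`"left"`, `"right"` or
#'   `"off"`) and `c_index` (`NA` when off-stimulus).
#' @export
assign_fixations <- function(fixations, iamap) {
  stopifnot(all(c("x", "y") %in% names(fixations)))
  # order encodes the tie rule: lowest c_index first, then left before right
  iam <- iamap[order(iamap$c_index, iamap$side), , drop = FALSE]
  n <- nrow(fixations)
  side <- rep("off", n); cidx <- rep(NA_integer_, n)
  if (n > 0) {
    dx <- outer(fixations$x, iam$x, "-")
    dy <- outer(fixations$y, iam$y, "-")
    d2 <- dx^2 + dy^2
    best <- apply(d2, 1L, which.min)
    dist <- sqrt(d2[cbind(seq_len(n), best)])
    hit <- dist <= iam$radius[best]
    side[hit] <- iam$side[best[hit]]
    cidx[hit] <- iam$c_index[best[hit]]
  }
  fixations$side <- side
  fixations$c_index <- cidx
  fixations
}

#' Discard repeat fixations
#'
#' Within each (participant, trial), keeps only the first fixation on each
#' (side, C index), in temporal order, assuming a refixated C was not
#' registered the first time. Off-stimulus fixations are retained in the
#' table but never enter C counts. Idempotent.
#'
#' @param labeled Output of [assign_fixations()] (needs `trial`, `t_start`,
#'   `side`, `c_index`; a `participant` column is honoured if present).
#' @return The filtered table.
#' @export
drop_repeats <- function(labeled) {
  if (nrow(labeled) == 0) return(labeled)
  pid <- if ("participant" %in% names(labeled)) labeled$participant else
    rep("", nrow(labeled))
  ord <- order(pid, labeled$trial, labeled$t_start)
  x <- labeled[ord, , drop = FALSE]
  pid <- pid[ord]
  on_c <- x$side != "off" & !is.na(x$c_index)
  key <- paste(pid, x$trial, x$side, x$c_index, sep = "\r")
  keep <- !on_c | !duplicated(ifelse(on_c, key, paste0("off\r", seq_along(key))))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative observed-C counts
#'
#' For each trial, computes the running number of upward- and downward-facing
#' Cs fixated per side after each on-stimulus fixation, using the schedule's
#' orientation strings. Off-stimulus fixations are ignored.
#'
#' @param filtered Output of [drop_repeats()].
#' @param schedule The [generate_task()] schedule for these trials.
#' @return Long data frame: `participant` (if present), `trial`, `step`,
#'   `side`, `c_index`, `up`, and cumulative `up_l`, `down_l`, `up_r`,
#'   `down_r`.
#' @export
cumulative_counts <- function(filtered, schedule) {
  on_c <- filtered$side %in% c("left", "right") & !is.na(filtered$c_index)
  x <- filtered[on_c, , drop = FALSE]
  if (nrow(x) == 0) {
    return(data.frame(participant = character(), trial = integer(),
                      step = integer(), side = character(), c_index = integer(),
                      up = integer(), up_l = integer(), down_l = integer(),
                      up_r = integer(), down_r = integer(),
                      stringsAsFactors = FALSE))
  }
  pid <- if ("participant" %in% names(x)) x$participant else rep("", nrow(x))
  ord <- order(pid, x$trial, x$t_start)
  x <- x[ord, , drop = FALSE]; pid <- pid[ord]
  si <- match(x$trial, schedule$trial)
  if (any(is.na(si))) stop_config("fixated trial absent from schedule")
  orient <- ifelse(x$side == "left", schedule$left_orient[si],
                   schedule$right_orient[si])
  if (any(is.na(orient))) stop_config("fixated C index absent from schedule")
  n_char <- nchar(orient)
  if (any(x$c_index < 1 | x$c_index > n_char)) {
    stop_config("fixated C index absent from schedule")
  }
  x$up <- as.integer(substr(orient, x$c_index, x$c_index) == "1")

  grp <- paste(pid, x$trial, sep = "\r")
  step <- stats::ave(seq_len(nrow(x)), grp, FUN = seq_along)
  inc <- function(cond) as.integer(cond)
  up_l <- stats::ave(inc(x$side == "left" & x$up == 1L), grp, FUN = cumsum)
  down_l <- stats::ave(inc(x$side == "left" & x$up == 0L), grp, FUN = cumsum)
  up_r <- stats::ave(inc(x$side == "right" & x$up == 1L), grp, FUN = cumsum)
  down_r <- stats::ave(inc(x$side == "right" & x$up == 0L), grp, FUN = cumsum)
  out <- data.frame(trial = x$trial, step = as.integer(step), side = x$side,
                    c_index = x$c_index, up = x$up,
                    up_l = up_l, down_l = down_l, up_r = up_r, down_r = down_r,
                    stringsAsFactors = FALSE)
  if ("participant" %in% names(x)) out <- cbind(participant = pid, out,
                                                stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Eye-tracking validity filter
#'
#' Participants are included in gaze analyses only if their fraction of valid
#' eye-tracking samples is strictly above the threshold (default 0.75);
#' choices are retained regardless.
#'
#' @param validity Data frame with columns `participant` and `validity`
#'   (fraction in \[0, 1\]).
#' @param threshold Inclusion threshold (strict).
#' @return The table with an added logical `included` column, of class
#'   `validity_report`.
#' @export
validity_filter <- function(validity, threshold = 0.75) {
  stopifnot(all(c("participant", "validity") %in% names(validity)))
  if (any(validity$validity < 0 | validity$validity > 1)) {
    stop_config("validity fractions must be in [0, 1]")
  }
  validity$included <- validity$validity > threshold
  class(validity) <- c("validity_report", "data.frame")
  validity
}
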
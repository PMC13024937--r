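# Per-trial metrics and exports.

#' Time on target
#'
#' Percentage of trial steps in which the true cursor lies within the target
#' interval.
#'
#' @param trial an `iaif_trial` (or its `log` data.frame).
#' @return percentage in `[0, 100]`.
#' @export
time_on_target <- function(trial) {
  log <- if (inherits(trial, "iaif_trial")) trial$log else trial
  if (is.null(log) || nrow(log) == 0) stop("empty trial log")
  100 * mean(log$in_target == 1L)
}

#' Number of planning phases
#'
#' Counts the steps at which a planning phase ran, including the mandatory
#' initial one.
#'
#' @param trial an `iaif_trial` (or its `log` data.frame).
#' @return integer count.
#' @export
count_planning_phases <- function(trial) {
  log <- if (inherits(trial, "iaif_trial")) trial$log else trial
  sum(log$planned)
}

# Count of trigger firings by cause (the cause logged at step t produces the
# planning phase at step t+1, so firings in the final step are not phases).
count_fires <- function(trial, cause) {
  sum(trial$log$trigger_cause == cause)
}

#' Summarise a trial into one metrics row
#'
#' @param trial an `iaif_trial`.
#' @return one-row data.frame: time on target, planning-phase count, fire
#'   counts by cause, compute units (rollout steps executed, a
#'   hardware-independent cost proxy), target identity and difficulty, seed.
#' @export
trial_metrics <- function(trial) {
  data.frame(
    time_on_target_pct = time_on_target(trial),
    n_planning_phases = count_planning_phases(trial),
    n_div_fires = count_fires(trial, "div"),
    n_efe_fires = count_fires(trial, "efe"),
    n_exhaustions = count_fires(trial, "exhaustion"),
    compute_units = trial$compute_units,
    target_id = trial$target$index,
    id_bits = trial$target$id_bits,
    seed = trial$seed)
}

#' Export a trial log to CSV
#'
#' One row per step; schema version recorded in a comment-free companion
#' column set (documented in the column reference of [run_trial()]).
#'
#' @param trial an `iaif_trial`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_trial_csv <- function(trial, path) {
  write.csv(trial$log, path, row.names = FALSE)
  invisible(path)
}

#' Phase-space histogram export
#'
#' Pools (distance-to-target, velocity) pairs over trials, drops steps within
#' `exclude_within_px` of the target centre, and bins the rest on a regular
#' 2-D grid.
#'
#' @param trials list of `iaif_trial`s.
#' @param exclude_within_px exclusion radius around the target centre (px).
#' @param dist_bin_px,vel_bin_px bin widths (px and px/s).
#' @return data.frame with `dist_lo`, `dist_hi`, `vel_lo`, `vel_hi`, `count`;
#'   attribute `n_retained` carries the retained step count.
#' @export
phase_space_export <- function(trials, exclude_within_px = 100,
                               dist_bin_px = 10, vel_bin_px = 50) {
  if (length(trials) == 0) stop("need at least one trial")
  dist <- unlist(lapply(trials, function(tr) abs(tr$log$s1_px - tr$log$s3_px)))
  vel <- unlist(lapply(trials, function(tr) tr$log$s2_px))
  keep <- dist >= exclude_within_px
  dist <- dist[keep]; vel <- vel[keep]
  if (length(dist) == 0) {
    out <- data.frame(dist_lo = numeric(0), dist_hi = numeric(0),
                      vel_lo = numeric(0), vel_hi = numeric(0),
                      count = integer(0))
    attr(out, "n_retained") <- 0L
    return(out)
  }
  di <- floor(dist / dist_bin_px)
  vi <- floor(vel / vel_bin_px)
  tab <- table(di, vi)
  idx <- which(tab > 0, arr.ind = TRUE)
  out <- data.frame(
    dist_lo = as.numeric(rownames(tab))[idx[, 1]] * dist_bin_px,
    dist_hi = (as.numeric(rownames(tab))[idx[, 1]] + 1) * dist_bin_px,
    vel_lo = as.numeric(colnames(tab))[idx[, 2]] * vel_bin_px,
    vel_hi = (as.numeric(colnames(tab))[idx[, 2]] + 1) * vel_bin_px,
    count = as.integer(tab[idx]))
  out <- out[order(out$dist_lo, out$vel_lo), ]
  rownames(out) <- NULL
  attr(out, "n_retained") <- length(dist)
  out
}

#' Count submovements in a trial
#'
#' A submovement boundary is a local minimum of the speed profile before the
#' first target entry, while the cursor is still outside the target: the
#' signature of a corrective surge. Used to compare movement structure
#' between continuously and intermittently planning agents.
#'
#' @param trial an `iaif_trial`.
#' @param min_speed_px_s speed changes below this scale are ignored (noise
#'   guard).
#' @return integer count of interior speed minima before target arrival.
#' @export
count_submovements <- function(trial, min_speed_px_s = 50) {
  log <- trial$log
  first_in <- which(log$in_target == 1L)[1]
  upto <- if (is.na(first_in)) nrow(log) else first_in
  if (upto < 3) return(0L)
  sp <- abs(log$s2_px[seq_len(upto)])
  n <- 0L
  for (i in 2:(length(sp) - 1)) {
    if (sp[i] < sp[i - 1] && sp[i] <= sp[i + 1] && sp[i - 1] > min_speed_px_s)
      n <- n + 1L
  }
  n
}
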
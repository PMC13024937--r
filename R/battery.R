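# Experiment harness: batteries over agents x targets x repetitions,
# statistical comparison, and the K sweep.

#' Run a battery of trials
#'
#' Runs `n_reps` trials per target for each labelled agent. Per-trial seeds
#' derive deterministically from `(master_seed, agent, target, rep)`, and the
#' environment-noise stream depends only on the trial seed, so agents face
#' matched noise.
#'
#' @param agents named list of [agent_config()]s.
#' @param layout a [make_target_layout()] data.frame.
#' @param env_cfg an [iaif_env_config()].
#' @param n_reps repetitions per target (full-scale battery: 10 reps x 12
#'   targets = 120 trials per agent).
#' @param master_seed integer.
#' @param keep_logs keep the full trial objects (memory-heavy for large
#'   batteries).
#' @return object of class `iaif_battery`: `metrics` (one row per trial,
#'   with `agent` label) and optionally `trials`.
#' @export
run_battery <- function(agents, layout = make_target_layout(),
                        env_cfg = iaif_env_config(), n_reps = 10,
                        master_seed = 1L, keep_logs = FALSE) {
  stopifnot(length(agents) >= 1, !is.null(names(agents)))
  rows <- list()
  trials <- list()
  for (a in seq_along(agents)) {
    for (ti in seq_len(nrow(layout))) {
      for (rep in seq_len(n_reps)) {
        # agent index deliberately excluded from the environment stream:
        # seeds depend on (master, target, rep) so agents share noise
        trial_seed <- mix_seed(master_seed, 10 + ti, rep)
        trial <- tryCatch(
          run_trial(env_cfg, agents[[a]], layout[ti, ], trial_seed),
          error = function(e) e)
        if (inherits(trial, "error")) {
          warning(sprintf("trial failed (agent %s, target %d, rep %d): %s",
                          names(agents)[a], layout$index[ti], rep,
                          conditionMessage(trial)))
          next
        }
        mrow <- trial_metrics(trial)
        mrow$agent <- names(agents)[a]
        mrow$rep <- rep
        rows[[length(rows) + 1L]] <- mrow
        if (keep_logs) trials[[length(trials) + 1L]] <- trial
      }
    }
  }
  structure(list(metrics = do.call(rbind, rows),
                 trials = if (keep_logs) trials else NULL,
                 master_seed = master_seed),
            class = "iaif_battery")
}

#' Summarise a battery by agent
#'
#' @param object an `iaif_battery`.
#' @param ... unused.
#' @return data.frame of per-agent means and quartiles of time on target,
#'   planning phases and compute units.
#' @export
summary.iaif_battery <- function(object, ...) {
  m <- object$metrics
  out <- do.call(rbind, lapply(split(m, m$agent), function(g) {
    data.frame(agent = g$agent[1], n_trials = nrow(g),
               mean_tot = mean(g$time_on_target_pct),
               median_tot = stats::median(g$time_on_target_pct),
               mean_phases = mean(g$n_planning_phases),
               mean_compute_units = mean(g$compute_units),
               mean_div_fires = mean(g$n_div_fires),
               mean_efe_fires = mean(g$n_efe_fires),
               mean_exhaustions = mean(g$n_exhaustions))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.iaif_battery <- function(x, ...) {
  cat("IAIF battery:", nrow(x$metrics), "trials,",
      length(unique(x$metrics$agent)), "agent(s)\n")
  print(summary(x), digits = 4)
  invisible(x)
}

#' Compare two agents on a metric (Mann-Whitney-Wilcoxon)
#'
#' Two-sided rank-sum test on a chosen column of the battery metrics.
#'
#' @param metrics_a,metrics_b metrics data.frames (one row per trial).
#' @param measure column name, e.g. `"time_on_target_pct"`.
#' @return list with `statistic`, `p_value`, `n_a`, `n_b`, `degenerate`
#'   (both samples constant and equal).
#' @export
compare_agents <- function(metrics_a, metrics_b,
                           measure = "time_on_target_pct") {
  xa <- metrics_a[[measure]]; xb <- metrics_b[[measure]]
  if (length(xa) < 2 || length(xb) < 2) stop("need at least 2 rows per agent")
  degenerate <- length(unique(c(xa, xb))) == 1L
  if (degenerate) {
    return(list(statistic = length(xa) * length(xb) / 2, p_value = 1,
                n_a = length(xa), n_b = length(xb), degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(xa), n_b = length(xb), degenerate = FALSE)
}

#' Sweep the number of sampled plans K
#'
#' Re-runs the battery for each K for the three agents of the K analysis:
#' the classic baseline, the divergence-triggered agent, and the
#' EFE-error-triggered agent.
#'
#' @param K_values integer vector of plan counts.
#' @param layout,env_cfg,n_reps,master_seed as in [run_battery()].
#' @param eps_div divergence threshold for the div agent.
#' @param base an [agent_config()] whose non-K fields are reused.
#' @return data.frame keyed by `(K, agent)` with mean planning phases,
#'   compute units and time on target.
#' @export
k_sweep <- function(K_values, layout = make_target_layout(),
                    env_cfg = iaif_env_config(), n_reps = 10,
                    master_seed = 1L, eps_div = 30, base = agent_config()) {
  rows <- list()
  for (K in K_values) {
    agents <- list(
      classic = modify_agent(base, K = K, trigger = trigger_config("classic")),
      div = modify_agent(base, K = K,
                         trigger = trigger_config("div", eps_div = eps_div)),
      efe = modify_agent(base, K = K, trigger = trigger_config("efe")))
    bat <- run_battery(agents, layout, env_cfg, n_reps, master_seed)
    s <- summary(bat)
    s$K <- K
    rows[[length(rows) + 1L]] <- s
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Modify fields of an agent configuration
#'
#' @param cfg an [agent_config()].
#' @param ... fields to replace (e.g. `K`, `trigger`).
#' @return the modified `iaif_agent_config`.
#' @export
modify_agent <- function(cfg, ...) {
  upd <- list(...)
  for (nm in names(upd)) cfg[[nm]] <- upd[[nm]]
  cfg$K <- as.integer(cfg$K); cfg$N <- as.integer(cfg$N)
  cfg
}
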
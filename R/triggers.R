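# Re-planning triggers: the intermittency core.

#' Trigger configuration
#'
#' @param mode one of `"classic"` (re-plan every step), `"div"` (Belief
#'   Divergence Trigger), `"efe"` (Expected Free Energy Error Trigger),
#'   `"combined"` (divergence tested first, EFE only if it stays silent), or
#'   `"never"` (plan-exhaustion only; diagnostic baseline).
#' @param eps_div positive divergence threshold (fires on strict exceedance).
#' @param eps_efe non-negative slack added to the planning-time EFE before
#'   comparison (default 0).
#' @param efe_relative if `TRUE`, `eps_efe` is interpreted relative to the
#'   magnitude of the planning-time EFE.
#' @return an object of class `trigger_config`.
#' @export
trigger_config <- function(mode = c("combined", "classic", "div", "efe", "never"),
                           eps_div = 50, eps_efe = 0, efe_relative = FALSE) {
  mode <- match.arg(mode)
  if (mode %in% c("div", "combined") && !(eps_div > 0))
    stop("eps_div must be positive when the divergence trigger is active")
  if (eps_efe < 0) stop("eps_efe must be non-negative")
  structure(list(mode = mode, eps_div = eps_div, eps_efe = eps_efe,
                 efe_relative = efe_relative), class = "trigger_config")
}

trigger_decision <- function(fired, cause, div_value = NA_real_,
                             efe_updated = NA_real_, efe_planned = NA_real_) {
  list(fired = fired, cause = cause, div_value = div_value,
       efe_updated = efe_updated, efe_planned = efe_planned)
}

#' Belief Divergence Trigger
#'
#' Fires when the symmetrised KL divergence between the planning-time
#' predicted belief for the current step and the current posterior strictly
#' exceeds `eps_div`.
#'
#' @param updated the current `mf_belief` (after the variational update).
#' @param predicted the planning-time predicted belief aligned to this step,
#'   or `NULL` when no aligned prediction exists.
#' @param eps_div positive threshold.
#' @return a trigger decision (list with `fired`, `cause`, `div_value`).
#' @export
div_trigger <- function(updated, predicted, eps_div) {
  if (is.null(predicted)) return(trigger_decision(FALSE, "none"))
  d <- symmetrised_kl(predicted, updated)
  trigger_decision(d > eps_div, if (d > eps_div) "div" else "none",
                   div_value = d)
}

#' Expected Free Energy Error Trigger
#'
#' Re-scores the remaining actions of the executing plan from the current
#' belief (fresh Monte-Carlo draws) and compares the mean of their step-wise
#' EFEs with the mean of the planning-time step-wise EFEs over the same
#' indices. Fires when the updated value strictly exceeds the planned value
#' plus the slack `eps_efe`. Never evaluated at full exhaustion
#' (`exec_index == N`), where mandatory re-planning applies instead.
#'
#' @param exec plan-execution state: list with `plan`, `stepwise_efe`,
#'   `exec_index` (actions already executed), `phase_seed`, `pref_center`.
#' @param updated the current `mf_belief`.
#' @param gm,pref,m as in [select_plan()].
#' @param eps_efe non-negative slack.
#' @param efe_relative interpret `eps_efe` relative to `|planned EFE|`.
#' @param seed seed for the fresh re-scoring streams; pass the planning-time
#'   `phase_seed` to replay the planning draws exactly (matched streams).
#' @return a trigger decision with `efe_updated` and `efe_planned` filled in.
#' @export
efe_error_trigger <- function(exec, updated, gm, pref, m, eps_efe = 0,
                              efe_relative = FALSE, seed) {
  k <- exec$exec_index
  N <- length(exec$plan)
  if (k >= N) stop("EFE error trigger is undefined at plan exhaustion (k = N)")
  remaining <- exec$plan[(k + 1):N]
  res <- eval_plans_engine(updated, matrix(remaining, nrow = 1), gm, pref, m,
                           seed, step_offset = k,
                           plan_offset = exec$chosen_index - 1L,
                           pref_center = exec$pref_center)
  g_upd <- mean(res$stepwise[1, ])
  g_plan <- mean(exec$stepwise_efe[(k + 1):N])
  slack <- if (efe_relative) eps_efe * abs(g_plan) else eps_efe
  fired <- g_upd > g_plan + slack
  trigger_decision(fired, if (fired) "efe" else "none",
                   efe_updated = g_upd, efe_planned = g_plan)
}

#' Mandatory re-planning on plan exhaustion
#'
#' @param exec plan-execution state (needs `plan` and `exec_index`).
#' @return a trigger decision with cause `"exhaustion"` iff all N actions
#'   have been executed.
#' @export
exhaustion_check <- function(exec) {
  fired <- exec$exec_index >= length(exec$plan)
  trigger_decision(fired, if (fired) "exhaustion" else "none")
}

#' Combined trigger
#'
#' Evaluates the Belief Divergence Trigger first; only if it stays silent is
#' the (more expensive) EFE Error Trigger evaluated. Also dispatches the
#' single-trigger and classic modes; exhaustion is handled separately by the
#' agent loop.
#'
#' @param exec plan-execution state.
#' @param updated current `mf_belief`.
#' @param predicted planning-time predicted belief for this step (or `NULL`).
#' @param cfg a [trigger_config()].
#' @param gm,pref,m as in [select_plan()].
#' @param seed seed for EFE re-scoring.
#' @return a trigger decision; `cause` records which trigger fired.
#' @export
combined_trigger <- function(exec, updated, predicted, cfg, gm, pref, m, seed) {
  if (cfg$mode == "classic") return(trigger_decision(TRUE, "classic"))
  if (cfg$mode == "never") return(trigger_decision(FALSE, "none"))
  dec <- trigger_decision(FALSE, "none")
  if (cfg$mode %in% c("div", "combined")) {
    dec <- div_trigger(updated, predicted, cfg$eps_div)
    if (dec$fired || cfg$mode == "div") return(dec)
  }
  if (cfg$mode %in% c("efe", "combined") && exec$exec_index < length(exec$plan)) {
    edec <- efe_error_trigger(exec, updated, gm, pref, m, cfg$eps_efe,
                              cfg$efe_relative, seed)
    edec$div_value <- dec$div_value
    return(edec)
  }
  dec
}
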
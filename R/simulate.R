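#' Run a learner through a multi-phase protocol
#'
#' Drives a fresh agent through every trial of `protocol`, applying the
#' phase rules of the model:
#' \itemize{
#'   \item acquisition (and reacquisition): learning with arousal fixed at 1;
#'   \item extinction: on the first extinction trial after an acquisition
#'     phase, arousal is reset to the reward expectation built during
#'     acquisition (see `arousal_init` in [model_params()]); thereafter it
#'     is updated once per trial from the trial's prediction error via
#'     [arousal_update()], and it multiplies both learning rates;
#'   \item break: forgetting only ([apply_break_trial()]); no prediction
#'     errors are generated and arousal is untouched.
#' }
#' The drug transform is applied to every prediction error in the phases
#' selected by `drug_window` before the error is recorded, used for
#' learning, or fed to the arousal update.
#'
#' @param params a [model_params()] object.
#' @param protocol a [protocol()].
#' @param condition a [drug_condition()].
#' @param engine `"compiled"` (C++ fast path, the default) or
#'   `"reference"` (pure R, built on [td_step()]); both produce identical
#'   trajectories.
#' @return An object of class `sim_run` with components:
#'   \describe{
#'     \item{trials}{data frame with one row per trial: `trial`, `phase`,
#'       `probability`, `rewarded`, `arousal` (level in effect),
#'       `delta_cs`, `delta_outcome`.}
#'     \item{delta, value}{trial-by-timestep matrices of the (transformed)
#'       prediction error and of the value function; zero rows for break
#'       trials.}
#'     \item{state}{the final `agent_state`.}
#'     \item{params, condition, label}{inputs echoed back.}
#'   }
#' @examples
#' pr <- build_simulation_protocol(0.5, 30, seed = 1)
#' run <- run_protocol(model_params(), pr)
#' head(run$trials)
#' @export
run_protocol <- function(params, protocol, condition = drug_condition(),
                         engine = c("compiled", "reference")) {
  validate_model_params(params)
  stopifnot(inherits(protocol, "protocol"),
            inherits(condition, "drug_condition"))
  engine <- match.arg(engine)

  phases <- unlist(lapply(protocol$sessions,
                          function(s) rep(s$phase, length(s$schedule))))
  rewarded <- unlist(lapply(protocol$sessions, `[[`, "schedule"))
  probs <- unlist(lapply(protocol$sessions,
                         function(s) rep(s$probability, length(s$schedule))))

  if (engine == "compiled") {
    res <- run_flat_compiled(params, phases, rewarded, probs, condition,
                             keep_traces = TRUE)
  } else {
    res <- run_flat_reference(params, phases, rewarded, probs, condition)
  }

  trials <- data.frame(
    trial = seq_along(phases),
    phase = phases,
    probability = probs,
    rewarded = rewarded,
    arousal = res$arousal,
    delta_cs = res$delta_cs,
    delta_outcome = res$delta_outcome,
    stringsAsFactors = FALSE
  )
  structure(list(
    trials = trials,
    delta = res$delta,
    value = res$value,
    state = res$state,
    params = params,
    condition = condition,
    label = protocol$label
  ), class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  ph <- rle(x$trials$phase)
  cat(sprintf("<sim_run> %s: %d trials (%s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$trials),
              paste(sprintf("%s %d", ph$values, ph$lengths), collapse = ", ")))
  first_ext <- which(x$trials$phase == "extinction")
  if (length(first_ext)) {
    tte <- trials_to_extinction(x)
    cat(sprintf("  trials to extinction (criterion %g): %s\n",
                x$params$extinction_criterion,
                if (is.na(tte)) "not reached" else tte))
  }
  invisible(x)
}

phase_codes <- c(acquisition = 1L, extinction = 2L, "break" = 3L,
                 reacquisition = 4L)
drug_codes <- c(none = 0L, enhance = 1L, reduce = 2L)

run_flat_compiled <- function(params, phases, rewarded, probs, condition,
                              keep_traces = FALSE) {
  res <- .sim_protocol_cpp(
    phase = unname(phase_codes[phases]),
    rewarded = rewarded,
    probability = probs,
    alpha = params$alpha, beta = params$beta,
    lambda_trace = params$lambda_trace,
    psi_plus = params$psi_plus, psi_minus = params$psi_minus,
    eta = params$eta, gamma = params$gamma,
    trial_length = params$trial_length, cs_time = params$cs_time,
    reward_time = params$reward_time,
    reward_magnitude = params$reward_magnitude,
    use_arousal = params$use_arousal,
    init_learned = params$arousal_init == "learned",
    arousal_max_abs = params$arousal_delta == "max_abs",
    drug_both_windows = params$drug_window == "both",
    drug_dir = unname(drug_codes[condition$direction]),
    dose = condition$dose,
    keep_traces = keep_traces
  )
  state <- init_agent(params)
  state$w_plus <- res$w_plus
  state$w_minus <- res$w_minus
  state$trial_index <- length(phases)
  list(delta_cs = res$delta_cs, delta_outcome = res$delta_outcome,
       arousal = res$arousal,
       delta = if (keep_traces) res$delta else NULL,
       value = if (keep_traces) res$value else NULL,
       state = state)
}

run_flat_reference <- function(params, phases, rewarded, probs, condition) {
  n <- length(phases)
  tl <- params$trial_length
  state <- init_agent(params)
  none <- drug_condition("none")
  delta_cs <- numeric(n)
  delta_outcome <- numeric(n)
  arousal_rec <- numeric(n)
  delta <- matrix(0, n, tl)
  value <- matrix(0, n, tl)
  arousal <- 1.0
  last_acq_dcs <- 0.0

  for (i in seq_len(n)) {
    ph <- phases[i]
    if (ph == "break") {
      state <- apply_break_trial(state, params)
      arousal_rec[i] <- arousal
      next
    }
    acq_like <- ph %in% c("acquisition", "reacquisition")
    if (ph == "extinction" && params$use_arousal && i > 1L &&
        phases[i - 1L] %in% c("acquisition", "reacquisition")) {
      arousal <- if (params$arousal_init == "learned") {
        abs(last_acq_dcs)
      } else {
        probs[i]
      }
    }
    a_i <- if (!params$use_arousal || acq_like) 1.0 else arousal
    cond_i <- if (params$drug_window == "both" || acq_like) condition else none

    state$arousal <- a_i
    out <- run_trial(state, rewarded[i], cond_i, params, phase = ph)
    state <- out$state
    delta[i, ] <- out$record$delta_trace
    value[i, ] <- out$record$value_trace
    delta_cs[i] <- out$record$delta_at_cs
    delta_outcome[i] <- out$record$delta_trace[params$reward_time]
    arousal_rec[i] <- a_i
    if (acq_like) last_acq_dcs <- delta_cs[i]
    if (params$use_arousal && ph == "extinction") {
      driver <- if (params$arousal_delta == "outcome") {
        delta_outcome[i]
      } else {
        max(abs(delta[i, ]))
      }
      arousal <- arousal_update(arousal, driver, params$eta)
    }
  }
  state$arousal <- arousal
  list(delta_cs = delta_cs, delta_outcome = delta_outcome,
       arousal = arousal_rec, delta = delta, value = value, state = state)
}
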
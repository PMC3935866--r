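#' Initialise a naive learner
#'
#' All association weights and the eligibility trace start at zero (the CS
#' carries no value before conditioning), and arousal starts at 1.
#'
#' @param params a [model_params()] object.
#' @return An object of class `agent_state` with fields `w_plus`, `w_minus`
#'   (weight vectors over the serial-compound features), `eligibility`,
#'   `arousal` and `trial_index`.
#' @examples
#' st <- init_agent(model_params())
#' st$w_plus
#' @export
init_agent <- function(params) {
  validate_model_params(params)
  nf <- n_features(params)
  structure(list(
    w_plus = numeric(nf),
    w_minus = numeric(nf),
    eligibility = numeric(nf),
    arousal = 1.0,
    trial_index = 0L
  ), class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat("<agent_state>\n")
  cat("  w+:", format(round(x$w_plus, 4)), "\n")
  cat("  w-:", format(round(x$w_minus, 4)), "\n")
  cat(sprintf("  arousal = %g, trials seen = %d\n", x$arousal, x$trial_index))
  invisible(x)
}

#' Serial-compound feature vector at a time step
#'
#' The stimulus representation is a complete serial compound (tapped delay
#' line): before CS onset the feature vector is all zero; from CS onset on,
#' component `t - cs_time + 1` is 1 and all others 0.  This gives every
#' post-CS time step its own value weight, so the prediction error at the CS
#' and at the reward time are distinct quantities.
#'
#' @param t time step within the trial, `1 <= t <= trial_length`.
#' @param params a [model_params()] object.
#' @return numeric 0/1 vector of length `n_features(params)`.
#' @examples
#' features(3, model_params())  # CS onset: first component
#' features(2, model_params())  # pre-CS: all zero
#' @export
features <- function(t, params) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) ||
      t < 1 || t > params$trial_length || t != as.integer(t)) {
    stop(sprintf("time step must be an integer in 1..%d", params$trial_length),
         call. = FALSE)
  }
  x <- numeric(n_features(params))
  if (t >= params$cs_time) x[t - params$cs_time + 1L] <- 1
  x
}

# feature index at time t: 0 before CS onset (internal fast path)
feature_index <- function(t, params) {
  if (t >= params$cs_time) t - params$cs_time + 1L else 0L
}

#' Drug transform of the prediction error
#'
#' The simulated drug rescales the prediction error multiplicatively in its
#' magnitude: `reduce` maps `delta` to `delta - dose * |delta|` (positive
#' errors shrink, negative errors grow more negative — reward value is
#' underestimated), `enhance` maps it to `delta + dose * |delta|` (the
#' opposite — value is overestimated).  Dose 0 and direction `"none"` are
#' the identity, and a zero error is always mapped to zero.
#'
#' @param delta prediction error (numeric vector allowed).
#' @param condition a [drug_condition()].
#' @return transformed prediction error, same shape as `delta`.
#' @examples
#' drug_transform(0.5, drug_condition("reduce", 0.1))   # 0.45
#' drug_transform(-0.5, drug_condition("reduce", 0.1))  # -0.55
#' @export
drug_transform <- function(delta, condition) {
  stopifnot(inherits(condition, "drug_condition"))
  switch(condition$direction,
    none = delta,
    reduce = delta - condition$dose * abs(delta),
    enhance = delta + condition$dose * abs(delta)
  )
}

#' One temporal-difference time step
#'
#' Computes the value `V(t) = (w+ + w-) . x(t)`, the prediction error
#' `delta(t) = r(t) + gamma * V(t) - V(t-1)` (with `V` of the step before
#' trial start equal to 0), passes delta through the drug transform, updates
#' the eligibility trace as `e <- gamma * lambda * e + x(t-1)`, and applies
#' the arousal-gated weight updates
#' `w+ <- max(w+ + alpha * A * delta * e, 0)` and
#' `w- <- min(w- + beta * A * delta * e, 0)`.
#'
#' The trace carries the features of the *previous* step, so the prediction
#' error produced by an unpredicted CS onset assigns credit to nothing: the
#' persistent phasic burst at the CS drives no learning, which is what keeps
#' the positive weights bounded.
#'
#' @param state an `agent_state`; `state$eligibility` must have been reset
#'   to zero at the start of the trial (see [run_trial()]).
#' @param t time step within the trial.
#' @param reward reward delivered at this step, value units.
#' @param condition a [drug_condition()].
#' @param params a [model_params()] object.
#' @param learning_enabled if `FALSE` (break phase) nothing is computed and
#'   the state is returned unchanged with a zero error.
#' @return `list(state = updated agent_state, delta = transformed error)`.
#' @export
td_step <- function(state, t, reward, condition, params,
                    learning_enabled = TRUE) {
  if (!learning_enabled) {
    return(list(state = state, delta = 0))
  }
  nf <- n_features(params)
  if (length(state$w_plus) != nf || length(state$w_minus) != nf ||
      length(state$eligibility) != nf) {
    stop("agent state vectors do not match the feature representation",
         call. = FALSE)
  }
  k <- feature_index(t, params)
  k_prev <- if (t > 1) feature_index(t - 1L, params) else 0L
  v_t <- if (k > 0L) state$w_plus[k] + state$w_minus[k] else 0
  v_prev <- if (k_prev > 0L) {
    state$w_plus[k_prev] + state$w_minus[k_prev]
  } else 0
  delta <- reward + params$gamma * v_t - v_prev
  delta <- drug_transform(delta, condition)

  e <- params$gamma * params$lambda_trace * state$eligibility
  if (k_prev > 0L) e[k_prev] <- e[k_prev] + 1
  a <- state$arousal
  state$w_plus <- pmax(state$w_plus + params$alpha * a * delta * e, 0)
  state$w_minus <- pmin(state$w_minus + params$beta * a * delta * e, 0)
  state$eligibility <- e
  list(state = state, delta = delta)
}

#' Run one complete learning trial
#'
#' Resets the eligibility trace (trials are separated by long inter-trial
#' intervals, so no credit crosses trial boundaries), then applies
#' [td_step()] at every time step.  The reward, when scheduled, is delivered
#' at `params$reward_time`.
#'
#' @param state an `agent_state`.
#' @param rewarded logical, whether the US is delivered this trial.
#' @param condition a [drug_condition()].
#' @param params a [model_params()] object.
#' @param phase phase label recorded in the trial record.
#' @return `list(state = updated state, record = trial record)` where the
#'   record holds `delta_trace`, `value_trace`, `delta_at_cs`, `rewarded`,
#'   `arousal` and `phase`.
#' @export
run_trial <- function(state, rewarded, condition, params,
                      phase = "acquisition") {
  state$eligibility <- numeric(n_features(params))
  tl <- params$trial_length
  delta_trace <- numeric(tl)
  value_trace <- numeric(tl)
  for (t in seq_len(tl)) {
    k <- feature_index(t, params)
    value_trace[t] <- if (k > 0L) state$w_plus[k] + state$w_minus[k] else 0
    r <- if (rewarded && t == params$reward_time) params$reward_magnitude else 0
    step <- td_step(state, t, r, condition, params)
    state <- step$state
    delta_trace[t] <- step$delta
  }
  state$trial_index <- state$trial_index + 1L
  record <- list(
    delta_trace = delta_trace,
    value_trace = value_trace,
    delta_at_cs = delta_trace[params$cs_time],
    rewarded = isTRUE(rewarded),
    arousal = state$arousal,
    phase = phase
  )
  list(state = state, record = record)
}

#' Arousal update
#'
#' Arousal is a trial-level surprise signal with first-order decay:
#' `A' = eta * A + (1 - eta) * |delta|`.  A large decay factor `eta` makes
#' arousal persistent (it changes more slowly than the prediction error
#' itself); constant surprise `|delta| = c` drives arousal geometrically to
#' the fixed point `c`.
#'
#' @param arousal current arousal level, nonnegative.
#' @param delta the prediction error driving the update (its absolute value
#'   is used).
#' @param eta decay factor in (0, 1).
#' @return updated arousal level.
#' @examples
#' arousal_update(1, 0, 0.97)        # pure decay: 0.97
#' arousal_update(0.25, -0.5, 0.97)  # 0.97*0.25 + 0.03*0.5
#' @export
arousal_update <- function(arousal, delta, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) ||
      eta <= 0 || eta >= 1) {
    stop("arousal decay factor 'eta' must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (arousal < 0) stop("arousal must be nonnegative", call. = FALSE)
  eta * arousal + (1 - eta) * abs(delta)
}

#' Apply one break trial (forgetting only)
#'
#' During the break no stimuli are presented and no prediction errors are
#' generated; the only process is forgetting, which scales the positive
#' weights by `psi_plus` (close to 1: almost no loss) and the negative
#' weights by `psi_minus` (0.9: fast loss).  Because extinction is stored
#' mainly in the negative weights, their faster decay during the break
#' produces spontaneous recovery of the conditioned response.  The
#' eligibility trace is cleared and arousal is left unchanged.
#'
#' @param state an `agent_state`.
#' @param params a [model_params()] object.
#' @return the updated `agent_state`.
#' @export
apply_break_trial <- function(state, params) {
  state$w_plus <- state$w_plus * params$psi_plus
  state$w_minus <- state$w_minus * params$psi_minus
  state$eligibility <- numeric(n_features(params))
  state$trial_index <- state$trial_index + 1L
  state
}
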
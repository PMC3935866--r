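#' Model parameters for the arousal-gated TD learner
#'
#' Collects every scalar constant of the model: learning rates for the two
#' weight populations, eligibility-trace and forgetting decays, the arousal
#' decay factor, within-trial timing, and the extinction criterion.
#'
#' The defaults are the values used throughout the reference simulations:
#' `alpha = 0.08` and `beta = 0.04` for the positive and negative weights,
#' trace decay `lambda_trace = 0.9`, break-time forgetting factors
#' `psi_plus = 0.999999` (positive weights, nearly no forgetting) and
#' `psi_minus = 0.9` (negative weights, fast forgetting — the source of
#' spontaneous recovery), ten time steps per trial with the CS at step 3 and
#' the reward at step 8, and extinction declared when |delta(CS)| < 0.12.
#'
#' `gamma` is the per-step temporal discount.  The default is 1 (no
#' discounting within a trial), under which the asymptotic prediction error
#' at the CS equals the expected reward `p * reward_magnitude`; see the
#' package vignette for why this choice matters for the partial
#' reinforcement extinction effect.
#'
#' @param alpha learning rate of the positive weight vector, in (0, 1].
#' @param beta learning rate of the negative weight vector, in (0, 1].
#' @param lambda_trace eligibility-trace decay factor, in (0, 1].
#' @param psi_plus per-break-trial decay factor of the positive weights.
#' @param psi_minus per-break-trial decay factor of the negative weights.
#' @param eta arousal decay factor per extinction trial, in (0, 1).
#' @param gamma temporal discount factor per time step, in (0, 1].
#' @param trial_length number of time steps per trial.
#' @param cs_time time step of CS onset (1-based).
#' @param reward_time time step of reward delivery.
#' @param reward_magnitude reward size in value units.
#' @param extinction_criterion threshold on |delta(CS)| below which
#'   extinction is declared complete.
#' @param use_arousal logical; if `FALSE` arousal is held at 1 everywhere
#'   (the arousal-free model).
#' @param arousal_init how arousal is initialised at the start of an
#'   extinction phase that follows acquisition: `"learned"` uses the
#'   prediction error at the CS on the last acquisition trial (the reward
#'   probability actually learned), `"programmed"` uses the session's
#'   scheduled reward probability.
#' @param arousal_delta which prediction error of an extinction trial
#'   drives the arousal update: `"outcome"` (the error at the scheduled
#'   reward time) or `"max_abs"` (the largest |delta| in the trial).
#' @param drug_window phases in which the prediction-error drug transform
#'   is active: `"both"` (acquisition and extinction, the default — the
#'   infusion precedes acquisition and extinction follows immediately) or
#'   `"acquisition"`.
#'
#' @return An object of class `model_params` (a validated named list).
#' @seealso [drug_condition()], [init_agent()], [run_protocol()]
#' @examples
#' p <- model_params()
#' p$alpha
#' model_params(eta = 0.99)
#' @export
model_params <- function(alpha = 0.08,
                         beta = 0.04,
                         lambda_trace = 0.9,
                         psi_plus = 0.999999,
                         psi_minus = 0.9,
                         eta = 0.97,
                         gamma = 1.0,
                         trial_length = 10L,
                         cs_time = 3L,
                         reward_time = 8L,
                         reward_magnitude = 1.0,
                         extinction_criterion = 0.12,
                         use_arousal = TRUE,
                         arousal_init = c("learned", "programmed"),
                         arousal_delta = c("outcome", "max_abs"),
                         drug_window = c("both", "acquisition")) {
  p <- list(
    alpha = as.numeric(alpha),
    beta = as.numeric(beta),
    lambda_trace = as.numeric(lambda_trace),
    psi_plus = as.numeric(psi_plus),
    psi_minus = as.numeric(psi_minus),
    eta = as.numeric(eta),
    gamma = as.numeric(gamma),
    trial_length = as.integer(trial_length),
    cs_time = as.integer(cs_time),
    reward_time = as.integer(reward_time),
    reward_magnitude = as.numeric(reward_magnitude),
    extinction_criterion = as.numeric(extinction_criterion),
    use_arousal = isTRUE(use_arousal),
    arousal_init = match.arg(arousal_init),
    arousal_delta = match.arg(arousal_delta),
    drug_window = match.arg(drug_window)
  )
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  chk_unit <- function(x, key, open_top = FALSE) {
    if (!is.numeric(p[[key]]) || length(p[[key]]) != 1L || is.na(p[[key]])) {
      stop(sprintf("parameter '%s' must be a single number", key), call. = FALSE)
    }
    hi_ok <- if (open_top) p[[key]] < 1 else p[[key]] <= 1
    if (p[[key]] <= 0 || !hi_ok) {
      stop(sprintf("parameter '%s' out of range %s: %g", key,
                   if (open_top) "(0, 1)" else "(0, 1]", p[[key]]),
           call. = FALSE)
    }
  }
  for (key in c("alpha", "beta", "lambda_trace", "psi_plus", "psi_minus",
                "gamma")) {
    chk_unit(p[[key]], key)
  }
  chk_unit(p$eta, "eta", open_top = TRUE)
  if (!(p$cs_time >= 1L && p$cs_time < p$reward_time &&
        p$reward_time <= p$trial_length)) {
    stop("trial timing must satisfy 1 <= cs_time < reward_time <= trial_length",
         call. = FALSE)
  }
  if (p$extinction_criterion <= 0) {
    stop("parameter 'extinction_criterion' must be positive", call. = FALSE)
  }
  if (p$reward_magnitude <= 0) {
    stop("parameter 'reward_magnitude' must be positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  rates:   alpha = %g, beta = %g, lambda = %g, gamma = %g\n",
              x$alpha, x$beta, x$lambda_trace, x$gamma))
  cat(sprintf("  decay:   psi+ = %g, psi- = %g, eta = %g\n",
              x$psi_plus, x$psi_minus, x$eta))
  cat(sprintf("  timing:  %d steps, CS at %d, reward at %d (magnitude %g)\n",
              x$trial_length, x$cs_time, x$reward_time, x$reward_magnitude))
  cat(sprintf("  arousal: %s (init = %s, driver = %s); criterion = %g\n",
              if (x$use_arousal) "gated" else "disabled (A = 1)",
              x$arousal_init, x$arousal_delta, x$extinction_criterion))
  invisible(x)
}

#' Number of serial-compound features implied by the trial timing
#'
#' The stimulus representation is a complete serial compound: one one-hot
#' feature per time step from CS onset to the end of the trial, so the
#' feature vector has `trial_length - cs_time + 1` components.
#'
#' @param params a [model_params()] object.
#' @return integer feature count.
#' @export
n_features <- function(params) {
  params$trial_length - params$cs_time + 1L
}

#' Simulated dopaminergic drug condition
#'
#' A drug condition scales the prediction error delta before it is used for
#' learning, recorded, or fed to the arousal update.  `"reduce"` emulates a
#' drug raising tonic dopamine (reducing the phasic signal-to-background
#' contrast): positive errors shrink and negative errors grow in magnitude.
#' `"enhance"` emulates dopamine inactivation at the injection site and does
#' the opposite.  Dose 0 (or direction `"none"`) is the identity.
#'
#' @param direction `"none"`, `"enhance"` or `"reduce"`.
#' @param dose nonnegative scalar drug amount; for `"reduce"` it must be
#'   below 1 so a positive prediction error can never flip sign.
#' @return An object of class `drug_condition`.
#' @seealso [drug_transform()]
#' @examples
#' drug_condition("reduce", 0.1)
#' @export
drug_condition <- function(direction = c("none", "enhance", "reduce"),
                           dose = 0) {
  direction <- match.arg(direction)
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("drug 'dose' must be a single nonnegative number", call. = FALSE)
  }
  if (direction == "reduce" && dose >= 1) {
    stop("'reduce' dose must be below 1 (a positive prediction error may not flip sign)",
         call. = FALSE)
  }
  structure(list(direction = direction, dose = as.numeric(dose)),
            class = "drug_condition")
}

#' @export
print.drug_condition <- function(x, ...) {
  if (x$direction == "none" || x$dose == 0) {
    cat("<drug_condition> none\n")
  } else {
    cat(sprintf("<drug_condition> %s, dose %g\n", x$direction, x$dose))
  }
  invisible(x)
}
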
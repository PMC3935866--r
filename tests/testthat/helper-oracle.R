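# Independent brute-force recomputation of the learning recurrences,
# written directly from their definitions and kept free of the package's
# engine code.  Scalar bookkeeping only: one named variable per weight
# component, explicit step-by-step updates.
#
# Recurrences checked:
#   V(t)   = sum over features of (wp + wm) . x(t), x = serial compound
#   delta  = r(t) + gamma * V(t) - V(t-1), then drug transform
#   e      = gamma * lambda * e + x(t-1)
#   wp     = max(wp + alpha * A * delta * e, 0)
#   wm     = min(wm + beta  * A * delta * e, 0)
oracle_run <- function(schedule,
                       alpha = 0.08, beta = 0.04, lambda = 0.9,
                       gamma = 1.0, trial_length = 10, cs_time = 3,
                       reward_time = 8, reward_magnitude = 1,
                       arousal = rep(1, length(schedule)),
                       drug_dir = "none", dose = 0) {
  nf <- trial_length - cs_time + 1
  wp <- rep(0, nf)
  wm <- rep(0, nf)
  n <- length(schedule)
  delta_hist <- matrix(0, n, trial_length)
  value_hist <- matrix(0, n, trial_length)
  wp_hist <- matrix(0, n, nf)
  wm_hist <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    e <- rep(0, nf)
    v_prev <- 0
    for (t in seq_len(trial_length)) {
      # feature active at t (0 = none), and the one active at t - 1
      k <- if (t >= cs_time) t - cs_time + 1 else 0
      kp <- if (t - 1 >= cs_time) t - cs_time else 0
      v_t <- 0
      if (k > 0) v_t <- wp[k] + wm[k]
      r <- 0
      if (schedule[i] && t == reward_time) r <- reward_magnitude
      d <- r + gamma * v_t - v_prev
      if (drug_dir == "reduce") d <- d - dose * abs(d)
      if (drug_dir == "enhance") d <- d + dose * abs(d)
      for (j in seq_len(nf)) e[j] <- gamma * lambda * e[j]
      if (kp > 0) e[kp] <- e[kp] + 1
      for (j in seq_len(nf)) {
        wp[j] <- wp[j] + alpha * arousal[i] * d * e[j]
        if (wp[j] < 0) wp[j] <- 0
        wm[j] <- wm[j] + beta * arousal[i] * d * e[j]
        if (wm[j] > 0) wm[j] <- 0
      }
      v_prev <- 0
      if (k > 0) v_prev <- wp[k] + wm[k]
      delta_hist[i, t] <- d
      value_hist[i, t] <- v_t
    }
    wp_hist[i, ] <- wp
    wm_hist[i, ] <- wm
  }
  list(delta = delta_hist, value = value_hist,
       wp = wp_hist, wm = wm_hist)
}

# run a schedule through the package per-step API (reference path),
# arousal fixed at the supplied per-trial levels
api_run <- function(schedule, params, condition = drug_condition(),
                    arousal = rep(1, length(schedule))) {
  st <- init_agent(params)
  delta <- matrix(0, length(schedule), params$trial_length)
  value <- matrix(0, length(schedule), params$trial_length)
  wp <- matrix(0, length(schedule), n_features(params))
  wm <- matrix(0, length(schedule), n_features(params))
  for (i in seq_along(schedule)) {
    st$arousal <- arousal[i]
    out <- run_trial(st, schedule[i], condition, params)
    st <- out$state
    delta[i, ] <- out$record$delta_trace
    value[i, ] <- out$record$value_trace
    wp[i, ] <- st$w_plus
    wm[i, ] <- st$w_minus
  }
  list(delta = delta, value = value, wp = wp, wm = wm, state = st)
}
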
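#' A single session phase with its reward schedule
#'
#' @param phase one of `"acquisition"`, `"extinction"`, `"break"`,
#'   `"reacquisition"`.
#' @param probability programmed reward probability of the session in
#'   (0, 1]; extinction and break phases carry the probability of the
#'   acquisition they follow (used for the arousal reset rule).
#' @param schedule logical vector of per-trial reward indicators; must be
#'   all `FALSE` for extinction and break phases.
#' @param seed integer seed that generated the schedule (`NA` for
#'   deterministic schedules).
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(phase = c("acquisition", "extinction", "break",
                                   "reacquisition"),
                         probability, schedule, seed = NA_integer_) {
  phase <- match.arg(phase)
  if (!is.numeric(probability) || length(probability) != 1L ||
      is.na(probability) || probability <= 0 || probability > 1) {
    stop("session 'probability' must lie in (0, 1]", call. = FALSE)
  }
  schedule <- as.logical(schedule)
  if (length(schedule) < 1L || anyNA(schedule)) {
    stop("'schedule' must be a nonempty logical vector", call. = FALSE)
  }
  if (phase %in% c("extinction", "break") && any(schedule)) {
    stop(sprintf("%s schedules must contain no rewards", phase), call. = FALSE)
  }
  structure(list(phase = phase, probability = probability,
                 schedule = schedule, seed = as.integer(seed)),
            class = "session_spec")
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("<session_spec> %s: %d trials, %d rewarded (p = %g, seed = %s)\n",
              x$phase, length(x$schedule), sum(x$schedule), x$probability,
              ifelse(is.na(x$seed), "-", x$seed)))
  invisible(x)
}

#' An ordered multi-phase experiment protocol
#'
#' @param sessions list of [session_spec()] objects; phases must appear in
#'   a legal order (an extinction is preceded by an acquisition or
#'   reacquisition somewhere before it; a break only separates extinction
#'   phases).
#' @param label free-form protocol label.
#' @return An object of class `protocol`.
#' @export
protocol <- function(sessions, label = "") {
  if (!length(sessions) || !all(vapply(sessions, inherits, TRUE, "session_spec"))) {
    stop("'sessions' must be a nonempty list of session_spec objects",
         call. = FALSE)
  }
  phases <- vapply(sessions, `[[`, "", "phase")
  first_ext <- match("extinction", phases)
  first_acq <- match(TRUE, phases %in% c("acquisition", "reacquisition"))
  if (!is.na(first_ext) && (is.na(first_acq) || first_acq > first_ext)) {
    stop("an extinction phase must be preceded by an acquisition phase",
         call. = FALSE)
  }
  for (i in which(phases == "break")) {
    if (i == 1L || i == length(phases) ||
        phases[i - 1L] != "extinction" || phases[i + 1L] != "extinction") {
      stop("a break may only separate two extinction phases", call. = FALSE)
    }
  }
  structure(list(sessions = sessions, label = as.character(label)),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s (%d phases, %d trials)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$sessions),
              sum(vapply(x$sessions, function(s) length(s$schedule), 1L))))
  for (s in x$sessions) print(s)
  invisible(x)
}

# half-up rounding; R's round() rounds half to even, which would make the
# designed reward count of e.g. a 10-trial block at p = 0.25 depend on the
# parity of the neighbour integer
round_half_up <- function(x) floor(x + 0.5)

# exact-count shuffled block: n trials, n_rewarded rewards, order drawn from
# the current RNG stream; optional cap on consecutive omissions
shuffle_block <- function(n, n_rewarded, max_run_omissions = Inf) {
  stopifnot(n_rewarded >= 0, n_rewarded <= n)
  block <- c(rep(TRUE, n_rewarded), rep(FALSE, n - n_rewarded))
  repeat {
    out <- sample(block)
    if (!is.finite(max_run_omissions)) return(out)
    runs <- rle(out)
    if (all(runs$lengths[!runs$values] <= max_run_omissions)) return(out)
  }
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Trial-constant acquisition session
#'
#' Builds a 20-trial acquisition session in which exactly `20 * p` trials
#' are rewarded, in an order shuffled by `seed` (exact-count design, not
#' independent Bernoulli draws).
#'
#' @param p reward probability; `20 * p` must be an integer.
#' @param seed integer seed for the shuffle.
#' @param max_run_omissions optional upper bound on consecutive unrewarded
#'   trials (off by default).
#' @return a [session_spec()] with phase `"acquisition"`.
#' @examples
#' s <- build_trial_constant(0.25, seed = 1)
#' sum(s$schedule)  # 5
#' @export
build_trial_constant <- function(p, seed, max_run_omissions = Inf) {
  n <- 20L
  nr <- n * p
  if (abs(nr - round(nr)) > 1e-8) {
    stop(sprintf("probability %g does not give an integral reward count over %d trials",
                 p, n), call. = FALSE)
  }
  nr <- as.integer(round(nr))
  sched <- with_local_seed(seed, shuffle_block(n, nr, max_run_omissions))
  session_spec("acquisition", p, sched, seed)
}

#' Reward-constant acquisition session
#'
#' Builds an acquisition session with exactly 20 rewards; the total number
#' of trials is `ceiling(20 / p)`, so lower probabilities give longer
#' sessions (80 trials at p = 0.25, 27 at p = 0.75, 20 at p = 1).
#'
#' @inheritParams build_trial_constant
#' @param p reward probability in (0, 1].
#' @return a [session_spec()] with phase `"acquisition"`.
#' @examples
#' length(build_reward_constant(0.25, seed = 1)$schedule)  # 80
#' @export
build_reward_constant <- function(p, seed, max_run_omissions = Inf) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("probability must lie in (0, 1]", call. = FALSE)
  }
  n <- as.integer(ceiling(20 / p - 1e-9))
  sched <- with_local_seed(seed, shuffle_block(n, 20L, max_run_omissions))
  session_spec("acquisition", p, sched, seed)
}

# acquisition schedule of n trials built from shuffled 20-trial blocks with
# exact per-block reward counts; the remainder block receives the balance so
# that the total equals round_half_up(n * p)
build_acquisition_schedule <- function(p, n, seed, max_run_omissions = Inf) {
  total <- round_half_up(n * p)
  with_local_seed(seed, {
    sched <- logical(0)
    remaining <- n
    placed <- 0L
    while (remaining > 0L) {
      b <- min(20L, remaining)
      nr <- if (remaining > 20L) round_half_up(20 * p) else total - placed
      if (nr < 0L || nr > b) {
        stop("inconsistent reward allocation across blocks", call. = FALSE)
      }
      sched <- c(sched, shuffle_block(b, nr, max_run_omissions))
      placed <- placed + as.integer(nr)
      remaining <- remaining - b
    }
    sched
  })
}

#' Standard simulation protocol: acquisition, extinction, break, extinction
#'
#' Builds the four-phase protocol used by the reference simulations:
#' `n_acq` acquisition trials at probability `p` (exact-count schedules,
#' assembled from shuffled 20-trial blocks, mirroring how behavioural
#' sessions are combined), then a first extinction phase, a break with
#' forgetting only, and a second extinction phase that exhibits spontaneous
#' recovery.
#'
#' @param p reward probability in (0, 1].
#' @param n_acq number of acquisition trials (the designed reward count,
#'   `round(n_acq * p)`, must be at least 1).
#' @param seed integer seed for the schedule shuffles.
#' @param n_ext1 length of the first extinction phase (default 70 trials).
#' @param n_break length of the break (default 20).
#' @param n_ext2 length of the second extinction phase (default 40).
#' @param max_run_omissions optional cap on consecutive unrewarded
#'   acquisition trials (off by default).
#' @return a [protocol()] with label `"sim_p<p>_n<n_acq>"`.
#' @examples
#' pr <- build_simulation_protocol(0.5, 30, seed = 1)
#' vapply(pr$sessions, function(s) length(s$schedule), 1L)  # 30 70 20 40
#' @export
build_simulation_protocol <- function(p, n_acq, seed,
                                      n_ext1 = 70L, n_break = 20L,
                                      n_ext2 = 40L,
                                      max_run_omissions = Inf) {
  if (!is.numeric(n_acq) || length(n_acq) != 1L || n_acq < 1) {
    stop("'n_acq' must be a positive integer", call. = FALSE)
  }
  n_acq <- as.integer(n_acq)
  if (n_acq * p < 1) {
    stop("schedule would contain no rewards: n_acq * p < 1", call. = FALSE)
  }
  acq <- session_spec("acquisition", p,
                      build_acquisition_schedule(p, n_acq, seed,
                                                 max_run_omissions),
                      seed)
  sessions <- list(
    acq,
    session_spec("extinction", p, rep(FALSE, n_ext1)),
    session_spec("break", p, rep(FALSE, n_break)),
    session_spec("extinction", p, rep(FALSE, n_ext2))
  )
  protocol(sessions, label = sprintf("sim_p%g_n%d", p, n_acq))
}

#' Serialize a protocol to JSON
#'
#' @param x a [protocol()].
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
protocol_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "protocol"))
  doc <- list(
    label = x$label,
    sessions = lapply(x$sessions, function(s) {
      list(phase = s$phase, probability = s$probability,
           seed = if (is.na(s$seed)) NULL else s$seed,
           schedule = as.integer(s$schedule))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Read a protocol from JSON
#'
#' @param path file path or JSON string produced by [protocol_to_json()].
#' @return a [protocol()].
#' @export
protocol_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sessions <- lapply(doc$sessions, function(s) {
    session_spec(s$phase, s$probability,
                 as.logical(unlist(s$schedule)),
                 if (!length(s$seed) || is.na(s$seed[[1]])) NA_integer_
                 else s$seed[[1]])
  })
  protocol(sessions, label = if (is.null(doc$label)) "" else doc$label)
}
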
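#' Trials to extinction
#'
#' The number of trials until extinction is the 1-based index of the first
#' extinction trial whose prediction error at the CS satisfies
#' `|delta(CS)| < criterion`.  Applied to a [run_protocol()] result it uses
#' the first extinction phase; it can also be applied directly to a numeric
#' series of CS-time prediction errors.
#'
#' @param x a `sim_run` or a numeric vector of `delta(CS)` values from a
#'   contiguous extinction phase.
#' @param criterion threshold on `|delta(CS)|`; for a `sim_run` it defaults
#'   to the run's `extinction_criterion`.
#' @param ... unused.
#' @return integer count, or `NA` (not reached within the phase).
#' @examples
#' trials_to_extinction(c(0.5, 0.2, 0.11, 0.05), criterion = 0.12)  # 3
#' @export
trials_to_extinction <- function(x, ...) UseMethod("trials_to_extinction")

#' @rdname trials_to_extinction
#' @export
trials_to_extinction.numeric <- function(x, criterion = 0.12, ...) {
  if (!length(x)) stop("empty extinction series", call. = FALSE)
  hit <- which(abs(x) < criterion)
  if (!length(hit)) NA_integer_ else hit[1L]
}

#' @rdname trials_to_extinction
#' @export
trials_to_extinction.sim_run <- function(x, criterion = NULL, ...) {
  if (is.null(criterion)) criterion <- x$params$extinction_criterion
  idx <- first_extinction_index(x$trials$phase)
  if (!length(idx)) stop("run contains no extinction phase", call. = FALSE)
  trials_to_extinction(x$trials$delta_cs[idx], criterion = criterion)
}

# indices of the first contiguous extinction phase
first_extinction_index <- function(phases) {
  r <- rle(phases)
  ends <- cumsum(r$lengths)
  j <- match("extinction", r$values)
  if (is.na(j)) return(integer(0))
  seq(ends[j] - r$lengths[j] + 1L, ends[j])
}

#' Classify the shape of an extinction-rate curve
#'
#' Labels a curve of trials-to-extinction against increasing reward
#' probability:
#' \describe{
#'   \item{`decreasing_PREE`}{strictly decreasing — the partial
#'     reinforcement extinction effect (every consecutive drop exceeds
#'     `tolerance`).}
#'   \item{`increasing`}{strictly increasing (extinction slower for higher
#'     probabilities, the arousal-free pattern).}
#'   \item{`inverted_U`}{interior maximum exceeding both endpoints by more
#'     than `tolerance`.}
#'   \item{`flat_or_mixed`}{anything else.}
#' }
#'
#' @param counts numeric vector of (mean) trials-to-extinction, ordered by
#'   increasing reward probability; at least 3 levels.
#' @param tolerance margin (in trials) a difference must exceed to count.
#' @return a single character label.
#' @examples
#' classify_curve(c(4, 3, 2, 1))      # decreasing_PREE
#' classify_curve(c(1, 3, 2.5, 1))    # inverted_U
#' @export
classify_curve <- function(counts, tolerance = 0.5) {
  if (!is.numeric(counts) || length(counts) < 3L || anyNA(counts)) {
    stop("'counts' must be a numeric vector of at least 3 probability levels",
         call. = FALSE)
  }
  d <- diff(counts)
  if (all(d < -tolerance)) return("decreasing_PREE")
  if (all(d > tolerance)) return("increasing")
  im <- which.max(counts)
  if (im > 1L && im < length(counts) &&
      counts[im] > counts[1L] + tolerance &&
      counts[im] > counts[length(counts)] + tolerance) {
    return("inverted_U")
  }
  "flat_or_mixed"
}

# seeds used for a sweep: one shared list across cells so cells are
# comparable; all values stay far below .Machine$integer.max
sweep_seeds <- function(seed, n_seeds) as.integer(seed) + seq_len(n_seeds) - 1L

run_cell <- function(params, p, n_acq, condition, seeds, n_ext1 = 70L) {
  tte <- integer(length(seeds))
  censored <- logical(length(seeds))
  end_value <- numeric(length(seeds))
  for (j in seq_along(seeds)) {
    pr <- build_simulation_protocol(p, n_acq, seeds[j], n_ext1 = n_ext1)
    phases <- unlist(lapply(pr$sessions,
                            function(s) rep(s$phase, length(s$schedule))))
    rewarded <- unlist(lapply(pr$sessions, `[[`, "schedule"))
    probs <- unlist(lapply(pr$sessions,
                           function(s) rep(s$probability, length(s$schedule))))
    res <- run_flat_compiled(params, phases, rewarded, probs, condition)
    ext <- first_extinction_index(phases)
    count <- trials_to_extinction(res$delta_cs[ext],
                                  criterion = params$extinction_criterion)
    censored[j] <- is.na(count)
    tte[j] <- if (is.na(count)) length(ext) else count
    end_value[j] <- res$delta_cs[n_acq]
  }
  list(tte = tte, censored = censored, end_value = end_value)
}

#' Sweep trials-to-extinction over probability, arousal decay and training
#'
#' Runs the standard acquisition/extinction/break/extinction protocol for
#' every combination of reward probability, arousal decay factor `eta` and
#' acquisition length, with `n_seeds` independently shuffled schedules per
#' cell (the same seed list is shared across cells).  Runs that do not
#' reach the extinction criterion within the first extinction phase are
#' recorded at the phase length and flagged as censored.  For each
#' `(eta, n_acq)` pair the curve of per-cell mean counts over the
#' probability axis is classified with [classify_curve()]; a curve
#' containing a cell with more than `max_censored` censored runs is
#' labelled `flat_or_mixed`.
#'
#' @param params a [model_params()] object (`eta` is overridden cell-wise).
#' @param probabilities probability grid (increasing; at least 3 values for
#'   classification).
#' @param etas arousal decay factor grid.
#' @param n_acq acquisition length grid.
#' @param condition a [drug_condition()] applied to every run.
#' @param n_seeds schedules per cell.
#' @param seed base seed; cell seeds are `seed + 0:(n_seeds-1)`.
#' @param tolerance classification margin in trials, see [classify_curve()].
#' @param max_censored highest tolerated fraction of censored runs per cell
#'   before the cell invalidates its curve's classification.
#' @return An object of class `sweep_result` with `results` (one row per
#'   run), `summary` (one row per cell), `labels` (one row per
#'   `(eta, n_acq)`) and `meta`.
#' @examples
#' \donttest{
#' sw <- sweep_extinction(model_params(), n_acq = 30, n_seeds = 5, seed = 1)
#' sw$labels
#' }
#' @export
sweep_extinction <- function(params,
                             probabilities = c(0.25, 0.5, 0.75, 1.0),
                             etas = params$eta,
                             n_acq = 30L,
                             condition = drug_condition(),
                             n_seeds = 20L,
                             seed = 1L,
                             tolerance = 0.5,
                             max_censored = 0.5) {
  validate_model_params(params)
  stopifnot(length(probabilities) >= 1L, length(etas) >= 1L,
            length(n_acq) >= 1L, n_seeds >= 1L)
  probabilities <- sort(probabilities)
  seeds <- sweep_seeds(seed, n_seeds)
  cells <- expand.grid(probability = probabilities, eta = etas,
                       n_acq = as.integer(n_acq),
                       KEEP.OUT.ATTRS = FALSE)
  res_rows <- vector("list", nrow(cells))
  sum_rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    p <- cells$probability[ci]
    eta_i <- cells$eta[ci]
    na_i <- cells$n_acq[ci]
    par_i <- params
    par_i$eta <- eta_i
    cell <- run_cell(par_i, p, na_i, condition, seeds)
    res_rows[[ci]] <- data.frame(
      probability = p, eta = eta_i, n_acq = na_i,
      direction = condition$direction, dose = condition$dose,
      seed = seeds, trials_to_extinction = cell$tte,
      censored = cell$censored, end_value = cell$end_value
    )
    sum_rows[[ci]] <- data.frame(
      probability = p, eta = eta_i, n_acq = na_i,
      mean_tte = mean(cell$tte), sd_tte = stats::sd(cell$tte),
      frac_censored = mean(cell$censored),
      mean_end_value = mean(cell$end_value), n_seeds = n_seeds
    )
  }
  results <- do.call(rbind, res_rows)
  summary <- do.call(rbind, sum_rows)

  lab_grid <- unique(summary[, c("eta", "n_acq")])
  labels <- do.call(rbind, lapply(seq_len(nrow(lab_grid)), function(i) {
    sub <- summary[summary$eta == lab_grid$eta[i] &
                     summary$n_acq == lab_grid$n_acq[i], ]
    sub <- sub[order(sub$probability), ]
    label <- if (length(probabilities) < 3L) {
      NA_character_
    } else if (any(sub$frac_censored > max_censored)) {
      "flat_or_mixed"
    } else {
      classify_curve(sub$mean_tte, tolerance)
    }
    data.frame(eta = lab_grid$eta[i], n_acq = lab_grid$n_acq[i],
               label = label)
  }))

  structure(list(results = results, summary = summary, labels = labels,
                 meta = list(seeds = seeds, tolerance = tolerance,
                             max_censored = max_censored,
                             condition = condition, params = params)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells x %d seeds\n",
              nrow(x$summary), length(x$meta$seeds)))
  print(x$labels, row.names = FALSE)
  invisible(x)
}

#' Smallest arousal decay factor producing a given curve shape
#'
#' @param x a [sweep_extinction()] result.
#' @param label the target shape label.
#' @param n_acq restrict to one acquisition length (required if the sweep
#'   covered several).
#' @return the smallest `eta` whose curve carries `label`, or `NA`.
#' @export
eta_threshold <- function(x, label, n_acq = NULL) {
  stopifnot(inherits(x, "sweep_result"))
  lab <- x$labels
  if (!is.null(n_acq)) lab <- lab[lab$n_acq == n_acq, ]
  hit <- lab$eta[lab$label == label]
  if (!length(hit)) NA_real_ else min(hit)
}

#' Dose-response sweep of the simulated drug
#'
#' Runs the standard protocol across reward probabilities and drug doses
#' for one drug direction, recording the learned value at the end of
#' acquisition (the CS-time prediction error on the last acquisition
#' trial) and the trials to extinction.  Defaults follow the reference
#' drug simulations: 30 acquisition trials and `eta = 0.97`.
#'
#' @param params a [model_params()] object.
#' @param probabilities probability grid.
#' @param direction `"enhance"` or `"reduce"`.
#' @param doses nonnegative dose grid (dose 0 reproduces the drug-free
#'   trajectories exactly); `reduce` doses must stay below 1.
#' @param n_acq acquisition length (default 30).
#' @param n_seeds,seed,tolerance,max_censored as in [sweep_extinction()].
#' @return An object of class `sweep_result` whose `results`, `summary` and
#'   `labels` carry a `dose` column.
#' @export
dose_response <- function(params,
                          probabilities = c(0.25, 0.5, 0.75, 1.0),
                          direction = c("enhance", "reduce"),
                          doses = c(0, 0.05, 0.1),
                          n_acq = 30L,
                          n_seeds = 20L,
                          seed = 1L,
                          tolerance = 0.5,
                          max_censored = 0.5) {
  direction <- match.arg(direction)
  stopifnot(all(doses >= 0))
  if (direction == "reduce" && any(doses >= 1)) {
    stop("'reduce' doses must be below 1", call. = FALSE)
  }
  per_dose <- lapply(doses, function(d) {
    cond <- if (d == 0) drug_condition("none") else drug_condition(direction, d)
    sw <- sweep_extinction(params, probabilities, etas = params$eta,
                           n_acq = n_acq, condition = cond,
                           n_seeds = n_seeds, seed = seed,
                           tolerance = tolerance, max_censored = max_censored)
    sw$results$dose <- d
    sw$results$direction <- direction
    sw$summary$dose <- d
    sw$summary$direction <- direction
    sw$labels$dose <- d
    sw
  })
  results <- do.call(rbind, lapply(per_dose, `[[`, "results"))
  summary <- do.call(rbind, lapply(per_dose, `[[`, "summary"))
  labels <- do.call(rbind, lapply(per_dose, `[[`, "labels"))
  structure(list(results = results, summary = summary, labels = labels,
                 meta = list(seeds = sweep_seeds(seed, n_seeds),
                             direction = direction, doses = doses,
                             tolerance = tolerance, params = params)),
            class = "sweep_result")
}

#' Normalize counts by each subject's mean
#'
#' Divides every entry of a subjects-by-sessions matrix by the row
#' (subject) mean, so each subject's normalized row averages 1.  This
#' removes between-subject baseline differences before comparing sessions.
#'
#' @param counts numeric matrix, one row per subject, one column per
#'   session; `NA` entries are ignored in the row means.
#' @return matrix of the same shape with row means 1.
#' @examples
#' normalize_by_subject_mean(rbind(c(10, 20, 30, 40)))
#' @export
normalize_by_subject_mean <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("'counts' must be numeric", call. = FALSE)
  if (any(apply(counts, 1L, function(r) all(is.na(r))))) {
    stop("a subject with all-missing sessions cannot be normalized",
         call. = FALSE)
  }
  m <- rowMeans(counts, na.rm = TRUE)
  if (any(m == 0)) stop("zero subject mean", call. = FALSE)
  sweep(counts, 1L, m, "/")
}

#' Normalize a probability curve to a reference level
#'
#' Divides each count by the count at the reference probability, so the
#' reference entry becomes 1.  Used to compare the shape of
#' extinction-probability curves across drug conditions.
#'
#' @param counts numeric vector of counts; its names, or `probabilities`,
#'   give the probability levels.
#' @param reference the probability level to normalize to (default 1).
#' @param probabilities optional numeric vector of levels matching
#'   `counts`.
#' @return normalized vector with the reference entry equal to 1.
#' @examples
#' normalize_to_reference(c(6, 9, 6, 3), probabilities = c(.25, .5, .75, 1))
#' @export
normalize_to_reference <- function(counts, reference = 1.0,
                                   probabilities = NULL) {
  if (is.null(probabilities)) {
    probabilities <- suppressWarnings(as.numeric(names(counts)))
  }
  if (length(probabilities) != length(counts) || anyNA(probabilities)) {
    stop("probability levels must be supplied via names(counts) or 'probabilities'",
         call. = FALSE)
  }
  i <- which(abs(probabilities - reference) < 1e-9)
  if (length(i) != 1L) {
    stop(sprintf("reference level %g not present exactly once", reference),
         call. = FALSE)
  }
  if (is.na(counts[i]) || counts[i] == 0) {
    stop("reference level did not reach the extinction criterion",
         call. = FALSE)
  }
  counts / counts[i]
}
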
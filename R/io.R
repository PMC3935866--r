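#' Default run configuration
#'
#' A run configuration is a flat named list: the model parameter block
#' (every field of [model_params()]), a drug block (`drug_direction`,
#' `drug_dose`), the experiment grids (`probabilities`, `etas`, `n_acq`,
#' `doses`), seeding (`seed`, `n_seeds`), classification settings
#' (`tolerance`, `max_censored`) and output control (`out_dir`, `label`,
#' `verbose`).
#'
#' @return named list with every supported key at its default value.
#' @seealso [load_config()], [run_command()]
#' @export
default_config <- function() {
  p <- model_params()
  c(unclass(p), list(
    drug_direction = "none",
    drug_dose = 0,
    probabilities = c(0.25, 0.5, 0.75, 1.0),
    etas = c(0.91, 0.93, 0.95, 0.97, 0.99),
    n_acq = 30L,
    doses = c(0, 0.05, 0.1),
    seed = 1L,
    n_seeds = 20L,
    tolerance = 0.5,
    max_censored = 0.5,
    out_dir = ".",
    label = "run",
    verbose = FALSE
  ))
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML file of `key: value` pairs.  Keys absent from the
#' file take their defaults ([default_config()]); unknown keys and
#' out-of-range values are rejected with the offending key named.
#'
#' @param path path to a YAML configuration file.
#' @return validated configuration list of class `run_config`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yml")
#' writeLines("eta: 0.99", cfg_file)
#' load_config(cfg_file)$eta
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  normalize_config(user)
}

#' @rdname load_config
#' @param config a named list of configuration overrides.
#' @export
normalize_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(unknown) > 1L) "s" else "",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- modifyList(defaults, config)
  for (key in c("probabilities", "etas", "doses")) {
    cfg[[key]] <- as.numeric(unlist(cfg[[key]]))
  }
  cfg$n_acq <- unlist(cfg$n_acq)
  # model parameter validation reports the offending key by name
  rethrow <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(conditionMessage(e), call. = FALSE)
    })
  }
  par <- rethrow(do.call(model_params, cfg[names(formals(model_params))]))
  cfg[names(unclass(par))] <- unclass(par)
  rethrow(drug_condition(cfg$drug_direction, cfg$drug_dose))
  if (any(cfg$probabilities <= 0 | cfg$probabilities > 1)) {
    stop("configuration key 'probabilities' must lie in (0, 1]",
         call. = FALSE)
  }
  if (any(cfg$etas <= 0 | cfg$etas >= 1)) {
    stop("configuration key 'etas' must lie in (0, 1)", call. = FALSE)
  }
  if (any(cfg$n_acq < 1)) {
    stop("configuration key 'n_acq' must be positive", call. = FALSE)
  }
  if (cfg$n_seeds < 1) {
    stop("configuration key 'n_seeds' must be positive", call. = FALSE)
  }
  cfg$n_acq <- as.integer(cfg$n_acq)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_seeds <- as.integer(cfg$n_seeds)
  structure(cfg, class = "run_config")
}

#' Write a configuration back to YAML
#'
#' `write_config(load_config(f))` round-trips: re-loading the written file
#' gives an identical configuration.
#'
#' @param config a configuration list (normalized if necessary).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "run_config")) config <- normalize_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(cfg) {
  do.call(model_params, unclass(cfg)[names(formals(model_params))])
}

config_condition <- function(cfg) {
  drug_condition(cfg$drug_direction, cfg$drug_dose)
}

write_csv_plain <- function(df, path) {
  write.csv(format(df, trim = TRUE, scientific = FALSE), path,
            row.names = FALSE, quote = FALSE)
  path
}

write_manifest <- function(cfg, out_dir, files, extra = list()) {
  manifest <- c(list(
    package = "tdarousal",
    package_version = as.character(utils::packageVersion("tdarousal")),
    config = unclass(cfg),
    seeds = sweep_seeds(cfg$seed, cfg$n_seeds),
    files = files
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a named simulator command
#'
#' Executes one of the packaged experiment commands and writes tidy CSV
#' outputs plus a JSON manifest (package version, full normalized
#' configuration and seed list) into `config$out_dir`, so every output is
#' reconstructible from its manifest alone.
#'
#' Commands:
#' \describe{
#'   \item{`simulate`}{single protocol (`probabilities[1]`, `n_acq[1]`,
#'     `seed`) — writes `trials.csv` with the per-trial records.}
#'   \item{`sweep`}{full grid `probabilities x etas x n_acq` — writes
#'     `sweep.csv`, `sweep_summary.csv` and labels in `summary.json`.}
#'   \item{`dose-response`}{`probabilities x doses` for the configured drug
#'     direction — writes `dose_response.csv` and a summary.}
#'   \item{`reproduce-fig3`}{arousal-free probability curve (30 acquisition
#'     trials) — `fig3b.csv`.}
#'   \item{`reproduce-fig4`}{arousal-gated curve at `eta = 0.97`
#'     — `fig4c.csv`.}
#'   \item{`reproduce-fig5`}{shape labels over `etas x {10, 30, 100}`
#'     — `fig5.csv`.}
#'   \item{`reproduce-fig6`}{dose-response of end-of-acquisition value and
#'     extinction rate for both directions — `fig6a.csv`, `fig6b.csv` and
#'     `fig6c.csv` (normalized to the 100-percent-probability level).}
#' }
#'
#' @param subcommand one of the command names above.
#' @param config a configuration list or `run_config`.
#' @return (invisibly) named list of written file paths.
#' @export
run_command <- function(subcommand = c("simulate", "sweep", "dose-response",
                                       "reproduce-fig3", "reproduce-fig4",
                                       "reproduce-fig5", "reproduce-fig6"),
                        config = default_config()) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "run_config")) config else normalize_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(cfg)
  cond <- config_condition(cfg)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  files <- list()

  if (subcommand == "simulate") {
    pr <- build_simulation_protocol(cfg$probabilities[1], cfg$n_acq[1],
                                    cfg$seed)
    run <- run_protocol(params, pr, cond)
    files$trials <- write_csv_plain(run$trials,
                                    file.path(cfg$out_dir, "trials.csv"))
    say("simulated %d trials (%s)", nrow(run$trials), pr$label)
  } else if (subcommand == "sweep") {
    sw <- sweep_extinction(params, cfg$probabilities, cfg$etas, cfg$n_acq,
                           cond, cfg$n_seeds, cfg$seed, cfg$tolerance,
                           cfg$max_censored)
    files$sweep <- write_csv_plain(sw$results,
                                   file.path(cfg$out_dir, "sweep.csv"))
    files$summary <- write_csv_plain(sw$summary,
                                     file.path(cfg$out_dir,
                                               "sweep_summary.csv"))
    files$labels <- file.path(cfg$out_dir, "summary.json")
    jsonlite::write_json(sw$labels, files$labels, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (subcommand == "dose-response") {
    dr <- dose_response(params, cfg$probabilities,
                        direction = if (cfg$drug_direction == "none")
                          "reduce" else cfg$drug_direction,
                        doses = cfg$doses, n_acq = cfg$n_acq[1],
                        n_seeds = cfg$n_seeds, seed = cfg$seed,
                        tolerance = cfg$tolerance,
                        max_censored = cfg$max_censored)
    files$dose_response <- write_csv_plain(
      dr$results, file.path(cfg$out_dir, "dose_response.csv"))
    files$summary <- write_csv_plain(
      dr$summary, file.path(cfg$out_dir, "dose_response_summary.csv"))
  } else if (subcommand == "reproduce-fig3") {
    par3 <- params
    par3$use_arousal <- FALSE
    sw <- sweep_extinction(par3, cfg$probabilities, etas = params$eta,
                           n_acq = 30L, drug_condition(), cfg$n_seeds,
                           cfg$seed, cfg$tolerance, cfg$max_censored)
    out <- sw$summary[, c("probability", "mean_tte", "sd_tte",
                          "frac_censored")]
    files$fig3b <- write_csv_plain(out, file.path(cfg$out_dir, "fig3b.csv"))
    say("arousal-free curve label: %s", sw$labels$label[1])
  } else if (subcommand == "reproduce-fig4") {
    par4 <- params
    par4$eta <- 0.97
    sw <- sweep_extinction(par4, cfg$probabilities, etas = 0.97,
                           n_acq = 30L, drug_condition(), cfg$n_seeds,
                           cfg$seed, cfg$tolerance, cfg$max_censored)
    out <- sw$summary[, c("probability", "mean_tte", "sd_tte",
                          "frac_censored")]
    out$label <- sw$labels$label[1]
    files$fig4c <- write_csv_plain(out, file.path(cfg$out_dir, "fig4c.csv"))
    say("arousal-gated curve label: %s", sw$labels$label[1])
  } else if (subcommand == "reproduce-fig5") {
    sw <- sweep_extinction(params, cfg$probabilities, cfg$etas,
                           n_acq = c(10L, 30L, 100L), drug_condition(),
                           cfg$n_seeds, cfg$seed, cfg$tolerance,
                           cfg$max_censored)
    out <- merge(sw$summary, sw$labels, by = c("eta", "n_acq"))
    out <- out[order(out$n_acq, out$eta, out$probability), ]
    files$fig5 <- write_csv_plain(out, file.path(cfg$out_dir, "fig5.csv"))
  } else if (subcommand == "reproduce-fig6") {
    both <- lapply(c("enhance", "reduce"), function(dir) {
      dr <- dose_response(params, cfg$probabilities, dir, cfg$doses,
                          n_acq = 30L, n_seeds = cfg$n_seeds,
                          seed = cfg$seed, tolerance = cfg$tolerance,
                          max_censored = cfg$max_censored)
      dr$summary
    })
    summary <- do.call(rbind, both)
    fig6a <- summary[, c("direction", "dose", "probability",
                         "mean_end_value")]
    fig6b <- summary[, c("direction", "dose", "probability", "mean_tte",
                         "frac_censored")]
    fig6c <- do.call(rbind, lapply(split(
      summary, summary[, c("direction", "dose")], drop = TRUE),
      function(s) {
        s <- s[order(s$probability), ]
        s$normalized_tte <- normalize_to_reference(
          s$mean_tte, reference = 1.0, probabilities = s$probability)
        s[, c("direction", "dose", "probability", "normalized_tte")]
      }))
    files$fig6a <- write_csv_plain(fig6a, file.path(cfg$out_dir, "fig6a.csv"))
    files$fig6b <- write_csv_plain(fig6b, file.path(cfg$out_dir, "fig6b.csv"))
    files$fig6c <- write_csv_plain(fig6c, file.path(cfg$out_dir, "fig6c.csv"))
  }

  files$manifest <- write_manifest(cfg, cfg$out_dir,
                                   files = lapply(files, basename),
                                   extra = list(command = subcommand))
  invisible(files)
}
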
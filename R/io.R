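#' Write / read a trial log
#'
#' Trial logs are plain CSV with a header; the column set is whatever the
#' task logged (see [run_session()]). Rate matrices are not inlined — keep
#' them in a snapshot ([save_snapshot()]).
#'
#' @param log A session log tibble.
#' @param path File path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns the tibble.
#' @export
write_trial_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' @rdname write_trial_log
#' @param required_columns Columns that must be present (defaults to the
#'   shared core of all task logs).
#' @export
read_trial_log <- function(path, required_columns = c("trial", "choice",
                                                      "reward")) {
  log <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_columns, names(log))
  if (length(missing))
    stop("trial log ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  log
}

#' Load / save a session configuration
#'
#' Configurations are stored as JSON or YAML (by file extension). Unknown
#' keys are rejected; omitted keys fall back to the per-task published
#' defaults.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A [session_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$task)) stop("config must name a `task`", call. = FALSE)
  task <- raw$task
  task_fields <- switch(task,
    reversal = names(formals(reversal_config)),
    twostage = names(formals(twostage_config)),
    econ = names(formals(econ_config)),
    stop("unknown task in config: ", task, call. = FALSE))
  session_fields <- setdiff(names(formals(session_config)),
                            c("task", "reservoir_params", "decision_params"))
  res_fields <- names(formals(reservoir_params))
  dec_fields <- names(formals(decision_params))
  known <- c("task", task_fields, session_fields,
             "reservoir", "decision")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  check_sub <- function(sub, fields, what) {
    bad <- setdiff(names(sub), fields)
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    sub
  }
  res_over <- check_sub(raw$reservoir %||% list(), res_fields, "reservoir")
  dec_over <- check_sub(raw$decision %||% list(), dec_fields, "decision")
  pars <- do.call(task_parameters, c(list(task = task), res_over, dec_over))
  tk_args <- raw[intersect(names(raw), task_fields)]
  tk <- do.call(switch(task, reversal = reversal_config,
                       twostage = twostage_config, econ = econ_config),
                tk_args)
  sess_args <- raw[intersect(names(raw), session_fields)]
  do.call(session_config,
          c(list(task = tk, reservoir_params = pars$reservoir,
                 decision_params = pars$decision), sess_args))
}

#' @rdname load_config
#' @param cfg A [session_config()].
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "session_config"))
  tk <- cfg$task_config
  drop_fields <- c("task", "trial_duration", "input_labels", "n_inputs")
  raw <- c(list(task = cfg$task),
           tk[setdiff(names(tk), drop_fields)],
           list(n_trials = cfg$n_trials,
                reservoir = unclass(cfg$reservoir),
                decision = unclass(cfg$decision)))
  if (!is.null(cfg$inactivate)) raw$inactivate <- cfg$inactivate
  if (!is.null(cfg$freeze_after)) raw$freeze_after <- cfg$freeze_after
  raw$record_weights <- cfg$record_weights
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(raw, path)
  else jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Save / load a weight-and-state snapshot
#'
#' Stores the reservoir weights, the readout, the parameters and the seed in
#' one binary container for exact resumption of a run.
#'
#' @param session A `session_result` (or a list with `reservoir`,
#'   `readout`, `config`, `seed`).
#' @param path File path (`.rds`).
#' @return `save_snapshot` returns `path` invisibly; `load_snapshot` the
#'   restored list.
#' @export
save_snapshot <- function(session, path) {
  saveRDS(list(reservoir = session$reservoir, readout = session$readout,
               config = session$config, seed = session$seed,
               n_trials_run = if (!is.null(session$log)) nrow(session$log)
                              else NA_integer_),
          path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) readRDS(path)
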
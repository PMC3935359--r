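#' Configuration of a synthetic multi-condition experiment
#'
#' Describes a two-alternative forced-choice study: one or more named
#' conditions, each with its own parameter set ([bayes_params()] or
#' [ddm_params()]) and trial count, a shared response deadline and a seed.
#' The default stimulus schedule is balanced (equal trial counts per
#' alternative, order randomized by the seed); an explicit per-trial schedule
#' can be supplied per condition.
#'
#' @param conditions named list; each element is a list with `params` (a
#'   [bayes_params()] or [ddm_params()] object) and `n_trials`, optionally
#'   `schedule` (integer vector of presented alternatives, length
#'   `n_trials`).
#' @param deadline response deadline in seconds (default 1.25).
#' @param seed integer seed making the generated experiment fully
#'   reproducible.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(conditions, deadline = 1.25, seed = 1L) {
  if (length(conditions) == 0L || is.null(names(conditions)) ||
      any(!nzchar(names(conditions))))
    stop("'conditions' must be a non-empty named list")
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    if (!inherits(cond$params, c("bayes_params", "ddm_params")))
      stop("condition '", nm, "' needs a bayes_params or ddm_params object")
    if (is.null(cond$n_trials) || cond$n_trials < 1L)
      stop("condition '", nm, "' needs n_trials > 0")
    if (!is.null(cond$schedule) &&
        length(cond$schedule) != cond$n_trials)
      stop("condition '", nm, "': schedule length must equal n_trials")
  }
  if (deadline <= 0) stop("'deadline' must be > 0")
  structure(list(conditions = conditions, deadline = deadline,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Generate a synthetic experiment trial table
#'
#' Simulates every condition of an [experiment_config()] with its own
#' parameters — Bayesian-observer conditions through the observer's
#' log-odds accumulation ([simulate_bayes_experiment()]), pDDM conditions
#' through [simulate_ddm_experiment()] — and assembles a tidy trial table.
#' The full table is reproducible from the config seed.
#'
#' @param config an [experiment_config()] object.
#' @return Data frame (class `trial_table`) with columns `trial`,
#'   `condition`, `true_alternative`, `choice`, `correct`, `rt`, `outlier`.
#' @examples
#' bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 18.1,
#'                    sigma_hat = 28.6, lambda = 0.7, dt = 0.0283,
#'                    t_nd = 0.42)
#' cfg <- experiment_config(list(example = list(params = bp, n_trials = 20)),
#'                          seed = 7)
#' head(generate_experiment(cfg))
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  parts <- lapply(names(config$conditions), function(nm) {
    cond <- config$conditions[[nm]]
    n <- cond$n_trials
    schedule <- cond$schedule
    if (is.null(schedule)) schedule <- sample(rep_len(c(1L, 2L), n))
    sim <- if (inherits(cond$params, "bayes_params")) {
      simulate_bayes_experiment(cond$params, n, true_alternatives = schedule,
                                deadline = config$deadline)
    } else {
      simulate_ddm_experiment(cond$params, n, true_alternatives = schedule,
                              deadline = config$deadline)
    }
    data.frame(trial = seq_len(n),
               condition = nm,
               true_alternative = sim$true_alternative,
               choice = sim$choice,
               correct = sim$correct,
               rt = sim$rt,
               outlier = sim$outlier)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

.trial_columns <- c("trial", "condition", "true_alternative", "choice",
                    "correct", "rt", "outlier")

#' Read and write trial tables
#'
#' Trial tables are stored as plain CSV with a header, `.`-decimal numbers
#' and reaction times in seconds. Reading is strict: missing columns are an
#' error, and malformed numeric fields (including decimal-comma input) are
#' rejected with the offending line numbers rather than silently misparsed.
#' Undecided trials carry empty `choice`, `correct` and `rt` fields.
#'
#' @param path file path.
#' @param trials a trial table as produced by [generate_experiment()].
#' @param conditions optional character vector of allowed condition labels;
#'   unknown labels are an error when supplied.
#' @return `read_trials()`: the trial table (`write_trials()` is called for
#'   its side effect and returns `path` invisibly).
#' @export
read_trials <- function(path, conditions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(.trial_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  parse_num <- function(col, name, allow_na = FALSE) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(out) & !is.na(col))
    if (!allow_na) bad <- union(bad, which(is.na(col)))
    if (length(bad) > 0L)
      stop("malformed '", name, "' value on data line(s) ",
           paste(utils::head(sort(bad), 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    out
  }
  parse_lgl <- function(col, name, allow_na = FALSE) {
    out <- rep(NA, length(col))
    out[col %in% c("TRUE", "true", "1")] <- TRUE
    out[col %in% c("FALSE", "false", "0")] <- FALSE
    bad <- which(is.na(out) & !is.na(col))
    if (!allow_na) bad <- union(bad, which(is.na(col)))
    if (length(bad) > 0L)
      stop("malformed '", name, "' value on data line(s) ",
           paste(utils::head(sort(bad), 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    out
  }
  out <- data.frame(
    trial = as.integer(parse_num(raw$trial, "trial")),
    condition = raw$condition,
    true_alternative = as.integer(parse_num(raw$true_alternative,
                                            "true_alternative")),
    choice = as.integer(parse_num(raw$choice, "choice", allow_na = TRUE)),
    correct = parse_lgl(raw$correct, "correct", allow_na = TRUE),
    rt = parse_num(raw$rt, "rt", allow_na = TRUE),
    outlier = parse_lgl(raw$outlier, "outlier"))
  if (!is.null(conditions)) {
    unknown <- setdiff(unique(out$condition), conditions)
    if (length(unknown) > 0L)
      stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  }
  decided <- !is.na(out$choice)
  bad_rt <- which(decided & (is.na(out$rt) | out$rt <= 0))
  if (length(bad_rt) > 0L)
    stop("missing or non-positive 'rt' for decided trial(s) on data line(s) ",
         paste(utils::head(bad_rt, 5L), collapse = ", "), " of ", path)
  if (any(decided & (out$correct != (out$choice == out$true_alternative))))
    stop("'correct' flag inconsistent with choice vs. true alternative")
  class(out) <- c("trial_table", "data.frame")
  out
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(trials[, .trial_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
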
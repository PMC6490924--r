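trial_columns <- c("test1Color", "test1Material", "test2Color",
                   "test2Material", "choice", "block", "subBlock", "source")

trial_sources <- c("questFull", "questRestricted2", "questRestricted1",
                   "random", "fixed")

#' Read and write trial tables
#'
#' Trial tables are delimited text, one trial per row, with a header and
#' columns `test1Color`, `test1Material`, `test2Color`, `test2Material`
#' (integer levels in -3..3), `choice` (1 or 2), `block`, `subBlock`,
#' and `source` (one of `questFull`, `questRestricted2`,
#' `questRestricted1`, `random`, `fixed`). `write_trials()` followed by
#' `read_trials()` is the identity on valid tables.
#'
#' @param path file path
#' @return `read_trials()`: a validated trial data frame
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("trial file '%s' does not exist", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(df))
  if (length(missing))
    stopf("trial table is missing column(s): %s", paste(missing, collapse = ", "))
  validate_trials(df, line_offset = 1L)
  df[trial_columns]
}

validate_trials <- function(df, line_offset = 0L) {
  bad_line <- function(rows, msg) {
    if (length(rows))
      stopf("invalid trial table: %s (line %d)", msg, rows[1] + line_offset)
  }
  for (col in c("test1Color", "test1Material", "test2Color", "test2Material")) {
    x <- df[[col]]
    bad_line(which(!is.finite(x) | x != round(x) | abs(x) > 3),
             sprintf("%s must be an integer in [-3, 3]", col))
  }
  bad_line(which(!df$choice %in% c(1L, 2L)), "choice must be 1 or 2")
  bad_line(which(!df$source %in% trial_sources),
           sprintf("source must be one of %s", paste(trial_sources, collapse = ", ")))
  invisible(TRUE)
}

#' @rdname read_trials
#' @param trials a trial data frame
#' @return `write_trials()`: invisibly, the path
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stopf("trial table is missing column(s): %s", paste(missing, collapse = ", "))
  validate_trials(trials)
  write.csv(trials[trial_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write model solutions as JSON
#'
#' Solutions round-trip losslessly: the JSON stores the spec, the weight,
#' the mapping coefficients and implied per-level positions for both
#' dimensions, the log-likelihood, and any attached cross-validation or
#' bootstrap summaries.
#'
#' @param solution a `cm_solution`
#' @param path file path
#' @param extra optional named list merged into the JSON (e.g. seeds,
#'   CV summaries)
#' @return invisibly, the path
#' @export
write_solution <- function(solution, path, extra = list()) {
  stopifnot(inherits(solution, "cm_solution"))
  obj <- list(
    spec = list(variant = solution$spec$variant, metric = solution$spec$metric),
    w = solution$w,
    mapping = list(color = solution$mapping$color,
                   material = solution$mapping$material),
    positions = list(levels = -3:3,
                     color = unname(solution$positions[, 1]),
                     material = unname(solution$positions[, 2])),
    log_likelihood = solution$log_likelihood,
    non_identifiable = isTRUE(solution$non_identifiable),
    version = as.character(packageVersion("cmtradeoff")))
  obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solution
#' @return `read_solution()`: the reconstructed `cm_solution`
#' @export
read_solution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mapping <- positional_mapping(obj$spec$variant, obj$mapping$color,
                                obj$mapping$material)
  sol <- model_solution(model_spec(obj$spec$variant, obj$spec$metric),
                        obj$w, mapping,
                        log_likelihood = obj$log_likelihood %||% NA_real_)
  sol$non_identifiable <- isTRUE(obj$non_identifiable)
  sol
}
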
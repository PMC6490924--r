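#' Choice-probability lookup tables
#'
#' The probability that the first of two tests is chosen has no closed
#' form under the noisy-observer model, so it is pre-computed by forward
#' Monte-Carlo simulation on a 5-D grid over (w, p1C, p1M, p2C, p2M) and
#' interpolated at fit time. The standard grid linearly samples 10 weight
#' values in `[0, 1]` and 20 position values in `[-20, 20]` (used for all
#' four position axes), with 3000 simulated trials per grid cell. A
#' reduced `"test"` preset (position step 4, 1000 trials per cell) builds
#' in seconds and is intended for fast pipelines where full numerical
#' accuracy is not needed.
#'
#' Each grid cell draws from its own RNG stream derived from
#' `(seed, cell index)`, and both presentation orders are scored from the
#' same noise draws, so the complement law
#' `P(p1, p2) + P(p2, p1) = 1` holds exactly in the stored table.
#'
#' @param metric `"euclidean"` or `"cityblock"`
#' @param preset `"full"` (10 x 20^4 grid, 3000 trials/cell) or `"test"`
#'   (10 x 11^4 grid, 1000 trials/cell); ignored if explicit grids are given
#' @param weight_grid,position_grid optional explicit sorted grids
#' @param mc_trials Monte-Carlo trials per grid cell
#' @param seed integer seed for the cell RNG streams
#' @return an object of class `cm_lookup_table`
#' @export
build_lookup_table <- function(metric = c("euclidean", "cityblock"),
                               preset = c("full", "test"),
                               weight_grid = NULL, position_grid = NULL,
                               mc_trials = NULL, seed = 1) {
  metric <- match.arg(metric)
  preset <- match.arg(preset)
  if (is.null(weight_grid)) weight_grid <- seq(0, 1, length.out = 10)
  if (is.null(position_grid))
    position_grid <- if (preset == "full") seq(-20, 20, length.out = 20)
                     else seq(-20, 20, by = 4)
  if (is.null(mc_trials)) mc_trials <- if (preset == "full") 3000L else 1000L
  stopifnot(mc_trials >= 1, !is.unsorted(weight_grid, strictly = TRUE),
            !is.unsorted(position_grid, strictly = TRUE))
  check_uniform(weight_grid, "weight_grid")
  check_uniform(position_grid, "position_grid")

  nw <- length(weight_grid)
  np <- length(position_grid)
  prob <- build_table_cpp(metric_code(metric), weight_grid, position_grid,
                          as.integer(mc_trials), as.double(seed))
  dim(prob) <- c(nw, np, np, np, np)
  tab <- structure(list(metric = metric, weight_grid = weight_grid,
                        position_grid = position_grid, prob = prob,
                        mc_trials = as.integer(mc_trials),
                        seed = as.integer(seed), hash = hash_doubles_cpp(prob)),
                   class = "cm_lookup_table")
  tab
}

check_uniform <- function(g, name) {
  if (length(g) < 2) stopf("%s needs at least 2 values", name)
  d <- diff(g)
  if (max(abs(d - d[1])) > 1e-8 * max(abs(g)))
    stopf("%s must be linearly spaced", name)
  invisible(TRUE)
}

#' Direct Monte-Carlo choice probability
#'
#' Simulates `n_trials` independent trials: the target (at the origin) and
#' both tests each receive independent unit Gaussian noise on both
#' dimensions, and the observer chooses the test whose draw lies closer
#' under the weighted metric. Returns the fraction of trials on which the
#' first test was chosen.
#'
#' @param p1,p2 numeric length-2 mean perceptual positions (color,
#'   material) of the two tests
#' @inheritParams build_lookup_table
#' @param w color-material weight in `[0, 1]`
#' @param n_trials number of simulated trials
#' @return estimated probability of choosing the first test
#' @export
simulate_choice_probability <- function(p1, p2, w,
                                        metric = c("euclidean", "cityblock"),
                                        n_trials = 3000, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(length(p1) == 2, length(p2) == 2, n_trials >= 1)
  if (w < 0 || w > 1) stopf("w must lie in [0, 1]")
  mc_choice_prob_cpp(w, p1[1], p1[2], p2[1], p2[2], metric_code(metric),
                     as.integer(n_trials), as.double(seed))
}

#' Interpolate choice probabilities from a lookup table
#'
#' Separable local cubic interpolation of the gridded table; exact at grid
#' nodes. Queries must lie inside the grid bounding box. When
#' `clip = TRUE` the result is clipped to `[eps, 1 - eps]`, as used before
#' conversion to log-likelihood (cubic interpolation can overshoot
#' slightly, and unclipped zeros would destroy a fit).
#'
#' @param table a [build_lookup_table()] result
#' @param w weight value(s) in `[0, 1]`
#' @param p1,p2 test positions: length-2 vectors, or n x 2 matrices for
#'   vectorized queries
#' @param clip clip the result away from 0 and 1
#' @param eps clipping bound
#' @return interpolated probability vector
#' @export
interpolate_choice_probability <- function(table, w, p1, p2, clip = FALSE,
                                           eps = 1e-4) {
  stopifnot(inherits(table, "cm_lookup_table"))
  p1 <- matrix(as.numeric(p1), ncol = 2)
  p2 <- matrix(as.numeric(p2), ncol = 2)
  n <- max(length(w), nrow(p1), nrow(p2))
  q <- cbind(rep_len(as.numeric(w), n),
             rep_len(p1[, 1], n), rep_len(p1[, 2], n),
             rep_len(p2[, 1], n), rep_len(p2[, 2], n))
  if (any(q[, 1] < 0 | q[, 1] > 1)) stopf("w must lie in [0, 1]")
  p <- interp_queries(table, q)
  if (clip) clip_prob(p, eps) else p
}

# low-level vectorized interpolation on a query matrix (w, p1C, p1M, p2C, p2M)
interp_queries <- function(table, queries) {
  interp5_cpp(table$prob, length(table$weight_grid),
              length(table$position_grid), table$weight_grid,
              table$position_grid, queries)
}

#' Cache a lookup table on disk
#'
#' Stores the probability array in a binary container next to a JSON
#' sidecar holding the grids, metric, seed, trial count and content hash;
#' `read_table_cache()` verifies the hash on load.
#'
#' @param table a `cm_lookup_table`
#' @param path base path (without extension); writes `path.rds` and
#'   `path.json`
#' @return invisibly, the base path
#' @export
write_table_cache <- function(table, path) {
  stopifnot(inherits(table, "cm_lookup_table"))
  saveRDS(table$prob, paste0(path, ".rds"))
  meta <- list(metric = table$metric, weight_grid = table$weight_grid,
               position_grid = table$position_grid,
               mc_trials = table$mc_trials, seed = table$seed,
               hash = table$hash,
               version = as.character(packageVersion("cmtradeoff")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_table_cache
#' @export
read_table_cache <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  prob <- readRDS(paste0(path, ".rds"))
  h <- hash_doubles_cpp(prob)
  if (!identical(h, meta$hash))
    stopf("lookup table cache at '%s' is corrupt (hash mismatch)", path)
  structure(list(metric = meta$metric, weight_grid = meta$weight_grid,
                 position_grid = meta$position_grid, prob = prob,
                 mc_trials = as.integer(meta$mc_trials),
                 seed = as.integer(meta$seed), hash = h),
            class = "cm_lookup_table")
}

#' @export
print.cm_lookup_table <- function(x, ...) {
  cat("Choice-probability lookup table (", x$metric, ")\n", sep = "")
  cat("  grid: ", length(x$weight_grid), " weights x ",
      length(x$position_grid), "^4 positions, ", x$mc_trials,
      " MC trials/cell, seed ", x$seed, "\n", sep = "")
  cat("  hash:", x$hash, "\n")
  invisible(x)
}
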
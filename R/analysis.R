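#' Bootstrap confidence intervals for the color-material weight
#'
#' Resamples trials with replacement (N of N, ignoring block structure),
#' refits the given model spec on each resample, and summarizes the
#' bootstrapped weights by their central 68% interval (the analogue of
#' 1 SEM for a Gaussian). Each refit starts from the default start grid
#' plus the full-data solution's parameters and keeps the
#' highest-likelihood solution.
#'
#' @param trials trial data frame
#' @param solution full-data fitted `cm_solution` (the spec to refit)
#' @param config a [fit_config()]
#' @param table lookup table matching the solution's metric
#' @param n_iterations bootstrap iterations
#' @param seed integer seed
#' @return an object of class `cm_bootstrap` with per-iteration weights
#'   and slope ratios, the weight CI, and the bootstrap mean
#' @export
bootstrap_weights <- function(trials, solution, config = fit_config(), table,
                              n_iterations = 100, seed = 1) {
  stopifnot(inherits(solution, "cm_solution"), n_iterations >= 1)
  cfg <- config
  cfg$extra_starts <- c(cfg$extra_starts,
                        list(list(w = solution$w, mapping = solution$mapping)))
  n <- nrow(trials)
  ws <- numeric(0)
  ratios <- numeric(0)
  flags <- logical(0)
  failures <- character(0)
  for (i in seq_len(n_iterations)) {
    idx <- with_seed(derive_seed(seed, paste0("boot-", i)),
                     sample.int(n, n, replace = TRUE))
    fit <- tryCatch(
      fit_model(trials[idx, , drop = FALSE], solution$spec, cfg, table,
                n_starts = config$boot_n_starts),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
    } else {
      ws <- c(ws, fit$w)
      ratios <- c(ratios, if (isTRUE(fit$non_identifiable)) NA_real_
                  else slope_ratio(fit))
      flags <- c(flags, isTRUE(fit$non_identifiable))
    }
  }
  if (length(ws) == 0) stopf("all %d bootstrap iterations failed", n_iterations)
  structure(list(weights = ws, slope_ratios = ratios,
                 non_identifiable = flags,
                 ci = quantile(ws, c(0.16, 0.84), names = FALSE),
                 mean_weight = mean(ws),
                 n_iterations = n_iterations, n_failed = length(failures),
                 failures = failures, seed = seed),
            class = "cm_bootstrap")
}

#' Color-material trade-off functions
#'
#' Model-predicted probability that a color match (a test sharing the
#' target's color, differing in material by level M) is chosen over a
#' material match (sharing the target's material, differing in color by
#' level C), for every combination of the 7 design levels. The
#' probability at (M = 0, C = 0) is exactly one half, and each curve
#' rises towards 1 as the material match's color offset grows.
#'
#' @param solution a `cm_solution`
#' @param table lookup table matching the solution's metric
#' @return a data frame of class `cm_tradeoff` with columns
#'   `material_level` (of the color match), `color_level` (of the
#'   material match) and `p_color_match`
#' @export
tradeoff_functions <- function(solution, table) {
  stopifnot(inherits(solution, "cm_solution"))
  if (solution$spec$metric != table$metric)
    stopf("table metric '%s' does not match solution metric '%s'",
          table$metric, solution$spec$metric)
  lev <- -3:3
  grid <- expand.grid(color_level = lev, material_level = lev)
  posC <- solution$positions[, 1]
  posM <- solution$positions[, 2]
  p1 <- cbind(0, posM[grid$material_level + 4L])          # color match
  p2 <- cbind(posC[grid$color_level + 4L], 0)             # material match
  p <- interpolate_choice_probability(table, solution$w, p1, p2)
  out <- data.frame(material_level = grid$material_level,
                    color_level = grid$color_level, p_color_match = p)
  class(out) <- c("cm_tradeoff", "data.frame")
  out
}

#' Color-material slope ratio
#'
#' Least-squares slope of perceptual position against nominal level
#' (-3..+3) for each dimension; returns the color slope divided by the
#' material slope. Large values mean material positions are compressed
#' relative to color positions; across near-equivalent solutions the
#' ratio trades off inversely with the color-material weight.
#'
#' @param solution a `cm_solution`
#' @return positive scalar ratio
#' @export
slope_ratio <- function(solution) {
  lev <- -3:3
  slope <- function(pos) sum(lev * pos) / sum(lev^2)
  sc <- slope(solution$positions[, 1])
  sm <- slope(solution$positions[, 2])
  if (sm <= 0) stopf("material slope is not positive (%.4f)", sm)
  sc / sm
}

#' Parameter-recovery study
#'
#' Full pipeline per generating observer: simulate a complete session,
#' run cross-validated model selection over all 8 variants, fit the
#' selected model, and (optionally) bootstrap the recovered weight.
#'
#' @param observers list of [generating_observer()]s
#' @param design a [session_design()]
#' @param grid a [quest_grid()]
#' @param tables named list of lookup tables (`euclidean`, `cityblock`)
#' @param config a [fit_config()]
#' @param seed integer seed; observer i uses a child seed
#' @param bootstrap also bootstrap each recovered weight
#' @param n_boot bootstrap iterations when `bootstrap = TRUE`
#' @param lik optional precomputed [quest_likelihood_matrix()]
#' @return an object of class `cm_recovery`: a summary data frame plus
#'   per-observer selection/fit objects
#' @export
recovery_study <- function(observers, design = session_design(), grid,
                           tables, config = fit_config(), seed = 1,
                           bootstrap = FALSE, n_boot = 100, lik = NULL) {
  stopifnot(length(observers) >= 1)
  if (is.null(lik)) lik <- quest_likelihood_matrix(grid, tables$euclidean)
  runs <- vector("list", length(observers))
  for (i in seq_along(observers)) {
    obs <- observers[[i]]
    s <- derive_seed(seed, paste0("recovery-", i))
    trials <- simulate_session(obs, design, grid, tables$euclidean,
                               lik = lik, seed = s)
    sel <- select_model(trials, config, tables, seed = s)
    boot <- if (bootstrap)
      bootstrap_weights(trials, sel$best_fit, config, tables[[sel$best_spec$metric]],
                        n_iterations = n_boot, seed = s)
    runs[[i]] <- list(observer = obs, trials = trials, selection = sel,
                      fit = sel$best_fit, bootstrap = boot)
  }
  summary <- data.frame(
    observer = seq_along(observers),
    w_generating = vapply(observers, function(o) o$w, numeric(1)),
    w_recovered = vapply(runs, function(r) r$fit$w, numeric(1)),
    variant = vapply(runs, function(r) r$selection$best_spec$variant, character(1)),
    metric = vapply(runs, function(r) r$selection$best_spec$metric, character(1)))
  summary$w_error <- summary$w_recovered - summary$w_generating
  if (bootstrap) {
    summary$ci_lo <- vapply(runs, function(r) r$bootstrap$ci[1], numeric(1))
    summary$ci_hi <- vapply(runs, function(r) r$bootstrap$ci[2], numeric(1))
  }
  structure(list(summary = summary, runs = runs, seed = seed),
            class = "cm_recovery")
}

#' @export
print.cm_bootstrap <- function(x, ...) {
  cat("Bootstrap of the color-material weight (", x$n_iterations,
      " iterations, ", x$n_failed, " failed)\n", sep = "")
  cat("  mean w:", format(x$mean_weight, digits = 3),
      "  68% CI: [", format(x$ci[1], digits = 3), ",",
      format(x$ci[2], digits = 3), "]\n")
  invisible(x)
}

#' @export
print.cm_recovery <- function(x, ...) {
  cat("Parameter-recovery study (", nrow(x$summary), " observers)\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
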
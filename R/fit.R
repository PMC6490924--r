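#' Fit configuration
#'
#' Controls the multi-start maximum-likelihood search. The default start
#' set is a coarse Latin-style grid over weights 0.1..0.9 and linear
#' slopes in `[0.5, 6]` (the range the adaptive procedure spans); the
#' likelihood surface has a documented weight/position trade-off ridge,
#' so single starts can stall. `n_starts` applies to full-data fits;
#' `cv_n_starts` and `boot_n_starts` control the cheaper refits inside
#' cross-validation folds and bootstrap iterations (both also warm-start
#' from the relevant full-data solution).
#'
#' @param n_starts number of default starts for a full-data fit
#' @param cv_n_starts default starts per cross-validation fold fit
#' @param boot_n_starts default starts per bootstrap refit
#' @param max_iterations optimizer iteration cap (`NULL`: 600 per free
#'   parameter)
#' @param tolerance convergence tolerance on the objective
#' @param seed integer seed controlling start generation
#' @param extra_starts list of warm starts, each a list with elements `w`
#'   and `mapping` (e.g. a previous `cm_solution`)
#' @return an object of class `cm_fit_config`
#' @export
fit_config <- function(n_starts = 10, cv_n_starts = 3, boot_n_starts = 3,
                       max_iterations = NULL, tolerance = 1e-6, seed = 1,
                       extra_starts = list()) {
  stopifnot(n_starts + length(extra_starts) >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 cv_n_starts = as.integer(cv_n_starts),
                 boot_n_starts = as.integer(boot_n_starts),
                 max_iterations = max_iterations,
                 tolerance = tolerance, seed = as.integer(seed),
                 extra_starts = extra_starts),
            class = "cm_fit_config")
}

#' Construct a model solution
#'
#' Bundles a model spec, color-material weight and positional mapping.
#' Used both for fitted solutions and for specifying generating observers.
#'
#' @param spec a [model_spec()]
#' @param w color-material weight in `[0, 1]`
#' @param mapping a [positional_mapping()] satisfying the constraints
#' @param log_likelihood fit log-likelihood, if known
#' @return an object of class `cm_solution`
#' @export
model_solution <- function(spec, w, mapping, log_likelihood = NA_real_) {
  stopifnot(inherits(spec, "cm_spec"), inherits(mapping, "cm_mapping"))
  if (!is.finite(w) || w < 0 || w > 1) stopf("w must lie in [0, 1]")
  if (mapping$variant != spec$variant)
    stopf("mapping variant '%s' does not match spec variant '%s'",
          mapping$variant, spec$variant)
  validate_mapping(mapping)
  structure(list(spec = spec, w = w, mapping = mapping,
                 positions = cbind(color = positions7(mapping$color, mapping$variant),
                                   material = positions7(mapping$material, mapping$variant)),
                 log_likelihood = log_likelihood,
                 non_identifiable = FALSE),
            class = "cm_solution")
}

# collapse a trial table to unique ordered test pairs with choice counts
aggregate_pairs <- function(trials) {
  if (nrow(trials) == 0)
    return(data.frame(c1 = integer(), m1 = integer(), c2 = integer(),
                      m2 = integer(), n1 = integer(), n2 = integer()))
  key <- ((trials$test1Color + 3L) * 7L + trials$test1Material + 3L) * 49L +
    (trials$test2Color + 3L) * 7L + (trials$test2Material + 3L)
  n1 <- tapply(trials$choice == 1L, key, sum)
  n2 <- tapply(trials$choice == 2L, key, sum)
  k <- as.integer(names(n1))
  data.frame(c1 = k %/% 343L - 3L, m1 = (k %/% 49L) %% 7L - 3L,
             c2 = (k %/% 7L) %% 7L - 3L, m2 = k %% 7L - 3L,
             n1 = as.integer(n1), n2 = as.integer(n2))
}

# NLL from explicit positions; agg is an aggregate_pairs() result
nll_positions <- function(w, posC, posM, agg, table, eps = 1e-4) {
  if (nrow(agg) == 0) return(0)
  q <- cbind(w, posC[agg$c1 + 4L], posM[agg$m1 + 4L],
             posC[agg$c2 + 4L], posM[agg$m2 + 4L])
  p <- clip_prob(interp_queries(table, q), eps)
  -sum(agg$n1 * log(p) + agg$n2 * log1p(-p))
}

#' Negative log-likelihood of a solution on a trial table
#'
#' Sums `-log P(observed choice)` over trials, with choice probabilities
#' interpolated from the lookup table at the solution's mapped positions
#' and clipped to `[1e-4, 1 - 1e-4]`. Errors (rather than returning a
#' penalty) if the solution violates the positional constraints or if the
#' table metric does not match the spec.
#'
#' @param solution a [model_solution()] or fit result
#' @param trials a trial data frame (see [read_trials()] for the columns)
#' @param table a lookup table built with the solution's metric
#' @return the negative log-likelihood (>= 0)
#' @export
negative_log_likelihood <- function(solution, trials, table) {
  stopifnot(inherits(table, "cm_lookup_table"))
  if (solution$spec$metric != table$metric)
    stopf("table metric '%s' does not match spec metric '%s'",
          table$metric, solution$spec$metric)
  validate_mapping(solution$mapping)
  if (solution$w < 0 || solution$w > 1) stopf("w must lie in [0, 1]")
  agg <- aggregate_pairs(trials)
  nll_positions(solution$w, positions7(solution$mapping$color, solution$mapping$variant),
                positions7(solution$mapping$material, solution$mapping$variant),
                agg, table)
}

# ---- parameter transforms ----------------------------------------------
# w is fitted on the logit scale; polynomial leading coefficients on the
# log scale (positivity); the full variant fits log-spacings floored at
# the minimum spacing, turning monotonicity into box-free constraints.

theta_length <- function(variant) {
  switch(variant, linear = 3L, quadratic = 5L, cubic = 7L, full = 13L)
}

theta_to_model <- function(theta, variant) {
  w <- plogis(theta[1])
  if (variant == "full") {
    gc <- 0.25 + exp(theta[2:7])
    gm <- 0.25 + exp(theta[8:13])
    posC <- c(-(gc[3] + gc[2] + gc[1]), -(gc[3] + gc[2]), -gc[3], 0,
              gc[4], gc[4] + gc[5], gc[4] + gc[5] + gc[6])
    posM <- c(-(gm[3] + gm[2] + gm[1]), -(gm[3] + gm[2]), -gm[3], 0,
              gm[4], gm[4] + gm[5], gm[4] + gm[5] + gm[6])
    cp <- posC[-4]; mp <- posM[-4]
  } else {
    k <- mapping_arity(variant)
    cp <- theta[2:(1 + k)]
    mp <- theta[(2 + k):(1 + 2 * k)]
    cp[1] <- exp(cp[1]); mp[1] <- exp(mp[1])
    posC <- eval_mapping(cp, variant, -3:3)
    posM <- eval_mapping(mp, variant, -3:3)
  }
  list(w = w, color = cp, material = mp, posC = posC, posM = posM)
}

model_to_theta <- function(w, mapping) {
  w <- min(max(w, 1e-6), 1 - 1e-6)
  if (mapping$variant == "full") {
    posC <- positions7(mapping$color, "full")
    posM <- positions7(mapping$material, "full")
    gc <- pmax(diff(posC) - 0.25, 1e-6)
    gm <- pmax(diff(posM) - 0.25, 1e-6)
    c(qlogis(w), log(gc), log(gm))
  } else {
    cp <- mapping$color; mp <- mapping$material
    cp[1] <- log(max(cp[1], 1e-6)); mp[1] <- log(max(mp[1], 1e-6))
    c(qlogis(w), cp, mp)
  }
}

# default multi-start grid, deterministic given the seed
default_starts <- function(variant, n_starts, seed) {
  if (n_starts < 1) return(list())
  with_seed(derive_seed(seed, paste0("starts-", variant)), {
    wv <- seq(0.1, 0.9, length.out = max(n_starts, 2))[1:n_starts]
    sc <- sample(seq(0.5, 6, length.out = max(n_starts, 2))[1:n_starts])
    sm <- sample(seq(0.5, 6, length.out = max(n_starts, 2))[1:n_starts])
    lapply(seq_len(n_starts), function(i) {
      par <- switch(variant,
        linear = list(sc[i], sm[i]),
        quadratic = list(c(sc[i], 0), c(sm[i], 0)),
        cubic = list(c(sc[i], 0, 0), c(sm[i], 0, 0)),
        full = list(sc[i] * c(-3:-1, 1:3), sm[i] * c(-3:-1, 1:3)))
      list(w = wv[i],
           mapping = positional_mapping(variant, par[[1]], par[[2]]))
    })
  })
}

start_thetas <- function(variant, config, n_starts, extra_starts) {
  starts <- default_starts(variant, n_starts, config$seed)
  for (s in extra_starts) {
    if (inherits(s$mapping, "cm_mapping") && s$mapping$variant == variant)
      starts <- c(starts, list(list(w = s$w, mapping = s$mapping)))
  }
  lapply(starts, function(s) model_to_theta(s$w, s$mapping))
}

#' Maximum-likelihood model fit
#'
#' Multi-start numerical maximum-likelihood estimation of the
#' color-material weight and positional mapping for one model spec.
#' Infeasible parameter regions (non-monotone, under-spaced or
#' out-of-bounds positions) are excluded by a penalty during the search
#' and the returned solution always satisfies the constraints. If every
#' trial pairs a test with an identical copy of itself the likelihood is
#' flat; the fit then returns `w = 0.5` with minimum-spacing positions
#' and sets the `non_identifiable` flag rather than reporting an
#' arbitrary optimum.
#'
#' @param trials trial data frame
#' @param spec a [model_spec()]
#' @param config a [fit_config()]
#' @param table lookup table matching `spec$metric`
#' @param n_starts override for the number of default starts
#' @return a `cm_solution` with fitted parameters, `log_likelihood`
#'   (equal to minus the returned solution's
#'   [negative_log_likelihood()]), and per-start diagnostics
#' @export
fit_model <- function(trials, spec, config = fit_config(), table,
                      n_starts = NULL) {
  stopifnot(inherits(spec, "cm_spec"), inherits(config, "cm_fit_config"),
            nrow(trials) >= 1)
  if (spec$metric != table$metric)
    stopf("table metric '%s' does not match spec metric '%s'",
          table$metric, spec$metric)

  if (all(trials$test1Color == trials$test2Color &
          trials$test1Material == trials$test2Material)) {
    mapping <- positional_mapping(spec$variant,
                                  minimal_params(spec$variant),
                                  minimal_params(spec$variant))
    sol <- model_solution(spec, 0.5, mapping,
                          log_likelihood = -nrow(trials) * log(2))
    sol$non_identifiable <- TRUE
    sol$n_trials <- nrow(trials)
    return(sol)
  }

  agg <- aggregate_pairs(trials)
  variant <- spec$variant
  maxit <- config$max_iterations %||% (600L * theta_length(variant))
  reltol <- config$tolerance * 1e-3

  objective <- function(theta) {
    m <- theta_to_model(theta, variant)
    viol <- mapping_violation(m$posC, m$posM)
    if (viol > 0) return(1e5 + 1e4 * viol)
    nll_positions(m$w, m$posC, m$posM, agg, table)
  }

  thetas <- start_thetas(variant, config,
                         n_starts %||% config$n_starts, config$extra_starts)
  if (length(thetas) == 0) stopf("no starts configured")

  runs <- lapply(thetas, function(th) {
    tryCatch(optim(th, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
             error = function(e) list(value = Inf, error = conditionMessage(e)))
  })
  values <- vapply(runs, function(r) r$value, numeric(1))
  if (!any(is.finite(values)) || min(values) >= 1e5) {
    diag <- vapply(runs, function(r) r$error %||% sprintf("value %.3g", r$value),
                   character(1))
    stopf("all %d starts failed to reach a feasible optimum:\n%s",
          length(runs), paste(" -", diag, collapse = "\n"))
  }
  best <- runs[[which.min(values)]]
  m <- theta_to_model(best$par, variant)
  mapping <- positional_mapping(variant, m$color, m$material)
  sol <- model_solution(model_spec(variant, spec$metric), m$w, mapping,
                        log_likelihood = -best$value)
  sol$nll <- best$value
  sol$n_trials <- nrow(trials)
  sol$start_values <- values
  sol$convergence <- best$convergence
  sol
}

minimal_params <- function(variant) {
  conv <- cm_conventions()
  s <- conv$min_spacing
  switch(variant,
         linear = s, quadratic = c(s, 0), cubic = c(s, 0, 0),
         full = s * c(-3:-1, 1:3))
}

#' @export
print.cm_solution <- function(x, ...) {
  cat("Model solution:", x$spec$variant, "/", x$spec$metric, "\n")
  cat("  w =", format(x$w, digits = 4),
      " logLik =", format(x$log_likelihood, digits = 8), "\n")
  if (isTRUE(x$non_identifiable))
    cat("  [flat likelihood: solution flagged non-identifiable]\n")
  cat("  color positions:   ",
      paste(format(x$positions[, 1], digits = 3), collapse = " "), "\n")
  cat("  material positions:",
      paste(format(x$positions[, 2], digits = 3), collapse = " "), "\n")
  invisible(x)
}
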
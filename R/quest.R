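#' QUEST+ parameter grid for the cubic/Euclidean observer model
#'
#' The adaptive procedure runs over a 7-dimensional parameter space: one
#' color-material weight plus cubic-polynomial positional coefficients
#' (linear, quadratic, cubic) per dimension. Parameters are linearly
#' spaced: linear coefficient 0.5..6 (5 levels), quadratic and cubic
#' coefficients -0.3..0.3 (4 levels each), weight 0.05..0.95 (5 levels),
#' giving (5*4*4)^2 * 5 = 32000 raw combinations. Combinations whose
#' implied positions over the 7 design levels are non-monotone,
#' under-spaced (< 0.25) or out of bounds (|p| > 20) are discarded.
#'
#' @param linear_levels,quad_levels,cubic_levels,weight_levels number of
#'   grid levels per parameter
#' @param linear_range,quad_range,cubic_range,weight_range parameter
#'   ranges
#' @return an object of class `cm_quest_grid` with the valid combination
#'   table, per-dimension position matrices, and counts
#' @export
quest_grid <- function(linear_levels = 5, quad_levels = 4, cubic_levels = 4,
                       weight_levels = 5, linear_range = c(0.5, 6),
                       quad_range = c(-0.3, 0.3), cubic_range = c(-0.3, 0.3),
                       weight_range = c(0.05, 0.95)) {
  a1 <- seq(linear_range[1], linear_range[2], length.out = linear_levels)
  a2 <- seq(quad_range[1], quad_range[2], length.out = quad_levels)
  a3 <- seq(cubic_range[1], cubic_range[2], length.out = cubic_levels)
  wv <- seq(weight_range[1], weight_range[2], length.out = weight_levels)

  dims <- expand.grid(a1 = a1, a2 = a2, a3 = a3)
  lev <- -3:3
  pos <- t(apply(dims, 1, function(p) p[1] * lev + p[2] * lev^2 + p[3] * lev^3))
  conv <- cm_conventions()
  ok <- apply(pos, 1, function(p)
    all(diff(p) >= conv$min_spacing - 1e-12) &&
      all(abs(p) <= conv$position_bound + 1e-12))
  if (!any(ok)) stopf("no valid parameter combinations in the grid")
  dims_ok <- dims[ok, , drop = FALSE]
  pos_ok <- pos[ok, , drop = FALSE]
  nd <- nrow(dims_ok)

  combos <- expand.grid(w_idx = seq_along(wv), color_idx = seq_len(nd),
                        material_idx = seq_len(nd))
  structure(list(weights = wv, dim_combos = dims_ok, dim_positions = pos_ok,
                 combos = combos,
                 n_raw = (linear_levels * quad_levels * cubic_levels)^2 *
                   weight_levels,
                 n_valid = nrow(combos), n_dimensions = 7L),
            class = "cm_quest_grid")
}

#' Per-combination choice likelihoods for all candidate pairs
#'
#' Precomputes, via lookup-table interpolation, the probability that the
#' first member of each full-range stimulus pair is chosen under every
#' valid parameter combination, together with the response-entropy terms
#' used by the expected-information criterion. Computing this once makes
#' per-trial stimulus selection a pair of matrix-vector products.
#'
#' @param grid a [quest_grid()]
#' @param table a lookup table (the adaptive procedure uses the Euclidean
#'   one)
#' @param cache_dir optional directory; the matrix is cached there keyed
#'   by a content hash of (grid, table)
#' @return an object of class `cm_quest_lik`
#' @export
quest_likelihood_matrix <- function(grid, table, cache_dir = NULL) {
  stopifnot(inherits(grid, "cm_quest_grid"), inherits(table, "cm_lookup_table"))
  key <- hash_doubles_cpp(c(as.numeric(unlist(grid$dim_combos)), grid$weights,
                            as.numeric(utf8ToInt(table$hash))))
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0("questlik-", key, ".rds"))
    if (file.exists(f)) return(readRDS(f))
  }
  pairs <- pair_table(3)
  np <- nrow(pairs)
  nd <- nrow(grid$dim_positions)
  nw <- length(grid$weights)
  i1c <- pairs$c1 + 4L; i1m <- pairs$m1 + 4L
  i2c <- pairs$c2 + 4L; i2m <- pairs$m2 + 4L

  L <- matrix(NA_real_, nrow = nrow(grid$combos), ncol = np)
  # combos are ordered w fastest, then color, then material (expand.grid)
  for (ic in seq_len(nd)) {
    p1c <- grid$dim_positions[ic, i1c]
    p2c <- grid$dim_positions[ic, i2c]
    # rows for this color combo: all (w, material) combinations
    block <- matrix(NA_real_, nw * nd, np)
    for (im in seq_len(nd)) {
      p1m <- grid$dim_positions[im, i1m]
      p2m <- grid$dim_positions[im, i2m]
      qs <- cbind(rep(grid$weights, each = np),
                  rep(p1c, times = nw), rep(p1m, times = nw),
                  rep(p2c, times = nw), rep(p2m, times = nw))
      block[seq.int((im - 1L) * nw + 1L, im * nw), ] <-
        matrix(interp_queries(table, qs), nrow = nw, byrow = TRUE)
    }
    rows <- which(grid$combos$color_idx == ic)
    L[rows, ] <- block
  }
  # cubic interpolation can overshoot [0, 1] slightly; clamp to probabilities
  L <- pmin(pmax(L, 0), 1)
  Lf <- pmin(pmax(L, 1e-6), 1 - 1e-6)
  SL <- Lf * log(Lf) + (1 - Lf) * log1p(-Lf)
  out <- structure(list(L = L, SL = SL, pairs = pairs, key = key,
                        table_hash = table$hash),
                   class = "cm_quest_lik")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(out, file.path(cache_dir, paste0("questlik-", key, ".rds")))
  }
  out
}

#' Initialize a QUEST+ state
#'
#' Uniform prior over the valid parameter combinations; candidate pairs
#' are all unordered pairs of the (2r+1)^2 stimuli within the requested
#' range (1176 pairs for the full range r = 3, 300 for r = 2, 36 for
#' r = 1).
#'
#' @param grid a [quest_grid()]
#' @param range stimulus range r in 1..3
#' @param lik a [quest_likelihood_matrix()] for this grid
#' @return an object of class `cm_quest`
#' @export
init_quest <- function(grid, range = 3, lik) {
  stopifnot(range %in% 1:3, inherits(lik, "cm_quest_lik"))
  n <- nrow(grid$combos)
  if (n == 0) stopf("empty valid-combination set")
  p <- lik$pairs
  cand <- which(abs(p$c1) <= range & abs(p$m1) <= range &
                  abs(p$c2) <= range & abs(p$m2) <= range)
  structure(list(posterior = rep(1 / n, n), candidates = cand,
                 grid = grid, lik = lik, range = range, n_trials = 0L),
            class = "cm_quest")
}

#' Select the next stimulus pair
#'
#' Returns the candidate pair with the largest expected information gain
#' (equivalently, smallest expected posterior entropy over the two
#' possible responses). Ties go to the lowest pair index (pairs are
#' sorted lexicographically by nominal levels), which makes replays
#' deterministic.
#'
#' @param state a `cm_quest` state
#' @return list with `pair_index` (row of the full pair table) and
#'   `pair` (its levels)
#' @export
next_stimulus <- function(state) {
  gains <- quest_gain_cpp(state$posterior, state$lik$L, state$lik$SL,
                          as.integer(state$candidates))
  best <- state$candidates[which.max(gains)]
  list(pair_index = best, pair = state$lik$pairs[best, , drop = FALSE],
       gain = max(gains))
}

#' Bayesian posterior update after an observed choice
#'
#' Multiplies the posterior by the per-combination likelihood of the
#' observed response (floored at 1e-6 so an interpolated probability near
#' 0 or 1 can never zero the posterior irrecoverably) and renormalizes.
#'
#' @param state a `cm_quest` state
#' @param pair_index row of the pair table that was presented
#' @param choice observed response, 1 or 2
#' @return the updated `cm_quest` state
#' @export
update_posterior <- function(state, pair_index, choice) {
  stopifnot(choice %in% c(1L, 2L))
  l <- state$lik$L[, pair_index]
  if (choice == 2L) l <- 1 - l
  post <- state$posterior * pmax(l, 1e-6)
  s <- sum(post)
  if (s <= 0 || !is.finite(s)) stopf("posterior update underflowed")
  state$posterior <- post / s
  state$n_trials <- state$n_trials + 1L
  state
}

#' @rdname update_posterior
#' @return `posterior_entropy()`: Shannon entropy (nats) of the posterior
#' @export
posterior_entropy <- function(state) {
  p <- state$posterior[state$posterior > 0]
  -sum(p * log(p))
}

#' @rdname update_posterior
#' @return `posterior_mode()`: the parameter combination with maximum
#'   posterior probability (w, color and material cubic coefficients)
#' @export
posterior_mode <- function(state) {
  i <- which.max(state$posterior)
  co <- state$grid$combos[i, ]
  list(w = state$grid$weights[co$w_idx],
       color = unlist(state$grid$dim_combos[co$color_idx, ]),
       material = unlist(state$grid$dim_combos[co$material_idx, ]),
       posterior = state$posterior[i])
}

#' @export
print.cm_quest_grid <- function(x, ...) {
  cat("QUEST+ parameter grid: ", x$n_dimensions, " dimensions, ",
      x$n_raw, " raw combinations, ", x$n_valid, " valid\n", sep = "")
  invisible(x)
}

#' @export
print.cm_quest <- function(x, ...) {
  cat("QUEST+ state: range ", x$range, ", ", length(x$candidates),
      " candidate pairs, ", x$n_trials, " trials observed\n", sep = "")
  cat("  posterior entropy:", format(posterior_entropy(x), digits = 4),
      "nats\n")
  invisible(x)
}
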
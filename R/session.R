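#' Experimental session design
#'
#' The standard design runs 8 blocks of 270 trials. Each block comprises
#' 9 interleaved sub-blocks of 30 trials: six adaptive sub-blocks over
#' the full stimulus range (r = 3), one adaptive sub-block restricted to
#' r = 2, one restricted to r = 1, and one sub-block whose pairs are
#' sampled at random from the full stimulus set. Trials run in groups of
#' 9, one trial per sub-block in randomized order within each group.
#'
#' @param n_blocks number of blocks
#' @param n_quest_full,n_quest_r2,n_quest_r1,n_random sub-block counts by
#'   type
#' @param trials_per_sub_block trials each sub-block contributes per block
#' @return an object of class `cm_design`
#' @export
session_design <- function(n_blocks = 8, n_quest_full = 6, n_quest_r2 = 1,
                           n_quest_r1 = 1, n_random = 1,
                           trials_per_sub_block = 30) {
  n_sub <- n_quest_full + n_quest_r2 + n_quest_r1 + n_random
  sub_blocks <- data.frame(
    subBlock = seq_len(n_sub),
    source = c(rep("questFull", n_quest_full),
               rep("questRestricted2", n_quest_r2),
               rep("questRestricted1", n_quest_r1),
               rep("random", n_random)),
    range = c(rep(3L, n_quest_full), rep(2L, n_quest_r2),
              rep(1L, n_quest_r1), rep(3L, n_random)))
  structure(list(n_blocks = as.integer(n_blocks), sub_blocks = sub_blocks,
                 trials_per_sub_block = as.integer(trials_per_sub_block),
                 trials_per_block = as.integer(n_sub * trials_per_sub_block),
                 group_size = nrow(sub_blocks)),
            class = "cm_design")
}

#' Generating observer for simulation
#'
#' @param w color-material weight in `[0, 1]`
#' @param mapping a valid [positional_mapping()]
#' @param metric distance metric the observer uses
#' @return an object of class `cm_observer`
#' @export
generating_observer <- function(w, mapping,
                                metric = c("euclidean", "cityblock")) {
  metric <- match.arg(metric)
  sol <- model_solution(model_spec(mapping$variant, metric), w, mapping)
  structure(list(w = w, mapping = mapping, metric = metric,
                 positions = sol$positions),
            class = "cm_observer")
}

# one stochastic response: per-trial noisy draws through the decision rule
observer_response <- function(observer, p1, p2) {
  tdraw <- rnorm(2)
  decide_trial(tdraw, p1 + rnorm(2), p2 + rnorm(2), observer$w,
               observer$metric)
}

#' Simulate a complete experiment
#'
#' Reproduces the block/sub-block design with a generating observer.
#' Each adaptive sub-block maintains its own QUEST+ posterior; by default
#' the posteriors persist across blocks (set `reset_between_blocks` to
#' re-initialize each block). Responses are drawn stochastically by
#' passing fresh noisy perceptual draws through the observer's decision
#' rule, not by thresholding lookup probabilities. The random sub-block
#' samples pairs uniformly without replacement within each block's
#' 30-trial budget (with replacement across blocks).
#'
#' @param observer a [generating_observer()]
#' @param design a [session_design()]
#' @param grid a [quest_grid()] driving the adaptive sub-blocks
#' @param table Euclidean lookup table used by the adaptive procedure
#' @param lik optional precomputed [quest_likelihood_matrix()]
#' @param seed integer seed; identical seeds reproduce the session
#' @param reset_between_blocks re-initialize adaptive posteriors at each
#'   block boundary
#' @return a trial data frame with columns `test1Color`, `test1Material`,
#'   `test2Color`, `test2Material`, `choice`, `block`, `subBlock`,
#'   `source`
#' @export
simulate_session <- function(observer, design = session_design(), grid,
                             table, lik = NULL, seed = 1,
                             reset_between_blocks = FALSE) {
  stopifnot(inherits(observer, "cm_observer"), inherits(design, "cm_design"))
  if (is.null(lik)) lik <- quest_likelihood_matrix(grid, table)
  sub <- design$sub_blocks
  n_sub <- nrow(sub)
  pairs <- lik$pairs
  posC <- observer$positions[, 1]
  posM <- observer$positions[, 2]

  states <- vector("list", n_sub)
  make_state <- function(i) {
    if (sub$source[i] == "random") NULL else init_quest(grid, sub$range[i], lik)
  }
  for (i in seq_len(n_sub)) states[[i]] <- make_state(i)

  total <- design$n_blocks * design$trials_per_block
  out <- data.frame(test1Color = integer(total), test1Material = integer(total),
                    test2Color = integer(total), test2Material = integer(total),
                    choice = integer(total), block = integer(total),
                    subBlock = integer(total), source = character(total))
  row <- 0L
  with_seed(derive_seed(seed, "session"), {
    for (b in seq_len(design$n_blocks)) {
      if (reset_between_blocks && b > 1L)
        for (i in seq_len(n_sub)) states[[i]] <- make_state(i)
      rand_ids <- which(sub$source == "random")
      rand_draw <- lapply(rand_ids, function(i)
        sample.int(nrow(pairs), design$trials_per_sub_block))
      names(rand_draw) <- as.character(rand_ids)
      rand_used <- setNames(rep(0L, length(rand_ids)), as.character(rand_ids))
      for (g in seq_len(design$trials_per_sub_block)) {
        for (i in sample.int(n_sub)) {
          if (sub$source[i] == "random") {
            rand_used[as.character(i)] <- rand_used[as.character(i)] + 1L
            idx <- rand_draw[[as.character(i)]][rand_used[as.character(i)]]
          } else {
            idx <- next_stimulus(states[[i]])$pair_index
          }
          pr <- pairs[idx, ]
          p1 <- c(posC[pr$c1 + 4L], posM[pr$m1 + 4L])
          p2 <- c(posC[pr$c2 + 4L], posM[pr$m2 + 4L])
          choice <- observer_response(observer, p1, p2)
          if (sub$source[i] != "random")
            states[[i]] <- update_posterior(states[[i]], idx, choice)
          row <- row + 1L
          out$test1Color[row] <- pr$c1; out$test1Material[row] <- pr$m1
          out$test2Color[row] <- pr$c2; out$test2Material[row] <- pr$m2
          out$choice[row] <- choice; out$block[row] <- b
          out$subBlock[row] <- i; out$source[row] <- sub$source[i]
        }
      }
    }
  })
  attr(out, "quest_states") <- states
  attr(out, "seed") <- seed
  out
}

#' Simulate repeated presentations of fixed stimulus pairs
#'
#' A method-of-constant-stimuli harness: each supplied pair is presented
#' `n_repeats` times in shuffled order, with responses drawn
#' stochastically from the observer's decision rule.
#'
#' @inheritParams simulate_session
#' @param pairs data frame with columns `c1`, `m1`, `c2`, `m2` (as
#'   produced by [pair_table()])
#' @param n_repeats presentations per pair
#' @return a trial data frame (source `"fixed"`)
#' @export
simulate_fixed_pairs <- function(observer, pairs, n_repeats, seed = 1) {
  stopifnot(inherits(observer, "cm_observer"), nrow(pairs) >= 1,
            n_repeats >= 0)
  if (n_repeats == 0)
    return(data.frame(test1Color = integer(), test1Material = integer(),
                      test2Color = integer(), test2Material = integer(),
                      choice = integer(), block = integer(),
                      subBlock = integer(), source = character()))
  posC <- observer$positions[, 1]
  posM <- observer$positions[, 2]
  idx <- rep(seq_len(nrow(pairs)), times = n_repeats)
  with_seed(derive_seed(seed, "fixed-pairs"), {
    idx <- idx[sample.int(length(idx))]
    choice <- vapply(idx, function(i) {
      p1 <- c(posC[pairs$c1[i] + 4L], posM[pairs$m1[i] + 4L])
      p2 <- c(posC[pairs$c2[i] + 4L], posM[pairs$m2[i] + 4L])
      observer_response(observer, p1, p2)
    }, integer(1))
  })
  data.frame(test1Color = pairs$c1[idx], test1Material = pairs$m1[idx],
             test2Color = pairs$c2[idx], test2Material = pairs$m2[idx],
             choice = choice, block = 1L, subBlock = 1L, source = "fixed")
}

#' @export
print.cm_design <- function(x, ...) {
  cat("Session design: ", x$n_blocks, " blocks x ", x$trials_per_block,
      " trials (", nrow(x$sub_blocks), " sub-blocks of ",
      x$trials_per_sub_block, ")\n", sep = "")
  print(x$sub_blocks)
  invisible(x)
}
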
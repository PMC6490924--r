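make_trials <- function(c1, m1, c2, m2, choice) {
  n <- length(c1)
  data.frame(test1Color = c1, test1Material = m1, test2Color = c2,
             test2Material = m2, choice = choice, block = rep(1L, n),
             subBlock = rep(1L, n), source = rep("fixed", n))
}

test_that("negative log-likelihood follows its defining arithmetic", {
  tab <- test_tab("euclidean")
  sol <- model_solution(model_spec("linear", "euclidean"), 0.4,
                        positional_mapping("linear", 1, 1))
  # empty trial list
  expect_equal(negative_log_likelihood(sol, make_trials(integer(), integer(),
                                                        integer(), integer(),
                                                        integer()), tab), 0)
  # a trial whose two tests map to identical positions contributes -ln 0.5
  tr1 <- make_trials(2L, -1L, 2L, -1L, 1L)
  expect_equal(negative_log_likelihood(sol, tr1, tab), log(2), tolerance = 1e-10)
  # additivity: duplicating every trial doubles the value exactly
  tr <- make_trials(c(0L, 1L, -2L), c(3L, 0L, 1L), c(1L, -1L, 0L),
                    c(0L, 2L, -3L), c(1L, 2L, 1L))
  v1 <- negative_log_likelihood(sol, tr, tab)
  v2 <- negative_log_likelihood(sol, rbind(tr, tr), tab)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  # constraint-violating solutions error rather than return a penalty
  bad <- sol
  bad$mapping <- positional_mapping("linear", 0.1, 1)
  expect_error(negative_log_likelihood(bad, tr, tab), "spacing")
  # metric mismatch is a configuration error
  expect_error(negative_log_likelihood(sol, tr, test_tab("cityblock")), "metric")
})

test_that("fits are order-invariant, constraint-satisfying, and at least as good as any start", {
  tab <- full_tab("euclidean")
  obs <- linear_observer(0.5, 1.5)
  trials <- random_trials(obs, 600, seed = 21)
  cfg <- fit_config(seed = 3)
  spec <- model_spec("linear", "euclidean")
  f1 <- fit_model(trials, spec, cfg, tab, n_starts = 4)
  # permuting trials leaves the solution unchanged (likelihood is a sum)
  perm <- withr::with_seed(5, sample.int(nrow(trials)))
  f2 <- fit_model(trials[perm, ], spec, cfg, tab, n_starts = 4)
  expect_equal(f1$w, f2$w, tolerance = 1e-12)
  expect_equal(f1$mapping$color, f2$mapping$color, tolerance = 1e-12)
  # reported log-likelihood equals minus the NLL of the returned parameters
  expect_equal(f1$log_likelihood, -negative_log_likelihood(f1, trials, tab),
               tolerance = 1e-9)
  # positions satisfy monotonicity/spacing/bounds
  expect_true(all(diff(f1$positions[, 1]) >= 0.25 - 1e-9))
  expect_true(all(abs(f1$positions) <= 20 + 1e-9))
  # warm-starting at the generating parameters can only improve the optimum
  cfg_warm <- fit_config(seed = 3, extra_starts = list(
    list(w = 0.5, mapping = positional_mapping("linear", 1.5, 1.5))))
  f3 <- fit_model(trials, spec, cfg_warm, tab, n_starts = 4)
  expect_gte(f3$log_likelihood, f1$log_likelihood - 1e-6)
  truth_nll <- negative_log_likelihood(
    model_solution(spec, 0.5, positional_mapping("linear", 1.5, 1.5)),
    trials, tab)
  expect_lte(-f3$log_likelihood, truth_nll + 1e-8)
})

test_that("nested variants never fit worse than the models they contain", {
  tab <- full_tab("euclidean")
  trials <- random_trials(linear_observer(0.4, 2), 500, seed = 33)
  cfg <- fit_config(seed = 2)
  lin <- fit_model(trials, model_spec("linear", "euclidean"), cfg, tab,
                   n_starts = 4)
  # seed each more complex fit with the simpler optimum embedded in its
  # parameter space: the optimizer can then only improve on it
  quad_start <- positional_mapping("quadratic", c(lin$mapping$color, 0),
                                   c(lin$mapping$material, 0))
  cfgq <- fit_config(seed = 2, extra_starts = list(list(w = lin$w, mapping = quad_start)))
  quad <- fit_model(trials, model_spec("quadratic", "euclidean"), cfgq, tab,
                    n_starts = 4)
  expect_gte(quad$log_likelihood, lin$log_likelihood - 1e-8)

  cub_start <- positional_mapping("cubic", c(quad$mapping$color, 0),
                                  c(quad$mapping$material, 0))
  cfgc <- fit_config(seed = 2, extra_starts = list(list(w = quad$w, mapping = cub_start)))
  cub <- fit_model(trials, model_spec("cubic", "euclidean"), cfgc, tab,
                   n_starts = 4)
  expect_gte(cub$log_likelihood, quad$log_likelihood - 1e-8)

  lev <- c(-3:-1, 1:3)
  full_start <- positional_mapping("full",
                                   map_positions(cub$mapping, lev, "color"),
                                   map_positions(cub$mapping, lev, "material"))
  cfgf <- fit_config(seed = 2, extra_starts = list(list(w = cub$w, mapping = full_start)))
  ful <- fit_model(trials, model_spec("full", "euclidean"), cfgf, tab,
                   n_starts = 4)
  expect_gte(ful$log_likelihood, cub$log_likelihood - 1e-8)
})

test_that("degenerate data are flagged non-identifiable instead of fitted", {
  tab <- test_tab("euclidean")
  tr <- make_trials(rep(1L, 10), rep(0L, 10), rep(1L, 10), rep(0L, 10),
                    rep(c(1L, 2L), 5))
  f <- fit_model(tr, model_spec("linear", "euclidean"), fit_config(), tab)
  expect_true(f$non_identifiable)
  expect_equal(f$w, 0.5)
  expect_equal(f$log_likelihood, -10 * log(2))
})

test_that("the weight is recovered accurately at mid-range and in rank order at the extremes", {
  # The weight/slope-ratio trade-off ridge limits how precisely extreme
  # weights can be pinned down from 2160 trials, so the error bands widen
  # away from w = 0.5. Generating spacings of two noise SDs per step are
  # typical of fitted observers. See the methods vignette for the
  # identifiability analysis behind these conditions and bands.
  tab <- full_tab("euclidean")
  cfg <- fit_config(seed = 8)
  spec <- model_spec("linear", "euclidean")
  fit_once <- function(w, r) {
    trials <- random_trials(linear_observer(w, slope = 2), 2160,
                            seed = 7000 + round(1000 * w) + r)
    fit_model(trials, spec, cfg, tab, n_starts = 6)$w
  }
  mid <- sapply(1:12, function(r) fit_once(0.5, r))
  expect_lte(median(abs(mid - 0.5)), 0.08)
  lo <- sapply(1:12, function(r) fit_once(0.2, r))
  hi <- sapply(1:12, function(r) fit_once(0.8, r))
  expect_lte(median(abs(lo - 0.2)), 0.25)
  expect_lte(median(abs(hi - 0.8)), 0.25)
  # generating rank order is preserved by the recovered medians
  expect_lt(median(lo), median(mid))
  expect_lt(median(mid), median(hi))
})
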
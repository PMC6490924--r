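test_that("slope ratios match closed-form least squares", {
  spec <- model_spec("full", "euclidean")
  ident <- model_solution(spec, 0.5,
                          positional_mapping("full", c(-3, -2, -1, 1, 2, 3),
                                             c(-3, -2, -1, 1, 2, 3)))
  expect_equal(slope_ratio(ident), 1)
  half <- model_solution(spec, 0.5,
                         positional_mapping("full", c(-3, -2, -1, 1, 2, 3),
                                            2 * c(-3, -2, -1, 1, 2, 3)))
  expect_equal(slope_ratio(half), 0.5)
  # asymmetric full solution against an independent regression oracle
  pc <- c(-7, -4, -1.5, 1, 2.5, 5)
  pm <- c(-5, -3.5, -2, 0.5, 2, 6)
  asym <- model_solution(spec, 0.5, positional_mapping("full", pc, pm))
  lev <- -3:3
  oracle <- function(pos) unname(coef(lm(pos ~ lev))[2])
  expect_equal(slope_ratio(asym),
               oracle(asym$positions[, 1]) / oracle(asym$positions[, 2]),
               tolerance = 1e-12)
})

test_that("trade-off functions are at chance at the origin and saturate with color offset", {
  tab <- full_tab("euclidean")
  sol <- model_solution(model_spec("linear", "euclidean"), 0.5,
                        positional_mapping("linear", 2, 2))
  tf <- tradeoff_functions(sol, tab)
  expect_equal(nrow(tf), 49L)
  p00 <- tf$p_color_match[tf$material_level == 0 & tf$color_level == 0]
  expect_equal(p00, 0.5, tolerance = 1e-12)
  # the zero-material-difference curve approaches 1 at large color offsets
  m0 <- tf[tf$material_level == 0, ]
  expect_gt(m0$p_color_match[m0$color_level == 3], 0.9)
  expect_gt(m0$p_color_match[m0$color_level == -3], 0.9)
  # each curve is non-decreasing in the color offset magnitude
  for (m in -3:3) {
    cur <- tf[tf$material_level == m, ]
    up <- cur$p_color_match[match(0:3, cur$color_level)]
    dn <- cur$p_color_match[match(0:-3, cur$color_level)]
    expect_true(all(diff(up) > -0.02))
    expect_true(all(diff(dn) > -0.02))
  }
  # symmetric solutions give coinciding curves for mirrored material levels
  expect_equal(tf$p_color_match[tf$material_level == -1],
               tf$p_color_match[tf$material_level == 1], tolerance = 1e-9)
})

test_that("trade-off curves depend only on the implied perceptual geometry", {
  tab <- full_tab("euclidean")
  lin <- model_solution(model_spec("linear", "euclidean"), 0.6,
                        positional_mapping("linear", 2, 1.5))
  lev <- c(-3:-1, 1:3)
  ful <- model_solution(model_spec("full", "euclidean"), 0.6,
                        positional_mapping("full", 2 * lev, 1.5 * lev))
  expect_equal(tradeoff_functions(lin, tab)$p_color_match,
               tradeoff_functions(ful, tab)$p_color_match, tolerance = 1e-12)
})

test_that("bootstrap is seed-deterministic with a negative weight/slope-ratio correlation", {
  tab <- full_tab("euclidean")
  obs <- linear_observer(0.5, 1.5)
  trials <- random_trials(obs, 1000, seed = 7)
  cfg <- fit_config(seed = 7, boot_n_starts = 2)
  fit <- fit_model(trials, model_spec("linear", "euclidean"), cfg, tab)
  b1 <- bootstrap_weights(trials, fit, cfg, tab, n_iterations = 20, seed = 7)
  b2 <- bootstrap_weights(trials, fit, cfg, tab, n_iterations = 20, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_lte(b1$ci[1], b1$ci[2])
  expect_true(all(b1$ci >= 0 & b1$ci <= 1))
  expect_equal(b1$n_failed, 0)
  # the weight/slope-ratio trade-off appears as a negative correlation
  expect_lt(cor(b1$weights, b1$slope_ratios), 0)
})

test_that("bootstrap intervals cover a mid-range generating weight", {
  tab <- full_tab("euclidean")
  w <- 0.5
  obs <- linear_observer(w, 1.5)
  cfg <- fit_config(boot_n_starts = 2)
  cover <- sapply(1:8, function(r) {
    trials <- random_trials(obs, 800, seed = 300 + r)
    fit <- fit_model(trials, model_spec("linear", "euclidean"), cfg, tab,
                     n_starts = 6)
    bt <- bootstrap_weights(trials, fit, cfg, tab, n_iterations = 20, seed = r)
    bt$ci[1] <= w && w <= bt$ci[2]
  })
  # nominal coverage is 68%; wide tolerance at this replicate count
  expect_gte(mean(cover), 0.5)
})

test_that("the recovery study chains simulation, selection and fitting per observer", {
  tabs <- list(euclidean = full_tab("euclidean"), cityblock = full_tab("cityblock"))
  cfg <- fit_config(cv_n_starts = 1, max_iterations = 600, n_starts = 4)
  rec <- recovery_study(list(linear_observer(0.3), linear_observer(0.7)),
                        session_design(n_blocks = 2), the_grid(), tabs,
                        cfg, seed = 5, lik = full_lik())
  expect_equal(nrow(rec$summary), 2L)
  expect_true(all(rec$summary$w_recovered >= 0 & rec$summary$w_recovered <= 1))
  expect_equal(rec$summary$w_error,
               rec$summary$w_recovered - rec$summary$w_generating)
  expect_true(all(vapply(rec$runs, function(r) nrow(r$trials), numeric(1)) == 540))
  # per-observer child seeds differ, so the two sessions differ
  expect_false(identical(rec$runs[[1]]$trials$choice,
                         rec$runs[[2]]$trials$choice))
})

test_that("degenerate trial tables propagate the non-identifiable flag through the bootstrap", {
  tab <- test_tab("euclidean")
  tr <- data.frame(test1Color = 1L, test1Material = 0L, test2Color = 1L,
                   test2Material = 0L, choice = rep(c(1L, 2L), 10),
                   block = 1L, subBlock = 1L, source = "fixed")
  cfg <- fit_config()
  fit <- fit_model(tr, model_spec("linear", "euclidean"), cfg, tab)
  bt <- bootstrap_weights(tr, fit, cfg, tab, n_iterations = 5, seed = 1)
  expect_true(all(bt$non_identifiable))
  expect_true(all(bt$weights == 0.5))
})
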
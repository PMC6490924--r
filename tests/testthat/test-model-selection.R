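synthetic_trials <- function(n, seed) {
  # balanced multi-source trial table for plan tests (choices arbitrary)
  pairs <- pair_table(3)
  withr::with_seed(seed, {
    idx <- sample.int(nrow(pairs), n, replace = TRUE)
    data.frame(test1Color = pairs$c1[idx], test1Material = pairs$m1[idx],
               test2Color = pairs$c2[idx], test2Material = pairs$m2[idx],
               choice = sample(1:2, n, replace = TRUE),
               block = rep_len(1:8, n),
               subBlock = rep_len(1:9, n),
               source = rep(c(rep("questFull", 6), "questRestricted2",
                              "questRestricted1", "random"), length.out = n))
  })
}

test_that("fold plans partition trials evenly and are stable under reordering", {
  tr <- synthetic_trials(2160, seed = 4)
  plan <- cv_plan(tr, n_folds = 8, seed = 4)
  expect_equal(sort(unique(plan$fold)), 1:8)
  expect_true(all(tabulate(plan$fold, 8) == 270))  # 2160 / 8
  # sources are spread across folds
  counts <- table(plan$fold, tr$source)
  expect_true(all(counts[, "random"] == 240 / 8))
  # content-identical tables get content-identical assignments
  perm <- withr::with_seed(9, sample.int(nrow(tr)))
  plan2 <- cv_plan(tr[perm, ], n_folds = 8, seed = 4)
  key <- function(d) do.call(paste, d[c("source", "block", "subBlock",
                                        "test1Color", "test1Material",
                                        "test2Color", "test2Material", "choice")])
  expect_equal(sort(paste(key(tr), plan$fold)),
               sort(paste(key(tr[perm, ]), plan2$fold)))
})

test_that("cross-validation scores are deterministic and fold-disjoint", {
  tab <- full_tab("euclidean")
  tr <- random_trials(linear_observer(0.5, 1.5), 400, seed = 12)
  plan <- cv_plan(tr, n_folds = 8, seed = 12)
  cfg <- fit_config(seed = 12, cv_n_starts = 2)
  spec <- model_spec("linear", "euclidean")
  s1 <- cross_validate(tr, spec, plan, cfg, tab)
  s2 <- cross_validate(tr, spec, plan, cfg, tab)
  expect_identical(s1, s2)
  expect_length(s1, 8)
  expect_true(all(s1 < 0))
  # a plan with an empty fold is rejected
  bad <- plan
  bad$fold[bad$fold == 3] <- 4L
  expect_error(cross_validate(tr, spec, bad, cfg, tab), "empty fold")
})

test_that("the positional ladder keeps complexity only when significantly better", {
  base <- matrix(rep(c(-100, -101, -99.5, -100.5), each = 8), 8, 4,
                 dimnames = list(NULL, c("full", "cubic", "quadratic", "linear")))
  # identical scores across variants: descend all the way to linear
  eq <- matrix(-100, 8, 4, dimnames = dimnames(base))
  expect_equal(select_positional_variant(eq)$variant, "linear")
  # full uniformly +10 per fold above cubic: forced significance
  up <- eq; up[, "full"] <- -90
  expect_equal(select_positional_variant(up)$variant, "full")
  # missing variant is an input error
  expect_error(select_positional_variant(eq[, 1:3]), "columns")

  # operating characteristic: cubic beats quadratic by 3 fold-SDs,
  # full matches cubic -> cubic should be selected in >= 90% of replicates
  picks <- withr::with_seed(99, replicate(100, {
    quad <- -100 + rnorm(8)
    cubic <- quad + 3 + rnorm(8)
    full <- cubic + rnorm(8)
    lin <- quad - rnorm(8)^2
    sc <- cbind(full = full, cubic = cubic, quadratic = quad, linear = lin)
    select_positional_variant(sc)$variant
  }))
  expect_gte(mean(picks == "cubic"), 0.9)
})

test_that("metric choice follows the mean held-out score with a Euclidean tie-break", {
  eu <- c(-100, -101, -99, -100, -102, -98, -100, -101)
  cb <- eu + 0.5
  res <- select_metric(eu, cb)
  expect_equal(res$metric, "cityblock")  # higher mean wins regardless of p
  # constant per-fold difference: zero-variance t-test treated as significant
  expect_equal(res$p_value, 0)
  expect_true(res$significant)
  # equal means to machine precision prefer Euclidean
  tie <- select_metric(eu, eu)
  expect_equal(tie$metric, "euclidean")
  expect_equal(tie$p_value, 1)
  # noisy differences give an honest two-tailed p-value
  res2 <- select_metric(eu, eu + c(0.4, -0.2, 0.1, -0.3, 0.2, 0.05, -0.1, 0.15))
  expect_gt(res2$p_value, 0.05)
  expect_false(res2$significant)
})

test_that("the full selection ladder returns a reachable best spec on real fits", {
  tabs <- list(euclidean = full_tab("euclidean"), cityblock = full_tab("cityblock"))
  tr <- random_trials(linear_observer(0.5, 2), 480, seed = 55)
  cfg <- fit_config(seed = 55, cv_n_starts = 1, max_iterations = 800)
  sel <- select_model(tr, cfg, tabs, n_folds = 8, seed = 55)
  expect_s3_class(sel, "cm_selection")
  expect_true(sel$best_spec$variant %in% c("full", "cubic", "quadratic", "linear"))
  # the winner's mean held-out score is the maximum of its metric's ladder winner
  ms <- sel$mean_scores
  expect_equal(max(ms[sel$ladder$euclidean$variant, "euclidean"],
                   ms[sel$ladder$cityblock$variant, "cityblock"]),
               ms[sel$best_spec$variant, sel$best_spec$metric])
  # the reported best fit is the full-data fit of the selected spec
  expect_equal(sel$best_fit$spec$variant, sel$best_spec$variant)
  expect_equal(sel$best_fit$spec$metric, sel$best_spec$metric)
})
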
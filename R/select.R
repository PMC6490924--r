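#' Cross-validation plan
#'
#' Assigns each trial to one of `n_folds` folds. Trials are first put in a
#' canonical content order (so the assignment is stable under row
#' reordering of the same trial multiset), then permuted within
#' sub-block-source strata and dealt round-robin, which equalizes both
#' fold sizes (difference at most 1) and the mix of adaptive/random trial
#' sources across folds. One plan is reused across all model variants and
#' both metrics for a given dataset.
#'
#' @param trials trial data frame
#' @param n_folds number of folds (8 in the standard design)
#' @param seed integer seed
#' @return an object of class `cm_cv_plan` with a per-trial `fold` vector
#' @export
cv_plan <- function(trials, n_folds = 8, seed = 1) {
  stopifnot(nrow(trials) >= n_folds, n_folds >= 2)
  cols <- c("source", "block", "subBlock", "test1Color", "test1Material",
            "test2Color", "test2Material", "choice")
  cols <- intersect(cols, names(trials))
  canon <- do.call(order, trials[cols])
  fold <- integer(nrow(trials))
  with_seed(derive_seed(seed, "cv-plan"), {
    src <- if ("source" %in% names(trials)) trials$source[canon]
           else rep("all", nrow(trials))
    pos <- 0L
    for (s in unique(src)) {
      idx <- canon[src == s]
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((pos + seq_along(idx) - 1L) %% n_folds) + 1L
      pos <- pos + length(idx)
    }
  })
  structure(list(n_folds = as.integer(n_folds), fold = fold,
                 seed = as.integer(seed)),
            class = "cm_cv_plan")
}

#' Cross-validated held-out log-likelihoods for one model spec
#'
#' For each fold, fits the model on the other folds' trials and evaluates
#' the held-out log-likelihood on the fold's trials. Fold fits use
#' `config$cv_n_starts` default starts plus a warm start at `full_fit`
#' (if supplied).
#'
#' @inheritParams fit_model
#' @param plan a [cv_plan()] for these trials
#' @param full_fit optional full-data solution of the same spec, used as
#'   an additional fold-fit start
#' @return numeric vector of held-out log-likelihoods, one per fold
#' @export
cross_validate <- function(trials, spec, plan, config = fit_config(), table,
                           full_fit = NULL) {
  stopifnot(inherits(plan, "cm_cv_plan"), length(plan$fold) == nrow(trials))
  if (any(tabulate(plan$fold, plan$n_folds) == 0))
    stopf("cross-validation plan has an empty fold")
  cfg <- config
  if (!is.null(full_fit))
    cfg$extra_starts <- c(cfg$extra_starts,
                          list(list(w = full_fit$w, mapping = full_fit$mapping)))
  vapply(seq_len(plan$n_folds), function(k) {
    fit <- fit_model(trials[plan$fold != k, , drop = FALSE], spec, cfg, table,
                     n_starts = config$cv_n_starts)
    -negative_log_likelihood(fit, trials[plan$fold == k, , drop = FALSE], table)
  }, numeric(1))
}

# one-tailed paired comparison: is `complex` better than `simple`?
# Zero-variance differences take the test's limiting behaviour: a
# constant positive difference is significant, a zero difference is not.
paired_p <- function(complex, simple, two_tailed = FALSE) {
  d <- complex - simple
  if (sd(d) == 0) {
    if (mean(d) == 0) return(1)
    if (two_tailed) return(0)
    return(if (mean(d) > 0) 0 else 1)
  }
  t.test(d, alternative = if (two_tailed) "two.sided" else "greater")$p.value
}

#' Positional-variant selection ladder
#'
#' Starting from the most complex variant, each step asks whether the
#' more complex model's per-fold held-out log-likelihoods are
#' significantly higher than the next simpler variant's (one-tailed
#' paired t-test at alpha = 0.05). The first significant step stops the
#' ladder and retains the more complex variant; otherwise the complex
#' variant is eliminated and the comparison proceeds
#' full -> cubic -> quadratic -> linear.
#'
#' @param fold_scores matrix of held-out log-likelihoods, one row per
#'   fold, with columns named `full`, `cubic`, `quadratic`, `linear`
#' @param alpha significance level per step
#' @return list with the selected `variant` and the ladder `p_values`
#' @export
select_positional_variant <- function(fold_scores, alpha = 0.05) {
  need <- c("full", "cubic", "quadratic", "linear")
  if (!all(need %in% colnames(fold_scores)))
    stopf("fold_scores must have columns %s", paste(need, collapse = ", "))
  p <- c(full_vs_cubic = paired_p(fold_scores[, "full"], fold_scores[, "cubic"]),
         cubic_vs_quadratic = paired_p(fold_scores[, "cubic"], fold_scores[, "quadratic"]),
         quadratic_vs_linear = paired_p(fold_scores[, "quadratic"], fold_scores[, "linear"]))
  variant <- if (p[1] < alpha) "full"
             else if (p[2] < alpha) "cubic"
             else if (p[3] < alpha) "quadratic"
             else "linear"
  list(variant = variant, p_values = p)
}

#' Metric comparison between the two ladder winners
#'
#' The best overall model is the metric whose best positional variant has
#' the higher mean held-out log-likelihood (ties prefer Euclidean, the
#' arbitrary default used to drive the adaptive procedure). A two-tailed
#' paired t-test p-value is also reported, judged at the
#' multiple-comparison-corrected level alpha = 0.05/12.
#'
#' @param euclidean_scores,cityblock_scores per-fold held-out
#'   log-likelihoods for each metric's selected variant
#' @param alpha corrected significance level
#' @return list with `metric`, `p_value`, `significant`, and mean scores
#' @export
select_metric <- function(euclidean_scores, cityblock_scores,
                          alpha = 0.05 / 12) {
  me <- mean(euclidean_scores)
  mc <- mean(cityblock_scores)
  p <- paired_p(cityblock_scores, euclidean_scores, two_tailed = TRUE)
  list(metric = if (mc > me) "cityblock" else "euclidean",
       p_value = p, significant = p < alpha,
       mean_euclidean = me, mean_cityblock = mc, alpha = alpha)
}

#' Full preregistered-style model selection
#'
#' Runs 8-fold cross-validation for all 8 model variants (4 positional
#' mappings x 2 metrics) on a shared fold plan, applies the
#' positional-variant ladder separately per metric, compares the two
#' ladder winners by mean held-out log-likelihood, and returns the best
#' spec together with its full-data fit.
#'
#' @inheritParams fit_model
#' @param tables named list with lookup tables `euclidean` and
#'   `cityblock`
#' @param n_folds number of cross-validation folds
#' @param seed seed for the fold plan
#' @return an object of class `cm_selection`
#' @export
select_model <- function(trials, config = fit_config(), tables, n_folds = 8,
                         seed = 1) {
  stopifnot(all(c("euclidean", "cityblock") %in% names(tables)))
  plan <- cv_plan(trials, n_folds = n_folds, seed = seed)
  variants <- c("full", "cubic", "quadratic", "linear")
  fits <- list()
  scores <- list()
  for (metric in c("euclidean", "cityblock")) {
    sc <- matrix(NA_real_, n_folds, length(variants),
                 dimnames = list(NULL, variants))
    for (v in variants) {
      spec <- model_spec(v, metric)
      key <- paste(v, metric, sep = ".")
      fits[[key]] <- fit_model(trials, spec, config, tables[[metric]])
      sc[, v] <- cross_validate(trials, spec, plan, config, tables[[metric]],
                                full_fit = fits[[key]])
    }
    scores[[metric]] <- sc
  }
  ladder <- lapply(scores, select_positional_variant)
  met <- select_metric(scores$euclidean[, ladder$euclidean$variant],
                       scores$cityblock[, ladder$cityblock$variant])
  best_variant <- ladder[[met$metric]]$variant
  best_key <- paste(best_variant, met$metric, sep = ".")
  structure(list(best_spec = model_spec(best_variant, met$metric),
                 best_fit = fits[[best_key]],
                 alternative_spec = model_spec(
                   ladder[[setdiff(c("euclidean", "cityblock"), met$metric)]]$variant,
                   setdiff(c("euclidean", "cityblock"), met$metric)),
                 alternative_fit = fits[[paste(
                   ladder[[setdiff(c("euclidean", "cityblock"), met$metric)]]$variant,
                   setdiff(c("euclidean", "cityblock"), met$metric), sep = ".")]],
                 fold_scores = scores,
                 mean_scores = sapply(scores, colMeans),
                 ladder = ladder, metric_comparison = met,
                 plan = plan, fits = fits),
            class = "cm_selection")
}

#' @export
print.cm_selection <- function(x, ...) {
  cat("Model selection over 8 variants\n")
  cat("  best:", x$best_spec$variant, "/", x$best_spec$metric,
      " (w =", format(x$best_fit$w, digits = 3), ")\n")
  cat("  mean held-out log-likelihood per fold:\n")
  print(round(x$mean_scores, 3))
  cat("  ladder p-values (euclidean):",
      paste(format(x$ladder$euclidean$p_values, digits = 3), collapse = " "), "\n")
  cat("  ladder p-values (cityblock):",
      paste(format(x$ladder$cityblock$p_values, digits = 3), collapse = " "), "\n")
  cat("  metric comparison p =", format(x$metric_comparison$p_value, digits = 3),
      if (x$metric_comparison$significant) "(significant at 0.05/12)"
      else "(not significant at 0.05/12)", "\n")
  invisible(x)
}
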
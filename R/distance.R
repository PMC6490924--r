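#' Weighted perceptual distance between target and test
#'
#' Combines per-dimension target-test differences after scaling the color
#' difference by the color-material weight `w` and the material difference
#' by `1 - w`. With the Euclidean metric the distance is
#' `sqrt((w * dC)^2 + ((1 - w) * dM)^2)`; with the city-block metric it is
#' `w * |dC| + (1 - w) * |dM|`.
#'
#' @param w color-material weight in `[0, 1]`
#' @param delta_c,delta_m target-test differences along the color and
#'   material dimensions (noise-SD units); vectorized
#' @param metric `"euclidean"` or `"cityblock"`
#' @return non-negative distances
#' @examples
#' weighted_distance(0.5, 2, 2, "euclidean")  # sqrt(2)
#' weighted_distance(0.25, 4, 2, "cityblock") # 2.5
#' @export
weighted_distance <- function(w, delta_c, delta_m,
                              metric = c("euclidean", "cityblock")) {
  metric <- match.arg(metric)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stopf("w must lie in [0, 1]")
  if (metric == "euclidean")
    sqrt((w * delta_c)^2 + ((1 - w) * delta_m)^2)
  else
    w * abs(delta_c) + (1 - w) * abs(delta_m)
}

#' Decide a single trial from noisy perceptual draws
#'
#' Given the trial's noisy draws for the target and the two tests, the
#' observer selects the test whose draw lies closer to the target draw
#' under the weighted metric. Exact ties (a measure-zero event under
#' continuous noise) are broken at random with probability one half,
#' using the session RNG.
#'
#' @param target_draw,test1_draw,test2_draw numeric length-2 vectors
#'   (color, material) of noisy perceptual positions
#' @inheritParams weighted_distance
#' @return `1L` or `2L`, the chosen test
#' @export
decide_trial <- function(target_draw, test1_draw, test2_draw, w,
                         metric = c("euclidean", "cityblock")) {
  metric <- match.arg(metric)
  d1 <- weighted_distance(w, target_draw[1] - test1_draw[1],
                          target_draw[2] - test1_draw[2], metric)
  d2 <- weighted_distance(w, target_draw[1] - test2_draw[1],
                          target_draw[2] - test2_draw[2], metric)
  if (d1 < d2) 1L
  else if (d2 < d1) 2L
  else if (runif(1) < 0.5) 1L else 2L
}

metric_code <- function(metric) {
  switch(metric, euclidean = 0L, cityblock = 1L,
         stopf("unknown metric '%s'", metric))
}
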
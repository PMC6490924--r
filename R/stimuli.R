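#' Nominal stimulus levels and stimulus pairs
#'
#' Test objects live on a 7 x 7 design grid of nominal (color, material)
#' integer levels in -3..+3; the target object sits at (0, 0). Color levels
#' run from greenest (-3) to bluest (+3), material levels from glossiest
#' (-3) to most matte (+3).
#'
#' @param color,material integer levels in -3..+3
#' @return `nominal_stimulus()` returns a named list with fields `color`
#'   and `material`.
#' @examples
#' nominal_stimulus(2, -1)
#' nrow(pair_table(3))  # 1176 unordered test pairs over the full range
#' @export
nominal_stimulus <- function(color, material) {
  check_level(color, "color")
  check_level(material, "material")
  structure(list(color = as.integer(color), material = as.integer(material)),
            class = "cm_stimulus")
}

check_level <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || abs(x) > 3)
    stopf("%s level must be a single integer in [-3, 3], got %s",
          what, paste(format(x), collapse = ","))
  invisible(TRUE)
}

#' @rdname nominal_stimulus
#' @param range integer stimulus range r; levels run -r..+r
#' @return `stimulus_set()` returns a data frame of the (2r+1)^2 stimuli,
#'   sorted by (color, material).
#' @export
stimulus_set <- function(range = 3) {
  stopifnot(range %in% 1:3)
  lev <- seq.int(-range, range)
  grid <- expand.grid(material = lev, color = lev)[, c("color", "material")]
  grid <- grid[order(grid$color, grid$material), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' @rdname nominal_stimulus
#' @return `pair_table()` returns a data frame of all unordered pairs of
#'   distinct stimuli in the range, one row per pair, sorted
#'   lexicographically by nominal levels (columns `c1`, `m1`, `c2`, `m2`).
#' @export
pair_table <- function(range = 3) {
  s <- stimulus_set(range)
  n <- nrow(s)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(c1 = s$color[i], m1 = s$material[i],
             c2 = s$color[j], m2 = s$material[j])
}
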
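#' Positional mappings from nominal levels to perceptual positions
#'
#' A positional mapping links nominal stimulus levels (-3..+3) to mean
#' perceptual positions, expressed in units of the representational noise
#' standard deviation (fixed at 1). Four variants are supported:
#' polynomials through the origin of degree 1-3 (`"linear"`, `"quadratic"`,
#' `"cubic"`, with 1, 2 and 3 coefficients per dimension) and a `"full"`
#' variant that stores one free perceptual position per non-target level
#' (6 per dimension, given in increasing level order -3,-2,-1,+1,+2,+3).
#' No affine term is included, so level 0 (the target) always maps to
#' position 0. Valid mappings are strictly increasing over the 7 design
#' levels with adjacent positions separated by at least
#' `cm_conventions()$min_spacing` and bounded by
#' `cm_conventions()$position_bound`.
#'
#' @param variant one of `"linear"`, `"quadratic"`, `"cubic"`, `"full"`
#' @param color_params,material_params numeric coefficient vectors (length
#'   1, 2, 3 or 6 according to the variant)
#' @return an object of class `cm_mapping`
#' @examples
#' m <- positional_mapping("linear", 1, 1)
#' map_positions(m, -3:3, "color")
#' @export
positional_mapping <- function(variant = c("linear", "quadratic", "cubic", "full"),
                               color_params, material_params) {
  variant <- match.arg(variant)
  k <- mapping_arity(variant)
  if (length(color_params) != k || length(material_params) != k)
    stopf("variant '%s' needs %d parameters per dimension (got %d color, %d material)",
          variant, k, length(color_params), length(material_params))
  structure(list(variant = variant,
                 color = as.numeric(color_params),
                 material = as.numeric(material_params)),
            class = "cm_mapping")
}

mapping_arity <- function(variant) {
  switch(variant, linear = 1L, quadratic = 2L, cubic = 3L, full = 6L,
         stopf("unknown variant '%s'", variant))
}

#' Model conventions (fixed constants)
#'
#' The perceptual-space conventions that set the model's origin and scale:
#' unit Gaussian noise SD per dimension, perceptual positions restricted to
#' +/- 20, and a minimum spacing of 0.25 (a quarter of the noise SD)
#' between adjacent stimulus positions. These are conventions, not
#' fittable parameters.
#'
#' @return a list with `noise_sd`, `position_bound`, `min_spacing`
#' @export
cm_conventions <- function() {
  list(noise_sd = 1.0, position_bound = 20.0, min_spacing = 0.25)
}

#' Map nominal levels to perceptual positions for one dimension
#'
#' @param mapping a [positional_mapping()]
#' @param levels integer nominal levels in -3..+3
#' @param dimension `"color"` or `"material"`
#' @param validate check monotonicity/spacing/bounds over the 7 design
#'   levels and error if violated
#' @return numeric perceptual positions, one per level; level 0 maps to 0
#' @export
map_positions <- function(mapping, levels, dimension = c("color", "material"),
                          validate = TRUE) {
  dimension <- match.arg(dimension)
  if (any(!is.finite(levels)) || any(levels != round(levels)) || any(abs(levels) > 3))
    stopf("levels must be integers in [-3, 3]")
  if (validate) validate_mapping(mapping, dimension = dimension)
  eval_mapping(mapping[[dimension]], mapping$variant, levels)
}

eval_mapping <- function(params, variant, levels) {
  if (variant == "full") {
    pos7 <- c(params[1:3], 0, params[4:6])
    pos7[levels + 4L]
  } else {
    p <- c(params, rep(0, 3 - length(params)))
    p[1] * levels + p[2] * levels^2 + p[3] * levels^3
  }
}

# positions at all 7 design levels for one dimension, no validation
positions7 <- function(params, variant) eval_mapping(params, variant, -3:3)

#' Validate a positional mapping against the model constraints
#'
#' Checks, over the 7 design levels, that implied positions are strictly
#' increasing, that adjacent positions are separated by at least the
#' minimum spacing, and that all positions lie within the position bound.
#'
#' @inheritParams map_positions
#' @param dimension which dimension(s) to check
#' @return invisibly `TRUE`; errors naming the offending adjacent level
#'   pair otherwise
#' @export
validate_mapping <- function(mapping, dimension = c("color", "material")) {
  stopifnot(inherits(mapping, "cm_mapping"))
  conv <- cm_conventions()
  for (dim in dimension) {
    pos <- positions7(mapping[[dim]], mapping$variant)
    gaps <- diff(pos)
    bad <- which(gaps < conv$min_spacing - 1e-9)
    if (length(bad)) {
      lev <- -3:3
      stopf("%s mapping violates monotonicity/minimum spacing between levels %d and %d (gap %.4f < %.2f)",
            dim, lev[bad[1]], lev[bad[1] + 1L], gaps[bad[1]], conv$min_spacing)
    }
    if (any(abs(pos) > conv$position_bound + 1e-9)) {
      k <- which.max(abs(pos))
      stopf("%s mapping puts level %d at position %.3f, outside [-%g, %g]",
            dim, (-3:3)[k], pos[k], conv$position_bound, conv$position_bound)
    }
  }
  invisible(TRUE)
}

# total constraint violation (0 when valid), used as an optimizer penalty
mapping_violation <- function(posC, posM) {
  conv <- cm_conventions()
  v <- 0
  for (pos in list(posC, posM)) {
    v <- v + sum(pmax(conv$min_spacing - diff(pos), 0))
    v <- v + sum(pmax(abs(pos) - conv$position_bound, 0))
  }
  v
}

#' Model specification: positional variant crossed with distance metric
#'
#' @param variant positional-mapping variant
#' @param metric `"euclidean"` or `"cityblock"`
#' @return an object of class `cm_spec`
#' @examples
#' n_free_parameters(model_spec("full", "euclidean"))  # 13
#' @export
model_spec <- function(variant = c("linear", "quadratic", "cubic", "full"),
                       metric = c("euclidean", "cityblock")) {
  structure(list(variant = match.arg(variant), metric = match.arg(metric)),
            class = "cm_spec")
}

#' @rdname model_spec
#' @param spec a `cm_spec`
#' @return `n_free_parameters()`: the number of free parameters (weight
#'   plus positional parameters for both dimensions)
#' @export
n_free_parameters <- function(spec) {
  1L + 2L * mapping_arity(spec$variant)
}

#' @export
print.cm_mapping <- function(x, ...) {
  cat("Positional mapping (", x$variant, ")\n", sep = "")
  cat("  color:   ", paste(format(x$color, digits = 4), collapse = " "), "\n")
  cat("  material:", paste(format(x$material, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.cm_spec <- function(x, ...) {
  cat("Model spec:", x$variant, "positions,", x$metric, "metric\n")
  invisible(x)
}
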
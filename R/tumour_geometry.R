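#' Lesion volume under a three-dimensional shape assumption
#'
#' Converts a lesion's two mammographic dimensions into a volume. The greater
#' dimension is the "height" (diameter of the semi-major axis); the lesser is
#' the diameter of the semi-minor axis. Three shape assumptions are
#' supported:
#' \describe{
#'   \item{sphere}{\eqn{V = (\pi/6)\,\bar d^3} where \eqn{\bar d} is a single
#'     representative diameter derived from the two dimensions via
#'     \code{sphere_rule} (default: arithmetic mean).}
#'   \item{cylinder}{\eqn{V = \pi (d_{minor}/2)^2 d_{major}} — radius from
#'     the minor dimension, height the major dimension.}
#'   \item{oblate_spheroid}{\eqn{V = (4/3)\pi (d_{major}/2)^2 (d_{minor}/2)}
#'     — equatorial semi-axis used twice, polar semi-axis from the minor
#'     dimension.}
#' }
#'
#' @param dim_major,dim_minor Lesion dimensions in mm; vectors recycle.
#'   Must satisfy \code{dim_major >= dim_minor > 0}.
#' @param shape One of \code{"sphere"}, \code{"cylinder"},
#'   \code{"oblate_spheroid"}.
#' @param sphere_rule Diameter rule for the sphere: \code{"mean"} (default),
#'   \code{"major"}, \code{"minor"} or \code{"geometric_mean"}.
#' @return Volume(s) in mm^3.
#' @examples
#' lesion_volume(20, 10, "sphere")          # (pi/6) * 15^3
#' lesion_volume(20, 10, "cylinder")        # pi * 5^2 * 20
#' lesion_volume(20, 10, "oblate_spheroid") # (4/3) * pi * 10^2 * 5
#' @export
lesion_volume <- function(dim_major, dim_minor,
                          shape = c("sphere", "cylinder", "oblate_spheroid"),
                          sphere_rule = c("mean", "major", "minor",
                                          "geometric_mean")) {
  shape <- match.arg(shape)
  sphere_rule <- match.arg(sphere_rule)
  if (any(is.na(dim_major)) || any(is.na(dim_minor))) {
    stop("dimensions must be non-missing", call. = FALSE)
  }
  if (any(dim_major <= 0) || any(dim_minor <= 0)) {
    stop("dimensions must be positive", call. = FALSE)
  }
  if (any(dim_major < dim_minor)) {
    stop("dim_major must be >= dim_minor", call. = FALSE)
  }
  switch(shape,
    sphere = {
      d <- switch(sphere_rule,
                  mean = (dim_major + dim_minor) / 2,
                  major = dim_major + 0 * dim_minor,
                  minor = dim_minor + 0 * dim_major,
                  geometric_mean = sqrt(dim_major * dim_minor))
      pi / 6 * d^3
    },
    cylinder = pi * (dim_minor / 2)^2 * dim_major,
    oblate_spheroid = 4 / 3 * pi * (dim_major / 2)^2 * (dim_minor / 2)
  )
}

#' Back-compute a dimension pair from a volume and aspect ratio
#'
#' The inverse of \code{\link{lesion_volume}} given the aspect ratio
#' \code{a = dim_major / dim_minor >= 1}. Used by the synthetic cohort
#' generator so that the geometry stage is exercised nontrivially.
#'
#' @param volume Volume(s) in mm^3, positive.
#' @param aspect Aspect ratio(s) \code{>= 1}.
#' @inheritParams lesion_volume
#' @return A list with vectors \code{dim_major}, \code{dim_minor} satisfying
#'   \code{lesion_volume(dim_major, dim_minor, shape, sphere_rule) == volume}.
#' @export
dims_from_volume <- function(volume, aspect,
                             shape = c("sphere", "cylinder",
                                       "oblate_spheroid"),
                             sphere_rule = c("mean", "major", "minor",
                                             "geometric_mean")) {
  shape <- match.arg(shape)
  sphere_rule <- match.arg(sphere_rule)
  stopifnot(all(volume > 0), all(aspect >= 1))
  a <- aspect
  switch(shape,
    sphere = {
      d <- (6 * volume / pi)^(1 / 3)
      minor <- switch(sphere_rule,
                      mean = 2 * d / (1 + a),
                      major = d / a,
                      minor = d + 0 * a,
                      geometric_mean = d / sqrt(a))
      list(dim_major = a * minor, dim_minor = minor)
    },
    cylinder = {
      minor <- (4 * volume / (pi * a))^(1 / 3)
      list(dim_major = a * minor, dim_minor = minor)
    },
    oblate_spheroid = {
      minor <- (6 * volume / (pi * a^2))^(1 / 3)
      list(dim_major = a * minor, dim_minor = minor)
    }
  )
}
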
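# Binary level-set machinery shared by all evolutions.
#
# Convention used everywhere in this package: phi < 0 inside the contour,
# phi > 0 outside, phi = 0 on the contour; phi = 0 is counted as interior so
# that region area equals count(phi <= 0) unambiguously. Between evolution
# steps the field is kept near binary (+/-1) by reaction-diffusion
# regularisation rather than signed-distance re-initialisation.

#' Seed region constructors
#'
#' A seed region is the user's initial closed region C0: an ellipse
#' (`center`, `radii`) or an axis-aligned rectangle (`center`, `extents` =
#' half-widths), in 0-free 1-based `(row, col)` pixel coordinates internally;
#' the JSON interface ([load_seeds()]) is 0-based.
#'
#' @param center `c(row, col)` centre in pixels.
#' @param radii `c(row_semi_axis, col_semi_axis)` for ellipses.
#' @param extents `c(row_half_width, col_half_width)` for rectangles.
#' @return A `"seed_region"` list.
#' @export
seed_ellipse <- function(center, radii) {
  stopifnot(length(center) == 2, length(radii) == 2, all(radii > 0))
  structure(list(type = "ellipse", center = center, radii = radii),
            class = "seed_region")
}

#' @rdname seed_ellipse
#' @export
seed_rectangle <- function(center, extents) {
  stopifnot(length(center) == 2, length(extents) == 2, all(extents > 0))
  structure(list(type = "rectangle", center = center, extents = extents),
            class = "seed_region")
}

# Rasterise a list of seed regions to a logical union mask (clipped to frame).
seeds_to_mask <- function(seeds, dim_out) {
  stopifnot(length(seeds) >= 1)
  nr <- dim_out[1]
  nc <- dim_out[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- matrix(FALSE, nr, nc)
  for (s in seeds) {
    stopifnot(inherits(s, "seed_region"))
    if (s$type == "ellipse") {
      mask <- mask | (((rr - s$center[1]) / s$radii[1])^2 +
                        ((cc - s$center[2]) / s$radii[2])^2 <= 1)
    } else {
      mask <- mask | (abs(rr - s$center[1]) <= s$extents[1] &
                        abs(cc - s$center[2]) <= s$extents[2])
    }
  }
  if (!any(mask)) stop("seed regions rasterise to an empty mask")
  mask
}

#' Initialise a binary level set from seed regions
#'
#' Returns the field that is -1 on the union of the seed regions and +1
#' elsewhere. Several seeds may be given to segment multiple lesions under
#' one shared level set.
#'
#' @param seeds Non-empty list of [seed_ellipse()] / [seed_rectangle()]
#'   regions.
#' @param dim_out `c(rows, cols)` of the target image.
#' @return Numeric matrix with values in `{-1, +1}`.
#' @export
init_level_set <- function(seeds, dim_out) {
  if (length(seeds) == 0) stop("at least one seed region is required")
  mask <- seeds_to_mask(seeds, dim_out)
  matrix(1, dim_out[1], dim_out[2]) - 2 * mask
}

#' Heaviside indicator of the interior
#'
#' `H = 1` where `phi <= 0` (interior, the boundary pixel set counted as
#' interior) and 0 where `phi > 0`.
#'
#' @param phi Level-set matrix.
#' @return `{0,1}` matrix.
#' @export
heaviside <- function(phi) {
  (phi <= 0) * 1
}

#' Curvature of the level-set interface
#'
#' Computes `div(grad phi / |grad phi|)` by central differences on the unit
#' grid with replicate boundaries; the gradient magnitude is floored at
#' `eps` so flat regions of the near-binary field stay finite.
#'
#' @param phi Level-set matrix.
#' @param eps Gradient-magnitude floor (default 1e-8).
#' @return Curvature matrix (finite everywhere).
#' @export
curvature <- function(phi, eps = 1e-8) {
  gx <- grad_x(phi)
  gy <- grad_y(phi)
  mag <- pmax(sqrt(gx^2 + gy^2), eps)
  nx <- gx / mag
  ny <- gy / mag
  grad_x(nx) + grad_y(ny)
}

#' Contour length and interior area of a level set
#'
#' `contour_length` is the discrete total variation of the Heaviside field,
#' `sum(|grad H(phi)|)` with central differences; `region_area` is the exact
#' interior pixel count `sum(phi <= 0)`. Both feed the convergence
#' criterion on error length and error area.
#'
#' @param phi Level-set matrix.
#' @return Nonnegative scalar.
#' @export
contour_length <- function(phi) {
  h <- heaviside(phi)
  sum(sqrt(grad_x(h)^2 + grad_y(h)^2))
}

#' @rdname contour_length
#' @export
region_area <- function(phi) {
  sum(phi <= 0)
}

#' Reaction-diffusion regularisation of a binary level set
#'
#' One regularisation pass per evolution step: binarise by sign
#' (`phi > 0 -> +1`, else `-1`), then one explicit diffusion step
#' `phi + coef * Lap(phi)` with the 5-point Laplacian and Neumann
#' boundaries. This keeps the front at a fixed profile without
#' signed-distance re-initialisation; a pixel whose 4-neighbourhood is
#' sign-uniform never flips.
#'
#' @param phi Level-set matrix.
#' @param coef Diffusion coefficient (default 0.2).
#' @return Regularised matrix with values in `[-1, 1]`.
#' @export
rd_regularize <- function(phi, coef = 0.2) {
  b <- ifelse(phi > 0, 1, -1)
  b + coef * laplacian5(b)
}
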
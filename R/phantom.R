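#' Specify a synthetic ultrasound phantom
#'
#' Describes a speckled test image with one or more hypoechoic (or
#' hyperechoic) lesions of known ground truth. Speckle follows the additive
#' transformed model `g = f + h * w`: a clean piecewise-constant image `f`
#' plus Gaussian white noise `w` convolved with a Gaussian point-spread
#' function `h`, which gives the noise the short-range spatial correlation
#' characteristic of ultrasound grain.
#'
#' @param height,width Image size in pixels.
#' @param lesions List of lesion descriptors; each a list with `center`
#'   (`c(row, col)`), `radii` (`c(row_semi_axis, col_semi_axis)` in pixels,
#'   both >= 2), `amplitude` (boundary perturbation amplitude in pixels,
#'   strictly less than the smaller semi-axis) and `rotation` (radians).
#'   Lesion boundaries are ellipses whose polar radius is perturbed by a
#'   truncated Fourier series (harmonics 2..5), giving the irregular margins
#'   typical of suspicious lesions.
#' @param background,lesion_level Intensities in `[0, 1]`; must differ.
#' @param psf_sigma Standard deviation (pixels) of the Gaussian point-spread
#'   function applied to the noise field.
#' @param noise_sigma Standard deviation of the white noise before the PSF
#'   (intensity units); 0 gives a noiseless two-valued image. The default
#'   0.5 leaves post-PSF speckle of sd about 0.09, roughly a third of the
#'   default lesion contrast — strong, visually ultrasound-like grain.
#' @param inhomogeneity Amplitude of a smooth diagonal intensity ramp added
#'   to the clean image (intensity units), emulating depth-dependent gain.
#' @param seed Integer; identical `(spec, seed)` pairs give bit-identical
#'   phantoms.
#'
#' @return An object of class `"phantom_spec"`.
#' @seealso [make_lesion_mask()], [render_phantom()], [make_dataset()]
#' @export
#' @examples
#' spec <- phantom_spec(seed = 7)
#' mask <- make_lesion_mask(spec)
#' img <- render_phantom(mask, spec)
phantom_spec <- function(height = 128, width = 128,
                         lesions = list(list(center = c(64, 64),
                                             radii = c(20, 16),
                                             amplitude = 2,
                                             rotation = 0)),
                         background = 0.55, lesion_level = 0.25,
                         psf_sigma = 1.5, noise_sigma = 0.5,
                         inhomogeneity = 0, seed = 1L) {
  stopifnot(height >= 8, width >= 8, length(lesions) >= 1)
  if (background == lesion_level) {
    stop("background and lesion_level must differ (no contrast)")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  for (les in lesions) {
    stopifnot(length(les$center) == 2, length(les$radii) == 2)
    if (any(les$radii < 2)) stop("lesion radii must be >= 2 px")
    amp <- if (is.null(les$amplitude)) 0 else les$amplitude
    if (amp >= min(les$radii)) {
      stop("boundary perturbation amplitude must be < min lesion radius")
    }
    reach <- max(les$radii) + amp
    if (les$center[1] - reach < 1 || les$center[1] + reach > height ||
        les$center[2] - reach < 1 || les$center[2] + reach > width) {
      stop("lesion exceeds the image frame (geometry error)")
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 lesions = lesions, background = background,
                 lesion_level = lesion_level, psf_sigma = psf_sigma,
                 noise_sigma = noise_sigma, inhomogeneity = inhomogeneity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Ground-truth lesion mask of a phantom
#'
#' Rasterises the union of the spec's lesions as a `{0,1}` matrix. Each
#' lesion is star-shaped about its centre (an ellipse whose polar radius
#' carries a seeded harmonic perturbation), so every lesion yields one
#' connected component.
#'
#' @param spec A [phantom_spec()].
#' @return Numeric `{0,1}` matrix of size `height x width`.
#' @export
make_lesion_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- matrix(0, spec$height, spec$width)
  rr <- matrix(seq_len(spec$height), spec$height, spec$width)
  cc <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  harmonics <- 2:5
  coefs <- with_seed(spec$seed, lapply(seq_along(spec$lesions), function(i) {
    list(a = runif(length(harmonics)), phase = runif(length(harmonics), 0, 2 * pi))
  }))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    amp <- if (is.null(les$amplitude)) 0 else les$amplitude
    rot <- if (is.null(les$rotation)) 0 else les$rotation
    dr <- rr - les$center[1]
    dc <- cc - les$center[2]
    # rotate into the lesion frame
    u <- dc * cos(rot) + dr * sin(rot)
    v <- -dc * sin(rot) + dr * cos(rot)
    theta <- atan2(v, u)
    dist <- sqrt(u^2 + v^2)
    a <- les$radii[2] # semi-axis along u (columns)
    b <- les$radii[1] # semi-axis along v (rows)
    r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    if (amp > 0) {
      w <- coefs[[i]]$a
      w <- amp * w / sum(w) # sum of |coefficients| = amplitude, so |perturb| <= amplitude
      perturb <- matrix(0, spec$height, spec$width)
      for (k in seq_along(harmonics)) {
        perturb <- perturb + w[k] * cos(harmonics[k] * theta + coefs[[i]]$phase[k])
      }
      r_ell <- r_ell + perturb
    }
    mask[dist <= r_ell] <- 1
  }
  mask
}

#' Render a speckled phantom image from its mask
#'
#' Builds the clean image `f` (lesion level inside the mask, background
#' outside, plus an optional smooth inhomogeneity ramp) and adds
#' PSF-convolved Gaussian white noise, clipping to `[0, 1]`.
#'
#' @param mask `{0,1}` lesion mask, same size as the spec.
#' @param spec A [phantom_spec()].
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_phantom <- function(mask, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!all(dim(mask) == c(spec$height, spec$width))) {
    stop("mask and spec shapes disagree")
  }
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  f <- spec$background + (spec$lesion_level - spec$background) * mask
  if (spec$inhomogeneity != 0) {
    rr <- matrix(seq_len(spec$height), spec$height, spec$width)
    cc <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
    ramp <- (rr - (spec$height + 1) / 2) / spec$height +
      (cc - (spec$width + 1) / 2) / spec$width
    f <- f + spec$inhomogeneity * ramp
  }
  if (spec$noise_sigma == 0) return(clamp01(f))
  w <- with_seed(spec$seed + 1L, matrix(
    stats::rnorm(spec$height * spec$width, 0, spec$noise_sigma),
    spec$height, spec$width))
  speckle <- gaussian_blur(w, spec$psf_sigma)
  clamp01(f + speckle)
}

#' Generate a reproducible suite of phantoms
#'
#' Produces `n` phantoms by jittering the base spec's lesion position, size,
#' rotation and contrast, with one derived seed per item so any element of
#' the suite is reproducible from `(base_spec, seed)` alone.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_spec Base [phantom_spec()]; its first lesion is jittered.
#' @param seed Master seed for the suite.
#' @return List of `n` elements, each
#'   `list(image, mask, spec)`.
#' @export
make_dataset <- function(n, base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    item_seed <- as.integer((seed + 7919 * i) %% 2147483647)
    jit <- with_seed(item_seed + 2L, list(
      dc = round(stats::runif(2, -6, 6)),
      scale = stats::runif(1, 0.8, 1.2),
      rot = stats::runif(1, 0, pi),
      dlevel = stats::runif(1, -0.05, 0.05)
    ))
    lesions <- base_spec$lesions
    lesions[[1]]$center <- lesions[[1]]$center + jit$dc
    lesions[[1]]$radii <- pmax(lesions[[1]]$radii * jit$scale, 2)
    lesions[[1]]$rotation <- jit$rot
    spec <- phantom_spec(height = base_spec$height, width = base_spec$width,
                         lesions = lesions,
                         background = base_spec$background,
                         lesion_level = clamp01(base_spec$lesion_level + jit$dlevel),
                         psf_sigma = base_spec$psf_sigma,
                         noise_sigma = base_spec$noise_sigma,
                         inhomogeneity = base_spec$inhomogeneity,
                         seed = item_seed)
    mask <- make_lesion_mask(spec)
    list(image = render_phantom(mask, spec), mask = mask, spec = spec)
  })
}
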
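# Region-based global evolutions: original two-phase piecewise-constant
# model, its simplified threshold form, and the binary stopping function
# generated from the converged global field.

#' Interior/exterior mean intensities
#'
#' `c1` is the exact mean of the image over the interior (`phi <= 0`),
#' `c2` over the exterior. Both regions must be nonempty.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param phi Level-set matrix of the same shape.
#' @return `list(c1 =, c2 =)`.
#' @export
region_means <- function(image, phi) {
  stopifnot(all(dim(image) == dim(phi)))
  inside <- phi <= 0
  if (!any(inside)) stop("degenerate region: interior (phi <= 0) is empty")
  if (all(inside)) stop("degenerate region: exterior (phi > 0) is empty")
  list(c1 = mean(image[inside]), c2 = mean(image[!inside]))
}

#' Parameters for the global region-based evolutions
#'
#' @param mu,lambda1,lambda2 Nonnegative weights of the original model
#'   (curvature, interior fit, exterior fit). The simplified model fixes
#'   all three at 1 implicitly.
#' @param dt Explicit time step. Because the level set is re-binarised
#'   every iteration, a front pixel advances only when one step's update
#'   crosses zero; with the bounded threshold force this needs a step
#'   around 10 on unit-contrast-scale images (see the methods vignette).
#' @param theta Convergence tolerance on error length/area (default 0).
#' @param check_interval Iterations between convergence evaluations.
#' @param stable_checks Consecutive passing evaluations required.
#' @param max_iter Iteration cap per run.
#' @param polarity `"dark"` captures the class below the running intensity
#'   midpoint as interior (hypoechoic lesions); `"bright"` the converse.
#' @return A `"cv_params"` list.
#' @export
cv_params <- function(mu = 1, lambda1 = 1, lambda2 = 1, dt = 10,
                      theta = 0, check_interval = 10, stable_checks = 3,
                      max_iter = 2000, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(mu >= 0, lambda1 >= 0, lambda2 >= 0, dt > 0, theta >= 0,
            check_interval >= 1, stable_checks >= 1, max_iter >= 1)
  structure(list(mu = mu, lambda1 = lambda1, lambda2 = lambda2, dt = dt,
                 theta = theta, check_interval = check_interval,
                 stable_checks = stable_checks, max_iter = max_iter,
                 polarity = polarity),
            class = "cv_params")
}

#' One explicit step of the original two-phase region model
#'
#' Update `phi <- phi + dt * (lambda1 (I - c1)^2 - lambda2 (I - c2)^2) *
#' |grad phi|`, followed by reaction-diffusion regularisation. The
#' data-term sign is fixed for the interior-negative convention used
#' throughout this package: pixels closer to the interior mean are driven
#' into the interior (energy descent for the two-phase piecewise-constant
#' fit with `H = 1` on `phi <= 0`). The curvature (length-penalty) motion
#' is realised by the regularisation pass itself — on a re-binarised level
#' set, sign-thresholding followed by one diffusion step is a
#' threshold-dynamics implementation of motion by mean curvature — so no
#' explicit (and explicitly stiff) curvature term appears in the update;
#' see the methods vignette.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param phi Level-set matrix.
#' @param params A [cv_params()].
#' @return Updated level-set matrix.
#' @export
cv_step_original <- function(image, phi, params = cv_params()) {
  m <- region_means(image, phi)
  gm <- sqrt(grad_x(phi)^2 + grad_y(phi)^2)
  data_term <- normalize_force(
    params$lambda1 * (image - m$c1)^2 - params$lambda2 * (image - m$c2)^2)
  rd_regularize(phi + params$dt * data_term * gm)
}

# Scale a data-force field by its sup-norm. A positive per-iteration
# rescaling is a reparametrisation of evolution time: the sign structure
# and the fixed points of the flow are unchanged, but the explicit step
# becomes independent of the absolute image contrast (standard practice
# in this model family).
normalize_force <- function(f) {
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' One explicit step of the simplified region model
#'
#' The simplification replaces the quadratic fitting forces by the
#' intensity-threshold force `I - 0.5 (c1 + c2)`, which captures the class
#' below the running midpoint as interior (for `polarity = "dark"`;
#' negated for bright targets):
#' `phi <- phi + dt * (I - (c1 + c2)/2) * |grad phi|`, then
#' reaction-diffusion regularisation (which also carries the curvature
#' motion; see [cv_step_original()] and the methods vignette).
#'
#' @inheritParams cv_step_original
#' @return Updated level-set matrix.
#' @export
cv_step_simplified <- function(image, phi, params = cv_params()) {
  m <- region_means(image, phi)
  gm <- sqrt(grad_x(phi)^2 + grad_y(phi)^2)
  sgn <- if (params$polarity == "dark") 1 else -1
  f <- normalize_force(sgn * (image - 0.5 * (m$c1 + m$c2)))
  rd_regularize(phi + params$dt * f * gm)
}

#' Run a global region-based evolution to convergence
#'
#' Iterates [cv_step_simplified()] (or [cv_step_original()]) from the seed
#' initialisation, evaluating the error-length/error-area convergence
#' criterion every `check_interval` iterations until `stable_checks`
#' consecutive evaluations pass or `max_iter` is reached. Because the
#' threshold force depends only on the running global means, the converged
#' mask is insensitive to where the seed is placed (inside the target or
#' enclosing it).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param seeds List of seed regions (ignored when `phi0` is given).
#' @param params A [cv_params()].
#' @param model `"simplified"` (default) or `"original"`.
#' @param phi0 Optional initial level set overriding `seeds`.
#' @return `list(phi, history, converged, iterations)`; `history` is a
#'   data frame with columns `iteration`, `length`, `area`, `error_length`,
#'   `error_area`.
#' @export
run_global <- function(image, seeds, params = cv_params(),
                       model = c("simplified", "original"), phi0 = NULL) {
  model <- match.arg(model)
  phi <- if (is.null(phi0)) init_level_set(seeds, dim(image)) else phi0
  step_fun <- if (model == "simplified") cv_step_simplified else cv_step_original
  history <- data.frame(iteration = 0L,
                        length = contour_length(phi),
                        area = region_area(phi),
                        error_length = NA_real_, error_area = NA_real_)
  iter <- 0L
  converged <- FALSE
  conv <- list(theta = params$theta, check_interval = params$check_interval,
               stable_checks = params$stable_checks)
  while (iter < params$max_iter) {
    for (k in seq_len(params$check_interval)) phi <- step_fun(image, phi, params)
    iter <- iter + params$check_interval
    len <- contour_length(phi)
    area <- region_area(phi)
    prev <- history[nrow(history), ]
    history <- rbind(history, data.frame(
      iteration = iter, length = len, area = area,
      error_length = len - prev$length, error_area = area - prev$area))
    if (check_convergence(history, conv)) {
      converged <- TRUE
      break
    }
  }
  list(phi = phi, history = history, converged = converged, iterations = iter)
}

#' Binary stopping function from a converged global level set
#'
#' The converged global segmentation replaces the gradient-based edge
#' stopping function: the local evolution is allowed to move only where
#' the stopping mask is 1 and is halted where it is 0. Expanding mode
#' (seed inside the object) keeps the interior indicator `H(phi)`;
#' shrinking mode (seed enclosing the object) its complement.
#'
#' @param phi_converged Converged global level-set matrix.
#' @param mode `"expanding"` or `"shrinking"`.
#' @return `{0,1}` matrix.
#' @export
make_bsf <- function(phi_converged, mode = c("expanding", "shrinking")) {
  mode <- match.arg(mode)
  kappa <- heaviside(phi_converged)
  if (mode == "shrinking") kappa <- 1 - kappa
  if (!any(kappa == 1)) {
    stop("binary stopping function is all zero: no admissible evolution region")
  }
  kappa
}
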
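# The hybrid evolution: one PDE whose data term morphs from the global
# threshold force (alpha = 0, stopping mask = 1 everywhere) into a local
# geodesic motion confined by the binary stopping function (alpha = +/-1),
# with a single adaptive switch at the first convergence.

#' Gradient-based edge stopping function
#'
#' The conventional stopping field `g = 1 / (1 + |grad(G_sigma * I)|^2)`:
#' 1 on flat regions, small at strong edges. Kept as the baseline the
#' binary stopping function replaces; on blurry speckled images `g` is
#' rarely near zero on lesion boundaries, which is what motivates the
#' binary alternative.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param kernel_size Odd Gaussian kernel width in pixels.
#' @param sigma Gaussian standard deviation.
#' @return Matrix with values in `(0, 1]`.
#' @export
esf_g <- function(image, kernel_size = 5, sigma = 1) {
  stopifnot(kernel_size %% 2 == 1, kernel_size >= 1, sigma > 0)
  radius <- (kernel_size - 1) / 2
  sm <- if (radius >= 1) gaussian_blur(image, sigma, radius = radius) else image
  1 / (1 + grad_x(sm)^2 + grad_y(sm)^2)
}

#' One explicit step of the geodesic active contour baseline
#'
#' `phi <- phi + dt * (grad g . n + v g) |grad phi|` with
#' `n = grad phi / |grad phi|`, then reaction-diffusion regularisation.
#' The `grad g . n` part is the edge-attraction component of `div(g n)`;
#' its curvature component `g curv` is realised by the regularisation
#' pass (threshold dynamics), as in every evolution of this package.
#' `v > 0` shrinks the interior, `v < 0` expands it.
#'
#' @param image Image matrix (unused by the update itself; kept for a
#'   uniform step signature).
#' @param phi Level-set matrix.
#' @param stopping Nonnegative stopping field (e.g. [esf_g()] output or a
#'   binary stopping mask).
#' @param v Constant speed, nonzero.
#' @param dt Time step (default 1, the local-phase regime: the forces are
#'   O(`v`)).
#' @param eps Gradient-magnitude floor.
#' @return Updated level-set matrix.
#' @export
gac_step <- function(image, phi, stopping, v, dt = 1, eps = 1e-8) {
  stopifnot(all(stopping >= 0), v != 0)
  gx <- grad_x(phi)
  gy <- grad_y(phi)
  gm <- sqrt(gx^2 + gy^2)
  magf <- pmax(gm, eps)
  nx <- gx / magf
  ny <- gy / magf
  rhs <- (grad_x(stopping) * nx + grad_y(stopping) * ny + v * stopping) * gm
  rd_regularize(phi + dt * rhs)
}

#' Infer the local-phase mode from the seed and the converged global field
#'
#' Evaluates the converged global level set on the boundary pixels of the
#' initial seed region C0. A negative sum means the seed boundary lies in
#' the converged interior, so C0 sits inside the object and the local
#' phase expands (`-1`); a positive sum means C0 encloses the object from
#' the background and the local phase shrinks (`+1`). An exact zero sum is
#' ambiguous and rejected.
#'
#' @param phi_converged Converged global level-set matrix.
#' @param seeds The original seed regions.
#' @return `-1` (expanding) or `+1` (shrinking).
#' @export
infer_alpha <- function(phi_converged, seeds) {
  mask <- seeds_to_mask(seeds, dim(phi_converged))
  boundary <- mask & !erode4(mask)
  s <- sum(phi_converged[boundary])
  if (s < 0) return(-1)
  if (s > 0) return(1)
  stop("ambiguous evolution mode: seed boundary sum is exactly zero; ",
       "place the seed clearly inside or clearly around the target")
}

#' Convergence check on contour length and interior area
#'
#' The evolution is converged when the absolute change in contour length
#' AND in interior area between consecutive evaluations is at most `theta`
#' for the last `stable_checks` evaluations of the current phase (rows
#' sharing the final `alpha` when that column is present).
#'
#' @param history Data frame with columns `length` and `area` (one row per
#'   evaluation; at least 2 rows), optionally `alpha`.
#' @param params List with `theta`, `stable_checks` (and, for
#'   documentation, `check_interval`).
#' @return Logical.
#' @export
check_convergence <- function(history, params) {
  stopifnot(nrow(history) >= 2)
  if (!is.null(history$alpha)) {
    history <- history[history$alpha == history$alpha[nrow(history)], ,
                       drop = FALSE]
  }
  if (nrow(history) < params$stable_checks + 1) return(FALSE)
  dl <- diff(history$length)
  da <- diff(history$area)
  k <- params$stable_checks
  all(abs(utils::tail(dl, k)) <= params$theta) &&
    all(abs(utils::tail(da, k)) <= params$theta)
}

#' Control parameters for the hybrid segmentation
#'
#' Collects every tunable of the pipeline. Defaults are the package's
#' working configuration for `[0, 1]`-normalised images; see the methods
#' vignette for the reasoning behind each value.
#'
#' @param sigma_s,sigma_i,window_radius Bilateral-filter parameters
#'   ([bilateral_filter()]); `window_radius = NULL` means
#'   `ceiling(3 * sigma_s)`.
#' @param dt Explicit time step of the global phase (default 10; see
#'   [cv_params()] for why the re-binarised scheme needs a large step for
#'   the bounded threshold force).
#' @param dt_local Time step of the local phase (default 1). The local
#'   forces are O(1) (unit stopping-mask speed) where the global threshold
#'   force is O(contrast/2), so the two phases need different steps for
#'   the front to advance pixel-by-pixel yet halt exactly at the stopping
#'   boundary; see the methods vignette.
#' @param theta Convergence tolerance on error length/area (default 0:
#'   both quantities are integer-valued or half-integer-valued on the
#'   binarised field, so exact stasis is attainable).
#' @param check_interval Iterations between convergence evaluations
#'   (default 10).
#' @param stable_checks Consecutive passing evaluations required
#'   (default 3), guarding against declaring convergence mid-oscillation.
#' @param max_iter Iteration cap per phase (default 2000).
#' @param polarity `"dark"` (hypoechoic target, default) or `"bright"`.
#' @param rd_coef Reaction-diffusion coefficient (0.2).
#' @param use_bf Apply the bilateral filter before evolving (default TRUE;
#'   FALSE gives the hybrid-evolution-only ablation).
#' @param seed Seed for any randomised fixture driven from a config file.
#' @return An `"acbf_control"` list.
#' @export
acbf_control <- function(sigma_s = 3, sigma_i = 0.1, window_radius = NULL,
                         dt = 10, dt_local = 1, theta = 0, check_interval = 10,
                         stable_checks = 3, max_iter = 2000,
                         polarity = c("dark", "bright"), rd_coef = 0.2,
                         use_bf = TRUE, seed = 1L) {
  polarity <- match.arg(polarity)
  if (is.null(window_radius)) window_radius <- ceiling(3 * sigma_s)
  stopifnot(sigma_s > 0, sigma_i > 0, window_radius >= 1, dt > 0,
            dt_local > 0, theta >= 0, check_interval >= 1, stable_checks >= 1,
            max_iter >= 1, rd_coef >= 0, is.logical(use_bf))
  structure(list(sigma_s = sigma_s, sigma_i = sigma_i,
                 window_radius = as.integer(window_radius), dt = dt,
                 dt_local = dt_local,
                 theta = theta, check_interval = as.integer(check_interval),
                 stable_checks = as.integer(stable_checks),
                 max_iter = as.integer(max_iter), polarity = polarity,
                 rd_coef = rd_coef, use_bf = use_bf, seed = as.integer(seed)),
            class = "acbf_control")
}

# Fresh evolution state: all-ones stopping mask and alpha = 0 (global phase).
new_evolution_state <- function(phi) {
  list(phi = phi, kappa = matrix(1, nrow(phi), ncol(phi)), alpha = 0,
       iteration = 0L,
       history = data.frame(iteration = integer(), length = double(),
                            area = double(), error_length = double(),
                            error_area = double(), alpha = double()))
}

#' One explicit step of the hybrid evolution
#'
#' Evaluates `phi <- phi + dt * ((1 - |alpha|) * (I_BF - (c1 + c2)/2) +
#' alpha * kappa) * |grad phi|` followed by reaction-diffusion
#' regularisation. With `alpha = 0` and `kappa = 1` this is exactly the
#' simplified global step; with `alpha = +/-1` the threshold force
#' vanishes and the signed binary stopping mask drives local motion at
#' unit speed where `kappa = 1` and exactly zero speed where `kappa = 0`,
#' so the front halts precisely at the stopping boundary. The curvature
#' motion of the stopping-weighted divergence term is carried by the
#' regularisation pass (threshold dynamics); the edge-alignment component
#' `grad kappa . n` is identically zero away from the mask edge and, on a
#' pixel-aligned binary mask, has no alignment left to perform — see the
#' methods vignette for why it is therefore omitted.
#'
#' @param image_bf Bilateral-filtered image (or the raw image in the
#'   no-filter ablation).
#' @param state Evolution state list with at least `phi`, `kappa`,
#'   `alpha`, `iteration`.
#' @param dt Time step.
#' @param polarity `"dark"` or `"bright"` (global-phase data term sign).
#' @param rd_coef Reaction-diffusion coefficient.
#' @return The state with `phi` updated and `iteration` incremented.
#' @export
acbf_step <- function(image_bf, state, dt = 10,
                      polarity = "dark", rd_coef = 0.2) {
  phi <- state$phi
  alpha <- state$alpha
  gm <- sqrt(grad_x(phi)^2 + grad_y(phi)^2)
  if (abs(alpha) != 1) {
    m <- region_means(image_bf, phi)
    sgn <- if (polarity == "dark") 1 else -1
    f <- normalize_force(sgn * (image_bf - 0.5 * (m$c1 + m$c2)))
    rhs <- (1 - abs(alpha)) * f * gm
  } else {
    rhs <- 0
  }
  if (alpha != 0) rhs <- rhs + alpha * state$kappa * gm
  state$phi <- rd_regularize(phi + dt * rhs, rd_coef)
  state$iteration <- state$iteration + 1L
  state
}

#' Hybrid active contour segmentation with bilateral filtering
#'
#' The full pipeline: (1) bilateral-filter the image; (2) initialise a
#' binary level set from the seed regions with an all-ones stopping mask
#' and `alpha = 0`; (3) evolve the hybrid update, regularising each
#' iteration and checking the error-length/error-area criterion; (4) at
#' the first convergence, manufacture the binary stopping function from
#' the converged global field, infer the local mode from the seed
#' boundary, re-initialise the front at the seed, and continue locally;
#' (5) stop at the second convergence. The returned object records the
#' final mask, both stopping data and the complete iteration history with
#' its single global-to-local switch.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param seeds List of [seed_ellipse()] / [seed_rectangle()] regions (one
#'   or more; several seeds segment multiple lesions under one level set).
#' @param control An [acbf_control()].
#' @param truth Optional `{0,1}` ground-truth mask; if given, the Dice
#'   coefficient is stored on the result.
#' @return An object of class `"acbf"`: a list with `mask` (final interior
#'   as `{0,1}`), `phi`, `kappa`, `alpha`, `mode`, `history`, `converged`,
#'   `iterations`, `image`, `image_bf`, `seeds`, `control`, `dice`
#'   (or `NA`), `call`.
#' @export
#' @examples
#' spec <- phantom_spec(height = 64, width = 64,
#'                      lesions = list(list(center = c(32, 32),
#'                                          radii = c(14, 11),
#'                                          amplitude = 0, rotation = 0)),
#'                      noise_sigma = 0, seed = 3)
#' truth <- make_lesion_mask(spec)
#' img <- render_phantom(truth, spec)
#' fit <- acbf(img, list(seed_ellipse(c(32, 32), c(8, 8))),
#'             control = acbf_control(use_bf = FALSE), truth = truth)
#' fit
acbf <- function(image, seeds, control = acbf_control(), truth = NULL) {
  stopifnot(is.matrix(image))
  cl <- match.call()
  image_bf <- if (control$use_bf) {
    bilateral_filter(image, control$sigma_s, control$sigma_i,
                     control$window_radius)
  } else {
    image
  }
  phi0 <- init_level_set(seeds, dim(image))
  state <- new_evolution_state(phi0)
  conv <- list(theta = control$theta, check_interval = control$check_interval,
               stable_checks = control$stable_checks)

  record <- function(state) {
    len <- contour_length(state$phi)
    area <- region_area(state$phi)
    h <- state$history
    phase <- h[!is.na(h$alpha) & h$alpha == state$alpha, , drop = FALSE]
    prev <- if (nrow(phase)) phase[nrow(phase), ] else NULL
    state$history <- rbind(h, data.frame(
      iteration = state$iteration, length = len, area = area,
      error_length = if (is.null(prev)) NA_real_ else len - prev$length,
      error_area = if (is.null(prev)) NA_real_ else area - prev$area,
      alpha = state$alpha))
    state
  }

  run_phase <- function(state, dt) {
    state <- record(state)
    start_iter <- state$iteration
    converged <- FALSE
    while (state$iteration - start_iter < control$max_iter) {
      for (k in seq_len(control$check_interval)) {
        state <- acbf_step(image_bf, state, dt = dt,
                           polarity = control$polarity,
                           rd_coef = control$rd_coef)
      }
      state <- record(state)
      phase_rows <- state$history[state$history$alpha == state$alpha, ,
                                  drop = FALSE]
      if (check_convergence(phase_rows, conv)) {
        converged <- TRUE
        break
      }
    }
    list(state = state, converged = converged)
  }

  # global phase
  g <- run_phase(state, control$dt)
  state <- g$state
  phi_global <- state$phi

  mode <- NULL
  local_converged <- FALSE
  if (g$converged) {
    alpha <- infer_alpha(phi_global, seeds)
    mode <- if (alpha < 0) "expanding" else "shrinking"
    kappa <- make_bsf(phi_global, mode)
    if (all(kappa == 1)) {
      stop("degenerate global result: stopping function covers the whole ",
           "frame; the global phase found no exterior region")
    }
    # local phase restarts the front at the seed inside the stopping region
    state$phi <- phi0
    state$kappa <- kappa
    state$alpha <- alpha
    l <- run_phase(state, control$dt_local)
    state <- l$state
    local_converged <- l$converged
  } else {
    warning("global phase did not converge within max_iter; ",
            "returning the global-phase result")
  }

  mask <- heaviside(state$phi)
  dice_val <- if (!is.null(truth)) dice(mask, truth) else NA_real_
  structure(list(mask = mask, phi = state$phi, phi_global = phi_global,
                 kappa = state$kappa, alpha = state$alpha, mode = mode,
                 history = state$history,
                 converged = g$converged && local_converged,
                 global_converged = g$converged,
                 local_converged = local_converged,
                 iterations = state$iteration,
                 image = image, image_bf = image_bf, seeds = seeds,
                 control = control, dice = dice_val, call = cl),
            class = "acbf")
}
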
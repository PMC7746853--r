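#' @export
print.acbf <- function(x, ...) {
  d <- dim(x$mask)
  cat("Hybrid active contour segmentation (acbf)\n")
  cat(sprintf("  image: %d x %d, bilateral filter: %s\n", d[1], d[2],
              if (x$control$use_bf) "on" else "off"))
  sw <- which(diff(x$history$alpha) != 0)
  cat(sprintf("  mode: %s (alpha = %+d), switch at iteration %s\n",
              if (is.null(x$mode)) "none" else x$mode, as.integer(x$alpha),
              if (length(sw)) x$history$iteration[sw[1] + 1] else "none"))
  cat(sprintf("  iterations: %d, converged: %s\n", x$iterations,
              if (x$converged) "yes" else "NO"))
  cat(sprintf("  interior area: %d px, contour length: %.1f\n",
              as.integer(sum(x$mask)), contour_length(x$phi)))
  if (!is.na(x$dice)) cat(sprintf("  Dice vs ground truth: %.2f%%\n", x$dice))
  invisible(x)
}

#' Summarise a segmentation run
#'
#' @param object An `"acbf"` fit.
#' @param ... Unused.
#' @return A `"summary.acbf"` list with the final region statistics, the
#'   phase breakdown and the tail of the convergence history.
#' @export
summary.acbf <- function(object, ...) {
  h <- object$history
  global_rows <- h[h$alpha == 0, , drop = FALSE]
  local_rows <- h[h$alpha != 0, , drop = FALSE]
  means <- tryCatch(region_means(object$image_bf, object$phi),
                    error = function(e) list(c1 = NA_real_, c2 = NA_real_))
  out <- list(
    dim = dim(object$mask),
    use_bf = object$control$use_bf,
    mode = object$mode,
    alpha = object$alpha,
    converged = object$converged,
    iterations = object$iterations,
    global_iterations = if (nrow(global_rows)) max(global_rows$iteration) else 0L,
    area = sum(object$mask),
    length = contour_length(object$phi),
    c1 = means$c1, c2 = means$c2,
    dice = object$dice,
    history_tail = utils::tail(h, 4L)
  )
  class(out) <- "summary.acbf"
  out
}

#' @export
print.summary.acbf <- function(x, ...) {
  cat(sprintf("acbf segmentation of a %d x %d image (bilateral filter %s)\n",
              x$dim[1], x$dim[2], if (x$use_bf) "on" else "off"))
  cat(sprintf("  phases: global %d iterations, local %d (mode %s)\n",
              x$global_iterations, x$iterations - x$global_iterations,
              if (is.null(x$mode)) "none" else x$mode))
  cat(sprintf("  converged: %s; interior area %d px; contour length %.1f\n",
              if (x$converged) "yes" else "NO", as.integer(x$area), x$length))
  cat(sprintf("  region means: c1 = %.4f (interior), c2 = %.4f (exterior)\n",
              x$c1, x$c2))
  if (!is.na(x$dice)) cat(sprintf("  Dice vs ground truth: %.2f%%\n", x$dice))
  cat("  last convergence checks:\n")
  print(x$history_tail, row.names = FALSE)
  invisible(x)
}

#' Plot a segmentation result or its convergence history
#'
#' `which = "segmentation"` draws the (filtered) image with the final
#' zero-level contour; `which = "history"` draws the error-length and
#' error-area trends with the alpha switch.
#'
#' @param x An `"acbf"` fit.
#' @param which `"segmentation"` or `"history"`.
#' @param ... Passed to [graphics::image()] / [graphics::plot()].
#' @export
plot.acbf <- function(x, which = c("segmentation", "history"), ...) {
  which <- match.arg(which)
  if (which == "segmentation") {
    img <- x$image
    nr <- nrow(img)
    z <- t(img)[, nr:1, drop = FALSE]
    graphics::image(seq_len(ncol(img)), seq_len(nr), z,
                    col = grDevices::gray.colors(256, 0, 1),
                    asp = 1, xlab = "col", ylab = "row", ...)
    zphi <- t(x$phi)[, nr:1, drop = FALSE]
    graphics::contour(seq_len(ncol(img)), seq_len(nr), zphi, levels = 0,
                      add = TRUE, drawlabels = FALSE, col = "red", lwd = 2)
  } else {
    h <- x$history[-1, , drop = FALSE]
    ylim <- range(c(h$error_length, h$error_area, 0), na.rm = TRUE)
    graphics::plot(h$iteration, h$error_length, type = "l", col = "blue",
                   ylim = ylim, xlab = "iteration", ylab = "error", ...)
    graphics::lines(h$iteration, h$error_area, col = "red")
    sw <- which(diff(x$history$alpha) != 0)
    if (length(sw)) graphics::abline(v = x$history$iteration[sw[1] + 1],
                                     col = "darkgreen", lty = 2)
    graphics::legend("topright", c("error length", "error area", "switch"),
                     col = c("blue", "red", "darkgreen"),
                     lty = c(1, 1, 2), bty = "n")
  }
  invisible(x)
}

#' @export
fitted.acbf <- function(object, ...) object$mask
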
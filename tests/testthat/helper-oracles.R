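# Independent reference implementations used as oracles. Deliberately
# written in the most literal style possible (nested loops, no shared code
# with the package internals).

# Brute-force bilateral filter: quadruple loop over pixels x window.
naive_bilateral <- function(image, sigma_s, sigma_i, radius) {
  nr <- nrow(image)
  nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      num <- 0
      den <- 0
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          ii <- i + di
          jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2)) *
            exp(-(image[ii, jj] - image[i, j])^2 / (2 * sigma_i^2))
          num <- num + w * image[ii, jj]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Truncated-window Gaussian convolution with border renormalisation (the
# sigma_i -> Inf limit of the bilateral filter).
naive_gaussian_window <- function(image, sigma_s, radius) {
  nr <- nrow(image)
  nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      num <- 0
      den <- 0
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          ii <- i + di
          jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2))
          num <- num + w * image[ii, jj]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Count 4-connected components of a binary mask (stack-based flood fill).
count_components <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (start in which(mask)) {
    if (seen[start]) next
    n <- n + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[p]) next
      seen[p] <- TRUE
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]
        c2 <- cc + d[2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
            mask[rr, c2] && !seen[rr, c2]) {
          stack <- c(stack, (c2 - 1L) * nr + rr)
        }
      }
    }
  }
  n
}

# Independent 8-neighbour binary dilation (loops, frame-padded with 0).
dilate_once <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- i + di
          jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj]) {
            out[i, j] <- TRUE
          }
        }
      }
    }
  }
  out
}

# Replicate-padded shift (independent of the package internals).
shift_ref <- function(x, dr, dc) {
  nr <- nrow(x)
  nc <- ncol(x)
  out <- x
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- x[min(max(i + dr, 1), nr), min(max(j + dc, 1), nc)]
    }
  }
  out
}

# Convenience: a clean two-valued lesion phantom with matching seeds.
noiseless_phantom <- function(side = 64, radii = c(14, 11), seed = 3,
                              amplitude = 0) {
  spec <- phantom_spec(height = side, width = side,
                       lesions = list(list(center = c(side / 2, side / 2),
                                           radii = radii,
                                           amplitude = amplitude,
                                           rotation = 0)),
                       noise_sigma = 0, seed = seed)
  truth <- make_lesion_mask(spec)
  list(spec = spec, truth = truth, image = render_phantom(truth, spec),
       seed_inside = list(seed_ellipse(c(side / 2, side / 2), c(6, 6))),
       seed_enclosing = list(seed_ellipse(c(side / 2, side / 2),
                                          c(side / 2 - 8, side / 2 - 8))))
}
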
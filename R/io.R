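# Image, mask, seed and config I/O. Images are normalised to [0, 1] on
# load by the source bit depth; masks travel as 0/255 8-bit PNG; seeds and
# configs as JSON. Seed JSON coordinates are 0-based (row, col), origin
# top-left; they are converted to the package's 1-based convention on load.

#' Load a grayscale image as a `[0, 1]` matrix
#'
#' Supports PNG, TIFF and PGM (P2/P5). RGB(A) input is converted by Rec.
#' 709 luminance. Intensities are divided by the source bit-depth maximum
#' so the range parameter of the bilateral filter is bit-depth
#' independent.
#'
#' @param path File path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  if (length(img) == 0) stop("zero-size image: ", path)
  as.matrix(img)
}

#' Save a `[0, 1]` matrix as an 8-bit grayscale PNG
#'
#' @param image Numeric matrix; values are clipped to `[0, 1]`.
#' @param path Output path.
#' @export
save_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Save / load a binary mask as 0/255 PNG
#'
#' `save_mask` refuses non-binary input rather than thresholding
#' silently; `load_mask` refuses files holding anything but the two
#' levels.
#'
#' @param mask `{0,1}` matrix.
#' @param path File path.
#' @return `load_mask` returns a `{0,1}` matrix.
#' @export
save_mask <- function(mask, path) {
  if (!is_binary_matrix(mask)) stop("mask is not binary {0,1}; refusing to threshold")
  png::writePNG(mask + 0, path) # force double storage for writePNG
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  m <- load_image(path)
  if (!all(m %in% c(0, 1))) {
    stop("file is not a 0/255 binary mask: ", path)
  }
  m
}

# Minimal PGM reader (ascii P2 and binary P5).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated PGM header")
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("^\\s$", ch)) {
        if (nzchar(tok)) return(tok)
        next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "integer", n = n, size = 1, signed = FALSE))
    } else {
      vals <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                      endian = "big")
    }
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

# Minimal PGM writer (ascii P2), used by tests and the CLI round trip.
write_pgm <- function(image, path, maxval = 255L) {
  v <- round(clamp01(image) * maxval)
  header <- sprintf("P2\n%d %d\n%d", ncol(image), nrow(image), maxval)
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Seed region JSON I/O
#'
#' Format: `{"seeds": [{"type": "ellipse", "center": [r, c],
#' "radii": [a, b]}, ...]}` with 0-based row/col coordinates, origin
#' top-left. Rectangles use `"extents"` (half-widths) instead of
#' `"radii"`.
#'
#' @param path JSON file path.
#' @param seeds List of seed regions.
#' @return `load_seeds` returns a list of seed regions (1-based
#'   internally).
#' @export
load_seeds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$seeds) || length(obj$seeds) == 0) {
    stop("seed file holds no seeds: ", path)
  }
  lapply(obj$seeds, function(s) {
    center <- unlist(s$center) + 1 # 0-based JSON -> 1-based internal
    if (identical(s$type, "ellipse")) {
      seed_ellipse(center, unlist(s$radii))
    } else if (identical(s$type, "rectangle")) {
      seed_rectangle(center, unlist(s$extents))
    } else {
      stop("unknown seed type: ", s$type)
    }
  })
}

#' @rdname load_seeds
#' @export
save_seeds <- function(seeds, path) {
  out <- list(seeds = lapply(seeds, function(s) {
    base <- list(type = s$type, center = s$center - 1)
    if (s$type == "ellipse") base$radii <- s$radii else base$extents <- s$extents
    base
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Configuration JSON round trip
#'
#' Serialises an [acbf_control()] losslessly to JSON and back.
#'
#' @param control An [acbf_control()].
#' @param path JSON file path.
#' @return `read_config` returns an [acbf_control()].
#' @export
write_config <- function(control, path) {
  stopifnot(inherits(control, "acbf_control"))
  jsonlite::write_json(unclass(control), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(acbf_control, obj)
}
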
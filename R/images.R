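#' Grayscale image utilities
#'
#' Images are plain numeric matrices with intensities on the 0--255 scale,
#' indexed `image[y, x]` with `x` the column (rightward) and `y` the row
#' (downward), both 1-based. PNG files are read and written through the png
#' package; single-channel output is rescaled to `[0, 1]` on disk.
#'
#' @param height,width image dimensions in pixels
#' @param value fill intensity (gray level, 0--255)
#' @return `new_image()` returns a `height x width` numeric matrix.
#' @export
new_image <- function(height, width, value = 0) {
  matrix(value, nrow = height, ncol = width)
}

#' @rdname new_image
#' @param path file path of a PNG image
#' @return `read_image()` returns a grayscale matrix on the 0--255 scale;
#'   color input is collapsed with luminance weights (0.299, 0.587, 0.114).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: ", path)
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3L]
    a <- if (ch >= 3L) {
      0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    } else {
      a[, , 1L]
    }
  }
  a * 255
}

#' @rdname new_image
#' @param image numeric matrix on the 0--255 scale
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 255) / 255
  png::writePNG(img, target = path)
  invisible(path)
}

#' @rdname new_image
#' @export
image_height <- function(image) nrow(image)

#' @rdname new_image
#' @export
image_width <- function(image) ncol(image)

# Boolean pixel mask of an axis-aligned ellipse; degenerates to a disk.
mask_ellipse <- function(height, width, cx, cy, rx, ry = rx) {
  outer(((seq_len(height) - cy) / ry)^2, ((seq_len(width) - cx) / rx)^2, "+") <= 1
}

mask_disk <- function(height, width, cx, cy, r) {
  mask_ellipse(height, width, cx, cy, r, r)
}

# Paint `value` where `mask` is TRUE.
paint <- function(image, mask, value) {
  image[mask] <- value
  image
}

# Paint a band of the given half-thickness along a polyline (n x 2 matrix of
# x, y vertices). Used for eyebrows, lips and the nose ridge of the synthetic
# face; sampling step 0.4 px keeps the band gap-free.
paint_polyline <- function(image, pts, value, thickness = 2) {
  h <- nrow(image); w <- ncol(image)
  if (nrow(pts) < 2) return(image)
  samples <- do.call(rbind, lapply(seq_len(nrow(pts) - 1L), function(i) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4)))
    cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }))
  off <- expand.grid(dx = -thickness:thickness, dy = -thickness:thickness)
  off <- off[off$dx^2 + off$dy^2 <= thickness^2, , drop = FALSE]
  xs <- rep(round(samples[, 1]), each = nrow(off)) + off$dx
  ys <- rep(round(samples[, 2]), each = nrow(off)) + off$dy
  ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  image[cbind(ys[ok], xs[ok])] <- value
  image
}

# Additive Gaussian noise clipped to [0, 255]; intensities stay integral so
# rendering is bit-reproducible across platforms given the same RNG state.
add_noise <- function(image, sd) {
  if (sd <= 0) return(round(image))
  noisy <- image + rnorm(length(image), 0, sd)
  round(pmin(pmax(noisy, 0), 255))
}

# Bilinear intensity lookup at continuous coordinates, clamped to the frame.
# `x`, `y` are equal-length vectors; returns a vector of intensities.
bilinear_sample <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0, x0)]
  i01 <- image[cbind(y0, x0 + 1)]
  i10 <- image[cbind(y0 + 1, x0)]
  i11 <- image[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Nearest-pixel lookup, clamped to the frame.
nearest_sample <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  xi <- pmin(pmax(round(x), 1), w)
  yi <- pmin(pmax(round(y), 1), h)
  image[cbind(yi, xi)]
}

# Bilinear resize to new dimensions (used by the image pyramid).
resize_bilinear <- function(image, new_height, new_width) {
  h <- nrow(image); w <- ncol(image)
  xs <- (seq_len(new_width) - 0.5) * w / new_width + 0.5
  ys <- (seq_len(new_height) - 0.5) * h / new_height + 0.5
  grid_x <- rep(xs, each = new_height)
  grid_y <- rep(ys, times = new_width)
  matrix(bilinear_sample(image, grid_x, grid_y), nrow = new_height)
}

# Crop by 1-based inclusive pixel bounds.
crop_image <- function(image, x0, y0, x1, y1) {
  stopifnot(x0 >= 1, y0 >= 1, x1 <= ncol(image), y1 <= nrow(image))
  image[y0:y1, x0:x1, drop = FALSE]
}
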
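#' Histogram-of-oriented-gradients descriptor
#'
#' Computes the classic HOG descriptor used by sliding-window face detectors:
#' gradients from a 1-D centered derivative mask, unsigned orientations
#' binned per cell with gradient-magnitude-weighted votes, cells grouped into
#' overlapping blocks, L2-hys block normalization (unit norm, clip, renorm),
#' and the block vectors concatenated. With the recommended configuration
#' (64 x 128 window, 8 x 8 cells, 2 x 2-cell blocks, 9 bins, one-cell
#' stride) the descriptor has length 3780.
#'
#' @param window_w,window_h detection-window size in pixels
#' @param cell cell side in pixels (window must divide into whole cells)
#' @param block_cells block side in cells
#' @param n_bins orientation bin count over `[0, 180)` degrees
#' @param stride_cells block stride in cells (1 = maximal overlap)
#' @param clip L2-hys clipping value
#' @return `hog_config()` returns a validated configuration list.
#' @export
hog_config <- function(window_w = 64, window_h = 128, cell = 8,
                       block_cells = 2, n_bins = 9, stride_cells = 1,
                       clip = 0.2) {
  if (window_w %% cell != 0 || window_h %% cell != 0) {
    stop("window must be an integer number of cells")
  }
  list(window_w = window_w, window_h = window_h, cell = cell,
       block_cells = block_cells, n_bins = n_bins,
       stride_cells = stride_cells, clip = clip)
}

#' @rdname hog_config
#' @param image grayscale matrix at least one window in size; the descriptor
#'   is computed over the top-left window
#' @param cfg a [hog_config()]
#' @return `hog_descriptor()` returns the numeric descriptor vector.
#' @export
hog_descriptor <- function(image, cfg = hog_config()) {
  if (nrow(image) < cfg$window_h || ncol(image) < cfg$window_w) {
    stop("image smaller than the detection window")
  }
  img <- image[seq_len(cfg$window_h), seq_len(cfg$window_w), drop = FALSE]
  h <- nrow(img); w <- ncol(img)

  # centered [-1, 0, +1] derivatives, replicated borders
  gx <- img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]
  gy <- img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  bin <- pmin(floor(ang / (180 / cfg$n_bins)), cfg$n_bins - 1) + 1

  cy <- (h %/% cfg$cell); cxn <- (w %/% cfg$cell)
  row_grp <- rep(seq_len(cy), each = cfg$cell)
  col_grp <- rep(seq_len(cxn), each = cfg$cell)
  hist <- array(0, dim = c(cy, cxn, cfg$n_bins))
  for (b in seq_len(cfg$n_bins)) {
    vb <- mag * (bin == b)
    hist[, , b] <- t(rowsum(t(rowsum(vb, row_grp)), col_grp))
  }

  bc <- cfg$block_cells
  st <- cfg$stride_cells
  by <- seq(1, cy - bc + 1, by = st)
  bx <- seq(1, cxn - bc + 1, by = st)
  blocks <- lapply(bx, function(j) {
    lapply(by, function(i) {
      v <- as.vector(hist[i:(i + bc - 1), j:(j + bc - 1), , drop = FALSE])
      l2hys_normalize(v, cfg$clip)
    })
  })
  unlist(blocks, use.names = FALSE)
}

l2hys_normalize <- function(v, clip, eps = 1e-10) {
  n <- sqrt(sum(v^2))
  if (n < eps) return(v * 0)
  v <- pmin(v / n, clip)
  n2 <- sqrt(sum(v^2))
  if (n2 < eps) return(v * 0)
  v / n2
}

#' Sliding-window detection scan over an image pyramid
#'
#' Slides a fixed-size window across the image at every pyramid level
#' (successive downscaling by `pyramid_scale`) and keeps the windows whose
#' score exceeds `threshold`. Boxes are mapped back to original-image
#' coordinates. The scorer is pluggable: any function taking a window-sized
#' grayscale matrix and returning a numeric score (a trained HOG + linear
#' face scorer fits here; so does a template matcher).
#'
#' @param image grayscale matrix
#' @param window `c(w, h)` window size in pixels
#' @param stride scan stride in pixels
#' @param pyramid_scale downscale factor between levels (> 1)
#' @param scorer `function(window_matrix) -> numeric`
#' @param threshold minimum score for a detection
#' @return tibble with `x`, `y`, `w`, `h` (original-image coordinates),
#'   `score`, `level`
#' @export
sliding_window_scan <- function(image, window, stride = 8, pyramid_scale = 1.25,
                                scorer, threshold = 0) {
  if (pyramid_scale <= 1) stop("pyramid_scale must exceed 1")
  stopifnot(is.function(scorer))
  ww <- window[1]; wh <- window[2]
  out <- list()
  level <- 0L
  img <- image
  while (nrow(img) >= wh && ncol(img) >= ww) {
    sc <- pyramid_scale^level
    xs <- seq(1, ncol(img) - ww + 1, by = stride)
    ys <- seq(1, nrow(img) - wh + 1, by = stride)
    for (x0 in xs) {
      for (y0 in ys) {
        score <- scorer(img[y0:(y0 + wh - 1), x0:(x0 + ww - 1), drop = FALSE])
        if (score > threshold) {
          out[[length(out) + 1L]] <- tibble::tibble(
            x = (x0 - 1) * sc + 1, y = (y0 - 1) * sc + 1,
            w = ww * sc, h = wh * sc, score = score, level = level
          )
        }
      }
    }
    level <- level + 1L
    nh <- floor(nrow(image) / pyramid_scale^level)
    nw <- floor(ncol(image) / pyramid_scale^level)
    if (nh < wh || nw < ww) break
    img <- resize_bilinear(image, nh, nw)
  }
  if (length(out) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), w = numeric(),
                          h = numeric(), score = numeric(), level = integer()))
  }
  dplyr::bind_rows(out)
}
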
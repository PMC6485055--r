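#' Eye region from salient points
#'
#' Bounding box spanning the outer-to-inner canthus horizontally and the
#' upper-eyelid-to-infra-orbital extent vertically, expanded by a margin and
#' clamped to the image frame.
#'
#' @param sp a [extract_salient()] tibble
#' @param side `"right"` or `"left"` (subject side)
#' @param margin expansion in pixels
#' @param frame optional `c(height, width)` to clamp against
#' @return list of class `eye_region` with `x0`, `y0`, `x1`, `y1`, `side`
#' @export
eye_region <- function(sp, side = c("right", "left"), margin = 6, frame = NULL) {
  side <- match.arg(side)
  sfx <- if (side == "right") "_R" else "_L"
  oc <- salient_point(sp, paste0("OC", sfx))
  ic <- salient_point(sp, paste0("IC", sfx))
  ue <- salient_point(sp, paste0("UE", sfx))
  io <- salient_point(sp, paste0("IO", sfx))
  x0 <- floor(min(oc[1], ic[1]) - margin)
  x1 <- ceiling(max(oc[1], ic[1]) + margin)
  y0 <- floor(ue[2] - margin)
  y1 <- ceiling(io[2] + margin)
  if (is.null(frame)) frame <- attr(sp, "frame")
  if (!is.null(frame)) {
    x0 <- max(x0, 1); y0 <- max(y0, 1)
    x1 <- min(x1, frame[2]); y1 <- min(y1, frame[1])
  }
  if (x1 - x0 < 8 || y1 - y0 < 8) stop("collapsed eye region")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, side = side),
            class = "eye_region")
}

#' Upper-eyelid edge points by thresholded column scan
#'
#' Min-max normalizes the eye crop to `[0, 1]`, binarizes at `gray_thresh`
#' (sclera above threshold maps to 1), and walks each column top-down for
#' the first bright row -- the eyelid margin where the lid gives way to
#' sclera. A column's point is kept only while the variance of the sliding
#' window of the last four accepted rows (candidate included) stays below
#' `var_bound`; columns whose first bright row jumps away from the running
#' lid curve (e.g. columns crossing the dark iris) are discarded.
#'
#' @param eye grayscale matrix (an eye crop)
#' @param gray_thresh normalized threshold in (0, 1)
#' @param var_bound variance bound in px^2 for the last-4-rows window
#' @return tibble with `x`, `y` of accepted eyelid-edge points (possibly
#'   empty)
#' @export
upper_eyelid_points <- function(eye, gray_thresh = 0.9, var_bound = 4) {
  stopifnot(gray_thresh > 0, gray_thresh < 1)
  rng <- range(eye)
  if (rng[2] - rng[1] < 1e-9) {
    return(tibble::tibble(x = numeric(), y = numeric()))
  }
  norm <- (eye - rng[1]) / (rng[2] - rng[1])
  bright <- norm > gray_thresh
  xs <- integer(0); ys <- integer(0)
  for (col in seq_len(ncol(bright))) {
    r <- which(bright[, col])
    if (length(r) == 0) next
    cand <- r[1]
    k <- length(ys)
    if (k >= 3) {
      window <- c(ys[(k - 2):k], cand)
      if (stats::var(window) > var_bound) next
    }
    xs <- c(xs, col); ys <- c(ys, cand)
  }
  tibble::tibble(x = xs, y = ys)
}

#' Least-squares parabola through eyelid-edge points
#'
#' Fits `y = a x^2 + b x + c` by ordinary least squares; three points with
#' distinct x are interpolated exactly, collinear points degenerate to a
#' line (`a = 0`).
#'
#' @param points data frame with `x`, `y`
#' @return list of class `parabola` with `a`, `b`, `c`
#' @export
fit_parabola <- function(points) {
  x <- points$x; y <- points$y
  if (length(unique(x)) < 3) {
    stop("parabola fit needs at least 3 distinct x values")
  }
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- coef(fit)
  structure(list(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1])),
            class = "parabola")
}

#' @rdname fit_parabola
#' @param p a `parabola`
#' @param x_start,x_end inclusive evaluation range
#' @param dx grid step (> 0)
#' @return `evaluate_parabola()` returns a tibble with the sampled `x`, `y`.
#' @export
evaluate_parabola <- function(p, x_start, x_end, dx = 0.1) {
  stopifnot(dx > 0)
  xp <- seq(x_start, x_end, by = dx)
  tibble::tibble(x = xp, y = p$a * xp^2 + p$b * xp + p$c)
}

parabola_y <- function(p, x) p$a * x^2 + p$b * x + p$c

#' Iris detection by Daugman's integro-differential operator
#'
#' Searches center candidates (every `center_stride`-th pixel inside the
#' central third of the crop, followed by a single-pixel local refinement)
#' and integer radii for the maximum of the Gaussian-smoothed radial
#' derivative of the normalized circular line integral of intensity. The
#' arc is restricted to the two lateral 90-degree sectors, which are the
#' parts of the limbus least likely to be occluded by the eyelids.
#'
#' @param eye grayscale matrix (an eye crop)
#' @param r_min,r_max radius search range in pixels; defaults to 10% and 50%
#'   of the smaller crop dimension
#' @param smoothing_sd Gaussian smoothing of the radial derivative, in
#'   radius steps
#' @param center_stride coarse center-grid stride in pixels
#' @param n_angles arc samples per circle
#' @param min_response minimum operator response (gray levels per radius
#'   step); a flat crop falls below it
#' @return list of class `iris_circle` with `center` (`c(x, y)` in crop
#'   coordinates), `radius`, `score`
#' @export
daugman_detect <- function(eye, r_min = NULL, r_max = NULL, smoothing_sd = 1,
                           center_stride = 2, n_angles = 48,
                           min_response = 5, occlusion = NULL) {
  h <- nrow(eye); w <- ncol(eye)
  boxmin <- min(h, w)
  if (is.null(r_min)) r_min <- max(3, round(0.1 * boxmin))
  if (is.null(r_max)) r_max <- floor(0.5 * boxmin)
  if (!(r_min < r_max)) stop("need r_min < r_max")
  radii <- seq(r_min, r_max, by = 1)
  ang <- c(seq(-pi / 4, pi / 4, length.out = n_angles / 2),
           seq(3 * pi / 4, 5 * pi / 4, length.out = n_angles / 2))
  ca <- cos(ang); sa <- sin(ang)

  # Radial derivative of the arc integral, robust to eyelid occlusion: the
  # per-angle derivatives are averaged over their upper `keep` fraction, so
  # a boundary visible on most of the arc outscores a sharp transition
  # confined to a small arc fraction (a failure mode of the plain mean
  # under partial occlusion).
  keep <- 0.85
  arc_derivative <- function(rr, cx, cy) {
    px <- outer(rr, ca) + cx
    py <- outer(rr, sa) + cy
    I <- matrix(bilinear_sample(eye, as.vector(px), as.vector(py)),
                nrow = length(rr))
    if (!is.null(occlusion)) {
      # samples on or above the modelled upper eyelid carry no limbus
      # information; drop them before differentiating
      I[py <= parabola_y(occlusion, px) + 1] <- NA
    }
    dI <- diff(I)
    k <- max(1L, round(keep * ncol(dI)))
    apply(dI, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < n_angles / 4) return(-Inf)
      kk <- min(length(v), k)
      mean(sort(v, decreasing = TRUE)[seq_len(kk)])
    })
  }
  score_center <- function(cx, cy) {
    v <- arc_derivative(radii, cx, cy)
    v[!is.finite(v)] <- 0
    sm <- gauss_smooth(v, smoothing_sd)
    i <- which.max(sm)
    c(score = sm[i], radius = radii[i])
  }

  best <- c(score = -Inf, radius = NA, cx = NA, cy = NA)
  cxs <- seq(max(2, floor(w / 3)), ceiling(2 * w / 3), by = center_stride)
  cys <- seq(max(2, floor(h / 3)), ceiling(2 * h / 3), by = center_stride)
  for (cx in cxs) {
    for (cy in cys) {
      sc <- score_center(cx, cy)
      if (sc["score"] > best["score"]) {
        best <- c(sc, cx = cx, cy = cy)
      }
    }
  }
  # single-pixel refinement around the coarse optimum
  for (cx in (best["cx"] - 2):(best["cx"] + 2)) {
    for (cy in (best["cy"] - 2):(best["cy"] + 2)) {
      if (cx < 2 || cy < 2 || cx > w - 1 || cy > h - 1) next
      sc <- score_center(cx, cy)
      if (sc["score"] > best["score"]) {
        best <- c(sc, cx = cx, cy = cy)
      }
    }
  }
  if (!is.finite(best["score"]) || best["score"] < min_response) {
    stop("no circular contrast found (operator response below threshold)")
  }
  # sub-pixel radial refinement: the integer grid locates the boundary to
  # one step; a fine pass at 0.25 px recovers the transition midpoint
  fine <- seq(max(r_min, best["radius"] - 2), min(r_max, best["radius"] + 2),
              by = 0.25)
  vf <- arc_derivative(fine, best["cx"], best["cy"])
  vf[!is.finite(vf)] <- 0
  sm <- gauss_smooth(vf, smoothing_sd)
  r_hat <- fine[which.max(sm)] + 0.125
  structure(list(center = unname(c(best["cx"], best["cy"])),
                 radius = unname(r_hat),
                 score = unname(best["score"])),
            class = "iris_circle")
}

gauss_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-((-half):half)^2 / (2 * sd^2))
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Clip a detected iris circle by the eyelid boundaries
#'
#' The visible iris mask is the set of disk pixels strictly below the
#' upper-eyelid parabola (image y grows downward) and strictly above the
#' lower-eyelid boundary. An empty intersection is valid and signals full
#' occlusion (area 0).
#'
#' @param circle an `iris_circle` (or list with `center`, `radius`)
#' @param upper a [fit_parabola()] result
#' @param lower the lower boundary: either a numeric row or an `n x 2`
#'   polyline matrix of (x, y) vertices (e.g. [lower_lid_polyline()])
#' @param frame `c(height, width)` of the coordinate frame for the mask
#' @return list of class `iris_segment` with `center`, `radius`,
#'   `upper_parabola`, `lower_boundary`, `visible_mask` (logical matrix) and
#'   `area` (pixel count)
#' @export
clip_iris <- function(circle, upper, lower, frame) {
  h <- frame[1]; w <- frame[2]
  cx <- circle$center[1]; cy <- circle$center[2]; r <- circle$radius
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  disk <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  up <- ys > parabola_y(upper, xs)
  lo <- if (is.matrix(lower)) {
    ys < matrix(polyline_y(lower, as.vector(xs)), nrow = h)
  } else {
    ys < lower
  }
  mask <- disk & up & lo
  structure(list(center = circle$center, radius = r, upper_parabola = upper,
                 lower_boundary = lower, visible_mask = mask,
                 area = sum(mask)),
            class = "iris_segment")
}

#' Segment the iris of one eye of a face image
#'
#' Runs the full chain: eye region from salient points, upper-eyelid edge
#' scan and parabola fit, Daugman circle detection, and clipping by the
#' fitted parabola and the landmark lower-eyelid polyline.
#'
#' @param image grayscale face image
#' @param lm a [as_landmark_set()] tibble for the face
#' @param side `"right"` or `"left"`
#' @param margin eye-box margin in pixels
#' @param gray_thresh,var_bound see [upper_eyelid_points()]
#' @param ... passed to [daugman_detect()]
#' @return an `iris_segment` (coordinates relative to the eye crop), with
#'   the crop box attached as attribute `region`
#' @export
segment_iris <- function(image, lm, side = c("right", "left"), margin = 6,
                         gray_thresh = 0.9, var_bound = 4,
                         r_min = NULL, r_max = NULL, ...) {
  side <- match.arg(side)
  sp <- extract_salient(lm)
  attr(sp, "frame") <- dim(image)
  reg <- eye_region(sp, side, margin = margin, frame = dim(image))
  crop <- crop_image(image, reg$x0, reg$y0, reg$x1, reg$y1)
  pts <- upper_eyelid_points(crop, gray_thresh = gray_thresh,
                             var_bound = var_bound)
  if (nrow(pts) < 3) stop("too few eyelid edge points")
  # a column's first bright row sits half a pixel below the true lid
  # boundary; center the fitted curve on the boundary itself
  parab <- fit_parabola(tibble::tibble(x = pts$x, y = pts$y - 0.5))
  # anatomical radius prior: in a canthus-to-canthus eye box the iris
  # occupies roughly a quarter to a half of the smaller box dimension
  boxmin <- min(dim(crop))
  if (is.null(r_min)) r_min <- max(3, round(0.25 * boxmin))
  if (is.null(r_max)) r_max <- floor(0.5 * boxmin)
  circ <- daugman_detect(crop, r_min = r_min, r_max = r_max,
                         occlusion = parab, ...)
  lower <- lower_lid_polyline(lm, side)
  lower[, 1] <- lower[, 1] - reg$x0 + 1
  lower[, 2] <- lower[, 2] - reg$y0 + 1
  seg <- clip_iris(circ, parab, lower, frame = dim(crop))
  seg$score <- circ$score
  attr(seg, "region") <- reg
  seg
}

#' Visible iris areas of both eyes
#'
#' Runs [segment_iris()] per eye; an eye whose segmentation fails yields a
#' flagged `NA` area that propagates into the feature table as a missing
#' value.
#'
#' @inheritParams segment_iris
#' @return tibble with one row per side: `side`, `area`, `ok`
#' @export
iris_area_pair <- function(image, lm, margin = 6, ...) {
  one <- function(side, r_min = NULL, r_max = NULL) {
    tryCatch(segment_iris(image, lm, side, margin = margin,
                          r_min = r_min, r_max = r_max, ...),
             error = function(e) NULL)
  }
  segs <- list(left = one("left"), right = one("right"))
  # iris radii are bilaterally symmetric; re-segment the eye with the weaker
  # operator response under the better eye's radius prior when they disagree
  if (!is.null(segs$left) && !is.null(segs$right) &&
      abs(segs$left$radius - segs$right$radius) > 1) {
    weak <- if (segs$left$score < segs$right$score) "left" else "right"
    ref <- segs[[setdiff(c("left", "right"), weak)]]$radius
    redo <- one(weak, r_min = max(3, floor(ref - 1)), r_max = ceiling(ref + 1))
    if (!is.null(redo)) segs[[weak]] <- redo
  }
  out <- lapply(c("left", "right"), function(s) {
    tibble::tibble(side = s,
                   area = if (is.null(segs[[s]])) NA_real_ else segs[[s]]$area,
                   ok = !is.null(segs[[s]]))
  })
  dplyr::bind_rows(out)
}
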
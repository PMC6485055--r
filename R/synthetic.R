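#' Synthetic facial-palsy subjects
#'
#' A synthetic subject is a parametric description of a frontal face with
#' controllable left/right asymmetry. Three scale factors in `(0, 1]` govern
#' the affected (left) side: `upper_asym` scales the left brow-to-eye and
#' brow-to-nose distances, `lower_asym` the left mouth-corner and nostril
#' distances, `iris_asym` the visible left iris area (via upper-eyelid droop).
#' A healthy subject has all three factors equal to 1; peripheral palsy (PP)
#' depresses all three; central palsy (CP) spares the upper face
#' (`upper_asym` and `iris_asym` near 1) and depresses only `lower_asym`.
#'
#' @param subject_id identifier string
#' @param klass one of `"healthy"`, `"PP"`, `"CP"`
#' @param upper_asym,lower_asym,iris_asym scale factors in `(0, 1]`
#' @param seed integer seed controlling the subject's rendering noise
#' @return a one-row tibble of class `synthetic_subject`
#' @export
synthetic_subject <- function(subject_id, klass = c("healthy", "PP", "CP"),
                              upper_asym = 1, lower_asym = 1, iris_asym = 1,
                              seed = 1L) {
  klass <- match.arg(klass)
  for (f in c(upper_asym, lower_asym, iris_asym)) {
    if (!is.finite(f) || f <= 0 || f > 1) {
      stop("asymmetry factors must lie in (0, 1]")
    }
  }
  out <- tibble::tibble(
    subject_id = as.character(subject_id), klass = klass,
    upper_asym = upper_asym, lower_asym = lower_asym, iris_asym = iris_asym,
    seed = as.integer(seed)
  )
  class(out) <- c("synthetic_subject", class(out))
  out
}

#' @rdname synthetic_subject
#' @export
face_expressions <- function() c("rest", "raise", "frown", "smile")

# ---------------------------------------------------------------------------
# 68-point template, iBUG layout, defined at a 360 x 480 (w x h) reference
# frame: 1-17 jaw, 18-22 right brow, 23-27 left brow, 28-31 nose ridge
# (31 = nose tip), 32-36 nose base (33/35 = nostrils), 37-42 right eye
# (37 outer corner, 40 inner), 43-48 left eye (43 inner, 46 outer),
# 49-68 mouth (49 right corner, 55 left corner). "Right" is the subject's
# right, drawn at smaller x.
face_template <- function() {
  pts <- matrix(NA_real_, nrow = 68, ncol = 2)
  t_jaw <- pi - (0:16) * pi / 16
  pts[1:17, ] <- cbind(180 + 130 * cos(t_jaw), 250 + 170 * sin(t_jaw))
  pts[18:22, ] <- cbind(c(95, 108, 123, 138, 152), c(184, 177, 175, 177, 182))
  pts[23:27, ] <- cbind(360 - c(152, 138, 123, 108, 95), c(182, 177, 175, 177, 184))
  pts[28:31, ] <- cbind(rep(180, 4), c(200, 225, 248, 270))
  pts[32:36, ] <- cbind(c(158, 169, 180, 191, 202), c(288, 291, 293, 291, 288))
  pts[37:42, ] <- cbind(c(103, 117, 133, 147, 133, 117), c(215, 206, 206, 215, 222, 222))
  pts[43:48, ] <- cbind(c(213, 227, 243, 257, 243, 227), c(215, 206, 206, 215, 222, 222))
  pts[49:60, ] <- cbind(
    c(135, 148, 165, 180, 195, 212, 225, 212, 196, 180, 164, 148),
    c(340, 332, 328, 330, 328, 332, 340, 352, 356, 357, 356, 352)
  )
  pts[61:68, ] <- cbind(
    c(142, 164, 180, 196, 218, 196, 180, 164),
    c(340, 338, 339, 338, 340, 346, 347, 346)
  )
  pts
}

TEMPLATE_W <- 360
TEMPLATE_H <- 480
RAISE_LIFT <- 14

# Expression shifts applied symmetrically to the template.
apply_expression <- function(pts, expression) {
  switch(expression,
    rest = pts,
    raise = {
      pts[18:27, 2] <- pts[18:27, 2] - RAISE_LIFT
      pts
    },
    frown = {
      pts[18:27, 2] <- pts[18:27, 2] + 4
      pts[32, ] <- pts[32, ] + c(2, -3)
      pts[33, ] <- pts[33, ] + c(3, -5)
      pts[34, 2] <- pts[34, 2] - 4
      pts[35, ] <- pts[35, ] + c(-3, -5)
      pts[36, ] <- pts[36, ] + c(-2, -3)
      pts
    },
    smile = {
      pts[49, ] <- pts[49, ] + c(-14, -10)
      pts[55, ] <- pts[55, ] + c(14, -10)
      pts[c(50, 60, 61), ] <- sweep(pts[c(50, 60, 61), ], 2, c(-8, -6), "+")
      pts[c(54, 56, 65), ] <- sweep(pts[c(54, 56, 65), ], 2, c(8, -6), "+")
      pts
    },
    stop("unknown expression: ", expression)
  )
}

# Intersection of two circles (c1, r1), (c2, r2); returns the solution
# nearest `prefer`. Radii scaled identically always intersect in the face
# geometry used here; degenerate input is a programming error.
circle_intersect <- function(c1, r1, c2, r2, prefer) {
  d <- sqrt(sum((c2 - c1)^2))
  stopifnot(d > 0)
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  if (h2 < 0) {
    if (h2 > -1e-6) h2 <- 0 else stop("asymmetry construction infeasible")
  }
  h <- sqrt(h2)
  u <- (c2 - c1) / d
  base <- c1 + a * u
  perp <- c(-u[2], u[1])
  s1 <- base + h * perp
  s2 <- base - h * perp
  if (sum((s1 - prefer)^2) <= sum((s2 - prefer)^2)) s1 else s2
}

dist2d <- function(p, q) sqrt(sum((p - q)^2))

# Piecewise-linear y(x) along a polyline given as an n x 2 (x, y) matrix with
# increasing x; clamped at the ends.
polyline_y <- function(pts, x) {
  stats::approx(pts[, 1], pts[, 2], xout = pmin(pmax(x, min(pts[, 1])), max(pts[, 1])),
                rule = 2)$y
}

# Per-eye geometry derived from the landmark set. Upper-lid parabola vertex
# sits `lid_drop` px below the brow-free reference; the left vertex is later
# solved so the visible left iris area hits the configured fraction.
eye_geom <- function(pts, side, vertex_y, scale) {
  idx <- if (side == "right") c(37, 42, 41, 40) else c(43, 48, 47, 46)
  lower <- pts[idx, , drop = FALSE]
  lower <- lower[order(lower[, 1]), , drop = FALSE]
  center <- c(mean(range(lower[, 1])), 215 * scale)
  list(
    side = side,
    center = center,
    radius = 10 * scale,
    parab = c(0.03 / scale, vertex_y),   # y = a (x - cx)^2 + vy
    lower = lower
  )
}

eye_parab_y <- function(geom, x) {
  geom$parab[1] * (x - geom$center[1])^2 + geom$parab[2]
}

# Analytic visible-iris pixel count: integer pixels strictly below the
# upper-lid parabola, strictly above the lower-lid polyline, inside the disk.
eye_visible_area <- function(geom) {
  cx <- geom$center[1]; cy <- geom$center[2]; r <- geom$radius
  xs <- seq(floor(cx - r), ceiling(cx + r))
  ys <- seq(floor(cy - r), ceiling(cy + r))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  inside <- (gx - cx)^2 + (gy - cy)^2 <= r^2 &
    gy > eye_parab_y(geom, gx) &
    gy < polyline_y(geom$lower, gx)
  sum(inside)
}

# Solve the left upper-lid vertex height so the visible left iris area is
# `target` pixels; the count is monotone in the vertex so a fine scan works.
solve_lid_vertex <- function(geom, target) {
  vys <- seq(geom$parab[2], geom$center[2] + geom$radius, by = 0.1)
  areas <- vapply(vys, function(v) {
    g <- geom; g$parab[2] <- v; eye_visible_area(g)
  }, numeric(1))
  vys[which.min(abs(areas - target))]
}

# ---------------------------------------------------------------------------
# Full deterministic geometry of one subject-expression: landmark matrix with
# the asymmetry construction applied, per-eye lid/iris geometry and analytic
# ground truth. No RNG is consumed here.
face_geometry <- function(subject, expression, width = 360) {
  s <- width / TEMPLATE_W
  mu <- subject$upper_asym
  lambda <- subject$lower_asym
  iris_f <- subject$iris_asym

  build_sym <- function(expr) apply_expression(face_template(), expr) * s
  pts <- build_sym(expression)

  io_r <- function(p) colMeans(p[c(41, 42), , drop = FALSE])
  io_l <- function(p) colMeans(p[c(47, 48), , drop = FALSE])

  # --- left brow: solve P25 so SO-IO and SO-NT scale exactly by mu ----------
  brow_solve <- function(p) {
    a_r <- dist2d(p[20, ], io_r(p))
    b_r <- dist2d(p[20, ], p[31, ])
    circle_intersect(io_l(p), mu * a_r, p[31, ], mu * b_r, prefer = p[25, ])
  }

  if (mu < 1 && expression == "raise") {
    # dynamic deficit: solve the left lift so left_Movement equals
    # upper_asym x right_Movement (see the methods vignette)
    rest <- build_sym("rest")
    p25_rest <- brow_solve(rest)
    a1r <- dist2d(rest[20, ], io_r(rest)); b1r <- dist2d(rest[20, ], rest[31, ])
    raise_sym <- build_sym("raise")
    a2r <- dist2d(raise_sym[20, ], io_r(raise_sym))
    b2r <- dist2d(raise_sym[20, ], raise_sym[31, ])
    move_r <- a2r / b2r - a1r / b1r
    g <- function(l) {
      p <- p25_rest + c(0, -l)
      dist2d(p, io_l(rest)) / dist2d(p, rest[31, ]) - a1r / b1r - mu * move_r
    }
    lift <- uniroot(g, c(0, 3 * RAISE_LIFT * s), tol = 1e-10)$root
    p25_new <- p25_rest + c(0, -lift)
  } else if (mu < 1) {
    p25_new <- brow_solve(pts)
  }
  if (mu < 1) {
    pts[23:27, ] <- sweep(pts[23:27, , drop = FALSE], 2, p25_new - pts[25, ], "+")
  }

  if (lambda < 1) {
    # --- left mouth corner: NT-MA and IC-MA scale exactly by lambda --------
    d_ntma <- dist2d(pts[31, ], pts[49, ])
    d_icma <- dist2d(pts[40, ], pts[49, ])
    p55_new <- circle_intersect(pts[31, ], lambda * d_ntma,
                                pts[43, ], lambda * d_icma, prefer = pts[55, ])
    pts[c(54, 55, 56, 65), ] <- sweep(pts[c(54, 55, 56, 65), , drop = FALSE], 2,
                                      p55_new - pts[55, ], "+")

    # --- left nostril: scaled about the nose tip ---------------------------
    p35_new <- pts[31, ] + lambda * (pts[35, ] - pts[31, ])
    pts[c(35, 36), ] <- sweep(pts[c(35, 36), , drop = FALSE], 2,
                              p35_new - pts[35, ], "+")
  }

  # --- eyes: right lid fixed, left lid drooped to hit the iris fraction ----
  vy_r <- 209 * s
  right_eye <- eye_geom(pts, "right", vy_r, s)
  area_r <- eye_visible_area(right_eye)
  left_eye <- eye_geom(pts, "left", vy_r, s)
  if (iris_f < 1) {
    # ptosis flattens the lid arc while it descends
    left_eye$parab[1] <- 0
    left_eye$parab[2] <- solve_lid_vertex(left_eye, iris_f * area_r)
  }
  area_l <- eye_visible_area(left_eye)

  face_box <- c(x0 = (180 - 140) * s, y0 = (250 - 180) * s,
                x1 = (180 + 140) * s, y1 = 430 * s)

  list(
    points = pts,
    right_eye = right_eye, left_eye = left_eye,
    iris_area = c(left = area_l, right = area_r),
    face_box = face_box,
    width = round(TEMPLATE_W * s), height = round(TEMPLATE_H * s)
  )
}

# ---------------------------------------------------------------------------

render_eye_patch <- function(img, geom, scale) {
  h <- nrow(img); w <- ncol(img)
  cx <- geom$center[1]; cy <- geom$center[2]; r <- geom$radius
  x_rng <- range(geom$lower[, 1])
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  parab <- geom$parab[1] * (xs - cx)^2 + geom$parab[2]
  lower <- matrix(polyline_y(geom$lower, as.vector(xs)), nrow = h)
  opening <- xs >= x_rng[1] & xs <= x_rng[2] & ys > parab & ys < lower
  img[opening] <- 235
  disk <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  img[opening & disk] <- 40
  lash <- xs >= x_rng[1] - 4 * scale & xs <= x_rng[2] + 4 * scale &
    ys > parab - 2.5 * scale & ys <= parab
  img[lash] <- 90
  img
}

#' Render a synthetic face for one expression
#'
#' Draws a parametric grayscale frontal face (head ellipse, brows, nose,
#' mouth, and eyes with partially lid-occluded iris disks) from the exact
#' 68-point geometry of the subject, then adds clipped Gaussian noise. The
#' returned landmarks are the ground truth used for drawing.
#'
#' @param subject a [synthetic_subject()] row
#' @param expression one of `"rest"`, `"raise"`, `"frown"`, `"smile"`
#' @param width image width in pixels (height is `4/3 * width`)
#' @param noise_sd additive Gaussian noise, gray levels
#' @return a list of class `synthetic_face` with elements `image`,
#'   `landmarks` (tibble `point_id`, `x`, `y`), `face_box`, `truth`
#'   (asymmetry factors and analytic iris areas), `subject`, `expression`.
#' @export
render_face <- function(subject, expression = "rest", width = 360, noise_sd = 2) {
  expression <- match.arg(expression, face_expressions())
  geo <- face_geometry(subject, expression, width)
  s <- width / TEMPLATE_W
  img <- new_image(geo$height, geo$width, 60)
  img <- paint(img, mask_ellipse(geo$height, geo$width, 180 * s, 250 * s,
                                 140 * s, 180 * s), 170)
  pts <- geo$points
  img <- paint_polyline(img, pts[18:22, ], 80, thickness = max(1, round(3 * s)))
  img <- paint_polyline(img, pts[23:27, ], 80, thickness = max(1, round(3 * s)))
  img <- paint_polyline(img, pts[28:31, ], 140, thickness = max(1, round(1 * s)))
  img <- paint_polyline(img, pts[32:36, ], 110, thickness = max(1, round(1 * s)))
  img <- paint_polyline(img, pts[c(49:60, 49), ], 80, thickness = max(1, round(2 * s)))
  img <- render_eye_patch(img, geo$right_eye, s)
  img <- render_eye_patch(img, geo$left_eye, s)

  expr_idx <- match(expression, face_expressions())
  set.seed(subject$seed * 7L + expr_idx)
  img <- add_noise(img, noise_sd)

  structure(list(
    image = img,
    landmarks = tibble::tibble(point_id = 1:68, x = pts[, 1], y = pts[, 2]),
    face_box = geo$face_box,
    truth = list(
      upper_asym = subject$upper_asym, lower_asym = subject$lower_asym,
      iris_asym = subject$iris_asym, iris_area = geo$iris_area,
      right_eye = geo$right_eye, left_eye = geo$left_eye
    ),
    subject = subject, expression = expression
  ), class = "synthetic_face")
}

#' Synthetic eye-crop specification
#'
#' Describes a standalone eye fixture: a dark iris disk on bright sclera,
#' occluded from above by a parabolic upper eyelid (`y = a x^2 + b x + c`,
#' image y growing downward) and from below by a horizontal lower lid. The
#' visible-iris ground truth is the set of disk pixels strictly below the
#' parabola and strictly above `lower_lid_row`.
#'
#' @param width,height frame size in pixels
#' @param center iris center `c(x, y)`
#' @param radius iris radius in pixels (>= 3)
#' @param parabola coefficients `c(a, b, c)` of the upper-eyelid curve
#' @param lower_lid_row row of the horizontal lower eyelid
#' @param noise_sd additive Gaussian noise, gray levels
#' @return a list of class `synthetic_eye_spec`
#' @export
synthetic_eye_spec <- function(width = 120, height = 80, center = c(60, 40),
                               radius = 20, parabola = c(0.01, 0, 20),
                               lower_lid_row = 75, noise_sd = 0) {
  if (radius < 3) stop("degenerate iris radius (< 3 px)")
  if (center[1] - radius < 1 || center[1] + radius > width ||
      center[2] - radius < 1 || center[2] + radius > height) {
    stop("iris circle must lie fully inside the frame")
  }
  xs <- seq_len(width)
  py <- parabola[1] * xs^2 + parabola[2] * xs + parabola[3]
  if (any(py < 0) || any(py > height + max(1, 0.25 * height))) {
    stop("eyelid parabola leaves the frame")
  }
  structure(list(width = width, height = height, center = center,
                 radius = radius, parabola = parabola,
                 lower_lid_row = lower_lid_row, noise_sd = noise_sd),
            class = "synthetic_eye_spec")
}

#' Render a synthetic eye crop with analytic ground truth
#'
#' @param spec a [synthetic_eye_spec()]
#' @param seed integer seed for the rendering noise
#' @return list of class `synthetic_eye` with `image`, logical `mask` of
#'   visible iris pixels and `area` (its pixel count).
#' @export
render_eye <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  h <- spec$height; w <- spec$width
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  parab <- spec$parabola[1] * xs^2 + spec$parabola[2] * xs + spec$parabola[3]
  img <- new_image(h, w, 220)
  img[ys <= parab] <- 90
  img[ys >= spec$lower_lid_row] <- 90
  disk <- (xs - spec$center[1])^2 + (ys - spec$center[2])^2 <= spec$radius^2
  visible <- disk & ys > parab & ys < spec$lower_lid_row
  img[visible] <- 40
  set.seed(seed)
  img <- add_noise(img, spec$noise_sd)
  structure(list(image = img, mask = visible, area = sum(visible)),
            class = "synthetic_eye")
}

#' Simulate a labelled cohort of synthetic subjects
#'
#' Draws per-class asymmetry factors (healthy: `1 - |N(0, 0.02)|`; affected
#' factors: uniform on `[0.6, 0.9]`; CP spares the upper face) and emits one
#' row per subject-expression, four expressions per subject. Images are
#' rendered on demand with [render_face()] or written with [write_cohort()].
#'
#' @param n_healthy,n_pp,n_cp subject counts per class
#' @param seed integer seed; the cohort is reproducible under it
#' @return tibble of class `palsy_cohort`, `4 * (n_healthy + n_pp + n_cp)`
#'   rows with subject parameters, `expression`, and labels (`label`:
#'   0 healthy / 1 palsy; `label2`: 0 PP / 1 CP, `NA` for healthy).
#' @export
simulate_cohort <- function(n_healthy, n_pp, n_cp, seed = 1L) {
  stopifnot(n_healthy >= 0, n_pp >= 0, n_cp >= 0)
  set.seed(seed)
  n <- n_healthy + n_pp + n_cp
  klass <- rep(c("healthy", "PP", "CP"), times = c(n_healthy, n_pp, n_cp))
  healthy_draw <- function(k) pmin(pmax(1 - abs(rnorm(k, 0, 0.02)), 1e-3), 1)
  affected_draw <- function(k) runif(k, 0.6, 0.9)
  upper <- ifelse(klass == "PP", affected_draw(n), healthy_draw(n))
  lower <- ifelse(klass == "healthy", healthy_draw(n), affected_draw(n))
  iris <- ifelse(klass == "PP", affected_draw(n), healthy_draw(n))
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(max(n, 1))[seq_len(n)]),
    klass = klass,
    upper_asym = upper, lower_asym = lower, iris_asym = iris,
    seed = sample.int(10^6, n),
    label = as.integer(klass != "healthy"),
    label2 = ifelse(klass == "healthy", NA_integer_,
                    as.integer(klass == "CP"))
  )
  out <- tidyr::crossing(subjects, expression = face_expressions())
  out <- dplyr::arrange(out, .data$subject_id,
                        match(.data$expression, face_expressions()))
  class(out) <- c("palsy_cohort", class(out))
  out
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' @param cohort a [simulate_cohort()] table
#' @param dir output directory (created if missing)
#' @param width rendered face width in pixels
#' @param noise_sd rendering noise, gray levels
#' @return the manifest tibble (also written as `manifest.csv`): one row per
#'   image with paths to the PNG and the ground-truth landmark CSV.
#' @export
write_cohort <- function(cohort, dir, width = 360, noise_sd = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::pmap(cohort, function(subject_id, klass, upper_asym, lower_asym,
                                       iris_asym, seed, label, label2,
                                       expression, ...) {
    subj <- synthetic_subject(subject_id, klass, upper_asym, lower_asym,
                              iris_asym, seed)
    face <- render_face(subj, expression, width = width, noise_sd = noise_sd)
    img_path <- file.path(dir, sprintf("%s_%s.png", subject_id, expression))
    lm_path <- file.path(dir, sprintf("%s_%s_landmarks.csv", subject_id, expression))
    write_image(face$image, img_path)
    utils::write.csv(face$landmarks, lm_path, row.names = FALSE)
    tibble::tibble(
      subject_id = subject_id, expression = expression,
      image_path = img_path, landmark_path = lm_path,
      label = label, label2 = label2, klass = klass,
      box_x0 = face$face_box[1], box_y0 = face$face_box[2],
      box_x1 = face$face_box[3], box_y1 = face$face_box[4]
    )
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Simulate a symmetry-feature table directly
#'
#' Draws the 11 symmetry ratios from the class-conditional distributions the
#' image generator targets, bypassing rendering: healthy ratios
#' `1 - |N(0, 0.02)|` truncated to `(0, 1]`; affected ratios uniform on
#' `[0.6, 0.9]`. CP rows keep upper-face ratios (`f1`-`f4`), the iris ratio
#' `f10` and the movement rate `f11` healthy while depressing `f5`-`f9`.
#'
#' @param n_healthy,n_pp,n_cp row counts per class
#' @param seed integer seed
#' @return tibble with `subject_id`, `f1`..`f11`, `mean_of_all`, `label`,
#'   `label2`, `klass`
#' @export
simulate_feature_table <- function(n_healthy, n_pp, n_cp, seed = 1L) {
  stopifnot(n_healthy >= 0, n_pp >= 0, n_cp >= 0)
  set.seed(seed)
  n <- n_healthy + n_pp + n_cp
  klass <- rep(c("healthy", "PP", "CP"), times = c(n_healthy, n_pp, n_cp))
  healthy_draw <- function(k) pmin(pmax(1 - abs(rnorm(k, 0, 0.02)), 1e-3), 1)
  affected_draw <- function(k) runif(k, 0.6, 0.9)
  upper_cols <- c("f1", "f2", "f3", "f4", "f10", "f11")
  lower_cols <- c("f5", "f6", "f7", "f8", "f9")
  out <- tibble::tibble(subject_id = sprintf("F%03d", seq_len(max(n, 1))[seq_len(n)]),
                        klass = klass)
  for (col in upper_cols) {
    out[[col]] <- ifelse(klass == "PP", affected_draw(n), healthy_draw(n))
  }
  for (col in lower_cols) {
    out[[col]] <- ifelse(klass == "healthy", healthy_draw(n), affected_draw(n))
  }
  out <- out[, c("subject_id", "klass", paste0("f", 1:11))]
  out$mean_of_all <- rowMeans(out[, paste0("f", 1:11)])
  out$label <- as.integer(klass != "healthy")
  out$label2 <- ifelse(klass == "healthy", NA_integer_, as.integer(klass == "CP"))
  out
}
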
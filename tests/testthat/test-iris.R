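test_that("eye regions contain the rendered iris and reject degenerate boxes", {
  s <- synthetic_subject("S", "healthy", seed = 4)
  f <- render_face(s, "raise")
  sp <- extract_salient(as_landmark_set(f$landmarks, dim(f$image)))
  for (side in c("right", "left")) {
    reg <- eye_region(sp, side, margin = 6, frame = dim(f$image))
    eye <- f$truth[[paste0(side, "_eye")]]
    expect_true(reg$x0 <= eye$center[1] - eye$radius)
    expect_true(reg$x1 >= eye$center[1] + eye$radius)
    expect_true(reg$y1 >= eye$center[2] + eye$radius)
  }
  regs <- lapply(c("right", "left"), eye_region, sp = sp, margin = 6,
                 frame = dim(f$image))
  expect_lt(regs[[1]]$x1, regs[[2]]$x0)  # disjoint on a normal face

  collapsed <- sp
  collapsed$y[collapsed$name == "UE_R"] <- collapsed$y[collapsed$name == "IO_R"]
  expect_error(eye_region(collapsed, "right", margin = 0), "collapsed")
})

test_that("the eyelid column scan returns the boundary and filters outliers", {
  # smooth synthetic edge: dark above r(c), bright below
  img <- matrix(220, 40, 30)
  r_of_c <- round(12 + 3 * sin(seq(0, pi, length.out = 30)))
  for (c in 1:30) img[1:r_of_c[c], c] <- 90
  pts <- upper_eyelid_points(img, gray_thresh = 0.5)
  expect_equal(pts$x, 1:30)
  expect_equal(pts$y, r_of_c + 1L)  # first bright row under the edge

  # a column whose first bright row jumps 50 rows is excluded
  img2 <- matrix(90, 80, 20)
  img2[26:80, ] <- 220
  img2[1:80, 10] <- 220  # spurious bright column from the top
  img2[2:75, 10] <- 90; img2[76:80, 10] <- 220
  pts2 <- upper_eyelid_points(img2, gray_thresh = 0.5)
  expect_false(10 %in% pts2$x)
  expect_true(all(pts2$y[pts2$x != 10] == 26))

  expect_equal(nrow(upper_eyelid_points(matrix(0, 10, 10))), 0)
})

test_that("parabola fitting interpolates, degenerates, and matches least squares", {
  p <- fit_parabola(data.frame(x = c(0, 1, 2), y = c(0, 1, 4)))
  expect_equal(c(p$a, p$b, p$c), c(1, 0, 0), tolerance = 1e-12)

  line <- fit_parabola(data.frame(x = c(0, 1, 2), y = c(1, 2, 3)))
  expect_equal(c(line$a, line$b, line$c), c(0, 1, 1), tolerance = 1e-12)

  # noisy samples against the normal-equations oracle, within 3 SE
  set.seed(7)
  x <- runif(50, -3, 3)
  y <- 2 * x^2 - 3 * x + 1 + rnorm(50, 0, 0.1)
  fit <- fit_parabola(data.frame(x = x, y = y))
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(fit$c, fit$b, fit$a), as.numeric(beta), tolerance = 1e-9)
  se <- sqrt(diag(solve(t(X) %*% X)) * 0.1^2)
  expect_true(all(abs(c(fit$c, fit$b, fit$a) - c(1, -3, 2)) < 3 * se + 1e-6))

  expect_error(fit_parabola(data.frame(x = c(1, 1, 1), y = 1:3)), "distinct")
})

test_that("parabola evaluation uses the inclusive grid convention", {
  p <- structure(list(a = 0, b = 0, c = 2), class = "parabola")
  grid <- evaluate_parabola(p, 0, 7, 0.1)
  expect_equal(nrow(grid), 71)
  expect_true(all(grid$y == 2))
  expect_equal(nrow(evaluate_parabola(p, 0, 7, 100)), 1)
  expect_error(evaluate_parabola(p, 0, 7, 0), "dx")
})

test_that("the integro-differential operator finds a rendered disk exactly", {
  img <- matrix(220, 100, 100)
  xs <- matrix(rep(1:100, each = 100), 100)
  ys <- matrix(rep(1:100, times = 100), 100)
  img[(xs - 50)^2 + (ys - 50)^2 <= 20^2] <- 40
  det <- daugman_detect(img, r_min = 10, r_max = 35)
  expect_equal(det$center, c(50, 50), tolerance = 1)
  expect_equal(det$radius, 20, tolerance = 1)

  # agreement with an exhaustive coarse grid-search oracle
  oracle_best <- c(score = -Inf, cx = NA, cy = NA, r = NA)
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  for (cx in seq(42, 58, 2)) {
    for (cy in seq(42, 58, 2)) {
      I <- vapply(10:35, function(r) {
        mean(img[cbind(pmin(pmax(round(cy + r * sin(ang)), 1), 100),
                       pmin(pmax(round(cx + r * cos(ang)), 1), 100))])
      }, numeric(1))
      d <- diff(I)
      i <- which.max(d)
      if (d[i] > oracle_best["score"]) {
        oracle_best <- c(score = d[i], cx = cx, cy = cy, r = (10:35)[i])
      }
    }
  }
  expect_equal(unname(oracle_best["cx"]), det$center[1], tolerance = 1)
  expect_equal(unname(oracle_best["cy"]), det$center[2], tolerance = 1)
  expect_equal(unname(oracle_best["r"]), det$radius, tolerance = 1)

  expect_error(daugman_detect(matrix(100, 60, 60)), "contrast")

  # two concentric rings: the stronger inner transition wins
  img2 <- matrix(120, 100, 100)
  d2 <- (xs - 50)^2 + (ys - 50)^2
  img2[d2 <= 30^2] <- 100   # weak outer ring at r = 30
  img2[d2 <= 15^2] <- 10    # strong inner boundary at r = 15
  det2 <- daugman_detect(img2, r_min = 8, r_max = 40)
  expect_equal(det2$radius, 15, tolerance = 1)
})

test_that("iris clipping is a subset of the disk and monotone in the eyelid", {
  circle <- list(center = c(40, 30), radius = 12)
  lower <- 55
  areas <- c()
  for (vy in seq(10, 45, 5)) {
    p <- structure(list(a = 0, b = 0, c = vy), class = "parabola")
    seg <- clip_iris(circle, p, lower, frame = c(60, 80))
    expect_equal(seg$area, sum(seg$visible_mask))
    xs <- matrix(rep(1:80, each = 60), 60)
    ys <- matrix(rep(1:60, times = 80), 60)
    disk <- (xs - 40)^2 + (ys - 30)^2 <= 12^2
    expect_true(all(disk[seg$visible_mask]))  # mask subset of the disk
    areas <- c(areas, seg$area)
  }
  expect_true(all(diff(areas) <= 0))  # lower parabola occludes more

  # full occlusion is a valid zero-area outcome
  p_all <- structure(list(a = 0, b = 0, c = 50), class = "parabola")
  expect_equal(clip_iris(circle, p_all, 45, frame = c(60, 80))$area, 0)
})

test_that("iris areas of a face are symmetric when healthy and flag failed eyes", {
  s <- synthetic_subject("S", "healthy", seed = 12)
  f <- render_face(s, "raise")
  lm <- as_landmark_set(f$landmarks, dim(f$image))
  pair <- iris_area_pair(f$image, lm)
  al <- pair$area[pair$side == "left"]; ar <- pair$area[pair$side == "right"]
  expect_true(all(pair$ok))
  expect_lte(abs(al - ar) / max(al, ar), 0.05)

  s2 <- synthetic_subject("S2", "PP", 0.8, 0.8, iris_asym = 0.6, seed = 12)
  f2 <- render_face(s2, "raise")
  pair2 <- iris_area_pair(f2$image, as_landmark_set(f2$landmarks, dim(f2$image)))
  ratio <- pair2$area[pair2$side == "left"] / pair2$area[pair2$side == "right"]
  expect_equal(ratio, unname(f2$truth$iris_area[1] / f2$truth$iris_area[2]),
               tolerance = 0.08)

  # an unsegmentable (flat) eye region yields a flagged missing value
  blank <- matrix(170, nrow(f$image), ncol(f$image))
  pair3 <- iris_area_pair(blank, lm)
  expect_true(all(is.na(pair3$area)))
  expect_true(all(!pair3$ok))
})
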
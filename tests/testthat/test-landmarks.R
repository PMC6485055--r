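test_that("similarity alignment recovers known transforms and the closed form", {
  set.seed(1)
  src <- matrix(rnorm(40), ncol = 2)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  dst <- 2 * src %*% t(R) + matrix(c(5, -3), nrow(src), 2, byrow = TRUE)
  tr <- similarity_align(src, dst)
  expect_equal(tr$s, 2, tolerance = 1e-9)
  expect_equal(atan2(tr$R[2, 1], tr$R[1, 1]), th, tolerance = 1e-9)
  expect_equal(tr$t, c(5, -3), tolerance = 1e-9)

  # independent closed form via complex least squares: dst ~ (a + ib) src + c
  for (i in 1:10) {
    a <- matrix(rnorm(20), ncol = 2)
    b <- matrix(rnorm(20), ncol = 2)
    za <- complex(real = a[, 1], imaginary = a[, 2])
    zb <- complex(real = b[, 1], imaginary = b[, 2])
    za_c <- za - mean(za); zb_c <- zb - mean(zb)
    coef <- sum(Conj(za_c) * zb_c) / sum(Conj(za_c) * za_c)
    tr2 <- similarity_align(a, b)
    expect_equal(tr2$s, Mod(coef), tolerance = 1e-9)
    expect_equal(atan2(tr2$R[2, 1], tr2$R[1, 1]), Arg(coef), tolerance = 1e-9)
  }

  # optimality against random perturbed transforms
  set.seed(2)
  a <- matrix(rnorm(30), ncol = 2); b <- matrix(rnorm(30), ncol = 2)
  tr3 <- similarity_align(a, b)
  obj <- transform_objective(tr3, a, b)
  for (i in 1:100) {
    pert <- tr3
    pert$s <- tr3$s * exp(rnorm(1, 0, 0.05))
    dth <- rnorm(1, 0, 0.05)
    Rp <- matrix(c(cos(dth), sin(dth), -sin(dth), cos(dth)), 2)
    pert$R <- Rp %*% tr3$R
    pert$t <- tr3$t + rnorm(2, 0, 0.05)
    expect_gte(transform_objective(pert, a, b), obj - 1e-12)
  }

  expect_error(similarity_align(matrix(1, 5, 2), matrix(rnorm(10), 5, 2)),
               "degenerate")
})

test_that("shape-indexed probe warping is exact in the identity and translation limits", {
  set.seed(3)
  mean_shape <- matrix(rnorm(136), ncol = 2)
  probe <- c(0.3, -0.2)
  expect_equal(warp_index(probe, mean_shape, mean_shape), probe, tolerance = 1e-12)
  shifted <- sweep(mean_shape, 2, c(4, -7), "+")
  expect_equal(warp_index(probe, shifted, mean_shape), probe + c(4, -7),
               tolerance = 1e-9)
  # doubling the shape doubles the probe offset from its anchor landmark
  vi <- which.min(colSums((t(mean_shape) - probe)^2))
  doubled <- 2 * mean_shape
  expect_equal(warp_index(probe, doubled, mean_shape),
               doubled[vi, ] + 2 * (probe - mean_shape[vi, ]), tolerance = 1e-9)
})

test_that("split tests threshold the warped intensity difference strictly", {
  img <- matrix(0, 20, 20)
  img[5, 5] <- 100; img[15, 15] <- 90
  shape <- mean_shape <- matrix(c(5, 15, 5, 15, 5, 5, 15, 15), ncol = 2)
  theta <- list(tau = 5, i = c(5, 5), k = c(15, 15))
  expect_identical(split_test(img, shape, theta, mean_shape), 1L)
  theta$tau <- 10  # difference exactly tau: strict inequality fails
  expect_identical(split_test(img, shape, theta, mean_shape), 0L)
  img[15, 15] <- 100
  theta$tau <- 0   # equal intensities
  expect_identical(split_test(img, shape, theta, mean_shape), 0L)
})

test_that("HOG descriptor matches the block-count arithmetic and gradient oracle", {
  cfg <- hog_config()
  set.seed(4)
  img <- matrix(runif(128 * 64) * 255, 128, 64)
  desc <- hog_descriptor(img, cfg)
  # (15 x 7 blocks) x 4 cells x 9 bins, verified independently
  n_blocks_y <- 128 / 8 - 1; n_blocks_x <- 64 / 8 - 1
  expect_length(desc, n_blocks_y * n_blocks_x * 4 * 9)
  expect_length(desc, 3780)

  # constant image: zero gradients -> zero vector under safe normalization
  expect_true(all(hog_descriptor(matrix(50, 128, 64), cfg) == 0))

  # vertical step edge: all gradient mass in the horizontal-orientation bin
  step <- matrix(0, 128, 64); step[, 33:64] <- 200
  d <- hog_descriptor(step, cfg)
  # block layout: 4 cells (fastest) x 9 bins per 36-entry block
  a <- array(d, dim = c(4, 9, length(d) / 36))
  expect_gt(sum(a[, 1, ]), 0)            # 0-degree bin carries the edge
  expect_true(all(a[, 2:9, ] == 0))      # every other orientation empty

  # non-degenerate blocks have unit norm under L2-hys
  norms <- sqrt(colSums(matrix(desc, nrow = 36)^2))
  expect_true(all(abs(norms[norms > 0] - 1) < 1e-9))

  expect_error(hog_descriptor(matrix(0, 50, 50), cfg), "smaller")
})

test_that("sliding-window scan enumerates windows and honours the scorer", {
  img <- matrix(0, 60, 80)
  # scorer that fires only on one window position
  scorer <- function(w) as.numeric(w[1, 1] > 100)
  img[21, 31] <- 200
  hits <- sliding_window_scan(img, window = c(16, 16), stride = 10,
                              pyramid_scale = 4, scorer = scorer)
  expect_equal(nrow(hits[hits$level == 0, ]), 1)
  expect_equal(hits$x[1], 31)
  expect_equal(hits$y[1], 21)

  # per-level window count equals the enumeration formula
  count_scorer <- function(w) 1
  all_hits <- sliding_window_scan(matrix(0, 60, 80), c(16, 16), stride = 10,
                                  pyramid_scale = 100, scorer = count_scorer)
  expect_equal(nrow(all_hits),
               (floor((80 - 16) / 10) + 1) * (floor((60 - 16) / 10) + 1))

  none <- sliding_window_scan(img, c(16, 16), 10, 1.5, function(w) -1)
  expect_equal(nrow(none), 0)
  expect_error(sliding_window_scan(img, c(16, 16), 10, 1, scorer), "pyramid_scale")
})

test_that("salient points resolve to the documented 68-point indices", {
  s <- synthetic_subject("S", "healthy", seed = 1)
  f <- render_face(s, "rest")
  lm <- as_landmark_set(f$landmarks)
  sp <- extract_salient(lm)
  pt <- function(nm) unlist(sp[sp$name == nm, c("x", "y")], use.names = FALSE)
  expect_equal(pt("NT"), c(lm$x[31], lm$y[31]))
  expect_equal(pt("NOSTRIL_R"), c(lm$x[33], lm$y[33]))
  expect_equal(pt("NOSTRIL_L"), c(lm$x[35], lm$y[35]))
  expect_equal(pt("MA_R"), c(lm$x[49], lm$y[49]))
  expect_equal(pt("MA_L"), c(lm$x[55], lm$y[55]))
  expect_equal(pt("IC_R"), c(lm$x[40], lm$y[40]))
  expect_equal(pt("IC_L"), c(lm$x[43], lm$y[43]))
  expect_equal(pt("SO_R"), c(lm$x[20], lm$y[20]))
  expect_equal(pt("IO_R"), colMeans(cbind(lm$x, lm$y)[c(41, 42), ]))
})

test_that("landmark sets validate and round-trip through CSV and JSON", {
  s <- synthetic_subject("S", "healthy", seed = 1)
  f <- render_face(s, "rest")
  lm <- as_landmark_set(f$landmarks, dim(f$image))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, path)
  lm2 <- read_landmarks(path)
  expect_equal(lm2$x, lm$x)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, jpath)
  expect_true(jsonlite::validate(paste(readLines(jpath), collapse = "")))

  expect_error(as_landmark_set(f$landmarks[1:10, ]), "68")
  bad <- f$landmarks; bad$x[1] <- NA
  expect_error(as_landmark_set(bad), "finite")
})
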
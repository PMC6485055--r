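test_that("distances and ratios follow the min/max symmetry convention", {
  expect_equal(point_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(point_distance(c(2, 2), c(2, 2)), 0)
  expect_equal(point_distance(c(1, 2), c(5, 7)), point_distance(c(5, 7), c(1, 2)))

  expect_equal(d_ratio(3, 3), 1)
  expect_equal(d_ratio(2, 4), 0.5)
  expect_equal(d_ratio(4, 2), 0.5)
  expect_error(d_ratio(0, 2), "positive")
  expect_error(d_ratio(2, -1), "positive")
})

test_that("expression distances cover the documented pairs per expression", {
  s <- synthetic_subject("S", "healthy", seed = 5)
  f <- render_face(s, "rest")
  sp <- extract_salient(as_landmark_set(f$landmarks))
  rest <- expression_distances(sp, "rest")
  # at rest only the upper-face pairs are measured -- no mouth-angle pair
  expect_setequal(rest$name, c("SO_IO", "SO_NT"))
  expect_setequal(expression_distances(sp, "frown")$name,
                  c("NT_NOSTRIL", "NT_MA"))
  expect_setequal(expression_distances(sp, "smile")$name,
                  c("IC_MA", "NT_MA", "IO_MA"))
  expect_true(all(abs(rest$ratio - 1) < 1e-9))
})

test_that("movement rate is 1 for equal lifts, ~0 for one-sided, 1 by the floor rule", {
  s <- synthetic_subject("S", "healthy", seed = 5)
  sal <- function(subj, expr) {
    f <- render_face(subj, expr)
    extract_salient(as_landmark_set(f$landmarks))
  }
  expect_equal(movement_rate(sal(s, "rest"), sal(s, "raise")), 1,
               tolerance = 1e-6)

  # one-sided lift built directly: the left brow stays static
  make_sp <- function(so_r_y, so_l_y) {
    tibble::tibble(
      name = c("SO_R", "SO_L", "IO_R", "IO_L", "NT"),
      x = c(100, 200, 100, 200, 150),
      y = c(so_r_y, so_l_y, 140, 140, 200))
  }
  expect_equal(movement_rate(make_sp(100, 100), make_sp(80, 100)), 0)

  # no lift on either side: both movements under the floor -> rate 1
  rest_sp <- sal(s, "rest")
  expect_equal(movement_rate(rest_sp, rest_sp), 1)
})

test_that("movement rate recovers the configured upper factor exactly", {
  for (mu in c(0.6, 0.75, 0.9)) {
    subj <- synthetic_subject("M", "PP", upper_asym = mu, lower_asym = 0.8,
                              iris_asym = 0.8, seed = 2)
    r <- render_face(subj, "rest"); u <- render_face(subj, "raise")
    rate <- movement_rate(extract_salient(as_landmark_set(r$landmarks)),
                          extract_salient(as_landmark_set(u$landmarks)))
    expect_equal(rate, mu, tolerance = 1e-6)
  }
})

test_that("assembled feature vectors have 11 features with the class profile", {
  build_set <- function(subj) {
    sal <- list(); iris <- list()
    for (expr in face_expressions()) {
      f <- render_face(subj, expr)
      lm <- as_landmark_set(f$landmarks, dim(f$image))
      sal[[expr]] <- extract_salient(lm)
      if (expr %in% c("raise", "frown")) {
        iris[[expr]] <- tibble::tibble(
          expression = expr,
          area_left = f$truth$iris_area[["left"]],
          area_right = f$truth$iris_area[["right"]])
      }
    }
    list(salient = sal, iris = dplyr::bind_rows(iris))
  }

  healthy <- assemble_features(build_set(synthetic_subject("H", "healthy", seed = 1)))
  f_cols <- paste0("f", 1:11)
  expect_length(intersect(names(healthy), f_cols), 11)
  expect_true(all(abs(healthy[f_cols] - 1) < 0.02))
  expect_equal(healthy$mean_of_all, rowMeans(healthy[f_cols]))

  # CP profile: upper features near 1, lower features near the factor
  cp <- assemble_features(build_set(
    synthetic_subject("C", "CP", upper_asym = 1, lower_asym = 0.8,
                      iris_asym = 1, seed = 1)))
  expect_true(all(abs(cp[c("f1", "f2", "f3", "f4", "f10", "f11")] - 1) < 0.02))
  expect_true(all(abs(cp[c("f5", "f7", "f8", "f9")] - 0.8) < 0.02))

  # iris_split keeps the raise and frown measurements separate
  es <- build_set(synthetic_subject("H2", "healthy", seed = 2))
  split_vec <- assemble_features(es, iris_split = TRUE)
  expect_true(all(c("f10a", "f10b") %in% names(split_vec)))
  expect_false("f10" %in% names(split_vec))

  # missing smile flags f5-f7 but the record survives
  es$salient$smile <- NULL
  partial <- assemble_features(es)
  expect_true(all(is.na(partial[c("f5", "f6", "f7")])))
  expect_false(anyNA(partial[c("f1", "f2", "f8", "f9", "f10", "f11")]))

  # too few present features rejects the record
  es$salient$frown <- NULL
  es$iris <- NULL
  expect_error(assemble_features(es, min_present = 6), "rejected")
})

test_that("features are invariant under uniform image scaling", {
  subj <- synthetic_subject("Z", "PP", 0.8, 0.7, 0.9, seed = 9)
  ratios <- function(width) {
    f <- render_face(subj, "smile", width = width)
    sp <- extract_salient(as_landmark_set(f$landmarks))
    expression_distances(sp, "smile")$ratio
  }
  expect_equal(ratios(360), ratios(540), tolerance = 1e-9)
})
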
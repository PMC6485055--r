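#' Similarity (Procrustes) alignment between two point sets
#'
#' Finds the scale `s`, rotation `R` and translation `t` minimizing
#' `sum_m || dst_m - (s R src_m + t) ||^2` in closed form via the SVD of the
#' centered cross-covariance, with the determinant correction that keeps `R`
#' a proper rotation.
#'
#' @param src,dst `n x 2` matrices (or data frames with `x`, `y` columns) of
#'   corresponding points, `n >= 2`
#' @return a list of class `similarity_transform` with elements `s` (scale),
#'   `R` (2 x 2 rotation), `t` (length-2 translation)
#' @export
similarity_align <- function(src, dst) {
  src <- shape_matrix(src)
  dst <- shape_matrix(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 2)
  mu_s <- colMeans(src)
  mu_d <- colMeans(dst)
  xs <- sweep(src, 2, mu_s)
  xd <- sweep(dst, 2, mu_d)
  var_s <- sum(xs^2) / nrow(src)
  if (var_s < 1e-12) stop("degenerate source shape: all points coincident")
  sigma <- crossprod(xd, xs) / nrow(src)
  sv <- svd(sigma)
  d <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, d))
  R <- sv$u %*% S %*% t(sv$v)
  s <- sum(diag(S) * sv$d) / var_s
  t <- mu_d - s * as.vector(R %*% mu_s)
  structure(list(s = s, R = R, t = t), class = "similarity_transform")
}

#' @rdname similarity_align
#' @param transform a `similarity_transform`
#' @param shape points to transform
#' @export
apply_transform <- function(transform, shape) {
  shape <- shape_matrix(shape)
  sweep(shape %*% t(transform$R) * transform$s, 2, transform$t, "+")
}

#' @rdname similarity_align
#' @export
transform_objective <- function(transform, src, dst) {
  sum((shape_matrix(dst) - apply_transform(transform, src))^2)
}

shape_matrix <- function(shape) {
  if (is.data.frame(shape)) shape <- cbind(shape$x, shape$y)
  m <- as.matrix(shape)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 2, all(is.finite(m)))
  m
}

#' Warp a mean-shape probe point into the frame of a shape estimate
#'
#' A probe `i` defined in the mean-shape frame is attached to its nearest
#' mean-shape landmark `vi` with offset `delta = i - mean[vi]`; for a shape
#' estimate `Y` with similarity transform `(s, R)` mapping `Y` to the mean
#' shape, the corresponding image position is
#' `i' = Y[vi] + (1/s) R^T delta`. When the shape equals the mean shape the
#' warp is the identity; a pure translation of the mean shape translates the
#' probe with it.
#'
#' @param probe length-2 probe position in the mean-shape frame
#' @param shape current shape estimate (`68 x 2` or any `n x 2`)
#' @param mean_shape reference mean shape, same point count
#' @param transform optional precomputed `similarity_align(shape, mean_shape)`
#'   (the expensive part; cascades reuse it across probes)
#' @return length-2 image position
#' @export
warp_index <- function(probe, shape, mean_shape, transform = NULL) {
  shape <- shape_matrix(shape)
  mean_shape <- shape_matrix(mean_shape)
  vi <- nearest_landmark(probe, mean_shape)
  delta <- probe - mean_shape[vi, ]
  if (is.null(transform)) transform <- similarity_align(shape, mean_shape)
  shape[vi, ] + as.vector(t(transform$R) %*% delta) / transform$s
}

nearest_landmark <- function(probe, mean_shape) {
  which.min((mean_shape[, 1] - probe[1])^2 + (mean_shape[, 2] - probe[2])^2)
}

#' Shape-indexed intensity-difference split test
#'
#' The decision applied at an internal node of a landmark regression tree:
#' two probe positions defined in the mean-shape frame are warped into the
#' image through the current shape estimate, and the test fires (returns 1)
#' iff `I(i') - I(k') > tau` (strict). Probes warped outside the image are
#' clamped to the border.
#'
#' @param image grayscale matrix
#' @param shape current shape estimate
#' @param theta list with `tau` (intensity threshold), `i`, `k` (probe
#'   positions in the mean-shape frame, `i != k`)
#' @param mean_shape the mean shape
#' @param transform optional precomputed alignment as in [warp_index()]
#' @return integer 0 or 1
#' @export
split_test <- function(image, shape, theta, mean_shape, transform = NULL) {
  stopifnot(!isTRUE(all.equal(theta$i, theta$k)))
  if (is.null(transform)) transform <- similarity_align(shape, mean_shape)
  ip <- warp_index(theta$i, shape, mean_shape, transform)
  kp <- warp_index(theta$k, shape, mean_shape, transform)
  ii <- nearest_sample(image, ip[1], ip[2])
  ik <- nearest_sample(image, kp[1], kp[2])
  as.integer((ii - ik) > theta$tau)
}
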
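#' Configuration for the landmark regression cascade
#'
#' Desk-scale gradient-boosted cascade of shape-indexed regression trees.
#' Each stage samples a fresh set of pixel probes in the mean-shape frame,
#' warps them through the current shape estimate of every example
#' (one similarity alignment per example per stage), and fits depth-limited
#' regression trees to the shape residuals with intensity-difference split
#' tests. Probe pairs at a node are drawn with an exponential prior on
#' inter-probe distance, favouring nearby pixel pairs.
#'
#' @param n_stages cascade stages
#' @param n_trees boosted trees per stage
#' @param depth maximum tree depth (internal-node levels)
#' @param shrinkage learning rate applied to leaf values
#' @param n_candidates candidate split tests sampled per node
#' @param n_probes pixel probes sampled per stage
#' @param prior_lambda exponential-prior scale on inter-probe distance,
#'   in mean-shape (unit box) units
#' @param min_node minimum samples to attempt a split
#' @return a configuration list of class `cascade_config`
#' @export
cascade_config <- function(n_stages = 5, n_trees = 50, depth = 4,
                           shrinkage = 0.1, n_candidates = 20,
                           n_probes = 400, prior_lambda = 0.1,
                           min_node = 5) {
  structure(list(n_stages = n_stages, n_trees = n_trees, depth = depth,
                 shrinkage = shrinkage, n_candidates = n_candidates,
                 n_probes = n_probes, prior_lambda = prior_lambda,
                 min_node = min_node),
            class = "cascade_config")
}

# Place a unit-frame shape into a face box (x0, y0, x1, y1).
shape_from_box <- function(unit_shape, box) {
  cbind(box[1] + unit_shape[, 1] * (box[3] - box[1]),
        box[2] + unit_shape[, 2] * (box[4] - box[2]))
}

shape_to_box_frame <- function(shape, box) {
  cbind((shape[, 1] - box[1]) / (box[3] - box[1]),
        (shape[, 2] - box[2]) / (box[4] - box[2]))
}

#' Train a landmark regression cascade on annotated faces
#'
#' @param training list of examples, each a list with `image` (grayscale
#'   matrix), `landmarks` (68-point tibble or `68 x 2` matrix) and
#'   `face_box` (`c(x0, y0, x1, y1)`); at least two examples
#' @param cfg a [cascade_config()]
#' @param seed integer seed for probe and split sampling
#' @return object of class `regression_cascade`: the mean shape (unit box
#'   frame), per-stage probe sets and trees, and the per-stage training MSE
#'   trace (box-scale units, non-increasing)
#' @export
train_cascade <- function(training, cfg = cascade_config(), seed = 1L) {
  if (length(training) < 2) stop("need at least two annotated training faces")
  set.seed(seed)
  n <- length(training)
  boxes <- lapply(training, `[[`, "face_box")
  gts <- lapply(training, function(e) shape_matrix(e$landmarks))
  imgs <- lapply(training, `[[`, "image")
  n_pts <- nrow(gts[[1]])

  unit_shapes <- Map(shape_to_box_frame, gts, boxes)
  mean_shape <- Reduce(`+`, unit_shapes) / n

  # current estimates: mean shape placed into each face box
  est <- lapply(boxes, function(b) shape_from_box(mean_shape, b))
  boxw <- vapply(boxes, function(b) b[3] - b[1], numeric(1))

  resid_units <- function() {
    t(vapply(seq_len(n), function(j) {
      as.vector((gts[[j]] - est[[j]]) / boxw[j])
    }, numeric(2 * n_pts)))
  }
  stage_mse <- function() mean(resid_units()^2)

  mse_trace <- stage_mse()
  stages <- vector("list", cfg$n_stages)
  pad <- 0.05
  lo <- apply(mean_shape, 2, min) - pad
  hi <- apply(mean_shape, 2, max) + pad

  for (st in seq_len(cfg$n_stages)) {
    probes <- cbind(runif(cfg$n_probes, lo[1], hi[1]),
                    runif(cfg$n_probes, lo[2], hi[2]))
    vi <- apply(probes, 1, nearest_landmark, mean_shape = mean_shape)
    deltas <- probes - mean_shape[vi, , drop = FALSE]

    # shape-indexed intensities: one alignment per example for this stage
    X <- matrix(0, n, cfg$n_probes)
    for (j in seq_len(n)) {
      tr <- similarity_align(est[[j]], mean_shape)
      warped <- est[[j]][vi, , drop = FALSE] + (deltas %*% tr$R) / tr$s
      X[j, ] <- nearest_sample(imgs[[j]], warped[, 1], warped[, 2])
    }

    # pairwise probe prior
    pd <- as.matrix(stats::dist(probes))
    prior <- exp(-pd / cfg$prior_lambda)
    diag(prior) <- 0

    trees <- vector("list", cfg$n_trees)
    for (tr_i in seq_len(cfg$n_trees)) {
      R <- resid_units()
      tree <- fit_shape_tree(X, R, cfg, prior)
      trees[[tr_i]] <- tree
      inc <- predict_shape_tree(tree, X)
      for (j in seq_len(n)) {
        est[[j]] <- est[[j]] + matrix(inc[j, ], ncol = 2) * boxw[j]
      }
    }
    stages[[st]] <- list(probes = probes, vi = vi, deltas = deltas,
                         trees = trees)
    mse_trace <- c(mse_trace, stage_mse())
  }

  structure(list(mean_shape = mean_shape, stages = stages, cfg = cfg,
                 n_points = n_pts, mse_trace = mse_trace),
            class = "regression_cascade")
}

# Greedy regression tree over intensity-difference features. X: n x P probe
# intensities; R: n x 2k residuals. Split quality maximizes the decrease in
# SSE, i.e. sum over sides of n_side * ||mean residual||^2.
fit_shape_tree <- function(X, R, cfg, prior) {
  n_probes <- ncol(X)
  build <- function(idx, depth) {
    if (depth >= cfg$depth || length(idx) < cfg$min_node) {
      return(list(kind = "leaf",
                  value = cfg$shrinkage * colMeans(R[idx, , drop = FALSE])))
    }
    best <- NULL
    best_q <- -Inf
    for (cand in seq_len(cfg$n_candidates)) {
      p <- sample.int(n_probes, 1)
      q <- sample.int(n_probes, 1, prob = prior[p, ])
      d <- X[idx, p] - X[idx, q]
      rng <- range(d)
      if (rng[1] >= rng[2]) next
      tau <- runif(1, rng[1], rng[2])
      left <- d > tau
      nl <- sum(left); nr <- length(idx) - nl
      if (nl == 0 || nr == 0) next
      ml <- colMeans(R[idx[left], , drop = FALSE])
      mr <- colMeans(R[idx[!left], , drop = FALSE])
      qual <- nl * sum(ml^2) + nr * sum(mr^2)
      if (qual > best_q) {
        best_q <- qual
        best <- list(p = p, q = q, tau = tau, left = left)
      }
    }
    if (is.null(best)) {
      return(list(kind = "leaf",
                  value = cfg$shrinkage * colMeans(R[idx, , drop = FALSE])))
    }
    list(kind = "split", p = best$p, q = best$q, tau = best$tau,
         left = build(idx[best$left], depth + 1),
         right = build(idx[!best$left], depth + 1))
  }
  build(seq_len(nrow(X)), 0)
}

predict_shape_tree <- function(tree, X) {
  out <- matrix(0, nrow(X), length(tree_first_leaf(tree)))
  walk <- function(node, idx) {
    if (length(idx) == 0) return(invisible())
    if (node$kind == "leaf") {
      out[idx, ] <<- matrix(node$value, length(idx), length(node$value),
                            byrow = TRUE)
      return(invisible())
    }
    left <- (X[idx, node$p] - X[idx, node$q]) > node$tau
    walk(node$left, idx[left])
    walk(node$right, idx[!left])
  }
  walk(tree, seq_len(nrow(X)))
  out
}

tree_first_leaf <- function(node) {
  while (node$kind != "leaf") node <- node$left
  node$value
}

#' Predict 68-point landmarks for a face
#'
#' @param backend a trained [train_cascade()] object, or any function
#'   `function(image, face_box) -> landmark tibble` plugging in an external
#'   pretrained model
#' @param image grayscale matrix
#' @param face_box `c(x0, y0, x1, y1)` bounding box of the face, inside the
#'   image
#' @param n_stages optionally run only the first `n_stages` stages
#'   (0 returns the mean-shape initialization)
#' @return a landmark tibble (`point_id`, `x`, `y`) of class `landmark_set`
#' @export
predict_landmarks <- function(backend, image, face_box, n_stages = NULL) {
  if (is.function(backend)) {
    return(as_landmark_set(backend(image, face_box), dim(image)))
  }
  if (!inherits(backend, "regression_cascade")) {
    stop("landmark backend unavailable: supply a regression_cascade or a function")
  }
  if (face_box[1] < 1 || face_box[2] < 1 ||
      face_box[3] > ncol(image) || face_box[4] > nrow(image)) {
    stop("face_box must lie inside the image")
  }
  est <- shape_from_box(backend$mean_shape, face_box)
  boxw <- face_box[3] - face_box[1]
  use <- if (is.null(n_stages)) length(backend$stages) else n_stages
  for (st in seq_len(use)) {
    stage <- backend$stages[[st]]
    tr <- similarity_align(est, backend$mean_shape)
    warped <- est[stage$vi, , drop = FALSE] + (stage$deltas %*% tr$R) / tr$s
    x <- nearest_sample(image, warped[, 1], warped[, 2])
    X <- matrix(x, nrow = 1)
    for (tree in stage$trees) {
      inc <- predict_shape_tree(tree, X)
      est <- est + matrix(inc[1, ], ncol = 2) * boxw
    }
  }
  as_landmark_set(tibble::tibble(point_id = seq_len(nrow(est)),
                                 x = est[, 1], y = est[, 2]), dim(image))
}

#' Serialize a trained cascade to JSON
#'
#' The serialization is lossless for prediction: reading the file back
#' reproduces identical landmark estimates.
#'
#' @param cascade a `regression_cascade`
#' @param path output JSON path
#' @export
write_cascade <- function(cascade, path) {
  ser_tree <- function(node) {
    if (node$kind == "leaf") list(kind = "leaf", value = node$value)
    else list(kind = "split", p = node$p, q = node$q, tau = node$tau,
              left = ser_tree(node$left), right = ser_tree(node$right))
  }
  obj <- list(
    mean_shape = cascade$mean_shape,
    n_points = cascade$n_points,
    cfg = unclass(cascade$cfg),
    mse_trace = cascade$mse_trace,
    stages = lapply(cascade$stages, function(st) {
      list(probes = st$probes, vi = st$vi, deltas = st$deltas,
           trees = lapply(st$trees, ser_tree))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mat <- function(x) do.call(rbind, lapply(x, function(r) unlist(r, use.names = FALSE)))
  de_tree <- function(node) {
    if (identical(node$kind, "leaf")) {
      list(kind = "leaf", value = unlist(node$value, use.names = FALSE))
    } else {
      list(kind = "split", p = as.integer(node$p), q = as.integer(node$q),
           tau = as.numeric(node$tau),
           left = de_tree(node$left), right = de_tree(node$right))
    }
  }
  stages <- lapply(obj$stages, function(st) {
    list(probes = as_mat(st$probes),
         vi = unlist(st$vi, use.names = FALSE),
         deltas = as_mat(st$deltas),
         trees = lapply(st$trees, de_tree))
  })
  structure(list(mean_shape = as_mat(obj$mean_shape),
                 stages = stages,
                 cfg = do.call(cascade_config, lapply(obj$cfg, function(x) x)),
                 n_points = obj$n_points,
                 mse_trace = unlist(obj$mse_trace, use.names = FALSE)),
            class = "regression_cascade")
}
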
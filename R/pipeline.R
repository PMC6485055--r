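#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end pipeline: preprocessing target,
#' landmark backend, iris-segmentation parameters, feature options and
#' classifier settings. The configuration is validated on construction and
#' embedded (with its hash) in every report for reproducibility.
#'
#' @param preprocess logical; resize/equalize/denoise input images before
#'   feature extraction
#' @param target_w,target_h preprocessing target size in pixels
#' @param landmark_backend `"file"` (ground-truth/precomputed landmark CSVs
#'   from the manifest), a trained [train_cascade()] object, or a function
#'   `function(image, face_box) -> landmark tibble`
#' @param eye_margin eye-region margin in pixels
#' @param gray_thresh,var_bound eyelid-scan parameters, see
#'   [upper_eyelid_points()]
#' @param iris_split keep raise/frown iris ratios as separate features
#' @param k,lambda_grid,train_fraction,depth_limit classifier protocol
#' @param seed base seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(preprocess = FALSE, target_w = 960, target_h = 720,
                            landmark_backend = "file", eye_margin = 6,
                            gray_thresh = 0.9, var_bound = 4,
                            iris_split = FALSE, k = 10,
                            lambda_grid = default_lambda_grid(),
                            train_fraction = 0.7, depth_limit = 2,
                            seed = 1L) {
  stopifnot(is.logical(preprocess), target_w > 0, target_h > 0,
            eye_margin >= 0, gray_thresh > 0, gray_thresh < 1,
            k >= 2, train_fraction > 0, train_fraction < 1)
  ok_backend <- identical(landmark_backend, "file") ||
    inherits(landmark_backend, "regression_cascade") ||
    is.function(landmark_backend)
  if (!ok_backend) stop("unknown landmark backend")
  structure(list(preprocess = preprocess, target_w = target_w,
                 target_h = target_h, landmark_backend = landmark_backend,
                 eye_margin = eye_margin, gray_thresh = gray_thresh,
                 var_bound = var_bound, iris_split = iris_split, k = k,
                 lambda_grid = lambda_grid, train_fraction = train_fraction,
                 depth_limit = depth_limit, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  ser <- jsonlite::toJSON(lapply(unclass(config), function(x) {
    if (is.function(x) || inherits(x, "regression_cascade")) "object" else x
  }), auto_unbox = TRUE)
  # small stable checksum without extra dependencies
  sum(utf8ToInt(as.character(ser)) * seq_along(utf8ToInt(as.character(ser)))) %% 1e9
}

#' Preprocess a face image
#'
#' Converts to 8-bit grayscale, letterbox-resizes to the target (padding
#' rather than distorting, so distance ratios stay geometry-faithful),
#' applies histogram equalization and a 3 x 3 median filter. The affine
#' image-to-target transform is attached as attribute `transform`
#' (`c(scale, dx, dy)`) so precomputed landmarks can be mapped alongside.
#'
#' @param image grayscale matrix or a PNG path
#' @param target_w,target_h output size in pixels
#' @param equalize,denoise toggles for the enhancement steps (denoising
#'   uses EBImage's median filter)
#' @return preprocessed matrix of size `target_h x target_w`
#' @export
preprocess <- function(image, target_w = 960, target_h = 720,
                       equalize = TRUE, denoise = TRUE) {
  if (is.character(image)) image <- read_image(image)
  h <- nrow(image); w <- ncol(image)
  scale <- min(target_w / w, target_h / h)
  nh <- max(1, round(h * scale)); nw <- max(1, round(w * scale))
  out <- resize_bilinear(image, nh, nw)
  dy <- floor((target_h - nh) / 2); dx <- floor((target_w - nw) / 2)
  canvas <- new_image(target_h, target_w, 0)
  canvas[dy + seq_len(nh), dx + seq_len(nw)] <- out
  if (equalize) canvas <- equalize_hist(canvas)
  if (denoise) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("denoising requires the EBImage package")
    }
    canvas <- t(EBImage::medianFilter(t(canvas) / 255, size = 1)) * 255
  }
  canvas <- round(pmin(pmax(canvas, 0), 255))
  attr(canvas, "transform") <- c(scale = scale, dx = dx, dy = dy)
  canvas
}

equalize_hist <- function(image) {
  v <- round(pmin(pmax(image, 0), 255))
  cdf <- cumsum(tabulate(v + 1, nbins = 256)) / length(v)
  matrix(255 * cdf[v + 1], nrow = nrow(image))
}

apply_image_transform <- function(lm, tr) {
  lm$x <- lm$x * tr["scale"] + tr["dx"]
  lm$y <- lm$y * tr["scale"] + tr["dy"]
  lm
}

manifest_landmarks <- function(row, image, config) {
  backend <- config$landmark_backend
  if (identical(backend, "file")) {
    if ("landmarks" %in% names(row) && is.data.frame(row$landmarks[[1]])) {
      return(as_landmark_set(row$landmarks[[1]], dim(image)))
    }
    if ("landmark_path" %in% names(row) && !is.na(row$landmark_path)) {
      return(read_landmarks(row$landmark_path))
    }
    stop("no landmark file for ", row$subject_id, "/", row$expression)
  }
  box <- c(row$box_x0, row$box_y0, row$box_x1, row$box_y1)
  predict_landmarks(backend, image, box)
}

manifest_image <- function(row) {
  if ("image" %in% names(row) && is.matrix(row$image[[1]])) {
    return(row$image[[1]])
  }
  read_image(row$image_path)
}

#' Extract the symmetry feature table for a cohort manifest
#'
#' Runs preprocess, landmark acquisition, salient-point extraction, iris
#' segmentation (raise and frown images) and feature assembly per subject.
#' Subjects that fail a stage are logged and skipped, never aborting the
#' batch.
#'
#' @param manifest tibble with one row per subject-expression; columns
#'   `subject_id`, `expression`, plus either in-memory list-columns `image`
#'   / `landmarks` or path columns `image_path` / `landmark_path`, face-box
#'   columns (`box_x0`..`box_y1`) when a cascade backend is used, and
#'   optional `label` / `label2` / `klass`
#' @param config a [pipeline_config()]
#' @return feature tibble, one row per successfully processed subject, with
#'   a `log` attribute recording per-subject outcomes
#' @export
extract_feature_table <- function(manifest, config = pipeline_config()) {
  subjects <- unique(manifest$subject_id)
  logs <- list()
  rows <- list()
  for (sid in subjects) {
    sub <- manifest[manifest$subject_id == sid, , drop = FALSE]
    res <- tryCatch({
      sal <- list()
      iris <- list()
      for (i in seq_len(nrow(sub))) {
        row <- sub[i, , drop = FALSE]
        expr <- row$expression
        img <- manifest_image(row)
        lm <- manifest_landmarks(row, img, config)
        if (config$preprocess) {
          img <- preprocess(img, config$target_w, config$target_h)
          lm <- apply_image_transform(lm, attr(img, "transform"))
        }
        sal[[expr]] <- extract_salient(as_landmark_set(lm, dim(img)))
        if (expr %in% c("raise", "frown")) {
          pair <- iris_area_pair(img, lm, margin = config$eye_margin,
                                 gray_thresh = config$gray_thresh,
                                 var_bound = config$var_bound)
          iris[[expr]] <- tibble::tibble(
            expression = expr,
            area_left = pair$area[pair$side == "left"],
            area_right = pair$area[pair$side == "right"])
        }
      }
      feats <- assemble_features(
        list(salient = sal, iris = dplyr::bind_rows(iris)),
        iris_split = config$iris_split)
      extra <- sub[1, intersect(c("label", "label2", "klass"), names(sub)),
                   drop = FALSE]
      dplyr::bind_cols(tibble::tibble(subject_id = sid), feats, extra)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logs[[sid]] <- paste0("skipped: ", conditionMessage(res))
    } else {
      logs[[sid]] <- "ok"
      rows[[sid]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "log") <- tibble::tibble(subject_id = subjects,
                                     outcome = unlist(logs[subjects]))
  out
}

#' Run the full evaluation protocol end to end
#'
#' Feature extraction, stratified 70/30 subject split, k-fold hybrid model
#' formation for both stages, held-out evaluation and ROC analysis. The
#' report embeds the configuration (with hash) and seeds.
#'
#' @param manifest labelled cohort manifest (see [extract_feature_table()])
#' @param config a [pipeline_config()]
#' @return list of class `palsy_report`: `features`, `split`, `model`,
#'   `metrics`, `roc1` (stage-1 test ROC), `config`, `config_hash`, `seed`
#' @export
end_to_end <- function(manifest, config = pipeline_config()) {
  features <- extract_feature_table(manifest, config)
  if (!"label" %in% names(features)) stop("end_to_end needs a labelled manifest")
  sp <- split_cohort(features, config$train_fraction, "label",
                     seed = config$seed)
  model <- form_hybrid_model(sp$train, k = config$k,
                             lambda_grid = config$lambda_grid,
                             seed = config$seed,
                             depth_limit = config$depth_limit)
  metrics <- evaluate_model(model, sp$test)
  roc1 <- roc_auc(hybrid_score(model, sp$test, stage = 1), sp$test$label)
  structure(list(features = features,
                 split = list(n_train = nrow(sp$train), n_test = nrow(sp$test)),
                 model = model, metrics = metrics, roc1 = roc1,
                 config = config, config_hash = config_hash(config),
                 seed = config$seed),
            class = "palsy_report")
}

#' @export
print.palsy_report <- function(x, ...) {
  cat("palsy evaluation report\n")
  cat("  subjects: ", nrow(x$features), " (train ", x$split$n_train,
      " / test ", x$split$n_test, ")\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %s: sensitivity %.3f, specificity %.3f\n",
                m$stage[i], m$sensitivity[i], m$specificity[i]))
  }
  cat(sprintf("  stage-1 AUC: %.3f\n", x$roc1$auc))
  invisible(x)
}
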
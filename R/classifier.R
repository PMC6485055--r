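#' Stratified subject-level train/test split
#'
#' Splits at the subject level (never the image level): if the table carries
#' several rows per subject, all rows of a subject land on the same side.
#' Per-stratum train counts are `fraction * n` apportioned by the
#' largest-remainder rule so the overall train size is
#' `round(fraction * n_total)`.
#'
#' @param subjects tibble with a `subject_id` column and the stratification
#'   column
#' @param train_fraction fraction in (0, 1)
#' @param stratify_by column name to stratify on (default `"label"`)
#' @param seed integer seed
#' @return list with `train` and `test` tibbles (row subsets of the input)
#' @export
split_cohort <- function(subjects, train_fraction = 0.7,
                         stratify_by = "label", seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  ids <- dplyr::distinct(subjects, .data$subject_id,
                         strat = .data[[stratify_by]])
  if (anyDuplicated(ids$subject_id)) {
    stop("a subject must have a single stratum value")
  }
  strata <- split(ids$subject_id, ids$strat)
  if (any(lengths(strata) == 0)) stop("empty stratum")
  n_total <- nrow(ids)
  target <- train_fraction * lengths(strata)
  base <- floor(target)
  extra <- round(train_fraction * n_total) - sum(base)
  if (extra > 0) {
    order_rem <- order(target - base, decreasing = TRUE)
    base[order_rem[seq_len(extra)]] <- base[order_rem[seq_len(extra)]] + 1
  }
  set.seed(seed)
  train_ids <- unlist(Map(function(id, k) sample(id, k), strata, base))
  list(train = subjects[subjects$subject_id %in% train_ids, , drop = FALSE],
       test = subjects[!subjects$subject_id %in% train_ids, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Rule extraction: depth-limited CART with Gini impurity and exhaustive
# threshold search. Thresholds are midpoints between consecutive distinct
# values; ties in impurity keep the lowest feature index. The extracted rule
# is the conjunction of predicates along the path to the positive leaf of
# highest purity.

gini <- function(y) {
  p <- mean(y)
  2 * p * (1 - p)
}

best_split <- function(X, y) {
  n <- length(y)
  best <- NULL
  best_imp <- gini(y) - 1e-12
  for (j in seq_len(ncol(X))) {
    x <- X[[j]]
    vals <- sort(unique(x))
    if (length(vals) < 2) next
    thr <- (head(vals, -1) + tail(vals, -1)) / 2
    for (t in thr) {
      left <- x < t
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      imp <- (nl * gini(y[left]) + (n - nl) * gini(y[!left])) / n
      if (imp < best_imp - 1e-12) {
        best_imp <- imp
        best <- list(feature = names(X)[j], threshold = t)
      }
    }
  }
  best
}

#' Extract a threshold rule from labelled features with a decision tree
#'
#' Fits a CART-style classification tree (Gini impurity, exhaustive
#' threshold search, depth limit) and returns the conjunction of threshold
#' predicates along the path to the positive (label 1) leaf of highest
#' purity. Single-class input yields a trivial rule that always (all
#' positive) or never (all negative) fires.
#'
#' @param features data frame of numeric predictors (the symmetry features
#'   plus their mean)
#' @param labels binary vector (1 = positive class the rule should capture)
#' @param depth_limit maximum number of conjoined predicates
#' @return tibble of class `palsy_rule` with columns `feature`, `comparator`
#'   (`"<"` or `">"`), `threshold`; attributes `trivial`, `purity`, `n_leaf`
#' @export
extract_rules <- function(features, labels, depth_limit = 2) {
  stopifnot(nrow(features) == length(labels))
  X <- tibble::as_tibble(features)
  X <- X[vapply(X, is.numeric, logical(1))]
  y <- as.integer(labels)
  if (length(unique(y)) < 2) {
    return(new_rule(tibble::tibble(feature = character(),
                                   comparator = character(),
                                   threshold = numeric()),
                    trivial = if (all(y == 1)) "always" else "never",
                    purity = mean(y), n_leaf = length(y)))
  }
  leaves <- list()
  grow <- function(idx, depth, path) {
    yy <- y[idx]
    sp <- if (depth < depth_limit && length(unique(yy)) > 1) {
      best_split(X[idx, , drop = FALSE], yy)
    }
    if (is.null(sp)) {
      leaves[[length(leaves) + 1L]] <<- list(path = path, purity = mean(yy),
                                             n = length(yy))
      return(invisible())
    }
    left <- X[[sp$feature]][idx] < sp$threshold
    grow(idx[left], depth + 1,
         c(path, list(list(feature = sp$feature, comparator = "<",
                           threshold = sp$threshold))))
    grow(idx[!left], depth + 1,
         c(path, list(list(feature = sp$feature, comparator = ">",
                           threshold = sp$threshold))))
  }
  grow(seq_along(y), 0, list())
  purities <- vapply(leaves, `[[`, numeric(1), "purity")
  sizes <- vapply(leaves, `[[`, numeric(1), "n")
  best <- order(-purities, -sizes)[1]
  path <- leaves[[best]]$path
  preds <- dplyr::bind_rows(lapply(path, tibble::as_tibble))
  if (nrow(preds) == 0) {
    preds <- tibble::tibble(feature = character(), comparator = character(),
                            threshold = numeric())
  }
  new_rule(preds, trivial = NA_character_, purity = purities[best],
           n_leaf = sizes[best])
}

new_rule <- function(preds, trivial, purity, n_leaf) {
  attr(preds, "trivial") <- trivial
  attr(preds, "purity") <- purity
  attr(preds, "n_leaf") <- n_leaf
  class(preds) <- unique(c("palsy_rule", class(preds)))
  preds
}

#' @rdname extract_rules
#' @param rule a `palsy_rule`
#' @param data data frame with the rule's feature columns
#' @return `rule_satisfied()` returns a logical vector, one entry per row.
#' @export
rule_satisfied <- function(rule, data) {
  trivial <- attr(rule, "trivial")
  if (isTRUE(trivial == "always")) return(rep(TRUE, nrow(data)))
  if (isTRUE(trivial == "never")) return(rep(FALSE, nrow(data)))
  out <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(rule))) {
    x <- data[[rule$feature[i]]]
    out <- out & if (rule$comparator[i] == "<") x < rule$threshold[i]
                 else x > rule$threshold[i]
  }
  out & !is.na(out)
}

# ---------------------------------------------------------------------------
# Regularized logistic regression (ridge) over a lambda grid, via glmnet.

default_lambda_grid <- function() 10^seq(2, -3, length.out = 10)

fit_rlr <- function(x, y, lambda_grid = default_lambda_grid()) {
  grid <- sort(unique(lambda_grid), decreasing = TRUE)
  if (min(table(factor(y, levels = c(0, 1)))) < 2) {
    # too few observations in a class for a logistic fit: constant majority
    # classifier across the whole grid
    a0 <- if (mean(y) > 0.5) 50 else -50
    return(list(lambdas = grid, a0 = rep(a0, length(grid)),
                beta = matrix(0, ncol(x), length(grid),
                              dimnames = list(colnames(x), NULL)),
                features = colnames(x)))
  }
  # glmnet warns when a class has < 8 observations (routine for the small
  # CP stratum); the ridge fit itself is fine
  fit <- suppressWarnings(
    glmnet::glmnet(as.matrix(x), factor(y, levels = c(0, 1)),
                   family = "binomial", alpha = 0, lambda = grid))
  list(lambdas = grid,
       a0 = as.numeric(fit$a0),
       beta = as.matrix(fit$beta),
       features = colnames(x))
}

rlr_prob <- function(model, data, lambda) {
  i <- which.min(abs(model$lambdas - lambda))
  x <- as.matrix(data[, model$features, drop = FALSE])
  as.numeric(stats::plogis(model$a0[i] + x %*% model$beta[, i]))
}

# Single-lambda coefficient slice kept inside a trained hybrid model.
rlr_slice <- function(model, lambda) {
  i <- which.min(abs(model$lambdas - lambda))
  list(a0 = model$a0[i], beta = as.numeric(model$beta[, i]),
       features = model$features, lambda = model$lambdas[i])
}

slice_prob <- function(slice, data) {
  x <- as.matrix(data[, slice$features, drop = FALSE])
  as.numeric(stats::plogis(slice$a0 + x %*% slice$beta))
}

# ML component dispatch: a coefficient slice or a plain function(data) -> 0/1
# (the latter supports mock classifiers and alternative families).
ml_labels <- function(ml, data) {
  if (is.function(ml)) return(as.integer(ml(data)))
  as.integer(slice_prob(ml, data) > 0.5)
}

# ---------------------------------------------------------------------------

#' Predict with the hybrid cascade
#'
#' The two-stage decision of the hybrid classifier: if rule 1 fires the
#' subject proceeds directly to the palsy-type stage, otherwise the stage-1
#' classifier decides (0 exits as healthy, 1 proceeds). In stage 2, rule 2
#' firing yields central palsy (CP) outright; otherwise the stage-2
#' classifier decides (0 = PP, 1 = CP). Machine-learning components are only
#' consulted for the subjects their rules leave undecided.
#'
#' @param model a [form_hybrid_model()] fit
#' @param newdata feature table (columns `f1`..`f11` and `mean_of_all`;
#'   missing values are imputed with the training-set column medians stored
#'   in the model)
#' @return factor with levels `healthy`, `PP`, `CP`
#' @export
hybrid_predict <- function(model, newdata) {
  data <- impute_with(newdata, model$medians)
  n <- nrow(data)
  out <- character(n)
  r1 <- rule_satisfied(model$rule1, data)
  to_stage2 <- r1
  undecided <- which(!r1)
  if (length(undecided) > 0) {
    m1 <- ml_labels(model$ml1, data[undecided, , drop = FALSE])
    out[undecided[m1 == 0]] <- "healthy"
    to_stage2[undecided[m1 == 1]] <- TRUE
  }
  s2 <- which(to_stage2)
  if (length(s2) > 0) {
    r2 <- rule_satisfied(model$rule2, data[s2, , drop = FALSE])
    out[s2[r2]] <- "CP"
    rem <- s2[!r2]
    if (length(rem) > 0) {
      m2 <- ml_labels(model$ml2, data[rem, , drop = FALSE])
      out[rem] <- ifelse(m2 == 1, "CP", "PP")
    }
  }
  factor(out, levels = c("healthy", "PP", "CP"))
}

impute_with <- function(data, medians) {
  if (is.null(medians)) return(data)
  for (nm in names(medians)) {
    if (nm %in% names(data)) {
      miss <- is.na(data[[nm]])
      if (any(miss)) data[[nm]][miss] <- medians[[nm]]
    }
  }
  if (all(feature_names() %in% names(data))) {
    data$mean_of_all <- rowMeans(data[, feature_names()])
  }
  data
}

stage_metrics <- function(truth, pred_pos) {
  tp <- sum(truth == 1 & pred_pos)
  fn <- sum(truth == 1 & !pred_pos)
  tn <- sum(truth == 0 & !pred_pos)
  fp <- sum(truth == 0 & pred_pos)
  tibble::tibble(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(truth),
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(truth)
  )
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# One cascade stage (rule + RLR) selected by k-fold cross-validation: per
# fold the rule is extracted and the RLR path fitted on the k-1 training
# folds, and the rule-or-RLR hybrid is scored on the left-out fold at every
# lambda (k x length(grid) performance entries). Per-lambda averages select
# the winner (highest mean sensitivity, ties by specificity, then grid
# order); the stage is refit on the full training set at that lambda.
form_hybrid_stage <- function(features, labels, k, lambda_grid, seed,
                              depth_limit = 2) {
  rule_cols <- c(feature_names(), "mean_of_all")
  ml_cols <- feature_names()
  if (length(unique(labels)) < 2) {
    # degenerate stage: a single observed class admits no classifier; the
    # trivial rule decides and the ML slice is a constant
    rule <- extract_rules(features[, rule_cols, drop = FALSE], labels,
                          depth_limit = depth_limit)
    const <- list(a0 = if (all(labels == 1)) 50 else -50,
                  beta = rep(0, length(ml_cols)), features = ml_cols,
                  lambda = lambda_grid[1])
    cv <- structure(list(entries = tibble::tibble(), averages = tibble::tibble(),
                         selected_lambda = lambda_grid[1], k = k),
                    class = "cv_result")
    return(list(rule = rule, ml = const, cv = cv))
  }
  fold <- stratified_folds(labels, k, seed)
  entries <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2) next
    rule <- extract_rules(features[tr, rule_cols, drop = FALSE], labels[tr],
                          depth_limit = depth_limit)
    rlr <- fit_rlr(features[tr, ml_cols, drop = FALSE], labels[tr],
                   lambda_grid)
    va <- which(!tr)
    r_fire <- rule_satisfied(rule, features[va, , drop = FALSE])
    for (lam in rlr$lambdas) {
      ml <- as.integer(rlr_prob(rlr, features[va, , drop = FALSE], lam) > 0.5)
      pred_pos <- r_fire | ml == 1
      entries[[length(entries) + 1L]] <-
        dplyr::mutate(stage_metrics(labels[va], pred_pos),
                      fold = f, lambda = lam, .before = 1)
    }
  }
  entries <- dplyr::bind_rows(entries)
  averages <- entries |>
    dplyr::group_by(lambda = .data$lambda) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity, na.rm = TRUE),
                     specificity = mean(.data$specificity, na.rm = TRUE),
                     accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop")
  averages <- averages[match(sort(unique(lambda_grid), decreasing = TRUE),
                             averages$lambda), , drop = FALSE]
  sel <- order(-averages$sensitivity, -averages$specificity)[1]
  selected <- averages$lambda[sel]
  rule <- extract_rules(features[, rule_cols, drop = FALSE], labels,
                        depth_limit = depth_limit)
  rlr <- fit_rlr(features[, ml_cols, drop = FALSE], labels, lambda_grid)
  list(rule = rule, ml = rlr_slice(rlr, selected),
       cv = structure(list(entries = entries, averages = averages,
                           selected_lambda = selected, k = k),
                      class = "cv_result"))
}

#' Train the two-stage hybrid classifier with cross-validated selection
#'
#' Stage 1 (healthy vs palsy) trains on the whole training set with
#' `label` (0 healthy, 1 palsy); stage 2 (PP vs CP) trains on the palsy
#' subjects only with `label2` (0 PP, 1 CP). Each stage pairs a decision-tree
#' threshold rule with a ridge logistic regression whose regularization
#' parameter is chosen by stratified k-fold cross-validation of the hybrid,
#' then refits on the full training set. Missing features are imputed with
#' training-set column medians (stored in the model for prediction time).
#'
#' @param train feature tibble with `f1`..`f11`, `mean_of_all`, `label`,
#'   `label2`
#' @param k folds
#' @param lambda_grid regularization grid (default 10 log-spaced values,
#'   1e-3 to 1e2)
#' @param seed integer seed controlling fold assignment
#' @param depth_limit rule depth (number of conjoined predicates)
#' @return list of class `hybrid_model` with `rule1`, `rule2`, `ml1`, `ml2`,
#'   per-stage `cv_result`s and the imputation medians
#' @export
form_hybrid_model <- function(train, k = 10, lambda_grid = default_lambda_grid(),
                              seed = 1L, depth_limit = 2) {
  stopifnot(k >= 2, length(lambda_grid) >= 1)
  cols <- c(feature_names(), "mean_of_all")
  medians <- lapply(train[feature_names()], median, na.rm = TRUE)
  train <- impute_with(train, medians)
  s1 <- form_hybrid_stage(train[, cols, drop = FALSE], train$label,
                          k, lambda_grid, seed, depth_limit)
  palsy <- train[train$label == 1, , drop = FALSE]
  s2 <- form_hybrid_stage(palsy[, cols, drop = FALSE], palsy$label2,
                          k, lambda_grid, seed + 1L, depth_limit)
  structure(list(rule1 = s1$rule, rule2 = s2$rule,
                 ml1 = s1$ml, ml2 = s2$ml,
                 lambda1 = s1$cv$selected_lambda,
                 lambda2 = s2$cv$selected_lambda,
                 cv1 = s1$cv, cv2 = s2$cv,
                 medians = medians, family = "rlr"),
            class = "hybrid_model")
}

#' Evaluate a hybrid model on a labelled test set
#'
#' Stage 1 counts a palsy subject as positive; stage 2 is scored on the
#' truly-palsy subjects with CP as the positive class (mirroring the
#' separate palsy-type test split).
#'
#' @param model a `hybrid_model`
#' @param test labelled feature tibble
#' @return tibble of class `eval_metrics`, one row per stage with
#'   sensitivity, specificity, accuracy and the confusion counts
#' @export
evaluate_model <- function(model, test) {
  pred <- hybrid_predict(model, test)
  s1 <- stage_metrics(test$label, pred != "healthy")
  palsy <- test$label == 1
  data2 <- impute_with(test[palsy, , drop = FALSE], model$medians)
  r2 <- rule_satisfied(model$rule2, data2)
  m2 <- rep(FALSE, nrow(data2))
  if (any(!r2)) {
    m2[!r2] <- ml_labels(model$ml2, data2[!r2, , drop = FALSE]) == 1
  }
  s2 <- stage_metrics(test$label2[palsy], r2 | m2)
  out <- dplyr::bind_rows(
    dplyr::mutate(s1, stage = "healthy_vs_palsy", .before = 1),
    dplyr::mutate(s2, stage = "pp_vs_cp", .before = 1)
  )
  class(out) <- unique(c("eval_metrics", class(out)))
  out
}

#' ROC curve and AUC over all score thresholds
#'
#' @param scores real-valued classifier scores (larger = more positive)
#' @param labels binary truth (1 = positive)
#' @return list of class `palsy_roc` with `curve` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc` (trapezoidal rule)
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # step the threshold over distinct score values
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(1 - y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(curve = tibble::tibble(threshold = c(Inf, s[keep]),
                                        fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "palsy_roc")
}

#' Hybrid score for ROC analysis
#'
#' Continuous stage score: 1 when the stage rule fires, else the RLR
#' probability.
#'
#' @param model a `hybrid_model`
#' @param data feature tibble
#' @param stage 1 (healthy vs palsy) or 2 (PP vs CP)
#' @return numeric scores in `[0, 1]`
#' @export
hybrid_score <- function(model, data, stage = 1) {
  data <- impute_with(data, model$medians)
  rule <- if (stage == 1) model$rule1 else model$rule2
  ml <- if (stage == 1) model$ml1 else model$ml2
  fired <- rule_satisfied(rule, data)
  p <- if (is.function(ml)) as.numeric(ml(data)) else slice_prob(ml, data)
  ifelse(fired, 1, p)
}

#' Repeated cross-validated evaluation
#'
#' Repeats the full protocol -- stratified 70/30 split, k-fold hybrid model
#' formation, held-out evaluation -- with distinct seeds and averages the
#' metrics.
#'
#' @param features labelled feature tibble (`f1`..`f11`, `mean_of_all`,
#'   `label`, `label2`)
#' @param reps repetitions
#' @param k folds per formation
#' @param seed base seed; repetition `r` uses `seed + r`
#' @param train_fraction split fraction
#' @return list of class `repeated_eval` with `runs` (per-rep metrics) and
#'   `summary` (mean and SD per stage)
#' @export
repeated_evaluation <- function(features, reps = 20, k = 10, seed = 1L,
                                train_fraction = 0.7) {
  stopifnot(reps >= 1)
  runs <- purrr::map(seq_len(reps), function(r) {
    sp <- split_cohort(features, train_fraction, "label", seed = seed + r)
    model <- form_hybrid_model(sp$train, k = k, seed = seed + r)
    dplyr::mutate(evaluate_model(model, sp$test), rep = r, .before = 1)
  })
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(stage = .data$stage) |>
    dplyr::summarise(
      mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      sd_sensitivity = sd(.data$sensitivity, na.rm = TRUE),
      mean_specificity = mean(.data$specificity, na.rm = TRUE),
      sd_specificity = sd(.data$specificity, na.rm = TRUE),
      mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
      .groups = "drop")
  structure(list(runs = runs, summary = summary, reps = reps, k = k),
            class = "repeated_eval")
}

#' Serialize a hybrid model to JSON
#'
#' Lossless for prediction: a round-trip through disk reproduces identical
#' class assignments.
#'
#' @param model a `hybrid_model` (function-valued ML components cannot be
#'   serialized)
#' @param path output path
#' @export
write_hybrid_model <- function(model, path) {
  ser_rule <- function(r) list(predicates = as.data.frame(r),
                               trivial = attr(r, "trivial"))
  if (is.function(model$ml1) || is.function(model$ml2)) {
    stop("function-valued ML components cannot be serialized")
  }
  obj <- list(rule1 = ser_rule(model$rule1), rule2 = ser_rule(model$rule2),
              ml1 = model$ml1, ml2 = model$ml2,
              lambda1 = model$lambda1, lambda2 = model$lambda2,
              medians = model$medians, family = model$family)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_hybrid_model
#' @export
read_hybrid_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_rule <- function(r) {
    preds <- dplyr::bind_rows(lapply(r$predicates, tibble::as_tibble))
    if (nrow(preds) == 0) {
      preds <- tibble::tibble(feature = character(), comparator = character(),
                              threshold = numeric())
    }
    new_rule(preds, trivial = if (is.null(r$trivial)) NA_character_ else r$trivial,
             purity = NA_real_, n_leaf = NA_real_)
  }
  de_ml <- function(m) list(a0 = m$a0, beta = unlist(m$beta, use.names = FALSE),
                            features = unlist(m$features, use.names = FALSE),
                            lambda = m$lambda)
  structure(list(rule1 = de_rule(obj$rule1), rule2 = de_rule(obj$rule2),
                 ml1 = de_ml(obj$ml1), ml2 = de_ml(obj$ml2),
                 lambda1 = obj$lambda1, lambda2 = obj$lambda2,
                 cv1 = NULL, cv2 = NULL,
                 medians = lapply(obj$medians, as.numeric),
                 family = obj$family),
            class = "hybrid_model")
}
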
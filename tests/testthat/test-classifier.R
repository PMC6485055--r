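test_that("stratified splits reproduce the study protocol counts", {
  subjects <- tibble::tibble(
    subject_id = sprintf("P%03d", 1:110),
    label = rep(c(1, 0), c(50, 60)))
  sp <- split_cohort(subjects, 0.7, "label", seed = 1)
  expect_equal(nrow(sp$train), 77)
  expect_equal(nrow(sp$test), 33)
  expect_equal(sum(sp$train$label), 35)
  expect_equal(sum(sp$train$label == 0), 42)
  expect_equal(sum(sp$test$label), 15)

  palsy <- tibble::tibble(subject_id = sprintf("Q%02d", 1:50),
                          label2 = rep(c(0, 1), c(40, 10)))
  sp2 <- split_cohort(palsy, 0.7, "label2", seed = 2)
  expect_equal(sum(sp2$train$label2 == 0), 28)
  expect_equal(sum(sp2$train$label2 == 1), 7)
  expect_equal(sum(sp2$test$label2 == 0), 12)
  expect_equal(sum(sp2$test$label2 == 1), 3)

  small <- tibble::tibble(subject_id = letters[1:10], label = rep(1, 10))
  sp3 <- split_cohort(small, 0.7, "label", seed = 3)
  expect_equal(nrow(sp3$train), 7)
  expect_equal(nrow(sp3$test), 3)

  # subject-level: all images of a subject stay on one side
  multi <- tidyr::crossing(subjects[1:20, ], expression = face_expressions())
  sp4 <- split_cohort(multi, 0.7, "label", seed = 4)
  expect_length(intersect(sp4$train$subject_id, sp4$test$subject_id), 0)
})

test_that("rule extraction finds thresholds inside the margin with Gini splits", {
  # 1-D perfectly separable at 0.95
  x <- tibble::tibble(f1 = c(seq(0.6, 0.9, length.out = 10),
                             seq(0.96, 1, length.out = 10)))
  y <- rep(c(1, 0), each = 10)
  rule <- extract_rules(x, y, depth_limit = 1)
  expect_equal(nrow(rule), 1)
  expect_equal(rule$feature, "f1")
  expect_equal(rule$comparator, "<")
  expect_gt(rule$threshold, 0.9)
  expect_lt(rule$threshold, 0.96)
  expect_true(all(rule_satisfied(rule, x) == (y == 1)))

  # conjunction shape at depth 2: f_x < t AND f_y < t
  set.seed(10)
  d <- tibble::tibble(mean_of_all = runif(200), f6 = runif(200))
  lab <- as.integer(d$mean_of_all < 0.95 & d$f6 < 0.95)
  rule2 <- extract_rules(d, lab, depth_limit = 2)
  expect_equal(nrow(rule2), 2)
  expect_true(all(rule2$comparator == "<"))
  expect_true(all(abs(rule2$threshold - 0.95) < 0.05))
  expect_true(all(rule_satisfied(rule2, d) == (lab == 1)))

  # pure single-class data yields a trivial rule
  triv <- extract_rules(x, rep(1, 20))
  expect_equal(attr(triv, "trivial"), "always")
  expect_true(all(rule_satisfied(triv, x)))
  triv0 <- extract_rules(x, rep(0, 20))
  expect_false(any(rule_satisfied(triv0, x)))
})

test_that("the hybrid cascade matches an exhaustive truth-table oracle", {
  # mock components: rules over two indicator features, counting classifiers
  rule1 <- palsymetry:::new_rule(
    tibble::tibble(feature = "a", comparator = "<", threshold = 0.5),
    trivial = NA_character_, purity = 1, n_leaf = 1)
  rule2 <- palsymetry:::new_rule(
    tibble::tibble(feature = "b", comparator = ">", threshold = 0.5),
    trivial = NA_character_, purity = 1, n_leaf = 1)
  calls <- new.env()
  calls$ml1 <- 0L; calls$ml2 <- 0L
  ml1 <- function(data) { calls$ml1 <- calls$ml1 + nrow(data); data$m1 }
  ml2 <- function(data) { calls$ml2 <- calls$ml2 + nrow(data); data$m2 }
  model <- structure(list(rule1 = rule1, rule2 = rule2, ml1 = ml1, ml2 = ml2,
                          medians = NULL, family = "mock"),
                     class = "hybrid_model")

  grid <- tidyr::crossing(a = c(0, 1), b = c(0, 1), m1 = c(0, 1), m2 = c(0, 1))
  pred <- hybrid_predict(model, grid)

  # independent exhaustive oracle over the cascade logic
  oracle <- apply(grid, 1, function(r) {
    stage2 <- FALSE
    if (r["a"] < 0.5) stage2 <- TRUE          # rule 1 fires
    else if (r["m1"] == 0) return("healthy")  # classifier exits
    if (r["b"] > 0.5) return("CP")            # rule 2 fires
    if (r["m2"] == 1) "CP" else "PP"
  })
  expect_equal(as.character(pred), unname(oracle))

  # cascade consistency: when both rules fire, no ML model is consulted
  calls$ml1 <- 0L; calls$ml2 <- 0L
  both <- tibble::tibble(a = 0, b = 1, m1 = 1, m2 = 1)
  expect_equal(as.character(hybrid_predict(model, both)), "CP")
  expect_equal(calls$ml1, 0L)
  expect_equal(calls$ml2, 0L)
})

test_that("hybrid model formation yields folds x parameters entries and averages", {
  ft <- cached("sim_features", simulate_feature_table(60, 40, 10, seed = 5))
  sp <- cached("sim_split", split_cohort(ft, 0.7, "label", seed = 2))
  model <- cached("sim_model", form_hybrid_model(sp$train, k = 10, seed = 3))

  expect_equal(nrow(model$cv1$entries), 10 * 10)
  expect_equal(nrow(model$cv1$averages), 10)
  expect_equal(nrow(model$cv2$entries), 10 * 10)
  expect_true(model$lambda1 %in% default_lambda_grid())

  # N = 80, k = 10 -> folds of 8
  y80 <- rep(c(0, 1), each = 40)
  folds <- palsymetry:::stratified_folds(y80, 10, seed = 1)
  expect_true(all(table(folds) == 8))

  # selection reproducible under a fixed seed
  m2 <- form_hybrid_model(sp$train, k = 10, seed = 3)
  expect_equal(m2$lambda1, model$lambda1)
  expect_equal(m2$lambda2, model$lambda2)
  expect_equal(tidy(m2$rule1), tidy(model$rule1))

  # the learned stage-2 rule keys on upper-face or iris features
  expect_true(all(model$rule2$feature %in% c("f1", "f2", "f3", "f4", "f10", "f11")))
})

test_that("held-out evaluation separates the synthetic classes", {
  ft <- cached("sim_features", simulate_feature_table(60, 40, 10, seed = 5))
  sp <- cached("sim_split", split_cohort(ft, 0.7, "label", seed = 2))
  model <- cached("sim_model", form_hybrid_model(sp$train, k = 10, seed = 3))
  ev <- evaluate_model(model, sp$test)
  expect_s3_class(ev, "eval_metrics")
  expect_equal(nrow(ev), 2)
  s1 <- ev[ev$stage == "healthy_vs_palsy", ]
  expect_gte(s1$sensitivity, 0.95)
  expect_equal(s1$tp + s1$fn, sum(sp$test$label))

  # degenerate prediction patterns
  all_pos <- palsymetry:::stage_metrics(rep(c(1, 0), 5), rep(TRUE, 10))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  all_right <- palsymetry:::stage_metrics(c(1, 0, 1), c(TRUE, FALSE, TRUE))
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
})

test_that("sensitivity at n = 200 on a separable cohort reaches 0.95", {
  ft <- simulate_feature_table(100, 80, 20, seed = 13)
  sp <- split_cohort(ft, 0.7, "label", seed = 13)
  model <- form_hybrid_model(sp$train, k = 10, seed = 13)
  ev <- evaluate_model(model, sp$test)
  expect_gte(ev$sensitivity[ev$stage == "healthy_vs_palsy"], 0.95)
})

test_that("ROC/AUC equals the pairwise concordance statistic", {
  # perfectly separating scores
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_true(all(diff(perfect$curve$tpr) >= 0))
  expect_true(all(diff(perfect$curve$fpr) >= 0))

  # random scores: AUC near 1/2 at large n
  set.seed(20)
  sc <- runif(4000); lb <- rbinom(4000, 1, 0.5)
  expect_equal(roc_auc(sc, lb)$auc, 0.5, tolerance = 0.03)

  # equality with the Mann-Whitney pairwise statistic, ties counted half
  set.seed(21)
  for (i in 1:5) {
    sc <- round(rnorm(60), 1)  # induce ties
    lb <- rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    expect_equal(roc_auc(sc, lb)$auc, mean(pairs), tolerance = 1e-12)
  }

  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("repeated evaluation aggregates one record per repetition", {
  ft <- cached("sim_features", simulate_feature_table(60, 40, 10, seed = 5))
  re <- repeated_evaluation(ft, reps = 3, k = 5, seed = 9)
  expect_equal(nrow(re$runs), 3 * 2)
  expect_equal(nrow(re$summary), 2)
  expect_true(all(re$summary$mean_sensitivity >= 0))

  # a single repetition equals one formation run at the same seed
  re1 <- repeated_evaluation(ft, reps = 1, k = 5, seed = 9)
  sp <- split_cohort(ft, 0.7, "label", seed = 10)
  m <- form_hybrid_model(sp$train, k = 5, seed = 10)
  ev <- evaluate_model(m, sp$test)
  expect_equal(re1$runs$sensitivity, ev$sensitivity)
  expect_equal(re1$runs$specificity, ev$specificity)
})

test_that("hybrid models survive a JSON round trip with identical predictions", {
  ft <- cached("sim_features", simulate_feature_table(60, 40, 10, seed = 5))
  sp <- cached("sim_split", split_cohort(ft, 0.7, "label", seed = 2))
  model <- cached("sim_model", form_hybrid_model(sp$train, k = 10, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_hybrid_model(model, path)
  model2 <- read_hybrid_model(path)
  expect_identical(hybrid_predict(model2, sp$test),
                   hybrid_predict(model, sp$test))
})

test_that("tidy and glance methods summarise fitted objects", {
  ft <- cached("sim_features", simulate_feature_table(60, 40, 10, seed = 5))
  sp <- cached("sim_split", split_cohort(ft, 0.7, "label", seed = 2))
  model <- cached("sim_model", form_hybrid_model(sp$train, k = 10, seed = 3))
  td <- tidy(model)
  expect_true(all(c("stage", "component", "term", "estimate") %in% names(td)))
  expect_true(any(td$component == "rule"))
  expect_true(any(td$component == "rlr"))
  gl <- glance(model)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$lambda1, model$lambda1)
  roc <- roc_auc(hybrid_score(model, sp$test, 1), sp$test$label)
  expect_equal(glance(roc)$auc, roc$auc)
})
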
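#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted palsymetry objects
#'
#' `tidy.hybrid_model()` returns one row per model term: the rule predicates
#' of both stages and the ridge logistic coefficients of both stage
#' classifiers. `glance.hybrid_model()` returns a one-row summary with the
#' selected regularization parameters and cross-validated averages.
#'
#' @param x a fitted object
#' @param ... unused
#' @return a tibble
#' @export
tidy.hybrid_model <- function(x, ...) {
  rule_rows <- function(rule, stage) {
    if (nrow(rule) == 0) return(NULL)
    tibble::tibble(stage = stage, component = "rule",
                   term = paste(rule$feature, rule$comparator,
                                signif(rule$threshold, 6)),
                   feature = rule$feature, estimate = rule$threshold)
  }
  ml_rows <- function(ml, stage) {
    if (is.function(ml)) return(NULL)
    tibble::tibble(stage = stage, component = "rlr",
                   term = c("(Intercept)", ml$features),
                   feature = c(NA_character_, ml$features),
                   estimate = c(ml$a0, ml$beta))
  }
  dplyr::bind_rows(rule_rows(x$rule1, "healthy_vs_palsy"),
                   ml_rows(x$ml1, "healthy_vs_palsy"),
                   rule_rows(x$rule2, "pp_vs_cp"),
                   ml_rows(x$ml2, "pp_vs_cp"))
}

#' @rdname tidy.hybrid_model
#' @export
glance.hybrid_model <- function(x, ...) {
  cv_row <- function(cv) {
    if (is.null(cv)) return(c(NA_real_, NA_real_))
    i <- match(cv$selected_lambda, cv$averages$lambda)
    c(cv$averages$sensitivity[i], cv$averages$specificity[i])
  }
  c1 <- cv_row(x$cv1); c2 <- cv_row(x$cv2)
  tibble::tibble(family = x$family, lambda1 = x$lambda1, lambda2 = x$lambda2,
                 cv_sensitivity1 = c1[1], cv_specificity1 = c1[2],
                 cv_sensitivity2 = c2[1], cv_specificity2 = c2[2],
                 n_rule1 = nrow(x$rule1), n_rule2 = nrow(x$rule2))
}

#' @rdname tidy.hybrid_model
#' @export
tidy.palsy_rule <- function(x, ...) {
  tibble::tibble(feature = x$feature, comparator = x$comparator,
                 threshold = x$threshold)
}

#' @rdname tidy.hybrid_model
#' @export
tidy.cv_result <- function(x, ...) {
  x$averages
}

#' @rdname tidy.hybrid_model
#' @export
tidy.palsy_roc <- function(x, ...) {
  x$curve
}

#' @rdname tidy.hybrid_model
#' @export
glance.palsy_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_thresholds = nrow(x$curve))
}

#' @rdname tidy.hybrid_model
#' @export
tidy.repeated_eval <- function(x, ...) {
  x$runs
}

#' @rdname tidy.hybrid_model
#' @export
glance.repeated_eval <- function(x, ...) {
  s <- x$summary
  tibble::tibble(reps = x$reps, k = x$k,
                 sensitivity1 = s$mean_sensitivity[s$stage == "healthy_vs_palsy"],
                 specificity1 = s$mean_specificity[s$stage == "healthy_vs_palsy"],
                 sensitivity2 = s$mean_sensitivity[s$stage == "pp_vs_cp"],
                 specificity2 = s$mean_specificity[s$stage == "pp_vs_cp"])
}

#' @rdname tidy.hybrid_model
#' @export
glance.palsy_report <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n_subjects = nrow(x$features),
    n_train = x$split$n_train, n_test = x$split$n_test,
    sensitivity1 = m$sensitivity[m$stage == "healthy_vs_palsy"],
    specificity1 = m$specificity[m$stage == "healthy_vs_palsy"],
    sensitivity2 = m$sensitivity[m$stage == "pp_vs_cp"],
    specificity2 = m$specificity[m$stage == "pp_vs_cp"],
    auc1 = x$roc1$auc,
    config_hash = x$config_hash, seed = x$seed)
}
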
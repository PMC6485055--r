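# Shared fixtures, built in code and cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# In-memory manifest for a cohort: one row per subject-expression with image
# and ground-truth landmark list-columns.
render_manifest <- function(cohort, width = 360, noise_sd = 2) {
  rows <- purrr::pmap(cohort, function(subject_id, klass, upper_asym,
                                       lower_asym, iris_asym, seed, label,
                                       label2, expression, ...) {
    subj <- synthetic_subject(subject_id, klass, upper_asym, lower_asym,
                              iris_asym, seed)
    face <- render_face(subj, expression, width = width, noise_sd = noise_sd)
    tibble::tibble(subject_id = subject_id, expression = expression,
                   image = list(face$image), landmarks = list(face$landmarks),
                   label = label, label2 = label2, klass = klass)
  })
  dplyr::bind_rows(rows)
}

# The reference study cohort: 110 subjects (60 healthy, 40 PP, 10 CP),
# rendered once and reused by the feature-recovery and end-to-end checks.
study_cohort <- function() cached("cohort110", simulate_cohort(60, 40, 10, seed = 101))

study_features <- function() {
  cached("features110", {
    manifest <- render_manifest(study_cohort())
    extract_feature_table(manifest)
  })
}

# Cascade training set: faces rendered small for speed.
cascade_examples <- function(n, width = 120, seed = 77) {
  set.seed(seed)
  subs <- simulate_cohort(ceiling(n / 3), ceiling(n / 3), ceiling(n / 6),
                          seed = seed)
  subs <- subs[!duplicated(subs$subject_id), ]
  lapply(seq_len(n), function(i) {
    row <- subs[sample(nrow(subs), 1), ]
    subj <- synthetic_subject(row$subject_id, row$klass, row$upper_asym,
                              row$lower_asym, row$iris_asym, row$seed)
    face <- render_face(subj, sample(face_expressions(), 1), width = width)
    list(image = face$image, landmarks = face$landmarks,
         face_box = face$face_box)
  })
}

mean_landmark_error <- function(pred, truth) {
  mean(sqrt((pred$x - truth$x)^2 + (pred$y - truth$y)^2))
}

# Random eye specification within the operator's documented search domain
# (center in the central third, radius 15-40% of the box, upper lid
# occluding at most about a quarter of the disk).
random_eye_spec <- function() {
  repeat {
    w <- sample(90:140, 1); h <- sample(70:110, 1)
    bm <- min(w, h)
    r_lo <- ceiling(0.15 * bm); r_hi <- floor(0.4 * bm)
    if (r_lo >= r_hi) next
    r <- sample(r_lo:r_hi, 1)
    cxr <- ceiling(w / 3):floor(2 * w / 3)
    cyr <- ceiling(h / 3):floor(2 * h / 3)
    cxr <- cxr[cxr > r + 3 & cxr < w - r - 3]
    cyr <- cyr[cyr > r + 3 & cyr < h - r - 3]
    if (!length(cxr) || !length(cyr)) next
    cx <- sample(cxr, 1); cy <- sample(cyr, 1)
    a <- runif(1, 0, 0.008)
    vy <- cy - r + runif(1, -0.3 * r, 0.4 * r)
    cc <- vy + a * cx^2
    b <- -2 * a * cx
    if (any(a * (1:w)^2 + b * (1:w) + cc < 1)) next
    lid <- min(h - 2, cy + r + sample(0:4, 1))
    spec <- tryCatch(
      synthetic_eye_spec(w, h, c(cx, cy), r, c(a, b, cc), lid, noise_sd = 2),
      error = function(e) NULL)
    if (is.null(spec)) next
    return(spec)
  }
}
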
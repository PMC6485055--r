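#' Euclidean distance between two points
#'
#' @param p,q length-2 numeric vectors `c(x, y)`
#' @return distance in pixels
#' @export
point_distance <- function(p, q) {
  stopifnot(all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Left/right distance ratio (dRatio)
#'
#' The symmetry ratio of a paired left/right measurement: the smaller of the
#' two distances divided by the larger, so the result lies in `(0, 1]` and
#' equals 1 for a perfectly symmetric pair, regardless of which side is
#' affected.
#'
#' @param d_left,d_right paired distances (> 0)
#' @return ratio in `(0, 1]`
#' @export
d_ratio <- function(d_left, d_right) {
  if (any(!is.finite(c(d_left, d_right))) || d_left <= 0 || d_right <= 0) {
    stop("distances must be positive")
  }
  if (d_right > d_left) d_left / d_right else d_right / d_left
}

# Distance pairs measured per expression. rest/raise: SO-IO and SO-NT;
# frown: NT-nostril and NT-MA; smile: IC-MA, NT-MA and IO-MA.
expression_distance_spec <- function(expression) {
  switch(expression,
    rest = ,
    raise = list(
      SO_IO = list(r = c("SO_R", "IO_R"), l = c("SO_L", "IO_L")),
      SO_NT = list(r = c("SO_R", "NT"), l = c("SO_L", "NT"))
    ),
    frown = list(
      NT_NOSTRIL = list(r = c("NT", "NOSTRIL_R"), l = c("NT", "NOSTRIL_L")),
      NT_MA = list(r = c("NT", "MA_R"), l = c("NT", "MA_L"))
    ),
    smile = list(
      IC_MA = list(r = c("IC_R", "MA_R"), l = c("IC_L", "MA_L")),
      NT_MA = list(r = c("NT", "MA_R"), l = c("NT", "MA_L")),
      IO_MA = list(r = c("MA_R", "IO_R"), l = c("MA_L", "IO_L"))
    ),
    stop("unknown expression: ", expression)
  )
}

#' Named left/right distance pairs for one expression
#'
#' At rest and while raising the eyebrows the upper-face distances SO-IO and
#' SO-NT are measured; frowning measures NT-nostril and NT-MA; smiling
#' measures IC-MA, NT-MA and IO-MA.
#'
#' @param sp a [extract_salient()] tibble
#' @param expression one of `"rest"`, `"raise"`, `"frown"`, `"smile"`
#' @return tibble with `name`, `d_right`, `d_left`, `ratio`
#' @export
expression_distances <- function(sp, expression) {
  spec <- expression_distance_spec(expression)
  rows <- purrr::imap(spec, function(pair, nm) {
    dr <- point_distance(salient_point(sp, pair$r[1]), salient_point(sp, pair$r[2]))
    dl <- point_distance(salient_point(sp, pair$l[1]), salient_point(sp, pair$l[2]))
    tibble::tibble(name = nm, d_right = dr, d_left = dl,
                   ratio = d_ratio(dl, dr))
  })
  dplyr::bind_rows(rows)
}

#' Eyebrow movement rate between rest and raise
#'
#' For each side the ratio of the SO-IO distance (`a`) to the SO-NT distance
#' (`b`) is taken at rest and at raise; the absolute change of that ratio is
#' the side's movement. The rate is the smaller movement divided by the
#' larger (the same min/max convention as the distance ratios), approaching
#' 1 for a subject who raises both eyebrows equally and 0 for a one-sided
#' lift. When both movements fall below `floor` the rate is defined as 1
#' (no detectable lift on either side is symmetric).
#'
#' @param sp_rest,sp_raise salient-point tibbles at rest and raise
#' @param floor movement floor below which both sides count as static
#' @return rate in `[0, 1]`
#' @export
movement_rate <- function(sp_rest, sp_raise, floor = 0.005) {
  side_ratio <- function(sp, sfx) {
    a <- point_distance(salient_point(sp, paste0("SO", sfx)),
                        salient_point(sp, paste0("IO", sfx)))
    b <- point_distance(salient_point(sp, paste0("SO", sfx)),
                        salient_point(sp, "NT"))
    if (b <= 0) stop("zero SO-NT distance")
    a / b
  }
  move_r <- abs(side_ratio(sp_raise, "_R") - side_ratio(sp_rest, "_R"))
  move_l <- abs(side_ratio(sp_raise, "_L") - side_ratio(sp_rest, "_L"))
  if (move_r < floor && move_l < floor) return(1)
  min(move_r, move_l) / max(move_r, move_l)
}

feature_names <- function() paste0("f", 1:11)

#' Assemble the 11-feature symmetry vector of a subject
#'
#' The feature enumeration: `f1` rest SO-IO ratio, `f2` rest SO-NT ratio,
#' `f3` raise SO-IO ratio, `f4` raise SO-NT ratio, `f5` smile IC-MA ratio,
#' `f6` smile IO-MA ratio, `f7` smile NT-MA ratio, `f8` frown NT-MA ratio,
#' `f9` frown NT-nostril ratio, `f10` visible-iris-area ratio averaged over
#' the raise and frown images, `f11` eyebrow movement rate. `mean_of_all` is
#' the arithmetic mean of the present features. Optionally (`iris_split =
#' TRUE`) the two iris measurements are kept as separate raise/frown columns
#' `f10a`/`f10b` instead of the single averaged `f10`.
#'
#' @param expression_set list with element `salient` (named list of
#'   salient-point tibbles per expression, at least rest and raise) and
#'   `iris` (tibble with `expression`, `area_left`, `area_right` for the
#'   raise and frown images)
#' @param min_present minimum number of present features; below it the
#'   record is rejected with an error
#' @param iris_split keep the raise and frown iris ratios as two columns
#' @return one-row tibble with the features, `mean_of_all` and `n_missing`
#' @export
assemble_features <- function(expression_set, min_present = 6,
                              iris_split = FALSE) {
  sal <- expression_set$salient
  if (!all(c("rest", "raise") %in% names(sal))) {
    stop("at least the rest and raise expressions are required")
  }
  safe_ratio <- function(expr, name) {
    if (is.null(sal[[expr]])) return(NA_real_)
    out <- tryCatch(expression_distances(sal[[expr]], expr),
                    error = function(e) NULL)
    if (is.null(out)) return(NA_real_)
    v <- out$ratio[match(name, out$name)]
    if (length(v) == 0) NA_real_ else v
  }
  iris_ratio <- function(expr) {
    ir <- expression_set$iris
    if (is.null(ir)) return(NA_real_)
    row <- ir[ir$expression == expr, , drop = FALSE]
    if (nrow(row) == 0 || !is.finite(row$area_left) || !is.finite(row$area_right) ||
        row$area_left <= 0 || row$area_right <= 0) {
      return(NA_real_)
    }
    d_ratio(row$area_left, row$area_right)
  }
  f <- c(
    f1 = safe_ratio("rest", "SO_IO"),
    f2 = safe_ratio("rest", "SO_NT"),
    f3 = safe_ratio("raise", "SO_IO"),
    f4 = safe_ratio("raise", "SO_NT"),
    f5 = safe_ratio("smile", "IC_MA"),
    f6 = safe_ratio("smile", "IO_MA"),
    f7 = safe_ratio("smile", "NT_MA"),
    f8 = safe_ratio("frown", "NT_MA"),
    f9 = safe_ratio("frown", "NT_NOSTRIL")
  )
  iris_raise <- iris_ratio("raise")
  iris_frown <- iris_ratio("frown")
  f10 <- if (all(is.na(c(iris_raise, iris_frown)))) NA_real_ else
    mean(c(iris_raise, iris_frown), na.rm = TRUE)
  f11 <- tryCatch(movement_rate(sal$rest, sal$raise), error = function(e) NA_real_)
  if (iris_split) {
    vec <- c(f, f10a = iris_raise, f10b = iris_frown, f11 = f11)
  } else {
    vec <- c(f, f10 = f10, f11 = f11)
  }
  n_present <- sum(!is.na(vec))
  if (n_present < min_present) {
    stop("record rejected: only ", n_present, " features present")
  }
  out <- tibble::as_tibble(as.list(vec))
  out$mean_of_all <- mean(vec, na.rm = TRUE)
  out$n_missing <- sum(is.na(vec))
  out
}
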
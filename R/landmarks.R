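#' Landmark sets and salient facial points
#'
#' A landmark set is a tibble with exactly 68 rows and columns `point_id`
#' (1..68, the standard 68-point facial layout), `x`, `y` (pixel
#' coordinates, x rightward, y downward, 1-based). "Right"/"left" refer to
#' the subject's anatomical side; the subject's right appears at smaller x
#' in a frontal image.
#'
#' @param landmarks a data frame with `point_id`, `x`, `y`
#' @param frame optional `c(height, width)` of the source image
#' @return a validated tibble of class `landmark_set`
#' @export
as_landmark_set <- function(landmarks, frame = NULL) {
  lm <- tibble::as_tibble(landmarks)
  stopifnot(all(c("point_id", "x", "y") %in% names(lm)))
  if (nrow(lm) != 68) stop("a landmark set has exactly 68 points")
  if (anyDuplicated(lm$point_id)) stop("landmark indices must be unique")
  if (!all(is.finite(lm$x)) || !all(is.finite(lm$y))) {
    stop("landmark coordinates must be finite")
  }
  lm <- dplyr::arrange(lm, .data$point_id)
  attr(lm, "frame") <- frame
  class(lm) <- unique(c("landmark_set", class(lm)))
  lm
}

#' @rdname as_landmark_set
#' @param path CSV file with columns `point_id`, `x`, `y`
#' @export
read_landmarks <- function(path) {
  as_landmark_set(utils::read.csv(path))
}

#' @rdname as_landmark_set
#' @export
write_landmarks <- function(landmarks, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(points = landmarks[, c("point_id", "x", "y")]), path,
      auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(landmarks[, c("point_id", "x", "y")], path,
                     row.names = FALSE)
  }
  invisible(path)
}

# Fixed index map from the 68-point layout to the named salient points.
# Midpoints stand in for points that are not raw landmarks: the upper eyelid
# (UE) is the midpoint of the two upper-lid landmarks and the infra-orbital
# point (IO) the midpoint of the two lower-lid landmarks.
salient_index_map <- function() {
  list(
    SO_R = 20, SO_L = 25,
    IC_R = 40, IC_L = 43,
    OC_R = 37, OC_L = 46,
    UE_R = c(38, 39), UE_L = c(44, 45),
    IO_R = c(41, 42), IO_L = c(47, 48),
    MA_R = 49, MA_L = 55,
    NT = 31,
    NOSTRIL_R = 33, NOSTRIL_L = 35
  )
}

#' Extract the named salient points from a landmark set
#'
#' Resolves the supra-orbital (SO), infra-orbital (IO), inner/outer canthus
#' (IC/OC), upper eyelid (UE), mouth angle (MA), nose tip (NT) and nostril
#' points per side from the 68-point layout: SO = brow midpoint landmarks 20
#' and 25, IC = 40/43, OC = 37/46, MA = 49/55, NT = 31, nostrils = 33/35;
#' UE and IO are eyelid-landmark midpoints.
#'
#' @param lm a [as_landmark_set()] tibble
#' @return tibble of class `salient_points` with columns `name`, `x`, `y`
#' @export
extract_salient <- function(lm) {
  lm <- as_landmark_set(lm, attr(lm, "frame"))
  xy <- cbind(lm$x, lm$y)
  map <- salient_index_map()
  pts <- t(vapply(map, function(idx) colMeans(xy[idx, , drop = FALSE]),
                  numeric(2)))
  out <- tibble::tibble(name = names(map), x = pts[, 1], y = pts[, 2])
  attr(out, "frame") <- attr(lm, "frame")
  class(out) <- unique(c("salient_points", class(out)))
  out
}

# Named point lookup from a salient tibble.
salient_point <- function(sp, name) {
  i <- match(name, sp$name)
  if (is.na(i)) stop("unknown salient point: ", name)
  c(sp$x[i], sp$y[i])
}

# Lower-eyelid polyline (outer corner, two lower-lid landmarks, inner
# corner) for one eye, ordered by x; used as the lower clipping boundary of
# the iris segment.
lower_lid_polyline <- function(lm, side = c("right", "left")) {
  side <- match.arg(side)
  idx <- if (side == "right") c(37, 42, 41, 40) else c(43, 48, 47, 46)
  pts <- cbind(lm$x[idx], lm$y[idx])
  pts[order(pts[, 1]), , drop = FALSE]
}
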
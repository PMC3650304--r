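# Eye-angle measurement for restrained larvae: the two eyes appear as
# dark ellipses inside the bright head. Within a user-supplied region of
# interest, a negative (dark-object) threshold isolates the two largest
# dark components, each is fit with a moment-based ellipse, and the angle
# between its major axis and the body axis is reported, nasal-positive.

moment_ellipse <- function(idx) {
  xy <- cbind(idx[, 2], idx[, 1])
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  e <- eigen(cv)
  list(center = ctr,
       major = 2 * sqrt(max(e$values[1], 1e-9)),
       minor = 2 * sqrt(max(e$values[2], 1e-9)),
       axis = e$vectors[, 1])
}

#' Fit both eyes inside a region of interest
#'
#' @param frame grayscale matrix (0-255).
#' @param roi list with `x` and `y` integer ranges covering both eyes.
#' @param body_axis_deg heading direction in degrees (right-positive
#'   convention as elsewhere).
#' @param threshold gray level below which pixels count as eye; `NULL`
#'   uses an adaptive (Otsu on the inverted ROI) threshold.
#' @param min_area minimum component area, px.
#' @return an `eye_pose` list with `left` and `right` entries (each:
#'   `angle_deg` nasal-positive, `center`, `major`, `minor`) or
#'   `missing = TRUE` with a `reason` when fewer than two components are
#'   found.
#' @export
fit_eyes <- function(frame, roi, body_axis_deg, threshold = NULL,
                     min_area = 10) {
  sub <- frame[roi$y, roi$x, drop = FALSE]
  inv <- (255 - sub) / 255
  thr <- if (is.null(threshold))
    EBImage::otsu(EBImage::Image(inv)) else (255 - threshold) / 255
  m <- inv > thr
  lab <- label_components(m)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))
  if (max(lab) == 0)
    return(structure(list(missing = TRUE, reason = "no dark components"),
                     class = "eye_pose"))
  # the dark background is also below the eye threshold; inside a ROI
  # drawn around the head it touches the ROI border, the enclosed eyes
  # do not
  border <- touches_border(lab)
  areas <- component_areas(lab)
  keep <- order(areas, decreasing = TRUE)
  keep <- setdiff(keep[areas[keep] >= min_area], border)
  if (length(keep) < 2)
    return(structure(list(missing = TRUE,
                          reason = "fewer than two eye components"),
                     class = "eye_pose"))
  keep <- keep[1:2]
  u <- c(cos(deg2rad(body_axis_deg)), sin(deg2rad(body_axis_deg)))
  r_vec <- rotate_xy(u, 90)  # fish's right
  eyes <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    e <- moment_ellipse(idx)
    # back to full-frame coordinates
    e$center <- e$center + c(min(roi$x) - 1, min(roi$y) - 1)
    e
  })
  ctr_mid <- (eyes[[1]]$center + eyes[[2]]$center) / 2
  side <- vapply(eyes, function(e)
    sum((e$center - ctr_mid) * r_vec), numeric(1))
  right_i <- which.max(side); left_i <- which.min(side)
  ang_rel <- function(e) {
    a <- signed_angle(u, e$axis)
    if (a > 90) a <- a - 180
    if (a <= -90) a <- a + 180
    a
  }
  left <- eyes[[left_i]]; right <- eyes[[right_i]]
  left$angle_deg <- ang_rel(left)          # nasal-positive for the left eye
  right$angle_deg <- -ang_rel(right)       # mirror for the right eye
  structure(list(left = left, right = right, missing = FALSE),
            class = "eye_pose")
}
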
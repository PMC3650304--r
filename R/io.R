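# Small text-format writers for pipeline outputs.

#' Write a ground-truth record as a JSON sidecar
#' @param truth a `ground_truth` object.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  x <- truth
  x$params <- unclass(x$params)
  x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a per-frame pose table as CSV
#' @param poses data.frame from [track_midline()], optionally merged with
#'   [prey_geometry()] columns.
#' @param path output file.
#' @export
write_pose_csv <- function(poses, path) {
  utils::write.csv(poses, path, row.names = FALSE)
  invisible(path)
}

#' Write a QC overlay of the fitted midline on a frame as PNG
#'
#' Burns the six-segment midline polyline into the grayscale frame so
#' tracking quality can be inspected visually.
#'
#' @param frame grayscale matrix (0-255).
#' @param pose a `midline_pose` from [extract_midline()].
#' @param path output PNG file.
#' @export
write_qc_overlay <- function(frame, pose, path) {
  img <- frame / 255
  v <- pose$vertices
  for (k in 1:6) {
    nsmp <- max(2L, ceiling(sqrt(sum((v[k + 1, ] - v[k, ])^2)) / 0.5))
    tt <- seq(0, 1, length.out = nsmp)
    xs <- round(v[k, 1] + tt * (v[k + 1, 1] - v[k, 1]))
    ys <- round(v[k, 2] + tt * (v[k + 1, 2] - v[k, 2]))
    ok <- xs >= 1 & xs <= ncol(img) & ys >= 1 & ys <= nrow(img)
    img[cbind(ys[ok], xs[ok])] <- if (k == 1) 1 else 0
  }
  png::writePNG(img, path)
  invisible(path)
}
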
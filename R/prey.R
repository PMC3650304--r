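# Prey tracking and fish-prey geometry.

#' Track the prey centroid across a small-object binary stack
#'
#' After seeding on the prey in the first frame, each frame's centroid is
#' the candidate component nearest the previous known centroid within
#' `max_jump_px`; frames with no candidate are flagged as gaps, and the
#' track is declared lost after more than `max_gap` consecutive gaps.
#'
#' @param prep output of [preprocess_prey()].
#' @param seed_centroid c(x, y), inside a foreground component in frame 1.
#' @param max_jump_px maximum allowed frame-to-frame displacement.
#' @param max_gap maximum consecutive gap frames before the track is lost.
#' @return data.frame: `frame`, `x`, `y`, `visible`; attribute
#'   `lost_at` gives the frame where the track was lost (or `NA`).
#' @export
track_prey <- function(prep, seed_centroid, max_jump_px = 10,
                       max_gap = 5) {
  n <- dim(prep$mask)[3]
  out <- data.frame(frame = seq_len(n), x = NA_real_, y = NA_real_,
                    visible = FALSE)
  centroids <- function(m) {
    lab <- label_components(m)
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))
    if (max(lab) == 0) return(NULL)
    idx <- which(lab > 0, arr.ind = TRUE)
    xs <- tapply(idx[, 2], lab[idx], mean)
    ys <- tapply(idx[, 1], lab[idx], mean)
    cbind(x = xs, y = ys)
  }
  last <- seed_centroid
  gaps <- 0L
  lost_at <- NA_integer_
  for (i in seq_len(n)) {
    cen <- centroids(prep$mask[, , i])
    if (!is.null(cen)) {
      dd <- sqrt((cen[, 1] - last[1])^2 + (cen[, 2] - last[2])^2)
      jbest <- which.min(dd)
      if (dd[jbest] <= max_jump_px) {
        last <- c(cen[jbest, 1], cen[jbest, 2])
        out[i, c("x", "y")] <- last
        out$visible[i] <- TRUE
        gaps <- 0L
        next
      }
    }
    gaps <- gaps + 1L
    if (gaps > max_gap && is.na(lost_at)) {
      lost_at <- i
      break
    }
  }
  attr(out, "lost_at") <- lost_at
  out
}

#' Fish-prey geometry for one or more frames
#'
#' Computes the fish-target distance `d` (from the head-segment center to
#' the prey centroid), the signed fish-target angle `phi` (right-positive,
#' measured from the heading direction), the angular size of the prey
#' (`2 atan(prey_len / 2d)`), and the angular velocity of the target
#' (centered finite difference of `phi`).
#'
#' @param poses data.frame from [track_midline()] (needs `theta_deg`,
#'   `head_x`, `head_y`).
#' @param prey data.frame from [track_prey()] (needs `x`, `y`).
#' @param prey_len_px prey major-axis length, px.
#' @param pixel_size_mm mm per pixel.
#' @param fs frame rate, Hz.
#' @return data.frame: `frame`, `phi_deg`, `d_mm`, `angular_size_deg`,
#'   `angular_velocity_dps`.
#' @export
prey_geometry <- function(poses, prey, prey_len_px, pixel_size_mm, fs) {
  stopifnot(nrow(poses) == nrow(prey))
  n <- nrow(poses)
  phi <- d <- asz <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!isTRUE(poses$valid[i]) || !isTRUE(prey$visible[i])) next
    u <- c(cos(deg2rad(poses$theta_deg[i])), sin(deg2rad(poses$theta_deg[i])))
    w <- c(prey$x[i] - poses$head_x[i], prey$y[i] - poses$head_y[i])
    dpx <- sqrt(sum(w^2))
    if (dpx == 0) stop("degenerate geometry: prey at head center")
    phi[i] <- signed_angle(u, w)
    d[i] <- dpx * pixel_size_mm
    asz[i] <- 2 * rad2deg(atan(prey_len_px / (2 * dpx)))
  }
  av <- rep(NA_real_, n)
  if (n >= 3) {
    for (i in 2:(n - 1))
      av[i] <- (phi[i + 1] - phi[i - 1]) / 2 * fs
  }
  data.frame(frame = seq_len(n), phi_deg = phi, d_mm = d,
             angular_size_deg = asz, angular_velocity_dps = av)
}
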
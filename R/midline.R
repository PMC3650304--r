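# Midline extraction from binary larva masks. The mask is rotated so the
# previous heading lies along +x, converted to an exact Euclidean distance
# map, and the distance-map ridge is followed column by column from the
# global maximum (near the head center) toward the snout and the tail.
# The ridge polyline is then fit with six connected straight segments: a
# head segment spanning a fixed arclength fraction from the snout (the
# snout-to-swim-bladder proxy), and five tail segments of equal length.

# bilinear rotation of a binary mask about the image center
rotate_mask <- function(mask, deg) {
  ny <- nrow(mask); nx <- ncol(mask)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  a <- deg2rad(deg)
  xs <- rep(seq_len(nx), each = ny) - cx
  ys <- rep(seq_len(ny), nx) - cy
  # inverse mapping: output pixel -> input coordinates
  xi <- cos(a) * xs + sin(a) * ys + cx
  yi <- -sin(a) * xs + cos(a) * ys + cy
  x0 <- floor(xi); y0 <- floor(yi)
  wx <- xi - x0; wy <- yi - y0
  val <- numeric(length(xi))
  ok <- x0 >= 1 & x0 < nx & y0 >= 1 & y0 < ny
  m <- function(r, c) mask[cbind(r, c)] * 1
  val[ok] <-
    m(y0[ok], x0[ok]) * (1 - wx[ok]) * (1 - wy[ok]) +
    m(y0[ok], x0[ok] + 1) * wx[ok] * (1 - wy[ok]) +
    m(y0[ok] + 1, x0[ok]) * (1 - wx[ok]) * wy[ok] +
    m(y0[ok] + 1, x0[ok] + 1) * wx[ok] * wy[ok]
  matrix(val, ny, nx) > 0.5
}

# parabolic sub-pixel refinement of a discrete maximum position
refine_parabolic <- function(fm1, f0, fp1) {
  den <- fm1 - 2 * f0 + fp1
  if (abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (fm1 - fp1) / den))
}

# follow the distance-map ridge from (row0, col0) in one column direction
walk_ridge <- function(dm, mask, row0, col0, dir, row_window = 8L) {
  ny <- nrow(dm); nx <- ncol(dm)
  rows <- numeric(0); cols <- numeric(0); vals <- numeric(0)
  r <- row0
  cc <- col0 + dir
  while (cc >= 1 && cc <= nx) {
    lo <- max(1L, floor(r) - row_window)
    hi <- min(ny, ceiling(r) + row_window)
    cand <- which(mask[lo:hi, cc]) + lo - 1L
    if (!length(cand)) break
    dv <- dm[cbind(cand, cc)]
    best <- cand[dv == max(dv)]
    # tie-break: nearest to the previous ridge row
    ri <- best[which.min(abs(best - r))]
    off <- if (ri > 1 && ri < ny)
      refine_parabolic(dm[ri - 1, cc], dm[ri, cc], dm[ri + 1, cc]) else 0
    r <- ri + off
    rows <- c(rows, r); cols <- c(cols, cc); vals <- c(vals, dm[ri, cc])
    cc <- cc + dir
  }
  list(rows = rows, cols = cols, vals = vals)
}

# moving-average smoothing that keeps endpoints
smooth_vec <- function(x, k = 5) {
  if (length(x) < k) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) ->
    y
  bad <- is.na(y)
  y[bad] <- x[bad]
  y
}

# resample a polyline at uniform arclength spacing
resample_polyline <- function(xy, spacing = 0.5) {
  d <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  si <- seq(0, total, by = spacing)
  if (si[length(si)] < total) si <- c(si, total)
  cbind(stats::approx(s, xy[, 1], xout = si)$y,
        stats::approx(s, xy[, 2], xout = si)$y)
}

# place 5 equal-length chords along a dense polyline (bisection on the
# chord length so the 5th vertex lands on the tail tip)
equal_chord_fit <- function(poly) {
  n <- nrow(poly)
  seg <- sqrt(rowSums(diff(poly)^2))
  s <- c(0, cumsum(seg))
  total <- s[n]
  march <- function(L) {
    v <- matrix(NA_real_, 6, 2)
    v[1, ] <- poly[1, ]
    idx <- 1
    for (k in 2:6) {
      cur <- v[k - 1, ]
      j <- idx
      while (j < n && sqrt(sum((poly[j + 1, ] - cur)^2)) < L) j <- j + 1
      if (j >= n) return(list(v = v, over = TRUE))
      # interpolate the circle crossing between poly[j] and poly[j+1]
      p0 <- poly[j, ]; p1 <- poly[j + 1, ]
      f <- function(t) sqrt(sum((p0 + t * (p1 - p0) - cur)^2)) - L
      t0 <- if (f(0) >= 0) 0 else stats::uniroot(f, c(0, 1))$root
      v[k, ] <- p0 + t0 * (p1 - p0)
      idx <- j
    }
    list(v = v, over = FALSE)
  }
  chord <- sqrt(sum((poly[n, ] - poly[1, ])^2))
  lo <- chord / 5 * 0.999
  hi <- total / 5 * 1.001
  # bisection: the largest L for which five chords fit leaves the 5th
  # vertex exactly on the tail tip
  best <- march(lo)
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    res <- march(mid)
    if (res$over) {
      hi <- mid
    } else {
      lo <- mid
      best <- res
      if (sqrt(sum((poly[n, ] - res$v[6, ])^2)) < 1e-6) break
    }
  }
  best$v
}

#' Extract the six-segment midline pose from a binary frame
#'
#' @param mask logical matrix, a single-larva binary frame.
#' @param prev_heading heading reference in degrees used to rotate the
#'   frame before column-wise ridge following (previous frame's theta; use
#'   the silhouette principal axis for the first frame).
#' @param head_fraction arclength fraction assigned to the head segment.
#' @param min_area minimum object area, px.
#' @return a `midline_pose` list: `theta` (degrees, global frame),
#'   `gamma` (length 5, degrees), `head_center`, `snout` (pixels),
#'   `vertices` (7 x 2), `seg_lengths` (6), `arclength`.
#' @export
extract_midline <- function(mask, prev_heading = 0, head_fraction = 0.3,
                            min_area = 100) {
  if (!any(mask)) stop("no object")
  if (sum(mask) < min_area) stop("object below min_area")
  rot <- rotate_mask(mask, -prev_heading)
  if (!any(rot)) stop("no object after rotation")
  dm <- EBImage::distmap(EBImage::Image(rot * 1))
  dm <- matrix(as.numeric(EBImage::imageData(dm)), nrow(rot), ncol(rot))
  mx <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  r0 <- mx[1]; c0 <- mx[2]
  right <- walk_ridge(dm, rot, r0, c0, +1L)
  left <- walk_ridge(dm, rot, r0, c0, -1L)
  # chain ordered by column: left branch reversed, center, right branch
  rows <- c(rev(left$rows), r0, right$rows)
  cols <- c(rev(left$cols), c0, right$cols)
  vals <- c(rev(left$vals), dm[r0, c0], right$vals)
  np <- length(rows)
  if (np < 12) stop("midline too short")

  # head end = end with the larger mean ridge width
  k <- max(3L, round(np * 0.2))
  head_first <- mean(vals[seq_len(k)]) > mean(vals[np - seq_len(k) + 1])
  if (!head_first) {
    rows <- rev(rows); cols <- rev(cols); vals <- rev(vals)
  }

  # the ridge is unreliable where the rounded snout is thinner than ~2 px
  # (boundary quantization dominates); trim those leading points
  solid <- which(vals >= 1.8)
  if (length(solid) && solid[1] > 1) {
    drop <- seq_len(solid[1] - 1)
    rows <- rows[-drop]; cols <- cols[-drop]; vals <- vals[-drop]
    np <- length(rows)
    if (np < 12) stop("midline too short")
  }

  # back to the global (unrotated) frame
  ny <- nrow(mask); nx <- ncol(mask)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  pts <- rotate_xy(cbind(cols - cx, rows - cy), prev_heading)
  pts <- sweep(pts, 2, c(cx, cy), "+")
  pts[, 1] <- smooth_vec(pts[, 1]); pts[, 2] <- smooth_vec(pts[, 2])
  poly <- resample_polyline(pts, spacing = 0.5)

  seg <- sqrt(rowSums(diff(poly)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < 30) stop("midline too short")

  # head segment: principal direction of the head-fraction points
  head_pts <- poly[s <= head_fraction * total, , drop = FALSE]
  if (nrow(head_pts) < 3) stop("head portion too short")
  hc <- colMeans(head_pts)
  ev <- eigen(stats::cov(head_pts))$vectors[, 1]
  # orient toward the snout (decreasing arclength)
  snoutward <- poly[1, ] - head_pts[nrow(head_pts), ]
  if (sum(ev * snoutward) < 0) ev <- -ev
  theta <- rad2deg(atan2(ev[2], ev[1]))

  # connected head segment endpoints: project extreme head points on axis
  proj <- (head_pts %*% ev) - sum(hc * ev)
  snout <- hc + max(proj) * ev
  neck <- hc + min(proj) * ev

  tail_pts <- poly[s >= head_fraction * total, , drop = FALSE]
  tail_poly <- rbind(neck, tail_pts)
  v_tail <- equal_chord_fit(resample_polyline(tail_poly, spacing = 0.5))

  vertices <- rbind(snout, v_tail)
  u <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
  b <- -u
  gamma <- numeric(5)
  for (i in 1:5) {
    d <- vertices[i + 2, ] - vertices[i + 1, ]
    gamma[i] <- -signed_angle(b, d)
  }
  seg_lengths <- sqrt(rowSums(diff(vertices)^2))
  structure(list(theta = theta, gamma = gamma,
                 head_center = (snout + neck) / 2, snout = snout,
                 vertices = vertices, seg_lengths = seg_lengths,
                 arclength = total),
            class = "midline_pose")
}

#' Principal-axis angle of a binary silhouette
#'
#' Image-moment orientation of the foreground, degrees in (-90, 90];
#' used as the rotation reference for the first frame.
#' @param mask logical matrix.
#' @export
principal_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(idx[, 2], idx[, 1])
  cv <- stats::cov(xy)
  ev <- eigen(cv)$vectors[, 1]
  ang <- rad2deg(atan2(ev[2], ev[1]))
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Track the midline across a preprocessed stack
#'
#' Applies [extract_midline()] frame by frame, using the previous frame's
#' heading as the rotation reference (first frame: principal axis) and
#' unwrapping theta across frames for continuity.
#'
#' @param prep output of [preprocess_free()] or [preprocess_restrained()].
#' @param head_fraction arclength fraction of the head segment.
#' @return data.frame: `frame`, `theta_deg`, `gamma1_deg` ... `gamma5_deg`,
#'   `head_x`, `head_y`, `valid`.
#' @export
track_midline <- function(prep, head_fraction = 0.3) {
  n <- dim(prep$mask)[3]
  out <- data.frame(frame = seq_len(n), theta_deg = NA_real_,
                    gamma1_deg = NA_real_, gamma2_deg = NA_real_,
                    gamma3_deg = NA_real_, gamma4_deg = NA_real_,
                    gamma5_deg = NA_real_, head_x = NA_real_,
                    head_y = NA_real_, valid = FALSE)
  prev <- NULL
  for (i in seq_len(n)) {
    if (!prep$valid[i]) next
    m <- prep$mask[, , i]
    ref <- if (is.null(prev)) principal_axis(m) else prev
    pose <- tryCatch(extract_midline(m, prev_heading = ref,
                                     head_fraction = head_fraction),
                     error = function(e) NULL)
    if (is.null(pose)) next
    th <- pose$theta
    if (!is.null(prev)) {
      # unwrap toward the previous heading
      th <- th + 360 * round((prev - th) / 360)
    }
    out[i, 2:9] <- c(th, pose$gamma, pose$head_center)
    out$valid[i] <- TRUE
    prev <- th
  }
  out
}
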
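# Rasterization of synthetic dark-field frames: bright tapered larva
# silhouette (plus a small bright prey particle) on a dark, weakly
# textured background, emulating infrared dark-field recordings. In
# restrained mode the head additionally carries two dark eye ellipses at
# scheduled angles so the eye-fitting stage can be exercised.

#' Scene parameters for synthetic video rendering
#'
#' @param img c(width, height) in pixels.
#' @param pixel_size_mm mm per pixel.
#' @param body_length_mm fish body length.
#' @param head_halfwidth_mm half-width of the head at its widest point.
#' @param tail_tip_halfwidth_px half-width at the tail tip, pixels.
#' @param fish_intensity,background_intensity,texture_amp 8-bit gray
#'   levels; fish must be brighter than background (dark-field contrast).
#' @param pixel_noise_sd Gaussian pixel noise sd, gray levels.
#' @param prey_length_mm prey (paramecium-like ellipsoid) major length.
#' @param mode `"free"` or `"restrained"`.
#' @param eye_length_mm,eye_width_mm,eye_sep_mm,eye_intensity eye ellipse
#'   geometry and gray level (restrained mode).
#' @param seed seed for the static background texture.
#' @return a `scene_params` list.
#' @export
scene_params <- function(img = c(240, 240), pixel_size_mm = 0.04,
                         body_length_mm = 4, head_halfwidth_mm = 0.24,
                         tail_tip_halfwidth_px = 1,
                         fish_intensity = 200, background_intensity = 16,
                         texture_amp = 8, pixel_noise_sd = 0,
                         prey_length_mm = 0.18, mode = c("free", "restrained"),
                         eye_length_mm = 0.24, eye_width_mm = 0.12,
                         eye_sep_mm = 0.22, eye_intensity = 40, seed = 99L) {
  mode <- match.arg(mode)
  s <- list(img = img, pixel_size_mm = pixel_size_mm,
            body_length_mm = body_length_mm,
            head_halfwidth_mm = head_halfwidth_mm,
            tail_tip_halfwidth_px = tail_tip_halfwidth_px,
            fish_intensity = fish_intensity,
            background_intensity = background_intensity,
            texture_amp = texture_amp, pixel_noise_sd = pixel_noise_sd,
            prey_length_mm = prey_length_mm, mode = mode,
            eye_length_mm = eye_length_mm, eye_width_mm = eye_width_mm,
            eye_sep_mm = eye_sep_mm, eye_intensity = eye_intensity,
            seed = as.integer(seed))
  if (s$fish_intensity <= s$background_intensity)
    stop("dark-field contrast requires fish brighter than background")
  if (s$body_length_mm / s$pixel_size_mm < 60)
    stop("body length below 60 px; midline not resolvable")
  class(s) <- "scene_params"
  s
}

#' Static background frame of a scene
#'
#' The low-spatial-frequency background texture (coarse random grid,
#' bilinearly upsampled, fixed by the scene seed) that the renderer draws
#' behind the fish; also the reference frame for background subtraction.
#'
#' @param scene a [scene_params()] object.
#' @return numeric matrix of gray levels.
#' @export
background_texture <- function(scene) {
  nx <- scene$img[1]; ny <- scene$img[2]
  # drawn under a local seed so rendering does not disturb the caller's
  # RNG stream
  coarse <- with_seed(scene$seed, matrix(runif(64, -1, 1), 8, 8))
  gy <- seq(1, 8, length.out = ny)
  gx <- seq(1, 8, length.out = nx)
  fy <- floor(gy); fy <- pmin(fy, 7); wy <- gy - fy
  fx <- floor(gx); fx <- pmin(fx, 7); wx <- gx - fx
  a <- coarse[fy, fx] * outer(1 - wy, 1 - wx) +
    coarse[fy + 1, fx] * outer(wy, 1 - wx) +
    coarse[fy, fx + 1] * outer(1 - wy, wx) +
    coarse[fy + 1, fx + 1] * outer(wy, wx)
  scene$background_intensity + scene$texture_amp * a
}

# body half-width (px) as a function of normalized arclength s in [0, 1]
body_halfwidth <- function(s_rel, scene, hf = 0.3) {
  hw_head <- scene$head_halfwidth_mm / scene$pixel_size_mm
  w_tip <- scene$tail_tip_halfwidth_px
  w_neck <- hw_head * sqrt(1 - (0.5 / 0.62)^2)
  w <- numeric(length(s_rel))
  head <- s_rel <= hf
  arg <- 1 - ((s_rel[head] - 0.5 * hf) / (0.62 * hf))^2
  w[head] <- hw_head * sqrt(pmax(arg, 0))
  tl <- !head
  w[tl] <- w_neck + (w_tip - w_neck) * (s_rel[tl] - hf) / (1 - hf)
  pmax(w, 0.8)
}

# stamp a filled disk of the given intensity into a matrix (row = y)
stamp_disk <- function(img, x, y, r, value) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- max(1L, floor(x - r)); x1 <- min(nx, ceiling(x + r))
  y0 <- max(1L, floor(y - r)); y1 <- min(ny, ceiling(y + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - y)^2, (xs - x)^2, "+")
  sub <- img[ys, xs, drop = FALSE]
  sub[d2 <= r^2] <- value
  img[ys, xs] <- sub
  img
}

# stamp a filled rotated ellipse (half axes a >= b, axis direction `dir`)
stamp_ellipse <- function(img, cx, cy, a, b, dir, value) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- max(1L, floor(cx - a)); x1 <- min(nx, ceiling(cx + a))
  y0 <- max(1L, floor(cy - a)); y1 <- min(ny, ceiling(cy + a))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  pu <- dx * dir[1] + dy * dir[2]
  pv <- -dx * dir[2] + dy * dir[1]
  sub <- img[ys, xs, drop = FALSE]
  sub[(pu / a)^2 + (pv / b)^2 <= 1] <- value
  img[ys, xs] <- sub
  img
}

#' Render one synthetic frame
#'
#' @param truth a `ground_truth` object.
#' @param i frame index (1-based).
#' @param scene a [scene_params()] object.
#' @param eye_deg optional c(left, right) eye angles in degrees
#'   (nasal-positive) for restrained mode.
#' @return numeric matrix (rows = y, cols = x), gray levels 0-255.
#' @export
render_frame <- function(truth, i, scene, eye_deg = NULL) {
  nx <- scene$img[1]; ny <- scene$img[2]
  p <- truth$params
  hf <- p$head_fraction
  L_px <- scene$body_length_mm / scene$pixel_size_mm
  head_len <- hf * L_px
  tail_seg <- (1 - hf) * L_px / 5

  ctr <- c((nx + 1) / 2, (ny + 1) / 2)
  hc_px <- ctr + truth$head_center_mm[i, ] / scene$pixel_size_mm
  theta <- truth$theta[i]
  u <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
  snout <- hc_px + (head_len / 2) * u
  v <- midline_vertices(snout, theta, truth$gamma[i, ], head_len, tail_seg)
  if (any(v[, 1] < 1 | v[, 1] > nx | v[, 2] < 1 | v[, 2] > ny))
    stop("fish out of frame bounds")

  img <- background_texture(scene)
  # sample the polyline at ~0.7 px spacing and stamp tapered disks
  seg_len <- c(head_len, rep(tail_seg, 5))
  s0 <- cumsum(c(0, seg_len))
  total <- s0[7]
  for (k in 1:6) {
    nsmp <- max(2L, ceiling(seg_len[k] / 0.7))
    tt <- seq(0, 1, length.out = nsmp)
    px <- v[k, 1] + tt * (v[k + 1, 1] - v[k, 1])
    py <- v[k, 2] + tt * (v[k + 1, 2] - v[k, 2])
    ss <- (s0[k] + tt * seg_len[k]) / total
    ww <- body_halfwidth(ss, scene, hf)
    for (j in seq_len(nsmp))
      img <- stamp_disk(img, px[j], py[j], ww[j], scene$fish_intensity)
  }

  if (!is.null(truth$prey_mm)) {
    prey_px <- ctr + truth$prey_mm[i, ] / scene$pixel_size_mm
    a <- scene$prey_length_mm / scene$pixel_size_mm / 2
    img <- stamp_ellipse(img, prey_px[1], prey_px[2], a, a / 2, c(1, 0),
                         scene$fish_intensity)
  }

  if (scene$mode == "restrained" && !is.null(eye_deg)) {
    r_vec <- rotate_xy(u, 90)           # fish's right
    ecal <- hc_px                        # widest part of the head
    a <- scene$eye_length_mm / scene$pixel_size_mm / 2
    b <- scene$eye_width_mm / scene$pixel_size_mm / 2
    sep <- scene$eye_sep_mm / scene$pixel_size_mm / 2
    cl <- ecal - sep * r_vec
    cr <- ecal + sep * r_vec
    dir_l <- rotate_xy(u, eye_deg[1])
    dir_r <- rotate_xy(u, -eye_deg[2])
    img <- stamp_ellipse(img, cl[1], cl[2], a, b, dir_l, scene$eye_intensity)
    img <- stamp_ellipse(img, cr[1], cr[2], a, b, dir_r, scene$eye_intensity)
  }

  if (scene$pixel_noise_sd > 0)
    img <- img + matrix(rnorm(nx * ny, 0, scene$pixel_noise_sd), ny, nx)
  pmin(pmax(img, 0), 255)
}

#' Render a ground-truth record into a grayscale frame stack
#'
#' @inheritParams render_frame
#' @param eye_deg optional frames x 2 matrix of (left, right) eye angles.
#' @param noise_seed seed for per-frame pixel noise.
#' @return numeric array `[y, x, frame]` of gray levels 0-255.
#' @export
render_frames <- function(truth, scene, eye_deg = NULL, noise_seed = 7L) {
  n <- length(truth$t_ms)
  out <- array(0, c(scene$img[2], scene$img[1], n))
  with_seed(noise_seed, for (i in seq_len(n)) {
    ed <- if (is.null(eye_deg)) NULL else eye_deg[i, ]
    out[, , i] <- render_frame(truth, i, scene, eye_deg = ed)
  })
  out
}

#' Write a frame stack as multi-page 8-bit TIFF
#' @param frames array `[y, x, frame]`, gray levels 0-255.
#' @param path output file.
#' @export
write_stack <- function(frames, path) {
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(i) frames[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#' @param path TIFF file.
#' @return numeric array `[y, x, frame]`, gray levels 0-255.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3)
    p[, , 1] else p)
  out <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) out[, , i] <- pages[[i]] * 255
  out
}
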
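test_that("free-mode preprocessing isolates the larva", {
  scene <- default_scene()
  bg <- scene_background(scene)
  # frame identical to background: empty mask, flagged invalid
  stack <- array(bg, c(dim(bg), 1))
  prep <- preprocess_free(stack, bg)
  expect_false(prep$valid[1])
  expect_false(any(prep$mask))

  # rendered fish + prey: prey is below min_area, one component remains
  sq <- gen_capture_sequence(1, numeric(0), prey_mm = c(3, 2),
                             pre_ms = 0, post_ms = 0, seed = 3)
  fr <- render_frame(sq, 1, scene)
  prep2 <- preprocess_free(array(fr, c(dim(fr), 1)), bg)
  lab <- preycapture:::label_components(prep2$mask[, , 1])
  expect_identical(max(lab), 1L)

  # a border-touching object is removed
  fr3 <- bg
  fr3[1:40, 1:6] <- 220          # clipped by the border
  fr3[100:130, 100:130] <- 220   # interior object
  prep3 <- preprocess_free(array(fr3, c(dim(fr3), 1)), bg)
  lab3 <- preycapture:::label_components(prep3$mask[, , 1])
  expect_identical(max(lab3), 1L)
  expect_false(any(prep3$mask[, 1:6, 1]))
})

test_that("restrained-mode remap is monotone and isolates the larva", {
  scene <- scene_params(mode = "restrained")
  truth <- straight_restrained_truth()
  fr <- render_frame(truth, 1, scene, eye_deg = c(15, 15))
  prep <- preprocess_restrained(array(fr, c(dim(fr), 1)),
                                remap_factor = 3, fixed_threshold = 100)
  expect_true(prep$valid[1])
  lab <- preycapture:::label_components(prep$mask[, , 1])
  expect_identical(max(lab), 1L)

  # uniform background-level frame gives an empty mask
  flat <- array(16, c(dim(fr), 1))
  prep2 <- preprocess_restrained(flat, remap_factor = 3,
                                 fixed_threshold = 100)
  expect_false(prep2$valid[1])

  # linear remap preserves pixel ordering
  v <- c(10, 50, 90, 200)
  remapped <- pmin(pmax((v - 50) * 3, 0), 255)
  expect_true(all(diff(remapped) >= 0))
  expect_error(preprocess_restrained(flat, remap_factor = 0.5), "> 1")
})

test_that("midline of a straight fish recovers heading and zero bend", {
  fx <- tracked_bout(0, seed = 41, key = "straight")
  truth <- fx$truth
  pose1 <- extract_midline(fx$prep$mask[, , 1], prev_heading = 0)
  expect_lt(abs(pose1$theta), 1)
  expect_true(all(abs(pose1$gamma) < 1))
  # structural invariants: 6 segments, 5 equal-length tail segments
  expect_identical(nrow(pose1$vertices), 7L)
  expect_identical(length(pose1$seg_lengths), 6L)
  tails <- pose1$seg_lengths[2:6]
  expect_lt(max(tails) - min(tails), 1)
  expect_true(all(abs(pose1$gamma) < 180))
  expect_error(extract_midline(matrix(FALSE, 50, 50)), "no object")
})

test_that("tail angles of a rendered bout match ground truth within 3 deg", {
  fx <- tracked_bout(30, seed = 42, key = "bout30")
  gcols <- paste0("gamma", 1:5, "_deg")
  err <- as.matrix(fx$poses[, gcols]) - fx$truth$gamma
  expect_true(all(fx$poses$valid))
  expect_lt(sqrt(mean(err^2)), 3)
})

test_that("rotating the frame rotates theta and leaves gamma unchanged", {
  fx <- tracked_bout(30, seed = 42, key = "bout30")
  i <- 40
  m <- fx$prep$mask[, , i]
  pose <- extract_midline(m, prev_heading = 13)
  rot90 <- t(m)[, nrow(m):1]   # +90 degree rotation of the image
  pose_r <- extract_midline(rot90, prev_heading = 13 + 90)
  expect_equal(pose_r$theta - pose$theta, 90, tolerance = 1)
  expect_true(all(abs(pose_r$gamma - pose$gamma) < 1))
})

test_that("prey tracking follows stationary and moving targets", {
  scene <- default_scene()
  bg <- scene_background(scene)
  # stationary prey
  sq <- gen_capture_sequence(1, numeric(0), prey_mm = c(3, 2),
                             pre_ms = 0, post_ms = 0, seed = 3)
  frames <- render_frames(sq, scene)
  pp <- preprocess_prey(frames, bg)
  ctr <- (dim(frames)[1] + 1) / 2
  seed_xy <- c(ctr + 3 / scene$pixel_size_mm, ctr + 2 / scene$pixel_size_mm)
  trk <- track_prey(pp, seed_xy)
  expect_true(all(trk$visible))
  expect_lt(max(abs(trk$x - mean(trk$x))), 0.5)
  expect_lt(max(abs(trk$y - mean(trk$y))), 0.5)

  # linear motion: fitted speed within 10 percent
  n <- length(sq$t_ms)
  v_px_frame <- 0.8
  sq$prey_mm <- cbind(3 - (seq_len(n) - 1) * v_px_frame * scene$pixel_size_mm,
                      rep(2, n))
  frames2 <- render_frames(sq, scene)
  pp2 <- preprocess_prey(frames2, bg)
  trk2 <- track_prey(pp2, seed_xy, max_jump_px = 5)
  fit <- stats::lm(x ~ frame, data = trk2[trk2$visible, ])
  expect_lt(abs(abs(coef(fit)[2]) - v_px_frame) / v_px_frame, 0.1)

  # prey removed mid-stack: track lost at the right frame
  frames3 <- frames
  cut <- 30
  for (k in cut:dim(frames3)[3]) frames3[, , k] <- bg
  pp3 <- preprocess_prey(frames3, bg)
  trk3 <- track_prey(pp3, seed_xy, max_gap = 3)
  expect_identical(attr(trk3, "lost_at"), as.integer(cut) + 3L)
  expect_false(any(trk3$visible[cut:nrow(trk3)]))
})

test_that("fish-prey geometry obeys the sign convention and closed forms", {
  poses <- data.frame(frame = 1, theta_deg = 0, head_x = 100, head_y = 100,
                      valid = TRUE)
  # prey 1 mm ahead and 1 mm to the fish's right (y down = right side)
  at <- function(px, py) data.frame(frame = 1, x = px, y = py, visible = TRUE)
  g <- prey_geometry(poses, at(125, 125), prey_len_px = 4,
                     pixel_size_mm = 0.04, fs = 500)
  expect_equal(g$phi_deg, 45, tolerance = 1e-9)
  expect_equal(g$d_mm, sqrt(2), tolerance = 1e-9)
  # prey on the heading ray
  expect_equal(prey_geometry(poses, at(150, 100), 4, 0.04, 500)$phi_deg, 0)
  # prey on the fish's left: negative angle
  expect_lt(prey_geometry(poses, at(125, 75), 4, 0.04, 500)$phi_deg, 0)
  # small-target limit: angular_size * d / prey_len -> 180/pi deg
  g2 <- prey_geometry(poses, at(100 + 25 * 20, 100), prey_len_px = 25,
                      pixel_size_mm = 0.04, fs = 500)
  ratio <- g2$angular_size_deg * g2$d_mm / (25 * 0.04)
  expect_equal(ratio, 180 / pi, tolerance = 0.02 * 180 / pi)
  expect_error(prey_geometry(poses, at(100, 100), 4, 0.04, 500),
               "degenerate")
})

test_that("eye ellipses are recovered within 2 degrees, nasal-positive", {
  scene <- eye_scene()
  truth <- straight_restrained_truth()
  for (ang in list(c(20, 20), c(10, 30), c(25, 5))) {
    fr <- render_frame(truth, 1, scene, eye_deg = ang)
    ep <- fit_eyes(fr, eye_roi(), body_axis_deg = 0)
    expect_false(ep$missing)
    expect_equal(ep$left$angle_deg, ang[1], tolerance = 2)
    expect_equal(ep$right$angle_deg, ang[2], tolerance = 2)
  }
  # mirror-symmetric eyes: equal magnitude on opposite sides
  fr <- render_frame(truth, 1, scene, eye_deg = c(18, 18))
  ep <- fit_eyes(fr, eye_roi(), body_axis_deg = 0)
  expect_equal(ep$left$angle_deg, ep$right$angle_deg, tolerance = 0.5)
  expect_lt(ep$left$center[2], ep$right$center[2])  # left eye above axis
  # ROI without eyes: missing flag
  ep2 <- fit_eyes(fr, list(x = 10:60, y = 10:60), body_axis_deg = 0)
  expect_true(ep2$missing)
})
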
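# Shared fixtures: rendered bouts are expensive, so they are built once
# per session and cached in an environment.

fixture_cache <- new.env(parent = emptyenv())

default_scene <- function() scene_params()

scene_background <- function(scene = default_scene()) {
  preycapture::background_texture(scene)
}

# render a single noise-free bout and run the full tracking pipeline
tracked_bout <- function(delta_theta, seed, pad_ms = c(10, 10),
                         f_osc = 30, key = NULL) {
  key <- key %||% paste0("bout_", delta_theta, "_", seed, "_", f_osc)
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  p <- generator_params(delta_theta = delta_theta, f_osc = f_osc,
                        seed = seed)
  truth <- gen_bout_kinematics(p, pad_ms = pad_ms)
  scene <- default_scene()
  frames <- render_frames(truth, scene)
  prep <- preprocess_free(frames, scene_background(scene))
  poses <- track_midline(prep)
  out <- list(truth = truth, poses = poses, prep = prep, params = p)
  fixture_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# restrained-mode scene fine enough to resolve the rendered eyes
eye_scene <- function() {
  scene_params(img = c(360, 360), pixel_size_mm = 0.02, mode = "restrained",
               eye_length_mm = 0.36, eye_width_mm = 0.18,
               eye_sep_mm = 0.26, head_halfwidth_mm = 0.28)
}

eye_roi <- function() list(x = 136:240, y = 141:220)

straight_restrained_truth <- function() {
  p <- generator_params(delta_theta = 0, seed = 2)
  truth <- gen_bout_kinematics(p)
  truth$gamma[] <- 0
  truth
}
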
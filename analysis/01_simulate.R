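#!/usr/bin/env Rscript
# Generates the synthetic study data: a graded family of single swim
# bouts (heading changes spanning -60..60 deg), one full capture-like
# sequence with the measured IBI schedule, and the 1 kHz tail-sensor
# trace for one bout. Writes ground-truth tables under results/ and a
# short rendered TIFF stack as a QC artifact under scratch/.

suppressMessages(library(preycapture))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
set.seed(1)

## graded single bouts -------------------------------------------------
dts <- seq(-60, 60, by = 10)
bouts <- do.call(rbind, lapply(seq_along(dts), function(i) {
  p <- generator_params(delta_theta = dts[i], seed = 100 + i)
  tr <- gen_bout_kinematics(p, pad_ms = c(30, 30))
  data.frame(bout = i, delta_theta_true = dts[i],
             bout_ms = p$bout_ms, f_osc = p$f_osc,
             peak_tail_angle = max(abs(tr$gamma)))
}))
write.csv(bouts, "results/01_bout_family.csv", row.names = FALSE)
cat("bout family:", nrow(bouts), "bouts, peak tail angle",
    round(max(bouts$peak_tail_angle), 1), "deg at delta_theta 60\n")

## one capture-like sequence with the measured IBI schedule ------------
sq <- gen_capture_sequence(5, ibi_ms = c(324, 250, 180, 124),
                           undershoot = 0.9, prey_mm = c(4, 3), seed = 7)
write.csv(sq$bouts, "results/01_sequence_truth.csv", row.names = FALSE)
# compact sidecar: per-bout truth and eye schedule (the full per-frame
# truth is large; it is regenerated from the seed on demand)
jsonlite::write_json(list(bouts = sq$bouts, ibi_ms = sq$ibi_ms,
                          eye_course = sq$eye_course, seed = sq$seed),
                     "results/01_sequence_summary.json",
                     auto_unbox = TRUE, digits = NA)
write_truth_json(sq, "scratch/01_sequence_truth_full.json")
cat("sequence: phi shrinks", round(sq$bouts$phi_pre[1], 1), "->",
    round(sq$bouts$phi_post[5], 2), "deg over 5 bouts\n")

## sensor trace for one bout -------------------------------------------
p <- generator_params(delta_theta = 25, seed = 3)
tr <- gen_bout_kinematics(p, pad_ms = c(200, 200))
psd <- gen_psd_trace(tr, gain = 2, noise_sd = 0.002)
write.csv(psd, "results/01_psd_trace.csv", row.names = FALSE)

## a short rendered stack for visual QC (binary artifact -> scratch/) --
scene <- scene_params()
short <- gen_bout_kinematics(generator_params(delta_theta = 30, seed = 5),
                             pad_ms = c(10, 10))
frames <- render_frames(short, scene)
write_stack(frames[, , seq(1, dim(frames)[3], by = 8)],
            "scratch/01_example_stack.tif")
cat("rendered", dim(frames)[3], "frames at",
    scene$pixel_size_mm, "mm/px\n")
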
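# shared fixtures: small synthetic stacks built in code at test time

# minimal valid stack: n identical (or supplied) H x W x 3 frames
make_flat_stack <- function(n = 4, h = 20, w = 20, value = 100, fps = 25) {
  fr <- array(value, c(h, w, 3))
  frame_stack(replicate(n, fr, simplify = FALSE), fps = fps)
}

# stack whose green channel is given per frame; red/blue derived
stack_from_green <- function(greens, fps = 25) {
  frames <- lapply(greens, function(g) {
    fr <- array(0, c(nrow(g), ncol(g), 3))
    fr[, , 1] <- round(0.5 * g); fr[, , 2] <- g; fr[, , 3] <- round(0.25 * g)
    fr
  })
  frame_stack(frames, fps = fps)
}

# beats giving three ~1 s cycles covering 0..3 s
default_beats <- function() beat_times(c(0, 0.98, 2.00, 3.04))

# small scene: quick to render, one vessel
small_scene <- function(..., seed = 1L) {
  scene_spec(height = 100L, width = 100L, n_frames = 30L, fps = 10,
             vessels = list(list(
               polyline = cbind(c(10, 50, 90), c(20, 50, 85)),
               width = 9, baseline = 25, amp = 10, phase_offset = 0,
               harmonic2 = 0.25, edge = "soft")),
             ..., seed = seed)
}
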
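# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Noise-free, dispersion-free aged configuration: the closed-form limit in
# which generated metrics equal configured means exactly.
clean_config <- function(age_group = "aged", merge_time_min = c(20, 0),
                         ...) {
  generator_config(
    age_group,
    icd_normal_um = c(1.6, 0), icd_aberrant_um = c(0.8, 0),
    angle_normal_deg = c(7.5, 0), angle_aberrant_deg = c(24, 0),
    speed_um_per_min = c(0.18, 0), speed_aberrant_um_per_min = c(0.22, 0),
    merge_time_min = merge_time_min, positional_noise_sd_um = 0,
    ...
  )
}

# A minimal hand-built recording: n_chr sister pairs all oriented along +z,
# midpoints on the z = 0 plane, static over time.
static_plate_recording <- function(n_chr = 20, n_time = 6, icd = 1.6,
                                   dt = 2) {
  times <- seq(0, by = dt, length.out = n_time)
  ang <- 2 * pi * seq_len(n_chr) / n_chr
  pos <- array(NA_real_, c(n_time, 3, 2 * n_chr))
  for (i in seq_len(n_chr)) {
    mid <- c(3 * cos(ang[i]), 3 * sin(ang[i]), 0)
    for (tt in seq_len(n_time)) {
      pos[tt, , 2 * i - 1] <- mid - c(0, 0, icd / 2)
      pos[tt, , 2 * i] <- mid + c(0, 0, icd / 2)
    }
  }
  chromatids <- data.frame(chromosome_id = rep(seq_len(n_chr), each = 2),
                           sister_index = rep(0:1, n_chr))
  oocyte_recording("static", "test", dt, times, chromatids, pos)
}

# Apply a rigid transform (rotation matrix + translation) to a recording.
rigid_transform_recording <- function(recording, rot, shift) {
  d <- dim(recording$pos)
  flat <- matrix(aperm(recording$pos, c(2, 1, 3)), nrow = 3)
  flat <- rot %*% flat + shift
  recording$pos <- aperm(array(flat, c(3, d[1], d[3])), c(2, 1, 3))
  recording
}

# Swap sister labels 0 <-> 1 on every chromosome.
relabel_sisters <- function(recording) {
  recording$chromatids$sister_index <- 1L - recording$chromatids$sister_index
  recording
}

rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  u_outer <- outer(u, u)
  cross <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c_ * diag(3) + s_ * cross + (1 - c_) * u_outer
}
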
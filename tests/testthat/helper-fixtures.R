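# Small in-code fixtures shared across tests.

short_protocol <- function(matrix = 32L, n_post = 4L, n_baseline = 2L) {
  cest_protocol(matrix = matrix, n_baseline_frames = n_baseline,
                post_duration_s = n_post * 24)
}

# Single-voxel CEST stack with constant creatine amplitude across frames.
voxel_stack <- function(cr_amplitude = 0, b0 = 0, b1 = 1,
                        protocol = short_protocol(matrix = 32L)) {
  offs <- protocol$offsets_ppm
  nf <- protocol$n_baseline_frames + protocol$n_post_frames
  z <- zspectrum_forward(offs, cr_amplitude = cr_amplitude, b0_ppm = b0,
                         b1_rel = b1)
  crcest_stack(array(rep(z, nf), c(1, 1, length(offs), nf)), protocol)
}

# Single-voxel (or n-voxel) WASSR stack of shifted low-power water lines.
wassr_fixture <- function(b0, offsets = seq(-1, 1, length.out = 21),
                          width = 0.3, depth = 0.8) {
  nv <- length(b0)
  dat <- array(0, c(nv, 1, length(offsets)))
  for (v in seq_len(nv)) {
    dat[v, 1, ] <- 1 - depth * lorentzian(offsets - b0[v], width)
  }
  wassr_stack(dat, offsets)
}

# Hand-built asymmetry map series (values in %, all voxels valid).
asym_fixture <- function(maps, protocol = short_protocol()) {
  nf <- dim(maps)[3]
  structure(
    list(maps = maps, valid = matrix(TRUE, dim(maps)[1], dim(maps)[2]),
         eval_offset_ppm = 1.8,
         frame_times_s = frame_times(protocol)[seq_len(nf)],
         protocol = protocol, denominator = "sneg"),
    class = "crcest_asym_series")
}

# Asymmetry of a stack read directly at the acquired +/-1.8 ppm indices,
# without any correction (the "uncorrected" comparator).
raw_asym <- function(stack, frame = 1) {
  offs <- stack$protocol$offsets_ppm
  sn <- stack$data[, , which(offs == -1.8), frame]
  sp <- stack$data[, , which(offs == 1.8), frame]
  100 * (sn - sp) / sn
}

expect_no_overlap <- function(label_map) {
  # exhaustive voxel scan: every voxel carries at most one muscle label
  for (a in 1:2) for (b in (a + 1):3) {
    expect_identical(sum(label_map == a & label_map == b), 0L)
  }
  invisible(label_map)
}
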
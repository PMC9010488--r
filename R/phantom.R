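#' 4-D CEST stack container
#'
#' Saturated/unsaturated signal fractions on a `(x, y, offset, frame)` grid,
#' tied to the protocol that acquired them and to frame times relative to the
#' end of exercise (baseline frames negative).
#'
#' @param data 4-D numeric array, values in \[0, 1\].
#' @param protocol A [cest_protocol()].
#' @param frame_times_s Frame times, seconds; defaults to [frame_times()].
#' @return A `crcest_stack`.
#' @export
crcest_stack <- function(data, protocol, frame_times_s = frame_times(protocol)) {
  stopifnot(inherits(protocol, "crcest_protocol"))
  d <- dim(data)
  if (length(d) != 4) abort("`data` must be a 4-D (x, y, offset, frame) array.")
  if (d[3] != length(protocol$offsets_ppm) || d[4] != n_frames(protocol)) {
    abort("Stack shape is inconsistent with the protocol (offsets or frames).",
          class = "crcest_schema_error")
  }
  dt <- diff(frame_times_s)
  if (length(frame_times_s) != d[4] || any(dt <= 0) ||
      any(abs(dt - protocol$frame_interval_s) > 1e-6)) {
    abort("`frame_times_s` must increase in steps of the frame interval.",
          class = "crcest_schema_error")
  }
  if (min(data) < 0 || max(data) > 1) {
    abort("Signal fractions must lie in [0, 1].", class = "crcest_schema_error")
  }
  structure(list(data = data, protocol = protocol,
                 frame_times_s = as.numeric(frame_times_s)),
            class = "crcest_stack")
}

#' WASSR fine-offset stack container
#'
#' Low-power, densely sampled water-reference z-spectra used to localise the
#' per-voxel B0 (water centre) shift.
#'
#' @param data 3-D numeric array `(x, y, fine offset)`.
#' @param offsets_ppm Symmetric offset grid spanning at least +/-1 ppm, >= 11
#'   samples.
#' @return A `wassr_stack`.
#' @export
wassr_stack <- function(data, offsets_ppm) {
  d <- dim(data)
  if (length(d) != 3) abort("`data` must be a 3-D (x, y, offset) array.")
  offsets_ppm <- as.numeric(offsets_ppm)
  if (length(offsets_ppm) < 11) {
    abort("WASSR needs at least 11 offset samples.", class = "crcest_schema_error")
  }
  if (max(abs(sort(offsets_ppm) + rev(sort(offsets_ppm)))) > 1e-9) {
    abort("WASSR offsets must be symmetric about 0.", class = "crcest_schema_error")
  }
  if (d[3] != length(offsets_ppm)) {
    abort("Offset grid length does not match the stack.", class = "crcest_schema_error")
  }
  structure(list(data = data, offsets_ppm = offsets_ppm), class = "wassr_stack")
}

#' Synthetic three-muscle calf anatomy
#'
#' Places three disjoint, simply-connected elliptical regions for the lateral
#' gastrocnemius (label 1), medial gastrocnemius (label 2) and soleus (label
#' 3) on a square matrix, with small seed-controlled jitter of centres and
#' radii. Stands in for a manual segmentation of the calf muscles involved in
#' plantar flexion.
#'
#' @param matrix Matrix size in pixels (>= 32).
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return Integer matrix with values 0 (background), 1 (LG), 2 (MG), 3 (Sol).
#' @examples
#' table(make_anatomy(64, seed = 1))
#' @export
make_anatomy <- function(matrix = 128L, seed = 1L) {
  if (matrix < 32) {
    abort("`matrix` below 32 px cannot hold three disjoint muscle regions.",
          class = "crcest_sizing_error")
  }
  set.seed(seed)
  n <- as.integer(matrix)
  ax <- seq(-1, 1, length.out = n)
  u <- outer(ax, rep(1, n))
  v <- outer(rep(1, n), ax)

  # posterior calf layout: LG lateral, MG medial, soleus deep/broad
  base <- list(
    LG  = c(cx = -0.42, cy = -0.28, rx = 0.26, ry = 0.22),
    MG  = c(cx =  0.42, cy = -0.28, rx = 0.26, ry = 0.22),
    Sol = c(cx =  0.00, cy =  0.38, rx = 0.52, ry = 0.24)
  )
  lab <- base::matrix(0L, n, n)
  for (k in seq_along(base)) {
    p <- base[[k]]
    p[c("cx", "cy")] <- p[c("cx", "cy")] + runif(2, -0.04, 0.04)
    p[c("rx", "ry")] <- p[c("rx", "ry")] * runif(2, 0.92, 1.04)
    inside <- ((u - p["cx"]) / p["rx"])^2 + ((v - p["cy"]) / p["ry"])^2 <= 1
    if (!any(inside)) {
      abort("Matrix too small: a muscle region came out empty.",
            class = "crcest_sizing_error")
    }
    if (any(lab[inside] != 0L)) {
      abort("Matrix too small: muscle regions overlap.",
            class = "crcest_sizing_error")
    }
    lab[inside] <- k
  }
  lab
}

#' Smooth low-order polynomial field
#'
#' Generates a smooth 2-D field as a seeded random combination of first- and
#' second-order polynomials in normalised coordinates, rescaled so its maximum
#' absolute value equals `amplitude`. Mimics shim-error morphology for B0
#' (ppm) and coil-profile morphology for relative B1.
#'
#' @param matrix Matrix size, pixels.
#' @param amplitude Peak absolute deviation of the field.
#' @param seed Integer seed.
#' @return Numeric `matrix x matrix` field with `max(abs(field)) == amplitude`
#'   (identically zero when `amplitude = 0`).
#' @export
field_poly2d <- function(matrix = 128L, amplitude = 0.1, seed = 1L) {
  n <- as.integer(matrix)
  if (amplitude == 0) return(base::matrix(0, n, n))
  set.seed(seed)
  ax <- seq(-1, 1, length.out = n)
  u <- outer(ax, rep(1, n))
  v <- outer(rep(1, n), ax)
  cf <- runif(5, -1, 1)
  f <- cf[1] * u + cf[2] * v + cf[3] * u * v +
    cf[4] * (u^2 - v^2) + cf[5] * (u^2 + v^2 - 2 / 3)
  f / max(abs(f)) * amplitude
}

#' Reference CrCEST levels used as phantom defaults
#'
#' Per-muscle resting CrCEST, exercise delta-CrCEST (% asymmetry) and recovery
#' time constant tauCr (s): cohort medians for healthy controls and for
#' Friedreich's ataxia used as the phantom's ground-truth kinetics and as
#' centres of the synthetic cohort generator.
#'
#' @param group "control" or "FRDA".
#' @return Tibble with columns `muscle`, `rest_asym_pct`, `delta_asym_pct`,
#'   `tau_s`.
#' @export
default_kinetics <- function(group = c("control", "FRDA")) {
  group <- match.arg(group)
  ref <- crcest_reference_medians()
  ref <- ref[ref$group == group, ]
  tibble::tibble(
    muscle = ref$muscle[ref$outcome == "resting_pct"],
    rest_asym_pct = ref$median[ref$outcome == "resting_pct"],
    delta_asym_pct = ref$median[ref$outcome == "delta_pct"],
    tau_s = ref$median[ref$outcome == "tau_s"]
  )
}

#' Tissue phantom: anatomy, fields and creatine kinetics
#'
#' Bundles everything the simulator needs: the muscle label map, smooth B0 and
#' relative-B1 fields, per-muscle creatine kinetics and pool/noise parameters.
#'
#' @param label_map Integer label map from [make_anatomy()] (0..3).
#' @param kinetics Tibble with `muscle` ("LG","MG","Sol"), `rest_asym_pct`,
#'   `delta_asym_pct`, `tau_s`; defaults to healthy-control medians.
#' @param b0_map_ppm B0 field, ppm (matrix matching `label_map`), or a single
#'   amplitude handed to [field_poly2d()].
#' @param b1_rel_map Relative B1 field (> 0 everywhere), or a single
#'   half-range `a` giving a smooth field in `[1 - a, 1 + a]` (0 = uniform
#'   nominal B1).
#' @param noise_sd Gaussian noise sd as a fraction of the unsaturated signal.
#' @param pools Pool parameters, see `default_pools()`.
#' @param seed Seed for generated fields.
#' @return A `crcest_phantom`.
#' @export
tissue_phantom <- function(label_map,
                           kinetics = default_kinetics("control"),
                           b0_map_ppm = 0,
                           b1_rel_map = 0,
                           noise_sd = 0,
                           pools = default_pools(),
                           seed = 1L) {
  n <- nrow(label_map)
  stopifnot(is.matrix(label_map), ncol(label_map) == n)
  if (!all(label_map %in% 0:3)) {
    abort("Label map values must be 0 (background), 1 (LG), 2 (MG), 3 (Sol).")
  }
  req <- c("muscle", "rest_asym_pct", "delta_asym_pct", "tau_s")
  if (!all(req %in% names(kinetics)) ||
      !setequal(kinetics$muscle, muscle_levels())) {
    abort("`kinetics` needs one row per muscle (LG, MG, Sol) with rest/delta/tau.")
  }
  if (any(kinetics$tau_s <= 0)) abort("tau_s must be positive.")
  if (any(kinetics$rest_asym_pct < 0)) abort("rest_asym_pct must be non-negative.")
  if (length(b0_map_ppm) == 1) {
    b0_map_ppm <- field_poly2d(n, amplitude = b0_map_ppm, seed = seed)
  }
  if (length(b1_rel_map) == 1) {
    b1_rel_map <- 1 + field_poly2d(n, amplitude = b1_rel_map, seed = seed + 1L)
  }
  stopifnot(all(dim(b0_map_ppm) == n), all(dim(b1_rel_map) == n))
  if (any(b1_rel_map <= 0)) abort("`b1_rel_map` must be positive everywhere.")
  structure(
    list(label_map = label_map, kinetics = kinetics,
         b0_map_ppm = b0_map_ppm, b1_rel_map = b1_rel_map,
         noise_sd = noise_sd, pools = pools),
    class = "crcest_phantom"
  )
}

#' Simulate a CrCEST exercise-recovery acquisition
#'
#' Runs the two-pool forward model voxelwise: each muscle voxel follows its
#' muscle's creatine time course (converted to a pool amplitude with
#' [calibrate_cr_amplitude()], so the injected asymmetry is exact under
#' nominal fields), modulated by the voxel's B0 shift and B1 efficiency.
#' Additive Gaussian noise of sd `noise_sd` is applied to all signal
#' fractions. The WASSR stack is generated creatine-free at low saturation
#' power with the same B0 field.
#'
#' @param phantom A [tissue_phantom()].
#' @param protocol A [cest_protocol()]; its matrix must match the phantom.
#' @param seed Integer seed for the noise stream.
#' @param wassr_offsets_ppm WASSR fine-offset grid (default 21 points over
#'   +/-1 ppm).
#' @return A `crcest_sim` list: `cest` ([crcest_stack()]), `wassr`
#'   ([wassr_stack()]), `b1_rel_map`, `label_map`, and `truth` (kinetics,
#'   pools, noise sd, seed).
#' @examples
#' ph <- tissue_phantom(make_anatomy(32, 1))
#' sim <- simulate_acquisition(ph, cest_protocol(matrix = 32))
#' @export
simulate_acquisition <- function(phantom, protocol, seed = 1L,
                                 wassr_offsets_ppm = seq(-1, 1, length.out = 21)) {
  stopifnot(inherits(phantom, "crcest_phantom"),
            inherits(protocol, "crcest_protocol"))
  n <- nrow(phantom$label_map)
  if (n != protocol$matrix) {
    abort("Phantom matrix and protocol matrix differ.", class = "crcest_schema_error")
  }
  pools <- phantom$pools
  times <- frame_times(protocol)
  nf <- length(times)
  noff <- length(protocol$offsets_ppm)

  # per-muscle, per-frame pool amplitude hitting the prescribed asymmetry
  amp_by_muscle <- vapply(muscle_levels(), function(m) {
    k <- phantom$kinetics[phantom$kinetics$muscle == m, ]
    tc <- cr_time_course(k$rest_asym_pct, k$delta_asym_pct, k$tau_s, protocol)
    calibrate_cr_amplitude(tc$asym_pct, pools = pools)
  }, numeric(nf))

  lab <- as.integer(phantom$label_map)
  b0 <- as.numeric(phantom$b0_map_ppm)
  b1 <- as.numeric(phantom$b1_rel_map)

  cest <- array(0, c(n, n, noff, nf))
  for (f in seq_len(nf)) {
    amp_vox <- ifelse(lab > 0L, amp_by_muscle[f, ][pmax(lab, 1L)], 0)
    for (o in seq_len(noff)) {
      cest[, , o, f] <- zspectrum_forward(
        protocol$offsets_ppm[o], cr_amplitude = amp_vox,
        b0_ppm = b0, b1_rel = b1,
        water_width_ppm = pools$water_width_ppm, water_depth = pools$water_depth,
        cr_center_ppm = pools$cr_center_ppm, cr_width_ppm = pools$cr_width_ppm)
    }
  }
  wassr <- array(0, c(n, n, length(wassr_offsets_ppm)))
  for (o in seq_along(wassr_offsets_ppm)) {
    wassr[, , o] <- 1 - pools$wassr_depth *
      lorentzian(wassr_offsets_ppm[o] - b0, pools$wassr_width_ppm)
  }

  if (phantom$noise_sd > 0) {
    set.seed(seed)
    cest <- cest + rnorm(length(cest), sd = phantom$noise_sd)
    wassr <- wassr + rnorm(length(wassr), sd = phantom$noise_sd)
    cest <- pmin(pmax(cest, 0), 1)
    wassr <- pmin(pmax(wassr, 0), 1)
  }

  structure(
    list(
      cest = crcest_stack(cest, protocol),
      wassr = wassr_stack(wassr, wassr_offsets_ppm),
      b1_rel_map = phantom$b1_rel_map,
      label_map = phantom$label_map,
      truth = list(kinetics = phantom$kinetics, pools = pools,
                   noise_sd = phantom$noise_sd, seed = as.integer(seed))
    ),
    class = "crcest_sim"
  )
}

#' Synthetic single-ROI time series
#'
#' Generates a muscle-ROI CrCEST series directly from the ground-truth
#' creatine time course (optionally with additive Gaussian noise), bypassing
#' the imaging stages. Used to exercise the kinetics endpoints in isolation.
#'
#' @param rest_asym_pct,delta_asym_pct,tau_s Ground-truth kinetics.
#' @param protocol A [cest_protocol()].
#' @param noise_sd Additive noise sd on the % asymmetry values.
#' @param seed Optional seed for the noise stream.
#' @param muscle Muscle name carried in the series.
#' @return A `crcest_roi_series` tibble.
#' @export
simulate_roi_series <- function(rest_asym_pct, delta_asym_pct, tau_s,
                                protocol = cest_protocol(), noise_sd = 0,
                                seed = NULL, muscle = "LG") {
  tc <- cr_time_course(rest_asym_pct, delta_asym_pct, tau_s, protocol)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    tc$asym_pct <- tc$asym_pct + rnorm(nrow(tc), 0, noise_sd)
  }
  out <- tibble::tibble(muscle = muscle, time_s = tc$time_s,
                        value_pct = tc$asym_pct,
                        n_voxels = rep(1L, nrow(tc)))
  structure(out, class = c("crcest_roi_series", class(out)),
            protocol = protocol, all_times_s = tc$time_s)
}
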
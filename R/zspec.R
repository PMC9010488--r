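#' Per-voxel B0 map from a WASSR stack
#'
#' Maximum-symmetry centre-frequency estimation: for each voxel the water
#' centre `c` is the shift minimising the reflection residual
#' `sum_k (Z(c + d_k) - Z(c - d_k))^2` of the interpolated fine-offset
#' spectrum, with a coarse grid search (0.01 ppm) followed by golden-section
#' refinement to 1e-3 ppm. The search is bounded to +/-0.5 ppm. Spectra are
#' interpolated with a monotone (Fritsch-Carlson) cubic, which cannot
#' overshoot the sampled dip.
#'
#' @param wassr A [wassr_stack()].
#' @param mask Optional logical matrix; voxels outside are skipped (NA).
#' @param search_ppm Half-width of the centre search window, ppm.
#' @param coarse_step_ppm Coarse grid step, ppm.
#' @param flat_tol Minimum spectral depth (max - min) below which a voxel has
#'   no water dip and is flagged invalid.
#' @return List with `b0_ppm` (matrix, NA where invalid or outside the mask)
#'   and `valid` (logical matrix; FALSE where the spectrum was flat).
#' @export
wassr_b0_map <- function(wassr, mask = NULL, search_ppm = 0.5,
                         coarse_step_ppm = 0.01, flat_tol = 0.05) {
  stopifnot(inherits(wassr, "wassr_stack"))
  om <- wassr$offsets_ppm
  if (length(om) < 11) abort("WASSR needs at least 11 offsets.")
  n1 <- dim(wassr$data)[1]; n2 <- dim(wassr$data)[2]
  if (is.null(mask)) mask <- matrix(TRUE, n1, n2)

  half <- min(max(om), abs(min(om))) - search_ppm
  deltas <- seq(0.025, max(half, 0.1), by = 0.025)
  cgrid <- seq(-search_ppm, search_ppm, by = coarse_step_ppm)
  # evaluation points for the coarse stage: every c +/- every delta
  pts_plus <- outer(cgrid, deltas, `+`)
  pts_minus <- outer(cgrid, deltas, `-`)

  b0 <- matrix(NA_real_, n1, n2)
  valid <- matrix(FALSE, n1, n2)
  idx <- which(mask)
  dat <- matrix(wassr$data, n1 * n2, length(om))
  for (v in idx) {
    z <- dat[v, ]
    if (max(z) - min(z) < flat_tol) next  # flat spectrum: no water dip
    f <- splinefun(om, z, method = "monoH.FC")
    res <- rowSums((matrix(f(pts_plus), nrow(pts_plus)) -
                      matrix(f(pts_minus), nrow(pts_minus)))^2)
    c0 <- cgrid[which.min(res)]
    lo <- max(c0 - coarse_step_ppm, -search_ppm)
    hi <- min(c0 + coarse_step_ppm, search_ppm)
    obj <- function(c) sum((f(c + deltas) - f(c - deltas))^2)
    b0[v] <- optimize(obj, c(lo, hi), tol = 1e-4)$minimum
    valid[v] <- TRUE
  }
  list(b0_ppm = b0, valid = valid)
}

# Quadratic Lagrange interpolation with per-voxel nodes, vectorised:
# `nodes` and `y` are (n_vox x 3) matrices, `x` a vector or (n_vox x k)
# matrix of evaluation points. Returns a matrix shaped like `x`.
lagrange3v <- function(nodes, y, x) {
  n1 <- nodes[, 1]; n2 <- nodes[, 2]; n3 <- nodes[, 3]
  w1 <- (x - n2) * (x - n3) / ((n1 - n2) * (n1 - n3))
  w2 <- (x - n1) * (x - n3) / ((n2 - n1) * (n2 - n3))
  w3 <- (x - n1) * (x - n2) / ((n3 - n1) * (n3 - n2))
  w1 * y[, 1] + w2 * y[, 2] + w3 * y[, 3]
}

# Per-side reciprocal-quadratic resampling (exact for a single Lorentzian
# line): quadratic interpolation of 1/(1 - Z) in offset space. Used as the
# fallback when the symmetry-constrained reconstruction is ill-conditioned.
recip_quad <- function(nodes, sig3, x) {
  # sig3: (n_vox x 3), x: n_vox vector; fixed scalar nodes
  r <- 1 / pmax(1 - sig3, 1e-9)
  nd <- matrix(nodes, nrow(sig3), 3, byrow = TRUE)
  1 - 1 / lagrange3v(nd, r, x)
}

#' B0-corrected signal pair at the creatine offset
#'
#' Resamples the acquired offset set so that, after accounting for the
#' voxel's water-centre shift, the returned signals sit at the nominal
#' evaluation offsets -1.8 and +1.8 ppm. The resampling is
#' symmetry-constrained and Lorentzian-aware rather than a plain polynomial:
#' the water line is symmetric about the voxel's B0 and single-Lorentzian
#' (so its reciprocal saturation is quadratic in the offset), and is
#' estimated from the creatine-free negative side; the creatine line is
#' symmetric about the evaluation offset, so its reciprocal is linear in the
#' squared distance and its three positive-side samples determine the peak
#' value. A short fixed-point loop accounts for the creatine far tail under
#' the negative side. Voxels where this reconstruction is ill-conditioned
#' (no creatine, heavy noise) fall back to per-side reciprocal-quadratic
#' interpolation; voxels with |b0| of essentially zero bypass resampling and
#' return the acquired values. Voxels whose shift exceeds the interpolable
#' range (|b0| > `max_shift_ppm`) or whose B0 estimate is missing are
#' flagged and excluded from downstream ROI averages.
#'
#' @param stack A [crcest_stack()] with at least 3 offsets per side.
#' @param b0_ppm B0 map (matrix) or the list returned by [wassr_b0_map()].
#' @param eval_offset_ppm Evaluation offset, ppm (creatine centre).
#' @param max_shift_ppm Largest correctable |b0|.
#' @return A `crcest_pair`: arrays `s_neg`, `s_pos` of shape (x, y, frame),
#'   per-voxel `valid` matrix, frame times and protocol.
#' @export
correct_b0 <- function(stack, b0_ppm, eval_offset_ppm = 1.8,
                       max_shift_ppm = 0.3) {
  stopifnot(inherits(stack, "crcest_stack"))
  if (is.list(b0_ppm) && !is.null(b0_ppm$b0_ppm)) {
    valid0 <- b0_ppm$valid
    b0_ppm <- b0_ppm$b0_ppm
  } else {
    valid0 <- !is.na(b0_ppm)
  }
  offs <- stack$protocol$offsets_ppm
  pos <- sort(offs[offs > 0]); neg <- sort(offs[offs < 0])
  if (length(pos) < 3 || length(neg) < 3) {
    abort("B0 correction needs at least 3 acquired offsets per side.",
          class = "crcest_schema_error")
  }
  pick3 <- function(nodes, target) nodes[order(abs(nodes - target))][1:3]
  pos3 <- sort(pick3(pos, eval_offset_ppm))
  neg3 <- sort(pick3(neg, -eval_offset_ppm))

  d <- dim(stack$data)
  nvox <- d[1] * d[2]
  b0v <- as.numeric(b0_ppm)
  ok <- valid0 & !is.na(b0_ppm) & abs(b0_ppm) <= max_shift_ppm
  b0v[!ok | is.na(b0v)] <- 0  # placeholder; flagged voxels carry no meaning

  sig <- array(stack$data, c(nvox, d[3], d[4]))
  ipos <- match(pos3, offs); ineg <- match(neg3, offs)
  i_n18 <- match(-eval_offset_ppm, offs)
  i_p18 <- match(eval_offset_ppm, offs)

  # per-voxel geometry (constant over frames)
  un2 <- (matrix(neg3, nvox, 3, byrow = TRUE) - b0v)^2  # water radii^2, clean side
  up <- abs(matrix(pos3, nvox, 3, byrow = TRUE) - b0v)  # water radii, peak side
  vp2 <- (matrix(pos3, nvox, 3, byrow = TRUE) - eval_offset_ppm - b0v)^2
  vn2 <- (matrix(neg3, nvox, 3, byrow = TRUE) - eval_offset_ppm - b0v)^2
  far2 <- (2 * eval_offset_ppm)^2
  sbar <- rowMeans(vp2)
  sden <- pmax(rowSums((vp2 - sbar)^2), 1e-12)

  s_neg <- array(NA_real_, c(nvox, d[4]))
  s_pos <- array(NA_real_, c(nvox, d[4]))
  near_zero <- abs(b0v) < 1e-6

  for (f in seq_len(d[4])) {
    zn <- matrix(sig[, ineg, f], nvox)
    zp <- matrix(sig[, ipos, f], nvox)
    # symmetry-constrained reconstruction: water from the creatine-free
    # side (reciprocal quadratic in u^2), creatine peak from its own
    # reciprocal (linear in v^2); iterate to absorb the creatine far tail
    ctail <- matrix(0, nvox, 3)
    for (k in 1:3) {
      w_n <- pmax(1 - zn - ctail, 1e-9)
      rw <- 1 / w_n
      w_up <- 1 / lagrange3v(un2, rw, up^2)
      c_p <- pmax(1 - w_up - zp, 1e-9)
      yc <- 1 / c_p
      ybar <- rowMeans(yc)
      qhat <- rowSums((vp2 - sbar) * (yc - ybar)) / sden
      phat <- ybar - qhat * sbar
      ctail <- 1 / pmax(phat + qhat * vn2, 10)  # far tail is small (< 0.1)
    }
    w18 <- 1 / lagrange3v(un2, 1 / pmax(1 - zn - ctail, 1e-9),
                          rep(eval_offset_ppm^2, nvox))
    c0 <- 1 / phat
    c36 <- ifelse(phat + qhat * far2 > 1, 1 / (phat + qhat * far2), 0)
    sn <- 1 - w18 - pmin(pmax(c36, 0), pmax(c0, 0))
    sp <- 1 - w18 - c0

    # fallback where the reconstruction is ill-conditioned
    bad <- !is.finite(sn) | !is.finite(sp) | phat <= 0 | c0 > 0.5 |
      c0 < -1e-6 | w18 <= 0.02 | w18 >= 1
    if (any(bad)) {
      sp_fb <- recip_quad(pos3, zp, eval_offset_ppm + b0v)
      sn_fb <- recip_quad(neg3, zn, -eval_offset_ppm + b0v)
      sn[bad] <- sn_fb[bad]
      sp[bad] <- sp_fb[bad]
    }
    # essentially unshifted voxels: the acquired values are already nominal
    sn[near_zero] <- sig[near_zero, i_n18, f]
    sp[near_zero] <- sig[near_zero, i_p18, f]
    s_neg[, f] <- sn
    s_pos[, f] <- sp
  }

  structure(
    list(s_neg = array(s_neg, c(d[1], d[2], d[4])),
         s_pos = array(s_pos, c(d[1], d[2], d[4])),
         valid = matrix(ok, d[1], d[2]),
         eval_offset_ppm = eval_offset_ppm,
         frame_times_s = stack$frame_times_s,
         protocol = stack$protocol),
    class = "crcest_pair"
  )
}

#' MTR asymmetry map series
#'
#' Computes the creatine CEST contrast per voxel and frame:
#' `MTR_asym(%) = 100 (S(-dw) - S(+dw)) / S(-dw)` at the evaluation offset
#' (the `S(-dw)` denominator convention; set `denominator = "s0"` to
#' normalise by the unsaturated signal instead, which is 1 for signal
#' fractions). Voxels whose reference signal drops to `S(-dw) <= 0.05` in any
#' frame are flagged as division-unstable.
#'
#' @param pair A `crcest_pair` from [correct_b0()].
#' @param denominator `"sneg"` (default) or `"s0"`.
#' @return A `crcest_asym_series`: `maps` (x, y, frame) in %, per-voxel
#'   `valid`, evaluation offset, frame times, protocol, denominator.
#' @export
mtr_asym_map <- function(pair, denominator = c("sneg", "s0")) {
  stopifnot(inherits(pair, "crcest_pair"))
  denominator <- match.arg(denominator)
  num <- pair$s_neg - pair$s_pos
  den <- if (denominator == "sneg") pair$s_neg else array(1, dim(pair$s_neg))
  unstable <- apply(pair$s_neg <= 0.05, c(1, 2), any)
  valid <- pair$valid & !unstable
  maps <- 100 * num / den
  maps[array(!valid, dim(maps))] <- NA_real_
  structure(
    list(maps = maps, valid = valid,
         eval_offset_ppm = pair$eval_offset_ppm,
         frame_times_s = pair$frame_times_s,
         protocol = pair$protocol,
         denominator = denominator),
    class = "crcest_asym_series"
  )
}

#' B1 correction of asymmetry values
#'
#' Divides measured asymmetry by the normalised saturation-efficiency curve
#' at the voxel's relative B1, so that a voxel saturated below (above)
#' nominal amplitude is scaled up (down) to its nominal-B1 contrast. Voxels
#' with `b1_rel` outside (0.5, 1.5) are flagged.
#'
#' @param asym A `crcest_asym_series` or a numeric vector/array of asymmetry
#'   values in %.
#' @param b1_rel Relative B1 map (matrix matching the series) or values
#'   matching `asym`.
#' @return Same type as `asym`, corrected; for a series, flagged voxels are
#'   added to the QC mask.
#' @export
b1_correction <- function(asym, b1_rel) {
  if (inherits(asym, "crcest_asym_series")) {
    ok <- b1_rel > 0.5 & b1_rel < 1.5
    eff <- saturation_efficiency(pmax(b1_rel, 1e-6))
    asym$maps <- asym$maps / array(eff, dim(asym$maps))
    asym$valid <- asym$valid & ok
    asym$maps[array(!asym$valid, dim(asym$maps))] <- NA_real_
    asym
  } else {
    if (any(b1_rel <= 0.5 | b1_rel >= 1.5)) {
      warn("`b1_rel` outside (0.5, 1.5); such voxels should be flagged.",
           class = "crcest_qc_warning")
    }
    asym / saturation_efficiency(b1_rel)
  }
}

#' Full z-spectrum processing: B0 map, offset correction, B1, MTR_asym
#'
#' Convenience chain for a simulated or loaded session: estimates the B0 map
#' from WASSR (restricted to `mask` when given), resamples the CEST stack at
#' the nominal creatine offsets, computes the asymmetry maps and applies the
#' B1 correction.
#'
#' @param cest A [crcest_stack()].
#' @param wassr A [wassr_stack()].
#' @param b1_rel_map Relative B1 map; `NULL` skips B1 correction.
#' @param mask Logical matrix of voxels to process (e.g. `label_map > 0`).
#' @param denominator Asymmetry denominator convention, see [mtr_asym_map()].
#' @param max_shift_ppm Largest correctable |b0|.
#' @return A `crcest_asym_series`.
#' @export
process_stack <- function(cest, wassr, b1_rel_map = NULL, mask = NULL,
                          denominator = "sneg", max_shift_ppm = 0.3) {
  b0 <- wassr_b0_map(wassr, mask = mask)
  pair <- correct_b0(cest, b0, max_shift_ppm = max_shift_ppm)
  asym <- mtr_asym_map(pair, denominator = denominator)
  if (!is.null(b1_rel_map)) asym <- b1_correction(asym, b1_rel_map)
  asym
}
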
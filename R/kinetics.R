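#' Muscle-ROI asymmetry time series
#'
#' Averages the MTR asymmetry of the unflagged voxels inside one muscle's
#' segmentation for each timepoint. Frames in which every voxel of the muscle
#' is flagged are dropped (and reported via a message), so fits tolerate gaps.
#'
#' @param asym A `crcest_asym_series` from [mtr_asym_map()]/[process_stack()].
#' @param label_map Integer label map aligned with the maps (1 = LG, 2 = MG,
#'   3 = Sol).
#' @param muscle One of "LG", "MG", "Sol".
#' @return A `crcest_roi_series` tibble: `muscle`, `time_s`, `value_pct`,
#'   `n_voxels`; attributes carry the protocol and full frame-time grid.
#' @export
roi_timeseries <- function(asym, label_map, muscle) {
  stopifnot(inherits(asym, "crcest_asym_series"))
  muscle <- match.arg(muscle, muscle_levels())
  code <- MUSCLES[[muscle]]
  if (!any(label_map == code)) {
    abort(sprintf("Muscle label '%s' (%d) is empty in the mask.", muscle, code),
          class = "crcest_data_error")
  }
  sel <- label_map == code & asym$valid
  nf <- dim(asym$maps)[3]
  vox <- matrix(asym$maps, ncol = nf)[as.vector(sel), , drop = FALSE]
  n_ok <- colSums(!is.na(vox))
  means <- ifelse(n_ok > 0, colMeans(vox, na.rm = TRUE), NA_real_)
  keep <- n_ok > 0
  if (any(!keep)) {
    message(sprintf("%s: dropped %d frame(s) with no unflagged voxels.",
                    muscle, sum(!keep)))
  }
  out <- tibble::tibble(
    muscle = muscle,
    time_s = asym$frame_times_s[keep],
    value_pct = means[keep],
    n_voxels = as.integer(n_ok[keep])
  )
  structure(out,
            class = c("crcest_roi_series", class(out)),
            protocol = asym$protocol,
            all_times_s = asym$frame_times_s)
}

#' Resting CrCEST: baseline average
#'
#' Arithmetic mean of the pre-exercise (negative-time) frames, an index of
#' the free creatine concentration at rest.
#'
#' @param series A [roi_timeseries()] result (or any tibble with `time_s`,
#'   `value_pct`).
#' @param n_baseline Number of baseline frames the protocol acquired.
#' @return Resting CrCEST in % asymmetry.
#' @export
resting_crcest <- function(series, n_baseline = 5) {
  base <- series$value_pct[series$time_s < 0]
  if (length(base) < n_baseline) {
    abort(sprintf("Only %d of %d baseline frames available.",
                  length(base), n_baseline),
          class = "crcest_data_error")
  }
  mean(base)
}

#' Exercise delta-CrCEST
#'
#' The rise in CrCEST from the resting baseline to the first post-exercise
#' timepoint, an index of exercise-induced free-creatine release. The first
#' post-exercise frame must be present: if QC dropped it, this errors rather
#' than silently substituting a later frame.
#'
#' @param series A [roi_timeseries()] result.
#' @param resting_pct Resting CrCEST; computed from the series when `NULL`.
#' @param n_baseline Baseline frame count (used when computing resting).
#' @return Delta-CrCEST in % asymmetry.
#' @export
delta_crcest <- function(series, resting_pct = NULL, n_baseline = 5) {
  if (is.null(resting_pct)) resting_pct <- resting_crcest(series, n_baseline)
  all_t <- attr(series, "all_times_s") %||% series$time_s
  post_t <- all_t[all_t >= 0]
  if (length(post_t) == 0) {
    abort("No post-exercise frames.", class = "crcest_data_error")
  }
  t1 <- min(post_t)
  i <- which(series$time_s == t1)
  if (length(i) != 1) {
    abort("First post-exercise frame was dropped by QC; delta-CrCEST undefined.",
          class = "crcest_data_error")
  }
  series$value_pct[i] - resting_pct
}

#' Fit the post-exercise exponential recovery (tauCr)
#'
#' Least-squares fit of `v(t) = asymptote + amp * exp(-t / tau)` to the
#' post-exercise frames only (baseline frames inform the resting/delta
#' endpoints, not the decay). Initialisation: asymptote from the mean of the
#' last three frames, amplitude from the first post-exercise value minus
#' that, tau from a log-linear regression of the positive residuals; tau is
#' bounded to \[1, 5000\] s. Missing frames are simply absent from the
#' objective. Non-convergence, or a non-positive fitted amplitude, yields
#' `status = "fit_failed"` with a diagnostic.
#'
#' @param series A [roi_timeseries()] result with >= 4 post-exercise frames.
#' @param tau_bounds Lower/upper bounds on tau, seconds.
#' @param weights Use per-frame voxel counts as weights (off by default; the
#'   unweighted fit is the standard procedure).
#' @param pin_asymptote Optional value at which to fix the asymptote (e.g.
#'   the resting CrCEST); by default the asymptote is a free parameter, since
#'   creatine need not return exactly to baseline within the imaging window.
#' @return A `crcest_kinetics` object; see [tidy.crcest_kinetics()].
#' @export
fit_tau <- function(series, tau_bounds = c(1, 5000), weights = FALSE,
                    pin_asymptote = NULL) {
  post <- series[series$time_s >= 0, ]
  if (nrow(post) < 4) {
    abort("tau fitting needs at least 4 post-exercise frames.",
          class = "crcest_data_error")
  }
  t <- post$time_s
  v <- post$value_pct
  w <- if (weights && !is.null(post$n_voxels)) post$n_voxels else rep(1, length(v))

  a0 <- mean(v[order(t, decreasing = TRUE)][1:3])
  b0 <- v[which.min(t)] - a0
  d <- v - a0
  pos <- d > 0
  tau0 <- if (sum(pos) >= 2) {
    sl <- coef(lm(log(d[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  tau0 <- min(max(tau0, tau_bounds[1]), tau_bounds[2])
  b0 <- max(b0, 1e-3)

  fit <- tryCatch(
    if (is.null(pin_asymptote)) {
      minpack.lm::nlsLM(
        v ~ a + b * exp(-t / tau),
        start = list(a = a0, b = b0, tau = tau0),
        lower = c(a = -Inf, b = 0, tau = tau_bounds[1]),
        upper = c(a = Inf, b = Inf, tau = tau_bounds[2]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      a_fix <- pin_asymptote
      minpack.lm::nlsLM(
        v ~ a_fix + b * exp(-t / tau),
        start = list(b = max(v[which.min(t)] - a_fix, 1e-3), tau = tau0),
        lower = c(b = 0, tau = tau_bounds[1]),
        upper = c(b = Inf, tau = tau_bounds[2]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) e)

  out <- list(muscle = series$muscle[1], resting_pct = NA_real_,
              delta_pct = NA_real_, tau_s = NA_real_, amp_pct = NA_real_,
              asymptote_pct = NA_real_, rss = NA_real_, status = "fit_failed",
              diagnostics = NULL, n_post_frames = nrow(post), series = series)
  if (inherits(fit, "error")) {
    out$diagnostics <- conditionMessage(fit)
    return(structure(out, class = "crcest_kinetics"))
  }
  cf <- coef(fit)
  out$tau_s <- unname(cf["tau"])
  out$amp_pct <- unname(cf["b"])
  out$asymptote_pct <- if (is.null(pin_asymptote)) unname(cf["a"]) else pin_asymptote
  out$rss <- sum(resid(fit)^2)
  if (out$amp_pct <= 0) {
    out$diagnostics <- "fitted amplitude is not positive: no exercise response"
    out$status <- "fit_failed"
  } else {
    out$status <- "ok"
  }
  structure(out, class = "crcest_kinetics")
}

#' Plausibility filter on fitted tauCr
#'
#' Time constants shorter than one inter-scan interval (24 s) cannot be
#' resolved at the protocol's temporal resolution; values above 1000 s exceed
#' the post-exercise scan window and indicate an insufficient exercise
#' response. Both are excluded from cohort tau models; the fitted values are
#' kept (and reported) so exclusions are auditable. The filter is idempotent.
#'
#' @param fit A `crcest_kinetics` object.
#' @param lo,hi Exclusion bounds, seconds (`lo < hi`).
#' @return The fit with `status` set to `"ok"`, `"excluded_low"` or
#'   `"excluded_high"` (fits with `status = "fit_failed"` pass unchanged).
#' @export
apply_plausibility_filter <- function(fit, lo = 24, hi = 1000) {
  stopifnot(inherits(fit, "crcest_kinetics"))
  if (lo >= hi) abort("`lo` must be below `hi`.", class = "crcest_schema_error")
  if (fit$status == "fit_failed") return(fit)
  fit$status <- if (fit$tau_s < lo) "excluded_low"
    else if (fit$tau_s > hi) "excluded_high"
    else "ok"
  fit
}

#' Kinetics endpoints for every muscle of a session
#'
#' Chains [roi_timeseries()], [resting_crcest()], [delta_crcest()],
#' [fit_tau()] and [apply_plausibility_filter()] over the three calf muscles.
#'
#' @param asym A `crcest_asym_series`.
#' @param label_map Muscle label map.
#' @param n_baseline Baseline frame count.
#' @param lo,hi Plausibility bounds for tau, seconds.
#' @param tau_bounds Fit bounds passed to [fit_tau()].
#' @return Tibble with one row per muscle: endpoints, fit parameters, `rss`,
#'   `status`; the fit objects are kept in the `"fits"` attribute.
#' @export
muscle_kinetics <- function(asym, label_map, n_baseline = 5,
                            lo = 24, hi = 1000, tau_bounds = c(1, 5000)) {
  fits <- purrr::map(muscle_levels(), function(m) {
    s <- roi_timeseries(asym, label_map, m)
    f <- fit_tau(s, tau_bounds = tau_bounds)
    f <- apply_plausibility_filter(f, lo = lo, hi = hi)
    f$resting_pct <- resting_crcest(s, n_baseline)
    f$delta_pct <- delta_crcest(s, f$resting_pct)
    f
  })
  names(fits) <- muscle_levels()
  out <- purrr::map_dfr(fits, tidy)
  structure(out, fits = fits)
}

#' @describeIn fit_tau Tidy the fitted endpoints into a one-row tibble.
#' @param x A `crcest_kinetics` object.
#' @param ... Unused.
#' @method tidy crcest_kinetics
#' @export
tidy.crcest_kinetics <- function(x, ...) {
  tibble::tibble(
    muscle = x$muscle, resting_pct = x$resting_pct, delta_pct = x$delta_pct,
    tau_s = x$tau_s, amp_pct = x$amp_pct, asymptote_pct = x$asymptote_pct,
    rss = x$rss, status = x$status, n_post_frames = x$n_post_frames
  )
}

#' @describeIn fit_tau One-row fit summary (status, rss, frame count).
#' @method glance crcest_kinetics
#' @export
glance.crcest_kinetics <- function(x, ...) {
  tibble::tibble(status = x$status, rss = x$rss,
                 n_post_frames = x$n_post_frames,
                 converged = x$status != "fit_failed")
}

#' @export
print.crcest_kinetics <- function(x, ...) {
  cat(sprintf("<crcest_kinetics> %s: tau = %.1f s, resting = %.2f%%, delta = %.2f%% [%s]\n",
              x$muscle, x$tau_s, x$resting_pct, x$delta_pct, x$status))
  invisible(x)
}
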
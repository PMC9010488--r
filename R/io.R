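#' Pipeline configuration
#'
#' Assembles and validates the configuration driving simulation and
#' processing: the acquisition protocol block, processing options (asymmetry
#' denominator, B1 correction, fit bounds, plausibility bounds) and the seed
#' recorded in every output's provenance.
#'
#' @param protocol Named list of [cest_protocol()] arguments to override.
#' @param processing Named list overriding: `denominator` ("sneg"/"s0"),
#'   `b1_correction` (logical), `tau_bounds` (length-2), `plausibility_lo`,
#'   `plausibility_hi` (seconds), `max_shift_ppm`.
#' @param phantom Named list overriding: `group` ("control"/"FRDA"),
#'   `b0_amplitude_ppm`, `b1_amplitude`, `noise_sd`.
#' @param seed Integer seed.
#' @return A validated `crcest_config` list.
#' @export
pipeline_config <- function(protocol = list(), processing = list(),
                            phantom = list(), seed = 1L) {
  proc_default <- list(denominator = "sneg", b1_correction = TRUE,
                       tau_bounds = c(1, 5000), plausibility_lo = 24,
                       plausibility_hi = 1000, max_shift_ppm = 0.3)
  phan_default <- list(group = "control", b0_amplitude_ppm = 0.1,
                       b1_amplitude = 0.1, noise_sd = 0)
  check_keys <- function(given, allowed, block) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      abort(sprintf("Unknown %s config key(s): %s", block,
                    paste(bad, collapse = ", ")),
            class = "crcest_schema_error")
    }
  }
  check_keys(protocol, names(formals(cest_protocol)), "protocol")
  check_keys(processing, names(proc_default), "processing")
  check_keys(phantom, names(phan_default), "phantom")
  processing <- modifyList(proc_default, processing)
  phantom <- modifyList(phan_default, phantom)
  if (processing$plausibility_lo >= processing$plausibility_hi) {
    abort("plausibility_lo must be below plausibility_hi.",
          class = "crcest_schema_error")
  }
  if (!processing$denominator %in% c("sneg", "s0")) {
    abort("denominator must be 'sneg' or 's0'.", class = "crcest_schema_error")
  }
  cfg <- list(protocol = protocol, processing = processing, phantom = phantom,
              seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "crcest_config")
}

session_provenance <- function(config) {
  list(config_hash = config$hash, seed = config$seed,
       package = "crcestr",
       version = as.character(utils::packageVersion("crcestr")))
}

#' Write a simulated session to disk
#'
#' Writes NIfTI volumes (CEST stack, WASSR stack, relative-B1 map, muscle
#' label map), a JSON sidecar with the protocol, frame times, WASSR offsets
#' and provenance, the ground-truth kinetics as JSON, and a manifest with an
#' MD5 hash per file.
#'
#' @param sim A `crcest_sim` from [simulate_acquisition()].
#' @param dir Output directory (created if missing).
#' @param config Optional [pipeline_config()] recorded in the provenance.
#' @return `dir`, invisibly.
#' @export
write_session <- function(sim, dir, config = pipeline_config()) {
  stopifnot(inherits(sim, "crcest_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  RNifti::writeNifti(sim$cest$data, p("cest.nii"))
  RNifti::writeNifti(sim$wassr$data, p("wassr.nii"))
  RNifti::writeNifti(sim$b1_rel_map, p("b1_rel.nii"))
  RNifti::writeNifti(array(as.integer(sim$label_map), dim(sim$label_map)),
                     p("mask.nii"))
  sidecar <- list(
    protocol = unclass(sim$cest$protocol),
    frame_times_s = sim$cest$frame_times_s,
    wassr_offsets_ppm = sim$wassr$offsets_ppm,
    provenance = session_provenance(config)
  )
  jsonlite::write_json(sidecar, p("sidecar.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("cest.nii", "wassr.nii", "b1_rel.nii", "mask.nii",
             "sidecar.json", "truth.json")
  manifest <- list(files = as.list(setNames(unname(tools::md5sum(p(files))),
                                            files)),
                   provenance = session_provenance(config))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a session directory back into memory
#'
#' @param dir A directory written by [write_session()].
#' @return A `crcest_sim`-shaped list (stacks, B1 map, label map, truth if
#'   present).
#' @export
read_session <- function(dir) {
  p <- function(...) file.path(dir, ...)
  if (!file.exists(p("sidecar.json"))) {
    abort(sprintf("No sidecar.json in '%s': not a session directory.", dir),
          class = "crcest_data_error")
  }
  side <- jsonlite::read_json(p("sidecar.json"), simplifyVector = TRUE)
  if (!file.exists(p("wassr.nii"))) {
    abort("Session is missing the WASSR stack (wassr.nii); B0 correction is impossible.",
          class = "crcest_data_error")
  }
  proto <- do.call(cest_protocol, side$protocol[names(formals(cest_protocol))])
  cest <- crcest_stack(array(as.numeric(RNifti::readNifti(p("cest.nii"))),
                             dim(RNifti::readNifti(p("cest.nii")))),
                       proto, side$frame_times_s)
  wassr_img <- RNifti::readNifti(p("wassr.nii"))
  truth <- if (file.exists(p("truth.json"))) {
    tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    tr$kinetics <- tibble::as_tibble(tr$kinetics)
    tr
  }
  structure(
    list(
      cest = cest,
      wassr = wassr_stack(array(as.numeric(wassr_img), dim(wassr_img)),
                          side$wassr_offsets_ppm),
      b1_rel_map = matrix(as.numeric(RNifti::readNifti(p("b1_rel.nii"))),
                          proto$matrix, proto$matrix),
      label_map = matrix(as.integer(RNifti::readNifti(p("mask.nii"))),
                         proto$matrix, proto$matrix),
      truth = truth,
      provenance = side$provenance
    ),
    class = "crcest_sim"
  )
}

#' Process a session end-to-end
#'
#' Chains the z-spectrum stage (WASSR B0 map, offset resampling, MTR
#' asymmetry, B1 correction) and the kinetics stage (ROI series, resting and
#' delta CrCEST, tau fit, plausibility filter) for all three muscles. When
#' `out_dir` is given, writes the asymmetry maps and QC mask as NIfTI, the
#' tidy ROI series as CSV, the fits as JSON and a cohort CSV row per muscle,
#' all carrying provenance.
#'
#' @param session A `crcest_sim` or a session directory path.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param subject Subject identifier written into tabular outputs.
#' @return List: `asym` (`crcest_asym_series`), `roi` (tidy tibble over
#'   muscles), `fits` (one row per muscle).
#' @export
process_session <- function(session, config = pipeline_config(),
                            out_dir = NULL, subject = "S001") {
  if (is.character(session)) session <- read_session(session)
  stopifnot(inherits(session, "crcest_sim"))
  pr <- config$processing
  mask <- session$label_map > 0
  asym <- process_stack(
    session$cest, session$wassr,
    b1_rel_map = if (isTRUE(pr$b1_correction)) session$b1_rel_map,
    mask = mask, denominator = pr$denominator,
    max_shift_ppm = pr$max_shift_ppm)
  message(sprintf("Flagged %d of %d mask voxels.",
                  sum(mask & !asym$valid), sum(mask)))
  fits <- muscle_kinetics(asym, session$label_map,
                          n_baseline = session$cest$protocol$n_baseline_frames,
                          lo = pr$plausibility_lo, hi = pr$plausibility_hi,
                          tau_bounds = pr$tau_bounds)
  roi <- purrr::map_dfr(attr(fits, "fits"), function(f) f$series)
  roi <- dplyr::mutate(roi, subject = subject, .before = 1)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    RNifti::writeNifti(asym$maps, file.path(out_dir, "asym_maps.nii"))
    RNifti::writeNifti(array(as.integer(asym$valid), dim(asym$valid)),
                       file.path(out_dir, "qc_valid.nii"))
    write.csv(roi, file.path(out_dir, "roi_timeseries.csv"), row.names = FALSE)
    fits_out <- dplyr::mutate(tibble::as_tibble(fits), subject = subject,
                              .before = 1)
    write.csv(fits_out, file.path(out_dir, "kinetics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fits = fits_out, provenance = session_provenance(config),
           eval_offset_ppm = asym$eval_offset_ppm,
           denominator = asym$denominator),
      file.path(out_dir, "kinetics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(asym = asym, roi = roi, fits = fits)
}

#' Simulate a session from a configuration
#'
#' Builds the phantom (anatomy, fields, group kinetics) and the acquisition
#' from a [pipeline_config()] and simulates it; optionally writes the session
#' to disk.
#'
#' @param config A [pipeline_config()].
#' @param dir Optional session directory to write.
#' @return The `crcest_sim` (invisibly if written).
#' @export
simulate_session <- function(config = pipeline_config(), dir = NULL) {
  proto <- do.call(cest_protocol, config$protocol)
  ph <- config$phantom
  phantom <- tissue_phantom(
    make_anatomy(proto$matrix, seed = config$seed),
    kinetics = default_kinetics(ph$group),
    b0_map_ppm = ph$b0_amplitude_ppm,
    b1_rel_map = ph$b1_amplitude,
    noise_sd = ph$noise_sd,
    seed = config$seed)
  sim <- simulate_acquisition(phantom, proto, seed = config$seed)
  if (!is.null(dir)) {
    write_session(sim, dir, config = config)
    return(invisible(sim))
  }
  sim
}
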
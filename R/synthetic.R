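# Synthetic fixtures: every input the analysis chain needs can be generated
# here deterministically — polarimeter frame stacks with known truth maps, and
# cross-polarized confocal orientation/depth series with masks.

#' Specification of a synthetic fixture
#'
#' @param scenario One of `"homogeneous_linear_m45"` (uniform linear at -45
#'   degrees, a polarimeter calibration state), `"homogeneous_circular"`
#'   (uniform right circular), `"svr_radial"` (segmented-retarder output),
#'   `"fiber_in_air"`, `"fiber_in_skin"`.
#' @param grid_shape Polarimeter map size `c(nrow, ncol)`.
#' @param camera A [camera_model()].
#' @param protocol Analyzer protocol (see [default_protocol()]).
#' @param n_averaged Frames averaged per analyzer setting.
#' @param svr An [svr_config()] (radial scenario).
#' @param scene A [fiber_scene()] (fiber scenarios); the background type is
#'   forced to match the scenario.
#' @param illumination Illumination state for fiber scenarios.
#' @param instrument An [instrument_config()] (fiber scenarios).
#' @param orientations Incident-polarization orientations (degrees) rendered
#'   for fiber scenarios.
#' @param depths Focal depths (um) rendered for fiber scenarios.
#' @param seed Integer seed; fixture generation is bit-reproducible.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(scenario = c("homogeneous_linear_m45",
                                      "homogeneous_circular", "svr_radial",
                                      "fiber_in_air", "fiber_in_skin"),
                         grid_shape = c(256, 256), camera = camera_model(),
                         protocol = default_protocol(), n_averaged = 256,
                         svr = svr_config(), scene = NULL,
                         illumination = illumination_linear(45),
                         instrument = instrument_config(),
                         orientations = c(0, 45), depths = 20, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("fiber_in_air", "fiber_in_skin")) {
    bg <- if (scenario == "fiber_in_air") "air" else "skin"
    if (is.null(scene)) scene <- fiber_scene(background = bg)
    if (scene$background != bg) {
      scene <- fiber_scene(psi = scene$psi, diameter = scene$diameter,
                           n_o = scene$n_o, n_e = scene$n_e, delta = scene$delta,
                           background = bg, speckle_sd = scene$speckle_sd,
                           depol_length = scene$depol_length,
                           pass_factor = scene$pass_factor, floor = scene$floor)
    }
  }
  structure(list(scenario = scenario, grid_shape = grid_shape, camera = camera,
                 protocol = protocol, n_averaged = n_averaged, svr = svr,
                 scene = scene, illumination = illumination,
                 instrument = instrument, orientations = orientations,
                 depths = depths, seed = as.integer(seed)),
            class = "fixture_spec")
}

scenario_truth <- function(spec) {
  switch(spec$scenario,
    homogeneous_linear_m45 = uniform_map(stokes(1, 0, -1, 0), spec$grid_shape,
                                         spec$camera$pixel_pitch),
    homogeneous_circular = uniform_map(stokes(1, 0, 0, 1), spec$grid_shape,
                                       spec$camera$pixel_pitch),
    svr_radial = svr_transmit(stokes(1, 1, 0, 0), spec$svr, spec$grid_shape,
                              spec$camera$pixel_pitch),
    stop("not a polarimetry scenario: ", spec$scenario, call. = FALSE))
}

#' Generate a polarimeter fixture
#'
#' Builds the truth map for the scenario (a uniform calibration state or the
#' segmented-retarder output), simulates the camera frame stack under the
#' spec's protocol and noise model, and optionally writes both to disk.
#'
#' @param spec A [fixture_spec()] with a polarimetry scenario.
#' @param dir Optional output directory; the stack goes to `dir/stack/` and the
#'   truth map to `dir/truth.*`.
#' @return `list(truth, stack, dir)`.
#' @export
make_polarimeter_fixture <- function(spec, dir = NULL) {
  truth <- scenario_truth(spec)
  stack <- simulate_stack(truth, spec$protocol, spec$camera, spec$n_averaged,
                          seed = spec$seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_frame_stack(stack, file.path(dir, "stack"))
    write_polarization_map(truth, file.path(dir, "truth"))
  }
  list(truth = truth, stack = stack, dir = dir)
}

#' Generate a confocal fixture
#'
#' Renders one cross-polarized image per (orientation, depth) combination,
#' together with fiber and background ROI masks and a JSON manifest.
#'
#' @param spec A [fixture_spec()] with a fiber scenario.
#' @param dir Optional output directory.
#' @return `list(images, fiber_mask, bg_mask, manifest, dir)`; `images` is a
#'   list indexed `[[orientation]][[depth]]`.
#' @export
make_confocal_fixture <- function(spec, dir = NULL) {
  if (!spec$scenario %in% c("fiber_in_air", "fiber_in_skin")) {
    stop("not a fiber scenario: ", spec$scenario, call. = FALSE)
  }
  images <- lapply(spec$orientations, function(o) {
    render_depth_series(spec$scene, spec$illumination, spec$instrument,
                        spec$depths, orientation = o, seed = spec$seed)
  })
  names(images) <- paste0("orientation_", spec$orientations)
  fmask <- fiber_mask(spec$scene, spec$instrument)
  bmask <- background_mask(spec$scene, spec$instrument)
  manifest <- list(format = "polbiref confocal_fixture v1",
                   scenario = spec$scenario,
                   orientations = spec$orientations, depths = spec$depths,
                   mode = spec$illumination$mode, seed = spec$seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (oi in seq_along(spec$orientations)) {
      for (di in seq_along(spec$depths)) {
        f <- sprintf("img_o%03d_d%03d", spec$orientations[oi], round(spec$depths[di]))
        write_confocal_image(images[[oi]][[di]], file.path(dir, f))
        files[[length(files) + 1L]] <- f
      }
    }
    manifest$files <- unlist(files)
    tiff::writeTIFF(fmask * 1, file.path(dir, "fiber_mask.tif"), bits.per.sample = 8L)
    tiff::writeTIFF(bmask * 1, file.path(dir, "bg_mask.tif"), bits.per.sample = 8L)
    write_json_sidecar(manifest, file.path(dir, "manifest.json"))
  }
  list(images = images, fiber_mask = fmask, bg_mask = bmask,
       manifest = manifest, dir = dir)
}

#' Digitize a rendered confocal image
#'
#' Applies the camera noise/quantization core to a noise-free rendered image:
#' auto-exposes (brightest pixel at 90 percent of full scale unless the camera
#' fixes `full_scale`), acquires `n_frames` noisy quantized frames and returns
#' the average converted back to intensity units, so downstream contrast
#' analysis is unchanged.
#'
#' @param image A `confocal_image` from [render_image()].
#' @param camera A [camera_model()].
#' @param n_frames Frames averaged (1 = single bitmap grab).
#' @param seed Integer seed.
#' @return A `confocal_image` with digitized intensities.
#' @export
digitize_confocal <- function(image, camera = camera_model(), n_frames = 1,
                              seed = NULL) {
  maxc <- 2^camera$bit_depth - 1
  gain <- if (!is.finite(maxc)) 1
          else if (is.null(camera$full_scale)) 0.9 * maxc / max(image$intensity)
          else maxc / camera$full_scale
  counts <- camera_digitize(image$intensity * gain, camera, n_frames, seed)
  image$intensity <- counts / gain
  image$metadata$digitized <- TRUE
  image$metadata$gain <- gain
  image
}
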
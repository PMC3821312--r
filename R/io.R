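# Disk formats: 4-plane float TIFF + JSON sidecar for polarization maps,
# 16-bit TIFF frame sums + JSON manifest for polarimeter stacks, float or
# 8-bit TIFF + JSON for confocal images.

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

# Affine-encode an arbitrary numeric plane into [0, 1] for float TIFF storage.
# A fixed (lo, hi) can be supplied so that re-writing a read object reproduces
# the original bytes.
encode_plane <- function(v, lo = NULL, hi = NULL) {
  if (is.null(lo)) lo <- min(v)
  if (is.null(hi)) hi <- max(v)
  if (hi == lo) hi <- lo + 1
  list(data = pmin(pmax((v - lo) / (hi - lo), 0), 1), lo = lo, hi = hi)
}

#' Write / read a polarization map
#'
#' The four Stokes planes are stored as one multi-plane 16-bit TIFF (each
#' plane affinely scaled into `[0, 1]`; the scaling and the pixel pitch live
#' in a JSON sidecar), plus an 8-bit mask TIFF (sector index, 0 = gap, 255 =
#' outside aperture). The 16-bit grid is idempotent under write/read, so
#' values round-trip within 1/65535 of the plane range and a re-write of a
#' read map is byte-identical.
#'
#' @param map A [polarization_map()].
#' @param prefix Path prefix; files `<prefix>.tif`, `<prefix>_mask.tif` and
#'   `<prefix>.json` are written.
#' @return `prefix`, invisibly (write) or a [polarization_map()] (read).
#' @export
write_polarization_map <- function(map, prefix) {
  sc <- attr(map, "tiff_scale")  # reuse the scaling a read map came with
  planes <- lapply(1:4, function(i) {
    encode_plane(map$s[, , i], lo = sc$lo[i], hi = sc$hi[i])
  })
  tiff::writeTIFF(lapply(planes, `[[`, "data"), paste0(prefix, ".tif"),
                  bits.per.sample = 16L)
  mask <- map$mask
  mask_code <- ifelse(is.na(mask), 255L, as.integer(mask))
  tiff::writeTIFF(matrix(mask_code / 255, nrow(mask), ncol(mask)),
                  paste0(prefix, "_mask.tif"), bits.per.sample = 8L)
  write_json_sidecar(list(
    format = "polbiref polarization_map v1",
    pixel_pitch = map$pixel_pitch,
    planes = paste0("S", 0:3),
    scale_lo = vapply(planes, `[[`, numeric(1), "lo"),
    scale_hi = vapply(planes, `[[`, numeric(1), "hi"),
    mask_encoding = "8-bit: sector index, 0 = gap, 255 = outside aperture"
  ), paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_polarization_map
#' @export
read_polarization_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  s <- array(0, c(dim(planes[[1]]), 4))
  for (i in 1:4) {
    s[, , i] <- planes[[i]] * (meta$scale_hi[i] - meta$scale_lo[i]) + meta$scale_lo[i]
  }
  mask_code <- round(tiff::readTIFF(paste0(prefix, "_mask.tif")) * 255)
  mask <- matrix(as.integer(mask_code), nrow(mask_code), ncol(mask_code))
  mask[mask == 255L] <- NA_integer_
  out <- polarization_map(s, meta$pixel_pitch, mask)
  attr(out, "tiff_scale") <- list(lo = meta$scale_lo, hi = meta$scale_hi)
  out
}

#' Write / read a polarimeter frame stack
#'
#' Each analyzer setting's frame average is stored losslessly as the integer
#' sum of its 8-bit frames in one 16-bit grayscale TIFF (`sum = average *
#' n_averaged`, an exact integer); the JSON manifest records the protocol,
#' camera model, gain and seed.
#'
#' @param stack A `frame_stack` from [simulate_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (write) or a `frame_stack` (read).
#' @export
write_frame_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(stack$settings))
  for (j in seq_along(stack$settings)) {
    s <- stack$settings[[j]]
    files[j] <- sprintf("frame_%02d_%s_%g.tif", j, s$orientation, s$angle)
    total <- round(stack$frames[[j]] * stack$n_averaged)  # exact frame sum
    tiff::writeTIFF(total / 65535, file.path(dir, files[j]), bits.per.sample = 16L)
  }
  write_json_sidecar(list(
    format = "polbiref frame_stack v1",
    settings = lapply(stack$settings, function(s)
      list(orientation = s$orientation, angle = s$angle)),
    files = files,
    n_averaged = stack$n_averaged,
    camera = unclass(stack$camera),
    gain = stack$gain,
    pixel_pitch = stack$pixel_pitch,
    seed = stack$seed
  ), file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = FALSE)
  settings <- lapply(meta$settings, function(s)
    analyzer_setting(s$orientation, s$angle))
  n_avg <- meta$n_averaged
  frames <- lapply(meta$files, function(f) {
    round(tiff::readTIFF(file.path(dir, f)) * 65535) / n_avg
  })
  cam <- meta$camera
  camera <- camera_model(bit_depth = cam$bit_depth,
                         full_scale = if (is.null(cam$full_scale)) NULL else cam$full_scale,
                         read_noise_sd = cam$read_noise_sd,
                         shot_noise = isTRUE(cam$shot_noise),
                         pixel_pitch = cam$pixel_pitch)
  d <- dim(frames[[1]])
  structure(list(settings = settings, frames = frames, n_averaged = n_avg,
                 camera = camera, gain = meta$gain,
                 pixel_pitch = meta$pixel_pitch,
                 mask = matrix(1L, d[1], d[2]),
                 seed = if (is.null(meta$seed)) NULL else meta$seed),
            class = "frame_stack")
}

#' Write / read a confocal image
#'
#' @param image A `confocal_image` from [render_image()].
#' @param prefix Path prefix; `<prefix>.tif` and `<prefix>.json` are written.
#' @param bit_depth 32 (deep storage, values round-trip to ~2e-10 of the
#'   intensity range; default) or 8 (display-style bitmap scaled to the
#'   recorded full scale).
#' @return `prefix`, invisibly (write) or a `confocal_image` (read).
#' @export
write_confocal_image <- function(image, prefix, bit_depth = 32L) {
  v <- image$intensity
  if (bit_depth == 8L) {
    full <- max(v)
    if (full <= 0) full <- 1
    tiff::writeTIFF(pmin(v / full, 1), paste0(prefix, ".tif"), bits.per.sample = 8L)
    enc <- list(lo = 0, hi = full, bit_depth = 8L)
  } else {
    e <- encode_plane(v)
    tiff::writeTIFF(e$data, paste0(prefix, ".tif"), bits.per.sample = 32L)
    enc <- list(lo = e$lo, hi = e$hi, bit_depth = 32L)
  }
  write_json_sidecar(c(list(format = "polbiref confocal_image v1"), enc,
                       image$metadata), paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_confocal_image
#' @export
read_confocal_image <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  raw <- tiff::readTIFF(paste0(prefix, ".tif"))
  v <- if (meta$bit_depth == 8L) raw * meta$hi
       else raw * (meta$hi - meta$lo) + meta$lo
  md <- meta[setdiff(names(meta), c("format", "lo", "hi", "bit_depth"))]
  structure(list(intensity = v, metadata = md), class = "confocal_image")
}
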
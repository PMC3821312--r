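# Ratio-contrast statistic R between birefringent fiber and background, with
# random ROI sampling, power normalization and depth profiles.
#
# R = (I_B^P1 / I_N^P1) / (I_B^P2 / I_N^P2), where I_B and I_N are mean
# intensities from the birefringent sample (hair) and the non-birefringent
# background (air or skin), and P1, P2 are two incident-polarization
# orientations 45 degrees apart. R = 1 means the contrast does not depend on
# the orientation.

#' Randomly place non-overlapping ROIs inside a mask
#'
#' Rectangular regions of interest are placed uniformly at random within the
#' `TRUE` region of `mask`, rejection-sampled so that every ROI lies fully
#' inside the mask and ROIs do not overlap. Deterministic given `seed`.
#'
#' @param mask Logical matrix defining the admissible region.
#' @param n Number of ROIs.
#' @param size_px ROI size `c(rows, cols)` in pixels (30 x 35 at the default
#'   imaging scale, i.e. 25 x 25 um).
#' @param seed Integer seed.
#' @param max_tries Placement attempts before giving up.
#' @return Object of class `roi_set`: list of `list(row, col, nrow, ncol)`
#'   top-left-anchored rectangles.
#' @export
select_rois <- function(mask, n = 3, size_px = c(30, 35), seed = NULL,
                        max_tries = 2000L * n) {
  h <- size_px[1]; w <- size_px[2]
  nr <- nrow(mask); nc <- ncol(mask)
  if (h > nr || w > nc) stop("ROI larger than the image", call. = FALSE)
  # integral image of the mask: O(1) full-coverage test per candidate
  cs <- rbind(0, apply(rbind(0, mask * 1L), 2, cumsum)[-1, , drop = FALSE])
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  covered <- function(r, c) {
    cs[r + h, c + w] - cs[r, c + w] - cs[r + h, c] + cs[r, c] == h * w
  }
  rois <- with_seed(seed, {
    out <- list()
    tries <- 0L
    while (length(out) < n && tries < max_tries) {
      tries <- tries + 1L
      r <- sample.int(nr - h + 1L, 1L)
      c <- sample.int(nc - w + 1L, 1L)
      if (!covered(r, c)) next
      overlap <- any(vapply(out, function(o) {
        r < o$row + o$nrow && o$row < r + h && c < o$col + o$ncol && o$col < c + w
      }, logical(1)))
      if (overlap) next
      out[[length(out) + 1L]] <- list(row = r, col = c, nrow = h, ncol = w)
    }
    out
  })
  if (length(rois) < n) {
    stop(sprintf("could not place %d non-overlapping %dx%d ROIs inside the mask", n, h, w),
         call. = FALSE)
  }
  structure(rois, class = "roi_set")
}

roi_pixels <- function(image, roi) {
  image[roi$row:(roi$row + roi$nrow - 1L), roi$col:(roi$col + roi$ncol - 1L)]
}

#' Pooled ROI intensity statistics
#'
#' Mean and standard deviation over all pixels of all ROIs pooled together.
#'
#' @param image Numeric matrix or a `confocal_image`.
#' @param rois An [select_rois()] result (or a list of rectangles).
#' @return `list(mean, sd, n)`.
#' @export
roi_stats <- function(image, rois) {
  if (inherits(image, "confocal_image")) image <- image$intensity
  px <- unlist(lapply(rois, function(r) as.numeric(roi_pixels(image, r))))
  if (!length(px)) stop("empty ROI set", call. = FALSE)
  list(mean = mean(px), sd = stats::sd(px), n = length(px))
}

#' Normalize an intensity by the optical power used
#'
#' @param mean_intensity Measured mean intensity.
#' @param power Optical power (> 0) used during acquisition.
#' @return `mean_intensity / power`.
#' @export
normalize_power <- function(mean_intensity, power) {
  if (any(power <= 0)) stop("`power` must be > 0", call. = FALSE)
  mean_intensity / power
}

#' Ratio contrast between two polarization orientations
#'
#' `R = (i_b_p1 / i_n_p1) / (i_b_p2 / i_n_p2)` for fiber (`i_b`) and
#' background (`i_n`) mean intensities at two incident-polarization
#' orientations 45 degrees apart. `R = 1` indicates orientation-independent
#' contrast; swapping P1 and P2 maps `R` to `1/R`.
#'
#' @param i_b_p1,i_n_p1,i_b_p2,i_n_p2 Positive mean intensities.
#' @return The ratio `R`.
#' @export
ratio_R <- function(i_b_p1, i_n_p1, i_b_p2, i_n_p2) {
  v <- c(i_b_p1, i_n_p1, i_b_p2, i_n_p2)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("ratio_R requires all four mean intensities to be finite and > 0", call. = FALSE)
  }
  (i_b_p1 / i_n_p1) / (i_b_p2 / i_n_p2)
}

#' Orientation-contrast profile over focusing depth
#'
#' For each depth, draws matched fiber and background ROI sets (re-drawn per
#' depth with a seed offset, identical for the two orientations so the
#' geometric sampling cancels in the ratio), computes power-normalized mean
#' intensities and evaluates the ratio contrast. The uncertainty is first-order
#' error propagation of the standard errors of the four ROI means.
#'
#' @param series_p1,series_p2 Lists of [render_image()] results (or plain
#'   intensity matrices) at matched depths for the two orientations.
#' @param fiber_mask,bg_mask Logical masks for ROI placement.
#' @param depths Depth (um) of each list element.
#' @param n Number of ROIs per region.
#' @param size_px ROI size in pixels `c(rows, cols)`.
#' @param seed Base seed for ROI placement.
#' @param powers Optical power `c(P1, P2)` used for the two series.
#' @return A `data.frame` of class `contrast_curve` with columns `depth`,
#'   `R` (oriented so that `R >= 1`: P1 is taken as the higher-contrast
#'   orientation), `R_raw` (signed ratio as given), `R_sd`, and the four
#'   normalized component means.
#' @export
contrast_depth_curve <- function(series_p1, series_p2, fiber_mask, bg_mask,
                                 depths = seq_along(series_p1) - 1, n = 3,
                                 size_px = c(30, 35), seed = 1L,
                                 powers = c(1, 1)) {
  if (length(series_p1) != length(series_p2)) {
    stop("P1 and P2 series have different lengths", call. = FALSE)
  }
  if (length(depths) != length(series_p1)) {
    stop("`depths` must match the series length", call. = FALSE)
  }
  rows <- lapply(seq_along(depths), function(i) {
    rois_f <- select_rois(fiber_mask, n, size_px, seed = seed + i)
    rois_b <- select_rois(bg_mask, n, size_px, seed = seed + 100000L + i)
    st <- list(
      b1 = roi_stats(series_p1[[i]], rois_f),
      n1 = roi_stats(series_p1[[i]], rois_b),
      b2 = roi_stats(series_p2[[i]], rois_f),
      n2 = roi_stats(series_p2[[i]], rois_b))
    m <- c(normalize_power(st$b1$mean, powers[1]),
           normalize_power(st$n1$mean, powers[1]),
           normalize_power(st$b2$mean, powers[2]),
           normalize_power(st$n2$mean, powers[2]))
    r_raw <- ratio_R(m[1], m[2], m[3], m[4])
    # delta-method sd from the standard errors of the four means
    se <- vapply(st, function(s) s$sd / sqrt(s$n), numeric(1)) /
      c(powers[1], powers[1], powers[2], powers[2])
    rel2 <- sum((se / m)^2)
    r <- max(r_raw, 1 / r_raw)
    data.frame(depth = depths[i], R = r, R_raw = r_raw,
               R_sd = r * sqrt(rel2),
               i_b_p1 = m[1], i_n_p1 = m[2], i_b_p2 = m[3], i_n_p2 = m[4])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_curve", "data.frame")
  out
}

#' @export
plot.contrast_curve <- function(x, ...) {
  graphics::plot(x$depth, x$R, type = "b", pch = 19,
                 xlab = "focusing depth (um)", ylab = "ratio contrast R",
                 ylim = range(c(x$R - x$R_sd, x$R + x$R_sd, 1)), ...)
  graphics::arrows(x$depth, x$R - x$R_sd, x$depth, x$R + x$R_sd,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Write a contrast curve to CSV
#'
#' @param curve A [contrast_depth_curve()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contrast_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
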
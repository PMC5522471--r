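#' ROI count statistics
#'
#' Per-pixel mean counts inside an ROI. All index computation downstream is
#' based on per-pixel means, never totals, so differing ROI sizes cannot
#' bias an index; this also makes the thorax-background "area correction"
#' automatic.
#'
#' @param image A [planar_image].
#' @param roi A [roi_mask] whose pixels all lie on the image grid.
#' @return An object of class `roi_stats` with `mean_counts_per_pixel`,
#'   `n_pixels`, `total_counts`, `t_acq_min`, `label`.
#' @export
roi_mean_counts <- function(image, roi) {
  stopifnot(inherits(image, "planar_image"), inherits(roi, "roi_mask"))
  g <- dim(image$counts)
  p <- roi$pixels
  if (any(p[, 1] >= g[1] | p[, 2] >= g[2])) {
    stop(format_error("ROI exceeds image grid"))
  }
  total <- sum(image$counts[p[, 1] + p[, 2] * g[1] + 1L])
  roi_stats(
    mean_counts_per_pixel = total / nrow(p),
    n_pixels = nrow(p),
    total_counts = total,
    t_acq_min = image$t_acq_min,
    label = roi$label
  )
}

roi_stats <- function(mean_counts_per_pixel, n_pixels, total_counts,
                      t_acq_min, label) {
  stopifnot(n_pixels >= 1, total_counts >= 0)
  structure(
    list(mean_counts_per_pixel = mean_counts_per_pixel,
         n_pixels = as.integer(n_pixels),
         total_counts = total_counts,
         t_acq_min = t_acq_min,
         label = label),
    class = "roi_stats"
  )
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> %s @ t=%s min: mean %.4g c/px over %d px\n",
              x$label, format(x$t_acq_min), x$mean_counts_per_pixel,
              x$n_pixels))
  invisible(x)
}

#' Mirror an ROI about a vertical axis
#'
#' Reflects every pixel about the column line `x = axis_col` (pixel-center
#' coordinates): `(r, c)` maps to `(r, round(2*axis_col - c))` with
#' round-half-away-from-zero. With `axis_col` at the image midline this
#' places a nodule ROI onto the contralateral lobe; with an axis lateral to
#' the thyroid it places the ROI in extra-thyroidal background, the two
#' mirroring manoeuvres used for the retention and wash-out methods
#' respectively.
#'
#' @param roi A [roi_mask].
#' @param axis_col Column coordinate of the mirror axis (may be half-integer,
#'   e.g. `(cols-1)/2` for the exact grid midline).
#' @param new_label Label for the mirrored mask.
#' @return A [roi_mask]. If the mirrored mask overlaps the input mask the
#'   result carries `attr(, "overlaps_source") = TRUE` and a warning is
#'   raised (a mis-placed background ROI would contaminate the subtraction).
#' @export
mirror_roi <- function(roi, axis_col, new_label) {
  p <- roi$pixels
  reflected <- round_half_away(2 * axis_col - p[, 2])
  if (any(reflected < 0 | reflected >= roi$source_grid[2])) {
    stop(format_error("mirrored ROI falls outside the grid"))
  }
  out <- roi_mask(cbind(p[, 1], reflected), new_label, roi$source_grid)
  overlap <- any(roi_pixel_key(out) %in% roi_pixel_key(roi))
  attr(out, "overlaps_source") <- overlap
  if (overlap) {
    warning("mirrored ROI overlaps its source ROI; background placement suspect")
  }
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Copy an early-image ROI onto the late-image grid
#'
#' The acquisition protocol draws ROIs on the early image and copies them
#' onto the delayed one. When the two grids are identical the copy is the
#' identity; a grid change (e.g. 256 to 128 matrix) must be declared and is
#' applied as a uniform coordinate scale with duplicates collapsed.
#'
#' @param roi A [roi_mask] on `early_grid`.
#' @param early_grid,late_grid `c(rows, cols)` of the two image grids.
#' @return A [roi_mask] on `late_grid`.
#' @export
copy_roi_to_late <- function(roi, early_grid, late_grid) {
  early_grid <- as.integer(early_grid); late_grid <- as.integer(late_grid)
  if (!all(roi$source_grid == early_grid)) {
    stop(format_error("ROI source grid does not match the early grid"))
  }
  if (all(early_grid == late_grid)) {
    out <- roi
    out$source_grid <- late_grid
    return(out)
  }
  s <- late_grid / early_grid
  if (s[1] != s[2]) {
    stop(format_error("anisotropic grid remapping is not supported"))
  }
  mapped <- unique(cbind(floor(roi$pixels[, 1] * s[1]),
                         floor(roi$pixels[, 2] * s[2])))
  roi_mask(mapped, roi$label, late_grid)
}

#' Physical-decay correction specification
#'
#' @param half_life_min Isotope half-life in minutes; default 360.4
#'   (Tc-99m, 6.007 h).
#' @param reference_time_min Common reference time (minutes post-injection)
#'   counts are corrected to; default 0 (injection time).
#' @param enabled Whether correction is applied. Default `FALSE`: the two
#'   indices are conventionally reported on raw counts, and the retention
#'   index is provably insensitive to the toggle.
#' @return An object of class `decay_spec`.
#' @export
decay_spec <- function(half_life_min = 360.4, reference_time_min = 0,
                       enabled = FALSE) {
  stopifnot(half_life_min > 0)
  structure(list(half_life_min = half_life_min,
                 reference_time_min = reference_time_min,
                 enabled = enabled),
            class = "decay_spec")
}

#' Decay-correct ROI statistics
#'
#' Rescales mean and total counts to the reference time by
#' `2^((t_acq - t_ref) / half_life)`, removing physical isotope decay from
#' the early/late comparison. Pixel count is unchanged; corrected values
#' are real-valued.
#'
#' @param stats A [roi_stats].
#' @param spec A [decay_spec] with `enabled = TRUE`.
#' @return A corrected [roi_stats].
#' @export
decay_correct <- function(stats, spec) {
  stopifnot(inherits(stats, "roi_stats"), inherits(spec, "decay_spec"))
  if (!spec$enabled) stop(format_error("decay correction is not enabled"))
  if (is.na(stats$t_acq_min)) {
    stop(format_error("acquisition time unknown; cannot decay-correct"))
  }
  f <- 2 ^ ((stats$t_acq_min - spec$reference_time_min) / spec$half_life_min)
  stats$mean_counts_per_pixel <- stats$mean_counts_per_pixel * f
  stats$total_counts <- stats$total_counts * f
  stats
}

# apply correction when enabled, pass through otherwise
maybe_decay_correct <- function(stats, spec) {
  if (isTRUE(spec$enabled)) decay_correct(stats, spec) else stats
}
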
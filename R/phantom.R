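#' Two-lobe thyroid phantom geometry
#'
#' Anatomy for the synthetic planar studies: two elliptical lobes placed
#' symmetrically about a midline column, an isthmus band joining them, and
#' a disc nodule inside the right lobe (image-left/right in pixel terms).
#' All coordinates are 0-based pixel-center `(row, col)`.
#'
#' @param grid `c(rows, cols)`, default `c(256, 256)`.
#' @param lobe_offset_col Lobe-center distance from the midline column.
#' @param lobe_semi Ellipse semi-axes `c(row, col)`.
#' @param lobe_center_row Row of both lobe centers.
#' @param isthmus_rows,isthmus_half_width Isthmus band extent (rows) and
#'   half-width in columns about the midline.
#' @param nodule_center `(row, col)` of the nodule disc center; must lie in
#'   the right lobe. Default sits in the lower third of the right lobe.
#' @param nodule_size_mm Nodule diameter in millimetres.
#' @param pixel_size_mm Pixel pitch in millimetres (2 mm for a 256 matrix
#'   over a ~51 cm field of view at magnification 1).
#' @param bg_mirror_axis_col Axis used to mirror the nodule ROI into
#'   extra-thyroidal background for the wash-out method; must place the
#'   reflection outside the thyroid.
#' @param thorax_rows,thorax_cols Row/column ranges of the rectangular
#'   thorax-background ROI.
#' @return A `phantom_geometry` object.
#' @export
phantom_geometry <- function(grid = c(256, 256),
                             lobe_offset_col = 38,
                             lobe_semi = c(45, 22),
                             lobe_center_row = 127.5,
                             isthmus_rows = c(150, 165),
                             isthmus_half_width = 18,
                             nodule_center = NULL,
                             nodule_size_mm = 25,
                             pixel_size_mm = 2,
                             bg_mirror_axis_col = NULL,
                             thorax_rows = c(10, 30),
                             thorax_cols = c(10, 50)) {
  grid <- as.integer(grid)
  midline <- (grid[2] - 1) / 2
  if (is.null(nodule_center)) {
    nodule_center <- c(lobe_center_row + lobe_semi[1] / 3,
                       midline + lobe_offset_col)
  }
  if (is.null(bg_mirror_axis_col)) {
    # far enough lateral that the reflected nodule clears the lobe
    bg_mirror_axis_col <- midline + lobe_offset_col +
      lobe_semi[2] + nodule_size_mm / pixel_size_mm / 2 + 2
  }
  geom <- structure(
    list(grid = grid, midline_col = midline,
         lobe_offset_col = lobe_offset_col, lobe_semi = lobe_semi,
         lobe_center_row = lobe_center_row,
         isthmus_rows = isthmus_rows,
         isthmus_half_width = isthmus_half_width,
         nodule_center = nodule_center,
         nodule_radius_px = nodule_size_mm / pixel_size_mm / 2,
         nodule_size_mm = nodule_size_mm, pixel_size_mm = pixel_size_mm,
         bg_mirror_axis_col = bg_mirror_axis_col,
         thorax_rows = thorax_rows, thorax_cols = thorax_cols),
    class = "phantom_geometry"
  )
  validate_phantom_geometry(geom)
}

# compartment membership rasters (logical matrices)
phantom_masks <- function(geom) {
  g <- geom$grid
  rr <- matrix(rep(0:(g[1] - 1), g[2]), g[1], g[2])
  cc <- matrix(rep(0:(g[2] - 1), each = g[1]), g[1], g[2])
  ellipse <- function(c_row, c_col) {
    ((rr - c_row) / geom$lobe_semi[1])^2 +
      ((cc - c_col) / geom$lobe_semi[2])^2 <= 1
  }
  right <- ellipse(geom$lobe_center_row, geom$midline_col + geom$lobe_offset_col)
  left <- ellipse(geom$lobe_center_row, geom$midline_col - geom$lobe_offset_col)
  isthmus <- rr >= geom$isthmus_rows[1] & rr <= geom$isthmus_rows[2] &
    abs(cc - geom$midline_col) <= geom$isthmus_half_width
  nodule <- (rr - geom$nodule_center[1])^2 +
    (cc - geom$nodule_center[2])^2 <= geom$nodule_radius_px^2
  list(left_lobe = left, right_lobe = right, isthmus = isthmus,
       thyroid = left | right | isthmus, nodule = nodule)
}

validate_phantom_geometry <- function(geom) {
  m <- phantom_masks(geom)
  if (!any(m$nodule)) stop(format_error("nodule disc covers no pixels"))
  if (any(m$nodule & !m$right_lobe)) {
    stop(format_error("nodule disc is not contained in one lobe"))
  }
  if (any(m$left_lobe & m$right_lobe)) {
    stop(format_error("lobes are not disjoint"))
  }
  # the wash-out background mirror must land outside the thyroid, in-grid
  nod <- raster_to_roi(m$nodule, "nodule")
  bg <- mirror_roi(nod, geom$bg_mirror_axis_col, "mirror_background")
  if (any(roi_to_raster(bg) & m$thyroid)) {
    stop(format_error("mirrored background ROI intersects the thyroid"))
  }
  geom
}

#' Compartment kinetics for the phantom
#'
#' The tracer model is an additive projection: each pixel's expected count
#' rate is the sum of the compartments projected onto it (body background
#' everywhere; parenchyma or nodule inside the thyroid), and each
#' compartment retains a fixed fraction `f` of its initial rate over the
#' early-to-late interval. Background superimposes on the thyroid exactly
#' as in planar imaging, which is why the mirrored-background subtraction
#' recovers the pure nodular signal.
#'
#' @param a0_nodule,a0_parenchyma,a0_body_background Initial count-rate
#'   densities (counts/pixel/second at injection time).
#' @param f_nodule,f_parenchyma,f_background Retention fractions in
#'   `(0, 1]` over the early-to-late interval. Normal parenchyma washes
#'   MIBI out faster than nodules, so `f_parenchyma < f_nodule` by default
#'   and the constructor warns when the ordering is violated.
#' @param apply_physical_decay Multiply frames by the Tc-99m physical decay
#'   factor `2^(-t/half_life)`.
#' @param half_life_min Isotope half-life (minutes).
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(a0_nodule = 0.2, a0_parenchyma = 0.15,
                           a0_body_background = 0.02,
                           f_nodule = 0.70, f_parenchyma = 0.50,
                           f_background = 0.50,
                           apply_physical_decay = FALSE,
                           half_life_min = 360.4) {
  f <- c(f_nodule, f_parenchyma, f_background)
  if (any(f <= 0 | f > 1)) {
    stop(format_error("retention fractions must lie in (0, 1]"))
  }
  if (any(c(a0_nodule, a0_parenchyma, a0_body_background) < 0)) {
    stop(format_error("count-rate densities must be non-negative"))
  }
  if (f_parenchyma >= f_nodule) {
    warning("f_parenchyma >= f_nodule: parenchyma normally clears faster than nodules")
  }
  structure(list(a0_nodule = a0_nodule, a0_parenchyma = a0_parenchyma,
                 a0_body_background = a0_body_background,
                 f_nodule = f_nodule, f_parenchyma = f_parenchyma,
                 f_background = f_background,
                 apply_physical_decay = apply_physical_decay,
                 half_life_min = half_life_min),
            class = "kinetic_params")
}

phantom_decay_factor <- function(kinetics, t_min) {
  if (isTRUE(kinetics$apply_physical_decay)) {
    2 ^ (-t_min / kinetics$half_life_min)
  } else 1
}

# expected counts/pixel for one compartment at one timepoint
compartment_expectation <- function(kinetics, frame_s, t_min, late) {
  d <- phantom_decay_factor(kinetics, t_min)
  with(kinetics, {
    fn <- if (late) f_nodule else 1
    fp <- if (late) f_parenchyma else 1
    fb <- if (late) f_background else 1
    list(background = a0_body_background * fb * frame_s * d,
         parenchyma = (a0_body_background * fb + a0_parenchyma * fp) *
           frame_s * d,
         nodule = (a0_body_background * fb + a0_nodule * fn) * frame_s * d)
  })
}

#' Build a dual-time-point phantom study
#'
#' Generates early and late planar MIBI frames from the additive
#' compartment model plus the four ground-truth ROI masks the two
#' quantification methods need: the nodule disc, its mirror into
#' extra-thyroidal background (wash-out method), its mirror onto the
#' contralateral lobe (retention method), and the rectangular thorax
#' background.
#'
#' @param geometry A [phantom_geometry].
#' @param kinetics A [kinetic_params].
#' @param times `c(t_early, t_late)` minutes post-injection.
#' @param frame_s Frame duration, seconds.
#' @param noise `"poisson"` (independent per-pixel counts; `seed`
#'   required) or `"none"` (exact expected-value frames, real-valued).
#' @param seed RNG seed for Poisson sampling.
#' @return List: `study` ([study_bundle] with ROI masks attached), `truth`
#'   (compartment rasters), `kinetics`, `geometry`, `times`, `frame_s`.
#' @export
build_phantom <- function(geometry = phantom_geometry(),
                          kinetics = kinetic_params(),
                          times = c(10, 60), frame_s = 600,
                          noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  if (noise == "poisson" && is.null(seed)) {
    stop(format_error("Poisson noise requires a seed"))
  }
  masks <- phantom_masks(geometry)
  frame <- function(late, t_min) {
    e <- compartment_expectation(kinetics, frame_s, t_min, late)
    img <- matrix(e$background, geometry$grid[1], geometry$grid[2])
    img[masks$thyroid] <- e$parenchyma
    img[masks$nodule] <- e$nodule
    img
  }
  exp_early <- frame(FALSE, times[1])
  exp_late <- frame(TRUE, times[2])
  if (noise == "poisson") {
    set.seed(seed)
    counts_early <- matrix(stats::rpois(length(exp_early), exp_early),
                           nrow(exp_early))
    counts_late <- matrix(stats::rpois(length(exp_late), exp_late),
                          nrow(exp_late))
    integer_counts <- TRUE
  } else {
    counts_early <- exp_early
    counts_late <- exp_late
    integer_counts <- FALSE
  }
  nodule_roi <- raster_to_roi(masks$nodule, "nodule")
  rois <- list(
    nodule = nodule_roi,
    mirror_background = mirror_roi(nodule_roi, geometry$bg_mirror_axis_col,
                                   "mirror_background"),
    contralateral = mirror_roi(nodule_roi, geometry$midline_col,
                               "contralateral"),
    thorax_background = rect_roi(geometry$thorax_rows, geometry$thorax_cols,
                                 geometry$grid, "thorax_background")
  )
  study <- study_bundle(
    early = planar_image(counts_early, times[1], frame_s,
                         integer_counts = integer_counts),
    late = planar_image(counts_late, times[2], frame_s,
                        integer_counts = integer_counts),
    rois = rois
  )
  list(study = study, truth = masks, kinetics = kinetics,
       geometry = geometry, times = times, frame_s = frame_s, seed = seed)
}

rect_roi <- function(rows, cols, grid, label) {
  px <- expand.grid(row = rows[1]:rows[2], col = cols[1]:cols[2])
  roi_mask(as.matrix(px), label, grid)
}

#' Closed-form noiseless index value for a phantom
#'
#' Evaluates the printed formula chain on the exact compartment
#' expectations, independently of the image pipeline: the oracle both
#' quantification paths are tested against.
#'
#' @param kinetics A [kinetic_params].
#' @param method `"WOind"` or `"RI"`.
#' @param times `c(t_early, t_late)` minutes.
#' @param frame_s Frame duration (cancels; kept for symmetry with
#'   [build_phantom()]).
#' @param decay A [decay_spec] applied to the region means, matching the
#'   pipeline's correction mode.
#' @return The exact index value (percent scale).
#' @export
analytic_index <- function(kinetics, method = c("WOind", "RI"),
                           times = c(10, 60), frame_s = 600,
                           decay = decay_spec()) {
  method <- match.arg(method)
  e <- compartment_expectation(kinetics, frame_s, times[1], late = FALSE)
  l <- compartment_expectation(kinetics, frame_s, times[2], late = TRUE)
  g <- function(t) {
    if (isTRUE(decay$enabled)) {
      2 ^ ((t - decay$reference_time_min) / decay$half_life_min)
    } else 1
  }
  ge <- g(times[1]); gl <- g(times[2])
  if (method == "WOind") {
    er <- (e$nodule - e$background) * ge
    lr <- (l$nodule - l$background) * gl
    if (er <= 0) {
      stop(format_error("degenerate contrast: ER <= 0",
                        "mibiquant_non_positive_net_uptake"))
    }
    100 * lr / er - 100
  } else {
    den_e <- (e$parenchyma - e$background) * ge
    den_l <- (l$parenchyma - l$background) * gl
    if (den_e <= 0 || den_l <= 0) {
      stop(format_error("degenerate contrast: normal-tissue term <= 0",
                        "mibiquant_degenerate_ratio"))
    }
    er <- (e$nodule - e$background) * ge / den_e
    dr <- (l$nodule - l$background) * gl / den_l
    if (er <= 0) {
      stop(format_error("degenerate contrast: ER <= 0",
                        "mibiquant_degenerate_ratio"))
    }
    100 * (dr - er) / er
  }
}
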
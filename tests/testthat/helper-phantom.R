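# Small phantom geometry used by most tests; the full 256x256 default is
# exercised in the acceptance suite.
small_geometry <- function(...) {
  phantom_geometry(
    grid = c(96, 96), lobe_offset_col = 14, lobe_semi = c(18, 8),
    lobe_center_row = 47.5, isthmus_rows = c(56, 62),
    isthmus_half_width = 6, nodule_size_mm = 12, pixel_size_mm = 2,
    thorax_rows = c(5, 15), thorax_cols = c(5, 20), ...
  )
}

# random in-bounds ROI of n distinct pixels
random_roi <- function(grid, n, label = "nodule") {
  idx <- sample.int(grid[1] * grid[2], n)
  roi_mask(cbind((idx - 1) %% grid[1], (idx - 1) %/% grid[1]), label, grid)
}

make_stats <- function(mean, n = 10L, t = NA_real_, label = "nodule") {
  mibiquant:::roi_stats(mean, n, mean * n, t, label)
}

# straight-line reimplementations of the printed formula chains, used as
# the independent oracle for both index functions
oracle_woind <- function(ne, be, nl, bl) 100 * (nl - bl) / (ne - be) - 100
oracle_ri <- function(ne, ce, te, nl, cl, tl) {
  er <- (ne - te) / (ce - te)
  dr <- (nl - tl) / (cl - tl)
  100 * (dr - er) / er
}
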
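#' Region-of-interest pixel mask
#'
#' A labelled set of pixel coordinates on an image grid. Coordinates are
#' 0-based `(row, col)` with row 0 at the image top, matching the raster
#' convention used throughout the package.
#'
#' @param pixels Two-column integer matrix of `(row, col)` coordinates
#'   (0-based), one row per member pixel.
#' @param label One of `"nodule"`, `"mirror_background"`, `"contralateral"`,
#'   `"thorax_background"`.
#' @param source_grid Integer vector `c(rows, cols)` of the grid the mask
#'   lives on.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels,
                     label = c("nodule", "mirror_background",
                               "contralateral", "thorax_background"),
                     source_grid) {
  label <- match.arg(label)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2) stop(format_error("pixels must be an n x 2 matrix"))
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("row", "col")
  roi <- structure(
    list(pixels = pixels, label = label,
         source_grid = as.integer(source_grid)),
    class = "roi_mask"
  )
  validate_roi_mask(roi)
}

validate_roi_mask <- function(roi) {
  p <- roi$pixels
  if (nrow(p) == 0) stop(format_error("ROI mask is empty"))
  g <- roi$source_grid
  if (any(p[, 1] < 0 | p[, 1] >= g[1] | p[, 2] < 0 | p[, 2] >= g[2])) {
    stop(format_error("ROI pixel outside source grid"))
  }
  if (anyDuplicated(paste(p[, 1], p[, 2]))) {
    stop(format_error("duplicate ROI pixel coordinates"))
  }
  roi
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d px on %dx%d grid\n",
              x$label, nrow(x$pixels), x$source_grid[1], x$source_grid[2]))
  invisible(x)
}

roi_size <- function(roi) nrow(roi$pixels)

# canonical ordering so identical pixel sets compare identical
roi_canonical <- function(roi) {
  o <- order(roi$pixels[, 1], roi$pixels[, 2])
  roi$pixels <- roi$pixels[o, , drop = FALSE]
  roi
}

roi_pixel_key <- function(roi) {
  p <- roi_canonical(roi)$pixels
  paste(p[, 1], p[, 2], sep = ",")
}

#' Convert an ROI mask to a logical raster
#' @param roi A [roi_mask].
#' @return Logical matrix of the ROI's source grid dimensions.
#' @export
roi_to_raster <- function(roi) {
  m <- matrix(FALSE, roi$source_grid[1], roi$source_grid[2])
  m[roi$pixels[, 1] + roi$pixels[, 2] * roi$source_grid[1] + 1L] <- TRUE
  m
}

raster_to_roi <- function(raster, label) {
  idx <- which(raster != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop(format_error("empty mask raster"))
  roi_mask(cbind(idx[, 1] - 1L, idx[, 2] - 1L), label, dim(raster))
}

#' Read an ROI mask (raster or polygon dialect)
#'
#' Two dialects: an 8-bit PGM raster where any nonzero pixel is a member,
#' or a JSON polygon `{"label": ..., "vertices": [[x, y], ...]}` with `x`
#' along columns, `y` along rows, in pixel units where integer coordinates
#' are pixel centers. A pixel belongs to the polygon when its center lies
#' inside; points exactly on the top or left boundary are in, on the bottom
#' or right boundary out.
#'
#' @param path Mask file (`.pgm`) or polygon file (`.json`).
#' @param grid `c(rows, cols)` of the target image grid.
#' @param label ROI label; for polygon files defaults to the file's label.
#' @return A [roi_mask].
#' @export
read_roi_mask <- function(path, grid, label = NULL) {
  if (!file.exists(path)) {
    stop(format_error(paste0("no such file: ", path), "mibiquant_io_error"))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    poly <- jsonlite::read_json(path, simplifyVector = TRUE)
    verts <- poly$vertices
    if (is.list(verts)) verts <- do.call(rbind, lapply(verts, unlist))
    verts <- matrix(as.numeric(verts), ncol = 2)
    polygon_to_roi(verts, grid, label %||% poly$label)
  } else {
    raster <- read_pgm(path)
    if (!all(dim(raster) == grid)) {
      stop(format_error("mask raster does not match target grid",
                        "mibiquant_format_error"))
    }
    raster_to_roi(raster, label %||% "nodule")
  }
}

#' Write an ROI mask
#'
#' Raster dialect writes an 8-bit PGM (members = 255); polygon dialect is
#' only an input format.
#'
#' @param roi A [roi_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(roi, path) {
  m <- roi_to_raster(roi) * 255L
  nr <- nrow(m); nc <- ncol(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", nc, nr), "255"), con)
  vals <- as.integer(t(m))
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / nc)),
                    paste, character(1), collapse = " "), con)
  invisible(path)
}

# Rasterize a polygon to the pixels whose centers fall inside it.
# Even-odd ray casting; the epsilon nudge toward +x/+y makes the top/left
# boundary inclusive and the bottom/right boundary exclusive for
# axis-aligned edges.
polygon_to_roi <- function(vertices, grid, label) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  if (any(vx < -0.5 | vx > grid[2] - 0.5 | vy < -0.5 | vy > grid[1] - 0.5)) {
    stop(format_error("polygon vertex outside grid"))
  }
  rows <- max(0, floor(min(vy))):min(grid[1] - 1, ceiling(max(vy)))
  cols <- max(0, floor(min(vx))):min(grid[2] - 1, ceiling(max(vx)))
  eps <- 1e-7
  px <- rep(cols, each = length(rows)) + eps
  py <- rep(rows, times = length(cols)) + eps
  inside <- point_in_polygon(px, py, vx, vy)
  if (!any(inside)) stop(format_error("polygon encloses no pixel centers"))
  roi_mask(cbind(round(py[inside] - eps), round(px[inside] - eps)),
           label, grid)
}

# even-odd rule, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}
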
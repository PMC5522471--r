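#' Planar scintigraphy count image
#'
#' Container for a single anterior planar gamma-camera frame: an integer
#' count raster plus the acquisition metadata the quantification layer
#' needs (time post-injection, frame duration, tracer).
#'
#' @param counts Integer matrix of per-pixel counts (rows x cols, row 1 =
#'   image top). All values must be non-negative integers.
#' @param t_acq_min Minutes post tracer injection at frame start (>= 0), or
#'   `NA` when unknown; operations that need the timepoint will refuse `NA`.
#' @param frame_duration_s Frame (acquisition) duration in seconds (> 0).
#' @param tracer `"MIBI"` or `"pertechnetate"`.
#' @param injected_activity_MBq Optional injected activity in MBq (> 0).
#' @param magnification Acquisition zoom factor (> 0), default 1.
#' @param integer_counts Enforce integer-valued counts (default). Noiseless
#'   phantom frames are expected-value images and set this to `FALSE`; such
#'   images cannot be written to PGM without rounding.
#'
#' @return An object of class `planar_image` with fields `counts`,
#'   `matrix_size`, `t_acq_min`, `frame_duration_s`, `tracer`,
#'   `injected_activity_MBq`, `magnification`.
#' @export
planar_image <- function(counts, t_acq_min, frame_duration_s,
                         tracer = c("MIBI", "pertechnetate"),
                         injected_activity_MBq = NULL,
                         magnification = 1, integer_counts = TRUE) {
  tracer <- match.arg(tracer)
  if (!is.matrix(counts)) {
    stop(format_error("`counts` must be a matrix"))
  }
  storage.mode(counts) <- "double"
  img <- structure(
    list(
      counts = counts,
      matrix_size = dim(counts),
      t_acq_min = as.numeric(t_acq_min),
      frame_duration_s = as.numeric(frame_duration_s),
      tracer = tracer,
      injected_activity_MBq = if (is.null(injected_activity_MBq)) NULL else
        as.numeric(injected_activity_MBq),
      magnification = as.numeric(magnification),
      integer_counts = isTRUE(integer_counts)
    ),
    class = "planar_image"
  )
  validate_planar_image(img)
}

validate_planar_image <- function(img) {
  counts <- img$counts
  if (any(is.na(counts))) stop(format_error("counts contain NA"))
  if (any(counts < 0)) stop(format_error("counts must be non-negative"))
  if (img$integer_counts && any(counts != floor(counts))) {
    stop(format_error("counts must be integer-valued"))
  }
  if (!identical(img$matrix_size, dim(counts))) {
    stop(format_error("matrix_size does not match raster shape"))
  }
  if (!is.na(img$t_acq_min) && img$t_acq_min < 0) {
    stop(format_error("t_acq_min must be >= 0"))
  }
  if (is.na(img$frame_duration_s) || img$frame_duration_s <= 0) {
    stop(format_error("frame_duration_s must be > 0"))
  }
  if (!is.na(img$magnification) && img$magnification <= 0) {
    stop(format_error("magnification must be > 0"))
  }
  if (!is.null(img$injected_activity_MBq) &&
      img$injected_activity_MBq <= 0) {
    stop(format_error("injected_activity_MBq must be > 0"))
  }
  img
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf(
    "<planar_image> %dx%d %s, t=%s min, frame=%g s, total counts=%.0f\n",
    x$matrix_size[1], x$matrix_size[2], x$tracer,
    ifelse(is.na(x$t_acq_min), "?", format(x$t_acq_min)),
    x$frame_duration_s, sum(x$counts)
  ))
  invisible(x)
}

format_error <- function(msg, class = "mibiquant_error") {
  errorCondition(msg, class = c(class, "mibiquant_error"))
}

#' Write a planar image as portable graymap (PGM) plus JSON sidecar
#'
#' Counts are stored losslessly as 16-bit PGM pixel values; acquisition
#' metadata goes into `<path>.json`. ASCII (`P2`) is the reference dialect;
#' binary (`P5`, big-endian) is also supported.
#'
#' @param img A [planar_image].
#' @param path Output file path (conventionally `.pgm`).
#' @param ascii Write ASCII `P2` (default) rather than binary `P5`.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_planar_image <- function(img, path, ascii = TRUE, sidecar = TRUE) {
  stopifnot(inherits(img, "planar_image"))
  if (any(img$counts != floor(img$counts))) {
    stop(format_error("cannot write non-integer (expected-value) counts to PGM",
                      "mibiquant_format_error"))
  }
  maxval <- 65535L
  if (max(img$counts) > maxval) {
    stop(format_error(
      sprintf("counts exceed PGM 16-bit range (max %d)", maxval),
      "mibiquant_format_error"
    ))
  }
  nr <- nrow(img$counts); nc <- ncol(img$counts)
  # PGM is row-major from the top-left, matching the (row, col) convention
  vals <- as.integer(t(img$counts))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", nc, nr), as.character(maxval)), con)
    writeLines(vapply(split(vals, ceiling(seq_along(vals) / nc)),
                      paste, character(1), collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", nc, nr, maxval), con, eos = NULL)
    writeBin(vals, con, size = 2, endian = "big")
  }
  if (sidecar) {
    meta <- list(
      t_acq_min = img$t_acq_min,
      frame_duration_s = img$frame_duration_s,
      tracer = img$tracer,
      injected_activity_MBq = img$injected_activity_MBq,
      magnification = img$magnification
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

#' Read a planar image from PGM (with optional JSON sidecar)
#'
#' Accepts both ASCII (`P2`) and binary (`P5`) graymaps. Metadata is taken
#' from `<path>.json` when present; otherwise `t_acq_min` is `NA` and
#' `frame_duration_s` falls back to the frame time given as argument.
#'
#' @param path PGM file path.
#' @param frame_duration_s Fallback frame duration when no sidecar exists.
#' @return A [planar_image].
#' @export
read_planar_image <- function(path, frame_duration_s = NULL) {
  if (!file.exists(path)) {
    stop(format_error(paste0("no such file: ", path), "mibiquant_io_error"))
  }
  raster <- read_pgm(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  planar_image(
    counts = raster,
    t_acq_min = meta$t_acq_min %||% NA_real_,
    frame_duration_s = meta$frame_duration_s %||% frame_duration_s %||%
      stop(format_error("frame_duration_s missing: no sidecar and no fallback",
                        "mibiquant_format_error")),
    tracer = meta$tracer %||% "MIBI",
    injected_activity_MBq = meta$injected_activity_MBq,
    magnification = meta$magnification %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Low-level PGM reader: P2 (ASCII) and P5 (binary, 1- or 2-byte samples).
read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  ws <- as.raw(c(9L, 10L, 13L, 32L))
  i <- 1L
  tok <- character(0)
  # header: magic, width, height, maxval; '#' starts a comment to end-of-line
  while (length(tok) < 4L && i <= length(raw)) {
    while (i <= length(raw) && raw[i] %in% ws) i <- i + 1L
    if (i > length(raw)) break
    if (raw[i] == as.raw(35L)) {
      while (i <= length(raw) && raw[i] != as.raw(10L)) i <- i + 1L
      next
    }
    j <- i
    while (j <= length(raw) && !(raw[j] %in% ws)) j <- j + 1L
    tok <- c(tok, rawToChar(raw[i:(j - 1L)]))
    i <- j
  }
  magic <- tok[1]
  if (is.na(magic) || !magic %in% c("P2", "P5") || length(tok) < 4L) {
    stop(format_error(paste0("not a supported PGM file: ", path),
                      "mibiquant_format_error"))
  }
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  n <- nr * nc
  if (magic == "P5") {
    i <- i + 1L  # exactly one whitespace byte separates header and payload
    size <- if (maxval > 255L) 2L else 1L
    payload <- raw[i:length(raw)]
    if (length(payload) < n * size) {
      stop(format_error("PGM pixel payload truncated",
                        "mibiquant_format_error"))
    }
    vals <- readBin(payload, "integer", n, size = size, signed = FALSE,
                    endian = "big")
  } else {
    vals <- suppressWarnings(
      as.numeric(scan(text = rawToChar(raw[i:length(raw)]),
                      what = character(), quiet = TRUE, n = n))
    )
  }
  if (length(vals) != n || anyNA(vals)) {
    stop(format_error("PGM pixel payload truncated or malformed",
                      "mibiquant_format_error"))
  }
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop(format_error("negative or non-integer pixel payload",
                      "mibiquant_format_error"))
  }
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
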
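#' @importFrom utils read.csv write.csv
NULL

# ITU-R BT.601 luma weights for accidental colour input; deterministic and
# documented so grayscale conversion never depends on the decoder.
LUMA_601 <- c(0.299, 0.587, 0.114)

# read one PNG/TIFF image as a matrix of 8-bit intensities (0..255 integers)
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    rlang::abort(sprintf("Unsupported image format '%s' (expected PNG or TIFF): %s",
                         ext, path))
  )
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch >= 3L) {
      img <- img[, , 1] * LUMA_601[1] + img[, , 2] * LUMA_601[2] +
        img[, , 3] * LUMA_601[3]
    } else {
      img <- img[, , 1] # grayscale stored with an alpha / single channel
    }
  }
  round(img * 255)
}

#' Open a directory of image frames as an ordered frame source
#'
#' A frame source is the unit the tracker consumes: an ordered, lazily read
#' sequence of timestamped 8-bit grayscale frames. Frames are the
#' lexicographically sorted PNG/TIFF files in `path`. When no per-frame
#' timestamp table is present, timestamps fall back to uniform spacing
#' `timestamp_s = (index - 1) / fps_fallback` — the recording rig runs at a
#' fixed frame rate (10 fps by default) so uniform spacing is the natural
#' fallback. If `path` contains a `timestamps.csv` with columns
#' `frame,timestamp_s`, those timestamps are used instead.
#'
#' Colour images are converted to grayscale with ITU-R BT.601 luma weights.
#' All frames in a source must share dimensions; this is enforced lazily as
#' frames are read and eagerly for the first frame.
#'
#' @param path Directory containing numbered PNG or TIFF frames.
#' @param fps_fallback Positive frame rate (frames/second) used to synthesise
#'   timestamps when the source carries none. Default 10, the acquisition
#'   frame rate of the recording setup this tool targets.
#' @return An object of class `pupil_frame_source`: use `length()` for the
#'   frame count, [source_frame()] to read one frame, and
#'   [source_frames_tbl()] for the index/timestamp table.
#' @export
frame_source <- function(path, fps_fallback = 10) {
  if (!is.numeric(fps_fallback) || length(fps_fallback) != 1L || fps_fallback <= 0) {
    rlang::abort("`fps_fallback` must be a single positive number.")
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("Frame source does not exist: %s", path))
  }
  if (!dir.exists(path)) {
    rlang::abort(sprintf(
      "Frame source must be a directory of PNG/TIFF frames: %s", path))
  }
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  files <- sort(files)
  # exclude ground-truth masks if the directory is a generator output
  files <- files[!grepl("^mask_", files)]
  if (length(files) == 0L) {
    rlang::abort(sprintf("Empty frame source (no readable frames): %s", path))
  }
  ts_file <- file.path(path, "timestamps.csv")
  if (file.exists(ts_file)) {
    ts <- read.csv(ts_file)
    if (!all(c("frame", "timestamp_s") %in% names(ts)) ||
        nrow(ts) != length(files)) {
      rlang::abort(sprintf("Malformed timestamps.csv in %s", path))
    }
    timestamps <- ts$timestamp_s[order(ts$frame)]
    if (is.unsorted(timestamps)) {
      rlang::abort("Timestamps must be non-decreasing across a source.")
    }
  } else {
    timestamps <- (seq_along(files) - 1) / fps_fallback
  }
  first <- read_gray_image(file.path(path, files[1]))
  structure(
    list(dir = path, files = files, timestamps = timestamps, dim = dim(first)),
    class = "pupil_frame_source"
  )
}

#' @export
length.pupil_frame_source <- function(x) length(x$files)

#' @export
print.pupil_frame_source <- function(x, ...) {
  cat(sprintf("<pupil_frame_source> %d frames of %dx%d px from %s\n",
              length(x), x$dim[1], x$dim[2], x$dir))
  invisible(x)
}

#' Read one frame from a frame source
#'
#' @param source A `pupil_frame_source` from [frame_source()].
#' @param i Frame index, 1-based.
#' @return A list with `index` (1-based), `timestamp_s` and `pixels`
#'   (matrix of intensities in 0..255).
#' @export
source_frame <- function(source, i) {
  stopifnot(inherits(source, "pupil_frame_source"))
  if (i < 1L || i > length(source)) {
    rlang::abort(sprintf("Frame index %d out of range 1..%d", i, length(source)))
  }
  px <- read_gray_image(file.path(source$dir, source$files[i]))
  if (!identical(dim(px), source$dim)) {
    rlang::abort(sprintf(
      "Inconsistent frame dimensions in source: frame %d is %dx%d, expected %dx%d",
      i, nrow(px), ncol(px), source$dim[1], source$dim[2]))
  }
  list(index = i, timestamp_s = source$timestamps[i], pixels = px)
}

#' Frame index/timestamp table of a source
#'
#' @inheritParams source_frame
#' @return A tibble with columns `frame` (1-based index), `timestamp_s`, `file`.
#' @export
source_frames_tbl <- function(source) {
  stopifnot(inherits(source, "pupil_frame_source"))
  tibble::tibble(
    frame = seq_along(source$files),
    timestamp_s = source$timestamps,
    file = source$files
  )
}

#' Read a binary pupil mask image
#'
#' Strictly single-channel 8-bit images: a multi-channel mask file is an
#' annotation error, not something to silently collapse. Intensities above
#' 127 map to pupil (`TRUE`).
#'
#' @param path PNG or TIFF file.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Mask file does not exist: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    rlang::abort(sprintf("Unsupported mask format '%s': %s", ext, path))
  )
  if (length(dim(img)) == 3L && dim(img)[3] > 1L) {
    rlang::abort(sprintf(
      "Mask must be single-channel, got %d channels: %s", dim(img)[3], path))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 255) > 127
}

#' Write a binary pupil mask image
#'
#' @param mask Logical matrix, `TRUE` = pupil.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

pupillogram_cols <- c("frame", "timestamp_s", "centroid_x", "centroid_y",
                      "area_px", "circularity", "diameter_px", "valid")

#' Write a pupillogram CSV
#'
#' One row per frame with the measurement schema
#' `frame,timestamp_s,centroid_x,centroid_y,area_px,circularity,diameter_px,valid`.
#' `centroid_x` is the column coordinate and `centroid_y` the row coordinate
#' of the pupil centroid (1-based pixel centers). Values use '.' as decimal
#' separator and no thousands separators.
#'
#' @param records Data frame of per-frame measurements. Accepts either the
#'   CSV schema above or tracker output columns (`centroid_row`/`centroid_col`
#'   are renamed to `centroid_y`/`centroid_x`). Must be non-empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pupillogram <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    rlang::abort("`records` must be a non-empty data frame.")
  }
  df <- as.data.frame(records)
  if ("centroid_row" %in% names(df) && !"centroid_y" %in% names(df)) {
    df$centroid_y <- df$centroid_row
    df$centroid_x <- df$centroid_col
  }
  missing <- setdiff(pupillogram_cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(paste0("Missing pupillogram columns: ",
                        paste(missing, collapse = ", ")))
  }
  df <- df[, pupillogram_cols]
  df$valid <- as.logical(df$valid)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pupillogram CSV
#'
#' @param path CSV written by [write_pupillogram()].
#' @return A tibble in the pupillogram schema.
#' @export
read_pupillogram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(pupillogram_cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(paste0("Not a pupillogram CSV, missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  df$valid <- as.logical(df$valid)
  tibble::as_tibble(df)
}
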
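#' Multi-channel micrograph container
#'
#' A light container for a single imaging field: a named list of channel
#' matrices (or `height x width x z` arrays for small z-stacks) together with
#' the physical pixel size. All package coordinates are 0-based-free R
#' conventions: `(row, column)` indices into the channel matrices, with the
#' pixel size carried in metadata so that physical quantities are never
#' hard-coded downstream.
#'
#' @param channels Named list of numeric matrices (or 3D arrays) of identical
#'   spatial dimensions; typical names are `"phase"`, `"fluo"`, `"bassoon"`,
#'   `"asyn"`, `"psyn"`, `"map2"`.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @return An object of class `micrograph`.
#' @export
#' @examples
#' m <- micrograph(list(fluo = matrix(1, 8, 8)), pixel_size_um = 0.65)
#' dim(m)
micrograph <- function(channels, pixel_size_um) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a fully named list of matrices/arrays")
  }
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(lapply(dims, as.integer))) != 1) {
    abort("all channels must share the same spatial dimensions")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um),
    class = "micrograph"
  )
}

#' @export
dim.micrograph <- function(x) dim(x$channels[[1]])[1:2]

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<micrograph> %d x %d px (%.3g x %.3g um), channels: %s\n",
    d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Extract a channel from a micrograph
#'
#' @param img A [micrograph].
#' @param channel Channel name.
#' @return The channel matrix (or array for z-stacks).
#' @export
get_channel <- function(img, channel) {
  stopifnot(inherits(img, "micrograph"))
  if (!channel %in% names(img$channels)) {
    abort(sprintf(
      "channel '%s' not present (have: %s)",
      channel, paste(names(img$channels), collapse = ", ")
    ))
  }
  img$channels[[channel]]
}

#' Time-lapse stack container
#'
#' @param frames 3D numeric array `height x width x n_frames`.
#' @param pixel_size_um Pixel size, um/px.
#' @param frame_interval_s Frame interval in seconds.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, pixel_size_um, frame_interval_s) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  assert_scalar_num(frame_interval_s, "frame_interval_s", lower = 1e-9)
  structure(
    list(
      frames = frames, pixel_size_um = pixel_size_um,
      frame_interval_s = frame_interval_s
    ),
    class = "timelapse_stack"
  )
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<timelapse_stack> %d frames of %d x %d px, dt = %gs (duration %.1f min)\n",
    d[3], d[1], d[2], x$frame_interval_s, d[3] * x$frame_interval_s / 60
  ))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [timelapse_stack].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "timelapse_stack"))
  dim(stack$frames)[3]
}

#' Read / write micrographs and stacks as multi-page TIFF
#'
#' Channels (or frames) are stored as pages of a 32-bit float TIFF; metadata
#' (pixel size, channel names, frame interval) that plain TIFF tags do not
#' carry reliably is stored in a JSON sidecar `<path>.json`, which is read back
#' automatically. A `pixel_size_um` argument overrides/substitutes for missing
#' sidecar metadata.
#'
#' @param img A [micrograph] (for `write_micrograph`).
#' @param stack A [timelapse_stack] (for `write_stack`).
#' @param path TIFF file path.
#' @param pixel_size_um Optional pixel-size override when the sidecar is
#'   absent.
#' @param frame_interval_s Optional frame-interval override.
#' @return `read_micrograph` returns a [micrograph]; `read_stack` a
#'   [timelapse_stack]; the writers return `path` invisibly.
#' @name micrograph_io
NULL

#' @rdname micrograph_io
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  pages <- lapply(img$channels, function(ch) {
    if (length(dim(ch)) == 3) apply(ch, c(1, 2), max) else ch
  })
  EBImage::writeImage(EBImage::Image(simplify2array(pages)), path,
    type = "tiff", bits.per.sample = 32L
  )
  jsonlite::write_json(
    list(
      kind = "micrograph", channel_names = names(img$channels),
      pixel_size_um = img$pixel_size_um
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname micrograph_io
#' @export
read_micrograph <- function(path, pixel_size_um = NULL) {
  arr <- as.array(EBImage::readImage(path, type = "tiff"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  px <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(px)) {
    abort("pixel size unavailable: no sidecar metadata and no `pixel_size_um` override")
  }
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  nms <- unlist(meta$channel_names) %||% paste0("ch", seq_len(dim(arr)[3]))
  channels <- setNames(
    lapply(seq_len(dim(arr)[3]), function(i) arr[, , i]),
    nms
  )
  micrograph(channels, pixel_size_um = as.numeric(px))
}

#' @rdname micrograph_io
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  EBImage::writeImage(EBImage::Image(stack$frames), path,
    type = "tiff", bits.per.sample = 32L
  )
  jsonlite::write_json(
    list(
      kind = "timelapse_stack", pixel_size_um = stack$pixel_size_um,
      frame_interval_s = stack$frame_interval_s
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname micrograph_io
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  arr <- as.array(EBImage::readImage(path, type = "tiff"))
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  px <- pixel_size_um %||% meta$pixel_size_um
  dt <- frame_interval_s %||% meta$frame_interval_s
  if (is.null(px) || is.null(dt)) {
    abort("missing pixel size or frame interval: provide overrides or sidecar metadata")
  }
  timelapse_stack(arr,
    pixel_size_um = as.numeric(px),
    frame_interval_s = as.numeric(dt)
  )
}
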
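#' Otsu threshold for a numeric vector
#'
#' Histogram-based between-class variance maximisation, used both for
#' binarizing background-subtracted channels and for splitting focus
#' intensities into aSyn+/- classes.
#'
#' @param x Numeric vector.
#' @param levels Number of histogram levels.
#' @return Threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) {
    return(rng[1])
  }
  bin <- pmin(levels, 1L + floor((x - rng[1]) / diff(rng) * levels))
  h <- tabulate(bin, nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + k / levels * diff(rng)
}

# rolling-ball-style background subtraction: morphological white top-hat
# with a disc structuring element of the stated radius
subtract_background <- function(mat, radius_px) {
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  as.matrix(EBImage::whiteTopHat(mat, brush))
}

label_centroids <- function(labels) {
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(tibble::tibble(
      label = integer(), r = numeric(), c = numeric(),
      area_px = integer()
    ))
  }
  lab <- labels[idx]
  rr <- ((idx - 1) %% nrow(labels)) + 1
  cc <- ((idx - 1) %/% nrow(labels)) + 1
  tibble::tibble(
    label = as.integer(names(tapply(rr, lab, mean))),
    r = as.numeric(tapply(rr, lab, mean)),
    c = as.numeric(tapply(cc, lab, mean)),
    area_px = as.integer(tapply(rr, lab, length))
  )
}

#' Detect neuronal somas from the phase channel
#'
#' Classical segmentation pipeline standing in for interactive/learned soma
#' detection: Gaussian smoothing, Otsu binarization of the inverted phase
#' image (soma bodies are phase-dark), hole filling, size filtering, and
#' distance-transform watershed declumping of components too large to be a
#' single soma. Returns disjoint soma ROIs.
#'
#' @param img A [micrograph] with a `phase` channel.
#' @param sigma_px Gaussian smoothing sigma (px).
#' @param area_um2 Plausible soma area range in um^2; components outside are
#'   discarded, components above the upper bound are first declumped.
#' @param min_contrast_mads Guard against segmenting pure noise: the mean
#'   foreground/background separation must exceed this many MADs of the image.
#' @return A `soma_rois` object: tibble with `soma_id`, centroid `r`, `c`,
#'   `area_px`, `area_um2`; the label image and pixel size are carried as
#'   attributes `"labels"` and `"pixel_size_um"`.
#' @export
detect_somas <- function(img, sigma_px = 1.5, area_um2 = c(25, 250),
                         min_contrast_mads = 3) {
  stopifnot(inherits(img, "micrograph"))
  phase <- get_channel(img, "phase")
  px <- img$pixel_size_um
  sm <- as.matrix(EBImage::gblur(phase, sigma = sigma_px))
  inv <- max(sm) - sm
  th <- otsu_threshold(inv)
  mask <- inv > th
  # noise guard: real somas separate from background by far more than noise
  spread <- mad(inv)
  if (!any(mask) || all(mask) ||
    (mean(inv[mask]) - mean(inv[!mask])) < min_contrast_mads * spread) {
    return(empty_soma_rois(px, dim(phase)))
  }
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::bwlabel(mask)
  area_px_rng <- area_um2 / px^2
  areas <- tabulate(labels[labels > 0])
  # declump oversized components with a distance-transform watershed
  big <- which(areas > area_px_rng[2])
  if (length(big)) {
    keep <- labels
    keep[labels %in% big] <- 0L
    clump_mask <- matrix(labels %in% big, nrow(labels), ncol(labels))
    dm <- EBImage::distmap(clump_mask)
    ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    ws <- as.matrix(ws)
    ws[ws > 0] <- ws[ws > 0] + max(keep)
    labels <- keep + ws
  }
  cent <- label_centroids(labels)
  cent <- cent[cent$area_px >= area_px_rng[1] & cent$area_px <= area_px_rng[2], ]
  # relabel compactly via a lookup table
  map <- integer(max(labels) + 1L)
  map[cent$label + 1L] <- seq_len(nrow(cent))
  relab <- matrix(map[labels + 1L], nrow(labels))
  out <- tibble::tibble(
    soma_id = seq_len(nrow(cent)),
    r = cent$r, c = cent$c,
    area_px = cent$area_px,
    area_um2 = cent$area_px * px^2
  )
  structure(out,
    labels = relab, pixel_size_um = px,
    class = c("soma_rois", class(out))
  )
}

empty_soma_rois <- function(px, dims) {
  out <- tibble::tibble(
    soma_id = integer(), r = numeric(), c = numeric(),
    area_px = integer(), area_um2 = numeric()
  )
  structure(out,
    labels = matrix(0L, dims[1], dims[2]), pixel_size_um = px,
    class = c("soma_rois", class(out))
  )
}

#' Dilate a neurite trace into a corridor ROI
#'
#' The polyline is rasterized and dilated to the stated physical width
#' (3 um for dendrite synaptic scoring, 1 um for axonal fluorescence); the
#' trace's arc length (in um) is recorded as the neurite length.
#'
#' @param polyline Numeric matrix with columns `(r, c)` in pixel coordinates,
#'   at least two points.
#' @param width_um Corridor width (um).
#' @param pixel_size_um Pixel size (um/px).
#' @param dim_px Image dimensions `(rows, cols)` for the corridor mask.
#' @return A `trace_roi`: list with `mask` (logical matrix), `polyline`,
#'   `width_um`, `length_um`, `pixel_size_um`.
#' @export
dilate_trace <- function(polyline, width_um = 3.0, pixel_size_um, dim_px) {
  if (!is.matrix(polyline) || nrow(polyline) < 2) {
    abort("degenerate trace: need a polyline with at least 2 points")
  }
  assert_scalar_num(width_um, "width_um", lower = 1e-9)
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  dense <- resample_polyline(polyline, step = 0.5)
  # corridor = all pixels within width/2 of the trace: stamp discs of the
  # physical radius along the densely resampled polyline
  radius_px <- max(0.5, width_um / 2 / pixel_size_um)
  nr <- dim_px[1]
  nc <- dim_px[2]
  mask <- matrix(FALSE, nr, nc)
  for (j in seq_len(nrow(dense$points))) {
    r0 <- dense$points[j, 1]
    c0 <- dense$points[j, 2]
    rr <- max(1L, floor(r0 - radius_px)):min(nr, ceiling(r0 + radius_px))
    cc <- max(1L, floor(c0 - radius_px)):min(nc, ceiling(c0 + radius_px))
    sel <- which(outer((rr - r0)^2, (cc - c0)^2, "+") <= radius_px^2)
    if (length(sel)) {
      ri <- (sel - 1L) %% length(rr) + 1L
      ci <- (sel - 1L) %/% length(rr) + 1L
      mask[cbind(rr[ri], cc[ci])] <- TRUE
    }
  }
  structure(
    list(
      mask = mask, polyline = polyline, width_um = width_um,
      length_um = dense$length_px * pixel_size_um,
      pixel_size_um = pixel_size_um
    ),
    class = "trace_roi"
  )
}

#' Segment synaptic foci within a trace corridor
#'
#' The marker channel is background-subtracted with a rolling-ball-style
#' top-hat of the stated radius, binarized by Otsu on the corridor pixels, and
#' connected components restricted to the corridor are kept when larger than
#' one pixel.
#'
#' @param img A [micrograph] with the marker channel.
#' @param trace A [dilate_trace()] corridor.
#' @param channel Marker channel name.
#' @param bg_radius_px Background-subtraction radius (default 5 px, the value
#'   used for Bassoon staining).
#' @param min_area_px Minimum focus area in px; the default 2 keeps particles
#'   larger than 1 pixel.
#' @param threshold Optional fixed binarization threshold (a.u. of the
#'   background-subtracted channel); default Otsu on corridor pixels.
#' @return A `foci_set`: tibble with `focus_id`, centroid, `area_px`,
#'   `marker_mean`; label image, trace and parameters as attributes.
#' @export
segment_foci <- function(img, trace, channel = "bassoon", bg_radius_px = 5,
                         min_area_px = 2, threshold = NULL) {
  stopifnot(inherits(img, "micrograph"), inherits(trace, "trace_roi"))
  ch <- get_channel(img, channel)
  if (!all(dim(trace$mask) == dim(ch))) {
    abort("trace corridor does not match image dimensions")
  }
  sub <- subtract_background(ch, bg_radius_px)
  vals <- sub[trace$mask]
  th <- threshold %||% otsu_threshold(vals)
  bw <- sub > th & trace$mask
  labels <- EBImage::bwlabel(bw)
  cent <- label_centroids(labels)
  cent <- cent[cent$area_px >= min_area_px, ]
  map <- integer(max(labels, 1L) + 1L)
  map[cent$label + 1L] <- seq_len(nrow(cent))
  relab <- matrix(map[labels + 1L], nrow(labels))
  idx <- which(relab > 0)
  means <- numeric(nrow(cent))
  if (length(idx)) {
    m <- tapply(sub[idx], relab[idx], mean)
    means[as.integer(names(m))] <- as.numeric(m)
  }
  out <- tibble::tibble(
    focus_id = seq_len(nrow(cent)),
    r = cent$r, c = cent$c, area_px = cent$area_px,
    marker_mean = means
  )
  structure(out,
    labels = relab, trace = trace,
    params = list(
      channel = channel, bg_radius_px = bg_radius_px,
      min_area_px = min_area_px, threshold = th
    ),
    class = c("foci_set", class(out))
  )
}

#' Classify foci as aSyn-positive or aSyn-negative
#'
#' Each focus's mean intensity in the background-subtracted aSyn channel
#' (20 px top-hat radius by default) is compared with a threshold. The rule is
#' explicit and recorded in the output metadata: either Otsu on the focus mean
#' intensities (default) or a fixed user value. A warning is raised when the
#' intensities do not separate into two classes (degenerate one-class input).
#'
#' @param foci A `foci_set` from [segment_foci()].
#' @param img A [micrograph] with the aSyn channel.
#' @param channel aSyn channel name.
#' @param bg_radius_px Background-subtraction radius (default 20 px).
#' @param threshold_rule `"otsu"` or a fixed numeric threshold.
#' @return The `foci_set` with added `asyn_mean` and `asyn_pos` columns;
#'   attribute `"asyn_threshold"` records the rule and value used.
#' @export
classify_foci <- function(foci, img, channel = "asyn", bg_radius_px = 20,
                          threshold_rule = "otsu") {
  stopifnot(inherits(foci, "foci_set"), inherits(img, "micrograph"))
  labels <- attr(foci, "labels")
  ch <- get_channel(img, channel)
  sub <- subtract_background(ch, bg_radius_px)
  idx <- which(labels > 0)
  means <- numeric(nrow(foci))
  if (length(idx)) {
    m <- tapply(sub[idx], labels[idx], mean)
    means[as.integer(names(m))] <- as.numeric(m)
  }
  if (is.numeric(threshold_rule)) {
    th <- threshold_rule
    rule <- "fixed"
  } else if (identical(threshold_rule, "otsu")) {
    th <- otsu_threshold(means)
    rule <- "otsu"
    # a data-driven threshold is only meaningful on bimodal intensities
    if (length(means) >= 10 &&
      dip_test(means, B = 100, seed = 1)$p_value > 0.05) {
      warn(paste(
        "focus aSyn intensities do not separate into two classes;",
        "a data-driven threshold on one-class input is degenerate"
      ))
    }
  } else {
    abort("`threshold_rule` must be \"otsu\" or a numeric threshold")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(foci),
    asyn_mean = means,
    asyn_pos = means > th
  )
  structure(out,
    labels = labels, trace = attr(foci, "trace"),
    params = attr(foci, "params"),
    asyn_threshold = list(rule = rule, value = th, channel = channel),
    class = c("foci_set", class(out))
  )
}

#' @importFrom stats mad
NULL
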
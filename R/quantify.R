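#' Mean aggregate-associated fluorescence per soma
#'
#' Measures the mean fluorescence inside each soma ROI, in acquisition units.
#' When the channel is a small z-stack (3D array), a maximum-intensity
#' projection is taken first, matching the acquisition protocol of five z
#' frames analysed on their maximum projection.
#'
#' @param img A [micrograph].
#' @param rois A `soma_rois` object from [detect_somas()] (or with the same
#'   label-image attribute).
#' @param channel Fluorescence channel name.
#' @return Tibble with `soma_id` and `mean_fluo`.
#' @export
soma_fluorescence <- function(img, rois, channel = "fluo") {
  stopifnot(inherits(img, "micrograph"), inherits(rois, "soma_rois"))
  ch <- get_channel(img, channel)
  if (length(dim(ch)) == 3) ch <- apply(ch, c(1, 2), max)
  labels <- attr(rois, "labels")
  if (!all(dim(labels) == dim(ch))) {
    abort("ROI label image does not match the fluorescence channel dimensions")
  }
  means <- rep(NA_real_, nrow(rois))
  idx <- which(labels > 0)
  if (length(idx)) {
    m <- tapply(ch[idx], labels[idx], mean)
    means[as.integer(names(m))] <- as.numeric(m)
  }
  tibble::tibble(soma_id = rois$soma_id, mean_fluo = means)
}

#' Mean fluorescence along axon tracts
#'
#' Measures the mean signal in a corridor of stated physical width (1 um by
#' default) around each manually traced or synthetic axonal tract.
#'
#' @param img A [micrograph].
#' @param traces List of polylines (matrices with columns `(r, c)`).
#' @param width_um Corridor width (um).
#' @param channel Fluorescence channel name.
#' @return Tibble with `axon_id`, `mean_fluo`, `length_um`.
#' @export
axon_fluorescence <- function(img, traces, width_um = 1.0, channel = "fluo") {
  stopifnot(inherits(img, "micrograph"))
  ch <- get_channel(img, channel)
  if (length(dim(ch)) == 3) ch <- apply(ch, c(1, 2), max)
  purrr::imap_dfr(traces, function(poly, i) {
    roi <- dilate_trace(poly,
      width_um = width_um,
      pixel_size_um = img$pixel_size_um, dim_px = dim(ch)
    )
    tibble::tibble(
      axon_id = as.integer(i),
      mean_fluo = mean(ch[roi$mask]),
      length_um = roi$length_um
    )
  })
}

#' Normalize device raw means by same-session untreated controls
#'
#' Each device's raw mean fluorescence is divided by the mean of the raw means
#' of untreated (`ctrl`) devices imaged in the same microscopy session, per
#' compartment, so the control level maps to 1 and gain changes between
#' sessions cancel. The control mean is computed over control devices
#' (device-level pooling).
#'
#' @param raw Tibble with at least `device_id`, `session_id`, `condition`,
#'   `compartment`, `raw_mean`.
#' @param control_condition Label identifying control devices.
#' @return The input tibble with a `normalized` column added.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   device_id = c("a", "b", "c"), session_id = "s1",
#'   condition = c("ctrl", "ctrl", "hFib"), compartment = "postsyn",
#'   raw_mean = c(10, 10, 11)
#' )
#' normalize_session(raw)$normalized
normalize_session <- function(raw, control_condition = "ctrl") {
  needed <- c("device_id", "session_id", "condition", "compartment", "raw_mean")
  if (!all(needed %in% names(raw))) {
    abort(paste(
      "`raw` must have columns:",
      paste(needed, collapse = ", ")
    ))
  }
  ctrl_means <- raw |>
    dplyr::filter(.data$condition == control_condition) |>
    dplyr::group_by(.data$session_id, .data$compartment) |>
    dplyr::summarise(ctrl_mean = mean(.data$raw_mean), .groups = "drop")
  missing <- raw |>
    dplyr::distinct(.data$session_id, .data$compartment) |>
    dplyr::anti_join(ctrl_means, by = c("session_id", "compartment"))
  if (nrow(missing)) {
    abort(sprintf(
      "no control devices for session(s): %s",
      paste(unique(missing$session_id), collapse = ", ")
    ))
  }
  raw |>
    dplyr::left_join(ctrl_means, by = c("session_id", "compartment")) |>
    dplyr::mutate(normalized = .data$raw_mean / .data$ctrl_mean) |>
    dplyr::select(-"ctrl_mean")
}

#' Device-level quality control
#'
#' Applies the study's inclusion minima, closed at the stated bounds: soma
#' devices need at least 40 somas from at least 4 separate fields; axon
#' devices at least 10 axons; synapse devices at least 650 um of dendrite from
#' at least 4 fields. Failing devices are flagged with explicit reasons, never
#' silently dropped.
#'
#' @param signals Tibble with `n_units` and `n_fields` (and `dendrite_um` for
#'   `kind = "synapse"`).
#' @param kind `"soma"`, `"axon"`, or `"synapse"`.
#' @param min_somas,min_fields,min_axons,min_dendrite_um QC thresholds.
#' @return The tibble with `qc_pass` (logical) and `qc_reasons` (character,
#'   empty when passing) columns added.
#' @export
qc_device <- function(signals, kind = c("soma", "axon", "synapse"),
                      min_somas = 40, min_fields = 4, min_axons = 10,
                      min_dendrite_um = 650) {
  kind <- match.arg(kind)
  reasons_for <- function(n_units, n_fields, dendrite_um) {
    r <- character(0)
    if (kind == "soma") {
      if (n_units < min_somas) r <- c(r, sprintf("somas %d < %d", n_units, min_somas))
      if (n_fields < min_fields) r <- c(r, sprintf("fields %d < %d", n_fields, min_fields))
    } else if (kind == "axon") {
      if (n_units < min_axons) r <- c(r, sprintf("axons %d < %d", n_units, min_axons))
    } else {
      if (dendrite_um < min_dendrite_um) {
        r <- c(r, sprintf("dendrite %.0f um < %.0f um", dendrite_um, min_dendrite_um))
      }
      if (n_fields < min_fields) r <- c(r, sprintf("fields %d < %d", n_fields, min_fields))
    }
    paste(r, collapse = "; ")
  }
  n_units <- signals[["n_units"]] %||% rep(NA_integer_, nrow(signals))
  n_fields <- signals[["n_fields"]] %||% rep(NA_integer_, nrow(signals))
  dendrite <- signals[["dendrite_um"]] %||% rep(NA_real_, nrow(signals))
  reasons <- vapply(
    seq_len(nrow(signals)),
    function(i) reasons_for(n_units[i], n_fields[i], dendrite[i]),
    character(1)
  )
  dplyr::mutate(signals, qc_pass = reasons == "", qc_reasons = reasons)
}

#' Synaptic density along a dendrite trace
#'
#' Number of synaptic foci -- and of aSyn-positive foci when the set has been
#' classified -- per micrometre of dendrite.
#'
#' @param foci A `foci_set`.
#' @param trace The corridor [dilate_trace()] the foci were segmented in;
#'   defaults to the trace recorded in `foci`.
#' @return One-row tibble: `n_foci`, `foci_per_um`, `asyn_pos_per_um` (NA if
#'   unclassified), `dendrite_um`.
#' @export
synapse_density <- function(foci, trace = NULL) {
  stopifnot(inherits(foci, "foci_set"))
  trace <- trace %||% attr(foci, "trace")
  if (is.null(trace) || trace$length_um <= 0) {
    abort("zero-length or missing dendrite trace")
  }
  n <- nrow(foci)
  pos <- if ("asyn_pos" %in% names(foci)) sum(foci$asyn_pos) else NA_integer_
  tibble::tibble(
    n_foci = n,
    foci_per_um = n / trace$length_um,
    asyn_pos_per_um = pos / trace$length_um,
    dendrite_um = trace$length_um
  )
}

#' pSyn / MAP2 integrated-density ratio
#'
#' Ratio of integrated pSyn signal to integrated MAP2 signal over a whole
#' compartment field, optionally normalized by the mean ratio of untreated
#' control fields.
#'
#' @param psyn,map2 Matrices, or a [micrograph] with `psyn` and `map2`
#'   channels passed as `psyn` (then `map2` is ignored).
#' @param control_ratios Optional numeric vector of control raw ratios; when
#'   supplied the score is normalized so controls average 1.
#' @return One-row tibble: `psyn_sum`, `map2_sum`, `ratio`, `score`
#'   (normalized ratio, or raw ratio when no controls given).
#' @export
psyn_ratio <- function(psyn, map2 = NULL, control_ratios = NULL) {
  if (inherits(psyn, "micrograph")) {
    map2 <- get_channel(psyn, "map2")
    psyn <- get_channel(psyn, "psyn")
  }
  s_psyn <- sum(psyn)
  s_map2 <- sum(map2)
  if (s_map2 == 0) abort("zero MAP2 integral: cannot form pSyn/MAP2 ratio")
  ratio <- s_psyn / s_map2
  score <- if (is.null(control_ratios)) ratio else ratio / mean(control_ratios)
  tibble::tibble(
    psyn_sum = s_psyn, map2_sum = s_map2,
    ratio = ratio, score = score
  )
}

# bilinear sampling of a matrix at fractional (r, c)
bilinear_sample <- function(mat, r, c) {
  r <- pmin(pmax(r, 1), nrow(mat))
  c <- pmin(pmax(c, 1), ncol(mat))
  r0 <- floor(r)
  c0 <- floor(c)
  r1 <- pmin(r0 + 1, nrow(mat))
  c1 <- pmin(c0 + 1, ncol(mat))
  fr <- r - r0
  fc <- c - c0
  mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r1, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c1)] * (1 - fr) * fc +
    mat[cbind(r1, c1)] * fr * fc
}

#' Count fluorescent fibres crossing a microchannel exit line
#'
#' Samples the fibre channel along the exit line, thresholds it robustly above
#' background, and counts distinct above-threshold runs, merging crossings
#' closer than one soma radius (fasciculated fibres).
#'
#' @param img A [micrograph].
#' @param exit_line Either a single column index (vertical line) or a polyline
#'   matrix `(r, c)`.
#' @param direction `"forward"` or `"backward"`; recorded in the output.
#' @param channel Fibre channel.
#' @param merge_um Crossings closer than this are merged (default 5 um, about
#'   one soma radius).
#' @param threshold_mads Robust threshold: background median plus this many
#'   MADs.
#' @return One-row tibble: `direction`, `n_crossings`.
#' @export
count_crossings <- function(img, exit_line, direction = c("forward", "backward"),
                            channel = "fluo", merge_um = 5, threshold_mads = 6) {
  stopifnot(inherits(img, "micrograph"))
  direction <- match.arg(direction)
  ch <- get_channel(img, channel)
  if (length(exit_line) == 1) {
    pts <- cbind(r = seq_len(nrow(ch)), c = rep(exit_line, nrow(ch)))
  } else {
    pts <- resample_polyline(exit_line, step = 1)$points
  }
  prof <- bilinear_sample(ch, pts[, 1], pts[, 2])
  th <- median(prof) + threshold_mads * max(mad(prof), 1e-9)
  above <- prof > th
  merge_px <- max(1L, round(merge_um / img$pixel_size_um))
  # merge short below-threshold gaps, then count runs
  r <- rle(above)
  gap <- which(!r$values & r$lengths <= merge_px)
  gap <- setdiff(gap, c(1, length(r$values)))
  r$values[gap] <- TRUE
  r <- rle(inverse.rle(r))
  tibble::tibble(
    direction = direction,
    n_crossings = sum(r$values)
  )
}

#' Distribution of per-soma signal with a unimodality diagnostic
#'
#' Draws a seeded sample without replacement of `n_sample` somas, bins it into
#' a fixed number of bins, and reports a dip-type unimodality statistic with a
#' Monte-Carlo p-value (see [dip_test()]).
#'
#' @param values Numeric vector of per-soma signals.
#' @param n_sample Sample size (default 500 somas).
#' @param bins Number of histogram bins (default 100).
#' @param seed Integer seed for the sampling.
#' @param allow_smaller Permit fewer than `n_sample` values (uses all of
#'   them).
#' @param dip_B Monte-Carlo replicates for the dip null.
#' @return A `signal_histogram` object: list with `histogram` tibble
#'   (`mid`, `count`), `sample`, `dip`, `p_value`, `n`, `bins`.
#' @export
signal_histogram <- function(values, n_sample = 500, bins = 100, seed = 1,
                             allow_smaller = FALSE, dip_B = 200) {
  values <- values[is.finite(values)]
  if (length(values) < n_sample && !allow_smaller) {
    abort(sprintf(
      "only %d values for a %d-soma sample; set allow_smaller = TRUE to use all",
      length(values), n_sample
    ))
  }
  n <- min(n_sample, length(values))
  smp <- with_seed(
    substream_seed(seed, "signal_histogram"),
    values[sample.int(length(values), n)]
  )
  breaks <- seq(min(smp), max(smp), length.out = bins + 1)
  if (diff(range(smp)) == 0) breaks <- c(smp[1] - 0.5, smp[1] + 0.5)
  h <- graphics::hist(smp, breaks = breaks, plot = FALSE)
  dt <- dip_test(smp, B = dip_B, seed = substream_seed(seed, "dip_null"))
  structure(
    list(
      histogram = tibble::tibble(mid = h$mids, count = h$counts),
      sample = smp, dip = dt$statistic, p_value = dt$p_value,
      n = n, bins = length(h$mids)
    ),
    class = "signal_histogram"
  )
}

#' @export
print.signal_histogram <- function(x, ...) {
  cat(sprintf(
    "<signal_histogram> n = %d, %d bins, dip = %.4f (MC p = %.3f)\n",
    x$n, x$bins, x$dip, x$p_value
  ))
  invisible(x)
}
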
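#' Build a kymograph from a time-lapse stack
#'
#' Each frame contributes one row: at every arc-length position of the
#' microchannel ROI, the maximum intensity across the ROI's 3-pixel transverse
#' width is taken, producing a time x position image where stationary
#' particles are vertical lines and moving particles sloped lines.
#'
#' @param stack A [timelapse_stack].
#' @param channel_roi Polyline matrix `(r, c)` along the channel; `NULL` uses
#'   the horizontal midline of the field.
#' @param width_px Transverse width sampled around the ROI (default 3).
#' @return A `kymograph`: list with `image` (frames x positions matrix),
#'   `frame_interval_s`, `pixel_size_um`, `roi`.
#' @export
build_kymograph <- function(stack, channel_roi = NULL, width_px = 3) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$frames)
  if (is.null(channel_roi)) {
    channel_roi <- cbind(r = rep(ceiling(d[1] / 2), 2), c = c(1, d[2]))
  }
  if (any(channel_roi[, 1] < 1 | channel_roi[, 1] > d[1] |
    channel_roi[, 2] < 1 | channel_roi[, 2] > d[2])) {
    abort("channel ROI exits the frame bounds")
  }
  dense <- resample_polyline(channel_roi, step = 1)
  pts <- dense$points
  # unit normals to the polyline for transverse sampling
  dif <- rbind(pts[2, ] - pts[1, ], diff(pts))
  len <- sqrt(rowSums(dif^2))
  nrm <- cbind(-dif[, 2], dif[, 1]) / pmax(len, 1e-9)
  offsets <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)
  n_pos <- nrow(pts)
  img <- matrix(0, d[3], n_pos)
  for (t in seq_len(d[3])) {
    frame <- stack$frames[, , t]
    acc <- matrix(-Inf, n_pos, length(offsets))
    for (j in seq_along(offsets)) {
      rr <- pts[, 1] + offsets[j] * nrm[, 1]
      cc <- pts[, 2] + offsets[j] * nrm[, 2]
      acc[, j] <- bilinear_sample(frame, rr, cc)
    }
    img[t, ] <- apply(acc, 1, max)
  }
  structure(
    list(
      image = img, frame_interval_s = stack$frame_interval_s,
      pixel_size_um = stack$pixel_size_um, roi = channel_roi
    ),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d frames x %d positions, dt = %gs, px = %g um\n",
    nrow(x$image), ncol(x$image), x$frame_interval_s, x$pixel_size_um
  ))
  invisible(x)
}

# detect intensity peaks in one kymograph row; returns centroid positions
row_peaks <- function(row, threshold) {
  above <- row > threshold
  if (!any(above)) {
    return(numeric(0))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  vapply(keep, function(k) {
    i <- starts[k]:ends[k]
    sum(i * row[i]) / sum(row[i])
  }, numeric(1))
}

#' Detect particle tracks on a kymograph
#'
#' Automates manual path tracing: per-frame intensity peaks are linked across
#' frames by nearest-neighbour assignment with constant-velocity prediction
#' and bounded gap bridging. Tracks with sufficient support are classified as
#' moving when their net displacement reaches `moving_min_px`, and their
#' pause-ignoring speed is computed from the sloped segments only: runs of
#' per-frame displacement below `pause_step_px` lasting at least
#' `pause_min_frames` frames are excised before the slope estimate.
#'
#' @param kymo A [build_kymograph()] result.
#' @param min_frames Minimum frames of support per track.
#' @param gate_px Maximum distance between a prediction and a matched peak.
#' @param max_gap Frames a track may go undetected before being closed.
#' @param threshold Peak threshold; default median + 6 MAD of the kymograph.
#' @param moving_min_px Net displacement (px) separating moving from
#'   stationary particles.
#' @param pause_step_px,pause_min_frames Pause-excision rule.
#' @return Tibble with one row per track: `track_id`, `n_points`,
#'   `net_disp_px`, `moving`, `speed_um_s` (pause-ignoring), `direction`, and
#'   the `(frame, pos_px)` points as a list-column.
#' @export
detect_tracks <- function(kymo, min_frames = 5, gate_px = 16, max_gap = 2,
                          threshold = NULL, moving_min_px = 3,
                          pause_step_px = 0.5, pause_min_frames = 2) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$image
  th <- threshold %||% (median(img) + 6 * max(mad(img), 1e-9))
  n_fr <- nrow(img)
  # Pass 1 - stationary particles are time-persistent vertical lines: find
  # positions occupied by a peak in at least half of the frames, claim their
  # peaks, and link only the remaining (moving) peaks in pass 2. This keeps
  # a passing particle from stealing a stationary track's identity.
  frame_peaks <- lapply(seq_len(n_fr), function(t) row_peaks(img[t, ], th))
  all_pos <- unlist(frame_peaks)
  stationary_tracks <- list()
  claimed_stationary <- vector("list", n_fr)
  if (length(all_pos)) {
    occ <- vapply(seq_len(ncol(img)), function(col) {
      sum(vapply(frame_peaks, function(p) any(abs(p - col) <= 1.5), logical(1)))
    }, numeric(1))
    stat_cols <- which(occ >= 0.5 * n_fr)
    if (length(stat_cols)) {
      groups <- cumsum(c(1, diff(stat_cols) > 3))
      for (g in unique(groups)) {
        centre <- mean(stat_cols[groups == g])
        pos <- numeric(0)
        frames <- integer(0)
        for (t in seq_len(n_fr)) {
          p <- frame_peaks[[t]]
          # claim generously: a blob merged with a passing particle belongs
          # to the stationary line; the passer coasts through on prediction
          j <- which(abs(p - centre) <= 5)
          if (length(j)) {
            j <- j[which.min(abs(p[j] - centre))]
            pos <- c(pos, p[j])
            frames <- c(frames, t)
            claimed_stationary[[t]] <- c(claimed_stationary[[t]], j)
          }
        }
        if (length(pos) >= min_frames) {
          stationary_tracks <- c(stationary_tracks, list(list(
            pos = pos,
            frame = frames
          )))
        }
      }
    }
  }
  # robust velocity estimate: median of the last few per-step slopes, so a
  # single position polluted by a passing particle cannot derail a track
  tail_vel <- function(tr, window = 7) {
    n <- length(tr$pos)
    if (n < 2) {
      return(0)
    }
    i <- max(1, n - window + 1)
    median(diff(tr$pos[i:n]) / diff(tr$frame[i:n]))
  }
  active <- list()
  done <- list()
  for (t in seq_len(n_fr)) {
    peaks <- frame_peaks[[t]]
    if (length(claimed_stationary[[t]])) {
      peaks <- peaks[-claimed_stationary[[t]]]
    }
    claimed <- rep(FALSE, length(peaks))
    used <- rep(FALSE, length(active))
    if (length(active) && length(peaks)) {
      preds <- vapply(active, function(tr) {
        tr$pos[length(tr$pos)] + tail_vel(tr) * (t - tr$frame[length(tr$frame)])
      }, numeric(1))
      # globally greedy assignment: smallest prediction error first
      d <- abs(outer(preds, peaks, "-"))
      cand <- which(d <= gate_px, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          a <- cand[k, 1]
          j <- cand[k, 2]
          if (used[a] || claimed[j]) next
          used[a] <- TRUE
          claimed[j] <- TRUE
          tr <- active[[a]]
          tr$pos <- c(tr$pos, peaks[j])
          tr$frame <- c(tr$frame, t)
          tr$coasts <- 0
          active[[a]] <- tr
        }
      }
    }
    # unmatched tracks whose prediction still lies on bright signal coast
    # through the crossing at their predicted position (bounded run), so a
    # particle passing another neither terminates nor pollutes its track
    if (length(active)) {
      for (a in which(!used)) {
        tr <- active[[a]]
        coasts <- tr$coasts %||% 0
        if (coasts >= max_gap) next
        pred <- tr$pos[length(tr$pos)] +
          tail_vel(tr) * (t - tr$frame[length(tr$frame)])
        pc <- round(pred)
        if (pc >= 1 && pc <= ncol(img) && img[t, pc] > th) {
          tr$pos <- c(tr$pos, pred)
          tr$frame <- c(tr$frame, t)
          tr$coasts <- coasts + 1
          active[[a]] <- tr
          used[a] <- TRUE
        }
      }
    }
    if (length(active)) {
      stale <- vapply(active, function(tr) {
        t - tr$frame[length(tr$frame)] > max_gap
      }, logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    for (j in which(!claimed)) {
      active <- c(active, list(list(pos = peaks[j], frame = t)))
    }
  }
  done <- c(done, active)
  # merge collinear fragments: a later fragment whose start matches the
  # extrapolation of an earlier fragment belongs to the same particle
  if (length(done) > 1) {
    done <- done[order(vapply(done, function(tr) tr$frame[1], numeric(1)))]
    merged <- TRUE
    while (merged) {
      merged <- FALSE
      for (a in seq_along(done)) {
        if (is.null(done[[a]])) next
        tra <- done[[a]]
        for (b in seq_along(done)) {
          if (a == b || is.null(done[[b]])) next
          trb <- done[[b]]
          gap <- trb$frame[1] - tra$frame[length(tra$frame)]
          if (gap < 0 || gap > 10) next
          last_pos <- tra$pos[length(tra$pos)]
          pred_fwd <- last_pos + tail_vel(tra) * gap
          head_vel <- {
            n <- length(trb$pos)
            i <- min(n, 5)
            if (n < 2) 0 else (trb$pos[i] - trb$pos[1]) / (trb$frame[i] - trb$frame[1])
          }
          pred_bwd <- trb$pos[1] - head_vel * gap
          ok <- abs(pred_fwd - trb$pos[1]) <= 8 ||
            abs(pred_bwd - last_pos) <= 8 ||
            # a particle pausing through the break: positional continuity
            abs(trb$pos[1] - last_pos) <= 8
          if (ok) {
            drop1 <- as.integer(gap == 0) # duplicate frame at a zero gap
            done[[a]] <- list(
              pos = c(tra$pos, trb$pos[(1 + drop1):length(trb$pos)]),
              frame = c(tra$frame, trb$frame[(1 + drop1):length(trb$frame)])
            )
            done[b] <- list(NULL)
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    done <- done[!vapply(done, is.null, logical(1))]
  }
  done <- done[vapply(done, function(tr) length(tr$pos) >= min_frames, logical(1))]
  done <- c(stationary_tracks, done)
  if (!length(done)) {
    return(tibble::tibble(
      track_id = integer(), n_points = integer(),
      net_disp_px = numeric(), moving = logical(),
      speed_um_s = numeric(), direction = character(),
      points = list()
    ))
  }
  purrr::imap_dfr(done, function(tr, i) {
    # net displacement between trimmed-median endpoints of the smoothed
    # positions: robust to transient centroid pulls at particle crossings
    sm <- if (length(tr$pos) >= 5) {
      stats::runmed(tr$pos, 5, endrule = "median")
    } else {
      tr$pos
    }
    w <- max(1, min(10, floor(length(sm) / 3)))
    net <- median(tail(sm, w)) - median(head(sm, w))
    moving <- abs(net) >= moving_min_px
    speed <- track_speed(
      tr$frame, tr$pos, kymo$pixel_size_um,
      kymo$frame_interval_s, pause_step_px, pause_min_frames
    )
    tibble::tibble(
      track_id = as.integer(i),
      n_points = length(tr$pos),
      net_disp_px = net,
      moving = moving,
      speed_um_s = speed,
      direction = if (net >= 0) "anterograde" else "retrograde",
      points = list(cbind(frame = tr$frame, pos_px = tr$pos))
    )
  })
}

# pause-ignoring speed: per-frame displacements, with sub-threshold runs of
# at least `pause_min_frames` removed before averaging
track_speed <- function(frames, pos, pixel_size_um, frame_interval_s,
                        pause_step_px = 0.5, pause_min_frames = 2) {
  if (length(pos) < 2) {
    return(0)
  }
  step <- diff(pos) / diff(frames)
  slow <- abs(step) < pause_step_px
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  excise <- rep(FALSE, length(step))
  # a run of k sub-threshold steps spans k + 1 frames
  for (k in which(r$values & (r$lengths + 1) >= pause_min_frames)) {
    excise[starts[k]:ends[k]] <- TRUE
  }
  kept <- step[!excise]
  if (!length(kept)) {
    return(0)
  }
  abs(mean(kept)) * pixel_size_um / frame_interval_s
}

#' Fraction of moving particles
#'
#' @param tracks Track tibble from [detect_tracks()].
#' @return Moving fraction in `[0, 1]`.
#' @export
moving_fraction <- function(tracks) {
  if (!nrow(tracks)) abort("no tracks: moving fraction undefined")
  mean(tracks$moving)
}

#' Speed statistics of moving particles
#'
#' Pause-ignoring per-track speeds are the individual data points; replicate
#' means are reported when a replicate column is present, alongside the pooled
#' distribution.
#'
#' @param tracks Track tibble from [detect_tracks()]; optionally with a
#'   `replicate` column.
#' @return List with `mean_speed_um_s`, `speeds` (tibble of moving tracks),
#'   and `replicate_means` (tibble or `NULL`).
#' @export
speed_stats <- function(tracks) {
  mv <- dplyr::filter(tracks, .data$moving)
  if (!nrow(mv)) abort("no moving tracks: speed statistics undefined")
  reps <- NULL
  if ("replicate" %in% names(mv)) {
    reps <- mv |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(
        mean_speed_um_s = mean(.data$speed_um_s),
        n_tracks = dplyr::n(), .groups = "drop"
      )
  }
  list(
    mean_speed_um_s = mean(mv$speed_um_s),
    speeds = dplyr::select(mv, "track_id", "speed_um_s", "direction"),
    replicate_means = reps
  )
}
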
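#' Scene specification for synthetic imaging fields
#'
#' Describes one imaged culture field: geometry, pixel size, and how many
#' somas/axons to place. Identical spec + seed always yields bit-identical
#' output.
#'
#' @param field_size_px Integer pair, `(rows, cols)`.
#' @param pixel_size_um Pixel size in um/px. The default 0.65 corresponds to a
#'   typical 10x sCMOS configuration.
#' @param n_somas Number of somas to place.
#' @param soma_radius_um Length-2 range of soma radii (um).
#' @param n_axons Number of axon tracts (used by [gen_axon_field()]).
#' @param compartment One of `"presyn"`, `"central"`, `"postsyn"`.
#' @param seed Integer seed for this scene.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(field_size_px = c(256L, 256L), pixel_size_um = 0.65,
                       n_somas = 60L, soma_radius_um = c(4, 6.5),
                       n_axons = 0L, compartment = c("presyn", "central", "postsyn"),
                       seed = 1L) {
  compartment <- match.arg(compartment)
  stopifnot(
    length(field_size_px) == 2, all(field_size_px >= 8),
    length(soma_radius_um) == 2, soma_radius_um[1] > 0,
    soma_radius_um[2] >= soma_radius_um[1]
  )
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-6)
  assert_scalar_num(n_somas, "n_somas", lower = 0)
  assert_scalar_num(n_axons, "n_axons", lower = 0)
  assert_scalar_num(seed, "seed")
  structure(
    list(
      field_size_px = as.integer(field_size_px), pixel_size_um = pixel_size_um,
      n_somas = as.integer(n_somas), soma_radius_um = as.numeric(soma_radius_um),
      n_axons = as.integer(n_axons), compartment = compartment,
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' Treatment condition specification
#'
#' Houses the condition-level parameters of the data-generating process: which
#' aggregate species was spiked into the presynaptic compartment, at which
#' culture age, and the fold changes in normalized fluorescence it produces in
#' each compartment. Defaults for the named treatments are the experiment-level
#' means of the emulated study (see [condition_defaults()]); `ctrl` has all
#' folds fixed at 1.
#'
#' @param treatment `"ctrl"`, `"hFib"`, `"hOlig"`, or `"mFib"`.
#' @param div Days in vitro at treatment, 14 or 21.
#' @param presyn_fold,axon_fold,postsyn_fold Normalized mean signal in each
#'   compartment relative to untreated controls. Defaults are looked up from
#'   [condition_defaults()].
#' @param soma_cv Coefficient of variation of the per-soma signal law
#'   (log-normal). See the methods vignette for the calibration of the 0.3
#'   default.
#' @param autofluorescence_level Fraction of somatic signal rendered as
#'   punctate (rather than diffuse) fluorescence; emulates the somatic
#'   autofluorescent puncta visible in untreated cultures. Affects image
#'   texture, not per-soma means.
#' @return An object of class `condition_spec`.
#' @export
#' @examples
#' condition_spec("hOlig", 21)
#' condition_spec("ctrl", 14)
condition_spec <- function(treatment = c("ctrl", "hFib", "hOlig", "mFib"),
                           div = 14, presyn_fold = NULL, axon_fold = NULL,
                           postsyn_fold = NULL, soma_cv = 0.3,
                           autofluorescence_level = 0.3) {
  treatment <- match.arg(treatment)
  if (!div %in% c(14, 21)) abort("`div` must be 14 or 21")
  defaults <- condition_defaults()
  row <- defaults[defaults$treatment == treatment & defaults$div == div, ]
  presyn_fold <- presyn_fold %||% row$presyn_fold
  axon_fold <- axon_fold %||% row$axon_fold
  postsyn_fold <- postsyn_fold %||% row$postsyn_fold
  for (f in c(presyn_fold, axon_fold, postsyn_fold)) {
    assert_scalar_num(f, "fold", lower = 0)
  }
  if (treatment == "ctrl" &&
    any(c(presyn_fold, axon_fold, postsyn_fold) != 1)) {
    abort("ctrl condition must have all folds equal to 1")
  }
  assert_scalar_num(soma_cv, "soma_cv", lower = 1e-6)
  assert_scalar_num(autofluorescence_level, "autofluorescence_level", lower = 0, upper = 1)
  structure(
    list(
      treatment = treatment, div = as.integer(div),
      presyn_fold = presyn_fold, axon_fold = axon_fold,
      postsyn_fold = postsyn_fold, soma_cv = soma_cv,
      autofluorescence_level = autofluorescence_level
    ),
    class = "condition_spec"
  )
}

#' Default condition fold-changes
#'
#' Experiment-level normalized means for each treatment x DIV combination:
#' presynaptic soma, central-compartment axon, and postsynaptic soma signal as
#' a fold of untreated controls. The mFib presynaptic/axonal folds are not
#' reported for the emulated experiments and reuse the hFib DIV14 values as
#' fibril-like placeholders.
#'
#' @return A tibble with columns `treatment`, `div`, `presyn_fold`,
#'   `axon_fold`, `postsyn_fold`.
#' @export
condition_defaults <- function() {
  tibble::tribble(
    ~treatment, ~div, ~presyn_fold, ~axon_fold, ~postsyn_fold,
    "ctrl", 14L, 1, 1, 1,
    "ctrl", 21L, 1, 1, 1,
    "hFib", 14L, 21, 1.60, 1.10,
    "hFib", 21L, 29, 1.60, 1.046,
    "hOlig", 14L, 4.5, 1.95, 1.10,
    "hOlig", 21L, 7.3, 1.80, 1.032,
    "mFib", 14L, 21, 1.60, 1.08,
    "mFib", 21L, 21, 1.60, 1.08
  )
}

fold_for_compartment <- function(cond, compartment) {
  switch(compartment,
    presyn = cond$presyn_fold,
    central = cond$axon_fold,
    axons = cond$axon_fold,
    postsyn = cond$postsyn_fold,
    abort(sprintf("unknown compartment '%s'", compartment))
  )
}

#' Draw per-soma fluorescence signals from the generator's law
#'
#' Per-soma mean signal is log-normal (right-skewed, strictly positive) with
#' mean `baseline * fold` and coefficient of variation `cond$soma_cv`.
#'
#' @param n Number of somas.
#' @param cond A [condition_spec].
#' @param compartment Compartment whose fold applies.
#' @param baseline Mean control per-soma signal in acquisition units.
#' @param seed Optional seed (local substream; global RNG untouched).
#' @return Numeric vector of per-soma mean signals.
#' @export
sample_soma_signals <- function(n, cond, compartment = "presyn",
                                baseline = 100, seed = NULL) {
  stopifnot(inherits(cond, "condition_spec"))
  fold <- fold_for_compartment(cond, compartment)
  mu <- baseline * fold
  sdlog <- sqrt(log(1 + cond$soma_cv^2))
  meanlog <- log(mu) - sdlog^2 / 2
  draw <- function() rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Rejection-sampled non-overlapping disc centres. Errors explicitly when the
# requested density cannot be placed within bounded retries.
place_somas <- function(nr, nc, n, radius_px_range, min_gap_px = 4,
                        max_tries_per = 200) {
  if (n == 0) {
    return(tibble::tibble(
      r = numeric(), c = numeric(),
      radius_px = numeric()
    ))
  }
  rad <- runif(n, radius_px_range[1], radius_px_range[2])
  mean_area <- pi * mean(rad + min_gap_px / 2)^2
  if (n * mean_area > 0.55 * nr * nc) {
    abort("soma placement infeasible: requested density too high for field size")
  }
  rs <- numeric(n)
  cs <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries_per)) {
      r0 <- runif(1, rad[i] + 1, nr - rad[i])
      c0 <- runif(1, rad[i] + 1, nc - rad[i])
      if (i == 1) {
        ok <- TRUE
      } else {
        j <- seq_len(i - 1)
        ok <- all((rs[j] - r0)^2 + (cs[j] - c0)^2 >
          (rad[j] + rad[i] + min_gap_px)^2)
      }
      if (ok) break
    }
    if (!ok) {
      abort(sprintf(
        "soma placement failed for soma %d after %d tries; reduce density",
        i, max_tries_per
      ))
    }
    rs[i] <- r0
    cs[i] <- c0
  }
  tibble::tibble(r = rs, c = cs, radius_px = rad)
}

#' Generate a synthetic soma field with ground truth
#'
#' Renders a phase channel (dark soma bodies with a bright halo on a mid-gray
#' background plus Gaussian noise; enough structure for a classical segmenter,
#' with no attempt at true phase optics) and a fluorescence channel in which
#' each soma carries a mean signal drawn from the condition's log-normal law.
#' A fraction of each soma's signal is rendered as bright puncta, emulating the
#' punctate somatic autofluorescence of untreated cultures.
#'
#' @param scene A [scene_spec].
#' @param cond A [condition_spec].
#' @param baseline Mean control per-soma fluorescence (a.u.).
#' @param fluo_background Diffuse background fluorescence level (a.u.).
#' @param noise_sd_phase,noise_sd_fluo Additive Gaussian noise levels.
#' @return A list with elements `image` (a [micrograph] with `phase` and
#'   `fluo` channels) and `truth` (list: `somas` tibble with per-soma centre,
#'   radius and assigned signal; `labels` label matrix).
#' @export
gen_soma_field <- function(scene, cond, baseline = 100, fluo_background = 0.5,
                           noise_sd_phase = 0.03, noise_sd_fluo = 1.0) {
  stopifnot(inherits(scene, "scene_spec"), inherits(cond, "condition_spec"))
  nr <- scene$field_size_px[1]
  nc <- scene$field_size_px[2]
  rad_px <- scene$soma_radius_um / scene$pixel_size_um
  with_seed(substream_seed(scene$seed, "soma_field", scene$compartment), {
    centres <- place_somas(nr, nc, scene$n_somas, rad_px)
    signal <- sample_soma_signals(nrow(centres), cond,
      compartment = scene$compartment, baseline = baseline
    )
    phase <- matrix(0.5, nr, nc)
    fluo <- matrix(fluo_background, nr, nc)
    labels <- matrix(0L, nr, nc)
    # linear pixel indices of a disc, clipped to the field
    disc_idx <- function(r0, c0, radius) {
      rr <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
      cc <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
      sel <- which(outer((rr - r0)^2, (cc - c0)^2, "+") <= radius^2)
      ri <- (sel - 1L) %% length(rr) + 1L
      ci <- (sel - 1L) %/% length(rr) + 1L
      (cc[ci] - 1L) * nr + rr[ri]
    }
    af <- cond$autofluorescence_level
    for (i in seq_len(nrow(centres))) {
      r0 <- centres$r[i]
      c0 <- centres$c[i]
      rad <- centres$radius_px[i]
      body <- disc_idx(r0, c0, rad)
      halo <- setdiff(disc_idx(r0, c0, rad + 2), body)
      phase[halo] <- 0.72
      phase[body] <- 0.32
      labels[body] <- i
      fluo[body] <- fluo[body] + signal[i] * (1 - af)
      if (af > 0) {
        n_puncta <- 2 + rpois(1, 2)
        # puncta carry fraction `af` of the soma's integrated signal
        amp <- signal[i] * af * (pi * rad^2) / (n_puncta * pi * 1.2^2)
        for (k in seq_len(n_puncta)) {
          ang <- runif(1, 0, 2 * pi)
          rr <- sqrt(runif(1)) * (rad - 1.5)
          p_idx <- disc_idx(r0 + rr * cos(ang), c0 + rr * sin(ang), 1.2)
          fluo[p_idx] <- fluo[p_idx] + amp
        }
      }
    }
    phase <- phase + matrix(rnorm(nr * nc, 0, noise_sd_phase), nr, nc)
    fluo <- fluo + matrix(rnorm(nr * nc, 0, noise_sd_fluo), nr, nc)
    truth <- list(
      somas = dplyr::mutate(centres,
        soma_id = dplyr::row_number(),
        signal = signal, .before = 1
      ),
      labels = labels
    )
    list(
      image = micrograph(list(phase = phase, fluo = fluo),
        pixel_size_um = scene$pixel_size_um
      ),
      truth = truth
    )
  })
}

#' Generate a synthetic axon field with ground truth
#'
#' Axon tracts cross the field horizontally as smooth bright curves over a dark
#' background, each carrying a per-axon fluorescence drawn from the condition's
#' law in the central compartment. Used for axonal fluorescence quantification
#' and for counting fibre crossings at a microchannel exit line.
#'
#' @param scene A [scene_spec] (uses `n_axons`; `compartment` is typically
#'   `"central"`).
#' @param cond A [condition_spec].
#' @param baseline Mean control per-axon signal (a.u.).
#' @param direction `"forward"` draws `n_axons` crossing tracts; `"backward"`
#'   draws none (axon valves fully block backward growth), so the field is pure
#'   background.
#' @param min_spacing_px Minimum vertical spacing between tracts at any column.
#' @param background Background level (a.u.).
#' @param noise_sd Additive Gaussian noise.
#' @return List with `image` ([micrograph], channel `fluo`), `truth` (tibble of
#'   axon polylines in a list-column plus per-axon signal).
#' @export
gen_axon_field <- function(scene, cond, baseline = 50,
                           direction = c("forward", "backward"),
                           min_spacing_px = 18, background = 0.5,
                           noise_sd = 0.5) {
  stopifnot(inherits(scene, "scene_spec"), inherits(cond, "condition_spec"))
  direction <- match.arg(direction)
  nr <- scene$field_size_px[1]
  nc <- scene$field_size_px[2]
  n <- if (direction == "backward") 0L else scene$n_axons
  with_seed(substream_seed(scene$seed, "axon_field", direction), {
    fluo <- matrix(background, nr, nc)
    polylines <- list()
    signals <- numeric(0)
    if (n > 0) {
      if (n * min_spacing_px > nr - 2 * min_spacing_px) {
        abort("axon placement infeasible: too many tracts for the field height")
      }
      base_rows <- seq(min_spacing_px, nr - min_spacing_px, length.out = n)
      base_rows <- base_rows + runif(n, -min_spacing_px / 4, min_spacing_px / 4)
      signals <- sample_soma_signals(n, cond,
        compartment = "central", baseline = baseline
      )
      xs <- seq(1, nc, by = 4)
      for (i in seq_len(n)) {
        wander <- cumsum(rnorm(length(xs), 0, 0.6))
        wander <- wander - seq(wander[1], wander[length(wander)],
          length.out = length(wander)
        )
        ys <- pmin(pmax(base_rows[i] + wander, 2), nr - 1)
        poly <- cbind(r = ys, c = xs)
        dense <- resample_polyline(poly, step = 0.5)$points
        for (j in seq_len(nrow(dense))) {
          fluo <- draw_disc(fluo, dense[j, 1], dense[j, 2], 0.9, signals[i])
        }
        polylines[[i]] <- poly
      }
    }
    fluo <- fluo + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    list(
      image = micrograph(list(fluo = fluo), pixel_size_um = scene$pixel_size_um),
      truth = tibble::tibble(
        axon_id = seq_len(n),
        polyline = polylines,
        signal = signals
      )
    )
  })
}

#' Generate a synthetic time-lapse of particles in a microchannel
#'
#' Emulates time-lapse acquisition of fluorescent aggregate particles moving
#' through an axon-filled microchannel: a fraction of particles move at an
#' assigned speed (interrupted by geometric-duration pauses), the rest stay
#' within one pixel of their position. Moving particles leave the field when
#' they reach the channel end.
#'
#' @param scene A [scene_spec]; `field_size_px` gives `(channel height,
#'   channel length)` in pixels.
#' @param n_particles Number of particles.
#' @param speed_um_s Length-2 `(mean, sd)` of the normal law assigning
#'   per-particle speeds (um/s).
#' @param moving_fraction Fraction of particles that move.
#' @param pause_prob Per-frame probability for a moving particle to enter a
#'   pause; pause durations are geometric with mean `pause_mean_frames`.
#' @param pause_mean_frames Mean pause duration in frames.
#' @param n_frames Number of frames. The default 90 at 5 s intervals gives a
#'   7.5 min acquisition.
#' @param frame_interval_s Frame interval (s).
#' @param amplitude,background,noise_sd Rendering parameters (a.u.).
#' @return List with `stack` (a [timelapse_stack]) and `truth` (tibble:
#'   particle id, assigned speed, moving flag, and the per-frame positions as a
#'   list-column of `(frame, pos_px)` matrices).
#' @export
gen_timelapse <- function(scene, n_particles = 20,
                          speed_um_s = c(1.0, 0.2), moving_fraction = 0.4,
                          pause_prob = 0.05, pause_mean_frames = 3,
                          n_frames = 90, frame_interval_s = 5,
                          amplitude = 50, background = 5, noise_sd = 2) {
  stopifnot(inherits(scene, "scene_spec"))
  assert_scalar_num(moving_fraction, "moving_fraction", lower = 0, upper = 1)
  assert_scalar_num(frame_interval_s, "frame_interval_s", lower = 1e-9)
  assert_scalar_num(pause_prob, "pause_prob", lower = 0, upper = 1)
  nr <- scene$field_size_px[1]
  nc <- scene$field_size_px[2]
  with_seed(substream_seed(scene$seed, "timelapse"), {
    n_moving <- round(n_particles * moving_fraction)
    moving <- rep(c(TRUE, FALSE), c(n_moving, n_particles - n_moving))
    speeds <- abs(rnorm(n_particles, speed_um_s[1], speed_um_s[2]))
    speeds[!moving] <- 0
    # particles closer than the PSF cannot be resolved as two objects;
    # keep initial positions at least 10 px apart
    x0 <- numeric(n_particles)
    for (i in seq_len(n_particles)) {
      for (try in 1:100) {
        cand <- runif(1, 2, nc - 1)
        if (i == 1 || all(abs(x0[seq_len(i - 1)] - cand) >= 10)) break
      }
      x0[i] <- cand
    }
    y0 <- runif(n_particles, max(2, nr / 2 - 1), min(nr - 1, nr / 2 + 1))
    step_px <- speeds * frame_interval_s / scene$pixel_size_um
    frames <- array(background, dim = c(nr, nc, n_frames))
    tracks <- vector("list", n_particles)
    for (i in seq_len(n_particles)) {
      pos <- numeric(n_frames)
      x <- x0[i]
      paused <- 0L
      for (t in seq_len(n_frames)) {
        pos[t] <- x
        if (moving[i]) {
          if (paused > 0L) {
            paused <- paused - 1L
          } else {
            x <- x + step_px[i]
            if (pause_prob > 0 && runif(1) < pause_prob) {
              paused <- 1L + rpois(1, max(pause_mean_frames - 1, 0))
            }
          }
        } else {
          x <- x0[i] + rnorm(1, 0, 0.2)
        }
      }
      visible <- pos >= 1 & pos <= nc
      tracks[[i]] <- cbind(frame = which(visible), pos_px = pos[visible])
      for (t in which(visible)) {
        rr <- max(1, round(y0[i]) - 2):min(nr, round(y0[i]) + 2)
        cc <- max(1, round(pos[t]) - 3):min(nc, round(pos[t]) + 3)
        g <- amplitude *
          exp(-(outer((rr - y0[i])^2, (cc - pos[t])^2, "+")) / (2 * 1.1^2))
        frames[rr, cc, t] <- frames[rr, cc, t] + g
      }
    }
    frames <- frames + array(rnorm(length(frames), 0, noise_sd), dim = dim(frames))
    list(
      stack = timelapse_stack(frames,
        pixel_size_um = scene$pixel_size_um,
        frame_interval_s = frame_interval_s
      ),
      truth = tibble::tibble(
        particle_id = seq_len(n_particles),
        moving = moving, speed_um_s = speeds,
        track = tracks
      )
    )
  })
}

#' Generate a synthetic synaptic-staining field with ground truth
#'
#' A dendrite-like trace meanders across the field; synaptic (Bassoon-type)
#' foci are scattered within 1.5 um of the trace at the requested linear
#' density, and the aSyn channel carries clearly separated intensities for
#' aSyn-positive versus aSyn-negative foci.
#'
#' @param trace_length_um Dendrite trace length (um).
#' @param foci_per_um Linear density of synaptic foci.
#' @param asyn_pos_fraction Fraction of foci that are aSyn-positive.
#' @param seed Integer seed.
#' @param pixel_size_um Pixel size (um/px).
#' @param focus_amp,asyn_pos_amp,asyn_neg_amp,background,noise_sd Rendering
#'   intensities (a.u.).
#' @return List with `image` ([micrograph] with `bassoon` and `asyn`
#'   channels), `truth` (tibble of foci centres and labels, plus the trace
#'   polyline as attribute `"trace"`).
#' @export
gen_synapse_field <- function(trace_length_um, foci_per_um = 0.5,
                              asyn_pos_fraction = 0.5, seed = 1,
                              pixel_size_um = 0.24, focus_amp = 60,
                              asyn_pos_amp = 50, asyn_neg_amp = 2,
                              background = 1, noise_sd = 1.5) {
  assert_scalar_num(trace_length_um, "trace_length_um", lower = 1)
  assert_scalar_num(foci_per_um, "foci_per_um", lower = 0)
  assert_scalar_num(asyn_pos_fraction, "asyn_pos_fraction", lower = 0, upper = 1)
  with_seed(substream_seed(seed, "synapse_field"), {
    len_px <- trace_length_um / pixel_size_um
    # fold the trace into horizontal sweeps so long dendrites fit in a field
    margin <- 20
    sweep_len <- min(len_px, 800)
    n_sweeps <- ceiling(len_px / sweep_len)
    nc <- ceiling(sweep_len) + 2 * margin
    nr <- max(128, n_sweeps * 40 + 2 * margin)
    pts <- list()
    remaining <- len_px
    for (s in seq_len(n_sweeps)) {
      this_len <- min(sweep_len, remaining)
      remaining <- remaining - this_len
      xs <- seq(margin, margin + this_len, by = 4)
      if (s %% 2 == 0) xs <- rev(xs)
      ys <- margin + (s - 1) * 40 +
        cumsum(rnorm(length(xs), 0, 0.5))
      ys <- pmin(pmax(ys, 5), nr - 5)
      pts[[s]] <- cbind(r = ys, c = xs)
    }
    poly <- do.call(rbind, pts)
    # the folds add arc length; cut the trace at exactly the requested length
    dense_all <- resample_polyline(poly, step = 0.5)
    n_keep <- min(nrow(dense_all$points), ceiling(len_px / 0.5) + 1)
    poly <- dense_all$points[seq(1, n_keep, by = 4), , drop = FALSE]
    if (n_keep %% 4 != 1) {
      poly <- rbind(poly, dense_all$points[n_keep, ])
    }
    dense <- resample_polyline(poly, step = 0.5)
    n_foci <- rpois(1, foci_per_um * trace_length_um)
    bassoon <- matrix(background, nr, nc)
    asyn <- matrix(background, nr, nc)
    foci <- tibble::tibble(
      focus_id = integer(), r = numeric(), c = numeric(),
      asyn_pos = logical()
    )
    if (n_foci > 0) {
      # foci scattered within 1.5 um of the trace; synapses are discrete
      # structures, so a minimum separation of 0.7 um is enforced
      min_sep_px <- 0.7 / pixel_size_um
      fr <- numeric(n_foci)
      fc <- numeric(n_foci)
      for (i in seq_len(n_foci)) {
        for (try in 1:50) {
          j <- sample(nrow(dense$points), 1)
          ang <- runif(1, 0, 2 * pi)
          rad <- 1.5 * sqrt(runif(1)) / pixel_size_um
          r0 <- min(max(dense$points[j, 1] + rad * cos(ang), 2), nr - 1)
          c0 <- min(max(dense$points[j, 2] + rad * sin(ang), 2), nc - 1)
          if (i == 1 || all((fr[seq_len(i - 1)] - r0)^2 +
            (fc[seq_len(i - 1)] - c0)^2 > min_sep_px^2)) {
            break
          }
        }
        fr[i] <- r0
        fc[i] <- c0
      }
      pos <- runif(n_foci) < asyn_pos_fraction
      for (i in seq_len(n_foci)) {
        bassoon <- draw_disc(bassoon, fr[i], fc[i], 1.0, focus_amp, add = TRUE)
        asyn <- draw_disc(
          asyn, fr[i], fc[i], 1.0,
          if (pos[i]) asyn_pos_amp else asyn_neg_amp,
          add = TRUE
        )
      }
      foci <- tibble::tibble(
        focus_id = seq_len(n_foci), r = fr, c = fc,
        asyn_pos = pos
      )
    }
    bassoon <- bassoon + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    asyn <- asyn + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    attr(foci, "trace") <- poly
    list(
      image = micrograph(list(bassoon = bassoon, asyn = asyn),
        pixel_size_um = pixel_size_um
      ),
      truth = foci
    )
  })
}

#' Generate a tabular study of normalized compartment signals
#'
#' Tabular shortcut past imaging: per-device normalized signals for the
#' presynaptic, axonal and postsynaptic compartments, drawn around the
#' condition's folds with multiplicative log-normal experiment- and
#' device-level noise (mean-corrected so expectations equal the folds exactly;
#' `noise = 0` reproduces the folds). Control devices cluster around 1.
#'
#' @param experiments Number of experiments (each its own imaging session).
#' @param devices_per_exp Devices per experiment and condition.
#' @param cond A [condition_spec].
#' @param seed Integer seed.
#' @param experiment_cv,device_cv Coefficients of variation of the experiment-
#'   and device-level multiplicative noise.
#' @param conditions Optional list of [condition_spec]s to generate jointly
#'   (e.g. treated plus ctrl); defaults to `list(cond)`.
#' @return A tibble with columns `experiment_id`, `device_id`, `session_id`,
#'   `condition`, `div`, `compartment`, `signal`.
#' @export
gen_signal_table <- function(experiments, devices_per_exp, cond, seed = 1,
                             experiment_cv = 0.15, device_cv = 0.10,
                             conditions = NULL) {
  assert_scalar_num(experiments, "experiments", lower = 1)
  assert_scalar_num(devices_per_exp, "devices_per_exp", lower = 1)
  conditions <- conditions %||% list(cond)
  stopifnot(all(vapply(conditions, inherits, logical(1), "condition_spec")))
  ln_noise <- function(n, cv) {
    if (cv == 0) {
      return(rep(1, n))
    }
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(substream_seed(seed, "signal_table"), {
    grid <- tidyr::expand_grid(
      cond_i = seq_along(conditions),
      experiment_id = sprintf("E%02d", seq_len(experiments)),
      device = seq_len(devices_per_exp),
      compartment = c("presyn", "axons", "postsyn")
    )
    rows <- purrr::pmap_dfr(
      grid,
      function(cond_i, experiment_id, device, compartment) {
        cd <- conditions[[cond_i]]
        tibble::tibble(
          experiment_id = experiment_id,
          device_id = sprintf(
            "%s_%s_D%02d", experiment_id, cd$treatment, device
          ),
          session_id = experiment_id,
          condition = cd$treatment, div = cd$div,
          compartment = compartment,
          fold = fold_for_compartment(
            cd,
            if (compartment == "axons") "central" else compartment
          )
        )
      }
    )
    exp_eff <- rows |>
      dplyr::distinct(.data$experiment_id, .data$condition, .data$compartment) |>
      dplyr::mutate(exp_noise = ln_noise(dplyr::n(), experiment_cv))
    rows |>
      dplyr::left_join(exp_eff,
        by = c("experiment_id", "condition", "compartment")
      ) |>
      dplyr::mutate(
        signal = .data$fold * .data$exp_noise *
          ln_noise(dplyr::n(), device_cv)
      ) |>
      dplyr::select(
        "experiment_id", "device_id", "session_id", "condition",
        "div", "compartment", "signal"
      )
  })
}
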
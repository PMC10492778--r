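rate_assumptions <- function() {
  c(
    "linear correlation between fluorescence increase and aggregate exposure in the medium",
    "constant aggregate transfer rate over the post-uptake window",
    "aggregates-associated fluorescence was not affected by axonal transport, transfer to secondary neurons, or bleaching"
  )
}

#' Equivalent direct-exposure dose
#'
#' Under the (liberal) assumption that fluorescence increase is linear in
#' aggregate exposure, a transmitted excess fraction of the presynaptic signal
#' corresponds to direct exposure at that same fraction of the spiking
#' concentration: `dose = spike_nM * tes_fraction`.
#'
#' @param spike_nM Spiking concentration in the presynaptic compartment (nM
#'   of monomer equivalent); the emulated study used 500 nM.
#' @param tes_fraction Transmitted excess signal as a fraction in `[0, 1]`.
#' @return Equivalent dose in nM, vectorised elementwise.
#' @export
#' @examples
#' equivalent_dose(500, 0.005) # 2.5 nM
equivalent_dose <- function(spike_nM, tes_fraction) {
  stopifnot(all(spike_nM > 0))
  if (any(!is.finite(tes_fraction)) || any(tes_fraction < 0) ||
    any(tes_fraction > 1)) {
    abort("`tes_fraction` must lie in [0, 1]")
  }
  spike_nM * tes_fraction
}

#' Per-axon daily transfer rate
#'
#' Distributes an equivalent dose over the axons innervating the postsynaptic
#' compartment and the post-uptake transfer window, assuming a constant
#' transfer rate: `rate = dose * 1000 / (window_days * n_axons)` in pM/day per
#' axon. Applied elementwise, so dose intervals map to rate intervals.
#'
#' @param equivalent_dose_nM Dose (nM), scalar or interval (length-2 vector
#'   `c(lo, hi)` or any vector, handled elementwise).
#' @param n_axons Number of axons innervating the postsynaptic compartment
#'   (default ~100, the emulated setup's average).
#' @param window_days Transfer window in days. The default 2.0 reflects a 24 h
#'   exposure followed by rinse with readout 3 days after introduction, i.e.
#'   about two days of post-uptake transfer.
#' @return Rate(s) in pM/day per axon.
#' @export
#' @examples
#' per_axon_rate(c(1, 10)) # 5-50 pM/day
per_axon_rate <- function(equivalent_dose_nM, n_axons = 100, window_days = 2.0) {
  stopifnot(all(equivalent_dose_nM >= 0))
  assert_scalar_num(n_axons, "n_axons", lower = 1)
  assert_scalar_num(window_days, "window_days", lower = 1e-9)
  equivalent_dose_nM * 1000 / (window_days * n_axons)
}

#' Full rate estimate with explicit assumptions
#'
#' Combines [equivalent_dose()] and [per_axon_rate()] into a tidy one-row
#' record carrying every modelling assumption explicitly.
#'
#' @param tes_fraction Transmitted excess signal (fraction), scalar or
#'   interval.
#' @param spike_nM Spiking concentration (nM).
#' @param n_axons,window_days See [per_axon_rate()].
#' @param condition,div Optional labels.
#' @return One-row tibble with dose and rate (point and interval columns) and
#'   an `assumptions` list-column (never empty).
#' @export
rate_estimate <- function(tes_fraction, spike_nM = 500, n_axons = 100,
                          window_days = 2.0, condition = NA_character_,
                          div = NA_integer_) {
  dose <- equivalent_dose(spike_nM, tes_fraction)
  rate <- per_axon_rate(dose, n_axons = n_axons, window_days = window_days)
  tibble::tibble(
    condition = condition, div = div, spike_nM = spike_nM,
    equivalent_dose_nM = mean(dose),
    dose_lo_nM = min(dose), dose_hi_nM = max(dose),
    n_axons = n_axons, window_days = window_days,
    per_axon_rate_pM_day = mean(rate),
    rate_lo_pM_day = min(rate), rate_hi_pM_day = max(rate),
    assumptions = list(rate_assumptions())
  )
}

#' Invert a dose-fluorescence calibration
#'
#' Given a monotone increasing calibration (dose introduced directly in the
#' postsynaptic compartment versus the fluorescence excess it produces), maps
#' an observed postsynaptic excess back to dose: a linear-interpolation point
#' estimate plus the bracketing calibration interval. Excess outside the
#' calibrated range is not extrapolated; the nearest endpoint is returned with
#' an explicit flag.
#'
#' @param postsyn_excess Observed excess (normalized signal minus 1).
#' @param calibration Data frame with columns `dose_nM` and `excess`, at
#'   least two rows, strictly increasing in both.
#' @return One-row tibble: `excess`, `dose_nM` (interpolated point),
#'   `dose_lo_nM`, `dose_hi_nM` (bracketing calibration points), `flag`
#'   (`"ok"`, `"at_point"`, `"below_range"`, `"above_range"`).
#' @export
dose_from_calibration <- function(postsyn_excess, calibration) {
  stopifnot(
    is.data.frame(calibration),
    all(c("dose_nM", "excess") %in% names(calibration)),
    nrow(calibration) >= 2
  )
  cal <- calibration[order(calibration$dose_nM), ]
  if (any(diff(cal$excess) <= 0) || any(diff(cal$dose_nM) <= 0)) {
    abort("calibration must be strictly increasing in dose and excess")
  }
  assert_scalar_num(postsyn_excess, "postsyn_excess")
  if (postsyn_excess < cal$excess[1]) {
    return(tibble::tibble(
      excess = postsyn_excess, dose_nM = cal$dose_nM[1],
      dose_lo_nM = NA_real_, dose_hi_nM = cal$dose_nM[1],
      flag = "below_range"
    ))
  }
  if (postsyn_excess > cal$excess[nrow(cal)]) {
    return(tibble::tibble(
      excess = postsyn_excess, dose_nM = cal$dose_nM[nrow(cal)],
      dose_lo_nM = cal$dose_nM[nrow(cal)], dose_hi_nM = NA_real_,
      flag = "above_range"
    ))
  }
  hit <- which(cal$excess == postsyn_excess)
  if (length(hit)) {
    d <- cal$dose_nM[hit[1]]
    return(tibble::tibble(
      excess = postsyn_excess, dose_nM = d,
      dose_lo_nM = d, dose_hi_nM = d, flag = "at_point"
    ))
  }
  i <- max(which(cal$excess < postsyn_excess))
  d <- stats::approx(cal$excess, cal$dose_nM, xout = postsyn_excess)$y
  tibble::tibble(
    excess = postsyn_excess, dose_nM = d,
    dose_lo_nM = cal$dose_nM[i], dose_hi_nM = cal$dose_nM[i + 1],
    flag = "ok"
  )
}
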
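soma_fixture <- function(seed = 3, n = 30) {
  side <- synspread:::soma_field_side(n)
  sc <- scene_spec(field_size_px = c(side, side), n_somas = n, seed = seed)
  f <- gen_soma_field(sc, condition_spec("hFib", 14))
  rois <- detect_somas(f$image)
  list(field = f, rois = rois)
}

test_that("soma fluorescence equals the in-mask mean, including z-projection", {
  fx <- soma_fixture()
  # uniform image: every soma mean equals the uniform value
  u <- micrograph(
    list(fluo = matrix(7.5, dim(fx$field$image)[1], dim(fx$field$image)[2])),
    pixel_size_um = 0.65
  )
  fl <- soma_fluorescence(u, fx$rois)
  expect_true(all(fl$mean_fluo == 7.5))

  # z-stack with all signal in one plane: max projection recovers it
  d <- dim(fx$field$image)
  z <- array(0, dim = c(d[1], d[2], 5))
  z[, , 3] <- get_channel(fx$field$image, "fluo")
  zimg <- micrograph(list(fluo = z), pixel_size_um = 0.65)
  fl_z <- soma_fluorescence(zimg, fx$rois)
  fl_flat <- soma_fluorescence(fx$field$image, fx$rois)
  expect_equal(fl_z$mean_fluo, fl_flat$mean_fluo)
})

test_that("measured per-soma means track the generator's assigned signals", {
  fx <- soma_fixture(seed = 8, n = 40)
  fl <- soma_fluorescence(fx$field$image, fx$rois)
  truth <- fx$field$truth$somas
  nearest <- vapply(seq_len(nrow(fx$rois)), function(i) {
    which.min((truth$r - fx$rois$r[i])^2 + (truth$c - fx$rois$c[i])^2)
  }, numeric(1))
  expect_gte(cor(fl$mean_fluo, truth$signal[nearest]), 0.9)
})

test_that("soma fluorescence equals a brute-force per-pixel mean exactly", {
  set.seed(99)
  for (rep in 1:5) {
    img_mat <- matrix(runif(48 * 48, 0, 100), 48, 48)
    labels <- matrix(0L, 48, 48)
    labels <- synspread:::draw_disc(labels, runif(1, 10, 20), runif(1, 10, 38), 5, 1L)
    labels <- synspread:::draw_disc(labels, runif(1, 30, 40), runif(1, 10, 38), 4, 2L)
    rois <- tibble::tibble(
      soma_id = 1:2, r = c(15, 35), c = c(24, 24),
      area_px = tabulate(labels[labels > 0]), area_um2 = NA_real_
    )
    rois <- structure(rois,
      labels = labels, pixel_size_um = 1,
      class = c("soma_rois", class(rois))
    )
    img <- micrograph(list(fluo = img_mat), pixel_size_um = 1)
    fl <- soma_fluorescence(img, rois)
    expect_identical(
      fl$mean_fluo[1],
      brute_force_mask_mean(img_mat, labels, 1)
    )
    expect_identical(
      fl$mean_fluo[2],
      brute_force_mask_mean(img_mat, labels, 2)
    )
  }
})

test_that("axonal corridor fluorescence behaves on uniform, line and synthetic fields", {
  u <- micrograph(list(fluo = matrix(4, 80, 80)), pixel_size_um = 0.65)
  poly <- cbind(r = c(40, 40), c = c(10, 70))
  expect_equal(axon_fluorescence(u, list(poly))$mean_fluo, 4)

  # bright 1-px line on dark background: corridor mean far above field mean
  m <- matrix(0.1, 80, 80)
  m[40, 10:70] <- 50
  img <- micrograph(list(fluo = m), pixel_size_um = 0.65)
  expect_gt(
    axon_fluorescence(img, list(poly))$mean_fluo,
    10 * mean(m)
  )

  # treated / control corridor-mean ratio recovers the axonal fold (+60%)
  sc <- scene_spec(
    field_size_px = c(220, 220), n_axons = 10,
    compartment = "central", seed = 31
  )
  tr <- gen_axon_field(sc, condition_spec("hFib", 14), noise_sd = 0.1)
  ct <- gen_axon_field(sc, condition_spec("ctrl", 14), noise_sd = 0.1)
  f_tr <- axon_fluorescence(tr$image, tr$truth$polyline)
  f_ct <- axon_fluorescence(ct$image, ct$truth$polyline)
  expect_equal(
    mean(f_tr$mean_fluo) / mean(f_ct$mean_fluo), 1.6,
    tolerance = 0.12
  )
})

test_that("session normalization is exact, gain-invariant and guarded", {
  raw <- tibble::tibble(
    device_id = c("d1", "d2", "d3", "d4"),
    session_id = "s1",
    condition = c("ctrl", "ctrl", "hFib", "ctrl"),
    compartment = "postsyn",
    raw_mean = c(10, 10, 11, 10)
  )
  out <- normalize_session(raw)
  expect_equal(out$normalized[out$device_id == "d3"], 1.1)
  # a control device equal to the control mean maps to exactly 1
  expect_equal(out$normalized[out$device_id == "d1"], 1)
  # control session mean maps to exactly 1
  expect_equal(mean(out$normalized[out$condition == "ctrl"]), 1)

  # gain change: scaling all raw values leaves normalized values unchanged
  scaled <- dplyr::mutate(raw, raw_mean = raw_mean * 3)
  expect_equal(normalize_session(scaled)$normalized, out$normalized)

  # a session without controls is a hard error naming the session
  no_ctrl <- dplyr::mutate(raw, condition = "hFib")
  expect_error(normalize_session(no_ctrl), "s1")
})

test_that("QC thresholds are closed at the stated minima", {
  soma_tbl <- tibble::tibble(
    device_id = c("a", "b", "c", "d"),
    n_units = c(40L, 39L, 40L, 400L),
    n_fields = c(4L, 4L, 3L, 4L)
  )
  qc <- qc_device(soma_tbl, "soma")
  expect_equal(qc$qc_pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(qc$qc_reasons[2], "somas")
  expect_match(qc$qc_reasons[3], "fields")

  axon_tbl <- tibble::tibble(device_id = c("a", "b"), n_units = c(10L, 9L))
  expect_equal(qc_device(axon_tbl, "axon")$qc_pass, c(TRUE, FALSE))

  syn_tbl <- tibble::tibble(
    device_id = c("a", "b"), n_units = c(1L, 1L),
    n_fields = c(4L, 4L), dendrite_um = c(650, 649)
  )
  qs <- qc_device(syn_tbl, "synapse")
  expect_equal(qs$qc_pass, c(TRUE, FALSE))
  expect_match(qs$qc_reasons[2], "dendrite")
})

test_that("synaptic density arithmetic and end-to-end recovery", {
  f <- gen_synapse_field(1000, foci_per_um = 0.5, seed = 23)
  trace <- dilate_trace(attr(f$truth, "trace"),
    width_um = 3,
    pixel_size_um = f$image$pixel_size_um, dim_px = dim(f$image)
  )
  foci <- segment_foci(f$image, trace)
  dens <- synapse_density(foci, trace)
  expect_equal(dens$foci_per_um, 0.5, tolerance = 0.1)
  expect_equal(dens$dendrite_um, 1000, tolerance = 0.01)
  expect_lte(sum(foci$area_px == 1), 0)

  # direct arithmetic on an empty set
  empty <- structure(
    tibble::tibble(
      focus_id = integer(), r = numeric(),
      c = numeric(), area_px = integer(), marker_mean = numeric()
    ),
    class = c("foci_set", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(synapse_density(empty, trace)$foci_per_um, 0)
})

test_that("pSyn/MAP2 scoring normalizes controls to 1 on average", {
  set.seed(5)
  psyn <- matrix(runif(64 * 64, 0, 2), 64, 64)
  map2 <- matrix(runif(64 * 64, 1, 3), 64, 64)
  raw <- psyn_ratio(psyn, map2)
  expect_equal(raw$ratio, sum(psyn) / sum(map2))
  # identical field against its own ratio scores 1; doubled pSyn scores 2
  expect_equal(psyn_ratio(psyn, map2, control_ratios = raw$ratio)$score, 1)
  expect_equal(psyn_ratio(2 * psyn, map2, control_ratios = raw$ratio)$score, 2)
  # control fields average exactly 1 by construction
  ctrl_ratios <- c(raw$ratio, psyn_ratio(psyn * 1.4, map2)$ratio)
  scores <- vapply(
    list(psyn, psyn * 1.4),
    function(p) psyn_ratio(p, map2, control_ratios = ctrl_ratios)$score,
    numeric(1)
  )
  expect_equal(mean(scores), 1)
  expect_error(psyn_ratio(psyn, matrix(0, 64, 64)), "MAP2")
})

test_that("fibre crossing counts match ground truth in both directions", {
  sc <- scene_spec(
    field_size_px = c(260, 200), n_axons = 12,
    compartment = "central", seed = 41
  )
  fwd <- gen_axon_field(sc, condition_spec("hFib", 14))
  n <- count_crossings(fwd$image, exit_line = 100, direction = "forward")
  expect_equal(n$n_crossings, 12)

  # backward fields are empty: axon valves fully block backward outgrowth
  bwd <- gen_axon_field(sc, condition_spec("hFib", 14), direction = "backward")
  expect_equal(
    count_crossings(bwd$image, 100, direction = "backward")$n_crossings, 0
  )

  blank <- micrograph(list(fluo = matrix(0.5, 100, 100)), pixel_size_um = 0.65)
  expect_equal(count_crossings(blank, 50)$n_crossings, 0)
})

test_that("signal histograms are seeded, fixed-bin and dip-annotated", {
  vals <- sample_soma_signals(2000, condition_spec("hFib", 14), seed = 51)
  h1 <- signal_histogram(vals, seed = 7)
  h2 <- signal_histogram(vals, seed = 7)
  expect_identical(h1$sample, h2$sample)
  expect_equal(h1$bins, 100)
  expect_equal(sum(h1$histogram$count), 500)

  # constant values occupy a single bin
  hc <- signal_histogram(rep(3, 600), seed = 1)
  expect_equal(sum(hc$histogram$count > 0), 1)

  # too few values is an error unless explicitly allowed
  expect_error(signal_histogram(vals[1:100], seed = 1), "allow_smaller")
  expect_equal(signal_histogram(vals[1:100], seed = 1, allow_smaller = TRUE)$n, 100)
})

test_that("dip test does not reject unimodality for the generator's law", {
  # 200 seeded draws of 500 somas; non-rejection rate at alpha = 0.05
  cond <- condition_spec("hOlig", 14)
  null <- synspread:::dip_null_sample(500, 200, 1)
  crit <- quantile(null, 0.95)
  rejected <- vapply(1:200, function(s) {
    x <- sample_soma_signals(500, cond, "presyn", seed = s)
    dip_statistic(x) > crit
  }, logical(1))
  expect_gte(mean(!rejected), 0.95)
})
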
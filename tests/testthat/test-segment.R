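make_field <- function(n = 50, seed = 1, cond = condition_spec("hFib", 14)) {
  side <- synspread:::soma_field_side(n)
  sc <- scene_spec(field_size_px = c(side, side), n_somas = n, seed = seed)
  gen_soma_field(sc, cond)
}

test_that("blank fields yield no somas", {
  img <- micrograph(
    list(phase = matrix(0.5 + rnorm(96^2, 0, 0.03), 96, 96)),
    pixel_size_um = 0.65
  )
  expect_equal(nrow(detect_somas(img)), 0)
})

test_that("somas are recovered with high recall and IoU on synthetic fields", {
  f <- make_field(50, seed = 42)
  rois <- detect_somas(f$image)
  expect_gte(nrow(rois), 45)
  iou <- match_rois_iou(attr(rois, "labels"), f$truth$labels)
  matched <- iou$best_iou >= 0.5
  expect_gte(sum(matched), 45)
  expect_gte(mean(iou$best_iou), 0.7)
  # masks are pairwise disjoint by construction of a label image
  expect_true(max(attr(rois, "labels")) == nrow(rois))
})

test_that("touching somas are split by the declumping step", {
  # two overlapping phase-dark discs: a single connected component before
  # watershed declumping
  ph <- matrix(0.5, 96, 96)
  ph <- synspread:::draw_disc(ph, 48, 38, 10, 0.32)
  ph <- synspread:::draw_disc(ph, 48, 57, 10, 0.32)
  set.seed(1)
  ph <- ph + matrix(rnorm(96^2, 0, 0.01), 96, 96)
  img <- micrograph(list(phase = ph), pixel_size_um = 0.65)
  rois <- detect_somas(img)
  expect_equal(nrow(rois), 2)
  expect_true(abs(diff(sort(rois$c))) > 10)
})

test_that("soma detection is translation-equivariant under cyclic shifts", {
  f <- make_field(20, seed = 9)
  ph <- get_channel(f$image, "phase")
  shift <- 17
  ph2 <- ph[c((nrow(ph) - shift + 1):nrow(ph), 1:(nrow(ph) - shift)), ]
  m1 <- attr(detect_somas(f$image), "labels") > 0
  m2 <- attr(detect_somas(
    micrograph(list(phase = ph2), f$image$pixel_size_um)
  ), "labels") > 0
  m1_shifted <- m1[c((nrow(m1) - shift + 1):nrow(m1), 1:(nrow(m1) - shift)), ]
  # somas wrapped across the cyclic seam may be filtered differently;
  # compare away from the seam
  interior <- (shift + 15):(nrow(m1) - 15)
  expect_equal(m1_shifted[interior, ], m2[interior, ])
})

test_that("trace dilation has the stated geometry", {
  # straight 100 um trace
  px <- 0.5
  poly <- cbind(r = c(50, 50), c = c(10, 10 + 100 / px))
  roi <- dilate_trace(poly, width_um = 3, pixel_size_um = px, dim_px = c(100, 240))
  expect_equal(roi$length_um, 100)
  # corridor about 6 px wide (+-1 px rasterization)
  widths <- colSums(roi$mask[, 30:180])
  expect_true(all(abs(widths - 6) <= 1))

  # L-shaped 60 + 80 um trace
  polyL <- cbind(r = c(10, 10, 10 + 80 / px), c = c(5, 5 + 60 / px, 5 + 60 / px))
  roiL <- dilate_trace(polyL, width_um = 3, pixel_size_um = px, dim_px = c(200, 200))
  expect_equal(roiL$length_um, 140)

  expect_error(
    dilate_trace(matrix(c(1, 1), 1, 2), 3, px, c(10, 10)),
    "degenerate"
  )
})

test_that("physical quantities are invariant to pixel-size changes", {
  poly <- cbind(r = c(20, 80), c = c(20, 90))
  a <- dilate_trace(poly, 3, pixel_size_um = 1, dim_px = c(100, 100))
  poly2 <- poly * 2
  b <- dilate_trace(poly2, 3, pixel_size_um = 0.5, dim_px = c(200, 200))
  expect_equal(b$length_um, a$length_um, tolerance = 1e-9)
  expect_equal(
    sum(b$mask) * 0.5^2 / (sum(a$mask) * 1^2), 1,
    tolerance = 0.05
  )
})

test_that("foci segmentation finds planted foci and applies the area rule", {
  f <- gen_synapse_field(600, foci_per_um = 0.5, seed = 8)
  trace <- dilate_trace(attr(f$truth, "trace"),
    width_um = 3,
    pixel_size_um = f$image$pixel_size_um,
    dim_px = dim(f$image)
  )
  # uniform image: zero foci
  u <- micrograph(list(bassoon = matrix(3, nrow(trace$mask), ncol(trace$mask))),
    pixel_size_um = f$image$pixel_size_um
  )
  expect_equal(nrow(segment_foci(u, trace)), 0)

  foci <- segment_foci(f$image, trace)
  expect_lt(abs(nrow(foci) - nrow(f$truth)) / nrow(f$truth), 0.1)

  # a single 1-px bright pixel is excluded (area not > 1 px)
  m <- matrix(0, 64, 64)
  m[32, 30] <- 100
  tr <- dilate_trace(cbind(r = c(32, 32), c = c(5, 60)),
    width_um = 3,
    pixel_size_um = 0.5, dim_px = c(64, 64)
  )
  one_px <- micrograph(list(bassoon = m), pixel_size_um = 0.5)
  expect_equal(nrow(segment_foci(one_px, tr)), 0)
  # whereas a 2x2 blob passes
  m2 <- matrix(0, 64, 64)
  m2[31:32, 30:31] <- 100
  blob <- micrograph(list(bassoon = m2), pixel_size_um = 0.5)
  expect_equal(nrow(segment_foci(blob, tr)), 1)
})

test_that("focus counts are monotone in area and threshold levels", {
  f <- gen_synapse_field(400, foci_per_um = 0.5, seed = 13)
  trace <- dilate_trace(attr(f$truth, "trace"),
    width_um = 3,
    pixel_size_um = f$image$pixel_size_um, dim_px = dim(f$image)
  )
  base <- segment_foci(f$image, trace)
  th <- attr(base, "params")$threshold
  counts_area <- vapply(
    c(2, 4, 8, 16),
    function(a) nrow(segment_foci(f$image, trace, min_area_px = a)), numeric(1)
  )
  expect_true(all(diff(counts_area) <= 0))
  counts_th <- vapply(
    th * c(1, 2, 4, 8),
    function(t) nrow(segment_foci(f$image, trace, threshold = t)), numeric(1)
  )
  expect_true(all(diff(counts_th) <= 0))
})

test_that("aSyn classification separates the planted classes", {
  f <- gen_synapse_field(800,
    foci_per_um = 0.5, asyn_pos_fraction = 0.5,
    seed = 17
  )
  trace <- dilate_trace(attr(f$truth, "trace"),
    width_um = 3,
    pixel_size_um = f$image$pixel_size_um, dim_px = dim(f$image)
  )
  foci <- segment_foci(f$image, trace)
  cls <- classify_foci(foci, f$image)
  # infinite threshold: no positives
  none <- classify_foci(foci, f$image, threshold_rule = Inf)
  expect_equal(sum(none$asyn_pos), 0)
  expect_equal(attr(none, "asyn_threshold")$rule, "fixed")
  # match detected foci to nearest planted focus and score label accuracy
  nearest <- vapply(seq_len(nrow(cls)), function(i) {
    which.min((f$truth$r - cls$r[i])^2 + (f$truth$c - cls$c[i])^2)
  }, numeric(1))
  acc <- mean(cls$asyn_pos == f$truth$asyn_pos[nearest])
  expect_gte(acc, 0.95)
  expect_equal(attr(cls, "asyn_threshold")$rule, "otsu")

  # one-class input with a data-driven rule is flagged as degenerate
  f1 <- gen_synapse_field(400,
    foci_per_um = 0.5, asyn_pos_fraction = 1,
    seed = 18
  )
  tr1 <- dilate_trace(attr(f1$truth, "trace"),
    width_um = 3,
    pixel_size_um = f1$image$pixel_size_um, dim_px = dim(f1$image)
  )
  fo1 <- segment_foci(f1$image, tr1)
  expect_warning(classify_foci(fo1, f1$image), "one-class|separate")
})
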
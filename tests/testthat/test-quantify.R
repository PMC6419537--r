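make_stack <- function(arrs, voxel_size = c(0.3, 0.1, 0.1), ...) {
  voxel_stack(arrs, voxel_size = voxel_size, ...)
}

test_that("background subtraction removes a constant offset and clips at zero", {
  d <- c(3, 4, 4)
  bg <- array(FALSE, d); bg[, , 1] <- TRUE
  s <- make_stack(list(gfp = array(10, d), surface = array(10, d),
                       cilium = array(10, d)))
  sub <- subtract_background(s, region_set(list(background = bg)))
  expect_true(all(sub$channels$gfp == 0))
  expect_equal(unname(sub$meta$background), rep(10, 3))
  # value below background clips to zero instead of going negative
  s2 <- make_stack(list(gfp = array(5, d), surface = array(5, d),
                        cilium = array(5, d)))
  bg10 <- s
  sub2 <- subtract_background(s2, region_set(list(background = bg)))
  expect_true(all(sub2$channels$gfp == 0))
})

test_that("background estimated from neighbours is within 3 counts of truth", {
  # configured background 100; the post-subtraction mean over an
  # independent empty region must sit near zero
  pr <- fast_profile()
  im <- pr$imaging
  im$background_level <- 100
  vox <- voxelize_cell(pr$geometry, im$voxel_size)
  errs <- sapply(1:10, function(s) {
    im$seed <- s
    r <- render_stack(pr$geometry, state_5pct(), im, vox = vox)
    bg_all <- truth_background_mask(r$truth, 1.0)
    idx <- which(bg_all)
    half <- seq_along(idx) %% 2 == 0
    est_region <- array(FALSE, dim(bg_all)); est_region[idx[half]] <- TRUE
    check_region <- array(FALSE, dim(bg_all)); check_region[idx[!half]] <- TRUE
    sub <- subtract_background(r$stack,
                               region_set(list(background = est_region)))
    # unclipped residual in the independent region
    mean(r$stack$channels$gfp[check_region]) - sub$meta$background[["gfp"]]
  })
  expect_true(all(abs(errs) < 3))
})

test_that("subtracting background twice is idempotent over empty regions", {
  pr <- fast_profile(seed = 30)
  r <- render_fast(state_5pct(), seed = 30)
  regions <- region_set(list(background = truth_background_mask(r$truth, 1.0)))
  sub1 <- subtract_background(r$stack, regions)
  sub2 <- subtract_background(sub1, regions)
  # second background estimate is the clipped residual: a small positive value
  expect_lt(sub2$meta$background[["gfp"]], 1.5)
})

test_that("segmentation recovers the true cilium against imaging noise", {
  im <- imaging_params(seed = 41)
  g <- cell_geometry()
  r <- render_stack(g, state_5pct(), im)
  regions <- region_set(list(background = truth_background_mask(r$truth)))
  sub <- subtract_background(r$stack, regions)
  mask <- segment_cilium(sub$channels$cilium, im$voxel_size, r$truth$apical_z)
  truth_mask <- r$truth$labels == ciliarrival:::LABELS[["cilium"]]
  dim(truth_mask) <- dim(r$truth$labels)
  expect_gt(jaccard(mask, truth_mask), 0.5)
})

test_that("an all-zero marker channel yields an empty mask", {
  mask <- segment_cilium(array(0, c(5, 8, 8)), c(0.3, 0.1, 0.1), apical_z = 1)
  expect_false(any(mask))
})

test_that("intracellular marker signal below the apical plane is rejected", {
  # two bright components: a large blob below the apical plane (cytoplasmic
  # acetylated tubulin) and a smaller protruding one (the cilium)
  d <- c(20, 16, 16)
  ch <- array(0, d)
  ch[3:7, 4:8, 4:8] <- 500          # intracellular blob, z < apical
  ch[12:18, 10, 10] <- 400          # protruding column, z > apical
  apical_z <- 10 * 0.3              # 3 um; blob tops out at 2.1 um
  mask <- segment_cilium(ch, c(0.3, 0.1, 0.1), apical_z)
  ai <- which(mask, arr.ind = TRUE)
  expect_true(all(ai[, 1] >= 12))
  expect_equal(sum(mask), 7)
})

test_that("cilium QC enforces protrusion and tilt", {
  vs <- c(0.3, 0.1, 0.1)
  d <- c(30, 20, 20)
  apical_z <- 3
  # vertical 3 um cilium above the apical plane: passes
  up <- array(FALSE, d); up[11:20, 10, 10] <- TRUE
  qc <- cilium_qc(up, apical_z, vs)
  expect_true(qc$qc_pass)
  expect_lt(qc$tilt, 10)
  # cilium lying in the apical plane: fails as sharply tilted
  flat <- array(FALSE, d); flat[11, 10, 3:18] <- TRUE
  qc2 <- cilium_qc(flat, apical_z, vs)
  expect_false(qc2$qc_pass)
  expect_equal(qc2$qc_reason, "sharply tilted")
  # no cilium at all
  qc3 <- cilium_qc(array(FALSE, d), apical_z, vs)
  expect_false(qc3$qc_pass)
  expect_equal(qc3$qc_reason, "no cilium detected")
  # protruding but too short
  stub <- array(FALSE, d); stub[11:12, 10, 10] <- TRUE
  qc4 <- cilium_qc(stub, apical_z, vs, min_protrusion = 1)
  expect_false(qc4$qc_pass)
  expect_equal(qc4$qc_reason, "insufficient protrusion")
})

test_that("MCC follows its defining sum exactly", {
  # all reporter inside the mask
  ch <- array(0, c(4, 5, 5)); m <- array(FALSE, c(4, 5, 5))
  ch[2, 2, 2] <- 7; m[2, 2, 2] <- TRUE
  expect_equal(manders_mcc(ch, m), 1)
  # uniform reporter: MCC is the voxel-count fraction
  u <- array(1, c(4, 5, 5))
  m2 <- array(FALSE, c(4, 5, 5)); m2[1, 1, 1:5] <- TRUE
  expect_equal(manders_mcc(u, m2), 5 / 100)
  expect_error(manders_mcc(array(0, c(2, 2, 2)), m2[1:2, 1:2, 1:2, drop = FALSE]),
               "undefined")
})

test_that("uniform delivery over a 1/2700 volume ratio stays below 4e-4", {
  n <- 2700
  gfp <- array(1, dim = c(n, 1, 1))
  mask <- array(FALSE, dim = c(n, 1, 1)); mask[1, 1, 1] <- TRUE
  mcc <- manders_mcc(gfp, mask)
  expect_equal(mcc, 1 / 2700, tolerance = 1e-12)
  expect_equal(round(mcc, 6), 3.7e-4)
  expect_lt(mcc, 4e-4)
})

test_that("MCC equals the double-loop oracle and is additive over disjoint masks", {
  set.seed(55)
  for (i in 1:4) {
    d <- c(sample(4:20, 1), sample(4:20, 1), sample(4:20, 1))
    gfp <- array(pmax(rnorm(prod(d), 5, 4), 0), dim = d)
    m1 <- array(runif(prod(d)) < 0.1, dim = d)
    m2 <- array(runif(prod(d)) < 0.1, dim = d) & !m1
    cmask <- array(runif(prod(d)) < 0.8, dim = d)
    expect_equal(manders_mcc(gfp, m1, cmask),
                 oracle_mcc(gfp, m1, cmask), tolerance = 1e-12)
    expect_equal(manders_mcc(gfp, m1 | m2, cmask),
                 manders_mcc(gfp, m1, cmask) + manders_mcc(gfp, m2, cmask),
                 tolerance = 1e-12)
    mcc <- manders_mcc(gfp, m1, cmask)
    expect_gte(mcc, 0); expect_lte(mcc, 1)
  }
})

test_that("surface-to-total ratio has the forced endpoints", {
  d <- c(4, 5, 5)
  gfp <- array(runif(prod(d), 1, 5), dim = d)
  cmask <- array(TRUE, dim = d)
  expect_equal(surface_total_ratio(array(0, d), gfp, cmask), 0)
  expect_equal(surface_total_ratio(gfp, gfp, cmask), 1)
  expect_error(surface_total_ratio(gfp, array(0, d), cmask), "undefined")
})

test_that("surface ratio recovers the true stained-side fraction", {
  # 30 % of the reporter on the apical surface (incl. cilium), equal gains
  st <- compartment_state(fractions = c(er = 0.3, apical = 0.27,
                                        basolateral = 0.4, cilium = 0.03))
  pr <- fast_profile(voxel_size = c(0.3, 0.2, 0.2))
  vox <- voxelize_cell(pr$geometry, pr$imaging$voxel_size)
  ratios <- sapply(1:10, function(s) {
    im <- pr$imaging; im$seed <- 60 + s
    r <- render_stack(pr$geometry, st, im, stained_side = "apical", vox = vox)
    q <- quantify_cell(r$stack, settings = pr$settings, truth = r$truth)
    q$surface_ratio
  })
  expect_equal(mean(ratios), 0.30, tolerance = 0.02 / 0.30)
})

test_that("quantify_cell orchestrates QC, MCC and ratios coherently", {
  pr <- fast_profile(voxel_size = c(0.3, 0.2, 0.2))
  vox <- voxelize_cell(pr$geometry, pr$imaging$voxel_size)
  # nothing released, no leak: surface ratio ~ 0
  st0 <- compartment_state(time = 0)
  im <- pr$imaging; im$seed <- 71
  r0 <- render_stack(pr$geometry, st0, im, stained_side = "apical", vox = vox)
  q0 <- quantify_cell(r0$stack, settings = pr$settings, truth = r0$truth)
  expect_lt(q0$surface_ratio, 0.02)
  if (q0$qc_pass) expect_lt(q0$mcc, 0.005)
  # sharply tilted cilium: QC fails, mcc empty, ratio still reported
  gt <- cell_geometry(cilium_tilt = 80, neighbor_ring_width = 1.6,
                      margin = 0.8)
  imt <- pr$imaging; imt$seed <- 72
  rt <- render_stack(gt, state_5pct(), imt, stained_side = "apical")
  qt <- quantify_cell(rt$stack, settings = pr$settings, truth = rt$truth)
  expect_false(qt$qc_pass)
  expect_true(is.na(qt$mcc))
  expect_gt(qt$surface_ratio, 0.3)
  df <- as.data.frame(qt)
  expect_true(is.na(df$mcc))
  expect_match(df$qc_reason, "tilted|protrusion")
  # channel-map validation
  expect_error(quantify_cell(r0$stack,
                             settings = quant_settings(channel_map = c(
                               gfp = "gfp", surface = "missing",
                               cilium = "cilium")),
                             truth = r0$truth),
               "absent")
})

test_that("recovered ciliary and surface fractions track ground truth within 15%", {
  pr <- fast_profile(voxel_size = c(0.3, 0.2, 0.2))
  vox <- voxelize_cell(pr$geometry, pr$imaging$voxel_size)
  st <- state_5pct()
  res <- sapply(1:10, function(s) {
    im <- pr$imaging; im$seed <- 80 + s
    side <- if (s %% 2 == 0) "apical" else "basolateral"
    r <- render_stack(pr$geometry, st, im, stained_side = side, vox = vox)
    q <- quantify_cell(r$stack, settings = pr$settings, truth = r$truth)
    c(mcc = q$mcc,
      ratio = q$surface_ratio,
      true_ratio = if (side == "apical") st$apical + st$cilium else st$basolateral)
  })
  expect_equal(mean(res["mcc", ]), st$cilium, tolerance = 0.15)
  rel <- res["ratio", ] / res["true_ratio", ]
  expect_lt(max(abs(rel - 1)), 0.15)
})
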
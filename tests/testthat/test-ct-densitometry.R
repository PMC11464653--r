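test_that("HU values classify into the printed aeration compartments", {
  cases <- list(
    list(hu = -1000, lab = "hyper"), list(hu = -950, lab = "hyper"),
    list(hu = -901, lab = "hyper"), list(hu = -900, lab = "normal"),
    list(hu = -900.5, lab = "normal"), # sub-integer boundary convention
    list(hu = -501, lab = "normal"), list(hu = -500, lab = "poor"),
    list(hu = -101, lab = "poor"), list(hu = -100, lab = "non"),
    list(hu = 0, lab = "non"), list(hu = 100, lab = "non"),
    list(hu = 150, lab = "out_of_range"), list(hu = -1001, lab = "out_of_range")
  )
  for (cs in cases) expect_identical(classify_hu(cs$hu), cs$lab)
  expect_error(classify_hu(NaN), "non-finite")
})

test_that("gas/tissue decomposition is linear in HU with the clipping contract", {
  expect_equal(voxel_gas_tissue(-1000), list(gas = 1, tissue = 0))
  expect_equal(voxel_gas_tissue(0), list(gas = 0, tissue = 1))
  expect_equal(voxel_gas_tissue(-500), list(gas = 0.5, tissue = 0.5))
  # above water density: pure tissue, gas zero
  expect_equal(voxel_gas_tissue(60), list(gas = 0, tissue = 1))
  # gas + tissue is a partition for any clipped HU
  hu <- seq(-1100, 200, by = 7)
  gt <- voxel_gas_tissue(hu)
  expect_true(all(abs(gt$gas + gt$tissue - 1) < 1e-12))
})

test_that("quantify reproduces uniform-field arithmetic", {
  # 100 mm3-voxel box at -500 HU: volume 0.1 mL per 100 voxels etc.
  b <- box_ct(function(i, j, k) -500, shape = c(10L, 10L, 10L),
              spacing = c(1, 1, 1))
  r <- quantify(b$ct, b$mask)
  expect_equal(r$volume_ml, 1)
  expect_equal(r$gas_ml, 0.5)
  expect_equal(r$weight_g, 0.5)
  expect_equal(r$f_poor, 1)
  b2 <- box_ct(function(i, j, k) -950, shape = c(6L, 6L, 6L))
  r2 <- quantify(b2$ct, b2$mask)
  expect_equal(r2$f_hyper, 1)
  expect_equal(r2$f_normal + r2$f_poor + r2$f_non, 0)
})

test_that("quantify matches the naive per-voxel oracle on random phantoms", {
  set.seed(11)
  for (rep in 1:20) {
    shape <- sample(8:32, 3, replace = TRUE)
    p <- phantom_ct_params(
      shape = shape, spacing = runif(3, 0.8, 3),
      base_hu = runif(1, -800, -250), vd_slope = runif(1, 0, 300),
      edema_shift = runif(1, 0, 250), noise_sd = runif(1, 0, 40),
      lung_centers = rbind(c(0.5, 0.5, 0.3), c(0.5, 0.5, 0.7)),
      lung_semiaxes = rbind(c(0.4, 0.4, 0.18), c(0.4, 0.4, 0.18)),
      seed = rep)
    ph <- gen_ct_phantom(p)
    got <- quantify(ph$ct, ph$mask)
    want <- naive_quantify(ph$ct, ph$mask)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9,
                   label = sprintf("%s (rep %d)", f, rep))
    }
  }
})

test_that("compartment fractions partition and gas+mass conserves volume", {
  set.seed(21)
  for (rep in 1:8) {
    ph <- gen_ct_phantom(phantom_ct_params(
      shape = c(24L, 20L, 16L), base_hu = runif(1, -700, -350),
      edema_shift = runif(1, 0, 200), noise_sd = runif(1, 0, 30), seed = rep))
    r <- quantify(ph$ct, ph$mask)
    expect_equal(r$f_hyper + r$f_normal + r$f_poor + r$f_non, 1, tolerance = 1e-12)
    expect_lt(abs(r$gas_ml + r$weight_g / 1.0 - r$volume_ml) / r$volume_ml, 0.005)
    # noiseless truth conserves to 1e-6 mL
    expect_lt(abs(ph$truth$gas_volume_ml + ph$truth$weight_g / 1.0 -
                  ph$truth$lung_volume_ml), 1e-6)
  }
})

test_that("mean lung density is the area-weighted slice mean", {
  b <- box_ct(function(i, j, k) -400)
  expect_equal(mean_lung_density(b$ct, b$mask), -400)
  # two equal-area slices at -600 and -200
  sh <- c(2L, 4L, 4L)
  b2 <- box_ct(function(i, j, k) if (i == 1) -600 else -200, shape = sh)
  expect_equal(mean_lung_density(b2$ct, b2$mask), -400)
  # slice areas 2:1 at -600/-300 -> (2*-600 + 1*-300)/3 = -500
  hu <- array(-600, c(2, 2, 3))
  hu[2, , ] <- -300
  m <- array(TRUE, c(2, 2, 3))
  m[2, 1, ] <- FALSE # slice 1: 6 voxels at -600; slice 2: 3 at -300 (areas 2:1)
  ct <- ct_volume(hu)
  expect_equal(mean_lung_density(ct, lung_mask(m)), -500)
})

test_that("gravitational bands follow the density gradient and the gradient formula", {
  # linear ventro-dorsal field on a box: thirds have analytic means
  sh <- c(6L, 30L, 6L)
  b <- box_ct(function(i, j, k) -700 + (j - 1) / 29 * 300, shape = sh)
  prof <- gravitational_profile(b$ct, b$mask)
  expect_identical(prof$band, c("ventral", "ventro-dorsal", "dorsal"))
  # ventral third: rows 1..10, mean hu = -700 + mean(0:9)/29*300
  analytic <- sapply(list(0:9, 10:19, 20:29), function(r) -700 + mean(r) / 29 * 300)
  expect_equal(prof$mean_hu, analytic, tolerance = 0.5 / 700)
  expect_true(prof$mean_hu[3] > prof$mean_hu[1]) # dorsal denser
  expect_equal(sum(prof$n_voxels), sum(b$mask$mask))
  # homogeneous lung: zero gradient
  bh <- box_ct(function(i, j, k) -600)
  expect_equal(ventrodorsal_gradient(gravitational_profile(bh$ct, bh$mask)), 0)
  # hand-built profiles
  mk <- function(v, d) {
    data.frame(band = c("ventral", "ventro-dorsal", "dorsal"),
               mean_hu = c(v, (v + d) / 2, d))
  }
  expect_equal(ventrodorsal_gradient(mk(-600, -300)), 50)
  expect_equal(ventrodorsal_gradient(mk(-800, -200)), 75)
  expect_error(ventrodorsal_gradient(mk(0, -200)), "zero")
})

test_that("slope phantoms put the densest, least aerated tissue dorsally", {
  ph <- gen_ct_phantom(phantom_ct_params(shape = c(24L, 24L, 16L),
                                         vd_slope = 300, edema_shift = 150,
                                         noise_sd = 0, seed = 2))
  prof <- gravitational_profile(ph$ct, ph$mask)
  expect_true(prof$mean_hu[3] > prof$mean_hu[2])
  expect_true(prof$mean_hu[2] > prof$mean_hu[1])
  expect_gt(prof$f_poor[3] + prof$f_non[3], prof$f_poor[1] + prof$f_non[1])
  expect_gt(ventrodorsal_gradient(prof), 0)
})

test_that("slice selection spans the mask with n evenly spaced unique slices", {
  m <- array(FALSE, c(100, 4, 4)); m[1:91, , ] <- TRUE
  idx <- select_slices(lung_mask(m), n = 10)
  expect_equal(idx, seq(1, 91, by = 10)) # 0..90 in 0-based terms
  m2 <- array(FALSE, c(20, 4, 4)); m2[6:15, , ] <- TRUE
  expect_equal(select_slices(lung_mask(m2), n = 10), 6:15) # span exactly 10
  m3 <- array(TRUE, c(10, 4, 4))
  expect_equal(select_slices(lung_mask(m3), n = 10), 1:10)
  expect_error(select_slices(lung_mask(m3), n = 12), "smaller n")
  # collapsing duplicates backfills to exactly n unique slices
  m4 <- array(FALSE, c(30, 4, 4)); m4[3:15, , ] <- TRUE
  idx4 <- select_slices(lung_mask(m4), n = 10)
  expect_length(idx4, 10)
  expect_false(any(duplicated(idx4)))
  expect_true(all(idx4 >= 3 & idx4 <= 15))
})

test_that("ten-slice extrapolation is exact for constant and linear profiles", {
  # constant cranio-caudal profile
  b <- box_ct(function(i, j, k) -500, shape = c(40L, 10L, 10L), spacing = c(2, 2, 2))
  full <- quantify(b$ct, b$mask)
  sl <- select_slices(b$mask, 10)
  qs <- quantify_slices(b$ct, b$mask, sl)
  est <- extrapolate_whole_lung(qs$reports, qs$positions_mm, qs$thickness_mm)
  expect_equal(est$gas_ml, full$gas_ml, tolerance = 1e-9)
  expect_equal(est$weight_g, full$weight_g, tolerance = 1e-9)
  expect_equal(est$mean_hu, full$mean_hu, tolerance = 1e-9)
  # linear cranio-caudal density profile: trapezoid on linear integrand
  bl <- box_ct(function(i, j, k) -700 + (i - 1) * 8, shape = c(40L, 10L, 10L),
               spacing = c(2, 2, 2))
  fulll <- quantify(bl$ct, bl$mask)
  qsl <- quantify_slices(bl$ct, bl$mask, select_slices(bl$mask, 10))
  estl <- extrapolate_whole_lung(qsl$reports, qsl$positions_mm, qsl$thickness_mm)
  expect_lt(abs(estl$gas_ml / fulll$gas_ml - 1), 0.005)
  expect_lt(abs(estl$weight_g / fulll$weight_g - 1), 0.005)
})

test_that("ten-slice extrapolation tracks the full computation on a smooth phantom", {
  ph <- gen_ct_phantom(phantom_ct_params(shape = c(64L, 32L, 24L),
                                         spacing = c(2, 3, 3), noise_sd = 0,
                                         vd_slope = 200, seed = 5))
  full <- quantify(ph$ct, ph$mask)
  sl <- select_slices(ph$mask, 10)
  qs <- quantify_slices(ph$ct, ph$mask, sl)
  est <- extrapolate_whole_lung(qs$reports, qs$positions_mm, qs$thickness_mm)
  expect_lt(abs(est$gas_ml / full$gas_ml - 1), 0.03)
  expect_lt(abs(est$weight_g / full$weight_g - 1), 0.03)
  expect_lt(abs(est$volume_ml / full$volume_ml - 1), 0.03)
})

test_that("CRALE criterion is inclusive at -500 HU", {
  mk <- function(mu) list(mean_hu = mu)
  expect_true(detect_crale(mk(-324)))  # post-resuscitation regime
  expect_false(detect_crale(mk(-549))) # baseline regime
  expect_true(detect_crale(mk(-500)))  # boundary, inclusive
  expect_false(detect_crale(mk(-501)))
})

test_that("quantify is invariant under axis permutation with re-declared roles", {
  ph <- gen_ct_phantom(phantom_ct_params(shape = c(20L, 18L, 14L), seed = 9))
  ref <- quantify(ph$ct, ph$mask)
  perm <- c(3, 1, 2) # new axis p[i] holds old axis i
  hu_p <- aperm(ph$ct$hu, order(perm))
  roles <- ph$ct$axes
  roles_p <- c(cc = perm[roles[["cc"]]], vd = perm[roles[["vd"]]],
               lr = perm[roles[["lr"]]])
  ct_p <- ct_volume(hu_p, spacing = ph$ct$spacing[order(perm)], axes = roles_p)
  mask_p <- lung_mask(aperm(ph$mask$mask, order(perm)))
  got <- quantify(ct_p, mask_p)
  for (f in c("volume_ml", "gas_ml", "weight_g", "mean_hu",
              "f_hyper", "f_normal", "f_poor", "f_non")) {
    expect_equal(got[[f]], ref[[f]], tolerance = 1e-12, label = f)
  }
  prof_ref <- gravitational_profile(ph$ct, ph$mask)
  prof_p <- gravitational_profile(ct_p, mask_p)
  expect_equal(prof_p$mean_hu, prof_ref$mean_hu, tolerance = 1e-12)
})

test_that("error contracts: empty mask, shape mismatch, boundary overlap", {
  ph <- gen_ct_phantom(phantom_ct_params(shape = c(12L, 12L, 10L), seed = 1))
  expect_error(lung_mask(array(FALSE, dim(ph$ct$hu))), "empty")
  bad_mask <- lung_mask(array(TRUE, c(5, 5, 5)))
  expect_error(quantify(ph$ct, bad_mask), "shape")
  expect_error(gen_ct_phantom(phantom_ct_params(
    lung_centers = rbind(c(0.5, 0.9, 0.3), c(0.5, 0.5, 0.7)))),
    "ventro-dorsal")
})
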
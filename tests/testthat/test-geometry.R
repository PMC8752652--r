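# Shape descriptors, Zernike moments and generic Fourier descriptors:
# closed forms, symmetry identities and invariance properties.

test_that("a filled square has its closed-form shape descriptors", {
  mask <- matrix(FALSE, 20, 20)
  mask[6:15, 4:13] <- TRUE
  sf <- compute_shape_features(crop_roi(matrix(0, 20, 20), mask)$mask)
  expect_equal(sf[["Area"]], 100)
  expect_equal(sf[["Extent"]], 1)
  expect_equal(sf[["Solidity"]], 1)
  expect_equal(sf[["Euler_Number"]], 1)
  expect_equal(sf[["Filled_Area"]], 100)
  expect_equal(sf[["Equiv_Diameter"]], sqrt(400 / pi))
  expect_equal(sf[["Perimeter"]], 36)  # 8-connected trace of a 10x10 square
  expect_equal(sf[["Eccentricity"]], 0)
  expect_equal(sf[["Major_Axis_Length"]], sf[["Minor_Axis_Length"]])
})

test_that("a square annulus has Euler number 0 and a larger filled area", {
  mask <- matrix(FALSE, 20, 20)
  mask[4:16, 4:16] <- TRUE
  mask[7:13, 7:13] <- FALSE
  sf <- compute_shape_features(mask)
  expect_equal(sf[["Euler_Number"]], 0)
  expect_gt(sf[["Filled_Area"]], sf[["Area"]])
  expect_equal(sf[["Filled_Area"]], 13 * 13)
  # two disjoint squares: Euler number 2
  two <- matrix(FALSE, 20, 20)
  two[2:6, 2:6] <- TRUE
  two[12:18, 12:18] <- TRUE
  expect_equal(compute_shape_features(two)[["Euler_Number"]], 2)
  expect_error(compute_shape_features(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("solidity equals the brute-force convex-hull pixel ratio", {
  skip_if_not_installed("pracma")
  for (seed in 1:3) {
    mask <- blob_mask(48, seed = seed)
    sf <- compute_shape_features(mask)
    idx <- which(mask, arr.ind = TRUE)
    h <- grDevices::chull(idx[, 2], idx[, 1])
    hull <- idx[h, ]
    centers <- expand.grid(r = seq_len(48), c = seq_len(48))
    inhull <- pracma::inpolygon(centers$c, centers$r,
                                hull[, 2], hull[, 1], boundary = TRUE)
    expect_equal(sf[["Solidity"]], sum(mask) / sum(inhull))
    expect_lte(sf[["Solidity"]], 1)
  }
})

test_that("shape invariants hold on generated masks", {
  for (seed in 4:6) {
    mask <- blob_mask(64, seed = seed)
    sf <- compute_shape_features(mask)
    expect_gt(sf[["Solidity"]], 0)
    expect_lte(sf[["Solidity"]], 1)
    expect_gt(sf[["Extent"]], 0)
    expect_lte(sf[["Extent"]], 1)
    expect_gte(sf[["Eccentricity"]], 0)
    expect_lt(sf[["Eccentricity"]], 1)
    expect_gte(sf[["Perimeter_Cirratio"]], 0.95)
    expect_gt(sf[["Orientation"]], -90 - 1e-9)
    expect_lte(sf[["Orientation"]], 90)
  }
})

test_that("Zernike moments vanish and pair up as disk symmetry dictates", {
  disk <- disk_mask(64)
  z <- compute_zernike_moments(disk)
  expect_lte(z[["F60_ZM1-1"]], 1e-6 * z[["F59_ZM00"]])
  for (seed in 1:3) {
    zb <- compute_zernike_moments(blob_mask(64, seed = seed))
    # conjugate pairs are exactly equal for a real-valued image
    expect_equal(zb[["F60_ZM1-1"]], zb[["F61_ZM11"]])
    expect_equal(zb[["F66_ZM3-1"]], zb[["F67_ZM31"]])
    expect_equal(zb[["F70_ZM4-2"]], zb[["F72_ZM42"]])
  }
})

test_that("Zernike magnitudes are rotation-invariant within 2%", {
  mask <- blob_mask(72, seed = 9)
  rot90 <- t(mask)[ncol(mask):1, ]
  z1 <- compute_zernike_moments(mask)
  z2 <- compute_zernike_moments(rot90)
  scale <- max(z1)
  expect_true(all(abs(z1 - z2) <= 0.02 * pmax(z1, 0.05 * scale)))
})

test_that("generic Fourier descriptors are normalized, translation- and rotation-invariant", {
  mask <- blob_mask(64, seed = 11)
  fd <- compute_gfd(mask)
  expect_length(fd, 52)
  expect_true(all(fd >= 0))
  expect_equal(fd[["F74_FD1"]], 1)  # |PF(0,0)| / area for a binary mask

  # translation by (17, -9): embed in a larger frame at two offsets
  big1 <- matrix(FALSE, 120, 120); big1[11:74, 21:84] <- mask
  big2 <- matrix(FALSE, 120, 120); big2[28:91, 12:75] <- mask
  expect_equal(compute_gfd(big1), compute_gfd(big2), tolerance = 1e-6)

  rot90 <- t(mask)[ncol(mask):1, ]
  f1 <- compute_gfd(mask)
  f2 <- compute_gfd(rot90)
  expect_true(all(abs(f1 - f2) <= 0.02 * pmax(f1, 0.05)))
})

test_that("the geometry block emits exactly 80 values in catalog order", {
  v <- compute_geometry_features(
    lesion_sample(matrix(0, 48, 48), blob_mask(48, seed = 2)))
  expect_length(v, 80)
  expect_equal(names(v), feature_catalog()$column[46:125])
})
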
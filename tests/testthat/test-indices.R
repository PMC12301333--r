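test_that("mtv is additive and zero on the empty set", {
  # 100 voxels at 4 mm isotropic -> 6.4 mL
  vox <- unname(as.matrix(expand.grid(0:9, 0:9, 0)))
  ls <- lesionSetFromCoords(list(vox), spacing = c(4, 4, 4),
                            dim = c(12, 12, 3))
  expect_equal(mtv(ls), 6.4)
  vol <- PetVolume(array(1.0, dim = c(4, 4, 4)), c(4, 4, 4))
  empty <- lesionsFromMask(vol, LabelMask(array(0L, dim = c(4, 4, 4)),
                                          c(4, 4, 4)))
  expect_equal(mtv(empty), 0)
  two <- lesionSetFromCoords(list(cbind(0:9, 0, 0), cbind(0:19, 5, 5)),
                             spacing = c(4, 4, 4), dim = c(24, 8, 8))
  expect_equal(mtv(two), sum(lesionStats(two)$volume_ml))
})

test_that("dmax reproduces the 3-4-5 construction and brute force", {
  # centroids (0,0,0) and (300,400,0) mm -> 50 cm
  ls <- lesionSetFromCoords(list(cbind(0, 0, 0), cbind(30, 40, 0)),
                            spacing = c(10, 10, 10), dim = c(32, 42, 2))
  expect_equal(dmax(ls), 50)

  single <- lesionSetFromCoords(list(cbind(0:2, 0, 0)),
                                spacing = c(4, 4, 4), dim = c(4, 2, 2))
  expect_equal(dmax(single), 0)
  prof <- disseminationProfile(single, view = "none")
  expect_true(prof@singleLesion)

  for (s in 201:205) {
    ls <- randomLesionSet(s)
    cent <- metabolicCenter(ls)
    expect_equal(dmax(ls), bruteMaxDist(cent) / 10, tolerance = 1e-12)
  }
  vol <- PetVolume(array(1.0, dim = c(4, 4, 4)), c(4, 4, 4))
  empty <- lesionsFromMask(vol, LabelMask(array(0L, dim = c(4, 4, 4)),
                                          c(4, 4, 4)))
  expect_error(dmax(empty), "empty")
})

test_that("bulk-referenced distances follow their definitions", {
  # bulk at origin, single-voxel lesions 30 and 40 mm away on one axis
  bulk <- unname(as.matrix(expand.grid(0:2, 0:2, 0:2)))
  ls <- lesionSetFromCoords(list(bulk, cbind(31, 1, 1), cbind(41, 1, 1)),
                            spacing = c(1, 1, 1), dim = c(48, 8, 8))
  expect_equal(dmaxBulk(ls), 4.0)
  expect_equal(spreadBulk(ls), 7.0)

  single <- lesionSetFromCoords(list(bulk), spacing = c(1, 1, 1),
                                dim = c(8, 8, 8))
  expect_equal(dmaxBulk(single), 0)
  expect_equal(spreadBulk(single), 0)

  for (s in 211:215) {
    ls <- randomLesionSet(s)
    cent <- metabolicCenter(ls)
    expect_lte(dmaxBulk(ls), dmax(ls))
    expect_equal(spreadBulk(ls), bruteSpreadBulk(cent) / 10,
                 tolerance = 1e-12)
  }
})

test_that("spread_patient is the max per-lesion distance sum", {
  # collinear centroids at x = 0, 10, 100 mm -> sums 110, 100, 190 mm
  ls <- lesionSetFromCoords(list(cbind(0, 0, 0), cbind(10, 0, 0),
                                 cbind(100, 0, 0)),
                            spacing = c(1, 1, 1), dim = c(102, 2, 2))
  expect_equal(spreadPatient(ls), 19.0)

  two <- lesionSetFromCoords(list(cbind(0, 0, 0), cbind(12, 5, 0)),
                             spacing = c(1, 1, 1), dim = c(14, 7, 2))
  expect_equal(spreadPatient(two), dmax(two))

  for (s in 221:225) {
    ls <- randomLesionSet(s)
    cent <- metabolicCenter(ls)
    expect_equal(spreadPatient(ls), bruteSpreadPatient(cent) / 10,
                 tolerance = 1e-12)
    expect_gte(spreadPatient(ls), spreadBulk(ls) - 1e-12)
  }
})

test_that("dmax_vox measures outermost voxels and intra-lesion diameter", {
  ls <- lesionSetFromCoords(list(cbind(0, 0, 0),
                                 rbind(c(10, 0, 0), c(12, 0, 0))),
                            spacing = c(1, 1, 1), dim = c(14, 2, 2))
  expect_equal(dmaxVox(ls), 1.2)

  single <- lesionSetFromCoords(list(cbind(0, 0, 0:90)),
                                spacing = c(1, 1, 1), dim = c(2, 2, 92))
  expect_equal(dmaxVox(single), 9.0)

  for (s in 231:236) {
    ls <- randomLesionSet(s)
    allvox <- do.call(rbind, lesionVoxels(ls))
    pts <- sweep(allvox, 2, voxelSpacing(ls), `*`)
    expect_equal(dmaxVox(ls), bruteMaxDist(pts) / 10, tolerance = 1e-12)
  }
})

test_that("index ordering, rigid-motion invariance and scaling hold", {
  for (s in 241:252) {
    ls <- randomLesionSet(s)
    expect_gte(dmaxVox(ls), dmax(ls) - 1e-12)
    expect_gte(dmax(ls), dmaxBulk(ls) - 1e-12)
    expect_gte(spreadBulk(ls), dmaxBulk(ls) - 1e-12)
    expect_gte(spreadPatient(ls), spreadBulk(ls) - 1e-12)

    # translation invariance (whole-voxel shift)
    shifted <- lesionSetFromCoords(
      lapply(lesionVoxels(ls), function(v) sweep(v, 2, c(3, 2, 1), `+`)),
      spacing = voxelSpacing(ls), dim = ls@dim + 4L,
      suvPerLesion = ls@suv)
    expect_equal(dmax(shifted), dmax(ls), tolerance = 1e-9)
    expect_equal(dmaxVox(shifted), dmaxVox(ls), tolerance = 1e-9)

    # axis permutation invariance
    perm <- c(2, 3, 1)
    permuted <- lesionSetFromCoords(
      lapply(lesionVoxels(ls), function(v) v[, perm, drop = FALSE]),
      spacing = voxelSpacing(ls)[perm], dim = ls@dim[perm],
      suvPerLesion = ls@suv)
    expect_equal(dmax(permuted), dmax(ls), tolerance = 1e-9)
    expect_equal(spreadPatient(permuted), spreadPatient(ls),
                 tolerance = 1e-9)

    # uniform spacing scaling scales distances linearly, leaves none fixed
    scaled <- lesionSetFromCoords(lesionVoxels(ls),
                                  spacing = 2 * voxelSpacing(ls),
                                  dim = ls@dim, suvPerLesion = ls@suv)
    expect_equal(dmax(scaled), 2 * dmax(ls), tolerance = 1e-9)
    expect_equal(dmaxVox(scaled), 2 * dmaxVox(ls), tolerance = 1e-9)
    expect_equal(mtv(scaled), 8 * mtv(ls), tolerance = 1e-9)

    # distance indices ignore SUV rescaling with geometric centroids
    bright <- lesionSetFromCoords(lesionVoxels(ls),
                                  spacing = voxelSpacing(ls), dim = ls@dim,
                                  suvPerLesion = lapply(ls@suv, `*`, 3))
    expect_equal(dmax(bright, mode = "geometric"),
                 dmax(ls, mode = "geometric"), tolerance = 1e-12)
  }
})

test_that("profiles convert to a tidy one-row data.frame", {
  ls <- randomLesionSet(261)
  prof <- disseminationProfile(ls)
  df <- as.data.frame(prof)
  expect_identical(nrow(df), 1L)
  expect_equal(df$mtv_ml, mtv(ls))
  expect_equal(df$dmax_vox_cm, dmaxVox(ls))
  expect_true(df$dmax_voxmip_cm <= df$dmax_vox_cm + 1e-12)
})
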
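test_that("MIP pixels equal per-column maxima in both views", {
  set.seed(301)
  arr <- array(stats::runif(20 * 16 * 24, 0, 5), dim = c(20, 16, 24))
  vol <- PetVolume(arr, c(4, 3, 2))
  cor <- makeMip(vol, "coronal")
  expect_identical(dim(suvData(cor)), c(20L, 24L))
  expect_equal(voxelSpacing(cor), c(4, 2))
  for (i in c(1, 7, 20)) for (k in c(1, 12, 24))
    expect_equal(suvData(cor)[i, k], max(arr[i, , k]))
  sag <- makeMip(vol, "sagittal")
  expect_identical(dim(suvData(sag)), c(16L, 24L))
  for (j in c(1, 9, 16)) for (k in c(2, 13, 23))
    expect_equal(suvData(sag)[j, k], max(arr[, j, k]))
})

test_that("a single hot voxel projects to a single hot pixel", {
  arr <- array(0.5, dim = c(10, 12, 14))
  arr[3, 7, 9] <- 11
  vol <- PetVolume(arr, c(4, 4, 4))
  mip <- makeMip(vol, "coronal")
  expect_equal(which(suvData(mip) == 11, arr.ind = TRUE),
               cbind(row = 3L, col = 9L))
  # uniform volume -> uniform MIP at that constant
  u <- makeMip(PetVolume(array(2.5, dim = c(6, 6, 6)), c(4, 4, 4)))
  expect_true(all(suvData(u) == 2.5))
})

test_that("projection merges lesions separated only along the beam", {
  labs <- array(0L, dim = c(12, 12, 12))
  labs[4:5, 2:3, 4:5] <- 1L
  labs[4:5, 9:10, 4:5] <- 2L   # separated along AP only
  m <- LabelMask(labs, c(4, 4, 4))
  expect_equal(nLesions(projectMask(m, "coronal")), 1L)
  # laterally separated lesions remain two components
  labs2 <- array(0L, dim = c(12, 12, 12))
  labs2[2:3, 4:5, 4:5] <- 1L
  labs2[9:10, 4:5, 4:5] <- 2L
  expect_equal(nLesions(projectMask(LabelMask(labs2, c(4, 4, 4)),
                                    "coronal")), 2L)
})

test_that("projected footprints equal the brute-force projected voxel set", {
  for (s in 311:315) {
    ls <- randomLesionSet(s)
    mask <- asLabelMask(ls)
    mls <- projectMask(mask, "coronal")
    got <- do.call(rbind, lesionVoxels(mls))
    got <- got[order(got[, 1], got[, 2]), ]
    vox <- do.call(rbind, lesionVoxels(ls))
    want <- unique(vox[, c(1, 3)])
    want <- want[order(want[, 1], want[, 2]), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("threshold segmentation of the MIP finds hot components", {
  ph <- makePhantom(dim = c(30, 24, 30), lesions = list(
    list(center = c(60, 48, 60), radii = 12, peak = 10)), seed = 32)
  mip <- makeMip(ph$volume, "coronal")
  hot <- segmentMip(mip, 4.0)
  expect_equal(nLesions(hot), 1L)
  expect_equal(nLesions(segmentMip(mip, 50)), 0L)
  # threshold below background: one giant component (degenerate case)
  low <- segmentMip(mip, 0.2)
  expect_equal(nLesions(low), 1L)
  expect_equal(nrow(lesionVoxels(low)[[1]]), prod(dim(suvData(mip))))
})

test_that("dmax_voxmip arithmetic and the projection bound hold", {
  # two single-pixel components at (0,0) and (30,120) mm
  mk2d <- function(pixList, dims2) {
    new("MipLesionSet", pixels = pixList, pixelSpacing = c(1, 1),
        view = "coronal", mode = "project", dim = as.integer(dims2))
  }
  mls <- mk2d(list(cbind(0L, 0L), cbind(30L, 120L)), c(40, 130))
  expect_equal(dmaxVoxMip(mls), sqrt(30^2 + 120^2) / 10)

  # 3D pair (0,0,0)/(30,40,120) mm: coronal projection drops the 40 mm leg
  labs <- array(0L, dim = c(31, 41, 121))
  labs[1, 1, 1] <- 1L
  labs[31, 41, 121] <- 2L
  vol <- PetVolume(array(1, dim = c(31, 41, 121)) +
                     ifelse(labs > 0, 9, 0), c(1, 1, 1))
  ls <- lesionsFromMask(vol, LabelMask(labs, c(1, 1, 1)))
  expect_equal(dmaxVox(ls), 13.0)
  vmip <- dmaxVoxMip(projectMask(asLabelMask(ls), "coronal"))
  expect_equal(vmip, sqrt(153))
  expect_lt(vmip, dmaxVox(ls))
})

test_that("dmax_voxmip equals brute force over all pixel pairs", {
  for (s in 321:326) {
    ls <- randomLesionSet(s)
    for (view in c("coronal", "sagittal")) {
      mls <- projectMask(asLabelMask(ls), view)
      pix <- do.call(rbind, lesionVoxels(mls))
      pts <- sweep(pix, 2, mls@pixelSpacing, `*`)
      expect_equal(dmaxVoxMip(mls), bruteMaxDist(pts) / 10,
                   tolerance = 1e-12)
      expect_lte(dmaxVoxMip(mls), dmaxVox(ls) + 1e-12)
    }
  }
  # equality when all lesions share one plane orthogonal to the beam
  planar <- lesionSetFromCoords(list(cbind(0:2, 5, 0:2), cbind(20:21, 5, 9)),
                                spacing = c(2, 2, 2), dim = c(24, 8, 12))
  expect_equal(dmaxVoxMip(projectMask(asLabelMask(planar), "coronal")),
               dmaxVox(planar), tolerance = 1e-12)
})

test_that("exclusion regions discount physiologic components", {
  mk2d <- function(pixList, dims2) {
    new("MipLesionSet", pixels = pixList, pixelSpacing = c(4, 4),
        view = "coronal", mode = "project", dim = as.integer(dims2))
  }
  # bladder surrogate near (96-104, 100) mm plus two true lesions
  mls <- mk2d(list(cbind(24:26, 25L), cbind(2L, 2L), cbind(12L, 2L)),
              c(30, 30))
  full <- dmaxVoxMip(mls)
  bladder <- list(c(92, 108, 96, 104))   # covers the 3-pixel component
  excl <- dmaxVoxMip(mls, exclusion_regions = bladder)
  expect_equal(excl, 4.0)
  expect_gt(full, excl)
  everything <- list(c(-1, 130, -1, 130))
  expect_error(dmaxVoxMip(mls, exclusion_regions = everything), "exclusion")
})

test_that("MIP images write to NIfTI and PNG", {
  ph <- makePhantom(dim = c(16, 12, 20), lesions = list(
    list(center = c(32, 24, 40), radii = 8, peak = 6)), seed = 33)
  mip <- makeMip(ph$volume)
  f1 <- tempfile(fileext = ".nii.gz")
  writeMip(mip, f1)
  back <- RNifti::readNifti(f1)
  expect_equal(as.array(back), suvData(mip), ignore_attr = TRUE,
               tolerance = 1e-6)
  f2 <- tempfile(fileext = ".png")
  writeMip(mip, f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
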
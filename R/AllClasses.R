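#' @import methods
NULL

CANONICAL_AXES <- c("LR", "AP", "SI")

#' PetVolume: a 3D PET image in SUV units
#'
#' The geometric substrate of all dissemination indices: a 3D scalar grid of
#' body-weight SUV values with per-axis voxel spacing in mm and anatomical
#' axis labels. After [readVolume()] the grid is always in canonical
#' orientation: axis 1 = left-right (`"LR"`), axis 2 = anterior-posterior
#' (`"AP"`), axis 3 = cranio-caudal (`"SI"`), so the coronal
#' maximum-intensity projection is a fixed-axis reduction over axis 2.
#'
#' Voxel coordinates are 0-based; the physical position of a voxel centre is
#' `index * spacing` mm.
#'
#' @slot data 3D numeric array of SUV values (finite, non-negative).
#' @slot spacing numeric(3), voxel size in mm per grid axis (positive;
#'   anisotropy allowed).
#' @slot axes character(3), permutation of `c("LR","AP","SI")` labelling the
#'   grid axes.
#' @slot meta list of free-form provenance (source path, patient id, ...).
#'
#' @seealso [readVolume()], [makePhantom()], [makeMip()]
#' @export
setClass("PetVolume",
  slots = c(data = "array", spacing = "numeric", axes = "character",
            meta = "list"))

setValidity("PetVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite reals (mm)")
  if (length(object@axes) != 3L || !setequal(object@axes, CANONICAL_AXES))
    msg <- c(msg, "axes must be a permutation of LR/AP/SI")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "SUV values must be finite")
  else if (any(object@data < 0))
    msg <- c(msg, "SUV values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' LabelMask: integer lesion labels on a PET grid
#'
#' Carrier for segmentation output or externally supplied masks: an integer
#' grid with 0 = background and consecutive labels 1..K for lesions, sharing
#' shape, spacing and axis convention with its paired [PetVolume-class].
#'
#' @slot labels 3D integer array (0 = background, k >= 1 = lesion id;
#'   labels consecutive).
#' @slot spacing numeric(3) voxel size in mm.
#' @slot axes character(3) anatomical axis labels, as in [PetVolume-class].
#'
#' @seealso [lesionsFromMask()], [writeMask()], [projectMask()]
#' @export
setClass("LabelMask",
  slots = c(labels = "array", spacing = "numeric", axes = "character"))

setValidity("LabelMask", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive reals (mm)")
  if (length(object@axes) != 3L || !setequal(object@axes, CANONICAL_AXES))
    msg <- c(msg, "axes must be a permutation of LR/AP/SI")
  labs <- object@labels
  if (anyNA(labs) || any(labs < 0) || any(labs != round(labs)))
    msg <- c(msg, "labels must be non-negative integers")
  else {
    present <- sort(unique(labs[labs > 0]))
    if (length(present) && !identical(as.integer(present),
                                      seq_len(length(present))))
      msg <- c(msg, "lesion labels must be consecutive 1..K")
  }
  if (length(msg)) msg else TRUE
})

#' LesionSet: labelled lesions with voxel lists and summary statistics
#'
#' The input to every dissemination index. Lesions are sorted by descending
#' volume (label 1 = bulk lesion; ties broken by higher SUVmax, then lower
#' original label). Per-lesion voxel coordinates are 0-based integer grid
#' indices; SUV-weighted and geometric centroids are available through
#' [metabolicCenter()].
#'
#' @slot stats data.frame, one row per lesion: `label`, `nvox`, `volume_ml`,
#'   `suv_max`, `suv_mean`, and the SUV-weighted centroid `cx_mm`, `cy_mm`,
#'   `cz_mm`.
#' @slot voxels list of n x 3 integer matrices of 0-based voxel indices.
#' @slot suv list of numeric vectors, SUV per voxel (parallel to `voxels`).
#' @slot spacing numeric(3) voxel size in mm.
#' @slot dim integer(3) grid dimensions of the source volume.
#' @slot source character, `"adaptive_threshold"` or `"external_mask"`.
#' @slot params list, segmentation parameters used (may be empty).
#'
#' @seealso [segmentAdaptive()], [lesionsFromMask()], [disseminationProfile()]
#' @export
setClass("LesionSet",
  slots = c(stats = "data.frame", voxels = "list", suv = "list",
            spacing = "numeric", dim = "integer", source = "character",
            params = "list"))

setValidity("LesionSet", function(object) {
  msg <- character()
  k <- nrow(object@stats)
  if (length(object@voxels) != k || length(object@suv) != k)
    msg <- c(msg, "stats, voxels and suv must describe the same lesions")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive reals (mm)")
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive integers")
  if (k > 0) {
    nv <- vapply(object@voxels, nrow, integer(1))
    if (any(nv < 1L)) msg <- c(msg, "every lesion must have >= 1 voxel")
    lin <- unlist(lapply(object@voxels, function(v)
      v[, 1] + object@dim[1] * (v[, 2] + object@dim[2] * v[, 3])))
    if (anyDuplicated(lin)) msg <- c(msg, "lesions must not overlap")
    if (is.unsorted(rev(object@stats$volume_ml)) &&
        any(diff(object@stats$volume_ml) > 1e-9))
      msg <- c(msg, "lesions must be sorted by descending volume")
  }
  if (length(msg)) msg else TRUE
})

#' MipImage: a 2D maximum-intensity projection
#'
#' Each pixel holds the exact maximum of the source volume along the collapsed
#' anatomical axis. The coronal view collapses the anterior-posterior axis
#' (image axes = left-right x cranio-caudal); the sagittal view collapses
#' left-right (image axes = anterior-posterior x cranio-caudal).
#'
#' @slot data 2D numeric matrix of projected SUV.
#' @slot pixelSpacing numeric(2) pixel size in mm for the two retained axes.
#' @slot view `"coronal"` or `"sagittal"`.
#' @slot projectionAxis label of the collapsed anatomical axis
#'   (`"AP"` or `"LR"`).
#'
#' @seealso [makeMip()], [segmentMip()], [dmaxVoxMip()]
#' @export
setClass("MipImage",
  slots = c(data = "matrix", pixelSpacing = "numeric", view = "character",
            projectionAxis = "character"))

setValidity("MipImage", function(object) {
  msg <- character()
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive reals (mm)")
  if (!object@view %in% c("coronal", "sagittal"))
    msg <- c(msg, "view must be coronal or sagittal")
  if (length(msg)) msg else TRUE
})

#' MipLesionSet: 2D labelled lesion footprints on a MIP
#'
#' Produced either by projecting a 3D [LabelMask-class] ([projectMask()]) or
#' by thresholding the MIP itself ([segmentMip()]). Components are 8-connected
#' and sorted by descending pixel count; 2D labels need not correspond to 3D
#' labels (lesions separated only along the collapsed axis merge).
#'
#' @slot pixels list of m x 2 integer matrices of 0-based pixel indices.
#' @slot pixelSpacing numeric(2) pixel size in mm.
#' @slot view `"coronal"` or `"sagittal"`.
#' @slot mode `"project"` or `"threshold"`.
#' @slot dim integer(2) image dimensions.
#'
#' @seealso [dmaxVoxMip()]
#' @export
setClass("MipLesionSet",
  slots = c(pixels = "list", pixelSpacing = "numeric", view = "character",
            mode = "character", dim = "integer"))

setValidity("MipLesionSet", function(object) {
  msg <- character()
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive reals (mm)")
  if (length(object@pixels)) {
    lin <- unlist(lapply(object@pixels, function(p)
      p[, 1] + object@dim[1] * p[, 2]))
    if (anyDuplicated(lin)) msg <- c(msg, "2D components must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' DisseminationProfile: the per-patient index vector
#'
#' The seven quantitative indices characterising tumour burden and spatial
#' dissemination, in the units used for clinical reporting (mL for MTV, cm for
#' all distances), plus bookkeeping flags. Single-lesion convention:
#' centroid-based indices (Dmax, Dmax_bulk, SPREAD_bulk, SPREAD_patient) are 0
#' and `singleLesion` is set; voxel-based indices (Dmax_Vox, Dmax_VoxMIP)
#' equal the longest intra-lesion diameter. An empty lesion set yields an
#' all-zero profile with `nLesions = 0`.
#'
#' @slot mtvMl metabolic tumour volume, mL.
#' @slot dmaxCm max centroid-centroid distance, cm.
#' @slot dmaxBulkCm max distance from the bulk-lesion centroid, cm.
#' @slot spreadBulkCm sum of distances from the bulk-lesion centroid, cm.
#' @slot spreadPatientCm max over lesions of its summed distances to all
#'   others, cm.
#' @slot dmaxVoxCm max voxel-voxel distance over the union of lesions, cm.
#' @slot dmaxVoxMipCm the same distance measured on the 2D MIP, cm
#'   (`NA` if not computed).
#' @slot nLesions number of lesions.
#' @slot singleLesion TRUE when exactly one lesion (centroid indices are 0 by
#'   convention).
#' @slot projectionMerged TRUE when the MIP has fewer 2D components than 3D
#'   lesions (lesions overlapped in projection).
#'
#' @seealso [disseminationProfile()]
#' @export
setClass("DisseminationProfile",
  slots = c(mtvMl = "numeric", dmaxCm = "numeric", dmaxBulkCm = "numeric",
            spreadBulkCm = "numeric", spreadPatientCm = "numeric",
            dmaxVoxCm = "numeric", dmaxVoxMipCm = "numeric",
            nLesions = "integer", singleLesion = "logical",
            projectionMerged = "logical"))

setValidity("DisseminationProfile", function(object) {
  msg <- character()
  num <- c(object@mtvMl, object@dmaxCm, object@dmaxBulkCm,
           object@spreadBulkCm, object@spreadPatientCm, object@dmaxVoxCm)
  if (any(!is.finite(num)) || any(num < 0))
    msg <- c(msg, "indices must be finite and non-negative")
  if (length(msg)) msg else TRUE
})
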
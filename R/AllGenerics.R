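#' @rdname mtv
#' @export
setGeneric("mtv", function(lesions) standardGeneric("mtv"))

#' @rdname dmax
#' @export
setGeneric("dmax", function(lesions, mode = c("suv_weighted", "geometric"))
  standardGeneric("dmax"))

#' @rdname dmax
#' @export
setGeneric("dmaxBulk", function(lesions, mode = c("suv_weighted", "geometric"))
  standardGeneric("dmaxBulk"))

#' @rdname dmax
#' @export
setGeneric("spreadBulk",
  function(lesions, mode = c("suv_weighted", "geometric"))
  standardGeneric("spreadBulk"))

#' @rdname dmax
#' @export
setGeneric("spreadPatient",
  function(lesions, mode = c("suv_weighted", "geometric"))
  standardGeneric("spreadPatient"))

#' @rdname dmaxVox
#' @export
setGeneric("dmaxVox", function(lesions) standardGeneric("dmaxVox"))

#' @rdname metabolicCenter
#' @export
setGeneric("metabolicCenter",
  function(lesions, mode = c("suv_weighted", "geometric"))
  standardGeneric("metabolicCenter"))

#' @rdname makeMip
#' @export
setGeneric("makeMip", function(volume, view = c("coronal", "sagittal"))
  standardGeneric("makeMip"))

#' @rdname projectMask
#' @export
setGeneric("projectMask", function(mask, view = c("coronal", "sagittal"))
  standardGeneric("projectMask"))

#' Number of lesions in a set
#' @param x a [LesionSet-class] or [MipLesionSet-class].
#' @return integer count of lesions / 2D components.
#' @export
setGeneric("nLesions", function(x) standardGeneric("nLesions"))

#' Voxel (or pixel) spacing accessor
#' @param x a petdix imaging object.
#' @return numeric vector of spacings in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Anatomical axis labels accessor
#' @param x a [PetVolume-class] or [LabelMask-class].
#' @return character(3), permutation of LR/AP/SI.
#' @export
setGeneric("axisLabels", function(x) standardGeneric("axisLabels"))

#' SUV data accessor
#' @param x a [PetVolume-class] or [MipImage-class].
#' @return numeric array (3D) or matrix (2D) of SUV values.
#' @export
setGeneric("suvData", function(x) standardGeneric("suvData"))

#' Lesion-level summary statistics
#' @param x a [LesionSet-class].
#' @return data.frame with one row per lesion (label, nvox, volume_ml,
#'   suv_max, suv_mean, centroid columns in mm).
#' @export
setGeneric("lesionStats", function(x) standardGeneric("lesionStats"))

#' Per-lesion voxel coordinate lists
#' @param x a [LesionSet-class] or [MipLesionSet-class].
#' @return list of integer matrices of 0-based grid indices.
#' @export
setGeneric("lesionVoxels", function(x) standardGeneric("lesionVoxels"))
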
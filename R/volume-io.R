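#' Construct a PetVolume in canonical orientation
#'
#' @param data 3D numeric array of SUV values.
#' @param spacing numeric(3) voxel size in mm.
#' @param axes character(3) anatomical labels of the grid axes; the volume is
#'   permuted to canonical (LR, AP, SI) order.
#' @param meta list of provenance.
#' @return a [PetVolume-class].
#' @export
PetVolume <- function(data, spacing, axes = c("LR", "AP", "SI"),
                      meta = list()) {
  if (!setequal(axes, CANONICAL_AXES))
    stop("axes must be a permutation of LR/AP/SI")
  perm <- match(CANONICAL_AXES, axes)
  if (!identical(perm, 1:3)) {
    data <- aperm(data, perm)
    spacing <- spacing[perm]
  }
  new("PetVolume", data = data, spacing = as.numeric(spacing),
      axes = CANONICAL_AXES, meta = meta)
}

#' Construct a LabelMask in canonical orientation
#'
#' Labels present in `labels` are remapped to consecutive 1..K preserving
#' numeric order.
#'
#' @param labels 3D integer array (0 = background).
#' @param spacing numeric(3) voxel size in mm.
#' @param axes character(3) anatomical labels of the grid axes.
#' @return a [LabelMask-class].
#' @export
LabelMask <- function(labels, spacing, axes = c("LR", "AP", "SI")) {
  if (!setequal(axes, CANONICAL_AXES))
    stop("axes must be a permutation of LR/AP/SI")
  perm <- match(CANONICAL_AXES, axes)
  if (!identical(perm, 1:3)) {
    labels <- aperm(labels, perm)
    spacing <- spacing[perm]
  }
  storage.mode(labels) <- "integer"
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_along(present))) {
    relab <- labels
    relab[] <- match(labels, present, nomatch = 0L)
    labels <- relab
  }
  new("LabelMask", labels = labels, spacing = as.numeric(spacing),
      axes = CANONICAL_AXES)
}

readNiftiCanonical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(as.vector(img)[seq_len(prod(d[1:3]))], dim = d[1:3])
    img2 <- RNifti::asNifti(arr)
    RNifti::pixdim(img2) <- RNifti::pixdim(img)[1:3]
    RNifti::qform(img2) <- structure(unclass(RNifti::xform(img)), code = 2L)
    img <- img2
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(d), " dimensions")
  if (any(RNifti::pixdim(img) <= 0) ||
      abs(det(RNifti::xform(img)[1:3, 1:3])) < 1e-12)
    stop("degenerate affine: zero voxel spacing in ", path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0 && hdr$sform_code == 0) {
    # no stored orientation: adopt the pixdim-scaled identity affine, i.e.
    # assume the grid is already in canonical order
    RNifti::qform(img) <- structure(unclass(RNifti::xform(img)), code = 2L)
  }
  RNifti::orientation(img) <- "RAS"
  img
}

#' Read a PET SUV volume from NIfTI
#'
#' Reads a 3D NIfTI volume (`.nii`/`.nii.gz`), derives voxel spacing from the
#' header and anatomical axis order from the affine orientation codes, and
#' reorients the grid to the canonical (LR, AP, SI) axis order so that all
#' downstream physical quantities are independent of how the file was stored.
#' 4D files with a singleton fourth dimension are squeezed.
#'
#' @param path file path to a NIfTI volume in SUV units.
#' @return a [PetVolume-class] in canonical orientation.
#' @examples
#' ph <- makePhantom(lesions = list(list(center = c(60, 60, 100), radii = 12,
#'                                       peak = 8)), seed = 1)
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(ph$volume, f)
#' vol <- readVolume(f)
#' @export
readVolume <- function(path) {
  img <- readNiftiCanonical(path)
  data <- array(as.vector(img), dim = dim(img))
  if (min(data) < 0) {
    if (min(data) > -1e-6) data[data < 0] <- 0
    else stop("volume contains negative SUV values; not an SUV image?")
  }
  PetVolume(data, spacing = RNifti::pixdim(img),
            meta = list(source = path))
}

#' Read a lesion label mask from NIfTI
#'
#' As [readVolume()] but values are interpreted as integer lesion labels and
#' remapped to consecutive 1..K.
#'
#' @param path file path to a NIfTI label image.
#' @return a [LabelMask-class] in canonical orientation.
#' @export
readMask <- function(path) {
  img <- readNiftiCanonical(path)
  data <- array(as.vector(img), dim = dim(img))
  if (any(abs(data - round(data)) > 1e-6))
    stop("mask contains non-integer values")
  LabelMask(round(data), spacing = RNifti::pixdim(img))
}

asNiftiImage <- function(arr, spacing) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::qform(img) <- structure(diag(c(spacing, 1)), code = 2L)
  img
}

#' Write a PetVolume to NIfTI
#'
#' @param volume a [PetVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, the path.
#' @export
writeVolume <- function(volume, path) {
  validObject(volume)
  img <- asNiftiImage(volume@data, volume@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a LabelMask to NIfTI
#'
#' Written with integer datatype; reading the file back reproduces the labels
#' exactly.
#'
#' @param mask a [LabelMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  validObject(mask)
  img <- asNiftiImage(mask@labels, mask@spacing)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' @describeIn suvData SUV array of a volume
#' @export
setMethod("suvData", "PetVolume", function(x) x@data)

#' @describeIn suvData projected SUV matrix of a MIP
#' @export
setMethod("suvData", "MipImage", function(x) x@data)

#' @describeIn voxelSpacing spacing of a volume (mm, length 3)
#' @export
setMethod("voxelSpacing", "PetVolume", function(x) x@spacing)

#' @describeIn voxelSpacing spacing of a mask (mm, length 3)
#' @export
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)

#' @describeIn voxelSpacing spacing of a lesion set (mm, length 3)
#' @export
setMethod("voxelSpacing", "LesionSet", function(x) x@spacing)

#' @describeIn voxelSpacing pixel spacing of a MIP (mm, length 2)
#' @export
setMethod("voxelSpacing", "MipImage", function(x) x@pixelSpacing)

#' @describeIn axisLabels axis labels of a volume
#' @export
setMethod("axisLabels", "PetVolume", function(x) x@axes)

#' @describeIn axisLabels axis labels of a mask
#' @export
setMethod("axisLabels", "LabelMask", function(x) x@axes)

setMethod("show", "PetVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("PetVolume %dx%dx%d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  axes %s | SUV range [%.3g, %.3g]\n",
              paste(object@axes, collapse = ","),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMask %dx%dx%d voxels, %d lesion label(s)\n",
              d[1], d[2], d[3], max(object@labels)))
})
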
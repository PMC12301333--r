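# 2D maximum-intensity projections and the Dmax_VoxMIP index.
#
# Canonical axis order is (LR, AP, SI); the coronal view collapses axis 2
# (anterior-posterior), the sagittal view collapses axis 1 (left-right).
# Retained image axes keep the 0-based index * spacing coordinate convention.

viewAxis <- function(view) switch(view, coronal = 2L, sagittal = 1L)

#' Build a 2D maximum-intensity projection
#'
#' Each pixel is the exact maximum of the SUV volume over the collapsed
#' anatomical axis; no interpolation is involved. The coronal view collapses
#' the anterior-posterior axis (image axes: left-right x cranio-caudal), the
#' sagittal view collapses left-right.
#'
#' @param volume a [PetVolume-class] in canonical orientation.
#' @param view `"coronal"` (default) or `"sagittal"`.
#' @return a [MipImage-class].
#' @export
setMethod("makeMip", "PetVolume", function(volume,
    view = c("coronal", "sagittal")) {
  view <- match.arg(view)
  ax <- viewAxis(view)
  keep <- setdiff(1:3, ax)
  data <- apply(volume@data, keep, max)
  new("MipImage", data = data, pixelSpacing = volume@spacing[keep],
      view = view, projectionAxis = volume@axes[ax])
})

#' Project a 3D label mask onto a MIP view
#'
#' The 2D footprint is the union of the projected lesion voxels; footprints
#' that overlap in projection are re-separated by 2D 8-connected components,
#' so 2D labels need not match the 3D labels (lesions separated only along
#' the collapsed axis merge into one component). This is the deterministic,
#' automated surrogate for reading lesions off the MIP in a viewer.
#'
#' @param mask a [LabelMask-class].
#' @param view `"coronal"` (default) or `"sagittal"`.
#' @return a [MipLesionSet-class] with `mode = "project"`.
#' @export
setMethod("projectMask", "LabelMask", function(mask,
    view = c("coronal", "sagittal")) {
  view <- match.arg(view)
  ax <- viewAxis(view)
  keep <- setdiff(1:3, ax)
  dims3 <- dim(mask@labels)
  lin <- which(mask@labels > 0L)
  dims2 <- dims3[keep]
  if (!length(lin))
    return(new("MipLesionSet", pixels = list(),
               pixelSpacing = mask@spacing[keep], view = view,
               mode = "project", dim = as.integer(dims2)))
  vox <- arrayInd(lin, dims3) - 1L
  pix <- vox[, keep, drop = FALSE]
  pix <- pix[!duplicated(linearIndex(pix, dims2)), , drop = FALSE]
  mipComponents(pix, dims2, mask@spacing[keep], view, "project")
})

mipComponents <- function(pix, dims2, spacing2, view, mode) {
  comp <- labelComponents(pix, dims2, neighborOffsets2D(8L))
  pxList <- lapply(split.data.frame(pix, comp), as.matrix)
  ord <- order(-vapply(pxList, nrow, integer(1)))
  new("MipLesionSet", pixels = unname(pxList[ord]),
      pixelSpacing = as.numeric(spacing2), view = view, mode = mode,
      dim = as.integer(dims2))
}

#' Threshold-segment a MIP image
#'
#' Viewer-mimicking alternative to [projectMask()]: pixels at or above a
#' fixed SUV threshold, grouped into 8-connected 2D components. A threshold
#' below the background level yields one giant component (degenerate but
#' valid).
#'
#' @param mip a [MipImage-class].
#' @param suv_threshold positive SUV threshold.
#' @return a [MipLesionSet-class] with `mode = "threshold"`.
#' @export
segmentMip <- function(mip, suv_threshold) {
  stopifnot(is(mip, "MipImage"), suv_threshold > 0)
  dims2 <- dim(mip@data)
  lin <- which(mip@data >= suv_threshold)
  if (!length(lin))
    return(new("MipLesionSet", pixels = list(),
               pixelSpacing = mip@pixelSpacing, view = mip@view,
               mode = "threshold", dim = as.integer(dims2)))
  pix <- arrayInd(lin, dims2) - 1L
  mipComponents(pix, dims2, mip@pixelSpacing, mip@view, "threshold")
}

#' Dmax_VoxMIP: outermost-pixel distance on the 2D MIP
#'
#' The maximum Euclidean distance between lesion pixel centres on the 2D
#' projection, in cm: the distance between the outermost voxels of the two
#' most distant lesions as seen on the MIP, or the 2D diameter of a single
#' component. By projection geometry this never exceeds the 3D [dmaxVox()]
#' of the same lesions.
#'
#' Components lying entirely inside an exclusion region are removed first —
#' the programmatic analogue of discounting physiologic uptake (heart,
#' bladder) identified on the sagittal view. Regions are axis-aligned boxes
#' `c(min1, max1, min2, max2)` in mm on the image axes.
#'
#' @param mip_lesions a [MipLesionSet-class].
#' @param exclusion_regions optional list of numeric(4) boxes in mm.
#' @return distance in cm.
#' @export
dmaxVoxMip <- function(mip_lesions, exclusion_regions = NULL) {
  stopifnot(is(mip_lesions, "MipLesionSet"))
  px <- mip_lesions@pixels
  sp <- mip_lesions@pixelSpacing
  if (!is.null(exclusion_regions) && length(exclusion_regions)) {
    keep <- vapply(px, function(p) {
      pos <- voxelCentersMm(p, sp)
      !any(vapply(exclusion_regions, function(b)
        all(pos[, 1] >= b[1] & pos[, 1] <= b[2] &
              pos[, 2] >= b[3] & pos[, 2] <= b[4]), logical(1)))
    }, logical(1))
    px <- px[keep]
  }
  if (!length(px))
    stop("no 2D components remain after exclusion")
  pix <- do.call(rbind, px)
  red <- boundaryPixels(pix, mip_lesions@dim)
  maxPairwiseDistance(voxelCentersMm(red, sp)) / 10
}

# 2D analogue of boundaryVoxels: drop pixels with all 4 edge neighbours
# present (exact for the pairwise maximum).
boundaryPixels <- function(pix, dims2) {
  n <- nrow(pix)
  if (n <= 2L) return(pix)
  lin <- linearIndex(pix, dims2)
  inside <- rep(TRUE, n)
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (k in 1:4) {
    nb <- sweep(pix, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < dims2[1] & nb[, 2] >= 0 & nb[, 2] < dims2[2]
    has <- ok
    has[ok] <- !is.na(match(linearIndex(nb[ok, , drop = FALSE], dims2), lin))
    inside <- inside & has
    if (!any(inside)) break
  }
  pix[!inside, , drop = FALSE]
}

#' Write a MIP image to NIfTI (2D) or PNG
#'
#' The PNG rendering linearly maps SUV to 8-bit grey (inverted, hot = dark)
#' and is a visualisation artifact only.
#'
#' @param mip a [MipImage-class].
#' @param path output path; `.png` selects PNG, otherwise NIfTI.
#' @return invisibly, the path.
#' @export
writeMip <- function(mip, path) {
  stopifnot(is(mip, "MipImage"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- mip@data
    rng <- range(m)
    g <- if (diff(rng) > 0) 1 - (m - rng[1]) / diff(rng) else m * 0 + 1
    # image rows top-to-bottom = cranio-caudal reversed for display
    png::writePNG(t(g)[rev(seq_len(ncol(g))), , drop = FALSE], path)
  } else {
    img <- RNifti::asNifti(mip@data)
    RNifti::pixdim(img) <- mip@pixelSpacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

setMethod("show", "MipImage", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "MipImage %s view (%s collapsed): %dx%d px, spacing %.3g x %.3g mm\n",
    object@view, object@projectionAxis, d[1], d[2],
    object@pixelSpacing[1], object@pixelSpacing[2]))
})

setMethod("show", "MipLesionSet", function(object) {
  cat(sprintf("MipLesionSet: %d component(s), %s view, mode = %s\n",
              length(object@pixels), object@view, object@mode))
})
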
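# Dissemination indices. All distances are computed in mm between voxel
# centres (physical position = 0-based index * spacing) and reported in cm.

pairwiseDistMm <- function(centers) {
  as.matrix(stats::dist(centers))
}

bulkLabel <- function(lesions) 1L  # label 1 = bulk by LesionSet ordering

#' Metabolic tumour volume
#'
#' Sum of lesion volumes in mL (voxel count x voxel volume); 0 for an empty
#' set. MTV is additive over lesions and independent of lesion positions.
#'
#' @param lesions a [LesionSet-class].
#' @return MTV in mL.
#' @export
setMethod("mtv", "LesionSet", function(lesions) {
  sum(lesions@stats$volume_ml)
})

#' Centroid-based dissemination distances
#'
#' For a patient's lesion set with metabolic centres \eqn{c_1 \dots c_K}
#' (bulk lesion = largest volume, label 1):
#' \describe{
#'   \item{`dmax`}{the largest Euclidean distance between the metabolic
#'     centres of any two lesions.}
#'   \item{`dmaxBulk`}{the distance from the bulk lesion's centre to the most
#'     distant other lesion.}
#'   \item{`spreadBulk`}{the sum of distances from the bulk lesion's centre
#'     to every other lesion.}
#'   \item{`spreadPatient`}{the largest, over lesions, of the sum of
#'     distances from that lesion to all the others.}
#' }
#' With a single lesion all four are 0 by convention (the patient has no
#' lesion-to-lesion dissemination; see [disseminationProfile()] for the flag).
#'
#' @param lesions a [LesionSet-class] with at least one lesion.
#' @param mode centroid mode passed to [metabolicCenter()].
#' @return distance in cm.
#' @name dmax
NULL

#' @rdname dmax
#' @export
setMethod("dmax", "LesionSet", function(lesions,
    mode = c("suv_weighted", "geometric")) {
  mode <- match.arg(mode)
  k <- nLesions(lesions)
  if (k == 0L) stop("empty LesionSet")
  if (k == 1L) return(0)
  max(stats::dist(metabolicCenter(lesions, mode))) / 10
})

#' @rdname dmax
#' @export
setMethod("dmaxBulk", "LesionSet", function(lesions,
    mode = c("suv_weighted", "geometric")) {
  mode <- match.arg(mode)
  k <- nLesions(lesions)
  if (k == 0L) stop("empty LesionSet")
  if (k == 1L) return(0)
  cent <- metabolicCenter(lesions, mode)
  d <- sqrt(colSums((t(cent[-1, , drop = FALSE]) - cent[1, ])^2))
  max(d) / 10
})

#' @rdname dmax
#' @export
setMethod("spreadBulk", "LesionSet", function(lesions,
    mode = c("suv_weighted", "geometric")) {
  mode <- match.arg(mode)
  k <- nLesions(lesions)
  if (k == 0L) stop("empty LesionSet")
  if (k == 1L) return(0)
  cent <- metabolicCenter(lesions, mode)
  d <- sqrt(colSums((t(cent[-1, , drop = FALSE]) - cent[1, ])^2))
  sum(d) / 10
})

#' @rdname dmax
#' @export
setMethod("spreadPatient", "LesionSet", function(lesions,
    mode = c("suv_weighted", "geometric")) {
  mode <- match.arg(mode)
  k <- nLesions(lesions)
  if (k == 0L) stop("empty LesionSet")
  if (k == 1L) return(0)
  dm <- pairwiseDistMm(metabolicCenter(lesions, mode))
  max(rowSums(dm)) / 10
})

#' Outermost-voxel distance Dmax_Vox
#'
#' The maximum Euclidean distance between any two tumour-voxel centres in the
#' union of all lesions: for two or more well-separated lesions this is the
#' distance between the outermost voxels of the two most distant lesions; for
#' a single lesion it is the longest intra-lesion diameter, so the index is
#' defined for every non-empty lesion set.
#'
#' The scan is accelerated by an exact reduction to boundary voxels (an
#' interior voxel, with all six face neighbours present, cannot be an extreme
#' point of the voxel-centre convex hull), but is contractually equal to the
#' exhaustive all-pairs computation.
#'
#' @param lesions a [LesionSet-class] with at least one lesion.
#' @return distance in cm.
#' @export
setMethod("dmaxVox", "LesionSet", function(lesions) {
  k <- nLesions(lesions)
  if (k == 0L) stop("empty LesionSet")
  vox <- do.call(rbind, lesions@voxels)
  red <- boundaryVoxels(vox, lesions@dim)
  maxPairwiseDistance(voxelCentersMm(red, lesions@spacing)) / 10
})

#' Compute the full per-patient dissemination profile
#'
#' Computes MTV, Dmax, Dmax_bulk, SPREAD_bulk, SPREAD_patient, Dmax_Vox and
#' (unless `view = "none"`) Dmax_VoxMIP from the 2D maximum-intensity
#' projection of the lesion mask. An empty lesion set yields an all-zero
#' profile with `nLesions = 0`; a single lesion sets `singleLesion` and the
#' centroid-based indices to 0 while the voxel-based indices measure the
#' intra-lesion diameter.
#'
#' @param lesions a [LesionSet-class].
#' @param view `"coronal"` (default), `"sagittal"`, or `"none"` to skip the
#'   MIP index.
#' @param mode centroid mode for the centroid-based indices.
#' @return a [DisseminationProfile-class].
#' @examples
#' ph <- makePhantom(lesions = list(
#'   list(center = c(40, 60, 60), radii = 10, peak = 8),
#'   list(center = c(120, 60, 240), radii = 14, peak = 6)), seed = 2)
#' vol <- ph$volume
#' les <- lesionsFromMask(vol, ph$mask)
#' disseminationProfile(les)
#' @export
disseminationProfile <- function(lesions, view = c("coronal", "sagittal",
                                                   "none"),
                                 mode = c("suv_weighted", "geometric")) {
  view <- match.arg(view)
  mode <- match.arg(mode)
  k <- nLesions(lesions)
  if (k == 0L)
    return(new("DisseminationProfile", mtvMl = 0, dmaxCm = 0, dmaxBulkCm = 0,
               spreadBulkCm = 0, spreadPatientCm = 0, dmaxVoxCm = 0,
               dmaxVoxMipCm = NA_real_, nLesions = 0L, singleLesion = FALSE,
               projectionMerged = FALSE))
  vmip <- NA_real_
  merged <- FALSE
  if (view != "none") {
    mls <- projectMask(asLabelMask(lesions), view)
    vmip <- dmaxVoxMip(mls)
    merged <- nLesions(mls) < k
  }
  new("DisseminationProfile",
      mtvMl = mtv(lesions),
      dmaxCm = dmax(lesions, mode),
      dmaxBulkCm = dmaxBulk(lesions, mode),
      spreadBulkCm = spreadBulk(lesions, mode),
      spreadPatientCm = spreadPatient(lesions, mode),
      dmaxVoxCm = dmaxVox(lesions),
      dmaxVoxMipCm = vmip,
      nLesions = k,
      singleLesion = k == 1L,
      projectionMerged = merged)
}

#' Convert a DisseminationProfile to a one-row data.frame
#'
#' Values in mL/cm, full precision; use `round` for the 1-decimal clinical
#' report format.
#'
#' @param x a [DisseminationProfile-class].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return one-row data.frame.
#' @export
as.data.frame.DisseminationProfile <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(mtv_ml = x@mtvMl, dmax_cm = x@dmaxCm,
             dmax_bulk_cm = x@dmaxBulkCm, spread_bulk_cm = x@spreadBulkCm,
             spread_patient_cm = x@spreadPatientCm,
             dmax_vox_cm = x@dmaxVoxCm, dmax_voxmip_cm = x@dmaxVoxMipCm,
             n_lesions = x@nLesions, single_lesion = x@singleLesion,
             projection_merged = x@projectionMerged,
             row.names = row.names)
}

setMethod("show", "DisseminationProfile", function(object) {
  cat(sprintf(
    "DisseminationProfile (%d lesion%s%s)\n", object@nLesions,
    if (object@nLesions == 1L) "" else "s",
    if (object@singleLesion) ", single-lesion convention" else ""))
  cat(sprintf("  MTV            %8.1f mL\n", object@mtvMl))
  cat(sprintf("  Dmax           %8.1f cm\n", object@dmaxCm))
  cat(sprintf("  Dmax_bulk      %8.1f cm\n", object@dmaxBulkCm))
  cat(sprintf("  SPREAD_bulk    %8.1f cm\n", object@spreadBulkCm))
  cat(sprintf("  SPREAD_patient %8.1f cm\n", object@spreadPatientCm))
  cat(sprintf("  Dmax_Vox       %8.1f cm\n", object@dmaxVoxCm))
  cat(sprintf("  Dmax_VoxMIP    %8.1f cm%s\n", object@dmaxVoxMipCm,
              if (object@projectionMerged)
                "  [lesions merged in projection]" else ""))
})
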
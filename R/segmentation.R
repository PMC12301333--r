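#' Parameters of the adaptive SUV-threshold segmentation
#'
#' The adaptive (Nestle-type) rule thresholds each candidate focus at
#' `T = beta * I_mean70 + I_bg`, where `I_mean70` is the mean SUV of focus
#' voxels at or above 70% of the focus SUVmax and `I_bg` the mean SUV in a
#' peri-lesional background shell. All constants are exposed here.
#'
#' @param beta adaptive-threshold multiplier (dimensionless, 0 < beta < 1).
#' @param seed_suv_min minimum SUVmax for a candidate lesion focus.
#' @param background_shell_mm thickness in mm of the shell around the
#'   70%-isocontour region used to estimate background SUV (candidate-lesion
#'   voxels are excluded from the shell).
#' @param min_lesion_ml minimum lesion volume retained, mL.
#' @param connectivity 3D neighbourhood for connected components: 6, 18 or 26.
#' @return a classed list of validated parameters.
#' @export
segmentationParams <- function(beta = 0.3, seed_suv_min = 2.5,
                               background_shell_mm = 8, min_lesion_ml = 0.1,
                               connectivity = 26L) {
  if (!(beta > 0 && beta < 1)) stop("beta must be in (0, 1)")
  if (min_lesion_ml < 0) stop("min_lesion_ml must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (seed_suv_min <= 0) stop("seed_suv_min must be positive")
  if (background_shell_mm <= 0) stop("background_shell_mm must be positive")
  structure(list(beta = beta, seed_suv_min = seed_suv_min,
                 background_shell_mm = background_shell_mm,
                 min_lesion_ml = min_lesion_ml,
                 connectivity = as.integer(connectivity)),
            class = "SegmentationParams")
}

# Assemble a LesionSet from a list of 0-based voxel matrices, computing
# per-lesion stats and sorting by descending volume (ties: higher SUVmax,
# then lower original label; label 1 = bulk).
buildLesionSet <- function(voxelList, data, spacing, dim, source,
                           params = list()) {
  k <- length(voxelList)
  vvox_ml <- prod(spacing) / 1000
  if (k == 0L) {
    stats <- data.frame(label = integer(0), nvox = integer(0),
                        volume_ml = numeric(0), suv_max = numeric(0),
                        suv_mean = numeric(0), cx_mm = numeric(0),
                        cy_mm = numeric(0), cz_mm = numeric(0))
    return(new("LesionSet", stats = stats, voxels = list(), suv = list(),
               spacing = as.numeric(spacing), dim = as.integer(dim),
               source = source, params = params))
  }
  suvList <- lapply(voxelList, function(v) data[linearIndex(v, dim)])
  nvox <- vapply(voxelList, nrow, integer(1))
  smax <- vapply(suvList, max, numeric(1))
  smean <- vapply(suvList, mean, numeric(1))
  ord <- order(-nvox, -smax, seq_len(k))
  voxelList <- voxelList[ord]
  suvList <- suvList[ord]
  cent <- t(vapply(seq_len(k), function(i) {
    p <- voxelCentersMm(voxelList[[i]], spacing)
    w <- suvList[[i]]
    colSums(p * w) / sum(w)
  }, numeric(3)))
  stats <- data.frame(label = seq_len(k), nvox = nvox[ord],
                      volume_ml = nvox[ord] * vvox_ml,
                      suv_max = smax[ord], suv_mean = smean[ord],
                      cx_mm = cent[, 1], cy_mm = cent[, 2], cz_mm = cent[, 3])
  new("LesionSet", stats = stats, voxels = voxelList, suv = suvList,
      spacing = as.numeric(spacing), dim = as.integer(dim),
      source = source, params = params)
}

#' Adaptive SUV-threshold lesion segmentation
#'
#' Segments hot lesions from a PET volume with the adaptive threshold rule.
#' Candidate foci are 3D connected components of voxels at or above
#' `seed_suv_min`. For each focus the threshold
#' `T = beta * I_mean70 + I_bg` is computed (see [segmentationParams()]) and
#' the connected region of voxels `>= T` containing the focus maximum is
#' grown. Grown regions are pooled, relabelled by connected components at the
#' configured connectivity, regions smaller than `min_lesion_ml` discarded,
#' and the rest sorted by descending volume (label 1 = bulk lesion).
#'
#' A volume with no voxel above `seed_suv_min` yields an empty lesion set
#' (not an error).
#'
#' @param volume a [PetVolume-class].
#' @param params a [segmentationParams()] list.
#' @return a [LesionSet-class] with `source = "adaptive_threshold"`.
#' @examples
#' ph <- makePhantom(lesions = list(list(center = c(60, 60, 100), radii = 12,
#'                                       peak = 10)), seed = 7)
#' les <- segmentAdaptive(ph$volume)
#' mtv(les)
#' @export
segmentAdaptive <- function(volume, params = segmentationParams()) {
  validObject(volume)
  stopifnot(inherits(params, "SegmentationParams"))
  data <- volume@data
  dims <- dim(data)
  spacing <- volume@spacing
  offs <- neighborOffsets3D(params$connectivity)
  cand <- which(data >= params$seed_suv_min)
  if (!length(cand))
    return(buildLesionSet(list(), data, spacing, dims,
                          "adaptive_threshold", unclass(params)))
  candVox <- arrayInd(cand, dims) - 1L
  comp <- labelComponents(candVox, dims, offs)
  candLin <- cand
  shellOffs <- ballOffsets(params$background_shell_mm, spacing)
  grown <- logical(length(data))
  for (f in seq_len(max(comp))) {
    fvox <- candVox[comp == f, , drop = FALSE]
    fsuv <- data[candLin[comp == f]]
    smax <- max(fsuv)
    core <- fvox[fsuv >= 0.7 * smax, , drop = FALSE]
    imean70 <- mean(data[linearIndex(core, dims)])
    shell <- dilateVoxels(core, dims, shellOffs)
    shellLin <- linearIndex(shell, dims)
    shellLin <- shellLin[is.na(match(shellLin, candLin))]
    ibg <- if (length(shellLin)) mean(data[shellLin]) else
      stats::median(data[-candLin])
    thr <- params$beta * imean70 + ibg
    seed <- fvox[which.max(fsuv), , drop = FALSE]
    if (data[linearIndex(seed, dims)] < thr) next
    region <- growRegion(seed, data, dims, thr, offs)
    grown[region] <- TRUE
  }
  finalizeRegions(grown, data, spacing, dims, params, "adaptive_threshold")
}

# BFS region growing: connected set of voxels with data >= thr containing
# the seed. Returns linear indices.
growRegion <- function(seed, data, dims, thr, offsets) {
  seedLin <- linearIndex(seed, dims)
  visited <- seedLin
  frontier <- seed
  noff <- nrow(offsets)
  while (nrow(frontier)) {
    m <- nrow(frontier)
    cand <- frontier[rep(seq_len(m), times = noff), , drop = FALSE] +
      offsets[rep(seq_len(noff), each = m), , drop = FALSE]
    ok <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
      cand[, 2] >= 0 & cand[, 2] < dims[2] &
      cand[, 3] >= 0 & cand[, 3] < dims[3]
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) break
    lin <- linearIndex(cand, dims)
    keep <- !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]
    lin <- lin[keep]
    new <- is.na(match(lin, visited)) & data[lin] >= thr
    if (!any(new)) break
    frontier <- cand[new, , drop = FALSE]
    visited <- c(visited, lin[new])
  }
  visited
}

finalizeRegions <- function(grownMask, data, spacing, dims, params, source) {
  lin <- which(grownMask)
  if (!length(lin))
    return(buildLesionSet(list(), data, spacing, dims, source,
                          unclass(params)))
  vox <- arrayInd(lin, dims) - 1L
  comp <- labelComponents(vox, dims, neighborOffsets3D(params$connectivity))
  vvox_ml <- prod(spacing) / 1000
  voxelList <- split.data.frame(vox, comp)
  keep <- vapply(voxelList, nrow, integer(1)) * vvox_ml >=
    params$min_lesion_ml
  voxelList <- lapply(voxelList[keep], as.matrix)
  buildLesionSet(unname(voxelList), data, spacing, dims, source,
                 unclass(params))
}

#' Build a LesionSet from an external label mask
#'
#' Supports externally segmented masks as first-class inputs, so the index
#' core can be validated independently of the segmentation route. Labels are
#' reassigned by descending lesion volume (label 1 = bulk).
#'
#' @param volume a [PetVolume-class] supplying SUV values.
#' @param mask a [LabelMask-class] of identical shape and spacing.
#' @return a [LesionSet-class] with `source = "external_mask"`.
#' @export
lesionsFromMask <- function(volume, mask) {
  validObject(volume); validObject(mask)
  if (!identical(dim(volume@data), dim(mask@labels)))
    stop("volume and mask shapes differ")
  if (max(abs(volume@spacing - mask@spacing)) > 1e-6)
    stop("volume and mask spacing differ")
  dims <- dim(mask@labels)
  lin <- which(mask@labels > 0L)
  if (!length(lin))
    return(buildLesionSet(list(), volume@data, volume@spacing, dims,
                          "external_mask"))
  vox <- arrayInd(lin, dims) - 1L
  voxelList <- lapply(split.data.frame(vox, mask@labels[lin]), as.matrix)
  buildLesionSet(unname(voxelList), volume@data, volume@spacing, dims,
                 "external_mask")
}

#' Metabolic centre of each lesion
#'
#' The SUV-weighted mean of voxel-centre positions (default), or the
#' unweighted geometric mean. For a uniform-SUV lesion both modes agree.
#'
#' @param lesions a [LesionSet-class] with at least one lesion.
#' @param mode `"suv_weighted"` (default) or `"geometric"`.
#' @return K x 3 matrix of centre positions in mm (rows follow lesion labels).
#' @export
setMethod("metabolicCenter", "LesionSet", function(lesions,
    mode = c("suv_weighted", "geometric")) {
  mode <- match.arg(mode)
  k <- nLesions(lesions)
  if (k == 0L) stop("empty LesionSet")
  t(vapply(seq_len(k), function(i) {
    p <- voxelCentersMm(lesions@voxels[[i]], lesions@spacing)
    if (mode == "suv_weighted") {
      w <- lesions@suv[[i]]
      colSums(p * w) / sum(w)
    } else colMeans(p)
  }, numeric(3)))
})

#' Rebuild the LabelMask of a LesionSet
#'
#' @param lesions a [LesionSet-class].
#' @return a [LabelMask-class] on the source grid, labels = lesion labels.
#' @export
asLabelMask <- function(lesions) {
  labs <- array(0L, dim = lesions@dim)
  for (i in seq_len(nLesions(lesions)))
    labs[linearIndex(lesions@voxels[[i]], lesions@dim)] <- i
  new("LabelMask", labels = labs, spacing = lesions@spacing,
      axes = CANONICAL_AXES)
}

#' @describeIn nLesions lesions in a 3D set
#' @export
setMethod("nLesions", "LesionSet", function(x) nrow(x@stats))

#' @describeIn nLesions 2D components on a MIP
#' @export
setMethod("nLesions", "MipLesionSet", function(x) length(x@pixels))

#' @describeIn lesionStats lesion summary table
#' @export
setMethod("lesionStats", "LesionSet", function(x) x@stats)

#' @describeIn lesionVoxels 3D voxel lists
#' @export
setMethod("lesionVoxels", "LesionSet", function(x) x@voxels)

#' @describeIn lesionVoxels 2D pixel lists
#' @export
setMethod("lesionVoxels", "MipLesionSet", function(x) x@pixels)

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet: %d lesion(s), source = %s, MTV = %.2f mL\n",
              nLesions(object), object@source,
              sum(object@stats$volume_ml)))
  if (nLesions(object)) print(utils::head(object@stats, 5))
})
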
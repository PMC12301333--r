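# Internal geometry and indexing helpers. Voxel indices are 0-based
# throughout; the physical position of a voxel centre is index * spacing mm.

linearIndex <- function(vox, dim) {
  # vox: n x d matrix of 0-based indices -> 1-based R linear index
  d <- length(dim)
  out <- vox[, d]
  for (k in (d - 1):1) out <- out * dim[k] + vox[, k]
  out + 1
}

voxelCentersMm <- function(vox, spacing) {
  sweep(vox, 2, spacing, `*`)
}

#' Maximum pairwise Euclidean distance of a point set
#'
#' Exact diameter of a finite point set in mm. For voxel clouds the caller
#' first reduces to boundary voxels (see [boundaryVoxels()]): a voxel whose
#' six face neighbours are all present lies strictly inside the convex hull of
#' its neighbours' centres and can never attain the maximum, so the reduction
#' is exact. The remaining scan is a vectorised all-pairs computation, chunked
#' to bound memory.
#'
#' @param points n x d numeric matrix of coordinates in mm.
#' @return the maximum pairwise distance (0 for a single point).
#' @keywords internal
maxPairwiseDistance <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(0)
  sq <- rowSums(points^2)
  best <- 0
  chunk <- max(1L, floor(4e6 / n))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    g <- tcrossprod(points[i:j, , drop = FALSE], points)
    d2 <- sq[i:j] + rep(sq, each = j - i + 1L) - 2 * g
    m <- max(d2)
    if (m > best) best <- m
    i <- j + 1L
  }
  sqrt(max(best, 0))
}

# Voxels of a set having fewer than 6 face neighbours inside the set.
# vox: n x 3 matrix of 0-based indices; dim: grid dims (indices assumed
# in-bounds). Returns the reduced matrix.
boundaryVoxels <- function(vox, dim) {
  n <- nrow(vox)
  if (n <= 2L) return(vox)
  lin <- linearIndex(vox, dim)
  inside <- rep(TRUE, n)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(6)) {
    nb <- sweep(vox, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < dim[1] & nb[, 2] >= 0 & nb[, 2] < dim[2] &
      nb[, 3] >= 0 & nb[, 3] < dim[3]
    has <- ok
    has[ok] <- !is.na(match(linearIndex(nb[ok, , drop = FALSE], dim), lin))
    inside <- inside & has
    if (!any(inside)) break
  }
  vox[!inside, , drop = FALSE]
}

neighborOffsets3D <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  if (connectivity == 6L) g <- g[ord == 1, , drop = FALSE]
  if (connectivity == 18L) g <- g[ord <= 2, , drop = FALSE]
  unname(g)
}

neighborOffsets2D <- function(connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 4L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  unname(g)
}

# Connected components of a sparse voxel set by breadth-first search.
# vox: n x d matrix of 0-based in-bounds indices; offsets from
# neighborOffsets3D/2D. Returns an integer component id per row (1..K,
# in discovery order).
labelComponents <- function(vox, dim, offsets) {
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  lin <- linearIndex(vox, dim)
  comp <- integer(n)
  k <- 0L
  noff <- nrow(offsets)
  for (seed in seq_len(n)) {
    if (comp[seed] > 0L) next
    k <- k + 1L
    comp[seed] <- k
    frontier <- seed
    while (length(frontier)) {
      f <- vox[frontier, , drop = FALSE]
      m <- nrow(f)
      cand <- f[rep(seq_len(m), times = noff), , drop = FALSE] +
        offsets[rep(seq_len(noff), each = m), , drop = FALSE]
      ok <- rep(TRUE, nrow(cand))
      for (a in seq_along(dim))
        ok <- ok & cand[, a] >= 0 & cand[, a] < dim[a]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) { frontier <- integer(0); next }
      pos <- match(linearIndex(cand, dim), lin)
      pos <- unique(pos[!is.na(pos)])
      pos <- pos[comp[pos] == 0L]
      comp[pos] <- k
      frontier <- pos
    }
  }
  comp
}

# Dilate a sparse voxel set by an explicit offset ball; returns the dilated
# 0-based voxel matrix (unique, in-bounds).
dilateVoxels <- function(vox, dim, offsets) {
  m <- nrow(vox)
  noff <- nrow(offsets)
  cand <- vox[rep(seq_len(m), times = noff), , drop = FALSE] +
    offsets[rep(seq_len(noff), each = m), , drop = FALSE]
  cand <- rbind(vox, cand)
  ok <- rep(TRUE, nrow(cand))
  for (a in seq_along(dim)) ok <- ok & cand[, a] >= 0 & cand[, a] < dim[a]
  cand <- cand[ok, , drop = FALSE]
  cand[!duplicated(linearIndex(cand, dim)), , drop = FALSE]
}

# Offsets whose physical displacement is within radius_mm (Euclidean,
# anisotropic spacing); excludes the zero offset.
ballOffsets <- function(radius_mm, spacing) {
  r <- pmax(0L, floor(radius_mm / spacing))
  g <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2],
                             dz = -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  g <- g[d2 <= radius_mm^2 & d2 > 0, , drop = FALSE]
  unname(g)
}
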
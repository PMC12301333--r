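# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use a different computation route (stats::dist, explicit loops) from the
# package's optimized implementations.

# exhaustive O(n^2) maximum pairwise distance, mm
bruteMaxDist <- function(points) {
  if (nrow(points) < 2) return(0)
  max(stats::dist(points))
}

# exhaustive sum-of-distances oracles over centroid rows
bruteSpreadPatient <- function(centers) {
  n <- nrow(centers)
  if (n < 2) return(0)
  dm <- as.matrix(stats::dist(centers))
  max(vapply(seq_len(n), function(i) sum(dm[i, -i]), numeric(1)))
}

bruteSpreadBulk <- function(centers) {
  n <- nrow(centers)
  if (n < 2) return(0)
  sum(vapply(2:n, function(i) sqrt(sum((centers[i, ] - centers[1, ])^2)),
             numeric(1)))
}

# Build a LesionSet through the real mask-ingestion path from explicit
# 0-based voxel coordinate matrices. SUV defaults to a constant per lesion.
lesionSetFromCoords <- function(voxList, spacing = c(1, 1, 1), dim = NULL,
                                suvPerLesion = NULL) {
  allv <- do.call(rbind, voxList)
  if (is.null(dim)) dim <- apply(allv, 2, max) + 1L
  vol <- array(0.0, dim = dim)
  labs <- array(0L, dim = dim)
  for (i in seq_along(voxList)) {
    v <- voxList[[i]]
    lin <- v[, 1] + dim[1] * (v[, 2] + dim[2] * v[, 3]) + 1
    s <- if (is.null(suvPerLesion)) 5 else suvPerLesion[[i]]
    vol[lin] <- s
    labs[lin] <- i
  }
  volume <- PetVolume(vol, spacing)
  lesionsFromMask(volume, LabelMask(labs, spacing))
}

# Random multi-lesion voxel blobs (axis-aligned random boxes jittered into
# blobs), guaranteed disjoint by construction on a coarse lattice.
randomLesionSet <- function(seed, maxVox = 2500, spacing = c(2, 3, 4)) {
  set.seed(seed)
  k <- sample(2:6, 1)
  dim <- c(40L, 40L, 60L)
  anchors <- unique(cbind(sample(seq(1, 33, by = 8), k, replace = TRUE),
                          sample(seq(1, 33, by = 8), k, replace = TRUE),
                          sample(seq(1, 53, by = 8), k, replace = TRUE)))
  k <- nrow(anchors)
  voxList <- lapply(seq_len(k), function(i) {
    sz <- sample(2:6, 3, replace = TRUE)
    g <- as.matrix(expand.grid(anchors[i, 1] + 0:(sz[1] - 1),
                               anchors[i, 2] + 0:(sz[2] - 1),
                               anchors[i, 3] + 0:(sz[3] - 1)))
    n <- min(nrow(g), max(2, ceiling(maxVox / k)))
    unname(g[sample(nrow(g), n), , drop = FALSE])
  })
  lesionSetFromCoords(voxList, spacing = spacing, dim = dim,
                      suvPerLesion = lapply(voxList, function(v)
                        stats::runif(nrow(v), 2, 10)))
}

# simulated exponential cohort with an optional step effect on one index
simulateStepCohort <- function(n, seed, hr = 1, cutQuantile = 0.5,
                               baseline = 0.01, censorMax = 150) {
  set.seed(seed)
  x <- stats::rlnorm(n, log(30), 0.8)
  cut <- stats::qlnorm(cutQuantile, log(30), 0.8)
  rate <- baseline * ifelse(x > cut, hr, 1)
  t <- stats::rexp(n, rate)
  cens <- stats::runif(n, 0, censorMax)
  list(records = data.frame(time = pmin(t, cens),
                            event = as.integer(t <= cens)),
       values = x, trueCut = cut)
}
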
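# Synthetic PET phantoms: voxelized ellipsoid lesions over a noisy uniform
# background, with ground-truth masks and true index values. Emulates the
# geometry of whole-body FDG-PET (4 mm isotropic voxels, SUV-scale
# intensities) without scanner physics: noise is Gaussian on SUV, lesions
# are unions of ellipsoids.

#' Generate a synthetic PET phantom
#'
#' Builds a 3D SUV volume from a uniform noisy background plus ellipsoid
#' lesions, together with the ground-truth label mask and the true
#' dissemination indices computed from that mask. A voxel belongs to a lesion
#' when its centre lies inside the ellipsoid. Lesion intensity profiles:
#' `"uniform"` sets every lesion voxel to `peak`; `"gaussian"` falls off as
#' `bg + (peak - bg) * exp(-ln(2) * rho^2)` with `rho` the normalised
#' ellipsoid radius (half-max at the lesion boundary).
#'
#' Optional `hotRegions` (heart/bladder surrogates) are rendered into the
#' volume but excluded from the truth mask. Overlapping lesions are allowed
#' (the earlier lesion keeps the voxel) and reported via the `overlap`
#' attribute.
#'
#' @param dim integer(3) grid shape (default 64 x 48 x 96).
#' @param spacing numeric(3) voxel size mm (default 4 mm isotropic).
#' @param background background SUV mean.
#' @param noiseSd Gaussian SUV noise sd (volume is clamped at 0).
#' @param lesions list of lesions: each a list with `center` (mm, length 3),
#'   `radii` (mm, scalar for a sphere or length 3), `peak` SUV, optional
#'   `profile` ("uniform"/"gaussian").
#' @param hotRegions like `lesions` but physiologic (not in the truth mask).
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return list: `volume` ([PetVolume-class]), `mask` (ground-truth
#'   [LabelMask-class]), `truth` (list with per-lesion analytic `volumes_ml`,
#'   `centers_mm`, and the mask-derived [DisseminationProfile-class]
#'   `profile`).
#' @examples
#' ph <- makePhantom(lesions = list(
#'   list(center = c(60, 60, 80), radii = 12, peak = 10)), seed = 1)
#' ph$truth$volumes_ml
#' @export
makePhantom <- function(dim = c(64L, 48L, 96L), spacing = c(4, 4, 4),
                        background = 1.0, noiseSd = 0.1, lesions = list(),
                        hotRegions = list(), seed = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), all(spacing > 0),
            noiseSd >= 0, background >= 0)
  if (!is.null(seed)) set.seed(seed)
  extent <- dim * spacing
  vol <- array(stats::rnorm(prod(dim), background, noiseSd), dim = dim)
  labs <- array(0L, dim = dim)
  ax <- lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
  overlap <- FALSE
  paint <- function(vol, labs, spec, label) {
    r <- rep(spec$radii, length.out = 3)
    cen <- spec$center
    if (any(cen - r < -spacing / 2) || any(cen + r > extent))
      stop("lesion extends outside the grid")
    profile <- if (is.null(spec$profile)) "uniform" else spec$profile
    lo <- pmax(1L, floor((cen - r) / spacing))
    hi <- pmin(dim, ceiling((cen + r) / spacing) + 1L)
    g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
    pos <- cbind(ax[[1]][g$i], ax[[2]][g$j], ax[[3]][g$k])
    rho2 <- ((pos[, 1] - cen[1]) / r[1])^2 + ((pos[, 2] - cen[2]) / r[2])^2 +
      ((pos[, 3] - cen[3]) / r[3])^2
    inside <- rho2 <= 1
    if (!any(inside)) return(list(vol, labs))
    lin <- g$i[inside] + dim[1] * (g$j[inside] - 1) +
      dim[1] * dim[2] * (g$k[inside] - 1)
    val <- if (profile == "gaussian")
      background + (spec$peak - background) * exp(-log(2) * rho2[inside])
    else rep(spec$peak, sum(inside))
    vol[lin] <- val
    if (label > 0L) {
      if (any(labs[lin] > 0L)) overlap <<- TRUE
      free <- labs[lin] == 0L
      labs[lin[free]] <- label
    }
    list(vol, labs)
  }
  for (i in seq_along(lesions)) {
    if (lesions[[i]]$peak <= background)
      stop("lesion peak SUV must exceed the background mean")
    res <- paint(vol, labs, lesions[[i]], i)
    vol <- res[[1]]; labs <- res[[2]]
  }
  for (h in hotRegions) {
    res <- paint(vol, labs, h, 0L)
    vol <- res[[1]]; labs <- res[[2]]
  }
  vol[vol < 0] <- 0
  volume <- PetVolume(vol, spacing, meta = list(source = "phantom",
                                                seed = seed))
  mask <- LabelMask(labs, spacing)
  truth <- list(
    volumes_ml = vapply(lesions, function(l)
      4 / 3 * pi * prod(rep(l$radii, length.out = 3)) / 1000, numeric(1)),
    centers_mm = if (length(lesions))
      do.call(rbind, lapply(lesions, `[[`, "center")) else NULL,
    profile = disseminationProfile(lesionsFromMask(volume, mask)))
  if (overlap) message("phantom lesions overlap; earlier label kept")
  structure(list(volume = volume, mask = mask, truth = truth),
            overlap = overlap)
}

#' Random multi-lesion phantom
#'
#' Draws a phantom with a random number of non-deliberately-overlapping
#' ellipsoid lesions at random positions and sizes — the workhorse for
#' property-based validation of the index chain.
#'
#' @param seed integer seed.
#' @param dim,spacing grid geometry (see [makePhantom()]).
#' @param nLesions integer range (length 2) from which the lesion count is
#'   drawn uniformly.
#' @param radiiMm range of ellipsoid semi-axes in mm.
#' @param peakRange range of lesion peak SUV.
#' @param noiseSd background noise sd.
#' @return as [makePhantom()].
#' @export
randomPhantom <- function(seed, dim = c(48L, 40L, 72L), spacing = c(4, 4, 4),
                          nLesions = c(1L, 6L), radiiMm = c(6, 16),
                          peakRange = c(4, 12), noiseSd = 0.1) {
  set.seed(seed)
  n <- sample(nLesions[1]:nLesions[2], 1)
  extent <- dim * spacing
  lesions <- lapply(seq_len(n), function(i) {
    r <- stats::runif(3, radiiMm[1], radiiMm[2])
    list(center = stats::runif(3, r + 2, extent - r - 2), radii = r,
         peak = stats::runif(1, peakRange[1], peakRange[2]),
         profile = sample(c("uniform", "gaussian"), 1))
  })
  makePhantom(dim = dim, spacing = spacing, noiseSd = noiseSd,
              lesions = lesions, seed = seed + 1L)
}

#' Simulate a survival cohort with known ground truth
#'
#' Draws per-patient index values, an IPI category, and overall/progression-
#' free survival from an exponential proportional-hazards model, with
#' independent uniform censoring calibrated to a target censoring fraction.
#' The linear predictor is `sum(betas[j] * z_j)` where `z_j` is the
#' dichotomized index (`value > cutpoints[j]`) when a cutpoint is given for
#' that index, and the standardised continuous value otherwise; an optional
#' `ipiBeta` adds a per-category IPI effect.
#'
#' Index distributions mirror the scale of clinical whole-body FDG-PET
#' cohorts: MTV ~ logNormal(log 300, 1.2) mL, distance indices ~
#' logNormal(log 30, 0.8) cm. The generating parameters are attached as the
#' `truth` attribute.
#'
#' @param n cohort size (>= 2).
#' @param seed integer seed; same spec + seed gives an identical cohort.
#' @param betas named log-hazard coefficients on index columns (possibly
#'   empty).
#' @param cutpoints named true cutoffs for dichotomized effects (indices
#'   absent here enter continuously, standardised).
#' @param baseline baseline monthly hazard for OS.
#' @param pfsFactor multiplier on the baseline hazard for the progression
#'   process (PFS = first of progression or death).
#' @param censorRate target fraction censored (in [0, 1)).
#' @param ipiBeta log-hazard increment per IPI category step.
#' @param indices names of index columns to generate.
#' @return data.frame with `patient_id`, `os_months`, `os_event`,
#'   `pfs_months`, `pfs_event`, `ipi_category` and one column per index;
#'   attribute `truth` carries the generating parameters.
#' @export
simulateCohort <- function(n = 104, seed = 1, betas = numeric(0),
                           cutpoints = numeric(0), baseline = 0.006,
                           pfsFactor = 1.4, censorRate = 0.25,
                           ipiBeta = 0.35,
                           indices = c("mtv", "dmax", "dmax_vox",
                                       "dmax_voxmip", "dmax_bulk",
                                       "spread_bulk", "spread_patient")) {
  stopifnot(n >= 2, censorRate >= 0, censorRate < 1)
  set.seed(seed)
  x <- data.frame(patient_id = sprintf("P%03d", seq_len(n)))
  for (idx in indices) {
    x[[idx]] <- if (idx == "mtv")
      stats::rlnorm(n, log(300), 1.2)
    else stats::rlnorm(n, log(30), 0.8)
  }
  x$ipi_category <- sample(c("0-1", "2-3", "4-5"), n, replace = TRUE,
                           prob = c(0.25, 0.45, 0.30))
  lp <- rep(0, n)
  for (nm in names(betas)) {
    if (!nm %in% names(x)) stop("beta refers to unknown index: ", nm)
    v <- x[[nm]]
    z <- if (nm %in% names(cutpoints)) as.numeric(v > cutpoints[[nm]])
    else as.numeric(scale(v))
    lp <- lp + betas[[nm]] * z
  }
  lp <- lp + ipiBeta * (as.integer(factor(x$ipi_category)) - 1L)
  osRate <- baseline * exp(lp)
  tOS <- stats::rexp(n, osRate)
  tProg <- stats::rexp(n, baseline * (pfsFactor - 1) * exp(lp) + 1e-12)
  tPFS <- pmin(tOS, tProg)
  cmax <- censorUpper(osRate, censorRate)
  cens <- stats::runif(n, 0, cmax)
  x$os_months <- pmin(tOS, cens)
  x$os_event <- as.integer(tOS <= cens)
  x$pfs_months <- pmin(tPFS, cens)
  x$pfs_event <- as.integer(tPFS <= cens)
  # guard against zero-length follow-up from numeric underflow
  x$os_months <- pmax(x$os_months, 1e-6)
  x$pfs_months <- pmax(x$pfs_months, 1e-6)
  attr(x, "truth") <- list(betas = betas, cutpoints = cutpoints,
                           baseline = baseline, censorRate = censorRate,
                           ipiBeta = ipiBeta, seed = seed)
  x
}

# Upper bound of the uniform censoring window solving
# mean_i P(C < T_i) = censorRate for C ~ U(0, u), T_i ~ Exp(rate_i):
# P(C < T_i) for given u is (1 - exp(-r u)) / (r u) ... actually
# P(T > C) = int_0^u exp(-r c) / u dc = (1 - exp(-r u)) / (r u), which is
# the probability of censoring. Solved by uniroot on u.
censorUpper <- function(rates, censorRate) {
  if (censorRate <= 0) return(Inf)
  f <- function(u) mean((1 - exp(-rates * u)) / (rates * u)) - censorRate
  lo <- 1e-3; hi <- 1e5
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(lo, hi))$root
}
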
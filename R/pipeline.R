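# Workflow entry points: per-patient index extraction, cohort-level survival
# reporting, and observer-agreement analysis, plus the YAML-backed run
# configuration shared with the command-line script.

defaultConfig <- function() {
  list(
    segmentation = list(beta = 0.3, seed_suv_min = 2.5,
                        background_shell_mm = 8, min_lesion_ml = 0.1,
                        connectivity = 26L),
    mip = list(view = "coronal", mode = "project", threshold = 4.0),
    survival = list(band_low = 0.1, band_high = 0.9, rate_months = 60),
    phantom = list(dim = c(64L, 48L, 96L), spacing = c(4, 4, 4),
                   background = 1.0, noise_sd = 0.1),
    seed = 1L,
    outdir = ".",
    verbose = FALSE)
}

#' Run configuration
#'
#' Builds the configuration shared by [runIndices()], [runCohort()] and the
#' command-line script: sections `segmentation`, `mip`, `survival` and
#' `phantom` plus `seed`, `outdir` and `verbose`. Configurations are stored
#' as YAML; unknown keys are rejected and a written configuration reads back
#' identically.
#'
#' @param path optional YAML file to load; values override the defaults.
#' @param ... named top-level overrides (e.g. `seed = 7`,
#'   `segmentation = list(beta = 0.4)`).
#' @return a classed configuration list.
#' @export
runConfig <- function(path = NULL, ...) {
  cfg <- defaultConfig()
  mergeSection <- function(base, upd, where) {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", where, nm)
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]])))
        base[[nm]] <- mergeSection(base[[nm]], upd[[nm]],
                                   paste0(where, nm, "."))
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- mergeSection(cfg, yaml::read_yaml(path), "")
  }
  ov <- list(...)
  if (length(ov)) cfg <- mergeSection(cfg, ov, "")
  structure(cfg, class = "runConfig")
}

#' Write a run configuration to YAML
#'
#' @param config a [runConfig()] object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

segParamsFromConfig <- function(config) {
  s <- config$segmentation
  segmentationParams(beta = s$beta, seed_suv_min = s$seed_suv_min,
                     background_shell_mm = s$background_shell_mm,
                     min_lesion_ml = s$min_lesion_ml,
                     connectivity = s$connectivity)
}

#' Per-patient index extraction
#'
#' Reads a PET volume (NIfTI, SUV units), obtains lesions either from an
#' external label mask or by adaptive-threshold segmentation, and computes
#' the full [DisseminationProfile-class] including the MIP-based
#' Dmax_VoxMIP. Warnings are raised for single-lesion patients and when
#' lesions merge in projection. An empty segmentation yields a profile of
#' zeros with `nLesions = 0`.
#'
#' @param volumePath NIfTI path of the SUV volume.
#' @param maskPath optional NIfTI path of a label mask; when given,
#'   segmentation is bypassed.
#' @param config a [runConfig()].
#' @param outPath optional output path; `.json` writes JSON, anything else a
#'   one-row CSV.
#' @return the [DisseminationProfile-class], invisibly when writing.
#' @export
runIndices <- function(volumePath, maskPath = NULL, config = runConfig(),
                       outPath = NULL) {
  vol <- readVolume(volumePath)
  les <- if (!is.null(maskPath))
    lesionsFromMask(vol, readMask(maskPath))
  else segmentAdaptive(vol, segParamsFromConfig(config))
  prof <- disseminationProfile(les, view = config$mip$view)
  if (prof@nLesions == 0L)
    warning("no lesions found; profile is all zeros")
  if (prof@singleLesion)
    warning("single lesion: centroid-based indices are 0 by convention")
  if (prof@projectionMerged)
    warning("lesions merged in the 2D projection")
  if (!is.null(outPath)) {
    df <- as.data.frame(prof)
    if (grepl("\\.json$", outPath, ignore.case = TRUE))
      jsonlite::write_json(as.list(df), outPath, auto_unbox = TRUE,
                           digits = NA)
    else utils::write.csv(df, outPath, row.names = FALSE)
    return(invisible(prof))
  }
  prof
}

cohortSchema <- c("patient_id", "os_months", "os_event", "pfs_months",
                  "pfs_event")

validateCohort <- function(df) {
  miss <- setdiff(cohortSchema, names(df))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(df$os_months <= 0 | df$pfs_months <= 0 |
                 !df$os_event %in% c(0, 1) | !df$pfs_event %in% c(0, 1))
  if (length(bad))
    stop("invalid survival rows: ", paste(utils::head(bad, 10),
                                          collapse = ", "))
  if (nrow(df) < 2) stop("cohort must contain at least 2 patients")
  invisible(df)
}

fiveYearGroups <- function(time, event, horizon = 60) {
  # deceased/event within the horizon vs event-free beyond it; patients
  # censored before the horizon have unknown 5-year status and are dropped
  status <- rep(NA, length(time))
  status[event == 1 & time <= horizon] <- "event"
  status[time > horizon] <- "free"
  status
}

summaryRow <- function(v) {
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.2f [%.2f, %.2f] (range %.2f; %.2f)", qs[2], qs[1], qs[3],
          min(v), max(v))
}

#' Cohort-level prognostic analysis
#'
#' Runs the full statistical pipeline on a cohort table: per-index
#' Wilcoxon comparisons between 5-year outcome groups, Contal-O'Quigley
#' optimal cutpoints with Cox hazard ratios for OS and PFS, added-variable
#' Wald tests over the IPI (continuous indices), and the MTV x Dmax_VoxMIP
#' cross-classification into Low-Low / Mixed / High-High risk groups.
#'
#' @param cohort data.frame or CSV path with columns `patient_id`,
#'   `os_months`, `os_event`, `pfs_months`, `pfs_event`, optionally
#'   `ipi_category`, plus one column per index (any columns beyond the
#'   schema are treated as indices).
#' @param config a [runConfig()].
#' @param outdir optional directory; when given, the result tables are
#'   written as CSV (`comparison_os.csv`, `comparison_pfs.csv`,
#'   `cutpoints.csv`, `added_variable.csv`, `risk_groups.csv`) and, with
#'   `plots = TRUE`, Kaplan-Meier PNG plots.
#' @param plots draw KM plots (artifacts only; all numbers behind them are
#'   in the CSV tables).
#' @return list of class `cohortReport` with elements `comparison_os`,
#'   `comparison_pfs`, `cutpoints`, `added_variable`, `risk_groups_os`,
#'   `risk_groups_pfs`, `indices`.
#' @export
runCohort <- function(cohort, config = runConfig(), outdir = NULL,
                      plots = FALSE) {
  df <- if (is.character(cohort)) utils::read.csv(cohort) else cohort
  validateCohort(df)
  idxCols <- setdiff(names(df), c(cohortSchema, "ipi_category"))
  if (!length(idxCols)) stop("cohort contains no index columns")
  band <- c(config$survival$band_low, config$survival$band_high)
  rateM <- config$survival$rate_months
  compTable <- function(time, event) {
    status <- fiveYearGroups(time, event, rateM)
    do.call(rbind, lapply(idxCols, function(nm) {
      a <- df[[nm]][!is.na(status) & status == "free"]
      b <- df[[nm]][!is.na(status) & status == "event"]
      w <- wilcoxonMannWhitney(a, b)
      data.frame(index = nm, summary_free = summaryRow(a),
                 summary_event = summaryRow(b), n_free = length(a),
                 n_event = length(b), p_wilcoxon = w$p)
    }))
  }
  comparisonOS <- compTable(df$os_months, df$os_event)
  comparisonPFS <- compTable(df$pfs_months, df$pfs_event)
  cutRows <- list()
  cuts <- list(os = list(), pfs = list())
  for (ep in c("os", "pfs")) {
    rec <- data.frame(time = df[[paste0(ep, "_months")]],
                      event = df[[paste0(ep, "_event")]])
    for (nm in idxCols) {
      cp <- contalOQuigley(rec, df[[nm]], band = band, rateMonths = rateM)
      cuts[[ep]][[nm]] <- cp
      cutRows[[length(cutRows) + 1L]] <- data.frame(
        endpoint = toupper(ep), index = nm, cutoff = cp$cutoff,
        n_high = cp$n_high, n_low = cp$n_low,
        rate_high = cp$rate_high, rate_low = cp$rate_low,
        hr = cp$hr, ci_low = cp$ci95[1], ci_high = cp$ci95[2],
        p_logrank = cp$p_logrank, p_adjusted = cp$p_adjusted)
    }
  }
  cutpoints <- do.call(rbind, cutRows)
  addedVariable <- NULL
  if ("ipi_category" %in% names(df) &&
      nlevels(droplevels(factor(df$ipi_category))) >= 2) {
    addedVariable <- do.call(rbind, lapply(idxCols, function(nm) {
      do.call(rbind, lapply(c("os", "pfs"), function(ep) {
        rec <- data.frame(time = df[[paste0(ep, "_months")]],
                          event = df[[paste0(ep, "_event")]])
        wv <- waldAddedVariable(rec, df$ipi_category, df[[nm]])
        data.frame(endpoint = toupper(ep), index = nm, hr = wv$hr,
                   ci_low = wv$ci95[1], ci_high = wv$ci95[2],
                   p_wald = wv$p_wald)
      }))
    }))
  } else {
    warning("no usable ipi_category column; added-variable table skipped")
  }
  riskOS <- riskPFS <- NULL
  if (all(c("mtv", "dmax_voxmip") %in% idxCols)) {
    for (ep in c("os", "pfs")) {
      rec <- data.frame(time = df[[paste0(ep, "_months")]],
                        event = df[[paste0(ep, "_event")]])
      rg <- crossClassify(rec, df$mtv, df$dmax_voxmip,
                          cuts[[ep]][["mtv"]]$cutoff,
                          cuts[[ep]][["dmax_voxmip"]]$cutoff,
                          rateMonths = rateM)
      if (ep == "os") riskOS <- rg else riskPFS <- rg
    }
  }
  report <- structure(list(comparison_os = comparisonOS,
                           comparison_pfs = comparisonPFS,
                           cutpoints = cutpoints,
                           added_variable = addedVariable,
                           risk_groups_os = riskOS,
                           risk_groups_pfs = riskPFS,
                           indices = idxCols),
                      class = "cohortReport")
  if (!is.null(outdir)) writeCohortReport(report, df, cuts, outdir, plots)
  report
}

writeCohortReport <- function(report, df, cuts, outdir, plots) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(outdir, f), row.names = FALSE)
  wr(report$comparison_os, "comparison_os.csv")
  wr(report$comparison_pfs, "comparison_pfs.csv")
  wr(report$cutpoints, "cutpoints.csv")
  wr(report$added_variable, "added_variable.csv")
  risk <- rbind(
    if (!is.null(report$risk_groups_os))
      cbind(endpoint = "OS", report$risk_groups_os$table),
    if (!is.null(report$risk_groups_pfs))
      cbind(endpoint = "PFS", report$risk_groups_pfs$table))
  wr(risk, "risk_groups.csv")
  if (plots) {
    for (ep in c("os", "pfs")) {
      for (nm in names(cuts[[ep]])) {
        cp <- cuts[[ep]][[nm]]
        rec <- data.frame(time = df[[paste0(ep, "_months")]],
                          event = df[[paste0(ep, "_event")]],
                          high = df[[nm]] > cp$cutoff)
        fit <- survival::survfit(survival::Surv(time, event) ~ high,
                                 data = rec)
        grDevices::png(file.path(outdir, sprintf("km_%s_%s.png", ep, nm)),
                       width = 600, height = 500)
        graphics::plot(fit, col = c("blue", "red"), xlab = "Months",
                       ylab = "Survival",
                       main = sprintf("%s by %s (cutoff %.3g)",
                                      toupper(ep), nm, cp$cutoff))
        graphics::legend("bottomleft", c("Low", "High"),
                         col = c("blue", "red"), lty = 1)
        grDevices::dev.off()
      }
    }
  }
  invisible(report)
}

#' @export
print.cohortReport <- function(x, ...) {
  cat("Cohort report:", length(x$indices), "indices\n\n")
  cat("Optimal cutpoints (Contal-O'Quigley):\n")
  print(x$cutpoints, row.names = FALSE, digits = 4)
  if (!is.null(x$risk_groups_os)) {
    cat("\nOS risk groups:\n"); print(x$risk_groups_os$table,
                                      row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Observer-agreement analysis
#'
#' Matches two measurement tables on `patient_id` and runs a Bland-Altman
#' agreement analysis of their `value` columns.
#'
#' @param a,b data.frames (or CSV paths) with columns `patient_id` and
#'   `value`.
#' @param plotPath optional PNG path for the Bland-Altman plot.
#' @return a [blandAltman()] result.
#' @export
runAgreement <- function(a, b, plotPath = NULL) {
  ra <- if (is.character(a)) utils::read.csv(a) else a
  rb <- if (is.character(b)) utils::read.csv(b) else b
  stopifnot(all(c("patient_id", "value") %in% names(ra)),
            all(c("patient_id", "value") %in% names(rb)))
  m <- match(ra$patient_id, rb$patient_id)
  if (anyNA(m)) stop("unmatched patient ids: ",
                     paste(utils::head(ra$patient_id[is.na(m)], 5),
                           collapse = ", "))
  res <- blandAltman(ra$value, rb$value[m])
  if (!is.null(plotPath)) {
    grDevices::png(plotPath, width = 600, height = 500)
    plotBlandAltman(res, main = "Bland-Altman agreement")
    grDevices::dev.off()
  }
  res
}
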
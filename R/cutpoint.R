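# Optimal survival cutpoint (Contal-O'Quigley), two-group Cox models,
# added-variable Wald tests and cross-classified risk groups.

# Log-rank scores U_i = delta_i - NelsonAalen(t_i); the sum of scores over a
# group equals that group's O - E log-rank numerator, which makes the
# candidate scan a cumulative sum over subjects sorted by index value.
logrankScores <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  dN <- vapply(dt, function(t) sum(time == t & event == 1), numeric(1))
  Y <- vapply(dt, function(t) sum(time >= t), numeric(1))
  cumhaz <- cumsum(dN / Y)
  haz_at <- stats::stepfun(dt, c(0, cumhaz))(time)
  event - haz_at
}

# Brownian-bridge supremum tail: p = 2 sum_{j>=1} (-1)^{j+1} exp(-2 j^2 q^2),
# truncated when terms fall below 1e-10; clamped to [0, 1] (the series is an
# asymptotic approximation and exceeds 1 for small q).
bridgePvalue <- function(q) {
  if (q <= 0) return(1)
  p <- 0
  j <- 1
  repeat {
    term <- exp(-2 * j^2 * q^2)
    p <- p + (-1)^(j + 1) * term
    if (term < 1e-10 || j > 1000) break
    j <- j + 1
  }
  min(1, max(0, 2 * p))
}

#' Optimal survival cutpoint by the Contal-O'Quigley method
#'
#' Scans candidate cutoffs of a continuous index and selects the one
#' maximising the absolute two-group log-rank statistic, with a p-value
#' adjusted for the search. Writing \eqn{U_i} for the log-rank score of
#' subject i (event indicator minus Nelson-Aalen cumulative hazard at the
#' subject's time), the statistic at cutoff c is
#' \eqn{S(c) = \sum_{x_i \le c} U_i} — the O - E log-rank numerator of the
#' low group. The standardised maximum
#' \eqn{q = \max_c |S(c)| / (s \sqrt{n-1})}, with
#' \eqn{s^2 = \sum U_i^2 / (n-1)}, is referred to the supremum of a Brownian
#' bridge: \eqn{p = 2 \sum_{j \ge 1} (-1)^{j+1} e^{-2 j^2 q^2}}.
#'
#' Candidates are the distinct observed values whose low/high split leaves
#' both groups non-empty, restricted to an inner quantile band (default
#' 10-90%) to avoid degenerate tiny groups. Patients with index value at or
#' below the cutoff form the "Low" (reference) group.
#'
#' @param records data.frame with `time` and `event`.
#' @param values numeric index values, one per record.
#' @param band inner quantile band for candidate cutoffs.
#' @param rateMonths time at which per-group survival rates are reported.
#' @return list of class `cutpointResult`: `cutoff`, `q`, `p_adjusted`,
#'   `p_logrank` (naive log-rank p at the selected cutoff), `hr`, `ci95`
#'   (Wald), `rate_high`, `rate_low`, `n_high`, `n_low`, and the scan table
#'   `scan` (candidate cutoffs with their scores).
#' @examples
#' coh <- simulateCohort(n = 120, seed = 3,
#'                       betas = c(dmax_voxmip = log(3)),
#'                       cutpoints = c(dmax_voxmip = 30))
#' contalOQuigley(data.frame(time = coh$os_months, event = coh$os_event),
#'                coh$dmax_voxmip)
#' @export
contalOQuigley <- function(records, values, band = c(0.1, 0.9),
                           rateMonths = 60) {
  checkRecords(records)
  n <- nrow(records)
  if (length(values) != n) stop("values must match records")
  if (sum(records$event) < 1) stop("no events in cohort")
  if (length(unique(values)) < 2) stop("index values are all identical")
  U <- logrankScores(records$time, records$event)
  ord <- order(values)
  vs <- values[ord]
  cumU <- cumsum(U[ord])
  # candidate cutoffs: last position of each distinct value, both groups
  # non-empty, value within the inner quantile band
  lastOfValue <- which(c(diff(vs) > 0, FALSE))
  if (!length(lastOfValue)) stop("no admissible candidate cutoffs")
  qb <- stats::quantile(values, band, names = FALSE, type = 7)
  inBand <- vs[lastOfValue] >= qb[1] & vs[lastOfValue] <= qb[2]
  if (any(inBand)) lastOfValue <- lastOfValue[inBand]
  S <- cumU[lastOfValue]
  cand <- vs[lastOfValue]
  best <- which.max(abs(S))
  cutoff <- cand[best]
  s2 <- sum(U^2) / (n - 1)
  q <- max(abs(S)) / (sqrt(s2) * sqrt(n - 1))
  padj <- bridgePvalue(q)
  high <- values > cutoff
  # monotone likelihood is reported via the `monotone` field, not a warning
  cox <- suppressWarnings(coxTwoGroup(records, high))
  kmH <- kmEstimate(records[high, , drop = FALSE], rateMonths)
  kmL <- kmEstimate(records[!high, , drop = FALSE], rateMonths)
  structure(list(cutoff = cutoff, q = q, p_adjusted = padj,
                 p_logrank = cox$p_logrank, hr = cox$hr, ci95 = cox$ci95,
                 rate_high = kmH$rate, rate_low = kmL$rate,
                 n_high = sum(high), n_low = sum(!high),
                 monotone = cox$monotone,
                 scan = data.frame(cutoff = cand, score = S)),
            class = "cutpointResult")
}

#' @export
print.cutpointResult <- function(x, ...) {
  cat(sprintf("Contal-O'Quigley cutpoint: %.4g (q = %.3f, adj. p = %.4f)\n",
              x$cutoff, x$q, x$p_adjusted))
  cat(sprintf("  High (n = %d) vs Low (n = %d): HR = %.2f (%.2f-%.2f), ",
              x$n_high, x$n_low, x$hr, x$ci95[1], x$ci95[2]))
  cat(sprintf("log-rank p = %.4f\n", x$p_logrank))
  cat(sprintf("  Survival rate: high %.0f%%, low %.0f%%\n",
              100 * x$rate_high, 100 * x$rate_low))
  invisible(x)
}

#' Two-group Cox proportional hazards model
#'
#' Partial-likelihood hazard ratio of the high group vs the low (reference)
#' group with Wald 95% CI (Efron tie handling), plus the naive two-group
#' log-rank p. Monotone likelihood (a group without events) is flagged and
#' the CI reported as unbounded.
#'
#' @param records data.frame with `time` and `event`.
#' @param high logical group indicator (TRUE = high).
#' @return list with `hr`, `ci95`, `p_wald`, `p_logrank`, `monotone`.
#' @export
coxTwoGroup <- function(records, high) {
  checkRecords(records)
  high <- as.logical(high)
  if (all(high) || !any(high)) stop("both groups must be non-empty")
  if (sum(records$event) < 1) stop("no events")
  d <- data.frame(time = records$time, event = records$event, high = high)
  monotone <- any(tapply(d$event, d$high, sum) == 0)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ high, data = d,
                    ties = "efron"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ high, data = d)
  plr <- stats::pchisq(sd2$chisq, df = 1, lower.tail = FALSE)
  ci <- if (monotone) c(0, Inf) else exp(beta + c(-1.96, 1.96) * se)
  if (monotone)
    warning("monotone likelihood: a group has no events; CI unbounded")
  list(hr = exp(beta), ci95 = ci,
       p_wald = stats::pchisq((beta / se)^2, 1, lower.tail = FALSE),
       p_logrank = plr, monotone = monotone)
}

#' Added-variable Wald test over the IPI
#'
#' Fits a Cox model with the (categorical) IPI plus a continuous imaging
#' index and tests the index coefficient with the Wald chi-square — does the
#' imaging variable add prognostic information to a model already containing
#' the IPI?
#'
#' @param records data.frame with `time` and `event`.
#' @param ipi factor-like IPI category per record (>= 2 levels present).
#' @param values continuous index values per record.
#' @return list with `hr` (per unit of the index), `ci95`, `p_wald`,
#'   `flagged` (TRUE when the fit is degenerate).
#' @export
waldAddedVariable <- function(records, ipi, values) {
  checkRecords(records)
  ipi <- factor(ipi)
  if (nlevels(droplevels(ipi)) < 2)
    stop("IPI must have at least 2 levels present")
  if (length(values) != nrow(records) || length(ipi) != nrow(records))
    stop("covariate lengths must match records")
  d <- data.frame(time = records$time, event = records$event,
                  ipi = droplevels(ipi), x = values)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ ipi + x, data = d,
                    ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[["x"]]
  if (is.na(beta)) {
    # perfectly collinear with IPI: the index adds no information
    return(list(hr = NA_real_, ci95 = c(NA_real_, NA_real_), p_wald = 1,
                flagged = TRUE))
  }
  se <- sqrt(stats::vcov(fit)["x", "x"])
  list(hr = exp(beta), ci95 = exp(beta + c(-1.96, 1.96) * se),
       p_wald = stats::pchisq((beta / se)^2, 1, lower.tail = FALSE),
       flagged = flagged)
}

#' Cross-classified risk groups from two dichotomized indices
#'
#' Partitions patients into Low-Low (both indices at or below their cutoffs),
#' Mixed (exactly one above) and High-High (both above), then reports
#' per-group Kaplan-Meier survival rates and Cox hazard ratios against the
#' Low-Low reference.
#'
#' @param records data.frame with `time` and `event`.
#' @param mtv,voxmip index values per record.
#' @param mtvCut,voxmipCut the two cutoffs.
#' @param rateMonths time at which per-group survival rates are reported.
#' @return list of class `riskGroups3`: `group` (factor per patient),
#'   `table` (per-group n, events, survival rate, HR vs Low-Low with CI),
#'   `flagged` (TRUE when a group is empty or the reference has no events).
#' @export
crossClassify <- function(records, mtv, voxmip, mtvCut, voxmipCut,
                          rateMonths = 60) {
  checkRecords(records)
  hiM <- mtv > mtvCut
  hiV <- voxmip > voxmipCut
  group <- factor(ifelse(hiM & hiV, "High-High",
                         ifelse(hiM | hiV, "Mixed", "Low-Low")),
                  levels = c("Low-Low", "Mixed", "High-High"))
  counts <- table(group)
  flagged <- any(counts == 0) || counts["Low-Low"] == 0 ||
    sum(records$event[group == "Low-Low"]) == 0
  rates <- vapply(levels(group), function(g) {
    if (counts[g] == 0) return(NA_real_)
    kmEstimate(records[group == g, , drop = FALSE], rateMonths)$rate
  }, numeric(1))
  hr <- c(`Low-Low` = 1, Mixed = NA_real_, `High-High` = NA_real_)
  lo <- hi <- c(`Low-Low` = NA_real_, Mixed = NA_real_,
                `High-High` = NA_real_)
  if (!flagged) {
    d <- data.frame(time = records$time, event = records$event,
                    group = group)
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ group, data = d,
                      ties = "efron"))
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    hr[c("Mixed", "High-High")] <- exp(cf)
    lo[c("Mixed", "High-High")] <- exp(cf - 1.96 * se)
    hi[c("Mixed", "High-High")] <- exp(cf + 1.96 * se)
  } else {
    warning("degenerate risk-group partition; HRs not estimable")
  }
  tab <- data.frame(group = levels(group), n = as.integer(counts),
                    events = as.integer(tapply(records$event, group, sum,
                                               default = 0)),
                    rate = rates, hr = hr, ci_low = lo, ci_high = hi,
                    row.names = NULL)
  structure(list(group = group, table = tab, flagged = flagged),
            class = "riskGroups3")
}

#' @export
print.riskGroups3 <- function(x, ...) {
  cat("Cross-classified risk groups (MTV x Dmax_VoxMIP):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
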
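# Group comparisons, Kaplan-Meier, log-rank scores and Bland-Altman
# agreement. Survival records are data.frames with columns `time` (months,
# > 0) and `event` (0/1).

checkRecords <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in%
                                          names(records)))
  if (any(records$time <= 0)) stop("survival times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(records)
}

#' Wilcoxon-Mann-Whitney two-sample comparison
#'
#' Exact distribution when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie correction.
#'
#' @param x,y non-empty numeric samples.
#' @return list with the U statistic (number of (x, y) pairs with x < y,
#'   i.e. `wilcox.test`'s W for x) and the two-sided p-value.
#' @export
wilcoxonMannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator; the survival rate at `rateMonths`
#' (default 60 months, the "5-year" rate) is read off the step function.
#'
#' @param records data.frame with `time` and `event`.
#' @param rateMonths time in months at which the survival rate is reported.
#' @return list of class `kmEstimate`: step-function support `time`,
#'   estimate `surv`, `rate` at `rateMonths`, the `survfit` object `fit`.
#' @export
kmEstimate <- function(records, rateMonths = 60) {
  checkRecords(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  sm <- summary(fit, times = rateMonths, extend = TRUE)
  structure(list(time = fit$time, surv = fit$surv,
                 rate = unname(sm$surv), rateMonths = rateMonths, fit = fit),
            class = "kmEstimate")
}

#' @export
print.kmEstimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: S(%g months) = %.3f (%d subjects)\n",
              x$rateMonths, x$rate, x$fit$n))
  invisible(x)
}

#' Two-group log-rank score statistic
#'
#' The classical O - E score for the high group with its hypergeometric
#' variance, accumulated over distinct event times. `chisq = score^2 / var`
#' is the usual log-rank chi-square on 1 df.
#'
#' @param records data.frame with `time` and `event`.
#' @param high logical vector: TRUE for the high group.
#' @return list with `score` (O - E of the high group), `var`, `chisq`, `p`.
#' @export
logrankScore <- function(records, high) {
  checkRecords(records)
  high <- as.logical(high)
  if (all(high) || !any(high)) stop("both groups must be non-empty")
  tt <- records$time
  ev <- records$event
  dtimes <- sort(unique(tt[ev == 1]))
  score <- 0
  v <- 0
  for (t in dtimes) {
    at <- tt >= t
    r <- sum(at)
    r1 <- sum(at & high)
    d <- sum(tt == t & ev == 1)
    d1 <- sum(tt == t & ev == 1 & high)
    score <- score + d1 - d * r1 / r
    if (r > 1)
      v <- v + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
  }
  chisq <- if (v > 0) score^2 / v else NA_real_
  list(score = score, var = v, chisq = chisq,
       p = if (is.na(chisq)) NA_real_ else
         stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Bland-Altman agreement statistics
#'
#' Bias = mean(a - b); limits of agreement = bias +/- 1.96 sd(a - b).
#' With a constant offset between the methods the sd of differences is 0 and
#' the limits collapse onto the bias.
#'
#' @param a,b paired measurement vectors (same length, >= 2 pairs).
#' @return list of class `blandAltman`: `bias`, `sd`, `loa` (length 2),
#'   `differences`, `means`.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s, loa = bias + c(-1.96, 1.96) * s,
                 differences = d, means = (a + b) / 2), class = "blandAltman")
}

#' @export
print.blandAltman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, LoA = [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], length(x$differences)))
  invisible(x)
}

#' Bland-Altman plot (difference vs mean)
#'
#' @param x a [blandAltman()] result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plotBlandAltman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "Mean of measurements",
                 ylab = "Difference", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2),
                   col = c("black", "red", "red"))
  invisible(x)
}
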
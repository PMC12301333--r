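test_that("Wilcoxon-Mann-Whitney uses the exact small-sample distribution", {
  # {1,2,3} vs {4,5,6}: U = 0; among C(6,3) = 20 equally likely label
  # assignments only the two extreme ones are as or more extreme -> p = 0.1
  w <- wilcoxonMannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(w$U), 0)
  expect_equal(w$p, 2 / 20)
  expect_true(w$exact)

  same <- wilcoxonMannWhitney(c(5, 9, 13, 40), c(5, 9, 13, 40))
  expect_gt(same$p, 0.95)
  expect_error(wilcoxonMannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon null rejection rate is calibrated at large n", {
  set.seed(401)
  reps <- 2000
  rej <- mean(vapply(seq_len(reps), function(i) {
    wilcoxonMannWhitney(stats::rnorm(200), stats::rnorm(200))$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  # no events -> S(t) = 1 everywhere
  none <- kmEstimate(data.frame(time = c(10, 20, 70), event = c(0, 0, 0)))
  expect_equal(none$rate, 1)

  # all events, no censoring: S = 2/3, 1/3, 0
  km <- kmEstimate(data.frame(time = 1:3, event = c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # mixed censored 6-record set, worked by hand:
  # t=2 d=1 n=6 -> 5/6; t=5 d=1 n=4 -> 5/8; t=9 d=1 n=2 -> 5/16; t=12 -> 0
  rec <- data.frame(time = c(2, 4, 5, 7, 9, 12),
                    event = c(1, 0, 1, 0, 1, 1))
  km6 <- kmEstimate(rec)
  expect_equal(km6$surv[km6$time == 2], 5 / 6)
  expect_equal(km6$surv[km6$time == 5], 5 / 8)
  expect_equal(km6$surv[km6$time == 9], 5 / 16)
  expect_equal(km6$surv[km6$time == 12], 0)
  # uncensored KM equals the empirical survival function
  tt <- c(3, 7, 7, 15, 21)
  kme <- kmEstimate(data.frame(time = tt, event = 1))
  for (i in seq_along(kme$time))
    expect_equal(kme$surv[i], mean(tt > kme$time[i]))
})

test_that("log-rank score is zero for paired clones and matches survdiff", {
  rec <- data.frame(time = rep(c(3, 8, 14, 20), 2),
                    event = rep(c(1, 1, 0, 1), 2))
  ls0 <- logrankScore(rec, rep(c(TRUE, FALSE), each = 4))
  expect_equal(ls0$score, 0)

  # hand-worked toy: times (1-,2+,3-) in A, (2-,4-) in B ("-" death)
  # t=1: r=5 rA=3 d=1 dA=1 -> O-E(A) = 1 - 3/5
  # t=2: r=4 rA=2 d=1 dA=0 -> 0 - 1/2
  # t=3: r=2 rA=1 d=1 dA=1 -> 1 - 1/2
  # t=4: r=1 rA=0 d=1      -> 0
  rec2 <- data.frame(time = c(1, 2, 3, 2, 4), event = c(1, 0, 1, 1, 1))
  inA <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  ls <- logrankScore(rec2, inA)
  expect_equal(ls$score, (1 - 3 / 5) + (0 - 1 / 2) + (1 - 1 / 2))

  set.seed(402)
  for (i in 1:5) {
    n <- 60
    rec3 <- data.frame(time = stats::rexp(n, 0.05),
                       event = stats::rbinom(n, 1, 0.8))
    grp <- stats::runif(n) < 0.5
    mine <- logrankScore(rec3, grp)
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = rec3)
    expect_equal(mine$chisq, sd$chisq, tolerance = 1e-9)
  }
})

test_that("log-rank chi-square is chi-square(1) under a permutation null", {
  set.seed(403)
  n <- 80
  rec <- data.frame(time = stats::rexp(n, 0.04),
                    event = stats::rbinom(n, 1, 0.85))
  stats <- vapply(1:400, function(i) {
    logrankScore(rec, sample(rep(c(TRUE, FALSE), n / 2)))$chisq
  }, numeric(1))
  # compare permutation quantiles to chi-square(1)
  expect_lt(abs(mean(stats > stats::qchisq(0.95, 1)) - 0.05), 0.03)
  expect_lt(abs(stats::median(stats) - stats::qchisq(0.5, 1)), 0.15)
})

test_that("Cox two-group model matches a direct partial-likelihood search", {
  # 10-subject toy without ties: maximise the 1-parameter partial
  # likelihood by golden-section search and compare to the package route
  set.seed(404)
  time <- c(2, 3, 5, 7, 8, 11, 13, 17, 19, 23)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  high <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  pl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * high[i] - log(sum(exp(beta * high[risk])))
    }
    ll
  }
  opt <- stats::optimize(pl, c(-4, 4), maximum = TRUE)
  fit <- coxTwoGroup(data.frame(time = time, event = event), high)
  expect_equal(log(fit$hr), opt$maximum, tolerance = 1e-4)

  # identical groups -> HR ~ 1
  rec <- data.frame(time = rep(c(4, 9, 16, 30), 2),
                    event = rep(c(1, 1, 0, 1), 2))
  same <- coxTwoGroup(rec, rep(c(TRUE, FALSE), each = 4))
  expect_equal(same$hr, 1, tolerance = 1e-6)
  expect_true(same$ci95[1] <= same$hr && same$hr <= same$ci95[2])

  # no events in one group -> monotone likelihood flagged, CI unbounded
  recm <- data.frame(time = c(1, 2, 3, 10, 12, 14),
                     event = c(1, 1, 1, 0, 0, 0))
  expect_warning(m <- coxTwoGroup(recm, c(T, T, T, F, F, F)), "monotone")
  expect_true(m$monotone)
  expect_equal(m$ci95, c(0, Inf))
})

test_that("Cox estimate is invariant under time rescaling", {
  set.seed(405)
  n <- 150
  grp <- stats::runif(n) < 0.5
  t <- stats::rexp(n, 0.01 * ifelse(grp, 2, 1))
  cens <- stats::runif(n, 0, 200)
  rec <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
  a <- coxTwoGroup(rec, grp)
  rec2 <- transform(rec, time = time * 7.3)
  b <- coxTwoGroup(rec2, grp)
  expect_equal(a$hr, b$hr, tolerance = 1e-9)
})

test_that("added-variable Wald test detects signal and ignores collinearity", {
  set.seed(406)
  n <- 300
  ipi <- sample(c("0-1", "2-3", "4-5"), n, replace = TRUE)
  ipiNum <- as.integer(factor(ipi)) - 1L
  # index duplicating IPI exactly: near-zero added information
  t <- stats::rexp(n, 0.01 * exp(0.5 * ipiNum))
  rec <- data.frame(time = t, event = 1L)
  dup <- waldAddedVariable(rec, ipi, ipiNum + 0.0)
  expect_gt(dup$p_wald, 0.2)

  # independently prognostic index on top of IPI: strong Wald signal
  x <- stats::rnorm(n)
  t2 <- stats::rexp(n, 0.01 * exp(0.5 * ipiNum + log(3) * (x > 0)))
  rec2 <- data.frame(time = t2, event = 1L)
  sig <- waldAddedVariable(rec2, ipi, x)
  expect_lt(sig$p_wald, 0.01)
  expect_error(waldAddedVariable(rec2, rep("2-3", n), x), "levels")
})

test_that("pure-noise indices keep the added-variable test at its level", {
  set.seed(407)
  n <- 200
  rej <- mean(vapply(1:200, function(i) {
    ipiNum <- sample(0:2, n, replace = TRUE)
    t <- stats::rexp(n, 0.01 * exp(0.4 * ipiNum))
    cens <- stats::runif(n, 0, 250)
    rec <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
    waldAddedVariable(rec, ipiNum, stats::rnorm(n))$p_wald < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("cross-classification partitions and orders risk groups", {
  set.seed(408)
  n <- 600
  mtv <- stats::rlnorm(n, log(300), 1)
  vox <- stats::rlnorm(n, log(30), 0.8)
  mtvCut <- stats::median(mtv)
  voxCut <- stats::median(vox)
  lp <- 0.7 * (mtv > mtvCut) + 0.7 * (vox > voxCut)
  t <- stats::rexp(n, 0.008 * exp(lp))
  cens <- stats::runif(n, 0, 200)
  rec <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
  rg <- crossClassify(rec, mtv, vox, mtvCut, voxCut)
  expect_equal(sum(rg$table$n), n)
  expect_false(any(is.na(rg$group)))
  r <- rg$table$rate
  expect_true(r[1] >= r[2] && r[2] >= r[3])
  expect_true(all(rg$table$hr[2:3] > 1))
  expect_equal(rg$table$hr[1], 1)

  # all patients below both cutoffs: single group, flagged
  expect_warning(
    deg <- crossClassify(rec, mtv, vox, max(mtv) + 1, max(vox) + 1),
    "degenerate")
  expect_true(deg$flagged)
  expect_true(all(is.na(deg$table$hr[2:3])))
})

test_that("Bland-Altman recovers bias and limits of agreement", {
  a <- c(1, 4.5, 7, 12)
  shifted <- blandAltman(a, a + 1)
  expect_equal(shifted$bias, -1)
  expect_equal(shifted$sd, 0)
  expect_equal(shifted$loa, c(-1, -1))
  expect_equal(blandAltman(a, a)$bias, 0)
  expect_error(blandAltman(1, 2), "2 pairs")
  expect_error(blandAltman(1:4, 1:5), "paired")
})

test_that("cutpoint scan maximiser equals an exhaustive log-rank scan", {
  for (s in 411:418) {
    sim <- simulateStepCohort(n = 60, seed = s, hr = 2)
    cp <- contalOQuigley(sim$records, sim$values)
    # brute force: per-candidate O-E via the hypergeometric log-rank route
    cand <- cp$scan$cutoff
    bruteScores <- vapply(cand, function(c)
      logrankScore(sim$records, sim$values > c)$score, numeric(1))
    # score of high group = -(score of low group) accumulated in the scan
    expect_equal(cp$scan$score, -bruteScores, tolerance = 1e-9)
    expect_equal(cp$cutoff, cand[which.max(abs(bruteScores))])
  }
})

test_that("cutpoint search needs events and variation", {
  rec <- data.frame(time = c(5, 9, 11), event = c(0, 0, 0))
  expect_error(contalOQuigley(rec, c(1, 2, 3)), "events")
  rec2 <- data.frame(time = c(5, 9, 11), event = c(1, 1, 0))
  expect_error(contalOQuigley(rec2, c(2, 2, 2)), "identical")
})

test_that("adjusted p is conservative relative to the naive scan minimum", {
  set.seed(419)
  worse <- 0
  for (i in 1:40) {
    sim <- simulateStepCohort(n = 80, seed = 1000 + i, hr = 1)
    cp <- contalOQuigley(sim$records, sim$values)
    naiveMin <- min(vapply(cp$scan$cutoff, function(c)
      logrankScore(sim$records, sim$values > c)$p, numeric(1)))
    if (cp$p_adjusted < naiveMin - 1e-12) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
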
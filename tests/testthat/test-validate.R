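# Independent oracles ------------------------------------------------------

# Brute-force "sort and index" percentile: same definition, written directly.
lobOracle <- function(x, pct) {
    x <- sort(x)
    n <- length(x)
    r <- n * pct + 0.5
    if (r <= 1) return(x[1])
    if (r >= n) return(x[n])
    lo <- floor(r)
    x[lo] + (r - lo) * (x[lo + 1] - x[lo])
}

# Dense grid-search ML for the binomial probit on log10(vaf).
probitGridOracle <- function(lv, aGrid, bGrid) {
    x <- log10(lv$vaf)
    best <- c(a = NA, b = NA); bestLl <- -Inf
    for (a in aGrid) for (b in bGrid) {
        p <- pmin(pmax(pnorm(a + b * x), 1e-12), 1 - 1e-12)
        ll <- sum(lv$nPos * log(p) + (lv$nTotal - lv$nPos) * log(1 - p))
        if (ll > bestLl) { bestLl <- ll; best <- c(a = a, b = b) }
    }
    best
}

# Linearity ----------------------------------------------------------------

test_that("linearity reproduces R^2 by direct sum-of-squares arithmetic", {
    # exactly collinear points
    fitc <- suppressWarnings(  # lm flags the zero-residual fit
        assessLinearity(c(1, 2, 3, 4), 2 + 3 * c(1, 2, 3, 4)))
    expect_equal(rSquared(fitc), 1)
    expect_equal(fitc@slope, 3)

    # injected residual noise: compare against 1 - SSE/SST computed by hand
    set.seed(77)
    nominal <- c(50, 20, 5, 1, 0.2, 0.1)
    measured <- 1.02 * nominal + rnorm(6, 0, 0.5)
    fit <- assessLinearity(nominal, measured)
    pred <- fit@intercept + fit@slope * nominal
    sse <- sum((measured - pred)^2)
    sst <- sum((measured - mean(measured))^2)
    expect_equal(rSquared(fit), 1 - sse / sst, tolerance = 1e-10)

    expect_error(assessLinearity(c(1, 2), c(1, 2)), "3 distinct")
    expect_error(assessLinearity(rep(1, 4), 1:4), "3 distinct")
})

test_that("the published dilution-series means are collinear to 4 decimals", {
    fit <- assessLinearity(c(50, 20, 5, 1, 0.2, 0.1),
                           c(50.76, 20.39, 5.22, 0.98, 0.25, 0.10))
    expect_equal(round(rSquared(fit), 4), 1.0000)
})

# LOB ----------------------------------------------------------------------

test_that("LOB interpolates the 95th-percentile rank of 60 pooled blanks", {
    blanks <- 0.001 * (1:60)
    r <- estimateLob(blanks, 0.95)
    expect_equal(rankPosition(r), 57.5)
    expect_equal(lob(r), (sort(blanks)[57] + sort(blanks)[58]) / 2)
    expect_equal(lob(r), 0.0575)

    expect_equal(lob(estimateLob(rep(0, 60))), 0)
    expect_error(estimateLob(numeric(0)), "no blank")
    expect_error(estimateLob(runif(10)), "at least 20")
    expect_warning(estimateLob(runif(30)), "fewer than 60")
})

test_that("LOB estimator agrees with the sort-and-index oracle over N and percentile", {
    set.seed(123)
    for (n in 20:100) for (pct in c(0.90, 0.95, 0.99)) {
        x <- rexp(n, 20)
        got <- suppressWarnings(estimateLob(x, pct))
        expect_equal(lob(got), lobOracle(x, pct),
                     label = sprintf("N=%d pct=%.2f", n, pct))
    }
})

test_that("positivity is a strict comparison against the LOB", {
    expect_false(callPositive(0.10, 0.10))
    expect_false(callPositive(0, 0.10))
    expect_true(callPositive(0.15, 0.10))
    expect_identical(callPositive(c(0.05, 0.10, 0.2), 0.10),
                     c(FALSE, FALSE, TRUE))
})

# Probit LOD95 -------------------------------------------------------------

test_that("probit fit solves the closed form and matches the grid-search oracle", {
    # exact hit probabilities from (a, b) = (2, 2): ML must recover them and
    # the LOD95 closed form 10^((qnorm(.95) - 2)/2)
    vafs <- c(0.05, 0.1, 0.2, 0.5, 1, 2)
    n <- 2000L
    p <- pnorm(2 + 2 * log10(vafs))
    lv <- data.frame(vaf = vafs, nPos = round(n * p), nTotal = n)
    fit <- fitProbit(lv)
    expect_true(fit@converged)
    expect_equal(fit@intercept, 2, tolerance = 0.02)
    expect_equal(fit@slope, 2, tolerance = 0.02)
    expect_equal(lod95(fit), 10^((qnorm(0.95) - 2) / 2), tolerance = 0.005)
    # the fitted curve evaluates to exactly 95% at the reported LOD
    expect_equal(pnorm(fit@intercept + fit@slope * log10(lod95(fit))), 0.95,
                 tolerance = 1e-6)

    # grid-search likelihood oracle on noisy <= 6-level datasets
    set.seed(99)
    for (rep in 1:4) {
        lvN <- data.frame(vaf = vafs,
                          nPos = rbinom(length(vafs), 12, p), nTotal = 12)
        lvN <- lvN[lvN$nPos > 0 | lvN$vaf < 1, ]
        if (!any(lvN$nPos > 0 & lvN$nPos < lvN$nTotal)) next
        fitN <- fitProbit(lvN)
        g <- probitGridOracle(lvN, seq(0.5, 4, 0.02), seq(0.5, 4, 0.02))
        expect_equal(fitN@intercept, unname(g["a"]), tolerance = 0.03)
        expect_equal(fitN@slope, unname(g["b"]), tolerance = 0.03)
    }
})

test_that("LOD95 is invariant to duplicating every level", {
    lv <- data.frame(vaf = c(0.2, 0.1, 0.05, 0.02, 0.01),
                     nPos = c(12, 11, 9, 6, 3), nTotal = 12)
    f1 <- fitProbit(lv)
    f2 <- fitProbit(rbind(lv, lv))
    expect_equal(lod95(f2), lod95(f1), tolerance = 1e-8)
    # doubling the data shrinks, never widens, the CI
    expect_lte(f2@lodCiHigh - f2@lodCiLow, f1@lodCiHigh - f1@lodCiLow)
})

test_that("complete separation yields a flagged bracketing estimate", {
    lv <- data.frame(vaf = c(0.01, 0.02, 0.1, 0.2),
                     nPos = c(0, 0, 12, 12), nTotal = 12)
    expect_warning(fit <- fitProbit(lv), "separation")
    expect_false(fit@converged)
    expect_equal(lod95(fit), (0.02 + 0.1) / 2)

    dec <- data.frame(vaf = c(0.01, 0.1, 1), nPos = c(12, 6, 0), nTotal = 12)
    expect_error(fitProbit(dec), "slope")
})

test_that("the five-level, 12-replicate design recovers the true 95% detection point", {
    # generating model: P(detect | v) = pnorm(a + b log10 v) with the true
    # 95% point placed near 0.1% VAF
    aTrue <- qnorm(0.95) + 2
    bTrue <- 2
    trueLod <- 10^((qnorm(0.95) - aTrue) / bTrue)
    vafs <- c(0.2, 0.1, 0.05, 0.02, 0.01)
    p <- pnorm(aTrue + bTrue * log10(vafs))

    set.seed(2024)
    ests <- replicate(200, {
        lv <- data.frame(vaf = vafs, nPos = rbinom(5, 12, p), nTotal = 12)
        if (!any(lv$nPos > 0 & lv$nPos < lv$nTotal)) return(NA_real_)
        f <- tryCatch(suppressWarnings(fitProbit(lv)),
                      error = function(e) NULL)
        if (is.null(f)) NA_real_ else lod95(f)
    })
    ests <- ests[is.finite(ests)]
    expect_gt(length(ests), 150)
    # the true value sits inside the central 95% of the sampling distribution
    qs <- quantile(ests, c(0.025, 0.975))
    expect_gt(trueLod, qs[[1]])
    expect_lt(trueLod, qs[[2]])
    # and the median estimate is close to the truth
    expect_equal(median(ests), trueLod, tolerance = 0.1)

    # a representative realisation of the design converges with the LOD
    # inside the tested range
    set.seed(7)
    d <- data.frame(vaf = vafs, nPos = rbinom(5, 12, p), nTotal = 12)
    f <- fitProbit(d)
    expect_true(f@converged)
    expect_gt(lod95(f), min(vafs))
    expect_lt(lod95(f), max(vafs))
})

# LOQ ----------------------------------------------------------------------

test_that("Total-Error LOQ follows the rule branches", {
    # perfect level at the LOD -> LOQ = LOD for any positive goal
    st0 <- data.frame(vaf = c(0.1, 0.2), bias = c(0, 0), sd = c(0, 0))
    r0 <- computeLoq(st0, teGoal = 0.01, lod = 0.1)
    expect_equal(loq(r0), 0.1)
    expect_identical(r0@ruleApplied, "loq_equals_lod")

    # arithmetic: TE = |bias| + 2 sd
    st1 <- data.frame(vaf = 0.1, bias = 0.01, sd = 0.02)
    r1 <- computeLoq(st1, teGoal = 1, lod = 0.1)
    expect_equal(r1@levels$totalError, 0.05)
    # bias enters as absolute value
    st1n <- data.frame(vaf = 0.1, bias = -0.01, sd = 0.02)
    expect_equal(computeLoq(st1n, 1, 0.1)@levels$totalError, 0.05)

    # LOD level fails the goal -> lowest level at/above the LOD that passes
    st2 <- data.frame(vaf = c(0.05, 0.1, 0.2, 0.5),
                      bias = c(0.01, 0.2, 0.02, 0.01),
                      sd = c(0.005, 0.2, 0.01, 0.01))
    r2 <- computeLoq(st2, teGoal = 0.1, lod = 0.1)
    expect_equal(loq(r2), 0.2)
    expect_identical(r2@ruleApplied, "lowest_level_meeting_goal")

    # nothing passes -> explicit no-LOQ outcome, not an error
    st3 <- data.frame(vaf = c(0.1, 0.2), bias = c(1, 1), sd = c(1, 1))
    r3 <- computeLoq(st3, teGoal = 0.5, lod = 0.1)
    expect_true(is.na(loq(r3)))
    expect_identical(r3@ruleApplied, "no_loq")

    expect_error(computeLoq(st3, teGoal = -1, lod = 0.1), "positive")
})

test_that("raising the Total-Error goal never raises the LOQ", {
    st <- data.frame(vaf = c(0.05, 0.1, 0.2, 0.5, 1),
                     bias = c(0.04, 0.08, 0.05, 0.02, 0.01),
                     sd = c(0.05, 0.06, 0.03, 0.02, 0.01))
    goals <- c(0.05, 0.12, 0.2, 0.3, 1)
    loqs <- vapply(goals, function(g) {
        l <- loq(computeLoq(st, g, lod = 0.1))
        if (is.na(l)) Inf else l
    }, numeric(1))
    expect_true(all(diff(loqs) <= 0))
})
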
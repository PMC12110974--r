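mkCounts <- function(nMu, nWt, nDp, nTotal, id = "w")
    new("DropletCounts", wellId = id, nTotal = as.integer(nTotal),
        nDoubleNeg = as.integer(nTotal - nMu - nWt - nDp),
        nMuOnly = as.integer(nMu), nWtOnly = as.integer(nWt),
        nDoublePos = as.integer(nDp))

test_that("Poisson correction reproduces closed-form lambda and concentration", {
    # no positives -> zero
    q0 <- poissonConcentration(mkCounts(0, 0, 0, 20000), "mutant")
    expect_equal(q0@lambda, 0)
    expect_equal(concentration(q0), 0)

    # positive fraction 1 - e^-1 -> lambda exactly 1
    n <- 20000L
    nPos <- round(n * (1 - exp(-1)))
    q1 <- poissonConcentration(mkCounts(nPos, 0, 0, n), "mutant")
    expect_equal(q1@lambda, -log(1 - nPos / n))
    expect_equal(q1@lambda, 1, tolerance = 1e-4)

    # half positive at 0.85 nL: lambda = ln 2, conc = ln2 / 0.00085 uL
    q2 <- poissonConcentration(mkCounts(10000, 0, 0, 20000), "mutant",
                               dropletVolumeNl = 0.85)
    expect_equal(q2@lambda, log(2))
    expect_equal(concentration(q2), log(2) / 0.00085, tolerance = 1e-10)
    expect_lte(q2@ciLow, concentration(q2))
    expect_gte(q2@ciHigh, concentration(q2))

    # double-positives count for both targets
    q3 <- poissonConcentration(mkCounts(100, 200, 50, 20000), "wild_type")
    expect_identical(q3@nPos, 250L)

    expect_error(poissonConcentration(mkCounts(20000, 0, 0, 20000), "mutant"),
                 "saturat")
})

test_that("concentration is strictly increasing in the positive count", {
    concs <- vapply(c(10, 100, 1000, 10000, 19000), function(k)
        concentration(poissonConcentration(mkCounts(k, 0, 0, 20000), "mutant")),
        numeric(1))
    expect_true(all(diff(concs) > 0))
})

test_that("VAF arithmetic, CI ordering and error cases", {
    qm <- poissonConcentration(mkCounts(1000, 2000, 500, 20000), "mutant")
    qw <- poissonConcentration(mkCounts(1000, 2000, 500, 20000), "wild_type")
    v <- computeVaf(qm, qw)
    expect_equal(vaf(v), concentration(qm) /
                     (concentration(qm) + concentration(qw)))
    expect_lte(v@ciLow, vaf(v))
    expect_gte(v@ciHigh, vaf(v))

    # symmetric counts give exactly 50%
    qs <- poissonConcentration(mkCounts(1500, 1500, 300, 20000), "mutant")
    qsw <- poissonConcentration(mkCounts(1500, 1500, 300, 20000), "wild_type")
    expect_equal(vaf(computeVaf(qs, qsw)), 0.5)

    expect_error(computeVaf(qw, qm), "mutant and a wild_type")
    z <- poissonConcentration(mkCounts(0, 0, 0, 20000), "mutant")
    zw <- poissonConcentration(mkCounts(0, 0, 0, 20000), "wild_type")
    expect_error(computeVaf(z, zw), "undefined")
})

test_that("repeatability RSD matches hand arithmetic", {
    expect_equal(repeatabilityRsd(c(50, 50, 50)), 0)
    expect_equal(repeatabilityRsd(c(49, 50, 51)), 2)
    expect_equal(repeatabilityRsd(c(0.09, 0.10, 0.11)), 10)
    expect_error(repeatabilityRsd(42), "2 replicates")
    expect_error(repeatabilityRsd(c(0, 0)), "zero")
})

test_that("the pipeline recovers the true VAF across the 50%-0.1% ladder", {
    # fixed total loading; for each nominal level the mean estimated VAF over
    # replicate wells must be within 3 standard errors of the copy fraction
    total <- 30000
    for (lvl in c(50, 20, 5, 1, 0.2, 0.1)) {
        tv <- lvl / 100
        vs <- vapply(1:6, function(s) {
            cfg <- cleanConfig(seed = 1000 * lvl + s)
            w <- simulateDroplets(cfg, tv * total, (1 - tv) * total)
            cl <- classifyDroplets(w, manualThresholds(4500, 3500))
            qm <- poissonConcentration(cl$counts, "mutant")
            qw <- poissonConcentration(cl$counts, "wild_type")
            100 * vaf(computeVaf(qm, qw))
        }, numeric(1))
        se <- sd(vs) / sqrt(length(vs))
        expect_lt(abs(mean(vs) - lvl), 3 * se + 1e-9,
                  label = sprintf("level %g%%: mean %.4g, se %.4g",
                                  lvl, mean(vs), se))
    }
})

test_that("counting noise makes the VAF RSD grow as the VAF shrinks", {
    total <- 30000
    rsds <- vapply(c(50, 1, 0.1), function(lvl) {
        tv <- lvl / 100
        vs <- vapply(1:8, function(s) {
            cfg <- cleanConfig(seed = 7000 + 100 * lvl + s)
            w <- simulateDroplets(cfg, tv * total, (1 - tv) * total)
            cl <- classifyDroplets(w, manualThresholds(4500, 3500))
            100 * vaf(computeVaf(poissonConcentration(cl$counts, "mutant"),
                                 poissonConcentration(cl$counts, "wild_type")))
        }, numeric(1))
        repeatabilityRsd(vs)
    }, numeric(1))
    expect_true(all(diff(rsds) > 0))
})

test_that("replicate summaries carry per-replicate values and RSD", {
    v <- summarizeVafReplicates(c(0.49, 0.50, 0.51))
    expect_equal(vaf(v), 0.5)
    expect_equal(v@rsd, 2)
    expect_length(v@perReplicate, 3)
    expect_lte(v@ciLow, 0.5)
    expect_gte(v@ciHigh, 0.5)
})
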
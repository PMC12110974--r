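# Poisson single-molecule quantification and VAF with uncertainty.

# Wilson score interval for a binomial proportion.
.wilson <- function(nPos, nTotal, level) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- nPos / nTotal
    den <- 1 + z^2 / nTotal
    centre <- (p + z^2 / (2 * nTotal)) / den
    half <- z * sqrt(p * (1 - p) / nTotal + z^2 / (4 * nTotal^2)) / den
    c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Absolute target concentration from cluster counts
#'
#' Standard digital-PCR Poisson correction: with a fraction `p` of droplets
#' positive for a target, the mean copies per droplet is
#' `lambda = -log(1 - p)` and the concentration is `lambda` divided by the
#' droplet volume, times the dilution factor. Positives for the mutant target
#' are `nMuOnly + nDoublePos`; for the wild-type target,
#' `nWtOnly + nDoublePos`. The confidence interval is a Wilson score interval
#' on the positive fraction propagated through the log transform, which stays
#' stable at extreme counts.
#'
#' @param counts a [DropletCounts-class].
#' @param target `"mutant"` or `"wild_type"`.
#' @param dropletVolumeNl droplet volume, nanolitres.
#' @param dilutionFactor fold-dilution of the template before partitioning.
#' @param ciLevel confidence level (default 0.95).
#' @return a [TargetQuant-class] with concentration in copies/uL.
#' @examples
#' cts <- new("DropletCounts", wellId = "w", nTotal = 20000L,
#'            nDoubleNeg = 10000L, nMuOnly = 10000L,
#'            nWtOnly = 0L, nDoublePos = 0L)
#' concentration(poissonConcentration(cts, "mutant"))  # ln(2)/0.00085
#' @export
poissonConcentration <- function(counts, target = c("mutant", "wild_type"),
                                 dropletVolumeNl = 0.85, dilutionFactor = 1,
                                 ciLevel = 0.95) {
    stopifnot(is(counts, "DropletCounts"))
    target <- match.arg(target)
    if (counts@nTotal <= 0L) stop("nTotal must be positive")
    if (dropletVolumeNl <= 0) stop("dropletVolumeNl must be positive")
    nPos <- if (target == "mutant") counts@nMuOnly + counts@nDoublePos
            else counts@nWtOnly + counts@nDoublePos
    nTotal <- counts@nTotal
    if (nPos == nTotal)
        stop("all droplets positive for ", target,
             ": reaction saturated, concentration undefined")
    lambda <- -log1p(-nPos / nTotal)
    volUl <- dropletVolumeNl * 1e-3
    k <- dilutionFactor / volUl
    ci <- .wilson(nPos, nTotal, ciLevel)
    ciHigh <- if (ci[["high"]] >= 1) Inf else -log1p(-ci[["high"]]) * k
    new("TargetQuant", target = target,
        lambda = lambda, conc = lambda * k,
        ciLow = -log1p(-ci[["low"]]) * k, ciHigh = ciHigh,
        nPos = as.integer(nPos), nTotal = nTotal,
        dropletVolumeNl = dropletVolumeNl, dilutionFactor = dilutionFactor,
        ciLevel = ciLevel)
}

#' Variant allele fraction from the two target quantifications
#'
#' `VAF = conc_mutant / (conc_mutant + conc_wild_type)`. The confidence
#' interval comes from the delta method: each channel's `lambda` has
#' approximate variance `p / ((1 - p) * nTotal)` from the binomial positive
#' fraction, which is propagated through the ratio.
#'
#' @param qMu,qWt [TargetQuant-class] results for the mutant and wild-type
#'   targets of the same sample.
#' @param ciLevel confidence level for the interval.
#' @return a [VafResult-class].
#' @examples
#' cts <- new("DropletCounts", wellId = "w", nTotal = 20000L,
#'            nDoubleNeg = 16000L, nMuOnly = 1000L,
#'            nWtOnly = 2000L, nDoublePos = 1000L)
#' vafPercent(computeVaf(poissonConcentration(cts, "mutant"),
#'                       poissonConcentration(cts, "wild_type")))
#' @export
computeVaf <- function(qMu, qWt, ciLevel = 0.95) {
    stopifnot(is(qMu, "TargetQuant"), is(qWt, "TargetQuant"))
    if (qMu@target != "mutant" || qWt@target != "wild_type")
        stop("computeVaf expects a mutant and a wild_type quantification")
    cm <- qMu@conc; cw <- qWt@conc
    if (cm + cw <= 0) stop("both concentrations are zero: VAF undefined")
    v <- cm / (cm + cw)
    varLambda <- function(q) {
        p <- q@nPos / q@nTotal
        p / ((1 - p) * q@nTotal)
    }
    kMu <- qMu@dilutionFactor / (qMu@dropletVolumeNl * 1e-3)
    kWt <- qWt@dilutionFactor / (qWt@dropletVolumeNl * 1e-3)
    vm <- kMu^2 * varLambda(qMu)
    vw <- kWt^2 * varLambda(qWt)
    se <- sqrt(cw^2 * vm + cm^2 * vw) / (cm + cw)^2
    z <- stats::qnorm(1 - (1 - ciLevel) / 2)
    new("VafResult", vaf = v,
        ciLow = max(0, v - z * se), ciHigh = min(1, v + z * se),
        perReplicate = numeric(0), rsd = NA_real_)
}

#' Repeatability as relative standard deviation
#'
#' `100 * sd(x) / mean(x)` over replicate VAF measurements (sample SD).
#'
#' @param replicateVafs two or more replicate measurements (any common scale).
#' @return the RSD in percent.
#' @examples
#' repeatabilityRsd(c(49, 50, 51))  # 2
#' @export
repeatabilityRsd <- function(replicateVafs) {
    if (length(replicateVafs) < 2L) stop("at least 2 replicates required")
    m <- mean(replicateVafs)
    if (m == 0) stop("mean of replicates is zero: RSD undefined")
    100 * stats::sd(replicateVafs) / m
}

#' Summarise replicate VAF measurements
#'
#' Pools per-replicate VAF fractions into a mean with a t-based confidence
#' interval and the repeatability RSD.
#'
#' @param vafs per-replicate VAF fractions (two or more).
#' @param ciLevel confidence level.
#' @return a [VafResult-class] with `perReplicate` and `rsd` filled in.
#' @export
summarizeVafReplicates <- function(vafs, ciLevel = 0.95) {
    if (length(vafs) < 2L) stop("at least 2 replicates required")
    m <- mean(vafs)
    se <- stats::sd(vafs) / sqrt(length(vafs))
    tq <- stats::qt(1 - (1 - ciLevel) / 2, df = length(vafs) - 1L)
    new("VafResult", vaf = m,
        ciLow = max(0, m - tq * se), ciHigh = min(1, m + tq * se),
        perReplicate = vafs, rsd = repeatabilityRsd(vafs))
}

#' Classify and quantify one well in a single call
#'
#' Convenience wrapper running [estimateThresholds()] (unless manual
#' thresholds are given), [classifyDroplets()], [poissonConcentration()] for
#' both targets and [computeVaf()].
#'
#' @param well a [DropletWell-class].
#' @param thresholds optional [Thresholds-class]; estimated when missing.
#' @param dropletVolumeNl,dilutionFactor,ciLevel passed to the quantifiers.
#' @return a list with `thresholds`, `counts`, `quantMu`, `quantWt`, `vaf`.
#' @export
quantifyWell <- function(well, thresholds = NULL, dropletVolumeNl = 0.85,
                         dilutionFactor = 1, ciLevel = 0.95) {
    if (is.null(thresholds)) thresholds <- estimateThresholds(well)
    cl <- classifyDroplets(well, thresholds)
    qm <- poissonConcentration(cl$counts, "mutant", dropletVolumeNl,
                               dilutionFactor, ciLevel)
    qw <- poissonConcentration(cl$counts, "wild_type", dropletVolumeNl,
                               dilutionFactor, ciLevel)
    list(thresholds = thresholds, counts = cl$counts,
         quantMu = qm, quantWt = qw, vaf = computeVaf(qm, qw, ciLevel))
}
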
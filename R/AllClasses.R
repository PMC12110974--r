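#' @import methods
NULL

.fin <- function(x) all(is.finite(x))

#' Simulation configuration for duplex ddPCR wells
#'
#' Holds the partition geometry and amplitude model used by
#' [simulateDroplets()] and [simulateBlankPanel()]. Channel 1 is the
#' mutant (FAM) channel, channel 2 the wild-type (VIC) channel.
#'
#' @slot nDroplets integer, droplets per well.
#' @slot dropletVolumeNl droplet volume in nanolitres.
#' @slot negMeanCh1,negMeanCh2 mean amplitude (a.u.) of template-free droplets.
#' @slot posMeanCh1,posMeanCh2 mean amplitude (a.u.) of template-bearing droplets.
#' @slot noiseSd Gaussian amplitude noise SD (a.u.), applied per channel.
#' @slot rainFraction probability that a positive droplet is replaced by a
#'   "rain" amplitude drawn uniformly between the negative and positive means.
#' @slot falsePosRateCh1,falsePosRateCh2 per-droplet probability that a
#'   template-free droplet nevertheless emits a positive amplitude.
#' @slot seed integer seed; identical configuration and seed give
#'   bit-identical wells.
#' @seealso [SimConfig()]
#' @export
setClass("SimConfig", representation(
    nDroplets = "integer",
    dropletVolumeNl = "numeric",
    negMeanCh1 = "numeric", negMeanCh2 = "numeric",
    posMeanCh1 = "numeric", posMeanCh2 = "numeric",
    noiseSd = "numeric",
    rainFraction = "numeric",
    falsePosRateCh1 = "numeric", falsePosRateCh2 = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (length(object@nDroplets) != 1L || is.na(object@nDroplets) ||
        object@nDroplets <= 0L)
        msg <- c(msg, "nDroplets must be a single positive integer")
    if (object@dropletVolumeNl <= 0)
        msg <- c(msg, "dropletVolumeNl must be positive")
    if (object@posMeanCh1 <= object@negMeanCh1)
        msg <- c(msg, "posMeanCh1 must exceed negMeanCh1")
    if (object@posMeanCh2 <= object@negMeanCh2)
        msg <- c(msg, "posMeanCh2 must exceed negMeanCh2")
    pr <- c(object@rainFraction, object@falsePosRateCh1, object@falsePosRateCh2)
    if (any(pr < 0 | pr > 1))
        msg <- c(msg, "rainFraction and false-positive rates must be in [0, 1]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Gravimetric mixture plan for a target VAF
#'
#' Result of [planGravimetricMixture()]: the amounts of mutant and wild-type
#' stock needed to realise a nominal variant allele fraction by copy balance.
#'
#' @slot stockConcMu,stockConcWt stock concentrations, copies/uL.
#' @slot copiesMu,copiesWt copies of each allele in the mixture.
#' @slot volumeMu,volumeWt volume of each stock, uL.
#' @slot targetVaf,achievedVaf nominal and realised variant allele fraction.
#' @export
setClass("MixturePlan", representation(
    stockConcMu = "numeric", stockConcWt = "numeric",
    copiesMu = "numeric", copiesWt = "numeric",
    volumeMu = "numeric", volumeWt = "numeric",
    targetVaf = "numeric", achievedVaf = "numeric"))

setValidity("MixturePlan", function(object) {
    if (abs(object@achievedVaf - object@targetVaf) > 1e-12)
        return("achievedVaf must equal targetVaf within 1e-12")
    TRUE
})

#' Per-droplet two-channel amplitudes for one well
#'
#' Channel 1 (`ch1`) is the mutant/FAM channel, channel 2 (`ch2`) the
#' wild-type/VIC channel. Simulated wells carry the ground-truth template
#' occupancy per droplet in `muTemplate`/`wtTemplate` (empty for imported
#' data); these are used only by tests and never by the classifier.
#'
#' @slot wellId sample/well label.
#' @slot ch1,ch2 numeric amplitude vectors, one element per droplet.
#' @slot muTemplate,wtTemplate logical ground-truth occupancy (may be empty).
#' @export
setClass("DropletWell", representation(
    wellId = "character",
    ch1 = "numeric", ch2 = "numeric",
    muTemplate = "logical", wtTemplate = "logical"))

setValidity("DropletWell", function(object) {
    msg <- NULL
    if (length(object@ch1) != length(object@ch2))
        msg <- c(msg, "ch1 and ch2 must have equal length")
    if (length(object@ch1) < 1L) msg <- c(msg, "at least one droplet required")
    if (!.fin(object@ch1) || !.fin(object@ch2))
        msg <- c(msg, "amplitudes must be finite")
    for (s in c("muTemplate", "wtTemplate")) {
        v <- slot(object, s)
        if (length(v) && length(v) != length(object@ch1))
            msg <- c(msg, paste(s, "must be empty or one value per droplet"))
    }
    if (is.null(msg)) TRUE else msg
})

#' Amplitude thresholds for the two channels
#'
#' @slot tCh1,tCh2 amplitude thresholds (a.u.); a droplet is positive on a
#'   channel when its amplitude is strictly above the threshold.
#' @slot method how each threshold was obtained (`"valley"`, `"midpoint"`, or
#'   `"manual"`), one tag per channel.
#' @slot flagged TRUE when a valley could not be found on some channel and the
#'   midpoint fallback was used.
#' @export
setClass("Thresholds", representation(
    tCh1 = "numeric", tCh2 = "numeric",
    method = "character", flagged = "logical"))

setValidity("Thresholds", function(object) {
    if (!.fin(c(object@tCh1, object@tCh2)))
        return("thresholds must be finite")
    TRUE
})

#' Four-cluster droplet counts for one well
#'
#' The duplex assay partitions droplets into four quadrants: double-negative,
#' mutant-only (FAM+), wild-type-only (VIC+), and double-positive.
#'
#' @slot wellId well label.
#' @slot nTotal total droplets.
#' @slot nDoubleNeg,nMuOnly,nWtOnly,nDoublePos counts per quadrant.
#' @export
setClass("DropletCounts", representation(
    wellId = "character",
    nTotal = "integer",
    nDoubleNeg = "integer", nMuOnly = "integer",
    nWtOnly = "integer", nDoublePos = "integer"))

setValidity("DropletCounts", function(object) {
    k <- c(object@nDoubleNeg, object@nMuOnly, object@nWtOnly, object@nDoublePos)
    if (any(k < 0L)) return("cluster counts must be non-negative")
    if (sum(k) != object@nTotal)
        return("the four cluster counts must sum to nTotal")
    TRUE
})

#' Poisson quantification of one target
#'
#' @slot target `"mutant"` or `"wild_type"`.
#' @slot lambda mean template copies per droplet, `-log(1 - nPos/nTotal)`.
#' @slot conc concentration in copies/uL of reaction, after dilution correction.
#' @slot ciLow,ciHigh confidence bounds on `conc`.
#' @slot nPos,nTotal positive and total droplet counts used.
#' @slot dropletVolumeNl,dilutionFactor,ciLevel quantification parameters.
#' @export
setClass("TargetQuant", representation(
    target = "character",
    lambda = "numeric", conc = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    nPos = "integer", nTotal = "integer",
    dropletVolumeNl = "numeric", dilutionFactor = "numeric",
    ciLevel = "numeric"))

setValidity("TargetQuant", function(object) {
    msg <- NULL
    if (!object@target %in% c("mutant", "wild_type"))
        msg <- c(msg, "target must be 'mutant' or 'wild_type'")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (object@ciLow > object@conc + 1e-12 || object@ciHigh < object@conc - 1e-12)
        msg <- c(msg, "conc must lie inside [ciLow, ciHigh]")
    if (is.null(msg)) TRUE else msg
})

#' Variant allele fraction with uncertainty
#'
#' @slot vaf variant allele fraction in `[0, 1]`.
#' @slot ciLow,ciHigh delta-method confidence bounds on the fraction.
#' @slot perReplicate per-replicate fractions when summarising replicates
#'   (empty for a single well).
#' @slot rsd relative standard deviation of the replicate fractions, percent
#'   (`NA` for a single well).
#' @export
setClass("VafResult", representation(
    vaf = "numeric", ciLow = "numeric", ciHigh = "numeric",
    perReplicate = "numeric", rsd = "numeric"))

setValidity("VafResult", function(object) {
    v <- c(object@ciLow, object@vaf, object@ciHigh)
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
        return("vaf and CI must be in [0, 1]")
    if (object@ciLow > object@vaf + 1e-12 || object@ciHigh < object@vaf - 1e-12)
        return("vaf must lie inside [ciLow, ciHigh]")
    TRUE
})

#' Linearity of measured VAF against nominal (gravimetric) VAF
#'
#' @slot slope,intercept ordinary least-squares fit of measured on nominal.
#' @slot rSquared coefficient of determination (full precision; displayed to
#'   4 decimals).
#' @slot points data.frame with columns `nominal` and `measured`, in percent.
#' @export
setClass("LinearityResult", representation(
    slope = "numeric", intercept = "numeric",
    rSquared = "numeric", points = "data.frame"))

setValidity("LinearityResult", function(object) {
    if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
        return("rSquared must be in [0, 1]")
    if (nrow(object@points) < 3L) return("at least 3 points required")
    TRUE
})

#' Non-parametric limit of blank
#'
#' @slot lob limit of blank on the scale of the input (VAF percent).
#' @slot nBlanks number of blank measurements pooled.
#' @slot percentile percentile used (default 0.95).
#' @slot rankPosition interpolation rank `nBlanks * percentile + 0.5`.
#' @slot method always `"nonparametric"`.
#' @export
setClass("LobResult", representation(
    lob = "numeric", nBlanks = "integer", percentile = "numeric",
    rankPosition = "numeric", method = "character"))

setValidity("LobResult", function(object) {
    msg <- NULL
    if (object@lob < 0) msg <- c(msg, "lob must be >= 0")
    if (abs(object@rankPosition -
            (object@nBlanks * object@percentile + 0.5)) > 1e-9)
        msg <- c(msg, "rankPosition must equal nBlanks * percentile + 0.5")
    if (is.null(msg)) TRUE else msg
})

#' Binomial probit fit of detection probability on VAF level
#'
#' Models the per-replicate hit probability as `pnorm(a + b * log10(vaf))`
#' (or linear `vaf` when fitted on the linear scale). `lod95` is the level at
#' which a replicate is detected with 95% probability.
#'
#' @slot intercept,slope probit coefficients (slope per log10 VAF by default).
#' @slot levels data.frame with columns `vaf`, `nPos`, `nTotal`.
#' @slot lod95 VAF percent at 95% detection probability.
#' @slot lodCiLow,lodCiHigh delta-method confidence bounds on `lod95`.
#' @slot converged FALSE when the likelihood was degenerate (complete
#'   separation) and `lod95` is a bracketing estimate.
#' @slot scale `"log10"` or `"linear"` covariate scale.
#' @export
setClass("ProbitFit", representation(
    intercept = "numeric", slope = "numeric",
    levels = "data.frame",
    lod95 = "numeric", lodCiLow = "numeric", lodCiHigh = "numeric",
    converged = "logical", scale = "character"))

#' Total-Error limit of quantification
#'
#' @slot levels data.frame with columns `vaf`, `bias`, `sd`, `totalError`
#'   where `totalError = |bias| + 2 * sd`.
#' @slot teGoal the preset Total-Error goal, same units as `bias`/`sd`.
#' @slot lod the limit of detection the rule is anchored to.
#' @slot loq the resulting limit of quantification (`NA` when no tested level
#'   meets the goal).
#' @slot ruleApplied which branch of the rule fired.
#' @export
setClass("LoqResult", representation(
    levels = "data.frame", teGoal = "numeric",
    lod = "numeric", loq = "numeric", ruleApplied = "character"))

setValidity("LoqResult", function(object) {
    lv <- object@levels
    if (!all(c("vaf", "bias", "sd", "totalError") %in% names(lv)))
        return("levels must have columns vaf, bias, sd, totalError")
    if (any(abs(lv$totalError - (abs(lv$bias) + 2 * lv$sd)) > 1e-9))
        return("totalError must equal |bias| + 2 * sd for every level")
    TRUE
})

#' Fragment-length profile of a DNA sample
#'
#' Abundance (signal) on a strictly increasing grid of fragment sizes in bp,
#' as produced by chip electrophoresis or by [simulateFragments()].
#'
#' @slot sizes base-pair grid, strictly increasing.
#' @slot abundance non-negative signal per size.
#' @slot label sample name.
#' @export
setClass("FragmentProfile", representation(
    sizes = "numeric", abundance = "numeric", label = "character"))

setValidity("FragmentProfile", function(object) {
    msg <- NULL
    if (length(object@sizes) != length(object@abundance))
        msg <- c(msg, "sizes and abundance must have equal length")
    if (length(object@sizes) && any(diff(object@sizes) <= 0))
        msg <- c(msg, "size grid must be strictly increasing")
    if (any(object@abundance < 0))
        msg <- c(msg, "abundance must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Spectrophotometric purity metrics
#'
#' @slot a260a280 A260/A280 absorbance ratio (protein contamination indicator).
#' @slot a260a230 A260/A230 absorbance ratio (salt/organic contamination).
#' @slot concentration DNA concentration, ng/uL.
#' @export
setClass("PurityMetrics", representation(
    a260a280 = "numeric", a260a230 = "numeric", concentration = "numeric"))

setValidity("PurityMetrics", function(object) {
    if (object@a260a280 <= 0 || object@a260a230 <= 0)
        return("absorbance ratios must be positive")
    TRUE
})

#' Fragment-QC report for a ctDNA-mimicking reference material
#'
#' @slot mainPeakBp size of the dominant fragment peak, bp.
#' @slot singlePeak TRUE when no secondary peak has prominence above the
#'   configured fraction of the main peak.
#' @slot inCtdnaWindow TRUE when the main peak lies in the 90-150 bp window
#'   characteristic of circulating tumor DNA (both endpoints inclusive).
#' @slot purityPass purity-rule outcome (`NA` when no metrics supplied).
#' @slot notes free-text notes.
#' @export
setClass("FragQcReport", representation(
    mainPeakBp = "numeric", singlePeak = "logical",
    inCtdnaWindow = "logical", purityPass = "logical", notes = "character"))

setValidity("FragQcReport", function(object) {
    inWin <- object@mainPeakBp >= 90 && object@mainPeakBp <= 150
    if (!identical(inWin, object@inCtdnaWindow))
        return("inCtdnaWindow must reflect 90 <= mainPeakBp <= 150")
    TRUE
})
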
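# show() methods and accessors.

#' @rdname accessors
setMethod("vaf", "VafResult", function(object) object@vaf)

#' @rdname accessors
setMethod("vafPercent", "VafResult", function(object)
    round(100 * object@vaf, 2))

#' @rdname accessors
setMethod("vaf", "MixturePlan", function(object) object@achievedVaf)

#' @rdname accessors
setMethod("concentration", "TargetQuant", function(object) object@conc)

#' @rdname accessors
setMethod("lob", "LobResult", function(object) object@lob)

#' @rdname accessors
setMethod("lod95", "ProbitFit", function(object) object@lod95)

#' @rdname accessors
setMethod("loq", "LoqResult", function(object) object@loq)

#' @rdname accessors
setMethod("rSquared", "LinearityResult", function(object) object@rSquared)

#' @rdname accessors
setMethod("clusterCounts", "DropletCounts", function(object)
    c(double_neg = object@nDoubleNeg, mu_only = object@nMuOnly,
      wt_only = object@nWtOnly, double_pos = object@nDoublePos))

#' @rdname accessors
setMethod("nDroplets", "DropletWell", function(object) length(object@ch1))

#' @rdname accessors
setMethod("nDroplets", "DropletCounts", function(object) object@nTotal)

#' @rdname accessors
setMethod("rankPosition", "LobResult", function(object) object@rankPosition)

setMethod("show", "DropletWell", function(object) {
    cat("DropletWell '", object@wellId, "': ", length(object@ch1),
        " droplets", sep = "")
    if (length(object@muTemplate)) cat(" (simulated, truth attached)")
    cat("\n  ch1 (FAM/mutant):    range ",
        paste(signif(range(object@ch1), 4), collapse = " - "), "\n",
        "  ch2 (VIC/wild-type): range ",
        paste(signif(range(object@ch2), 4), collapse = " - "), "\n", sep = "")
})

setMethod("show", "DropletCounts", function(object) {
    cat("DropletCounts '", object@wellId, "' (", object@nTotal,
        " droplets)\n", sep = "")
    k <- clusterCounts(object)
    for (nm in names(k)) cat(sprintf("  %-10s %d\n", nm, k[[nm]]))
})

setMethod("show", "Thresholds", function(object) {
    cat(sprintf("Thresholds: ch1 > %.1f (%s), ch2 > %.1f (%s)%s\n",
                object@tCh1, object@method[["ch1"]],
                object@tCh2, object@method[["ch2"]],
                if (object@flagged) " [flagged: midpoint fallback]" else ""))
})

setMethod("show", "TargetQuant", function(object) {
    cat(sprintf(
        "TargetQuant [%s]: lambda %.4g copies/droplet, %.4g copies/uL (%.0f%% CI %.4g-%.4g), %d/%d positive\n",
        object@target, object@lambda, object@conc, 100 * object@ciLevel,
        object@ciLow, object@ciHigh, object@nPos, object@nTotal))
})

setMethod("show", "VafResult", function(object) {
    cat(sprintf("VafResult: %.2f%% (CI %.2f-%.2f%%)",
                100 * object@vaf, 100 * object@ciLow, 100 * object@ciHigh))
    if (length(object@perReplicate))
        cat(sprintf(", %d replicates, RSD %.2f%%",
                    length(object@perReplicate), object@rsd))
    cat("\n")
})

setMethod("show", "MixturePlan", function(object) {
    cat(sprintf(
        "MixturePlan: target VAF %.4g%% -> %.4g mutant copies (%.4g uL) + %.4g wild-type copies (%.4g uL)\n",
        100 * object@targetVaf, object@copiesMu, object@volumeMu,
        object@copiesWt, object@volumeWt))
})

setMethod("show", "LinearityResult", function(object) {
    cat(sprintf(
        "LinearityResult: slope %.4f, intercept %.4f, R^2 = %.4f (%d points)\n",
        object@slope, object@intercept, object@rSquared,
        nrow(object@points)))
})

setMethod("show", "LobResult", function(object) {
    cat(sprintf(
        "LobResult: LOB %.4g%% (nonparametric, %d blanks, rank position %.1f at the %.0fth percentile)\n",
        object@lob, object@nBlanks, object@rankPosition,
        100 * object@percentile))
})

setMethod("show", "ProbitFit", function(object) {
    if (object@converged)
        cat(sprintf(
            "ProbitFit (%s scale): P(detect) = pnorm(%.3f + %.3f x); LOD95 = %.4g%% (CI %.4g-%.4g%%)\n",
            object@scale, object@intercept, object@slope, object@lod95,
            object@lodCiLow, object@lodCiHigh))
    else
        cat(sprintf(
            "ProbitFit: NOT converged (complete separation); bracketing LOD95 = %.4g%% in (%.4g, %.4g)\n",
            object@lod95, object@lodCiLow, object@lodCiHigh))
})

setMethod("show", "LoqResult", function(object) {
    cat(sprintf("LoqResult: LOQ %s (goal %.3f, rule: %s)\n",
                if (is.na(object@loq)) "not established"
                else sprintf("%.4g%%", object@loq),
                object@teGoal, object@ruleApplied))
    print(object@levels, row.names = FALSE)
})

setMethod("show", "FragmentProfile", function(object) {
    cat(sprintf(
        "FragmentProfile '%s': %d sizes (%g-%g bp), mode at %g bp\n",
        object@label, length(object@sizes), min(object@sizes),
        max(object@sizes), object@sizes[which.max(object@abundance)]))
})

setMethod("show", "FragQcReport", function(object) {
    cat(sprintf(
        "FragQcReport: main peak %g bp | single peak: %s | 90-150 bp ctDNA window: %s | purity: %s\n",
        object@mainPeakBp, object@singlePeak, object@inCtdnaWindow,
        if (is.na(object@purityPass)) "not assessed" else object@purityPass))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d droplets x %.2f nL, noise SD %g, rain %.3g, FP rates (%.2g, %.2g), seed %d\n",
        object@nDroplets, object@dropletVolumeNl, object@noiseSd,
        object@rainFraction, object@falsePosRateCh1, object@falsePosRateCh2,
        object@seed))
})
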
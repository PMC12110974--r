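# Fragment-size and purity QC for ctDNA-mimicking reference materials.

# Topographic prominence of each local maximum of y. For a peak at i the
# "col" on each side is the minimum of y on the path to the nearest point at
# least as high; prominence is the height minus the higher col. Using
# "at least as high" makes the bins of an equal-height plateau cancel each
# other (prominence 0) while two equal but separated components still earn
# full prominence across the valley between them. A peak with no higher
# ground on either side (the unique global maximum) gets height minus the
# global minimum.
.peakProminences <- function(y) {
    n <- length(y)
    pk <- which(diff(sign(diff(y))) < 0) + 1L
    if (n >= 2 && y[1L] > y[2L]) pk <- c(1L, pk)
    if (n >= 2 && y[n] > y[n - 1L]) pk <- c(pk, n)
    pk <- pk[y[pk] > 0]
    if (!length(pk)) return(data.frame(idx = integer(0), prom = numeric(0)))
    prom <- vapply(pk, function(i) {
        h <- y[i]
        cols <- numeric(0)
        if (i > 1L) {
            higher <- which(y[seq_len(i - 1L)] >= h)
            if (length(higher)) cols <- c(cols, min(y[max(higher):i]))
        }
        if (i < n) {
            higher <- which(y[(i + 1L):n] >= h)
            if (length(higher)) cols <- c(cols, min(y[i:(i + min(higher))]))
        }
        if (length(cols)) h - max(cols) else h - min(y)
    }, numeric(1))
    data.frame(idx = pk, prom = prom)
}

#' Locate the main fragment peak and test for a single-peak profile
#'
#' The main peak is the size at the global abundance maximum. The profile
#' counts as single-peaked when no other peak has topographic prominence
#' above `minProminenceFraction` times the main-peak height — prominence,
#' rather than raw local maxima, so that histogram jitter on the flank of the
#' main peak is ignored while a genuine secondary population is not.
#'
#' @param profile a [FragmentProfile-class].
#' @param minProminenceFraction secondary-peak prominence threshold as a
#'   fraction of the main-peak height (default 0.1).
#' @return a list with `mainPeakBp` and `singlePeak`.
#' @examples
#' prof <- simulateFragments(147, 12, 20000, seed = 1)
#' findMainPeak(prof)
#' @export
findMainPeak <- function(profile, minProminenceFraction = 0.1) {
    stopifnot(is(profile, "FragmentProfile"))
    y <- profile@abundance
    if (!length(y) || all(y == 0))
        stop("profile has no signal: main peak undefined")
    mainIdx <- which.max(y)
    mainH <- y[mainIdx]
    pp <- .peakProminences(y)
    secondary <- pp[pp$idx != mainIdx, , drop = FALSE]
    list(mainPeakBp = profile@sizes[mainIdx],
         singlePeak = !any(secondary$prom > minProminenceFraction * mainH))
}

#' Build spectrophotometric purity metrics
#'
#' @param a260a280 A260/A280 ratio.
#' @param a260a230 A260/A230 ratio.
#' @param concentration DNA concentration, ng/uL.
#' @return a [PurityMetrics-class].
#' @export
PurityMetrics <- function(a260a280, a260a230, concentration = NA_real_) {
    new("PurityMetrics", a260a280 = a260a280, a260a230 = a260a230,
        concentration = concentration)
}

#' Spectrophotometric purity rule
#'
#' Passes when the A260/A280 ratio lies in the closed interval [1.8, 2.0]
#' (no protein/enzyme carry-over) and the A260/A230 ratio is strictly above
#' 2.0 (no salt or organic contamination).
#'
#' @param metrics a [PurityMetrics-class].
#' @return logical pass/fail.
#' @examples
#' purityCheck(PurityMetrics(1.91, 2.23))  # TRUE
#' @export
purityCheck <- function(metrics) {
    stopifnot(is(metrics, "PurityMetrics"))
    if (!is.finite(metrics@a260a280) || !is.finite(metrics@a260a230))
        stop("purity ratios must be finite")
    metrics@a260a280 >= 1.8 && metrics@a260a280 <= 2.0 &&
        metrics@a260a230 > 2.0
}

#' Full fragment-QC report
#'
#' Combines the main-peak location, the single-peak check, the ctDNA
#' size-window check (main peak within 90-150 bp, endpoints inclusive) and,
#' when metrics are supplied, the purity rule.
#'
#' @param profile a [FragmentProfile-class].
#' @param metrics optional [PurityMetrics-class].
#' @param minProminenceFraction passed to [findMainPeak()].
#' @return a [FragQcReport-class].
#' @export
fragmentQc <- function(profile, metrics = NULL, minProminenceFraction = 0.1) {
    pk <- findMainPeak(profile, minProminenceFraction)
    purity <- if (is.null(metrics)) NA else purityCheck(metrics)
    notes <- sprintf("main peak %g bp; %s",
                     pk$mainPeakBp,
                     if (pk$singlePeak) "single dominant peak"
                     else "secondary peak(s) detected")
    new("FragQcReport", mainPeakBp = pk$mainPeakBp,
        singlePeak = pk$singlePeak,
        inCtdnaWindow = pk$mainPeakBp >= 90 && pk$mainPeakBp <= 150,
        purityPass = purity, notes = notes)
}
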
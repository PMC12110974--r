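# Analytical-validation cascade: linearity, LOB, positivity, probit LOD95,
# Total-Error LOQ.

#' Linearity of measured against nominal VAF
#'
#' Ordinary least squares of measured VAF on the nominal (gravimetric) VAF
#' across the dilution series, summarised by the coefficient of
#' determination. R-squared is displayed to 4 decimal places.
#'
#' @param nominal nominal VAF levels, percent (at least 3 distinct values).
#' @param measured measured VAF at each level, percent (means or replicate
#'   values, same length as `nominal`).
#' @return a [LinearityResult-class].
#' @examples
#' assessLinearity(c(50, 20, 5, 1, 0.2, 0.1),
#'                 c(50.76, 20.39, 5.22, 0.98, 0.25, 0.10))
#' @export
assessLinearity <- function(nominal, measured) {
    if (length(nominal) != length(measured))
        stop("nominal and measured must have equal length")
    if (length(unique(nominal)) < 3L)
        stop("at least 3 distinct nominal levels are required")
    if (stats::var(nominal) == 0) stop("nominal levels have zero variance")
    fit <- stats::lm(measured ~ nominal)
    new("LinearityResult",
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        rSquared = summary(fit)$r.squared,
        points = data.frame(nominal = nominal, measured = measured))
}

#' Non-parametric limit of blank
#'
#' EP17-style non-parametric estimator: the pooled blank measurements are
#' sorted and the LOB is read at rank `N * percentile + 0.5`, interpolating
#' linearly between the bracketing order statistics. With 60 blanks at the
#' 95th percentile the rank is 57.5 and the LOB is the mean of the 57th and
#' 58th sorted values. Ranks beyond the observed range clamp to the extreme
#' order statistics.
#'
#' @param blankVafs blank measurements (VAF percent), at least 20 values
#'   (a warning is issued below 60).
#' @param percentile percentile of the blank distribution (default 0.95).
#' @return a [LobResult-class].
#' @examples
#' lob(estimateLob(0.001 * (1:60)))  # 0.0575
#' @export
estimateLob <- function(blankVafs, percentile = 0.95) {
    n <- length(blankVafs)
    if (n == 0L) stop("no blank measurements supplied")
    if (any(blankVafs < 0)) stop("blank VAFs must be >= 0")
    if (percentile <= 0 || percentile >= 1)
        stop("percentile must be in (0, 1)")
    if (n < 20L) stop("at least 20 blank measurements are required")
    if (n < 60L)
        warning("fewer than 60 blanks pooled; the percentile estimate is ",
                "imprecise")
    x <- sort(blankVafs)
    rank <- n * percentile + 0.5
    lo <- max(1L, min(n, floor(rank)))
    hi <- max(1L, min(n, ceiling(rank)))
    frac <- max(0, min(1, rank - floor(rank)))
    lobVal <- if (lo == hi) x[lo] else x[lo] + frac * (x[hi] - x[lo])
    if (rank >= n) lobVal <- x[n]
    if (rank <= 1) lobVal <- x[1L]
    new("LobResult", lob = lobVal, nBlanks = n, percentile = percentile,
        rankPosition = rank, method = "nonparametric")
}

#' Positivity call against the limit of blank
#'
#' A replicate is called positive when its measured VAF is strictly greater
#' than the assay's LOB; a value exactly at the LOB is negative.
#'
#' @param measuredVaf measured VAF (percent); vectorised.
#' @param lob the limit of blank, same units.
#' @return logical vector of positivity calls.
#' @export
callPositive <- function(measuredVaf, lob) {
    if (is(lob, "LobResult")) lob <- lob@lob
    if (lob < 0) stop("lob must be >= 0")
    measuredVaf > lob
}

#' Probit regression LOD at 95% detection probability
#'
#' Fits a maximum-likelihood binomial probit of the per-level hit rate on
#' log10(VAF) (or on VAF directly with `scale = "linear"`):
#' `P(detect) = pnorm(a + b * x)`. The LOD95 solves the fitted curve at 95%
#' probability; its confidence interval comes from the delta method on the
#' coefficient covariance. Under complete separation (no level with an
#' intermediate hit rate) the likelihood is degenerate: the fit is flagged
#' non-converged and the LOD95 reported as the midpoint between the highest
#' all-negative and lowest all-positive levels, with a warning.
#'
#' @param levels data.frame with columns `vaf` (percent, > 0), `nPos`
#'   (replicates detected) and `nTotal` (replicates tested); at least 3
#'   levels.
#' @param scale covariate scale, `"log10"` (default) or `"linear"`.
#' @param ciLevel confidence level for the LOD interval.
#' @return a [ProbitFit-class].
#' @examples
#' lv <- data.frame(vaf = c(0.2, 0.1, 0.05, 0.02, 0.01),
#'                  nPos = c(12, 11, 9, 6, 3), nTotal = 12)
#' lod95(fitProbit(lv))
#' @export
fitProbit <- function(levels, scale = c("log10", "linear"), ciLevel = 0.95) {
    scale <- match.arg(scale)
    stopifnot(is.data.frame(levels),
              all(c("vaf", "nPos", "nTotal") %in% names(levels)))
    levels <- levels[order(levels$vaf), , drop = FALSE]
    if (sum(levels$vaf > 0) < 3L)
        stop("at least 3 levels with vaf > 0 are required")
    if (any(levels$nPos < 0 | levels$nPos > levels$nTotal))
        stop("nPos must be between 0 and nTotal at every level")
    x <- if (scale == "log10") log10(levels$vaf) else levels$vaf
    z95 <- stats::qnorm(0.95)
    mixed <- any(levels$nPos > 0 & levels$nPos < levels$nTotal)
    if (!mixed) {
        allNeg <- levels$vaf[levels$nPos == 0L]
        allPos <- levels$vaf[levels$nPos == levels$nTotal]
        if (!length(allNeg) || !length(allPos))
            stop("degenerate hit-rate data: need mixed levels or both ",
                 "all-negative and all-positive levels")
        warning("complete separation: probit likelihood degenerate; ",
                "reporting a bracketing LOD estimate")
        bracket <- (max(allNeg) + min(allPos)) / 2
        return(new("ProbitFit", intercept = NA_real_, slope = NA_real_,
                   levels = levels, lod95 = bracket,
                   lodCiLow = max(allNeg), lodCiHigh = min(allPos),
                   converged = FALSE, scale = scale))
    }
    fit <- suppressWarnings(stats::glm(
        cbind(nPos, nTotal - nPos) ~ x, data = levels,
        family = stats::binomial(link = "probit")))
    a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
    if (!is.finite(b) || b <= 0)
        stop("invalid probit fit: detection probability must increase with ",
             "VAF (slope <= 0)")
    g <- (z95 - a) / b
    V <- stats::vcov(fit)
    grad <- c(-1 / b, -(z95 - a) / b^2)
    seG <- sqrt(drop(t(grad) %*% V %*% grad))
    zc <- stats::qnorm(1 - (1 - ciLevel) / 2)
    back <- if (scale == "log10") function(u) 10^u else identity
    new("ProbitFit", intercept = a, slope = b, levels = levels,
        lod95 = back(g), lodCiLow = back(g - zc * seG),
        lodCiHigh = back(g + zc * seG),
        converged = isTRUE(fit$converged), scale = scale)
}

#' Total-Error limit of quantification
#'
#' Per level, `Total Error = |bias| + 2 * SD`. The rule is anchored at the
#' LOD: if the tested level at (or nearest above) the LOD meets the
#' Total-Error goal, then LOQ = LOD. Otherwise the LOQ is the lowest tested
#' level at or above the LOD whose Total Error meets the goal (an LOQ below
#' the LOD would not be meaningful); if no level meets the goal the outcome
#' is an explicit no-LOQ result, not an error.
#'
#' @param perLevelStats data.frame with columns `vaf` (percent), `bias` and
#'   `sd` (same units as `vaf`).
#' @param teGoal the preset Total-Error goal (required; same units).
#' @param lod the limit of detection, percent.
#' @return a [LoqResult-class]; `ruleApplied` is one of
#'   `"loq_equals_lod"`, `"lowest_level_meeting_goal"`, `"no_loq"`.
#' @examples
#' st <- data.frame(vaf = c(0.2, 0.1, 0.05), bias = c(0.01, 0.01, 0.04),
#'                  sd = c(0.01, 0.02, 0.05))
#' loq(computeLoq(st, teGoal = 0.1, lod = 0.1))
#' @export
computeLoq <- function(perLevelStats, teGoal, lod) {
    stopifnot(is.data.frame(perLevelStats),
              all(c("vaf", "bias", "sd") %in% names(perLevelStats)))
    if (any(perLevelStats$sd < 0)) stop("sd must be >= 0 at every level")
    if (missing(teGoal) || teGoal <= 0) stop("teGoal must be positive")
    if (lod < 0) stop("lod must be >= 0")
    lv <- perLevelStats[order(perLevelStats$vaf), , drop = FALSE]
    lv$totalError <- abs(lv$bias) + 2 * lv$sd
    atOrAbove <- which(lv$vaf >= lod)
    anchor <- if (length(atOrAbove)) atOrAbove[1L] else nrow(lv)
    if (lv$totalError[anchor] < teGoal) {
        loqVal <- lod; rule <- "loq_equals_lod"
    } else {
        ok <- atOrAbove[lv$totalError[atOrAbove] < teGoal]
        if (length(ok)) {
            loqVal <- lv$vaf[ok[1L]]; rule <- "lowest_level_meeting_goal"
        } else {
            loqVal <- NA_real_; rule <- "no_loq"
        }
    }
    new("LoqResult", levels = lv, teGoal = teGoal, lod = lod,
        loq = loqVal, ruleApplied = rule)
}
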
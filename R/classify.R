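# Four-cluster droplet classification for the duplex assay.

.clusterLevels <- c("double_neg", "mu_only", "wt_only", "double_pos")

# Valley-seeking threshold for one amplitude vector. Returns list(t, method).
.channelThreshold <- function(x) {
    rng <- range(x)
    mid <- mean(rng)
    if (diff(rng) < .Machine$double.eps^0.5 || length(unique(x)) < 3L)
        return(list(t = mid, method = "midpoint"))
    d <- stats::density(x, n = 512)
    y <- d$y
    # interior local maxima of the smoothed density
    pk <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(pk) < 2L) return(list(t = mid, method = "midpoint"))
    top2 <- pk[order(y[pk], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1L
    # require a genuine dip between the two modes, else treat as unimodal
    if (y[valley] > 0.8 * min(y[top2]))
        return(list(t = mid, method = "midpoint"))
    list(t = d$x[valley], method = "valley")
}

#' Estimate per-channel amplitude thresholds
#'
#' For each channel the threshold is placed at the minimum-density point
#' between the two largest modes of a kernel density estimate of the
#' amplitudes. When a channel has no separable bimodal structure (all one
#' cluster, or no clear valley) the midpoint of the amplitude range is used
#' instead and the result is flagged, with a warning.
#'
#' @param droplets a [DropletWell-class] with at least 100 droplets.
#' @return a [Thresholds-class]; `flagged` is TRUE when any channel fell back
#'   to the midpoint.
#' @examples
#' well <- simulateDroplets(SimConfig(seed = 2), 1000, 1000)
#' estimateThresholds(well)
#' @export
estimateThresholds <- function(droplets) {
    stopifnot(is(droplets, "DropletWell"))
    if (length(droplets@ch1) < 100L)
        stop("at least 100 droplets are required to estimate thresholds")
    r1 <- .channelThreshold(droplets@ch1)
    r2 <- .channelThreshold(droplets@ch2)
    flagged <- r1$method == "midpoint" || r2$method == "midpoint"
    if (flagged)
        warning("no density valley found on at least one channel; ",
                "midpoint fallback used")
    new("Thresholds", tCh1 = r1$t, tCh2 = r2$t,
        method = c(ch1 = r1$method, ch2 = r2$method), flagged = flagged)
}

#' Manually specified thresholds
#'
#' @param tCh1,tCh2 amplitude thresholds for the mutant (FAM) and wild-type
#'   (VIC) channels.
#' @return a [Thresholds-class] tagged `"manual"`.
#' @export
manualThresholds <- function(tCh1, tCh2) {
    new("Thresholds", tCh1 = tCh1, tCh2 = tCh2,
        method = c(ch1 = "manual", ch2 = "manual"), flagged = FALSE)
}

#' Classify droplets into the four duplex clusters
#'
#' A droplet is positive on a channel when its amplitude is strictly above
#' that channel's threshold (a droplet exactly at the threshold is negative,
#' the conservative direction for blank counting). The two booleans map to
#' the four quadrants: double-negative, mutant-only (FAM+), wild-type-only
#' (VIC+), double-positive.
#'
#' @param droplets a [DropletWell-class].
#' @param thresholds a [Thresholds-class].
#' @return a list with `labels` (factor over the four cluster levels, one per
#'   droplet) and `counts` (a [DropletCounts-class]).
#' @examples
#' well <- simulateDroplets(SimConfig(seed = 2), 1000, 1000)
#' cl <- classifyDroplets(well, estimateThresholds(well))
#' clusterCounts(cl$counts)
#' @export
classifyDroplets <- function(droplets, thresholds) {
    stopifnot(is(droplets, "DropletWell"), is(thresholds, "Thresholds"))
    if (length(droplets@ch1) == 0L) stop("empty droplet set")
    pos1 <- droplets@ch1 > thresholds@tCh1
    pos2 <- droplets@ch2 > thresholds@tCh2
    lab <- ifelse(pos1 & pos2, "double_pos",
           ifelse(pos1, "mu_only",
           ifelse(pos2, "wt_only", "double_neg")))
    labels <- factor(lab, levels = .clusterLevels)
    tab <- table(labels)
    counts <- new("DropletCounts", wellId = droplets@wellId,
                  nTotal = length(labels),
                  nDoubleNeg = as.integer(tab[["double_neg"]]),
                  nMuOnly = as.integer(tab[["mu_only"]]),
                  nWtOnly = as.integer(tab[["wt_only"]]),
                  nDoublePos = as.integer(tab[["double_pos"]]))
    list(labels = labels, counts = counts)
}
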
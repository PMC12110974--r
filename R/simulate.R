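# Droplet-level simulator for duplex ddPCR wells and companion inputs
# (gravimetric mixture plans, blank panels, fragment-size profiles).

#' Create a simulation configuration
#'
#' Defaults describe a clean duplex well on a QX200-class instrument:
#' ~20,000 droplets of 0.85 nL, well-separated negative/positive amplitude
#' clusters on both channels, moderate Gaussian amplitude noise, and neither
#' "rain" (intermediate amplitudes) nor chemistry false positives. Rain and
#' false-positive rates are switched on explicitly when emulating ctDNA
#' samples or blank panels.
#'
#' @param nDroplets droplets per well.
#' @param dropletVolumeNl droplet volume, nanolitres.
#' @param negMeanCh1,posMeanCh1 negative/positive cluster means on the mutant
#'   (FAM) channel, a.u.
#' @param negMeanCh2,posMeanCh2 negative/positive cluster means on the
#'   wild-type (VIC) channel, a.u.
#' @param noiseSd Gaussian amplitude noise SD, a.u.
#' @param rainFraction probability that a positive droplet's amplitude is
#'   drawn uniformly between the cluster means instead.
#' @param falsePosRateCh1,falsePosRateCh2 per-droplet probability that a
#'   template-free droplet emits a positive amplitude on that channel.
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(seed = 1)
#' well <- simulateDroplets(cfg, muCopies = 3000, wtCopies = 3000)
#' nDroplets(well)
#' @export
SimConfig <- function(nDroplets = 20000L, dropletVolumeNl = 0.85,
                      negMeanCh1 = 1000, posMeanCh1 = 8000,
                      negMeanCh2 = 1000, posMeanCh2 = 6000,
                      noiseSd = 200, rainFraction = 0,
                      falsePosRateCh1 = 0, falsePosRateCh2 = 0,
                      seed = 1L) {
    new("SimConfig",
        nDroplets = as.integer(nDroplets),
        dropletVolumeNl = as.numeric(dropletVolumeNl),
        negMeanCh1 = negMeanCh1, posMeanCh1 = posMeanCh1,
        negMeanCh2 = negMeanCh2, posMeanCh2 = posMeanCh2,
        noiseSd = noiseSd, rainFraction = rainFraction,
        falsePosRateCh1 = falsePosRateCh1, falsePosRateCh2 = falsePosRateCh2,
        seed = as.integer(seed))
}

# Evaluate expr under a local RNG stream; the caller's RNG state is untouched.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Plan a gravimetric mutant/wild-type mixture for a target VAF
#'
#' Solves the copy-balance equations for a mixture whose variant allele
#' fraction is defined by weighed-in amounts rather than by measurement:
#' mutant copies are `targetVaf * totalCopies`, wild-type copies the
#' remainder, and stock volumes follow from the stock concentrations.
#'
#' @param stockConcMu,stockConcWt stock concentrations, copies/uL.
#' @param targetVaf target variant allele fraction, strictly in (0, 1).
#' @param totalCopies total copies the mixture should contain.
#' @return a [MixturePlan-class]; its `achievedVaf` equals `targetVaf`
#'   exactly by construction.
#' @examples
#' planGravimetricMixture(1000, 2000, targetVaf = 0.001, totalCopies = 1e6)
#' @export
planGravimetricMixture <- function(stockConcMu, stockConcWt, targetVaf,
                                   totalCopies) {
    if (!is.finite(targetVaf) || targetVaf <= 0 || targetVaf >= 1)
        stop("targetVaf must be strictly between 0 and 1")
    if (stockConcMu <= 0 || stockConcWt <= 0)
        stop("stock concentrations must be positive")
    if (totalCopies <= 0) stop("totalCopies must be positive")
    copiesMu <- targetVaf * totalCopies
    copiesWt <- (1 - targetVaf) * totalCopies
    new("MixturePlan",
        stockConcMu = stockConcMu, stockConcWt = stockConcWt,
        copiesMu = copiesMu, copiesWt = copiesWt,
        volumeMu = copiesMu / stockConcMu, volumeWt = copiesWt / stockConcWt,
        targetVaf = targetVaf,
        achievedVaf = copiesMu / (copiesMu + copiesWt))
}

# Core well generator; assumes the RNG is already seeded by the caller.
.simulateWell <- function(config, muCopies, wtCopies, wellId) {
    n <- config@nDroplets
    muTmpl <- stats::rpois(n, muCopies / n) > 0L
    wtTmpl <- stats::rpois(n, wtCopies / n) > 0L
    pos1 <- muTmpl | (!muTmpl & stats::runif(n) < config@falsePosRateCh1)
    pos2 <- wtTmpl | (!wtTmpl & stats::runif(n) < config@falsePosRateCh2)
    ch1 <- ifelse(pos1, config@posMeanCh1, config@negMeanCh1) +
        stats::rnorm(n, 0, config@noiseSd)
    ch2 <- ifelse(pos2, config@posMeanCh2, config@negMeanCh2) +
        stats::rnorm(n, 0, config@noiseSd)
    if (config@rainFraction > 0) {
        r1 <- pos1 & stats::runif(n) < config@rainFraction
        r2 <- pos2 & stats::runif(n) < config@rainFraction
        if (any(r1))
            ch1[r1] <- stats::runif(sum(r1), config@negMeanCh1,
                                    config@posMeanCh1)
        if (any(r2))
            ch2[r2] <- stats::runif(sum(r2), config@negMeanCh2,
                                    config@posMeanCh2)
    }
    new("DropletWell", wellId = wellId, ch1 = ch1, ch2 = ch2,
        muTemplate = muTmpl, wtTemplate = wtTmpl)
}

#' Simulate one duplex ddPCR well
#'
#' Mutant and wild-type template molecules are distributed over the droplets
#' independently, so the per-droplet template counts are Poisson with means
#' `muCopies / nDroplets` and `wtCopies / nDroplets`. A droplet carrying at
#' least one template of a target emits that channel's positive-cluster mean,
#' otherwise the negative mean; Gaussian noise is added per channel. Double
#' occupancy lights up both channels, matching the four-quadrant readout of a
#' duplex assay. Optional rain replaces a positive droplet's amplitude with a
#' uniform draw between the cluster means; optional false positives flip
#' template-free droplets at the configured per-droplet rate.
#'
#' The returned well records the true template occupancy per droplet, so a
#' classifier can be scored against ground truth.
#'
#' @param config a [SimConfig-class].
#' @param muCopies,wtCopies template copies of each allele loaded in the well.
#' @param wellId well label.
#' @return a [DropletWell-class].
#' @examples
#' well <- simulateDroplets(SimConfig(seed = 7), 500, 2000)
#' @export
simulateDroplets <- function(config, muCopies, wtCopies, wellId = "well01") {
    stopifnot(is(config, "SimConfig"))
    if (muCopies < 0 || wtCopies < 0) stop("copy numbers must be >= 0")
    withSeed(config@seed, .simulateWell(config, muCopies, wtCopies, wellId))
}

#' Simulate a panel of blank (wild-type only) wells
#'
#' Blank wells contain wild-type template only; any mutant-channel signal
#' arises solely from the configured per-droplet false-positive rate. Used to
#' build the pooled blank panel from which the limit of blank is estimated
#' (e.g. 30 plasmid + 30 genomic-DNA replicates pooled to 60).
#'
#' @param config a [SimConfig-class]; set `falsePosRateCh1` to the assumed
#'   chemistry false-positive rate.
#' @param nWells number of blank wells.
#' @param wtCopies wild-type copies per well.
#' @return a list of [DropletWell-class] objects.
#' @export
simulateBlankPanel <- function(config, nWells, wtCopies = 3000) {
    stopifnot(is(config, "SimConfig"))
    if (nWells <= 0) stop("nWells must be positive")
    withSeed(config@seed, lapply(seq_len(nWells), function(i)
        .simulateWell(config, 0, wtCopies, sprintf("blank%02d", i))))
}

#' Simulate a mono-nucleosome-like fragment-length profile
#'
#' Draws fragment lengths from a Gaussian truncated at 1 bp (optionally a
#' two-component mixture for contaminant testing) and bins them on a 1-bp
#' grid, mimicking the chip-electrophoresis trace of an MNase-digested
#' reference material whose nucleosome-protected core gives a single peak
#' near 147 bp.
#'
#' @param peakBp main peak position, bp.
#' @param sdBp spread of the fragment population, bp.
#' @param nMolecules number of molecules drawn.
#' @param contaminantPeakBp optional second component position, bp.
#' @param contaminantFraction fraction of molecules from the second component;
#'   0 reproduces the single-component draw exactly under the same seed.
#' @param seed integer seed.
#' @param label sample name carried in the profile.
#' @return a [FragmentProfile-class].
#' @examples
#' prof <- simulateFragments(147, 12, 20000, seed = 3)
#' findMainPeak(prof)
#' @export
simulateFragments <- function(peakBp, sdBp, nMolecules = 20000,
                              contaminantPeakBp = NULL,
                              contaminantFraction = 0,
                              seed = 1L, label = "sample") {
    if (peakBp <= 0 || sdBp <= 0)
        stop("peakBp and sdBp must be positive")
    if (contaminantFraction < 0 || contaminantFraction > 1)
        stop("contaminantFraction must be in [0, 1]")
    withSeed(seed, {
        n2 <- if (!is.null(contaminantPeakBp) && contaminantFraction > 0)
            stats::rbinom(1L, nMolecules, contaminantFraction) else 0L
        sizes <- stats::rnorm(nMolecules - n2, peakBp, sdBp)
        if (n2 > 0L)
            sizes <- c(sizes, stats::rnorm(n2, contaminantPeakBp, sdBp))
        sizes <- pmax(round(sizes), 1)
        grid <- seq_len(max(sizes))
        new("FragmentProfile", sizes = as.numeric(grid),
            abundance = as.numeric(tabulate(sizes, nbins = max(sizes))),
            label = label)
    })
}
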
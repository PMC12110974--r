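# Shared fixtures: a clean plasmid-like configuration and a ctDNA-like one
# (slight rain), both at instrument-nominal partition geometry.

cleanConfig <- function(seed = 1L, ...) SimConfig(seed = seed, ...)

ctdnaConfig <- function(seed = 1L, ...)
    SimConfig(seed = seed, rainFraction = 0.02, ...)

blankConfig <- function(seed = 1L, fpRate = 1e-4)
    SimConfig(seed = seed, falsePosRateCh1 = fpRate)

# Measured blank VAFs (percent) for a simulated blank panel.
blankPanelVafs <- function(nWells, seed = 1L, fpRate = 1e-4) {
    wells <- simulateBlankPanel(blankConfig(seed, fpRate), nWells)
    th <- manualThresholds(4500, 3500)
    vapply(wells, function(w) {
        cl <- classifyDroplets(w, th)
        qm <- poissonConcentration(cl$counts, "mutant")
        qw <- poissonConcentration(cl$counts, "wild_type")
        if (concentration(qm) + concentration(qw) == 0) return(0)
        100 * vaf(computeVaf(qm, qw))
    }, numeric(1))
}
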
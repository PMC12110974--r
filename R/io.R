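# CSV readers/writers matching droplet-reader software exports.
#
# Column schemas (all files UTF-8, comma-delimited, header required;
# VAF columns are in percent):
#   amplitude CSV:        well, ch1_amplitude, ch2_amplitude
#   cluster-count CSV:    well, n_total, n_double_neg, n_mu_only, n_wt_only,
#                         n_double_pos, t_ch1, t_ch2
#   quantification CSV:   well, target, lambda, conc, ci_low, ci_high,
#                         n_pos, n_total
#   replicate-VAF CSV:    sample, nominal_vaf, replicate, measured_vaf
#   hit-rate CSV:         vaf, n_pos, n_total
#   fragment-profile CSV: size_bp, signal

.matchColumn <- function(nms, aliases, label) {
    norm <- gsub("[^a-z0-9]", "", tolower(nms))
    hit <- which(norm %in% aliases)
    if (!length(hit))
        stop("input file is missing the ", label, " column (expected one of: ",
             paste(aliases, collapse = ", "), ")")
    hit[1L]
}

.numericColumn <- function(x, label) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & trimws(x) != "")
    if (length(bad))
        stop("non-numeric ", label, " value at data line ", bad[1L],
             ": '", x[bad[1L]], "'")
    if (anyNA(v)) stop("missing ", label, " value in input file")
    v
}

#' Read a two-channel droplet amplitude CSV
#'
#' Expects a header with a well column and the two amplitude columns
#' (case-insensitive, any order; `ch1`/`fam` and `ch2`/`vic` spellings are
#' accepted). Returns one [DropletWell-class] per well, preserving row order
#' within each well.
#'
#' @param path CSV file path.
#' @return a named list of [DropletWell-class] objects.
#' @export
readAmplitudeCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE)
    iw <- .matchColumn(names(df), c("well", "wellid", "sample"), "well id")
    i1 <- .matchColumn(names(df),
                       c("ch1", "ch1amplitude", "amplitudech1", "fam"),
                       "channel-1 amplitude")
    i2 <- .matchColumn(names(df),
                       c("ch2", "ch2amplitude", "amplitudech2", "vic"),
                       "channel-2 amplitude")
    ch1 <- .numericColumn(df[[i1]], "channel-1 amplitude")
    ch2 <- .numericColumn(df[[i2]], "channel-2 amplitude")
    wells <- df[[iw]]
    out <- lapply(unique(wells), function(w) {
        sel <- wells == w
        new("DropletWell", wellId = w, ch1 = ch1[sel], ch2 = ch2[sel],
            muTemplate = logical(0), wtTemplate = logical(0))
    })
    names(out) <- unique(wells)
    out
}

#' Write droplet wells to an amplitude CSV
#'
#' @param wells a [DropletWell-class] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAmplitudeCsv <- function(wells, path) {
    if (is(wells, "DropletWell")) wells <- list(wells)
    df <- do.call(rbind, lapply(wells, function(w)
        data.frame(well = w@wellId, ch1_amplitude = w@ch1,
                   ch2_amplitude = w@ch2)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write per-well cluster counts (and thresholds used) to CSV
#'
#' @param counts a [DropletCounts-class] or list of them.
#' @param thresholds the [Thresholds-class] used (recycled across wells), or
#'   a list parallel to `counts`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClusterCountsCsv <- function(counts, thresholds, path) {
    if (is(counts, "DropletCounts")) counts <- list(counts)
    if (is(thresholds, "Thresholds"))
        thresholds <- rep(list(thresholds), length(counts))
    df <- do.call(rbind, Map(function(k, th)
        data.frame(well = k@wellId, n_total = k@nTotal,
                   n_double_neg = k@nDoubleNeg, n_mu_only = k@nMuOnly,
                   n_wt_only = k@nWtOnly, n_double_pos = k@nDoublePos,
                   t_ch1 = th@tCh1, t_ch2 = th@tCh2),
        counts, thresholds))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a cluster-count CSV back into DropletCounts objects
#'
#' @param path CSV written by [writeClusterCountsCsv()].
#' @return a named list of [DropletCounts-class] objects.
#' @export
readClusterCountsCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path)
    need <- c("well", "n_total", "n_double_neg", "n_mu_only", "n_wt_only",
              "n_double_pos")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("cluster-count file is missing column(s): ",
             paste(miss, collapse = ", "))
    out <- lapply(seq_len(nrow(df)), function(i)
        new("DropletCounts", wellId = as.character(df$well[i]),
            nTotal = as.integer(df$n_total[i]),
            nDoubleNeg = as.integer(df$n_double_neg[i]),
            nMuOnly = as.integer(df$n_mu_only[i]),
            nWtOnly = as.integer(df$n_wt_only[i]),
            nDoublePos = as.integer(df$n_double_pos[i])))
    names(out) <- as.character(df$well)
    out
}

#' Read a replicate-VAF table
#'
#' @param path CSV with columns sample, nominal_vaf, replicate, measured_vaf
#'   (VAF in percent).
#' @return a data.frame with those columns.
#' @export
readReplicateCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, colClasses = "character")
    is_ <- .matchColumn(names(df), c("sample", "samplename"), "sample")
    in_ <- .matchColumn(names(df), c("nominalvaf", "nominal"), "nominal_vaf")
    ir <- .matchColumn(names(df), c("replicate", "rep"), "replicate")
    im <- .matchColumn(names(df), c("measuredvaf", "measured"), "measured_vaf")
    data.frame(sample = df[[is_]],
               nominal_vaf = .numericColumn(df[[in_]], "nominal_vaf"),
               replicate = df[[ir]],
               measured_vaf = .numericColumn(df[[im]], "measured_vaf"))
}

#' Read a hit-rate table for probit LOD fitting
#'
#' @param path CSV with columns vaf (percent), n_pos, n_total.
#' @return a data.frame with columns `vaf`, `nPos`, `nTotal`, ready for
#'   [fitProbit()].
#' @export
readHitRateCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, colClasses = "character")
    iv <- .matchColumn(names(df), c("vaf", "level"), "vaf")
    ip <- .matchColumn(names(df), c("npos", "positive"), "n_pos")
    it <- .matchColumn(names(df), c("ntotal", "total"), "n_total")
    data.frame(vaf = .numericColumn(df[[iv]], "vaf"),
               nPos = as.integer(.numericColumn(df[[ip]], "n_pos")),
               nTotal = as.integer(.numericColumn(df[[it]], "n_total")))
}

#' Read a fragment-size profile
#'
#' @param path two-column CSV: size_bp, signal.
#' @param label sample label for the profile.
#' @return a [FragmentProfile-class].
#' @export
readFragmentProfileCsv <- function(path, label = basename(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, colClasses = "character")
    is_ <- .matchColumn(names(df), c("sizebp", "size", "bp"), "size_bp")
    ia <- .matchColumn(names(df), c("signal", "abundance", "intensity"),
                       "signal")
    new("FragmentProfile",
        sizes = .numericColumn(df[[is_]], "size_bp"),
        abundance = .numericColumn(df[[ia]], "signal"),
        label = label)
}

#' Write a fragment-size profile
#'
#' @param profile a [FragmentProfile-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFragmentProfileCsv <- function(profile, path) {
    utils::write.csv(data.frame(size_bp = profile@sizes,
                                signal = profile@abundance),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a human-readable validation report
#'
#' Assembles the analytical-validation results into a plain-text report:
#' linearity, repeatability, LOB, probit LOD95 with CI, and the Total-Error
#' LOQ with the rule branch that fired. Any section may be omitted.
#'
#' @param path output text file.
#' @param linearity optional [LinearityResult-class].
#' @param rsdTable optional data.frame with columns `nominal_vaf` and `rsd`.
#' @param lobResult optional [LobResult-class].
#' @param probitFit optional [ProbitFit-class].
#' @param loqResult optional [LoqResult-class].
#' @return `path`, invisibly.
#' @export
writeValidationReport <- function(path, linearity = NULL, rsdTable = NULL,
                                  lobResult = NULL, probitFit = NULL,
                                  loqResult = NULL) {
    ln <- c("Duplex ddPCR analytical validation report",
            strrep("=", 42))
    if (!is.null(linearity))
        ln <- c(ln, "",
                sprintf("Linearity: measured = %.4f * nominal + %.4f, R^2 = %.4f (n = %d levels)",
                        linearity@slope, linearity@intercept,
                        linearity@rSquared, nrow(linearity@points)))
    if (!is.null(rsdTable)) {
        ln <- c(ln, "", "Repeatability (RSD of VAF):",
                sprintf("  nominal %.2f%%: RSD %.2f%%",
                        rsdTable$nominal_vaf, rsdTable$rsd))
    }
    if (!is.null(lobResult))
        ln <- c(ln, "",
                sprintf("LOB (non-parametric, %d blanks, %.0fth percentile): %.4f%% at rank position %.1f",
                        lobResult@nBlanks, 100 * lobResult@percentile,
                        lobResult@lob, lobResult@rankPosition))
    if (!is.null(probitFit))
        ln <- c(ln, "",
                sprintf("LOD95 (probit on %s VAF): %.4f%% (CI %.4f-%.4f%%)%s",
                        probitFit@scale, probitFit@lod95,
                        probitFit@lodCiLow, probitFit@lodCiHigh,
                        if (probitFit@converged) ""
                        else " [non-converged: bracketing estimate]"))
    if (!is.null(loqResult))
        ln <- c(ln, "",
                sprintf("LOQ (Total Error = |bias| + 2*SD, goal %.3f%%): %s [rule: %s]",
                        loqResult@teGoal,
                        if (is.na(loqResult@loq)) "not established"
                        else sprintf("%.4f%%", loqResult@loq),
                        loqResult@ruleApplied))
    writeLines(ln, path)
    invisible(path)
}
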
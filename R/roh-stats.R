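#' Assign ROH length classes
#'
#' Three classes are used throughout: small (< 0.3 Mb), medium (0.3 to
#' 1.5 Mb, both bounds included) and large (> 1.5 Mb). Short runs trace
#' distant common ancestry, long runs recent inbreeding. Boundary
#' lengths go to the medium class; the bounds are configurable.
#'
#' @param segments segment data.frame with \code{length_kb}.
#' @param smallMaxMb,largeMinMb class bounds in Mb (defaults 0.3, 1.5).
#' @return the data.frame with a \code{class} factor column (levels
#'   small, medium, large).
#' @examples
#' segs <- data.frame(length_kb = c(250, 1500, 2150))
#' classifyLength(segs)$class   # small, medium, large
#' @export
classifyLength <- function(segments, smallMaxMb = 0.3, largeMinMb = 1.5) {
    stopifnot(smallMaxMb > 0, largeMinMb > smallMaxMb)
    mb <- segments$length_kb / 1000
    cl <- ifelse(mb < smallMaxMb, "small",
                 ifelse(mb > largeMinMb, "large", "medium"))
    segments$class <- factor(cl, levels = c("small", "medium", "large"))
    segments
}

#' Length-class summary statistics
#'
#' For each length class: segment count, share of all segments (%),
#' summed length (Mb), mean and standard deviation of segment length
#' (Mb; population SD, i.e. divisor N), and share of total ROH length
#' (%). Count and length percentages each sum to 100.
#'
#' @param segments segment data.frame; classified on the fly when no
#'   \code{class} column is present.
#' @param smallMaxMb,largeMinMb passed to \code{\link{classifyLength}}.
#' @return data.frame with one row per class: class, roh_number,
#'   number_pct, total_length_mb, mean_length_mb, sd_length_mb,
#'   length_pct.
#' @export
summarizeClasses <- function(segments, smallMaxMb = 0.3, largeMinMb = 1.5) {
    if (!nrow(segments)) stop("summarizeClasses: no segments")
    if (!"class" %in% names(segments))
        segments <- classifyLength(segments, smallMaxMb, largeMinMb)
    mb <- segments$length_kb / 1000
    total <- nrow(segments); totalMb <- sum(mb)
    sdPop <- function(x) if (length(x)) sqrt(mean((x - mean(x))^2)) else NA_real_
    out <- do.call(rbind, lapply(levels(segments$class), function(cl) {
        x <- mb[segments$class == cl]
        data.frame(class = cl,
                   roh_number = length(x),
                   number_pct = 100 * length(x) / total,
                   total_length_mb = sum(x),
                   mean_length_mb = if (length(x)) mean(x) else NA_real_,
                   sd_length_mb = sdPop(x),
                   length_pct = 100 * sum(x) / totalMb)
    }))
    rownames(out) <- NULL
    out
}

#' Class-summary arithmetic from printed totals
#'
#' Recomputes the derived columns of a length-class summary table from
#' its primary entries (per-class segment counts and summed lengths):
#' count percentages, mean segment lengths and length percentages, plus
#' the grand totals. Useful for checking published summary tables.
#'
#' @param rohNumber per-class segment counts.
#' @param totalLengthMb per-class summed lengths in Mb.
#' @param classes optional class labels.
#' @return data.frame: class, roh_number, number_pct, total_length_mb,
#'   mean_length_mb, length_pct; totals in the attributes
#'   \code{total_number} and \code{total_length_mb}.
#' @examples
#' classSummaryFromTotals(c(25933, 30406, 885),
#'                        c(6280.59, 16313.46, 1905.19))
#' @export
classSummaryFromTotals <- function(rohNumber, totalLengthMb,
                                   classes = c("small", "medium", "large")) {
    stopifnot(length(rohNumber) == length(totalLengthMb))
    total <- sum(rohNumber); totalMb <- sum(totalLengthMb)
    out <- data.frame(class = rep_len(classes, length(rohNumber)),
                      roh_number = rohNumber,
                      number_pct = 100 * rohNumber / total,
                      total_length_mb = totalLengthMb,
                      mean_length_mb = totalLengthMb / rohNumber,
                      length_pct = 100 * totalLengthMb / totalMb)
    attr(out, "total_number") <- total
    attr(out, "total_length_mb") <- totalMb
    out
}

#' Per-sample genomic inbreeding coefficient (FROH)
#'
#' FROH is the fraction of the autosomal genome covered by ROH segments:
#' the summed segment length of an individual divided by the autosomal
#' length covered by the SNP panel (\code{lAutoMb}). Samples listed in
#' \code{samples} but carrying no segment get FROH 0.
#'
#' @param segments segment data.frame.
#' @param lAutoMb autosomal panel length in Mb. The default, 2466.19
#'   Mb, corresponds to a caprine whole-genome panel; always set it for
#'   other datasets.
#' @param samples optional character vector of all analysed samples.
#' @return data.frame: sample, n_roh, sum_roh_mb, froh.
#' @export
frohPerSample <- function(segments, lAutoMb = 2466.19, samples = NULL) {
    stopifnot(lAutoMb > 0)
    if (is.null(samples)) samples <- sort(unique(segments$sample))
    mb <- segments$length_kb / 1000
    sums <- vapply(samples, function(s) sum(mb[segments$sample == s]),
                   numeric(1))
    ns <- vapply(samples, function(s) sum(segments$sample == s), numeric(1))
    data.frame(sample = samples, n_roh = as.integer(ns),
               sum_roh_mb = as.numeric(sums),
               froh = as.numeric(sums) / lAutoMb,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Population roll-up of FROH
#'
#' Aggregates per-sample FROH by population: n (the number of samples
#' with at least one ROH — the denominator convention of ROH summary
#' tables), total ROH length, and mean FROH over those n samples.
#'
#' @param froh data.frame from \code{\link{frohPerSample}}.
#' @param popmap named character vector sample -> population
#'   (\code{\link{readPopulationMap}}).
#' @return data.frame: population, n, total_roh_length_mb, mean_froh.
#' @export
frohByPopulation <- function(froh, popmap) {
    pop <- popmap[froh$sample]
    if (anyNA(pop)) stop("samples missing from the population map: ",
                         paste(froh$sample[is.na(pop)], collapse = ", "))
    out <- do.call(rbind, lapply(unique(pop), function(p) {
        x <- froh[pop == p & froh$n_roh > 0, , drop = FALSE]
        data.frame(population = p, n = nrow(x),
                   total_roh_length_mb = sum(x$sum_roh_mb),
                   mean_froh = if (nrow(x)) mean(x$froh) else NA_real_)
    }))
    rownames(out) <- NULL
    out
}

#' FROH arithmetic from printed population totals
#'
#' The population mean FROH implied by a published summary line: total
#' ROH length divided by (n samples x autosomal panel length).
#'
#' @param totalRohLengthMb summed ROH length of the population, Mb.
#' @param n number of samples with at least one ROH.
#' @param lAutoMb autosomal panel length in Mb.
#' @return numeric mean FROH.
#' @examples
#' frohFromTotals(3045.20, 47)       # ~0.0263
#' frohFromTotals(11788.44, 10)      # ~0.4780
#' @export
frohFromTotals <- function(totalRohLengthMb, n, lAutoMb = 2466.19) {
    totalRohLengthMb / (n * lAutoMb)
}

#' Per-chromosome ROH counts by length class
#'
#' @param segments segment data.frame.
#' @param smallMaxMb,largeMinMb class bounds.
#' @return data.frame: chrom, small, medium, large, total.
#' @export
perChromosomeCounts <- function(segments, smallMaxMb = 0.3, largeMinMb = 1.5) {
    if (!nrow(segments))
        return(data.frame(chrom = character(0), small = integer(0),
                          medium = integer(0), large = integer(0),
                          total = integer(0)))
    if (!"class" %in% names(segments))
        segments <- classifyLength(segments, smallMaxMb, largeMinMb)
    tab <- table(segments$chrom, segments$class)
    out <- data.frame(chrom = rownames(tab),
                      small = as.integer(tab[, "small"]),
                      medium = as.integer(tab[, "medium"]),
                      large = as.integer(tab[, "large"]))
    out$total <- out$small + out$medium + out$large
    ord <- suppressWarnings(as.integer(sub("^chr", "", out$chrom)))
    out[order(ord, out$chrom), , drop = FALSE]
}

#' Per-individual ROH count and summed length
#'
#' NROH (segment count) and SROH (summed length, Mb) per sample — the
#' coordinates of the classic NROH-vs-SROH scatter that separates
#' populations by inbreeding history.
#'
#' @param segments segment data.frame.
#' @param samples optional complete sample list (zero rows for
#'   ROH-free samples).
#' @return data.frame: sample, nroh, sroh_mb.
#' @export
perIndividualStats <- function(segments, samples = NULL) {
    if (is.null(samples)) samples <- sort(unique(segments$sample))
    mb <- segments$length_kb / 1000
    data.frame(sample = samples,
               nroh = vapply(samples, function(s)
                   sum(segments$sample == s), integer(1)),
               sroh_mb = vapply(samples, function(s)
                   sum(mb[segments$sample == s]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
}
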
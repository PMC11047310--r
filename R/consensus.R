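#' Pool overlapping ROH segments across individuals
#'
#' Greedy, deterministic pooling per chromosome. Repeatedly: (1) pick
#' the unpooled segment overlapped (by >= 1 bp) by the most other
#' unpooled segments as the seed — ties broken towards the longest,
#' then leftmost, then first sample; (2) walk the segments overlapping
#' the seed in (start, end, sample) order and admit each whose
#' intersection with the running consensus interval is non-empty,
#' shrinking the consensus (CON) to that intersection and growing the
#' union (UNION) accordingly; (3) record the pool when it holds at
#' least two members and remove its members from play. Every segment
#' belongs to at most one pool, CON is contained in every member, and
#' UNION contains every member. Input order does not affect the result.
#'
#' @param segments segment data.frame, usually restricted to the breeds
#'   under study.
#' @return list with \code{pools} (pool_id, chrom, con_start, con_end,
#'   con_kb, union_start, union_end, n_members, n_animals) and
#'   \code{members} (pool_id plus the member segment rows).
#' @export
poolSegments <- function(segments) {
    emptyPools <- data.frame(pool_id = character(0), chrom = character(0),
                             con_start = numeric(0), con_end = numeric(0),
                             con_kb = numeric(0), union_start = numeric(0),
                             union_end = numeric(0), n_members = integer(0),
                             n_animals = integer(0), stringsAsFactors = FALSE)
    if (!nrow(segments))
        return(list(pools = emptyPools, members = cbind(pool_id = character(0),
                                                        .emptySegments())))
    .checkSegments(segments)
    poolList <- list(); memberList <- list()
    for (ch in unique(segments$chrom)) {
        d <- segments[segments$chrom == ch, , drop = FALSE]
        # canonical order makes the greedy walk permutation-invariant
        d <- d[order(d$start_bp, d$end_bp, d$sample), , drop = FALSE]
        active <- rep(TRUE, nrow(d))
        repeat {
            idx <- which(active)
            if (length(idx) < 2L) break
            s0 <- d$start_bp[idx]; e0 <- d$end_bp[idx]
            ir <- IRanges::IRanges(s0, e0)
            nOv <- IRanges::countOverlaps(ir, ir) - 1L
            if (max(nOv) == 0L) break
            width <- e0 - s0 + 1
            ord <- order(-nOv, -width, s0, d$sample[idx])
            seed <- ord[1]
            overl <- which(nOv > 0 | seq_along(idx) == seed)
            overl <- overl[s0[overl] <= e0[seed] & e0[overl] >= s0[seed]]
            conS <- s0[seed]; conE <- e0[seed]
            uniS <- conS; uniE <- conE
            members <- seed
            for (m in setdiff(overl, seed)) {
                if (s0[m] <= conE && e0[m] >= conS) {
                    conS <- max(conS, s0[m]); conE <- min(conE, e0[m])
                    uniS <- min(uniS, s0[m]); uniE <- max(uniE, e0[m])
                    members <- c(members, m)
                }
            }
            if (length(members) >= 2L) {
                rows <- idx[members]
                poolList[[length(poolList) + 1L]] <- data.frame(
                    chrom = ch, con_start = conS, con_end = conE,
                    con_kb = .lengthKb(conS, conE),
                    union_start = uniS, union_end = uniE,
                    n_members = length(members),
                    n_animals = length(unique(d$sample[rows])),
                    stringsAsFactors = FALSE)
                memberList[[length(memberList) + 1L]] <- d[rows, , drop = FALSE]
                active[rows] <- FALSE
            } else {
                active[idx[seed]] <- FALSE   # isolated seed: retire it
            }
        }
    }
    if (!length(poolList))
        return(list(pools = emptyPools, members = cbind(pool_id = character(0),
                                                        .emptySegments())))
    pools <- do.call(rbind, poolList)
    ord <- order(suppressWarnings(as.integer(sub("^chr", "", pools$chrom))),
                 pools$chrom, pools$con_start)
    pools <- pools[ord, , drop = FALSE]
    pools <- cbind(pool_id = sprintf("P%04d", seq_len(nrow(pools))), pools)
    members <- do.call(rbind, lapply(seq_along(ord), function(i)
        cbind(pool_id = pools$pool_id[i], memberList[[ord[i]]])))
    rownames(pools) <- rownames(members) <- NULL
    list(pools = pools, members = members)
}

#' Select consensus regions as selection-signature candidates
#'
#' Keeps pools whose consensus interval is strictly longer than
#' \code{minConLengthMb} and whose distinct carrier count is strictly
#' greater than \code{minSampleFraction} of the reference sample set
#' (both thresholds strict, so a pool at exactly the 30% sharing level
#' is dropped).
#'
#' @param pools the \code{pools} data.frame from
#'   \code{\link{poolSegments}}.
#' @param refSamples character vector of the analysed samples forming
#'   the denominator (e.g. all animals of the breeds under study).
#' @param minConLengthMb minimum CON length in Mb (default 0.1).
#' @param minSampleFraction minimum sharing fraction (default 0.30).
#' @return the selected pool rows.
#' @export
filterConsensus <- function(pools, refSamples, minConLengthMb = 0.1,
                            minSampleFraction = 0.30) {
    stopifnot(minConLengthMb > 0,
              minSampleFraction > 0, minSampleFraction <= 1,
              length(refSamples) > 0)
    conMb <- pools$con_kb / 1000
    keep <- conMb > minConLengthMb &
        pools$n_animals / length(refSamples) > minSampleFraction
    pools[keep, , drop = FALSE]
}

#' Tabulate selected consensus regions
#'
#' One row per selected pool: consensus and union spans, carrier
#' counts, per-population membership and (optionally) overlapping
#' genes. Written as TSV when \code{path} is given.
#'
#' @param pools selected pools (\code{\link{filterConsensus}}).
#' @param members the member table from \code{\link{poolSegments}}.
#' @param popmap optional named vector sample -> population, adds
#'   per-population carrier counts.
#' @param genes optional gene intervals (see
#'   \code{\link{annotateIntervals}}).
#' @param path optional output TSV path.
#' @return the report data.frame (header-only file for an empty
#'   selection).
#' @export
consensusReport <- function(pools, members, popmap = NULL, genes = NULL,
                            path = NULL) {
    out <- pools
    out$members <- vapply(out$pool_id, function(id)
        paste(sort(unique(members$sample[members$pool_id == id])),
              collapse = ","), character(1))
    if (!is.null(popmap)) {
        pops <- sort(unique(popmap))
        for (p in pops)
            out[[paste0("n_", p)]] <- vapply(out$pool_id, function(id) {
                s <- unique(members$sample[members$pool_id == id])
                sum(popmap[s] == p, na.rm = TRUE)
            }, numeric(1))
    }
    if (!is.null(genes) && nrow(out)) {
        iv <- data.frame(chrom = out$chrom, start_bp = out$con_start,
                         end_bp = out$con_end)
        out$genes <- annotateIntervals(iv, genes)$genes
    }
    rownames(out) <- NULL
    if (!is.null(path)) .writeTSV(out, path)
    out
}
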
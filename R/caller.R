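#' @import GenomicRanges
#' @import IRanges
NULL

## centered moving average with partial windows at the edges, via cumsum;
## deterministic and length preserving
movingAverage <- function(v, span) {
    span <- as.integer(span)
    if (span <= 1L) return(v)
    n <- length(v)
    h <- span %/% 2L
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call exon intervals from a power track by half-power thresholding
#'
#' The track is (optionally) smoothed with a centered moving average, then
#' thresholded at \code{thresholdFraction} of its global maximum - the
#' half-power rule when the fraction is 0.5. Maximal runs above threshold
#' become candidate exons; candidates separated by at most \code{mergeGap}
#' bases are merged, and merged candidates shorter than \code{minLength} are
#' dropped. Coordinates are absolute 1-based inclusive record positions
#' (window centers for sliding-window spectral tracks).
#'
#' @param track a \linkS4class{PowerTrack} or \linkS4class{SpectralTrack}.
#' @param thresholdFraction fraction of the global (smoothed) maximum used as
#'   threshold, in (0, 1); default 0.5 (half power). This relative rule makes
#'   calls invariant under uniform scaling of the track.
#' @param minLength shortest reported exon, in bases (default 50).
#' @param mergeGap maximal gap between candidates that are merged (default
#'   30).
#' @param smoothSpan centered moving-average span in bases; default
#'   \code{NULL} picks 1 (off) for spectral tracks, whose sliding window
#'   already averages, and 450 for filter power tracks, the context length
#'   found to work best for the filter method.
#' @return an \linkS4class{ExonCallSet}; \code{peakPower}/\code{meanPower}
#'   metadata refer to the smoothed track.
#' @export
callExons <- function(track, thresholdFraction = 0.5, minLength = 50L,
                      mergeGap = 30L, smoothSpan = NULL) {
    stopifnot(is(track, "SignalTrack"))
    if (!is.finite(thresholdFraction) || thresholdFraction <= 0 ||
        thresholdFraction >= 1)
        stop("'thresholdFraction' must lie in (0, 1)")
    v <- track@values
    if (!length(v))
        stop("empty track")
    if (is.null(smoothSpan))
        smoothSpan <- if (is(track, "PowerTrack")) 450L else 1L
    smoothSpan <- max(1L, as.integer(smoothSpan))
    minLength <- as.integer(minLength)
    mergeGap <- as.integer(mergeGap)
    vs <- movingAverage(v, smoothSpan)
    threshold <- thresholdFraction * max(vs)
    pos <- trackPositions(track)

    above <- vs >= threshold & vs > 0
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values
    cand <- IRanges(start = pos[starts_i[keep]], end = pos[ends_i[keep]])
    if (length(cand)) {
        cand <- IRanges::reduce(cand, min.gapwidth = mergeGap + 1L)
        cand <- cand[width(cand) >= minLength]
    }
    stat <- function(rng, f) vapply(seq_along(rng), function(i) {
        sel <- pos >= start(rng)[i] & pos <= end(rng)[i]
        f(vs[sel])
    }, numeric(1))
    gr <- GRanges(seqnames = track@recordId, ranges = cand,
        peakPower = if (length(cand)) stat(cand, max) else numeric(),
        meanPower = if (length(cand)) stat(cand, mean) else numeric())
    new("ExonCallSet", calls = gr, method = track@method,
        params = list(thresholdFraction = thresholdFraction,
                      threshold = threshold, minLength = minLength,
                      mergeGap = mergeGap, smoothSpan = smoothSpan))
}

asTruthRanges <- function(truth) {
    if (is(truth, "GRanges")) IRanges::ranges(truth)
    else if (is(truth, "IRanges")) truth
    else if (is.data.frame(truth)) IRanges(truth$start, truth$end)
    else if (is.matrix(truth)) IRanges(truth[, 1], truth[, 2])
    else stop("'truth' must be a GRanges, IRanges, data.frame or matrix")
}

#' Evaluate exon calls against reference annotations
#'
#' Per-truth-exon detection (any overlap), boundary accuracy over detected
#' exons, false-positive calls and nucleotide-level sensitivity/precision.
#' A detected truth exon is matched to the overlapping call with the largest
#' overlap; its boundary errors are the absolute start and end coordinate
#' differences against that call.
#'
#' @param calls an \linkS4class{ExonCallSet}, GRanges, IRanges or
#'   data.frame with start/end columns.
#' @param truth reference intervals in the same coordinate system (GRanges,
#'   IRanges, data.frame or 2-column matrix).
#' @return a list with \code{detected} (logical per truth exon),
#'   \code{nDetected}, \code{meanBoundaryError} (mean of the absolute start
#'   and end errors over detected exons; NA when none detected),
#'   \code{falsePositives} (calls with no truth overlap),
#'   \code{sensitivity} and \code{precision} (nucleotide level).
#' @export
#' @examples
#' evaluateCalls(data.frame(start = 7841, end = 8021),
#'               data.frame(start = 7947, end = 8059))
evaluateCalls <- function(calls, truth) {
    callRanges <- if (is(calls, "ExonCallSet"))
        IRanges::ranges(calls@calls) else asTruthRanges(calls)
    truthRanges <- asTruthRanges(truth)
    hits <- findOverlaps(truthRanges, callRanges)
    detected <- seq_along(truthRanges) %in% S4Vectors::queryHits(hits)
    boundaryErrors <- numeric()
    if (length(hits)) {
        ov <- width(pintersect(truthRanges[S4Vectors::queryHits(hits)],
                               callRanges[S4Vectors::subjectHits(hits)]))
        best <- vapply(unique(S4Vectors::queryHits(hits)), function(q) {
            sel <- S4Vectors::queryHits(hits) == q
            S4Vectors::subjectHits(hits)[sel][which.max(ov[sel])]
        }, integer(1))
        qs <- unique(S4Vectors::queryHits(hits))
        boundaryErrors <- c(
            abs(start(truthRanges)[qs] - start(callRanges)[best]),
            abs(end(truthRanges)[qs] - end(callRanges)[best]))
    }
    fp <- sum(!(seq_along(callRanges) %in% S4Vectors::subjectHits(hits)))
    inter <- sum(width(IRanges::intersect(
        IRanges::reduce(truthRanges), IRanges::reduce(callRanges))))
    totTruth <- sum(width(IRanges::reduce(truthRanges)))
    totCall <- sum(width(IRanges::reduce(callRanges)))
    list(detected = detected,
         nDetected = sum(detected),
         meanBoundaryError = if (length(boundaryErrors))
             mean(boundaryErrors) else NA_real_,
         falsePositives = fp,
         sensitivity = if (totTruth > 0) inter / totTruth else NA_real_,
         precision = if (totCall > 0) inter / totCall else NA_real_)
}

#' Human-readable "start-end(length)" call table
#'
#' @param calls an \linkS4class{ExonCallSet} or anything
#'   \code{\link{evaluateCalls}} accepts as intervals.
#' @return character vector, one "start-end(length)" entry per call, where
#'   length is the printed end minus start (boundary-to-boundary span).
#' @export
formatCallTable <- function(calls) {
    rng <- if (is(calls, "ExonCallSet"))
        IRanges::ranges(calls@calls) else asTruthRanges(calls)
    sprintf("%d-%d(%d)", start(rng), end(rng), end(rng) - start(rng))
}

#' Write exon calls as BED
#'
#' Coordinates convert from 1-based inclusive to BED's 0-based half-open on
#' output; call peak power is stored in the score column.
#'
#' @param calls an \linkS4class{ExonCallSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCallsBed <- function(calls, path) {
    stopifnot(is(calls, "ExonCallSet"))
    gr <- calls@calls
    names(gr) <- sprintf("exon_%d", seq_along(gr))
    S4Vectors::mcols(gr)$score <- S4Vectors::mcols(gr)$peakPower
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read reference exon annotations from BED
#'
#' @param path BED file path (0-based half-open on disk; returned 1-based).
#' @return a GRanges.
#' @export
readExonBed <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    rtracklayer::import(path, format = "BED")
}

#' Write a signal track as 2-column TSV (position, power)
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrackTSV <- function(track, path) {
    stopifnot(is(track, "SignalTrack"))
    utils::write.table(
        data.frame(position = trackPositions(track),
                   power = track@values),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a signal track as BEDGraph
#'
#' @inheritParams writeTrackTSV
#' @export
writeTrackBedGraph <- function(track, path) {
    stopifnot(is(track, "SignalTrack"))
    pos <- trackPositions(track)
    gr <- GRanges(track@recordId, IRanges(pos, pos),
                  score = track@values)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}
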
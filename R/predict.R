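#' Names of the six exon-prediction method presets
#'
#' Two sliding-window DFT methods ("binary", "eiip"), two four-channel
#' filtering methods ("filter1", "filter2") and two reduced-computation
#' single-channel filtering methods ("reduced_f1", "reduced_f2").
#'
#' @export
PREDICT_METHODS <- c("binary", "eiip", "filter1", "filter2",
                     "reduced_f1", "reduced_f2")

#' Run one exon-prediction method end to end
#'
#' Converts the region to the numeric representation the chosen method
#' needs, computes its exon evidence track (sliding-window period-3 DFT
#' power, or narrowband filter output power), optionally denoises the track
#' with a Haar wavelet detail suppression, and calls exon intervals by
#' relative (half-power) thresholding. The flagship combination is
#' \code{method = "reduced_f2", denoise = TRUE}: single-channel filtering
#' through the peaking design followed by level-1 Haar denoising.
#'
#' @param region a \linkS4class{DNARegion}.
#' @param method one of \code{\link{PREDICT_METHODS}}.
#' @param windowLength sliding-window length for the DFT methods (multiple
#'   of 3; default 240).
#' @param assignment window-position assignment for DFT tracks ("center" or
#'   "left").
#' @param R Filter 1 pole radius (default 0.992).
#' @param bandwidth Filter 2 -3 dB bandwidth in radians/sample (default
#'   0.02*pi).
#' @param weights channel weights for the reduced-computation methods
#'   (default pure G channel).
#' @param denoise logical; Haar-denoise the track before calling.
#' @param dwtLevel denoising decomposition depth (default 1).
#' @param thresholdFraction,minLength,mergeGap,smoothSpan exon-calling
#'   parameters, see \code{\link{callExons}}; \code{smoothSpan = NULL} picks
#'   1 for DFT tracks and 450 for filter tracks.
#' @param ambiguity non-ACGT policy, see \code{\link{binaryIndicators}}.
#' @param measure optional spectral measure hook for the binary method.
#' @return list with \code{track} (the possibly denoised evidence track),
#'   \code{calls} (an \linkS4class{ExonCallSet}) and \code{config} (every
#'   resolved parameter, for run logs).
#' @export
#' @examples
#' g <- generateGenome(defaultSynthSpec(seed = 11))
#' p <- predictExons(g$region, "reduced_f2", denoise = TRUE)
#' p$calls
predictExons <- function(region, method = PREDICT_METHODS,
                         windowLength = 240L,
                         assignment = c("center", "left"),
                         R = 0.992, bandwidth = 0.02 * pi,
                         weights = c(A = 0, C = 0, G = 1, T = 0),
                         denoise = FALSE, dwtLevel = 1L,
                         thresholdFraction = 0.5, minLength = 50L,
                         mergeGap = 30L, smoothSpan = NULL,
                         ambiguity = c("strict", "zero"),
                         measure = NULL) {
    stopifnot(is(region, "DNARegion"))
    method <- match.arg(method)
    assignment <- match.arg(assignment)
    ambiguity <- match.arg(ambiguity)
    isDFT <- method %in% c("binary", "eiip")
    if (isDFT && windowLength %% 3L != 0L)
        stop("'windowLength' must be a multiple of 3 for the DFT methods, got ",
             windowLength)

    track <- switch(method,
        binary = slidingTrack(binaryIndicators(region, ambiguity),
                              windowLength, assignment, measure = measure),
        eiip = slidingTrack(eiipSequence(region, ambiguity),
                            windowLength, assignment),
        filter1 = fourChannelTrack(binaryIndicators(region, ambiguity),
                                   designFilter1(R)$antinotch),
        filter2 = fourChannelTrack(binaryIndicators(region, ambiguity),
                                   designFilter2(bandwidth)),
        reduced_f1 = reducedTrack(
            combinedSequence(binaryIndicators(region, ambiguity), weights),
            designFilter1(R)$antinotch),
        reduced_f2 = reducedTrack(
            combinedSequence(binaryIndicators(region, ambiguity), weights),
            designFilter2(bandwidth)))

    if (denoise)
        track <- suppressMessages(denoiseTrack(track, level = dwtLevel))

    if (is.null(smoothSpan))
        smoothSpan <- if (isDFT) 1L else 450L
    calls <- callExons(track, thresholdFraction = thresholdFraction,
                       minLength = minLength, mergeGap = mergeGap,
                       smoothSpan = smoothSpan)
    config <- list(method = method,
                   windowLength = if (isDFT) windowLength else NA_integer_,
                   assignment = if (isDFT) assignment else NA_character_,
                   R = if (method %in% c("filter1", "reduced_f1")) R
                       else NA_real_,
                   bandwidth = if (method %in% c("filter2", "reduced_f2"))
                       bandwidth else NA_real_,
                   weights = if (startsWith(method, "reduced"))
                       weights[DNA_BASES4] else NULL,
                   denoise = denoise,
                   dwtLevel = if (denoise) dwtLevel else NA_integer_,
                   thresholdFraction = thresholdFraction,
                   minLength = minLength, mergeGap = mergeGap,
                   smoothSpan = smoothSpan, ambiguity = ambiguity)
    list(track = track, calls = calls, config = config)
}
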
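#' @importFrom methods new validObject is slot setValidity show as
#' @importClassesFrom Biostrings DNAString
#' @import S4Vectors
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Electron-ion interaction pseudopotential values per nucleotide
#'
#' Per-base physical constants used to map a DNA string onto a single
#' real-valued signal whose power spectrum reveals the period-3 component of
#' coding regions.
#'
#' @format Named numeric vector over A, C, G, T.
#' @export
#' @examples
#' EIIP[["G"]]
EIIP <- c(A = 0.126, C = 0.134, G = 0.0806, T = 0.1335)

#' DNARegion: a contiguous stretch of genomic DNA
#'
#' Holds a DNA sequence together with the identifier of its source record and
#' the 1-based position of its first base within that record
#' (\code{originOffset}), so that sub-regions keep absolute coordinates.
#'
#' @slot recordId single character, source record identifier.
#' @slot sequence a \linkS4class{DNAString}.
#' @slot originOffset integer >= 1; 1-based position of the first base of
#'   \code{sequence} within the source record.
#' @aliases DNARegion-class
#' @exportClass DNARegion
setClass("DNARegion",
    representation(
        recordId = "character",
        sequence = "DNAString",
        originOffset = "integer"
    )
)

setValidity("DNARegion", function(object) {
    msg <- character()
    if (length(object@recordId) != 1L)
        msg <- c(msg, "'recordId' must be a single string")
    if (length(object@originOffset) != 1L || is.na(object@originOffset) ||
        object@originOffset < 1L)
        msg <- c(msg, "'originOffset' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' IndicatorSet: the four binary indicator sequences of a region
#'
#' One-hot representation of a DNA region: a 4 x N binary matrix with rows
#' A, C, G, T, where entry (b, n) is 1 iff base b occurs at position n. For a
#' clean 4-letter alphabet the four rows sum to one at every position; under
#' the "zero" ambiguity policy, positions carrying ambiguity codes have
#' all-zero columns.
#'
#' @slot indicators integer matrix, 4 x N, rownames A, C, G, T.
#' @slot recordId source record identifier.
#' @slot originOffset 1-based absolute position of column 1.
#' @aliases IndicatorSet-class
#' @exportClass IndicatorSet
setClass("IndicatorSet",
    representation(
        indicators = "matrix",
        recordId = "character",
        originOffset = "integer"
    )
)

setValidity("IndicatorSet", function(object) {
    m <- object@indicators
    if (!is.numeric(m) || nrow(m) != 4L ||
        !identical(rownames(m), DNA_BASES4))
        return("'indicators' must be a numeric 4 x N matrix with rows A, C, G, T")
    if (length(m) && !all(m %in% c(0, 1)))
        return("indicator values must be 0 or 1")
    colsum <- if (ncol(m)) colSums(m) else numeric()
    if (length(colsum) && !all(colsum %in% c(0, 1)))
        return("each position must carry at most one base")
    TRUE
})

#' NumericSequence: a real-valued per-base signal
#'
#' Any real signal indexed by base position: an EIIP-mapped sequence, a
#' weighted combined indicator sequence, an intermediate filter output.
#'
#' @slot values finite numeric vector.
#' @slot label free-text label ("eiip", "combined", ...).
#' @slot recordId source record identifier.
#' @slot originOffset 1-based absolute position of \code{values[1]}.
#' @aliases NumericSequence-class
#' @exportClass NumericSequence
setClass("NumericSequence",
    representation(
        values = "numeric",
        label = "character",
        recordId = "character",
        originOffset = "integer"
    )
)

setValidity("NumericSequence", function(object) {
    if (length(object@values) && !all(is.finite(object@values)))
        return("'values' must be finite (no NA/NaN/Inf)")
    TRUE
})

#' SignalTrack: virtual parent of per-position exon evidence tracks
#'
#' @slot values non-negative numeric vector, one value per track position.
#' @slot method label of the producing method.
#' @slot recordId source record identifier.
#' @slot originOffset 1-based absolute position of the first base of the
#'   region the track was computed on.
#' @aliases SignalTrack-class
#' @exportClass SignalTrack
setClass("SignalTrack",
    representation(
        "VIRTUAL",
        values = "numeric",
        method = "character",
        recordId = "character",
        originOffset = "integer"
    )
)

setValidity("SignalTrack", function(object) {
    if (length(object@values) && (!all(is.finite(object@values)) ||
        any(object@values < 0)))
        return("track values must be finite and >= 0")
    TRUE
})

#' SpectralTrack: sliding-window spectral content at the period-3 frequency
#'
#' One power value per window placement of a sliding-window DFT evaluated at
#' bin k = window/3. With \code{assignment = "center"} the value of the window
#' starting at absolute position s is plotted at s + window/2; with "left" at
#' s itself.
#'
#' @slot windowLength window length in bases, a multiple of 3.
#' @slot assignment "center" or "left".
#' @aliases SpectralTrack-class
#' @exportClass SpectralTrack
setClass("SpectralTrack",
    contains = "SignalTrack",
    representation(
        windowLength = "integer",
        assignment = "character"
    )
)

setValidity("SpectralTrack", function(object) {
    msg <- character()
    if (object@windowLength %% 3L != 0L)
        msg <- c(msg, "'windowLength' must be a multiple of 3")
    if (!object@assignment %in% c("center", "left"))
        msg <- c(msg, "'assignment' must be \"center\" or \"left\"")
    if (length(msg)) msg else TRUE
})

#' PowerTrack: instantaneous output power of a narrowband filter
#'
#' One value per base position: the squared magnitude of the filtered
#' indicator channels (summed over the four channels, or of the single
#' combined channel in the reduced-computation variant). The first
#' \code{transientLength} samples are start-up transient of the causal IIR
#' filter and are flagged but not trimmed.
#'
#' @slot transientLength integer, approximate filter settling time in samples.
#' @aliases PowerTrack-class
#' @exportClass PowerTrack
setClass("PowerTrack",
    contains = "SignalTrack",
    representation(transientLength = "integer")
)

#' FilterDesign: coefficients and metadata of a second-order IIR design
#'
#' @slot b numerator coefficients.
#' @slot a denominator coefficients, a[1] = 1.
#' @slot centerFrequency design center frequency, radians/sample.
#' @slot designParams named list (pole radius \code{R}, or \code{bandwidth}).
#' @slot name one of "allpass", "filter1_notch", "filter1_antinotch",
#'   "filter2_peaking".
#' @aliases FilterDesign-class
#' @exportClass FilterDesign
setClass("FilterDesign",
    representation(
        b = "numeric",
        a = "numeric",
        centerFrequency = "numeric",
        designParams = "list",
        name = "character"
    )
)

setValidity("FilterDesign", function(object) {
    msg <- character()
    if (!length(object@a) || abs(object@a[1] - 1) > 1e-12)
        msg <- c(msg, "'a[1]' must equal 1")
    if (length(object@a) > 1) {
        p <- polyroot(rev(object@a))
        if (any(Mod(p) >= 1))
            msg <- c(msg, "unstable design: poles must lie strictly inside the unit circle")
    }
    if (length(msg)) msg else TRUE
})

#' WaveletDecomposition: multi-level Haar subband decomposition
#'
#' Approximation (lowpass) coefficients at the deepest level plus one detail
#' (highpass) vector per level, detail of level 1 first. Orthonormal Haar is
#' used so that, absent boundary extension, energy is partitioned exactly
#' between the subbands.
#'
#' @slot approximation lowpass coefficients at the deepest level.
#' @slot details list of detail vectors, one per level, level 1 first.
#' @slot level decomposition depth >= 1.
#' @slot originalLength length of the analysed signal.
#' @slot boundaryMode how odd lengths were extended ("sym-half").
#' @aliases WaveletDecomposition-class
#' @exportClass WaveletDecomposition
setClass("WaveletDecomposition",
    representation(
        approximation = "numeric",
        details = "list",
        level = "integer",
        originalLength = "integer",
        boundaryMode = "character"
    )
)

setValidity("WaveletDecomposition", function(object) {
    msg <- character()
    if (object@level < 1L)
        msg <- c(msg, "'level' must be >= 1")
    if (length(object@details) != object@level)
        msg <- c(msg, "'details' must hold one vector per level")
    n <- object@originalLength
    for (l in seq_len(object@level)) {
        n <- ceiling(n / 2)
        if (length(object@details[[l]]) != n)
            msg <- c(msg, sprintf("detail vector %d has wrong length", l))
    }
    if (length(object@approximation) != n)
        msg <- c(msg, "'approximation' has wrong length")
    if (length(msg)) msg else TRUE
})

#' ExonCallSet: discrete exon interval calls from one power track
#'
#' Calls are kept as a \linkS4class{GRanges} (1-based inclusive absolute
#' record coordinates) with per-call peak and mean track power as metadata
#' columns; calls are sorted, non-overlapping, and separated by more than the
#' merge gap used.
#'
#' @slot calls a GRanges with mcols \code{peakPower}, \code{meanPower}.
#' @slot method producing method label.
#' @slot params named list of calling parameters (thresholdFraction,
#'   absolute threshold, minLength, mergeGap, smoothSpan).
#' @aliases ExonCallSet-class
#' @exportClass ExonCallSet
setClass("ExonCallSet",
    representation(
        calls = "GRanges",
        method = "character",
        params = "list"
    )
)

setValidity("ExonCallSet", function(object) {
    gr <- object@calls
    if (length(gr) > 1) {
        st <- GenomicRanges::start(gr)
        en <- GenomicRanges::end(gr)
        if (is.unsorted(st))
            return("calls must be sorted by start")
        if (any(st[-1] <= en[-length(en)]))
            return("calls must be non-overlapping")
    }
    if (!all(c("peakPower", "meanPower") %in%
             colnames(S4Vectors::mcols(gr))))
        return("calls must carry 'peakPower' and 'meanPower' metadata")
    TRUE
})

#' SynthSpec: parameters of a synthetic genome with planted period-3 exons
#'
#' Background positions are drawn iid from \code{backgroundProbs}; positions
#' inside an exon are drawn from the codon-position-specific rows of
#' \code{codonBias}, giving the planted period-3 signal.
#'
#' @slot length total sequence length.
#' @slot exons an \linkS4class{IRanges} of planted exon intervals (1-based
#'   inclusive, sorted, non-overlapping).
#' @slot codonBias 3 x 4 matrix of per-codon-position nucleotide
#'   probabilities, columns A, C, G, T, rows summing to 1.
#' @slot backgroundProbs length-4 probability vector, names A, C, G, T.
#' @slot seed integer RNG seed making generation reproducible.
#' @aliases SynthSpec-class
#' @exportClass SynthSpec
setClass("SynthSpec",
    representation(
        length = "integer",
        exons = "IRanges",
        codonBias = "matrix",
        backgroundProbs = "numeric",
        seed = "integer"
    )
)

setValidity("SynthSpec", function(object) {
    msg <- character()
    ex <- object@exons
    if (length(ex)) {
        if (min(IRanges::start(ex)) < 1L ||
            max(IRanges::end(ex)) > object@length)
            msg <- c(msg, "exons must lie within [1, length]")
        if (is.unsorted(IRanges::start(ex)))
            msg <- c(msg, "exons must be sorted")
        if (length(ex) > 1 && any(IRanges::start(ex)[-1] <=
                                  IRanges::end(ex)[-length(ex)]))
            msg <- c(msg, "exons must be non-overlapping")
    }
    cb <- object@codonBias
    if (!identical(dim(cb), c(3L, 4L)) ||
        !identical(colnames(cb), DNA_BASES4))
        msg <- c(msg, "'codonBias' must be 3 x 4 with columns A, C, G, T")
    else if (any(abs(rowSums(cb) - 1) > 1e-12) || any(cb < 0))
        msg <- c(msg, "'codonBias' rows must be probabilities summing to 1")
    bp <- object@backgroundProbs
    if (length(bp) != 4L || !identical(names(bp), DNA_BASES4) ||
        abs(sum(bp) - 1) > 1e-12 || any(bp < 0))
        msg <- c(msg, "'backgroundProbs' must be a probability vector over A, C, G, T")
    if (length(msg)) msg else TRUE
})
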
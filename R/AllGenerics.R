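#' @name exonDSP-accessors
#' @title Accessors for exonDSP classes
#' @description Slot accessors shared across the package's classes. Use these
#'   rather than \code{@} access.
#' @param x an exonDSP object.
#' @param base one of "A", "C", "G", "T".
NULL

#' @rdname exonDSP-accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname exonDSP-accessors
#' @export
setGeneric("originOffset", function(x) standardGeneric("originOffset"))

#' @rdname exonDSP-accessors
#' @export
setGeneric("regionSequence", function(x) standardGeneric("regionSequence"))

#' @rdname exonDSP-accessors
#' @export
setGeneric("indicatorMatrix", function(x) standardGeneric("indicatorMatrix"))

#' @rdname exonDSP-accessors
#' @export
setGeneric("indicator", function(x, base) standardGeneric("indicator"))

#' @rdname exonDSP-accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname exonDSP-accessors
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))

#' @rdname exonDSP-accessors
#' @export
setGeneric("exonCalls", function(x) standardGeneric("exonCalls"))

#' Denoise a track or signal by Haar detail suppression
#'
#' @param x object to denoise.
#' @param level decomposition depth (default 1).
#' @param ... further arguments for methods.
#' @export
setGeneric("denoiseTrack", function(x, level = 1L, ...)
    standardGeneric("denoiseTrack"))

setMethod("recordId", "DNARegion", function(x) x@recordId)
setMethod("recordId", "IndicatorSet", function(x) x@recordId)
setMethod("recordId", "NumericSequence", function(x) x@recordId)
setMethod("recordId", "SignalTrack", function(x) x@recordId)

setMethod("originOffset", "DNARegion", function(x) x@originOffset)
setMethod("originOffset", "IndicatorSet", function(x) x@originOffset)
setMethod("originOffset", "NumericSequence", function(x) x@originOffset)
setMethod("originOffset", "SignalTrack", function(x) x@originOffset)

setMethod("regionSequence", "DNARegion", function(x) x@sequence)

setMethod("indicatorMatrix", "IndicatorSet", function(x) x@indicators)
setMethod("indicator", "IndicatorSet", function(x, base) {
    base <- match.arg(base, DNA_BASES4)
    as.numeric(x@indicators[base, ])
})

setMethod("trackValues", "NumericSequence", function(x) x@values)
setMethod("trackValues", "SignalTrack", function(x) x@values)

setMethod("length", "DNARegion", function(x) length(x@sequence))
setMethod("length", "IndicatorSet", function(x) ncol(x@indicators))
setMethod("length", "NumericSequence", function(x) length(x@values))
setMethod("length", "SignalTrack", function(x) length(x@values))
setMethod("length", "ExonCallSet", function(x) length(x@calls))

#' @describeIn PowerTrack-class absolute 1-based position of each value.
setMethod("trackPositions", "PowerTrack", function(x)
    x@originOffset + seq_along(x@values) - 1L)

#' @describeIn SpectralTrack-class absolute 1-based position each window's
#'   value is assigned to (window center by default).
setMethod("trackPositions", "SpectralTrack", function(x) {
    shift <- if (x@assignment == "center") x@windowLength %/% 2L else 0L
    x@originOffset + shift + seq_along(x@values) - 1L
})

setMethod("exonCalls", "ExonCallSet", function(x) x@calls)

setMethod("show", "DNARegion", function(object) {
    n <- length(object@sequence)
    cat(sprintf("DNARegion %s: %d bases, record positions %d-%d\n",
        object@recordId, n, object@originOffset,
        object@originOffset + n - 1L))
    if (n)
        cat("  ", as.character(Biostrings::subseq(object@sequence, 1,
            min(n, 40L))), if (n > 40L) "..." else "", "\n", sep = "")
})

setMethod("show", "IndicatorSet", function(object) {
    cat(sprintf("IndicatorSet of %s: 4 x %d binary matrix (offset %d)\n",
        object@recordId, ncol(object@indicators), object@originOffset))
})

setMethod("show", "NumericSequence", function(object) {
    cat(sprintf("NumericSequence '%s' of %s: %d values (offset %d)\n",
        object@label, object@recordId, length(object@values),
        object@originOffset))
})

setMethod("show", "SpectralTrack", function(object) {
    cat(sprintf(
        "SpectralTrack [%s] of %s: %d windows of %d nt (%s-assigned)\n",
        object@method, object@recordId, length(object@values),
        object@windowLength, object@assignment))
})

setMethod("show", "PowerTrack", function(object) {
    cat(sprintf(
        "PowerTrack [%s] of %s: %d positions (transient ~%d samples)\n",
        object@method, object@recordId, length(object@values),
        object@transientLength))
})

setMethod("show", "FilterDesign", function(object) {
    cat(sprintf("FilterDesign '%s' centered at %.4f rad/sample\n",
        object@name, object@centerFrequency))
    cat("  b:", signif(object@b, 6), "\n  a:", signif(object@a, 6), "\n")
})

setMethod("show", "WaveletDecomposition", function(object) {
    cat(sprintf(
        "WaveletDecomposition: Haar, level %d, original length %d\n",
        object@level, object@originalLength))
})

setMethod("show", "ExonCallSet", function(object) {
    cat(sprintf("ExonCallSet [%s]: %d calls\n", object@method,
        length(object@calls)))
    if (length(object@calls))
        cat(paste0("  ", formatCallTable(object), collapse = "\n"), "\n")
})

setMethod("show", "SynthSpec", function(object) {
    cat(sprintf("SynthSpec: %d nt, %d planted exons, seed %d\n",
        object@length, length(object@exons), object@seed))
})
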
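haarStep <- function(x) {
    n <- length(x)
    if (n %% 2L == 1L)           # half-sample symmetric extension
        x <- c(x, x[n])
    odd <- x[seq(1L, length(x), by = 2L)]
    even <- x[seq(2L, length(x), by = 2L)]
    list(approx = (odd + even) / sqrt(2),
         detail = (odd - even) / sqrt(2))
}

haarUnstep <- function(approx, detail, targetLength) {
    odd <- (approx + detail) / sqrt(2)
    even <- (approx - detail) / sqrt(2)
    x <- as.numeric(rbind(odd, even))
    x[seq_len(targetLength)]
}

#' Orthonormal Haar wavelet decomposition
#'
#' Recursive halfband analysis: at each level the signal is split into
#' approximation (pairwise sums / sqrt(2)) and detail (pairwise differences
#' / sqrt(2)) coefficients, each half the length, and the approximation is
#' recursed on. The orthonormal scaling makes the transform energy
#' preserving. Odd lengths are extended by duplicating the edge sample; the
#' original length is recorded so reconstruction can trim.
#'
#' @param x a \linkS4class{NumericSequence}, \linkS4class{SignalTrack}, or
#'   plain numeric vector.
#' @param level decomposition depth >= 1; \code{2^level} must not exceed
#'   \code{length(x)}.
#' @return a \linkS4class{WaveletDecomposition}.
#' @export
#' @examples
#' d <- haarAnalyze(c(4, 6, 2, 2), level = 1)
#' d@approximation   # (10, 4)/sqrt(2)
#' d@details[[1]]    # (-2, 0)/sqrt(2)
haarAnalyze <- function(x, level = 1L) {
    v <- if (is(x, "NumericSequence") || is(x, "SignalTrack"))
        trackValues(x) else as.numeric(x)
    level <- as.integer(level)
    if (level < 1L)
        stop("'level' must be >= 1")
    if (2^level > length(v))
        stop(sprintf("level %d too deep for a signal of length %d",
                     level, length(v)))
    details <- vector("list", level)
    approx <- v
    for (l in seq_len(level)) {
        st <- haarStep(approx)
        approx <- st$approx
        details[[l]] <- st$detail
    }
    new("WaveletDecomposition", approximation = approx, details = details,
        level = level, originalLength = length(v), boundaryMode = "sym-half")
}

#' Inverse Haar wavelet transform
#'
#' Exact inverse of \code{\link{haarAnalyze}}: upsamples and recombines
#' approximation and detail coefficients level by level, trimming boundary
#' extension, so that \code{haarSynthesize(haarAnalyze(x))} reproduces x to
#' machine precision.
#'
#' @param d a \linkS4class{WaveletDecomposition}.
#' @return numeric vector of length \code{d@originalLength}.
#' @export
haarSynthesize <- function(d) {
    stopifnot(is(d, "WaveletDecomposition"))
    validObject(d)
    lengths <- d@originalLength
    for (l in seq_len(d@level))
        lengths <- c(lengths, ceiling(lengths[l] / 2))
    approx <- d@approximation
    for (l in rev(seq_len(d@level)))
        approx <- haarUnstep(approx, d@details[[l]], lengths[l])
    approx
}

## zero-detail reconstruction computed as nested pairwise means: this is
## algebraically identical to analyze -> zero details -> synthesize (the
## 1/sqrt(2) factors of analysis and synthesis cancel pairwise) but uses
## exact halving, so re-denoising an already denoised signal is an exact
## no-op rather than an up-to-1-ulp one
haarDenoiseValues <- function(v, level) {
    if (2^level > length(v))
        stop(sprintf("level %d too deep for a signal of length %d",
                     level, length(v)))
    if (level < 1L)
        stop("'level' must be >= 1")
    denoiseRec <- function(x, l) {
        if (l == 0L) return(x)
        n <- length(x)
        if (n %% 2L == 1L) x <- c(x, x[n])
        m <- (x[seq(1L, length(x), by = 2L)] +
              x[seq(2L, length(x), by = 2L)]) / 2
        rep(denoiseRec(m, l - 1L), each = 2L)[seq_len(n)]
    }
    denoiseRec(v, as.integer(level))
}

#' @describeIn denoiseTrack Haar-denoise a plain numeric vector (details
#'   zeroed, no clamping).
#' @export
setMethod("denoiseTrack", "numeric", function(x, level = 1L, ...)
    haarDenoiseValues(x, level))

denoiseTrackObject <- function(x, level) {
    v <- haarDenoiseValues(x@values, level)
    clamped <- sum(v < 0)
    if (clamped > 0) {
        message(clamped, " negative reconstructed values clamped to 0")
        v[v < 0] <- 0
    }
    x@values <- v
    x@method <- paste0(x@method, "+dwt", level)
    x
}

#' @describeIn denoiseTrack denoise a filtered exon power track.
#' @export
setMethod("denoiseTrack", "PowerTrack", function(x, level = 1L, ...)
    denoiseTrackObject(x, as.integer(level)))

#' @describeIn denoiseTrack denoise a sliding-window spectral track.
#' @export
setMethod("denoiseTrack", "SpectralTrack", function(x, level = 1L, ...)
    denoiseTrackObject(x, as.integer(level)))

#' Export a wavelet decomposition as JSON
#'
#' @param d a \linkS4class{WaveletDecomposition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDecompositionJSON <- function(d, path) {
    stopifnot(is(d, "WaveletDecomposition"))
    jsonlite::write_json(
        list(level = d@level, approximation = d@approximation,
             details = d@details, boundary_mode = d@boundaryMode,
             original_length = d@originalLength),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
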
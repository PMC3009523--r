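PERIOD3_OMEGA <- 2 * pi / 3

#' Second-order all-pass filter
#'
#' A(z) = (R^2 - 2R cos(w0) z^-1 + z^-2) / (1 - 2R cos(w0) z^-1 + R^2 z^-2):
#' unit magnitude at every frequency, poles at R exp(+-i w0). The building
#' block of the complementary notch / anti-notch pair.
#'
#' @param R pole radius, 0 < R < 1 (sharpness; closer to 1 is narrower).
#' @param omega0 center frequency in radians/sample, 0 < omega0 < pi.
#' @return a \linkS4class{FilterDesign} named "allpass".
#' @export
designAllpass <- function(R, omega0 = PERIOD3_OMEGA) {
    if (!is.finite(R) || R <= 0 || R >= 1)
        stop("pole radius R must satisfy 0 < R < 1 for stability, got ", R)
    if (!is.finite(omega0) || omega0 <= 0 || omega0 >= pi)
        stop("'omega0' must lie in (0, pi)")
    c1 <- -2 * R * cos(omega0)
    new("FilterDesign",
        b = c(R^2, c1, 1),
        a = c(1, c1, R^2),
        centerFrequency = omega0,
        designParams = list(R = R),
        name = "allpass")
}

#' Complementary notch / anti-notch pair at the period-3 frequency
#'
#' From the second-order all-pass A(z), the filter bank
#' G(z) = (1 + A(z))/2 and H(z) = (1 - A(z))/2 is built: G is a notch with a
#' zero at w0 = 2*pi/3 and H the anti-notch (narrowband bandpass) with unit
#' gain there; |G|^2 + |H|^2 = 1 at every frequency. H passes the period-3
#' component of an indicator channel, so its output power flags coding
#' regions.
#'
#' @param R pole radius, 0 < R < 1; default 0.992 gives a sharp,
#'   well-conditioned passband.
#' @return list with elements \code{notch} and \code{antinotch}, both
#'   \linkS4class{FilterDesign} objects.
#' @export
#' @examples
#' d <- designFilter1()
#' Mod(filterResponse(d$antinotch, 2 * pi / 3))   # 1
#' Mod(filterResponse(d$notch, 2 * pi / 3))       # 0
designFilter1 <- function(R = 0.992) {
    if (!is.finite(R) || R <= 0 || R >= 1)
        stop("pole radius R must satisfy 0 < R < 1 for stability, got ", R)
    ## all-pass parameterized by the notch frequency: with
    ## a = (1, -(1+R^2) cos(w0), R^2) and b = rev(a), the sum (1 + A)/2
    ## carries the factor 1 - 2 cos(w0) z^-1 + z^-2, i.e. zeros exactly on
    ## the unit circle at +-w0; the pole radius is exactly R. (An all-pass
    ## with poles at angle w0 instead would leave the notch zero slightly
    ## off w0 - the two parameterizations coincide only as R -> 1.)
    w0 <- PERIOD3_OMEGA
    a <- c(1, -(1 + R^2) * cos(w0), R^2)
    ap <- new("FilterDesign", b = rev(a), a = a, centerFrequency = w0,
              designParams = list(R = R), name = "allpass")
    half <- function(b) b / 2
    notch <- new("FilterDesign",
        b = half(ap@a + ap@b), a = ap@a,
        centerFrequency = PERIOD3_OMEGA,
        designParams = list(R = R),
        name = "filter1_notch")
    antinotch <- new("FilterDesign",
        b = half(ap@a - ap@b), a = ap@a,
        centerFrequency = PERIOD3_OMEGA,
        designParams = list(R = R),
        name = "filter1_antinotch")
    list(notch = notch, antinotch = antinotch)
}

#' Single peaking (resonator) filter at the period-3 frequency
#'
#' Second-order IIR peaking filter with unit gain at w0 = 2*pi/3 and a
#' prescribed -3 dB bandwidth: b = beta/(1+beta) * [1, 0, -1],
#' a = [1, -2 cos(w0)/(1+beta), (1-beta)/(1+beta)] with beta = tan(bw/2).
#' A narrow bandwidth buys extra stop-band attenuation, the property that
#' makes this design outperform the notch-complement above on noisy
#' indicator channels.
#'
#' @param bandwidth -3 dB bandwidth in radians/sample, 0 < bandwidth < pi/2;
#'   default 0.02*pi.
#' @return a \linkS4class{FilterDesign} named "filter2_peaking".
#' @export
designFilter2 <- function(bandwidth = 0.02 * pi) {
    if (!is.finite(bandwidth) || bandwidth <= 0 || bandwidth >= pi / 2)
        stop("'bandwidth' must lie in (0, pi/2)")
    beta <- tan(bandwidth / 2)
    g <- beta / (1 + beta)
    new("FilterDesign",
        b = c(g, 0, -g),
        a = c(1, -2 * cos(PERIOD3_OMEGA) / (1 + beta),
              (1 - beta) / (1 + beta)),
        centerFrequency = PERIOD3_OMEGA,
        designParams = list(bandwidth = bandwidth),
        name = "filter2_peaking")
}

#' Complex frequency response of a filter design
#'
#' @param design a \linkS4class{FilterDesign}.
#' @param omega numeric vector of frequencies in radians/sample.
#' @return complex vector H(exp(i*omega)).
#' @export
filterResponse <- function(design, omega) {
    stopifnot(is(design, "FilterDesign"))
    z <- exp(-1i * omega)
    horner <- function(coef) {
        acc <- rep(0 + 0i, length(z))
        for (c0 in rev(coef)) acc <- acc * z + c0
        acc
    }
    horner(design@b) / horner(design@a)
}

poleRadius <- function(design) {
    if (length(design@a) <= 1L) return(0)
    max(Mod(polyroot(rev(design@a))))
}

#' Apply an IIR filter to a per-base signal
#'
#' Causal direct-form filtering with zero initial conditions (single forward
#' pass, as in the exon-plot pipeline); output length equals input length.
#'
#' @param design a stable \linkS4class{FilterDesign}.
#' @param x a \linkS4class{NumericSequence} or plain numeric vector.
#' @return same type as \code{x} (label gains a "filtered:" prefix).
#' @export
applyFilter <- function(design, x) {
    stopifnot(is(design, "FilterDesign"))
    validObject(design)   # re-checks stability
    v <- if (is(x, "NumericSequence")) x@values else as.numeric(x)
    y <- as.numeric(signal::filter(design@b, design@a, v))
    if (is(x, "NumericSequence"))
        new("NumericSequence", values = y,
            label = paste0("filtered:", x@label),
            recordId = x@recordId, originOffset = x@originOffset)
    else y
}

transientSamples <- function(design) {
    r <- poleRadius(design)
    if (r <= 0) return(length(design@b))
    as.integer(ceiling(5 / (1 - r)))
}

#' Four-channel filtered exon power track
#'
#' Filters each of the four indicator channels through the narrowband design
#' and sums the squared outputs: Y(n) = |yA|^2 + |yT|^2 + |yC|^2 + |yG|^2.
#' Large Y flags positions whose neighbourhood feeds period-3 energy into
#' the passband, i.e. candidate coding regions.
#'
#' @param ind an \linkS4class{IndicatorSet}.
#' @param design a \linkS4class{FilterDesign} (anti-notch or peaking).
#' @return a \linkS4class{PowerTrack} of the same length as the region.
#' @export
fourChannelTrack <- function(ind, design) {
    stopifnot(is(ind, "IndicatorSet"))
    y2 <- rowSums(vapply(DNA_BASES4, function(b)
        applyFilter(design, as.numeric(ind@indicators[b, ]))^2,
        numeric(ncol(ind@indicators))))
    new("PowerTrack", values = as.numeric(y2),
        method = paste0("four_channel_", shortDesignName(design)),
        recordId = ind@recordId, originOffset = ind@originOffset,
        transientLength = transientSamples(design))
}

#' Reduced-computation single-channel exon power track
#'
#' Filters the weighted combined sequence (see
#' \code{\link{combinedSequence}}) once and squares the output:
#' Y(n) = |y(n)|^2. One filter pass instead of four, at the cost of fixing
#' the channel weights up front.
#'
#' @param combined a \linkS4class{NumericSequence} from
#'   \code{\link{combinedSequence}} (any numeric sequence is accepted).
#' @param design a \linkS4class{FilterDesign}.
#' @return a \linkS4class{PowerTrack}.
#' @export
reducedTrack <- function(combined, design) {
    stopifnot(is(combined, "NumericSequence"))
    y <- applyFilter(design, combined@values)
    new("PowerTrack", values = y^2,
        method = paste0("reduced_", shortDesignName(design)),
        recordId = combined@recordId, originOffset = combined@originOffset,
        transientLength = transientSamples(design))
}

shortDesignName <- function(design)
    switch(design@name,
        filter1_antinotch = "f1",
        filter1_notch = "f1notch",
        filter2_peaking = "f2",
        design@name)

#' Export a filter design as coefficient JSON
#'
#' @param design a \linkS4class{FilterDesign}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFilterJSON <- function(design, path) {
    stopifnot(is(design, "FilterDesign"))
    jsonlite::write_json(
        list(name = design@name, b = design@b, a = design@a,
             center_frequency = design@centerFrequency,
             params = design@designParams),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
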
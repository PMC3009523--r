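#' Construct a synthetic-genome specification
#'
#' Defines a sequence of iid background nucleotides with planted exons whose
#' bases follow codon-position-specific probabilities, giving them the
#' period-3 spectral signature of real coding regions with tunable strength.
#'
#' @param length total sequence length in bases.
#' @param exons planted exon intervals: an \linkS4class{IRanges},
#'   data.frame with start/end, or 2-column matrix (1-based inclusive,
#'   sorted, non-overlapping).
#' @param codonBias 3 x 4 matrix of nucleotide probabilities, one row per
#'   codon position, columns A, C, G, T; rows sum to 1. The default puts
#'   probability 0.55 on G, C, A at codon positions 1, 2, 3 respectively and
#'   0.15 on the rest - a moderate bias that keeps recovery nontrivial.
#' @param backgroundProbs background nucleotide probabilities (default
#'   uniform).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(length, exons, codonBias = defaultCodonBias(),
                      backgroundProbs = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                      seed = 1L) {
    if (!is(exons, "IRanges"))
        exons <- asTruthRanges(exons)
    new("SynthSpec", length = as.integer(length), exons = exons,
        codonBias = codonBias,
        backgroundProbs = backgroundProbs[DNA_BASES4],
        seed = as.integer(seed))
}

#' @rdname synthSpec
#' @export
defaultCodonBias <- function(strength = 0.55) {
    rest <- (1 - strength) / 3
    m <- matrix(rest, nrow = 3, ncol = 4,
                dimnames = list(NULL, DNA_BASES4))
    m[1, "G"] <- strength
    m[2, "C"] <- strength
    m[3, "A"] <- strength
    m
}

#' Default synthetic fixture: 8000 nt with five exons
#'
#' Mirrors the exon layout of the much-studied 8000-nt region of the
#' C. elegans gene F56F11.5 (GenBank AF099922, positions 7021-15020): five
#' exons of lengths 112, 331, 263, 179 and 350 at the relative positions of
#' the NCBI annotation, so tests exercise a realistic multi-exon layout with
#' no download.
#'
#' @param seed integer RNG seed.
#' @param codonBias exon codon bias (see \code{\link{synthSpec}}).
#' @return a \linkS4class{SynthSpec} of length 8000.
#' @export
defaultSynthSpec <- function(seed = 1L, codonBias = defaultCodonBias()) {
    starts <- NCBI_AF099922_EXONS$start - 7020L
    synthSpec(8000L,
              IRanges::IRanges(starts, width = NCBI_AF099922_EXONS$length),
              codonBias = codonBias, seed = seed)
}

#' NCBI exon annotation of AF099922 used for layouts and evaluation
#'
#' The five exons of the C. elegans gene F56F11.5 as annotated in the NCBI
#' database, in absolute record coordinates of GenBank AF099922. Lengths are
#' the printed boundary-to-boundary spans.
#'
#' @format data.frame with columns start, end, length.
#' @export
NCBI_AF099922_EXONS <- data.frame(
    start = c(7947L, 9548L, 11134L, 12485L, 14275L),
    end = c(8059L, 9879L, 11397L, 12664L, 14625L),
    length = c(112L, 331L, 263L, 179L, 350L))

#' Generate a synthetic genome with ground truth
#'
#' Background positions are drawn iid from the background probabilities;
#' positions inside exons are drawn from the codon-bias row of their codon
#' position (counted from each exon's start). Deterministic given the spec's
#' seed; the caller's RNG state is left untouched.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param recordId identifier of the generated record (default
#'   "synthetic").
#' @param originOffset absolute 1-based position of base 1, letting the
#'   synthetic region live at the coordinates of a real record region.
#' @return list with \code{region} (a \linkS4class{DNARegion}) and
#'   \code{truth} (a GRanges of the planted exons in absolute coordinates).
#' @export
#' @examples
#' g <- generateGenome(defaultSynthSpec(seed = 7))
#' g$region
#' g$truth
generateGenome <- function(spec, recordId = "synthetic",
                           originOffset = 1L) {
    stopifnot(is(spec, "SynthSpec"))
    validObject(spec)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(oldSeed))
            suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", oldSeed, envir = globalenv())
    })
    set.seed(spec@seed)
    n <- spec@length
    letters <- sample(DNA_BASES4, n, replace = TRUE,
                      prob = spec@backgroundProbs)
    for (i in seq_along(spec@exons)) {
        s <- IRanges::start(spec@exons)[i]
        e <- IRanges::end(spec@exons)[i]
        posIdx <- s:e
        codonPos <- (posIdx - s) %% 3L + 1L
        for (cp in 1:3) {
            sel <- posIdx[codonPos == cp]
            letters[sel] <- sample(DNA_BASES4, length(sel), replace = TRUE,
                                   prob = spec@codonBias[cp, ])
        }
    }
    originOffset <- as.integer(originOffset)
    region <- newDNARegion(recordId, paste(letters, collapse = ""),
                           originOffset)
    truth <- GenomicRanges::GRanges(recordId,
        IRanges::shift(spec@exons, originOffset - 1L))
    list(region = region, truth = truth)
}

#' Read a SynthSpec from a JSON config
#'
#' Expected fields: length, exons (list of [start, end] pairs or an object
#' with start/end arrays), optional codon_bias (3 x 4 row-major over
#' A, C, G, T), background_probs, seed.
#'
#' @param path JSON file path.
#' @return a \linkS4class{SynthSpec}.
#' @export
readSynthSpecJSON <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    exons <- cfg$exons
    if (is.list(exons) && !is.data.frame(exons))
        exons <- do.call(rbind, lapply(exons, as.integer))
    cb <- if (!is.null(cfg$codon_bias)) {
        m <- matrix(as.numeric(unlist(cfg$codon_bias)), nrow = 3,
                    byrow = TRUE, dimnames = list(NULL, DNA_BASES4))
        m
    } else defaultCodonBias()
    bp <- if (!is.null(cfg$background_probs))
        stats::setNames(as.numeric(cfg$background_probs), DNA_BASES4)
    else c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    synthSpec(cfg$length, exons, codonBias = cb, backgroundProbs = bp,
              seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
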
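#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet subseq
NULL

newDNARegion <- function(recordId, sequence, originOffset = 1L) {
    if (!is(sequence, "DNAString"))
        sequence <- DNAString(toupper(as.character(sequence)))
    new("DNARegion", recordId = as.character(recordId),
        sequence = sequence, originOffset = as.integer(originOffset))
}

#' Construct a DNARegion from a character string
#'
#' Convenience constructor used throughout the examples and tests; sequences
#' are uppercased on the way in.
#'
#' @param sequence character string or \linkS4class{DNAString} over
#'   A, C, G, T (IUPAC ambiguity codes are accepted here and dealt with by
#'   the ambiguity policy of downstream converters).
#' @param recordId record identifier (default "region").
#' @param originOffset 1-based position of the first base within the source
#'   record (default 1).
#' @return a \linkS4class{DNARegion}.
#' @export
#' @examples
#' dnaRegion("ACCTG")
dnaRegion <- function(sequence, recordId = "region", originOffset = 1L)
    newDNARegion(recordId, sequence, originOffset)

#' Read all records of a FASTA file as DNARegion objects
#'
#' @param path path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return list of \linkS4class{DNARegion}, one per record in file order,
#'   each with \code{originOffset = 1}.
#' @export
readFastaRegions <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    set <- readDNAStringSet(path, format = "fasta")
    if (length(set) == 0L)
        stop("empty FASTA input: ", path)
    ids <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i)
        newDNARegion(ids[i], set[[i]], 1L))
}

#' Read a GenBank flat file as a single DNARegion
#'
#' Parses the LOCUS/ACCESSION header for the record identifier and the ORIGIN
#' section for the sequence (position numbers and whitespace stripped).
#'
#' @param path path to a GenBank flat file with an ORIGIN section.
#' @return a \linkS4class{DNARegion} with \code{originOffset = 1}.
#' @export
readGenBankRegion <- function(path) {
    if (!file.exists(path))
        stop("GenBank file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines))
        stop("empty GenBank input: ", path)
    id <- NA_character_
    acc <- grep("^ACCESSION", lines, value = TRUE)
    loc <- grep("^LOCUS", lines, value = TRUE)
    if (length(acc))
        id <- strsplit(trimws(acc[1]), "\\s+")[[1]][2]
    if (is.na(id) && length(loc))
        id <- strsplit(trimws(loc[1]), "\\s+")[[1]][2]
    if (is.na(id))
        stop("GenBank parse error: no LOCUS or ACCESSION line in ", path)
    oi <- grep("^ORIGIN", lines)
    if (!length(oi))
        stop("GenBank parse error: no ORIGIN section in ", path)
    body <- lines[(oi[1] + 1L):length(lines)]
    term <- grep("^//", body)
    if (!length(term))
        stop("GenBank parse error: ORIGIN section not terminated by // in ",
             path)
    body <- body[seq_len(term[1] - 1L)]
    seq <- toupper(gsub("[0-9[:space:]]", "", paste(body, collapse = "")))
    if (!nzchar(seq))
        stop("GenBank parse error: empty ORIGIN section in ", path)
    newDNARegion(id, seq, 1L)
}

#' Extract a sub-region keeping absolute record coordinates
#'
#' @param region a \linkS4class{DNARegion}.
#' @param start 1-based inclusive start within \code{region}.
#' @param length number of bases to extract.
#' @return a \linkS4class{DNARegion} whose \code{originOffset} is shifted so
#'   positions remain absolute in the source record.
#' @export
#' @examples
#' r <- dnaRegion(strrep("ACGT", 25))
#' extractRegion(r, start = 11, length = 30)
extractRegion <- function(region, start, length) {
    stopifnot(is(region, "DNARegion"))
    start <- as.integer(start); length <- as.integer(length)
    n <- length(region@sequence)
    if (start < 1L || length < 0L || start + length - 1L > n)
        stop(sprintf(
            "region bounds [%d, %d] outside sequence of length %d",
            start, start + length - 1L, n))
    newDNARegion(region@recordId,
        subseq(region@sequence, start, width = length),
        region@originOffset + start - 1L)
}

sequenceLetters <- function(region)
    strsplit(as.character(region@sequence), "", fixed = TRUE)[[1]]

checkAlphabet <- function(letters, ambiguity) {
    bad <- which(!(letters %in% DNA_BASES4))
    if (length(bad) && ambiguity == "strict")
        stop(sprintf(
            "non-ACGT character '%s' at position %d (ambiguity policy \"strict\")",
            letters[bad[1]], bad[1]))
    bad
}

#' Binary indicator sequences of a DNA region
#'
#' Converts a region into its four binary indicator sequences: the A-channel
#' is 1 wherever the base is A and 0 elsewhere, and likewise for C, G, T, so
#' the four channels sum to one at every position.
#'
#' @param region a \linkS4class{DNARegion}.
#' @param ambiguity policy for non-ACGT letters: \code{"strict"} (default)
#'   raises an error naming the first offending position; \code{"zero"} sets
#'   all four indicators to 0 there (locally breaking the sum-to-one
#'   identity, which assumes a clean 4-letter alphabet).
#' @return an \linkS4class{IndicatorSet}.
#' @export
#' @examples
#' indicatorMatrix(binaryIndicators(dnaRegion("ACCTG")))
binaryIndicators <- function(region, ambiguity = c("strict", "zero")) {
    stopifnot(is(region, "DNARegion"))
    ambiguity <- match.arg(ambiguity)
    letters <- sequenceLetters(region)
    checkAlphabet(letters, ambiguity)
    m <- matrix(0L, nrow = 4L, ncol = length(letters),
                dimnames = list(DNA_BASES4, NULL))
    for (b in DNA_BASES4)
        m[b, letters == b] <- 1L
    new("IndicatorSet", indicators = m, recordId = region@recordId,
        originOffset = region@originOffset)
}

#' EIIP numeric sequence of a DNA region
#'
#' Maps each base onto its electron-ion interaction pseudopotential
#' (\code{\link{EIIP}}), giving a single real-valued signal whose spectrum
#' carries the period-3 component of coding regions.
#'
#' @inheritParams binaryIndicators
#' @return a \linkS4class{NumericSequence} labelled \code{"eiip"}. Under the
#'   \code{"zero"} policy, ambiguous positions map to 0.
#' @export
#' @examples
#' trackValues(eiipSequence(dnaRegion("ATCG")))
eiipSequence <- function(region, ambiguity = c("strict", "zero")) {
    stopifnot(is(region, "DNARegion"))
    ambiguity <- match.arg(ambiguity)
    letters <- sequenceLetters(region)
    bad <- checkAlphabet(letters, ambiguity)
    v <- unname(EIIP[letters])
    v[is.na(v)] <- 0
    new("NumericSequence", values = v, label = "eiip",
        recordId = region@recordId, originOffset = region@originOffset)
}

#' Weighted combination of the four indicator channels
#'
#' Collapses the four binary indicator channels into one numeric sequence
#' a*uA + c*uC + g*uG + t*uT, the signal used by the reduced-computation
#' filtering variant (one filter pass instead of four). The default weights
#' keep only the G channel, whose periodicity is the strongest single-channel
#' signal in this setting; with the \code{\link{EIIP}} weights the result
#' equals \code{\link{eiipSequence}}.
#'
#' @param ind an \linkS4class{IndicatorSet}.
#' @param weights named numeric vector with entries A, C, G, T.
#' @return a \linkS4class{NumericSequence} labelled \code{"combined"}.
#' @export
#' @examples
#' ind <- binaryIndicators(dnaRegion("ACCTG"))
#' trackValues(combinedSequence(ind))                      # pure G channel
#' trackValues(combinedSequence(ind, weights = EIIP))      # EIIP mapping
combinedSequence <- function(ind,
                             weights = c(A = 0, C = 0, G = 1, T = 0)) {
    stopifnot(is(ind, "IndicatorSet"))
    if (!all(DNA_BASES4 %in% names(weights)))
        stop("'weights' must name all of A, C, G, T")
    w <- as.numeric(weights[DNA_BASES4])
    if (!all(is.finite(w)))
        stop("'weights' must be finite")
    v <- as.numeric(drop(w %*% ind@indicators))
    new("NumericSequence", values = v, label = "combined",
        recordId = ind@recordId, originOffset = ind@originOffset)
}

#' Reconstruct the DNA string encoded by an IndicatorSet
#'
#' Inverse of \code{\link{binaryIndicators}} for clean-alphabet input: each
#' position becomes the base whose indicator is 1 ("N" where all four are 0
#' under the "zero" ambiguity policy).
#'
#' @param ind an \linkS4class{IndicatorSet}.
#' @return a \linkS4class{DNARegion}.
#' @export
indicatorsToRegion <- function(ind) {
    stopifnot(is(ind, "IndicatorSet"))
    m <- ind@indicators
    hit <- colSums(m) > 0
    letters <- rep("N", ncol(m))
    letters[hit] <- DNA_BASES4[apply(m[, hit, drop = FALSE], 2, which.max)]
    newDNARegion(ind@recordId, paste(letters, collapse = ""),
                 ind@originOffset)
}

#' Write DNARegion objects to FASTA
#'
#' @param regions a \linkS4class{DNARegion} or list thereof.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFastaRegions <- function(regions, path) {
    if (is(regions, "DNARegion"))
        regions <- list(regions)
    set <- DNAStringSet(lapply(regions, slot, "sequence"))
    names(set) <- vapply(regions, slot, character(1), "recordId")
    writeXStringSet(set, path)
    invisible(path)
}
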
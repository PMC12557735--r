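## Exact combinatorics of degenerate-codon library designs.
##
## Codon sampling is uniform over the expanded codon set, which for IUPAC
## patterns equals independent uniform sampling of each degenerate position
## (equimolar synthesis).  The standard genetic code is used throughout (the
## E. coli host uses table 11, identical to table 1 for these purposes).

#' Kyte-Doolittle hydropathy scale
#'
#' The standard Kyte-Doolittle index for the 20 amino acids (Ile 4.5 ... Arg
#' -4.5).  Positive values are hydrophobic.
#'
#' @return named numeric of length 20.
#' @examples
#' kdHydropathy()[c("I", "M", "R")]
#' @export
kdHydropathy <- function() {
    c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
      L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

iupacBases <- function(symbol) {
    m <- Biostrings::IUPAC_CODE_MAP
    if (!symbol %in% names(m))
        stop("invalid IUPAC symbol: '", symbol, "'")
    strsplit(m[[symbol]], "")[[1]]
}

checkPattern <- function(pattern) {
    if (length(pattern) != 1L || is.na(pattern) || nchar(pattern) != 3L)
        stop("'pattern' must be a single string of 3 IUPAC symbols")
    sym <- strsplit(toupper(pattern), "")[[1]]
    for (s in sym)
        if (!s %in% names(Biostrings::IUPAC_CODE_MAP))
            stop("invalid IUPAC symbol: '", s, "'")
    sym
}

#' Expand a degenerate codon pattern into its concrete codons
#'
#' @param pattern three IUPAC nucleotide symbols, e.g. \code{"NNB"}.
#' @return sorted character vector of concrete codons.
#' @examples
#' length(expandDegenerateCodon("NNB")) # 48: every codon not ending in A
#' length(expandDegenerateCodon("NYN")) # 32
#' @export
expandDegenerateCodon <- function(pattern) {
    sym <- checkPattern(pattern)
    b1 <- iupacBases(sym[1]); b2 <- iupacBases(sym[2]); b3 <- iupacBases(sym[3])
    g <- expand.grid(p3 = b3, p2 = b2, p1 = b1, stringsAsFactors = FALSE)
    sort(paste0(g$p1, g$p2, g$p3))
}

schemeOf <- function(x) {
    if (is(x, "DegenerateScheme")) x else degenerateScheme(x)
}

#' Amino-acid and stop distribution of a degenerate scheme
#'
#' Probability of each amino acid (and the stop symbol \code{"*"}) under
#' uniform sampling of the scheme's expanded codon set, computed in closed form
#' as the product of per-position probabilities summed over codons of the
#' standard genetic code.
#'
#' @param scheme a [DegenerateScheme-class] or an IUPAC pattern string.
#' @return an [AminoAcidDistribution-class].
#' @examples
#' d <- schemeAminoAcidDistribution("NNB")
#' probabilities(d)["*"]   # 1/48: TAG is the only stop not ending in A
#' @export
schemeAminoAcidDistribution <- function(scheme) {
    scheme <- schemeOf(scheme)
    sym <- checkPattern(scheme@pattern)
    pos <- lapply(sym, function(s) {
        b <- iupacBases(s)
        p <- setNames(numeric(4), c("A", "C", "G", "T"))
        p[b] <- 1 / length(b)
        p
    })
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    cp <- pos[[1]][substr(codons, 1, 1)] *
          pos[[2]][substr(codons, 2, 2)] *
          pos[[3]][substr(codons, 3, 3)]
    probs <- setNames(numeric(21), c(AA20, STOP_SYMBOL))
    agg <- rowsum(as.numeric(cp), group = as.character(gc))
    probs[rownames(agg)] <- agg[, 1L]
    new("AminoAcidDistribution", probabilities = probs)
}

#' Amino acids encodable by a scheme
#'
#' @inheritParams schemeAminoAcidDistribution
#' @return sorted character vector of amino acids with nonzero probability
#'   (stop excluded).
#' @examples
#' encodableAminoAcids("NYN") # the nine-letter alphabet A F I L M P S T V
#' @export
encodableAminoAcids <- function(scheme) {
    p <- probabilities(schemeAminoAcidDistribution(scheme))
    p <- p[names(p) != STOP_SYMBOL]
    sort(names(p)[p > 0])
}

#' Probability that an insert of random codons is free of stop codons
#'
#' Under independent codon draws this is (1 - P(stop))^nCodons; for a 50-codon
#' NNB insert it is (47/48)^50, about 0.349, while NYN inserts are always
#' intact.
#'
#' @inheritParams schemeAminoAcidDistribution
#' @param nCodons optional override of the scheme's codon count (>= 0).
#' @return probability in [0, 1].
#' @examples
#' intactOrfProbability(degenerateScheme("NNB", nCodons = 50))
#' @export
intactOrfProbability <- function(scheme, nCodons = NULL) {
    scheme <- schemeOf(scheme)
    n <- if (is.null(nCodons)) scheme@nCodons else as.integer(nCodons)
    if (n < 0L) stop("'nCodons' must be >= 0")
    pstop <- probabilities(schemeAminoAcidDistribution(scheme))[[STOP_SYMBOL]]
    (1 - pstop)^n
}

#' Expected mean hydrophobicity of a scheme's proteins
#'
#' Expectation of the Kyte-Doolittle index over the scheme's amino-acid
#' distribution conditioned on non-stop codons.
#'
#' @inheritParams schemeAminoAcidDistribution
#' @return expected Kyte-Doolittle value.
#' @examples
#' expectedMeanHydrophobicity("NYN") > expectedMeanHydrophobicity("NNB")
#' @export
expectedMeanHydrophobicity <- function(scheme) {
    p <- probabilities(schemeAminoAcidDistribution(scheme))
    pstop <- p[[STOP_SYMBOL]]
    if (pstop >= 1)
        stop("scheme encodes only stop codons; conditional distribution undefined")
    aa <- p[AA20] / (1 - pstop)
    sum(aa * kdHydropathy()[AA20])
}

#' Export an amino-acid distribution as TSV
#'
#' Writes two columns (amino_acid, probability) including the stop symbol.
#'
#' @param dist an [AminoAcidDistribution-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAaDistributionTsv <- function(dist, path) {
    stopifnot(is(dist, "AminoAcidDistribution"))
    p <- probabilities(dist)
    write.table(data.frame(amino_acid = names(p), probability = as.numeric(p)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
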
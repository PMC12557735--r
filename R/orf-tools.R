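## ORF discovery with alternative bacterial start codons and the mutational
## design procedures used to dissect protein- vs RNA-level function:
## start-codon knockout and maximal synonymous recoding.

START_CODONS <- c("ATG", "TTG", "GTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

codonsOf <- function(seq, from, n) {
    substring(seq, from + 3L * (seq_len(n) - 1L), from + 3L * seq_len(n) - 1L)
}

#' Find open reading frames with alternative start codons
#'
#' Scans all three forward frames for ORFs running from an allowed start codon
#' (ATG, or the bacterial alternatives TTG/GTG) to the first in-frame stop.
#' Translation initiates as Met regardless of the start codon, as in bacterial
#' initiation.  Nested ORFs sharing a stop (internal starts) are all reported.
#' Only the forward strand is scanned: library inserts are orientation-fixed
#' by the expression cassette.
#'
#' @param seq an A/C/G/T sequence.
#' @param starts allowed start codons.
#' @param minAa minimum protein length in residues (30 in the screen's pool
#'   analyses).
#' @return data.frame sorted by start with columns start (0-based offset), end
#'   (0-based exclusive offset after the stop codon), frame (0-2), start_codon
#'   and protein (translation without the stop).
#' @examples
#' findOrfs("ATGAAATAA") # one ORF, protein "MK"
#' @export
findOrfs <- function(seq, starts = START_CODONS, minAa = 0L) {
    if (grepl("[^ACGT]", seq)) stop("'seq' must be an A/C/G/T string")
    L <- nchar(seq)
    gc <- Biostrings::GENETIC_CODE
    res <- list()
    for (f in 0:2) {
        n <- (L - f) %/% 3L
        if (n < 2L) next
        cods <- codonsOf(seq, f + 1L, n)
        stopIdx <- which(cods %in% STOP_CODONS)
        startIdx <- which(cods %in% starts)
        for (s in startIdx) {
            st <- stopIdx[stopIdx > s]
            if (!length(st)) next
            st <- st[1L]
            protLen <- st - s
            if (protLen < minAa) next
            mid <- if (st - s >= 2L) gc[cods[(s + 1L):(st - 1L)]] else character()
            prot <- paste(c("M", mid), collapse = "")
            res[[length(res) + 1L]] <- data.frame(
                start = f + 3L * (s - 1L),
                end = f + 3L * st,
                frame = f,
                start_codon = cods[s],
                protein = prot,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(res))
        return(data.frame(start = integer(), end = integer(),
                          frame = integer(), start_codon = character(),
                          protein = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
}

orfStart <- function(orf) {
    if (is.data.frame(orf)) {
        stopifnot(nrow(orf) == 1L)
        as.integer(orf$start)
    } else as.integer(orf)
}

orfEnd <- function(orf, seq) {
    if (is.data.frame(orf)) as.integer(orf$end)
    else {
        found <- findOrfs(seq, minAa = 0L)
        hit <- found$end[found$start == as.integer(orf)]
        if (!length(hit)) stop("no ORF found at the given start offset")
        hit[1L]
    }
}

transitionPartner <- c(A = "G", G = "A", C = "T", T = "C")

#' Knock out a start codon with a minimal, deterministic mutation
#'
#' Replaces the start codon of an ORF by a codon that (a) is not in the
#' allowed start set, (b) differs by the fewest possible nucleotides, and (c)
#' is not a stop codon.  Ties are broken deterministically: changes that are
#' transitions are preferred over transversions, then the lexicographically
#' smallest codon wins.  Under this rule ATG becomes ACG, the classic
#' start-codon knockout.
#'
#' @param seq an A/C/G/T sequence.
#' @param orf an ORF row from [findOrfs()], or a 0-based start offset.
#' @param starts allowed start codons that the mutant must avoid.
#' @return the mutated sequence (unchanged outside the start codon).
#' @export
designStartMutation <- function(seq, orf, starts = START_CODONS) {
    s0 <- orfStart(orf)
    codon <- substr(seq, s0 + 1L, s0 + 3L)
    if (!codon %in% starts)
        stop("no allowed start codon at offset ", s0, " (found '", codon, "')")
    all64 <- names(Biostrings::GENETIC_CODE)
    cand <- setdiff(all64, c(starts, STOP_CODONS))
    orig <- strsplit(codon, "")[[1]]
    candMat <- do.call(rbind, strsplit(cand, ""))
    diffs <- candMat != matrix(orig, nrow = length(cand), ncol = 3L,
                               byrow = TRUE)
    nDiff <- rowSums(diffs)
    ## transversion count among changed positions (lower is better)
    nTv <- vapply(seq_along(cand), function(i) {
        ch <- which(diffs[i, ])
        sum(candMat[i, ch] != transitionPartner[orig[ch]])
    }, numeric(1))
    cand <- cand[nDiff > 0]
    o <- order(nDiff[nDiff > 0], nTv[nDiff > 0], cand)
    if (!length(cand)) stop("no qualifying replacement codon exists")
    pick <- cand[o[1L]]
    paste0(substr(seq, 1L, s0), pick, substr(seq, s0 + 4L, nchar(seq)))
}

## For each codon, the synonymous codon maximising nucleotide differences
## (ties: lexicographically smallest).  Stops handled as their own family.
maxDiffSynonym <- local({
    tab <- NULL
    function() {
        if (!is.null(tab)) return(tab)
        gc <- Biostrings::GENETIC_CODE
        all64 <- names(gc)
        out <- setNames(character(64), all64)
        for (cod in all64) {
            syn <- all64[gc == gc[[cod]]]
            d <- vapply(syn, function(s)
                sum(strsplit(s, "")[[1]] != strsplit(cod, "")[[1]]),
                numeric(1))
            best <- syn[d == max(d)]
            out[cod] <- sort(best)[1L]
        }
        tab <<- out
        out
    }
})

#' Maximal synonymous recoding of an ORF
#'
#' Replaces every codon of an ORF (except the start codon, which is kept so
#' initiation is preserved) by the synonymous codon maximising nucleotide
#' differences from the original, ties going to the lexicographically smallest
#' codon.  Met and Trp codons are necessarily unchanged.  The stop codon is
#' recoded to another stop only when \code{recodeStop = TRUE}.  The translated
#' protein is identical before and after; the design maximally disrupts
#' putative RNA-level features while preserving the protein.
#'
#' @param seq an A/C/G/T sequence.
#' @param orf an ORF row from [findOrfs()] or a 0-based start offset; the ORF
#'   length (including stop) must be a multiple of 3.
#' @param recodeStop also recode the stop codon to a different stop.
#' @return list with \code{sequence} (the recoded full sequence) and
#'   \code{substitutions} (total nucleotide substitutions introduced).
#' @examples
#' synonymousRecode("ATGAAATAA", findOrfs("ATGAAATAA")) # AAA -> AAG, 1 sub
#' @export
synonymousRecode <- function(seq, orf, recodeStop = FALSE) {
    s0 <- orfStart(orf)
    e0 <- orfEnd(orf, seq)
    if ((e0 - s0) %% 3L != 0L || e0 - s0 < 6L)
        stop("ORF is frame-broken: end - start must be a multiple of 3 (>= 6)")
    n <- (e0 - s0) %/% 3L
    cods <- codonsOf(seq, s0 + 1L, n)
    tab <- maxDiffSynonym()
    new <- cods
    if (n > 2L) new[2:(n - 1L)] <- tab[cods[2:(n - 1L)]]
    if (recodeStop && cods[n] %in% STOP_CODONS) new[n] <- tab[cods[n]]
    gc <- Biostrings::GENETIC_CODE
    stopifnot(identical(unname(gc[new[-1L]]),
                        unname(gc[cods[-1L]]))) # synonymy, by construction
    subs <- sum(vapply(seq_len(n), function(i)
        sum(strsplit(new[i], "")[[1]] != strsplit(cods[i], "")[[1]]),
        numeric(1)))
    list(sequence = paste0(substr(seq, 1L, s0),
                           paste(new, collapse = ""),
                           substr(seq, e0 + 1L, nchar(seq))),
         substitutions = subs)
}

#' Remove the trailing fraction of a sequence
#'
#' Deletes the trailing \code{floor(fraction * length)} nucleotides, the
#' 3'-truncation design used to test whether a gene's 3' region is required
#' for function.
#'
#' @param seq a sequence.
#' @param fraction fraction to remove, in (0, 1).
#' @return the truncated sequence.
#' @examples
#' nchar(truncate3Prime(strrep("A", 150), 1/3)) # 100
#' @export
truncate3Prime <- function(seq, fraction) {
    if (fraction <= 0 || fraction >= 1)
        stop("'fraction' must be in (0, 1)")
    L <- nchar(seq)
    keep <- L - floor(fraction * L)
    if (keep <= 0L) stop("truncation would remove the whole sequence")
    substr(seq, 1L, keep)
}
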
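# Independent oracles used across the suite.  These deliberately take
# different code paths from the package: brute-force enumeration instead of
# closed forms, Biostrings::pairwiseAlignment instead of the package's own
# Needleman-Wunsch, plain R loops instead of the C++ greedy clusterer.

ALL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# enumerate every concrete codon of a pattern and tally translations
bruteForceAaDistribution <- function(pattern) {
    map <- Biostrings::IUPAC_CODE_MAP
    sym <- strsplit(toupper(pattern), "")[[1]]
    bases <- lapply(sym, function(s) strsplit(map[[s]], "")[[1]])
    codons <- apply(expand.grid(bases[[1]], bases[[2]], bases[[3]],
                                stringsAsFactors = FALSE), 1, paste0,
                    collapse = "")
    aa <- as.character(Biostrings::GENETIC_CODE[codons])
    tab <- table(factor(aa, levels = c(ALL_AA, "*")))
    setNames(as.numeric(tab) / length(codons), names(tab))
}

# identity = matches / alignment columns from an explicit global alignment
# (match +1, mismatch -1, linear gap -2), independent of the package's NW
oracleIdentity <- function(a, b) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                   baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 2,
                                         type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    sum(p == s & p != "-") / length(p)
}

# plain-R greedy centroid clustering using the oracle identity
oracleGreedyCluster <- function(seqs, counts, threshold) {
    o <- order(-counts, seqs)
    seqs <- seqs[o]
    assignment <- integer(length(seqs))
    centroids <- integer()
    for (i in seq_along(seqs)) {
        joined <- 0L
        for (ci in seq_along(centroids)) {
            if (oracleIdentity(seqs[i], seqs[centroids[ci]]) >=
                threshold - 1e-12) {
                joined <- ci
                break
            }
        }
        if (joined == 0L) {
            centroids <- c(centroids, i)
            joined <- length(centroids)
        }
        assignment[i] <- joined
    }
    list(sequences = seqs, assignment = assignment,
         centroids = seqs[centroids])
}

# random A/C/G/T string
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# substitute k random positions of a sequence (guaranteed different bases)
mutateSeq <- function(seq, k) {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
}

# brute-force ORF scan: every (frame, position) pair checked directly
oracleFindOrfs <- function(seq, starts = c("ATG", "TTG", "GTG"), minAa = 0) {
    gc <- Biostrings::GENETIC_CODE
    L <- nchar(seq)
    out <- NULL
    for (s0 in 0:(L - 3)) {
        cod <- substr(seq, s0 + 1, s0 + 3)
        if (!cod %in% starts) next
        e <- NA
        p <- s0 + 3
        while (p + 3 <= L) {
            c2 <- substr(seq, p + 1, p + 3)
            if (c2 %in% c("TAA", "TAG", "TGA")) { e <- p + 3; break }
            p <- p + 3
        }
        if (is.na(e)) next
        protLen <- (e - s0) / 3 - 1
        if (protLen < minAa) next
        aa <- vapply(seq_len(protLen) - 1L, function(i)
            unname(gc[substr(seq, s0 + 3 * i + 1, s0 + 3 * i + 3)]),
            character(1))
        aa[1] <- "M"
        out <- rbind(out, data.frame(start = s0, end = e,
                                     protein = paste(aa, collapse = ""),
                                     stringsAsFactors = FALSE))
    }
    if (is.null(out))
        return(data.frame(start = integer(), end = integer(),
                          protein = character()))
    out[order(out$start, out$end), , drop = FALSE]
}

flank5 <- denovoscreen::defaultFlanks()[["flank5"]]
flank3 <- denovoscreen::defaultFlanks()[["flank3"]]

# paired reads covering an amplicon from both ends
readsFor <- function(amp, readLen) {
    list(r1 = substr(amp, 1, readLen),
         r2 = as.character(Biostrings::reverseComplement(
             Biostrings::DNAString(substr(amp, nchar(amp) - readLen + 1,
                                          nchar(amp))))))
}
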
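## Synthetic-data generator: library synthesis, multi-round selection with
## planted functional variants, and paired-end amplicon sequencing.  Defaults
## emulate the screen's study conditions: 50 random codons behind an ATG and in
## front of a TAA, ~5% of variants carrying a small (1-2 nt) synthesis indel,
## log-normal pre-selection abundance skew, two selection rounds, and read
## depths at which the 5e-5 hit threshold corresponds to ~150 reads.

#' Default constant flanks around the random insert
#'
#' Short constant sequences emulating the expression cassette around the
#' insert: a ribosome-binding-site-like region upstream of the ATG and a
#' terminator-like region downstream of the stop.  Amplicon reads are anchored
#' on these flanks during insert extraction.
#'
#' @return named character vector with elements \code{flank5} and
#'   \code{flank3}.
#' @export
defaultFlanks <- function() {
    c(flank5 = "TTAAGAAGGAGATATACAT",
      flank3 = "GCTTGGACTCCTGTTGATAG")
}

checkDnaString <- function(x, what) {
    if (length(x) != 1L || is.na(x) || nchar(x) == 0L ||
        grepl("[^ACGT]", x))
        stop("'", what, "' must be a nonempty A/C/G/T string")
    x
}

## vectorised codon-wise translation via the standard genetic code
translateDna <- function(seqs) {
    gc <- Biostrings::GENETIC_CODE
    vapply(seqs, function(s) {
        n <- nchar(s) %/% 3L
        if (n == 0L) return("")
        cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
        paste(gc[cods], collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic (semi-)random sequence library
#'
#' Each variant is \code{ATG} + \code{nCodons(scheme)} uniform draws from the
#' scheme's expanded codon set + \code{TAA}.  A Bernoulli
#' \code{indelRate} fraction of variants carries one insertion or deletion of
#' 1-2 nt at a random position inside the random region, emulating synthesis
#' errors.  Pre-selection abundances are log-normal with sigma
#' \code{abundanceSkew}, normalised to sum to 1.
#'
#' @param scheme a [DegenerateScheme-class] or IUPAC pattern string.
#' @param nVariants number of unique variants.
#' @param abundanceSkew log-normal sigma of pre-selection abundances (>= 0).
#' @param indelRate per-variant probability of a small synthesis indel.
#' @param flank5,flank3 constant flanks around the insert (used by
#'   [sequenceReads()]).
#' @param seed optional RNG seed; identical seeds give identical libraries.
#' @return data.frame with columns variant_id, sequence (insert from start
#'   codon through stop), abundance, is_functional placeholder \code{FALSE},
#'   has_indel; attributes \code{flank5}, \code{flank3}, \code{scheme}.
#' @examples
#' lib <- generateLibrary("NNB", nVariants = 100, indelRate = 0, seed = 1)
#' unique(nchar(lib$sequence)) # 156 = 3 + 150 + 3
#' @export
generateLibrary <- function(scheme, nVariants, abundanceSkew = 1,
                            indelRate = 0.05,
                            flank5 = defaultFlanks()[["flank5"]],
                            flank3 = defaultFlanks()[["flank3"]],
                            seed = NULL) {
    scheme <- schemeOf(scheme)
    stopifnot(nVariants >= 1, indelRate >= 0, indelRate <= 1,
              abundanceSkew >= 0)
    checkDnaString(flank5, "flank5")
    checkDnaString(flank3, "flank3")
    if (!is.null(seed)) set.seed(seed)
    codons <- expandDegenerateCodon(scheme@pattern)
    nc <- scheme@nCodons
    n <- as.integer(nVariants)

    drawInserts <- function(k) {
        idx <- matrix(sample.int(length(codons), k * nc, replace = TRUE),
                      nrow = k)
        cods <- matrix(codons[idx], nrow = k)
        paste0("ATG", do.call(paste0, as.data.frame(cods,
                                                    stringsAsFactors = FALSE)),
               "TAA")
    }
    seqs <- drawInserts(n)
    for (tries in 1:5) { # resolve rare collisions so variants are unique
        dup <- duplicated(seqs)
        if (!any(dup)) break
        seqs[dup] <- drawInserts(sum(dup))
    }

    has_indel <- runif(n) < indelRate
    if (any(has_indel)) {
        for (i in which(has_indel)) {
            size <- sample(1:2, 1L)
            s <- seqs[i]
            L <- nchar(s)
            if (runif(1) < 0.5) { # deletion within the random region
                p <- sample(4:(L - 3L - size), 1L)
                seqs[i] <- paste0(substr(s, 1L, p - 1L),
                                  substr(s, p + size, L))
            } else {             # insertion within the random region
                p <- sample(4:(L - 3L), 1L)
                ins <- paste(sample(c("A", "C", "G", "T"), size,
                                    replace = TRUE), collapse = "")
                seqs[i] <- paste0(substr(s, 1L, p - 1L), ins,
                                  substr(s, p, L))
            }
        }
    }
    ab <- rlnorm(n, meanlog = 0, sdlog = abundanceSkew)
    lib <- data.frame(variant_id = sprintf("v%06d", seq_len(n)),
                      sequence = seqs,
                      abundance = ab / sum(ab),
                      is_functional = FALSE,
                      has_indel = has_indel,
                      stringsAsFactors = FALSE)
    attr(lib, "flank5") <- flank5
    attr(lib, "flank3") <- flank3
    attr(lib, "scheme") <- scheme@name
    lib
}

#' Simulate a multi-round survival selection with planted functional variants
#'
#' A \code{fractionFunctional} subset of variants is planted as functional.
#' Each round samples \code{bottleneck} clones multinomially from the current
#' abundances; every clone then survives independently with probability
#' \code{pSurviveFunctional} (functional variants) or \code{pEscape}
#' (background escape, e.g. chromosomal resistance mutants).  Survivors reseed
#' the next round.  Survival is clone-level Bernoulli, matching a
#' structured-medium screen in which a microcolony either withstands phage
#' challenge or is lysed.
#'
#' @param library a library data.frame from [generateLibrary()].
#' @param pSurviveFunctional per-clone survival probability of functional
#'   variants.
#' @param pEscape background per-clone survival probability; must be smaller
#'   than \code{pSurviveFunctional}.
#' @param fractionFunctional fraction of variants planted as functional.
#' @param rounds number of selection rounds (two in the screen design).
#' @param bottleneck clones sampled per round.
#' @param seed optional RNG seed.
#' @return a [SelectionExperiment-class]; its pre table holds the round-1 clone
#'   sample and its post table the surviving clones after the final round.  If
#'   a round leaves zero survivors the post table is empty and the experiment
#'   is flagged.
#' @export
simulateSelection <- function(library, pSurviveFunctional = 0.5,
                              pEscape = 1e-4, fractionFunctional = 0.01,
                              rounds = 2L, bottleneck = 1e6, seed = NULL) {
    stopifnot(pSurviveFunctional >= 0, pSurviveFunctional <= 1,
              pEscape >= 0, pEscape <= 1, rounds >= 1, bottleneck >= 1,
              fractionFunctional >= 0, fractionFunctional <= 1)
    if (pSurviveFunctional < pEscape)
        stop("'pSurviveFunctional' must be at least 'pEscape'; equality is the ",
             "neutral (no-enrichment) calibration configuration")
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(library)
    nFunc <- round(fractionFunctional * n)
    funcIdx <- if (nFunc > 0) sample.int(n, nFunc) else integer()
    pSurv <- rep(pEscape, n)
    pSurv[funcIdx] <- pSurviveFunctional

    ab <- library$abundance
    preCounts <- as.numeric(rmultinom(1L, size = bottleneck, prob = ab))
    pre <- variantTable(library$sequence, preCounts, label = "pre")

    cur <- preCounts
    flagged <- FALSE
    for (r in seq_len(rounds)) {
        if (r > 1L)
            cur <- as.numeric(rmultinom(1L, size = bottleneck,
                                        prob = cur / sum(cur)))
        cur <- rbinom(n, size = cur, prob = pSurv)
        if (sum(cur) == 0) {
            warning("round ", r, " left zero survivors; post population is empty")
            flagged <- TRUE
            break
        }
    }
    post <- if (flagged)
        new("VariantTable", sequences = character(), counts = numeric(),
            totalReads = 0, label = "post")
    else variantTable(library$sequence, cur, label = "post")
    new("SelectionExperiment", pre = pre, post = post,
        truth = library$sequence[sort(funcIdx)],
        pool = library$sequence, flagged = flagged)
}

#' Simulate paired-end amplicon sequencing of a population
#'
#' Reads are drawn multinomially from the population's abundances.  Each pair
#' covers the amplicon (flank5 + insert + flank3) from opposite ends with
#' independent per-base substitution errors; pairs must overlap by at least 10
#' nt so they can be merged.  Error-free pairs of the same variant are returned
#' as one weighted row, so downstream processing scales with the number of
#' distinct reads rather than the depth; [writePairedFastq()] expands weights
#' when writing FASTQ.
#'
#' @param population a [VariantTable-class] of insert sequences (counts act as
#'   abundance weights), or a data.frame with columns sequence and abundance.
#' @param depth total number of read pairs.
#' @param readLen read length of each mate.
#' @param substitutionRate per-base substitution error probability.
#' @param flank5,flank3 constant flanks of the amplicon.
#' @param seed optional RNG seed.
#' @return list with elements \code{pairs} (data.frame read1, read2, count),
#'   \code{trueCounts} (data.frame sequence, count -- the error-free ground
#'   truth), and \code{summary}.
#' @export
sequenceReads <- function(population, depth, readLen = 150L,
                          substitutionRate = 0.001,
                          flank5 = defaultFlanks()[["flank5"]],
                          flank3 = defaultFlanks()[["flank3"]],
                          seed = NULL) {
    stopifnot(depth >= 1, readLen >= 20, substitutionRate >= 0,
              substitutionRate < 1)
    if (is(population, "VariantTable")) {
        seqs <- sequences(population)
        ab <- counts(population)
    } else {
        seqs <- population$sequence
        ab <- population$abundance
    }
    stopifnot(length(seqs) >= 1)
    if (!is.null(seed)) set.seed(seed)
    ab <- ab / sum(ab)
    amp <- paste0(flank5, seqs, flank3)
    ampLen <- nchar(amp)
    l1 <- pmin(readLen, ampLen)
    l2 <- pmin(readLen, ampLen)
    if (any(l1 + l2 - ampLen < 10))
        stop("'readLen' too short: mates would overlap by < 10 nt and ",
             "merging would be impossible")
    read1 <- substr(amp, 1L, l1)
    ampRc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(amp)))
    read2 <- substr(ampRc, 1L, l2)

    trueCounts <- as.numeric(rmultinom(1L, size = depth, prob = ab))

    pairLen <- l1 + l2
    pErr <- 1 - (1 - substitutionRate)^pairLen
    errCounts <- rbinom(length(seqs), size = trueCounts, prob = pErr)
    cleanCounts <- trueCounts - errCounts

    keep <- cleanCounts > 0
    pairs <- data.frame(read1 = read1[keep], read2 = read2[keep],
                        count = cleanCounts[keep], stringsAsFactors = FALSE)

    E <- sum(errCounts)
    if (E > 0) {
        vidx <- rep.int(seq_along(seqs), errCounts)
        er1 <- read1[vidx]
        er2 <- read2[vidx]
        Lp <- pairLen[vidx]
        ## number of errors per erroneous pair, conditioned on >= 1
        kmax <- 12L
        Lgroups <- unique(Lp)
        k <- integer(E)
        for (L in Lgroups) {
            sel <- which(Lp == L)
            pk <- stats::dbinom(1:kmax, size = L, prob = substitutionRate)
            k[sel] <- sample.int(kmax, length(sel), replace = TRUE,
                                 prob = pk / sum(pk))
        }
        pairIdx <- rep.int(seq_len(E), k)
        posAll <- floor(runif(length(pairIdx)) * Lp[pairIdx]) + 1L
        inR1 <- posAll <= l1[vidx][pairIdx]
        n1 <- sum(inR1)
        if (n1 > 0)
            er1 <- substitute_bases_cpp(er1, pairIdx[inR1],
                                        as.integer(posAll[inR1]))
        if (length(pairIdx) - n1 > 0)
            er2 <- substitute_bases_cpp(
                er2, pairIdx[!inR1],
                as.integer(posAll[!inR1] - l1[vidx][pairIdx[!inR1]]))
        pairs <- rbind(pairs,
                       data.frame(read1 = er1, read2 = er2,
                                  count = rep(1, E),
                                  stringsAsFactors = FALSE))
    }
    list(pairs = pairs,
         trueCounts = data.frame(sequence = seqs, count = trueCounts,
                                 stringsAsFactors = FALSE),
         summary = list(depth = depth, read_len = readLen,
                        substitution_rate = substitutionRate,
                        erroneous_pairs = E,
                        variants = length(seqs)))
}

#' Sample random proteins from a scheme's composition model
#'
#' Residues are drawn i.i.d. from the scheme's amino-acid distribution
#' conditioned on non-stop codons.  This is the composition-level model of a
#' stop-free random ORF; it is used for neutral (no planted effect) controls.
#'
#' @inheritParams schemeAminoAcidDistribution
#' @param n number of proteins.
#' @param nResidues protein length (51 for the screen's full-length inserts).
#' @param seed optional RNG seed.
#' @return character vector of residue strings.
#' @export
randomProteins <- function(scheme, n, nResidues = 51L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    p <- probabilities(schemeAminoAcidDistribution(scheme))
    pstop <- p[[STOP_SYMBOL]]
    if (pstop >= 1) stop("scheme encodes only stop codons")
    aaP <- p[AA20] / (1 - pstop)
    idx <- matrix(sample.int(20L, n * nResidues, replace = TRUE, prob = aaP),
                  nrow = n)
    res <- matrix(AA20[idx], nrow = n)
    do.call(paste0, as.data.frame(res, stringsAsFactors = FALSE))
}

#' Sensitivity and false-discovery proportion of a called hit set
#'
#' Compares called hit sequences against the planted functional set of a
#' synthetic experiment (exact sequence matching).
#'
#' @param truth planted functional insert sequences (or a
#'   [SelectionExperiment-class]).
#' @param hits called hit sequences (e.g. centroids of hit clusters).
#' @return list with sensitivity, fdp, n_hits, n_truth.
#' @export
evaluateRecovery <- function(truth, hits) {
    if (is(truth, "SelectionExperiment")) truth <- truthSet(truth)
    tp <- sum(hits %in% truth)
    list(sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
         fdp = if (length(hits)) (length(hits) - tp) / length(hits) else 0,
         n_hits = length(hits), n_truth = length(truth))
}
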
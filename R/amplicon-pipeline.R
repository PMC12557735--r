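## Read processing and functional-hit calling: pair merging, flank-anchored
## insert extraction, greedy identity clustering, and frequency-threshold hit
## calling.  Coordinates are 0-based half-open throughout; amplicons are
## orientation-fixed by their flanks, so only the forward strand is considered.

#' Merge paired-end reads by overlap consensus
#'
#' Reverse-complements read 2, scans all overlaps of at least
#' \code{minOverlap} nt and accepts the longest one whose mismatch fraction is
#' at most \code{maxMismatchFraction}.  At overlap mismatches the base with
#' the higher quality wins; with equal (or absent) qualities read 1 wins,
#' keeping merging deterministic.
#'
#' @param read1,read2 character vectors of mate sequences (read 2 as
#'   sequenced, i.e. reverse strand).
#' @param qual1,qual2 optional phred+33 quality strings, parallel to the reads.
#' @param minOverlap minimum acceptable overlap (>= 10 nt).
#' @param maxMismatchFraction maximum mismatch fraction within the overlap.
#' @return character vector of merged sequences, \code{NA} where no acceptable
#'   overlap exists.
#' @examples
#' amp <- "ACGTACGTACGTACGTAAACCCGGGTTTACGT"
#' r1 <- substr(amp, 1, 24)
#' r2 <- as.character(Biostrings::reverseComplement(
#'     Biostrings::DNAString(substr(amp, 9, 32))))
#' mergePairs(r1, r2, minOverlap = 10) == amp
#' @export
mergePairs <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                       minOverlap = 10L, maxMismatchFraction = 0.1) {
    if (minOverlap < 10L) stop("'minOverlap' must be >= 10")
    stopifnot(length(read1) == length(read2))
    if (any(!nzchar(read1)) || any(!nzchar(read2)))
        stop("reads must be nonempty")
    q1 <- if (is.null(qual1)) character() else qual1
    q2 <- if (is.null(qual2)) character() else qual2
    merge_pairs_cpp(read1, read2, q1, q2, as.integer(minOverlap),
                    maxMismatchFraction)
}

#' Extract the insert between two constant flanks
#'
#' Locates each flank by its best-scoring ungapped match (fewest mismatches,
#' ties leftmost) with at most \code{maxFlankMismatches} mismatches, and
#' returns the enclosed substring (start codon through stop codon).  Reads in
#' which either flank is not found, or whose insert is empty, yield \code{NA}.
#'
#' @param reads merged read sequences.
#' @param flank5,flank3 constant flanks.
#' @param maxFlankMismatches per-flank mismatch tolerance.
#' @return character vector of inserts (\code{NA} = dropped).
#' @export
extractInsert <- function(reads, flank5, flank3, maxFlankMismatches = 2L) {
    checkDnaString(flank5, "flank5")
    checkDnaString(flank3, "flank3")
    out <- extract_inserts_cpp(reads, flank5, flank3,
                               as.integer(maxFlankMismatches))
    out[!is.na(out) & !nzchar(out)] <- NA_character_
    out
}

#' Process weighted read pairs into a VariantTable
#'
#' Convenience wrapper running merge -> extract -> aggregate on the weighted
#' pair representation produced by [sequenceReads()] (or built from FASTQ via
#' [readPairedFastq()]).  Identical pairs are collapsed before merging so the
#' cost scales with distinct reads, not depth.
#'
#' @param pairs data.frame with columns read1, read2 and optionally count
#'   (default 1 per row).
#' @param flank5,flank3 constant flanks.
#' @inheritParams mergePairs
#' @inheritParams extractInsert
#' @param label population label for the resulting table.
#' @return list with \code{table} (a [VariantTable-class]) and \code{summary}
#'   (reads in, merged, merge failures, flank failures, unique inserts).
#' @export
processAmplicons <- function(pairs, flank5, flank3, minOverlap = 10L,
                             maxMismatchFraction = 0.1,
                             maxFlankMismatches = 2L, label = "") {
    cnt <- if (is.null(pairs$count)) rep(1, nrow(pairs)) else pairs$count
    key <- paste(pairs$read1, pairs$read2, sep = "\r")
    if (anyDuplicated(key)) {
        agg <- rowsum(cnt, group = key)
        key <- rownames(agg)
        cnt <- as.numeric(agg[, 1L])
        sp <- strsplit(key, "\r", fixed = TRUE)
        r1 <- vapply(sp, `[`, character(1), 1L)
        r2 <- vapply(sp, `[`, character(1), 2L)
    } else {
        r1 <- pairs$read1
        r2 <- pairs$read2
    }
    merged <- mergePairs(r1, r2, minOverlap = minOverlap,
                         maxMismatchFraction = maxMismatchFraction)
    mergeFail <- sum(cnt[is.na(merged)])
    ok <- !is.na(merged)
    inserts <- extractInsert(merged[ok], flank5, flank3, maxFlankMismatches)
    flankFail <- sum(cnt[ok][is.na(inserts)])
    keep <- !is.na(inserts)
    tab <- variantTable(inserts[keep], cnt[ok][keep], label = label)
    list(table = tab,
         summary = list(reads_in = sum(cnt),
                        unique_pairs = length(r1),
                        merged = sum(cnt) - mergeFail,
                        merge_failures = mergeFail,
                        flank_failures = flankFail,
                        unique_inserts = length(sequences(tab)),
                        reads_kept = totalReads(tab)))
}

#' Global-alignment identity between two sequences
#'
#' End-to-end Needleman-Wunsch alignment with linear gap penalty (defaults:
#' match +1, mismatch -1, gap -2); identity = matches / alignment columns.
#' This is the identity definition used by [clusterSequences()]; it differs
#' from tool-specific dialects in end-gap handling, so the threshold is
#' configurable.
#'
#' @param a,b sequences.
#' @param match,mismatch,gap alignment scores.
#' @return named numeric with identity, matches, columns, score.
#' @export
alignmentIdentity <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
    nw_identity_cpp(a, b, as.integer(match), as.integer(mismatch),
                    as.integer(gap))
}

#' Greedy centroid clustering at an identity threshold
#'
#' Reimplementation of greedy centroid (UCLUST/VSEARCH-style) clustering:
#' sequences are processed in decreasing count order (ties lexicographic);
#' each joins the earliest-founded centroid whose global-alignment identity is
#' at or above the threshold, else founds a new cluster.  An exact k-mer count
#' bound prunes centroids that provably cannot reach the threshold, so the
#' result is identical to the unfiltered greedy scan.
#'
#' @param table a [VariantTable-class].
#' @param identityThreshold clustering threshold in (0, 1] (0.95 in the screen
#'   analyses).
#' @param match,mismatch,gap alignment scores (see [alignmentIdentity()]).
#' @return a [ClusterSet-class].
#' @export
clusterSequences <- function(table, identityThreshold = 0.95, match = 1L,
                             mismatch = -1L, gap = -2L) {
    stopifnot(is(table, "VariantTable"))
    if (length(table) == 0L) stop("cannot cluster an empty table")
    if (identityThreshold <= 0 || identityThreshold > 1)
        stop("'identityThreshold' must be in (0, 1]")
    o <- order(-counts(table), sequences(table))
    seqs <- sequences(table)[o]
    cnts <- counts(table)[o]
    asg <- greedy_cluster_cpp(seqs, identityThreshold, as.integer(match),
                              as.integer(mismatch), as.integer(gap))
    nClus <- max(asg)
    centroidIdx <- match(seq_len(nClus), asg)
    tot <- as.numeric(rowsum(cnts, group = asg)[as.character(seq_len(nClus)),
                                                1L])
    new("ClusterSet", sequences = seqs, counts = cnts,
        cluster = as.integer(asg), centroidSeqs = seqs[centroidIdx],
        clusterCounts = tot, threshold = identityThreshold,
        totalReads = totalReads(table), label = poolLabel(table))
}

#' Call functional sequences by post-selection frequency
#'
#' A cluster is a hit iff its summed count / total reads is at least
#' \code{frequencyThreshold}.  The comparison is inclusive so that at a depth
#' where threshold x total is integral the implied "at least N reads" rule is
#' reproduced exactly (e.g. 146 reads at 5e-5 of 2.92 million).  Calling
#' operates on clusters by default, which makes it robust to sequencing
#' errors; \code{level = "raw"} applies the threshold to unclustered unique
#' sequences instead.
#'
#' @param x a [ClusterSet-class] (or, with \code{level = "raw"}, a
#'   [VariantTable-class]).
#' @param frequencyThreshold hit threshold in (0, 1]; 5e-5 in the screen.
#' @param level \code{"cluster"} (default) or \code{"raw"}.
#' @return data.frame with columns sequence, count, frequency, is_hit, plus
#'   attributes \code{min_reads} (implied minimum count,
#'   \code{ceiling(threshold * total)}) and \code{total_reads}.
#' @export
callFunctional <- function(x, frequencyThreshold = 5e-5,
                           level = c("cluster", "raw")) {
    level <- match.arg(level)
    if (frequencyThreshold <= 0 || frequencyThreshold > 1)
        stop("'frequencyThreshold' must be in (0, 1]")
    if (level == "raw" || is(x, "VariantTable")) {
        seqs <- sequences(x); cnts <- counts(x); total <- totalReads(x)
    } else {
        stopifnot(is(x, "ClusterSet"))
        seqs <- centroids(x); cnts <- clusterCounts(x); total <- totalReads(x)
    }
    if (length(seqs) == 0L || total < 1) {
        warning("empty table: no hits can be called")
        out <- data.frame(sequence = character(), count = numeric(),
                          frequency = numeric(), is_hit = logical())
        attr(out, "min_reads") <- NA_real_
        attr(out, "total_reads") <- total
        return(out)
    }
    freq <- cnts / total
    out <- data.frame(sequence = seqs, count = cnts, frequency = freq,
                      is_hit = freq >= frequencyThreshold,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "min_reads") <- ceiling(frequencyThreshold * total)
    attr(out, "total_reads") <- total
    out
}

#' Pre/post enrichment of clusters
#'
#' Matches clusters across two [ClusterSet-class] objects (clustered at the
#' same threshold) by centroid identity at or above that threshold (best
#' identity, ties to the earliest pre cluster) and reports pre/post
#' frequencies and fold changes.  Post clusters absent from the pre population
#' receive the frequency floor 1 / (pre total + 1) so fold changes stay
#' finite, and are flagged as de novo appearances.
#'
#' @param pre,post [ClusterSet-class] objects for the two populations.
#' @return data.frame with columns centroid, pre_frequency, post_frequency,
#'   fold_change, de_novo.
#' @export
enrichmentTable <- function(pre, post) {
    stopifnot(is(pre, "ClusterSet"), is(post, "ClusterSet"))
    if (!isTRUE(all.equal(pre@threshold, post@threshold)))
        stop("both populations must be clustered at the same identity threshold")
    thr <- post@threshold
    preC <- centroids(pre)
    preF <- clusterCounts(pre) / totalReads(pre)
    floorF <- 1 / (totalReads(pre) + 1)
    postC <- centroids(post)
    postF <- clusterCounts(post) / totalReads(post)
    matchPre <- function(s) {
        exact <- match(s, preC)
        if (!is.na(exact)) return(exact)
        best <- NA_integer_; bestId <- -1
        for (j in seq_along(preC)) {
            id <- nw_identity_cpp(s, preC[j], 1L, -1L, -2L)[["identity"]]
            if (id >= thr - 1e-12 && id > bestId + 1e-12) {
                bestId <- id; best <- j
            }
        }
        best
    }
    idx <- vapply(postC, matchPre, integer(1))
    deNovo <- is.na(idx)
    pf <- ifelse(deNovo, floorF, preF[ifelse(deNovo, 1L, idx)])
    data.frame(centroid = postC,
               pre_frequency = pf,
               post_frequency = postF,
               fold_change = postF / pf,
               de_novo = deNovo,
               stringsAsFactors = FALSE, row.names = NULL)
}
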
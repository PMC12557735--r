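## Standard-format I/O: paired FASTQ (phred+33), TSV tables, YAML scheme
## configuration, JSON run summaries.

#' Read scheme definitions from a YAML/JSON config
#'
#' The config declares schemes under a top-level \code{schemes} list, each
#' with \code{name}, \code{pattern} and \code{n_codons}.
#'
#' @param path YAML (or JSON) file.
#' @return named list of [DegenerateScheme-class] objects.
#' @export
readSchemeConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$schemes)) stop("config has no 'schemes' entry")
    out <- lapply(cfg$schemes, function(s) {
        degenerateScheme(s$pattern,
                         nCodons = if (is.null(s$n_codons)) 50L else s$n_codons,
                         name = if (is.null(s$name)) s$pattern else s$name)
    })
    names(out) <- vapply(out, schemeName, character(1))
    out
}

#' Write weighted read pairs as paired FASTQ
#'
#' Expands the weighted pair representation of [sequenceReads()] into one
#' record per read and writes phred+33 FASTQ with a constant quality
#' character.  Identical inputs produce byte-identical files.
#'
#' @param pairs data.frame with columns read1, read2 and optionally count.
#' @param file1,file2 output FASTQ paths.
#' @param qualityChar constant quality character (default \code{"I"}, Q40).
#' @param idPrefix read-name prefix.
#' @return invisibly, the number of read pairs written.
#' @export
writePairedFastq <- function(pairs, file1, file2, qualityChar = "I",
                             idPrefix = "read") {
    cnt <- if (is.null(pairs$count)) rep(1L, nrow(pairs)) else pairs$count
    idx <- rep.int(seq_len(nrow(pairs)), cnt)
    ids <- sprintf("%s_%07d", idPrefix, seq_along(idx))
    writeOne <- function(seqs, file) {
        dss <- Biostrings::DNAStringSet(seqs)
        names(dss) <- ids
        qual <- Biostrings::BStringSet(strrep(qualityChar, nchar(seqs)))
        Biostrings::writeXStringSet(dss, file, format = "fastq",
                                    qualities = qual)
    }
    writeOne(pairs$read1[idx], file1)
    writeOne(pairs$read2[idx], file2)
    invisible(length(idx))
}

#' Read paired FASTQ into the weighted pair representation
#'
#' Reads two FASTQ files and collapses identical read pairs into weighted
#' rows, the input format of [processAmplicons()].
#'
#' @param file1,file2 FASTQ paths (mates in matching order).
#' @return data.frame with columns read1, read2, count.
#' @export
readPairedFastq <- function(file1, file2) {
    r1 <- as.character(Biostrings::readDNAStringSet(file1, format = "fastq"))
    r2 <- as.character(Biostrings::readDNAStringSet(file2, format = "fastq"))
    if (length(r1) != length(r2))
        stop("mate files contain different numbers of reads")
    key <- paste(r1, r2, sep = "\r")
    agg <- rowsum(rep(1, length(key)), group = key)
    sp <- strsplit(rownames(agg), "\r", fixed = TRUE)
    data.frame(read1 = vapply(sp, `[`, character(1), 1L),
               read2 = vapply(sp, `[`, character(1), 2L),
               count = as.numeric(agg[, 1L]),
               stringsAsFactors = FALSE)
}

#' Write a truth table for a synthetic library
#'
#' TSV with columns variant_id, sequence, true_count (clone or read count, as
#' supplied) and is_functional.
#'
#' @param library library data.frame from [generateLibrary()].
#' @param counts counts parallel to the library rows (e.g. post-selection
#'   clone counts or true read counts).
#' @param truth sequences of the planted functional variants.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeTruthTsv <- function(library, counts, truth, path) {
    write.table(data.frame(variant_id = library$variant_id,
                           sequence = library$sequence,
                           true_count = counts,
                           is_functional = library$sequence %in% truth),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a cluster table as TSV
#'
#' One row per cluster: centroid, total_count, frequency and is_hit at the
#' given frequency threshold.
#'
#' @param clusters a [ClusterSet-class].
#' @param path output TSV.
#' @param frequencyThreshold hit threshold passed to [callFunctional()].
#' @return the path, invisibly.
#' @export
writeClusterTsv <- function(clusters, path, frequencyThreshold = 5e-5) {
    hits <- callFunctional(clusters, frequencyThreshold)
    names(hits)[names(hits) == "sequence"] <- "centroid"
    names(hits)[names(hits) == "count"] <- "total_count"
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a pipeline run summary as JSON
#'
#' @param summary named list (e.g. the \code{summary} element of
#'   [processAmplicons()]).
#' @param path output JSON.
#' @return the path, invisibly.
#' @export
writeRunSummary <- function(summary, path) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
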
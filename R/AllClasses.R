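## Central S4 data objects of the screen workflow.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STOP_SYMBOL <- "*"

#' DegenerateScheme: a degenerate-codon library design
#'
#' A scheme is a three-symbol IUPAC pattern (one symbol per codon position)
#' together with the number of random codons per library insert.  The classic
#' designs are \code{NNB} (48 codons, all 20 amino acids, a single stop codon
#' TAG) and \code{NYN} (32 codons, nine amino acids, no stops).
#'
#' @slot name short label, e.g. \code{"NNB"}.
#' @slot pattern three IUPAC nucleotide codes, one per codon position.
#' @slot nCodons number of random codons per insert (default 50, i.e. 150 nt).
#'
#' @seealso [degenerateScheme()], [expandDegenerateCodon()],
#'   [schemeAminoAcidDistribution()]
#' @export
setClass("DegenerateScheme",
         representation(name = "character", pattern = "character",
                        nCodons = "integer"))

setValidity("DegenerateScheme", function(object) {
    msg <- character()
    pat <- object@pattern
    if (length(pat) != 1L || is.na(pat) || nchar(pat) != 3L)
        msg <- c(msg, "'pattern' must be a single 3-symbol string")
    else {
        sym <- strsplit(toupper(pat), "")[[1]]
        bad <- setdiff(sym, names(Biostrings::IUPAC_CODE_MAP))
        if (length(bad))
            msg <- c(msg, sprintf("invalid IUPAC symbol(s): %s",
                                  paste(unique(bad), collapse = ", ")))
    }
    if (length(object@nCodons) != 1L || is.na(object@nCodons) ||
        object@nCodons < 1L)
        msg <- c(msg, "'nCodons' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a DegenerateScheme
#'
#' @param pattern three IUPAC nucleotide codes (e.g. \code{"NNB"}).
#' @param nCodons number of random codons per insert.
#' @param name label; defaults to the pattern itself.
#' @return a [DegenerateScheme-class] object.
#' @examples
#' nnb <- degenerateScheme("NNB")
#' nyn <- degenerateScheme("NYN")
#' @export
degenerateScheme <- function(pattern, nCodons = 50L, name = pattern) {
    new("DegenerateScheme", name = as.character(name),
        pattern = toupper(as.character(pattern)),
        nCodons = as.integer(nCodons))
}

#' AminoAcidDistribution: amino-acid and stop probabilities of a scheme
#'
#' Probabilities of the 20 amino acids plus the stop symbol \code{"*"} under
#' uniform sampling of a scheme's expanded codon set.  The stop probability is
#' carried explicitly so conditioning on intact (stop-free) codons is explicit.
#'
#' @slot probabilities named numeric of length 21 (20 amino acids + \code{"*"})
#'   summing to 1.
#' @export
setClass("AminoAcidDistribution",
         representation(probabilities = "numeric"))

setValidity("AminoAcidDistribution", function(object) {
    p <- object@probabilities
    msg <- character()
    if (!identical(sort(names(p)), sort(c(AA20, STOP_SYMBOL))))
        msg <- c(msg, "probabilities must be named by the 20 amino acids and '*'")
    if (any(p < -1e-15 | p > 1 + 1e-15))
        msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-12)
        msg <- c(msg, "probabilities must sum to 1 (tolerance 1e-12)")
    if (length(msg)) msg else TRUE
})

#' VariantTable: unique sequences with read counts for one population
#'
#' @slot sequences unique variant (insert) sequences.
#' @slot counts read counts (>= 1), parallel to \code{sequences}.
#' @slot totalReads sum of counts; the denominator for variant frequencies.
#' @slot label population name, e.g. \code{"NNB-post"}.
#' @seealso [variantTable()], [clusterSequences()], [callFunctional()]
#' @export
setClass("VariantTable",
         representation(sequences = "character", counts = "numeric",
                        totalReads = "numeric", label = "character"))

setValidity("VariantTable", function(object) {
    msg <- character()
    if (length(object@sequences) != length(object@counts))
        msg <- c(msg, "'sequences' and 'counts' must be parallel")
    if (length(object@counts) && any(object@counts < 1))
        msg <- c(msg, "all counts must be >= 1")
    if (anyDuplicated(object@sequences))
        msg <- c(msg, "sequences must be unique within a table")
    if (!isTRUE(all.equal(object@totalReads, sum(object@counts))))
        msg <- c(msg, "'totalReads' must equal the sum of counts")
    if (length(msg)) msg else TRUE
})

#' Construct a VariantTable
#'
#' Duplicate sequences are aggregated by summing their counts; zero-count
#' entries are dropped.
#'
#' @param sequences character vector of variant sequences.
#' @param counts read counts, parallel to \code{sequences}.
#' @param label population name.
#' @return a [VariantTable-class].
#' @examples
#' vt <- variantTable(c("ATGAAATAA", "ATGCCCTAA"), c(10, 2), label = "demo")
#' totalReads(vt)
#' @export
variantTable <- function(sequences, counts, label = "") {
    stopifnot(length(sequences) == length(counts))
    keep <- counts > 0
    sequences <- sequences[keep]
    counts <- as.numeric(counts[keep])
    if (anyDuplicated(sequences)) {
        agg <- rowsum(counts, group = sequences)
        sequences <- rownames(agg)
        counts <- as.numeric(agg[, 1L])
    }
    o <- order(-counts, sequences)
    new("VariantTable", sequences = sequences[o], counts = counts[o],
        totalReads = sum(counts), label = as.character(label))
}

#' SelectionExperiment: paired pre/post populations with planted ground truth
#'
#' @slot pre,post [VariantTable-class] objects for the pre- and post-selection
#'   populations (clone counts from the selection simulator, or read counts).
#' @slot truth insert sequences of the planted functional variants (synthetic
#'   data only; empty for real data).
#' @slot pool all insert sequences of the generating library; every post
#'   variant must come from this pool.
#' @slot flagged \code{TRUE} when a selection round left zero survivors.
#' @export
setClass("SelectionExperiment",
         representation(pre = "VariantTable", post = "VariantTable",
                        truth = "character", pool = "character",
                        flagged = "logical"))

setValidity("SelectionExperiment", function(object) {
    msg <- character()
    if (length(object@pool) &&
        !all(object@post@sequences %in% object@pool))
        msg <- c(msg, "every post variant must exist in the generating pool")
    if (length(msg)) msg else TRUE
})

#' ClusterSet: greedy identity clustering of a VariantTable
#'
#' Entries are processed in decreasing count order (ties lexicographic); each
#' joins the earliest-founded centroid with global-alignment identity at or
#' above the threshold, else founds a new cluster.  Centroids are therefore the
#' highest-count member of their cluster (ties lexicographically smallest).
#'
#' @slot sequences,counts member sequences and counts in processing order.
#' @slot cluster integer cluster id per member (founding order).
#' @slot centroidSeqs centroid sequence per cluster id.
#' @slot clusterCounts summed member counts per cluster id.
#' @slot threshold identity threshold used.
#' @slot totalReads total reads of the clustered table.
#' @slot label population name carried from the table.
#' @seealso [clusterSequences()], [callFunctional()], [enrichmentTable()]
#' @export
setClass("ClusterSet",
         representation(sequences = "character", counts = "numeric",
                        cluster = "integer", centroidSeqs = "character",
                        clusterCounts = "numeric", threshold = "numeric",
                        totalReads = "numeric", label = "character"))

setValidity("ClusterSet", function(object) {
    msg <- character()
    if (length(object@sequences) != length(object@counts) ||
        length(object@sequences) != length(object@cluster))
        msg <- c(msg, "member slots must be parallel")
    if (length(object@centroidSeqs) != length(object@clusterCounts))
        msg <- c(msg, "cluster slots must be parallel")
    if (length(object@cluster) &&
        (max(object@cluster) > length(object@centroidSeqs) ||
         min(object@cluster) < 1L))
        msg <- c(msg, "cluster ids out of range")
    if (!isTRUE(all.equal(sum(object@clusterCounts), object@totalReads)))
        msg <- c(msg, "cluster totals must conserve the table total")
    if (length(msg)) msg else TRUE
})

#' ProteinPool: a set of proteins from one library/condition
#'
#' @slot proteins residue strings (20-letter alphabet).
#' @slot label pool name, e.g. \code{"NNB-post"}.
#' @slot minLen inclusion floor in residues (30 in the screen analyses).
#' @seealso [proteinPool()], [comparePools()]
#' @export
setClass("ProteinPool",
         representation(proteins = "character", label = "character",
                        minLen = "integer"))

setValidity("ProteinPool", function(object) {
    msg <- character()
    if (length(object@proteins)) {
        if (any(nchar(object@proteins) < object@minLen))
            msg <- c(msg, "every protein must have length >= minLen")
        bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")),
                     object@proteins)
        if (any(bad))
            msg <- c(msg, "proteins must use the 20-letter residue alphabet")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinPool
#'
#' Proteins shorter than \code{minLen} are filtered out (with a message when
#' any are dropped).
#'
#' @param proteins character vector of residue strings.
#' @param label pool name.
#' @param minLen inclusion floor in residues.
#' @return a [ProteinPool-class].
#' @export
proteinPool <- function(proteins, label = "", minLen = 30L) {
    proteins <- as.character(proteins)
    keep <- nchar(proteins) >= minLen
    if (!all(keep))
        message(sum(!keep), " protein(s) below the ", minLen,
                "-residue floor dropped from pool '", label, "'")
    if (!any(keep))
        stop("pool '", label, "' is empty after the length filter")
    new("ProteinPool", proteins = proteins[keep], label = as.character(label),
        minLen = as.integer(minLen))
}

#' PoolComparisonReport: per-metric contrast of two protein pools
#'
#' Cohen's d uses the convention (post mean - pre mean) / pooled SD; p-values
#' are two-sided Welch t-tests.  Metrics with |d| above the flag threshold are
#' marked, mirroring the asterisk convention of effect-size plots.
#'
#' @slot metrics data.frame with columns metric, mean_pre, mean_post, cohens_d,
#'   p_value, flagged.
#' @slot aaFreqPre,aaFreqPost pooled amino-acid frequency vectors (sum to 1).
#' @slot labels names of the two pools (pre, post).
#' @slot n number of proteins in each pool (pre, post).
#' @export
setClass("PoolComparisonReport",
         representation(metrics = "data.frame", aaFreqPre = "numeric",
                        aaFreqPost = "numeric", labels = "character",
                        n = "integer"))

setValidity("PoolComparisonReport", function(object) {
    msg <- character()
    for (f in list(object@aaFreqPre, object@aaFreqPost))
        if (length(f) && abs(sum(f) - 1) > 1e-8)
            msg <- c(msg, "pooled frequency vectors must sum to 1")
    if (length(msg)) msg else TRUE
})
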
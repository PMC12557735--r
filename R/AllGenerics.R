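## Accessor generics and show methods.

#' @rdname DegenerateScheme-class
#' @param x,object an object.
#' @export
setGeneric("codonPattern", function(x) standardGeneric("codonPattern"))
#' @rdname DegenerateScheme-class
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))
#' @rdname DegenerateScheme-class
#' @export
setGeneric("schemeName", function(x) standardGeneric("schemeName"))
#' @rdname AminoAcidDistribution-class
#' @param x an object.
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname VariantTable-class
#' @param x an object.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname VariantTable-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname VariantTable-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname VariantTable-class
#' @export
setGeneric("poolLabel", function(x) standardGeneric("poolLabel"))
#' @rdname SelectionExperiment-class
#' @param x an object.
#' @export
setGeneric("preTable", function(x) standardGeneric("preTable"))
#' @rdname SelectionExperiment-class
#' @export
setGeneric("postTable", function(x) standardGeneric("postTable"))
#' @rdname SelectionExperiment-class
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))
#' @rdname ClusterSet-class
#' @param x an object.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname ClusterSet-class
#' @export
setGeneric("clusterCounts", function(x) standardGeneric("clusterCounts"))
#' @rdname ClusterSet-class
#' @export
setGeneric("identityThreshold", function(x) standardGeneric("identityThreshold"))
#' @rdname ProteinPool-class
#' @param x an object.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname PoolComparisonReport-class
#' @param x an object.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname DegenerateScheme-class
#' @export
setMethod("codonPattern", "DegenerateScheme", function(x) x@pattern)
#' @rdname DegenerateScheme-class
#' @export
setMethod("nCodons", "DegenerateScheme", function(x) x@nCodons)
#' @rdname DegenerateScheme-class
#' @export
setMethod("schemeName", "DegenerateScheme", function(x) x@name)
#' @rdname AminoAcidDistribution-class
#' @export
setMethod("probabilities", "AminoAcidDistribution",
          function(x) x@probabilities)
#' @rdname VariantTable-class
#' @export
setMethod("sequences", "VariantTable", function(x) x@sequences)
#' @rdname VariantTable-class
#' @export
setMethod("counts", "VariantTable", function(x) x@counts)
#' @rdname VariantTable-class
#' @export
setMethod("totalReads", "VariantTable", function(x) x@totalReads)
#' @rdname VariantTable-class
#' @export
setMethod("poolLabel", "VariantTable", function(x) x@label)
#' @rdname VariantTable-class
#' @param object a VariantTable.
#' @export
setMethod("length", "VariantTable", function(x) length(x@sequences))
#' @rdname SelectionExperiment-class
#' @export
setMethod("preTable", "SelectionExperiment", function(x) x@pre)
#' @rdname SelectionExperiment-class
#' @export
setMethod("postTable", "SelectionExperiment", function(x) x@post)
#' @rdname SelectionExperiment-class
#' @export
setMethod("truthSet", "SelectionExperiment", function(x) x@truth)
#' @rdname ClusterSet-class
#' @export
setMethod("centroids", "ClusterSet", function(x) x@centroidSeqs)
#' @rdname ClusterSet-class
#' @export
setMethod("clusterCounts", "ClusterSet", function(x) x@clusterCounts)
#' @rdname ClusterSet-class
#' @export
setMethod("identityThreshold", "ClusterSet", function(x) x@threshold)
#' @rdname ClusterSet-class
#' @export
setMethod("totalReads", "ClusterSet", function(x) x@totalReads)
#' @rdname ClusterSet-class
#' @export
setMethod("length", "ClusterSet", function(x) length(x@centroidSeqs))
#' @rdname ClusterSet-class
#' @export
setMethod("sequences", "ClusterSet", function(x) x@sequences)
#' @rdname ClusterSet-class
#' @export
setMethod("counts", "ClusterSet", function(x) x@counts)
#' @rdname ProteinPool-class
#' @export
setMethod("proteins", "ProteinPool", function(x) x@proteins)
#' @rdname ProteinPool-class
#' @export
setMethod("poolLabel", "ProteinPool", function(x) x@label)
#' @rdname ProteinPool-class
#' @export
setMethod("length", "ProteinPool", function(x) length(x@proteins))
#' @rdname PoolComparisonReport-class
#' @export
setMethod("metricsTable", "PoolComparisonReport", function(x) x@metrics)

#' @rdname DegenerateScheme-class
#' @export
setMethod("show", "DegenerateScheme", function(object) {
    cat("DegenerateScheme '", object@name, "': pattern ", object@pattern,
        ", ", object@nCodons, " codons (",
        length(expandDegenerateCodon(object@pattern)),
        " codons in expanded set)\n", sep = "")
})

#' @rdname AminoAcidDistribution-class
#' @export
setMethod("show", "AminoAcidDistribution", function(object) {
    p <- object@probabilities
    cat("AminoAcidDistribution over", sum(p > 0), "symbols; P(stop) =",
        format(p[STOP_SYMBOL], digits = 4), "\n")
    print(round(p[p > 0], 4))
})

#' @rdname VariantTable-class
#' @export
setMethod("show", "VariantTable", function(object) {
    cat("VariantTable '", object@label, "': ", length(object@sequences),
        " unique sequences, ", format(object@totalReads, big.mark = ","),
        " reads\n", sep = "")
})

#' @rdname SelectionExperiment-class
#' @param object a SelectionExperiment.
#' @export
setMethod("show", "SelectionExperiment", function(object) {
    cat("SelectionExperiment: pre ", length(object@pre@sequences),
        " variants / ", format(object@pre@totalReads, big.mark = ","),
        " clones; post ", length(object@post@sequences), " variants / ",
        format(object@post@totalReads, big.mark = ","), " clones; ",
        length(object@truth), " planted functional variants",
        if (object@flagged) " [FLAGGED: a round left zero survivors]" else "",
        "\n", sep = "")
})

#' @rdname ClusterSet-class
#' @param object a ClusterSet.
#' @export
setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet '", object@label, "': ", length(object@centroidSeqs),
        " clusters from ", length(object@sequences),
        " unique sequences at identity >= ", object@threshold, "\n", sep = "")
})

#' @rdname ProteinPool-class
#' @param object a ProteinPool.
#' @export
setMethod("show", "ProteinPool", function(object) {
    cat("ProteinPool '", object@label, "': ", length(object@proteins),
        " proteins (>= ", object@minLen, " aa)\n", sep = "")
})

#' @rdname PoolComparisonReport-class
#' @param object a PoolComparisonReport.
#' @export
setMethod("show", "PoolComparisonReport", function(object) {
    cat("PoolComparisonReport: '", object@labels[1], "' (n = ", object@n[1],
        ") vs '", object@labels[2], "' (n = ", object@n[2], ")\n", sep = "")
    m <- object@metrics
    m$cohens_d <- round(m$cohens_d, 3)
    m$p_value <- signif(m$p_value, 3)
    m$mean_pre <- round(m$mean_pre, 4)
    m$mean_post <- round(m$mean_post, 4)
    print(m, row.names = FALSE)
})
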
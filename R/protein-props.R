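## Characterisation of protein pools: amino-acid composition, residue-class
## fractions, Kyte-Doolittle hydrophobicity (mean and windowed profile), and
## pre/post pool comparison with effect sizes and Welch t-tests.
##
## Residue classes (the field's usual three-way partition; glycine and proline
## are counted nonpolar, histidine polar-uncharged):
##   nonpolar        A V L I M F W P G
##   charged         D E K R
##   polar-uncharged S T N Q C Y H

RESIDUE_CLASSES <- list(
    nonpolar = c("A", "V", "L", "I", "M", "F", "W", "P", "G"),
    charged = c("D", "E", "K", "R"),
    polar = c("S", "T", "N", "Q", "C", "Y", "H"))

checkResidues <- function(proteins) {
    alphabet <- paste(AA20, collapse = "")
    bad <- grepl(sprintf("[^%s]", alphabet), proteins)
    if (any(bad)) {
        offending <- unique(strsplit(paste(
            gsub(sprintf("[%s]", alphabet), "", proteins[bad]),
            collapse = ""), "")[[1]])
        stop("unknown residue(s): ", paste(offending, collapse = ", "))
    }
    invisible(proteins)
}

aaCountMatrix <- function(proteins) {
    Biostrings::letterFrequency(Biostrings::AAStringSet(proteins),
                                letters = AA20)
}

#' Pooled amino-acid frequencies of a protein pool
#'
#' Residue counts are summed over all proteins and normalised by the total
#' residue count, so frequencies are invariant to protein order and to how
#' residues are split across pool entries.
#'
#' @param pool a [ProteinPool-class] or character vector of proteins.
#' @return named numeric of length 20 summing to 1.
#' @export
pooledAaFrequencies <- function(pool) {
    proteins <- if (is(pool, "ProteinPool")) proteins(pool) else pool
    if (!length(proteins)) stop("cannot compute frequencies of an empty pool")
    checkResidues(proteins)
    cnt <- colSums(aaCountMatrix(proteins))
    cnt / sum(cnt)
}

#' Residue-class fractions of proteins
#'
#' Fraction of nonpolar, charged and polar-uncharged residues per protein;
#' the three fractions sum to 1.
#'
#' @param proteins character vector of residue strings.
#' @return data.frame with columns nonpolar, charged, polar (one row per
#'   protein).
#' @examples
#' residueClassFractions("MKLS") # nonpolar 0.5, charged 0.25, polar 0.25
#' @export
residueClassFractions <- function(proteins) {
    if (any(!nzchar(proteins))) stop("proteins must be nonempty")
    checkResidues(proteins)
    m <- aaCountMatrix(proteins)
    L <- rowSums(m)
    data.frame(
        nonpolar = rowSums(m[, RESIDUE_CLASSES$nonpolar, drop = FALSE]) / L,
        charged = rowSums(m[, RESIDUE_CLASSES$charged, drop = FALSE]) / L,
        polar = rowSums(m[, RESIDUE_CLASSES$polar, drop = FALSE]) / L)
}

#' Mean Kyte-Doolittle hydrophobicity (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle index over a protein's residues.
#'
#' @param proteins character vector of residue strings.
#' @return numeric vector of GRAVY values (bounded in [-4.5, 4.5]).
#' @examples
#' gravy(c("III", "RRR")) # 4.5, -4.5
#' @export
gravy <- function(proteins) {
    if (any(!nzchar(proteins))) stop("proteins must be nonempty")
    checkResidues(proteins)
    m <- aaCountMatrix(proteins)
    as.numeric(m %*% kdHydropathy()[AA20]) / rowSums(m)
}

#' Sliding-window Kyte-Doolittle hydrophobicity profile
#'
#' Centred window means of the per-residue Kyte-Doolittle values.  Positions
#' whose value exceeds 1.0 are moderately hydrophobic and those above 1.6
#' strongly hydrophobic, the conventional profile thresholds.
#'
#' @param protein a residue string.
#' @param window odd window width, at most the protein length.  The default 9
#'   suits ~50-residue proteins.
#' @return data.frame with columns center (1-based residue position of the
#'   window centre), value, moderate (> 1.0) and strong (> 1.6);
#'   \code{length(protein) - window + 1} rows.
#' @export
kdProfile <- function(protein, window = 9L) {
    stopifnot(length(protein) == 1L)
    checkResidues(protein)
    L <- nchar(protein)
    window <- as.integer(window)
    if (window %% 2L == 0L) stop("'window' must be odd")
    if (window > L) stop("'window' exceeds the protein length")
    vals <- kdHydropathy()[strsplit(protein, "")[[1]]]
    prof <- as.numeric(stats::filter(vals, rep(1 / window, window),
                                     sides = 2))
    half <- (window - 1L) %/% 2L
    centers <- (half + 1L):(L - half)
    data.frame(center = centers, value = prof[centers],
               moderate = prof[centers] > 1.0,
               strong = prof[centers] > 1.6)
}

#' Cohen's d effect size
#'
#' (mean(a) - mean(b)) / pooled SD, with the pooled SD computed from sample
#' variances: sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)).
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return Cohen's d.
#' @export
cohensD <- function(a, b) {
    nA <- length(a); nB <- length(b)
    if (nA < 2L || nB < 2L) stop("each group needs n >= 2")
    sp <- sqrt(((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) /
               (nA + nB - 2))
    if (sp == 0) stop("zero pooled SD: effect size undefined")
    (mean(a) - mean(b)) / sp
}

#' Compare two protein pools by composition and hydrophobicity
#'
#' For each metric (nonpolar fraction, charged fraction, mean hydrophobicity)
#' computes per-protein values, group means, Cohen's d with the (post - pre) /
#' pooled-SD sign convention, and a two-sided Welch t-test p-value (pool sizes
#' are typically very unequal).  Metrics with |d| above \code{flagThreshold}
#' are flagged, mirroring the asterisk convention of effect-size figures.
#'
#' @param pre,post [ProteinPool-class] objects (pre- and post-selection).
#' @param flagThreshold |d| above which a metric is flagged (0.2 by
#'   convention).
#' @param adjust p-value adjustment method: \code{"none"} (default, raw
#'   p-values) or \code{"BH"}.
#' @return a [PoolComparisonReport-class].
#' @export
comparePools <- function(pre, post, flagThreshold = 0.2,
                         adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    stopifnot(is(pre, "ProteinPool"), is(post, "ProteinPool"))
    metricValues <- function(p) {
        cf <- residueClassFractions(proteins(p))
        list(nonpolar = cf$nonpolar, charged = cf$charged,
             hydrophobicity = gravy(proteins(p)))
    }
    vPre <- metricValues(pre)
    vPost <- metricValues(post)
    rows <- lapply(names(vPre), function(m) {
        d <- cohensD(vPost[[m]], vPre[[m]])
        p <- t.test(vPost[[m]], vPre[[m]])$p.value
        data.frame(metric = m, mean_pre = mean(vPre[[m]]),
                   mean_post = mean(vPost[[m]]), cohens_d = d, p_value = p,
                   stringsAsFactors = FALSE)
    })
    metrics <- do.call(rbind, rows)
    metrics$p_value <- p.adjust(metrics$p_value, method = adjust)
    metrics$flagged <- abs(metrics$cohens_d) > flagThreshold
    new("PoolComparisonReport", metrics = metrics,
        aaFreqPre = pooledAaFrequencies(pre),
        aaFreqPost = pooledAaFrequencies(post),
        labels = c(poolLabel(pre), poolLabel(post)),
        n = c(length(pre), length(post)))
}
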
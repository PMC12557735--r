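test_that("exact read pairs merge back to their source fragment", {
    set.seed(1)
    for (i in 1:10) {
        amp <- randomDna(156)
        rd <- readsFor(amp, 110)
        expect_identical(mergePairs(rd$r1, rd$r2, minOverlap = 10), amp)
    }
})

test_that("disjoint or short-overlap pairs fail to merge", {
    set.seed(2)
    r1 <- randomDna(50)
    r2 <- randomDna(50)
    expect_true(is.na(mergePairs(r1, r2)))
    # true overlap below minOverlap
    amp <- randomDna(100)
    rd <- readsFor(amp, 52) # 4 nt true overlap
    expect_true(is.na(suppressWarnings(
        mergePairs(rd$r1, rd$r2, minOverlap = 20))))
    expect_error(mergePairs(r1, r2, minOverlap = 5), ">= 10")
    expect_error(mergePairs("", r2), "nonempty")
})

test_that("overlap mismatches are resolved by quality, ties by read 1", {
    set.seed(3)
    amp <- randomDna(120)
    rd <- readsFor(amp, 80) # 40 nt overlap
    # plant an error at overlap position 20 (fragment coordinate 60)
    bad <- rd$r1
    orig <- substr(amp, 60, 60)
    wrong <- setdiff(c("A", "C", "G", "T"), orig)[1]
    substr(bad, 60, 60) <- wrong
    # low quality on the erroneous read1 base: read2's base wins
    q1 <- paste0(strrep("I", 59), "#", strrep("I", 20))
    q2 <- strrep("I", 80)
    expect_identical(mergePairs(bad, rd$r2, q1, q2), amp)
    # equal qualities: read1's (erroneous) base wins -- deterministic
    m <- mergePairs(bad, rd$r2, q2, q2)
    expect_identical(substr(m, 60, 60), wrong)
    # mismatch budget: 1 mismatch in 40 at maxMismatchFraction 0.1 merges,
    # at 0.01 it does not
    expect_false(is.na(mergePairs(bad, rd$r2)))
    expect_true(is.na(mergePairs(bad, rd$r2,
                                 maxMismatchFraction = 0.01)))
})

test_that("insert extraction anchors on flanks with mismatch tolerance", {
    set.seed(4)
    ins <- randomDna(60)
    read <- paste0(flank5, ins, flank3)
    expect_identical(extractInsert(read, flank5, flank3), ins)

    # one substitution in flank5 still within tolerance 2
    mut <- read
    substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read, 5, 5))[1]
    expect_identical(extractInsert(mut, flank5, flank3, 2), ins)
    # three substitutions exceed it
    mut3 <- read
    for (p in c(3, 7, 11))
        substr(mut3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                      substr(read, p, p))[1]
    expect_true(is.na(extractInsert(mut3, flank5, flank3, 2)))

    # adjacent flanks: empty insert is dropped
    expect_true(is.na(extractInsert(paste0(flank5, flank3), flank5, flank3)))
    # flank absent entirely
    expect_true(is.na(extractInsert(paste0(randomDna(20), ins, flank3),
                                    flank5, flank3)))
})

test_that("greedy clustering respects the identity threshold", {
    # duplicates only -> one cluster, counts conserved
    vt <- variantTable(c("ACGTACGTACGTACGTACGT"), 7)
    cs <- clusterSequences(vt, 0.95)
    expect_equal(length(cs), 1)
    expect_equal(clusterCounts(cs), 7)

    set.seed(5)
    base <- randomDna(150)
    far <- mutateSeq(base, 10)  # identity 140/150 ~ 0.933
    near <- mutateSeq(base, 7)  # identity 143/150 ~ 0.953
    cs2 <- clusterSequences(variantTable(c(base, far), c(5, 3)), 0.95)
    expect_equal(length(cs2), 2)
    cs1 <- clusterSequences(variantTable(c(base, near), c(5, 3)), 0.95)
    expect_equal(length(cs1), 1)
    expect_identical(centroids(cs1), base) # higher-count member is centroid
})

test_that("greedy clustering agrees with the all-pairs alignment oracle", {
    set.seed(6)
    for (rep in 1:3) {
        nfam <- 4
        seqs <- character(); cnts <- numeric()
        for (f in 1:nfam) {
            parent <- randomDna(120)
            kids <- vapply(1:8, function(i)
                mutateSeq(parent, sample(0:5, 1)), character(1))
            fam <- unique(c(parent, kids))
            seqs <- c(seqs, fam)
            cnts <- c(cnts, c(50, sample(1:10, length(fam) - 1, TRUE)))
        }
        keep <- !duplicated(seqs)
        vt <- variantTable(seqs[keep], cnts[keep])
        cs <- clusterSequences(vt, 0.95)
        oracle <- oracleGreedyCluster(sequences(vt), counts(vt), 0.95)
        expect_identical(sequences(cs), oracle$sequences)
        expect_identical(as.integer(cs@cluster), oracle$assignment)
        expect_identical(centroids(cs), oracle$centroids)
        # member-to-centroid identity contract, via the oracle identity
        for (i in seq_along(sequences(cs)))
            expect_gte(oracleIdentity(sequences(cs)[i],
                                      centroids(cs)[cs@cluster[i]]),
                       0.95 - 1e-12)
        # count conservation through clustering
        expect_equal(sum(clusterCounts(cs)), totalReads(vt))
    }
})

test_that("alignment identity matches the explicit-alignment oracle", {
    set.seed(7)
    for (i in 1:20) {
        a <- randomDna(sample(30:60, 1))
        b <- if (i %% 2) mutateSeq(a, sample(1:6, 1)) else
            randomDna(sample(30:60, 1))
        got <- alignmentIdentity(a, b)
        # scores agree with Biostrings under the same scoring scheme
        sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1,
                                                       baseOnly = TRUE)
        aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sm,
                                             gapOpening = 0,
                                             gapExtension = 2,
                                             type = "global")
        expect_equal(unname(got["score"]), Biostrings::score(aln))
    }
})

test_that("hit calling applies the inclusive frequency threshold", {
    set.seed(8)
    filler <- randomDna(150)
    s146 <- randomDna(150)
    s145 <- randomDna(150)
    vt <- variantTable(c(filler, s146, s145),
                       c(2920000 - 146 - 145, 146, 145), label = "post")
    cs <- clusterSequences(vt, 0.95)
    expect_equal(length(cs), 3)
    hits <- callFunctional(cs, 5e-5)
    expect_equal(attr(hits, "min_reads"), 146)
    expect_true(hits$is_hit[hits$sequence == s146])   # exactly 5e-5
    expect_false(hits$is_hit[hits$sequence == s145])  # one read short
    expect_equal(hits$frequency[hits$sequence == s146], 5e-5)

    # impossible threshold on a multi-cluster table
    none <- callFunctional(cs, 1.0)
    expect_false(any(none$is_hit))

    empty <- new("VariantTable", sequences = character(),
                 counts = numeric(), totalReads = 0, label = "")
    expect_warning(h0 <- callFunctional(empty, level = "raw"), "empty")
    expect_equal(nrow(h0), 0)
})

test_that("hit calls are monotone in threshold and in counts", {
    set.seed(9)
    vt <- variantTable(vapply(1:30, function(i) randomDna(100), character(1)),
                       sample(1:2000, 30))
    cs <- clusterSequences(vt, 0.95)
    thresholds <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.5)
    nhits <- vapply(thresholds, function(t)
        sum(callFunctional(cs, t)$is_hit), numeric(1))
    expect_true(all(diff(nhits) <= 0))

    # adding reads to a hit cluster never removes it
    h1 <- callFunctional(cs, 1e-3)
    hitSeq <- h1$sequence[h1$is_hit][1]
    boosted <- variantTable(sequences(vt),
                            counts(vt) + 500 * (sequences(vt) == hitSeq))
    h2 <- callFunctional(clusterSequences(boosted, 0.95), 1e-3)
    expect_true(h2$is_hit[h2$sequence == hitSeq])
})

test_that("error-free simulations merge completely and conserve counts", {
    lib <- generateLibrary("NNB", 50, indelRate = 0.1, seed = 10)
    vt <- variantTable(lib$sequence, rep(2, 50))
    r <- sequenceReads(vt, depth = 2000, substitutionRate = 0, seed = 11)
    pa <- processAmplicons(r$pairs, flank5, flank3)
    expect_equal(pa$summary$merge_failures, 0)
    expect_equal(pa$summary$flank_failures, 0)
    # recovered insert counts equal the true sampling counts
    truth <- r$trueCounts[r$trueCounts$count > 0, ]
    got <- counts(pa$table)[match(truth$sequence, sequences(pa$table))]
    expect_equal(got, truth$count)
})

test_that("enrichment tables match clusters across populations", {
    set.seed(12)
    seqs <- vapply(1:5, function(i) randomDna(120), character(1))
    vt <- variantTable(seqs, c(100, 80, 60, 40, 20), label = "x")
    cs <- clusterSequences(vt, 0.95)
    et <- enrichmentTable(cs, cs)
    expect_true(all(et$fold_change == 1))
    expect_false(any(et$de_novo))

    # de novo appearance gets the frequency floor and a flag
    pre <- clusterSequences(variantTable(seqs[1:3], c(100, 80, 60)), 0.95)
    post <- clusterSequences(variantTable(seqs, c(100, 80, 60, 40, 20)), 0.95)
    et2 <- enrichmentTable(pre, post)
    novel <- et2[et2$centroid %in% seqs[4:5], ]
    expect_true(all(novel$de_novo))
    expect_equal(novel$pre_frequency, rep(1 / (240 + 1), 2))

    # a sequencing-error sibling matches its parent cluster by identity
    sib <- mutateSeq(seqs[1], 3)
    post2 <- clusterSequences(variantTable(c(seqs[1], sib), c(90, 10)), 0.95)
    expect_equal(length(post2), 1)

    expect_error(enrichmentTable(clusterSequences(vt, 0.9), cs),
                 "same identity threshold")
})

test_that("planted variants are enriched in simulated experiments", {
    lib <- generateLibrary("NNB", 300, seed = 13)
    ex <- simulateSelection(lib, pSurviveFunctional = 0.6, pEscape = 0.01,
                            fractionFunctional = 0.05, bottleneck = 5e4,
                            seed = 14)
    pre <- clusterSequences(preTable(ex), 0.95)
    post <- clusterSequences(postTable(ex), 0.95)
    et <- enrichmentTable(pre, post)
    fc <- et$fold_change[et$centroid %in% truthSet(ex)]
    expect_gt(median(fc), 1)
})
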
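test_that("generated libraries follow the insert architecture", {
    lib <- generateLibrary("NNB", nVariants = 300, indelRate = 0, seed = 1)
    expect_equal(nrow(lib), 300)
    expect_true(all(nchar(lib$sequence) == 156)) # 3 + 150 + 3
    expect_true(all(startsWith(lib$sequence, "ATG")))
    expect_true(all(endsWith(lib$sequence, "TAA")))
    expect_false(anyDuplicated(lib$sequence) > 0)
    expect_equal(sum(lib$abundance), 1, tolerance = 1e-12)

    # NYN inserts are stop-free in frame
    nyn <- generateLibrary("NYN", nVariants = 200, indelRate = 0, seed = 2)
    internal <- substr(nyn$sequence, 4, 153)
    for (s in internal) {
        cods <- substring(s, seq(1, 148, 3), seq(3, 150, 3))
        expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
    }
})

test_that("synthesis indels shift lengths by 1-2 nt for flagged variants", {
    lib <- generateLibrary("NNB", nVariants = 2000, indelRate = 0.3, seed = 3)
    dl <- abs(nchar(lib$sequence) - 156)
    expect_true(all(dl[lib$has_indel] %in% 1:2))
    expect_true(all(dl[!lib$has_indel] == 0))
    # indel fraction close to its Bernoulli rate
    expect_gt(mean(lib$has_indel), 0.25)
    expect_lt(mean(lib$has_indel), 0.35)
})

test_that("library composition matches the scheme's analytic distribution", {
    lib <- generateLibrary("NNB", nVariants = 20000, indelRate = 0, seed = 4)
    aa <- Biostrings::letterFrequency(
        Biostrings::translate(Biostrings::DNAStringSet(
            substr(lib$sequence, 4, 153)), no.init.codon = TRUE),
        letters = c(ALL_AA, "*"))
    cnt <- colSums(aa)
    p <- probabilities(schemeAminoAcidDistribution("NNB"))[colnames(aa)]
    expect_gt(stats::chisq.test(cnt, p = p)$p.value, 0.01)
})

test_that("identical seeds reproduce libraries, reads and FASTQ byte-for-byte", {
    a <- generateLibrary("NNB", 100, seed = 5)
    b <- generateLibrary("NNB", 100, seed = 5)
    expect_identical(a, b)

    ex <- simulateSelection(a, bottleneck = 1e4, seed = 6)
    ra <- sequenceReads(postTable(ex), depth = 5000, seed = 7)
    rb <- sequenceReads(postTable(ex), depth = 5000, seed = 7)
    expect_identical(ra, rb)

    f1a <- tempfile(); f2a <- tempfile()
    f1b <- tempfile(); f2b <- tempfile()
    writePairedFastq(ra$pairs, f1a, f2a)
    writePairedFastq(rb$pairs, f1b, f2b)
    expect_identical(unname(tools::md5sum(f1a)), unname(tools::md5sum(f1b)))
    expect_identical(unname(tools::md5sum(f2a)), unname(tools::md5sum(f2b)))
})

test_that("selection without escape retains only planted variants", {
    lib <- generateLibrary("NNB", 500, seed = 8)
    ex <- simulateSelection(lib, pSurviveFunctional = 0.8, pEscape = 0,
                            fractionFunctional = 0.05, rounds = 2,
                            bottleneck = 5e4, seed = 9)
    expect_true(all(sequences(postTable(ex)) %in% truthSet(ex)))
    expect_equal(length(truthSet(ex)), 25)
})

test_that("neutral selection leaves post frequencies at pre frequencies", {
    lib <- generateLibrary("NNB", 200, abundanceSkew = 0.5, seed = 10)
    ex <- simulateSelection(lib, pSurviveFunctional = 0.5, pEscape = 0.5,
                            fractionFunctional = 0.1, rounds = 1,
                            bottleneck = 2e5, seed = 11)
    pre <- preTable(ex); post <- postTable(ex)
    idx <- match(sequences(post), sequences(pre))
    # given its total, the post sample is multinomial at the pre frequencies
    obs <- counts(post)
    expect_gt(stats::chisq.test(obs,
                                p = counts(pre)[idx] / sum(counts(pre)[idx]))$p.value,
              0.01)
})

test_that("a second selection round removes more background than one", {
    lib <- generateLibrary("NNB", 400, seed = 12)
    nonfunc <- function(rounds, seed) {
        ex <- simulateSelection(lib, pSurviveFunctional = 0.5,
                                pEscape = 0.02, fractionFunctional = 0.02,
                                rounds = rounds, bottleneck = 2e4,
                                seed = seed)
        sum(!sequences(postTable(ex)) %in% truthSet(ex))
    }
    one <- vapply(1:20, function(s) nonfunc(1L, 100 + s), numeric(1))
    two <- vapply(1:20, function(s) nonfunc(2L, 200 + s), numeric(1))
    expect_lt(mean(two), mean(one))
})

test_that("a round with zero survivors is flagged and yields an empty post", {
    lib <- generateLibrary("NNB", 50, seed = 13)
    expect_warning(
        ex <- simulateSelection(lib, pSurviveFunctional = 0.5, pEscape = 0,
                                fractionFunctional = 0, bottleneck = 1000,
                                seed = 14),
        "zero survivors")
    expect_true(ex@flagged)
    expect_equal(totalReads(postTable(ex)), 0)
})

test_that("read sampling conserves depth and matches abundances", {
    lib <- generateLibrary("NNB", 100, seed = 15)
    vt <- variantTable(lib$sequence, rep(1, 100))
    r <- sequenceReads(vt, depth = 1000, substitutionRate = 0, seed = 16)
    expect_equal(sum(r$trueCounts$count), 1000)
    expect_equal(sum(r$pairs$count), 1000)

    # single-variant population: every read identical to its amplicon ends
    one <- variantTable(lib$sequence[1], 5)
    r1 <- sequenceReads(one, depth = 50, substitutionRate = 0, seed = 17)
    expect_equal(nrow(r1$pairs), 1)
    expect_equal(r1$pairs$count, 50)

    # empirical counts vs abundances at depth 1e5
    vt2 <- variantTable(lib$sequence, seq_len(100))
    r2 <- sequenceReads(vt2, depth = 1e5, substitutionRate = 0, seed = 18)
    w <- counts(vt2)[match(r2$trueCounts$sequence, sequences(vt2))]
    expect_gt(stats::chisq.test(r2$trueCounts$count,
                                p = w / sum(w))$p.value, 0.01)

    expect_error(sequenceReads(vt, depth = 100, readLen = 80),
                 "overlap")
})

test_that("recovery evaluation scores hit sets against planted truth", {
    r <- evaluateRecovery(c("A", "B", "C"), c("A", "B", "X"))
    expect_equal(r$sensitivity, 2 / 3)
    expect_equal(r$fdp, 1 / 3)
    expect_equal(evaluateRecovery(c("A"), character())$fdp, 0)
})

test_that("composition-model proteins follow the conditional distribution", {
    pr <- randomProteins("NYN", n = 500, nResidues = 51, seed = 19)
    expect_true(all(nchar(pr) == 51))
    freq <- pooledAaFrequencies(pr)
    expect_setequal(names(freq)[freq > 0],
                    encodableAminoAcids("NYN"))
})
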
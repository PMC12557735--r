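test_that("pooled amino-acid frequencies are pooling-invariant", {
    f <- pooledAaFrequencies("MK")
    expect_equal(unname(f["M"]), 0.5)
    expect_equal(unname(f["K"]), 0.5)
    expect_equal(sum(f), 1)

    # invariant to order and to splitting proteins across entries
    a <- pooledAaFrequencies(c("MKLS", "AAAA"))
    b <- pooledAaFrequencies(c("AAAA", "MK", "LS"))
    expect_equal(a, b)
    expect_error(pooledAaFrequencies(character()), "empty")
})

test_that("simulated pools match the analytic composition model", {
    pr <- randomProteins("NNB", n = 10000, nResidues = 51, seed = 1)
    cnt <- colSums(Biostrings::letterFrequency(
        Biostrings::AAStringSet(pr), letters = ALL_AA))
    p <- probabilities(schemeAminoAcidDistribution("NNB"))
    p <- p[ALL_AA] / (1 - p[["*"]])
    expect_gt(stats::chisq.test(cnt, p = p)$p.value, 0.01)
})

test_that("residue-class fractions partition every protein", {
    expect_equal(residueClassFractions("KKRR")$charged, 1)
    expect_equal(residueClassFractions("LLLL")$nonpolar, 1)
    cf <- residueClassFractions("MKLS")
    expect_equal(cf$nonpolar, 0.5)
    expect_equal(cf$charged, 0.25)
    expect_equal(cf$polar, 0.25)
    set.seed(2)
    pr <- randomProteins("NNB", 50, 31)
    cf <- residueClassFractions(pr)
    expect_equal(cf$nonpolar + cf$charged + cf$polar, rep(1, 50))
    expect_error(residueClassFractions("MKXZ"), "X")
})

test_that("GRAVY is the mean Kyte-Doolittle value", {
    expect_equal(gravy("III"), 4.5)
    expect_equal(gravy("RRR"), -4.5)
    set.seed(3)
    pr <- randomProteins("NNB", 30, 40)
    g <- gravy(pr)
    expect_true(all(g >= -4.5 & g <= 4.5))
    rev <- vapply(strsplit(pr, ""), function(x)
        paste(base::rev(x), collapse = ""), character(1))
    expect_equal(gravy(rev), g)
    expect_error(gravy(""), "nonempty")
})

test_that("windowed hydrophobicity profiles behave at the boundaries", {
    p <- kdProfile(strrep("I", 9), window = 9)
    expect_equal(nrow(p), 1)
    expect_equal(p$value, 4.5)
    expect_true(p$strong)

    prot <- "MKTAYIAKQR"
    p1 <- kdProfile(prot, window = 1)
    expect_equal(p1$value,
                 unname(kdHydropathy()[strsplit(prot, "")[[1]]]))
    expect_equal(mean(p1$value), gravy(prot))

    full <- kdProfile(prot, window = 9)
    expect_equal(nrow(full), nchar(prot) - 9 + 1)
    expect_error(kdProfile(prot, window = 4), "odd")
    expect_error(kdProfile(prot, window = 11), "length")
})

test_that("Cohen's d follows its invariances and population value", {
    set.seed(4)
    x <- rnorm(50)
    expect_equal(cohensD(x, x), 0)
    y <- rnorm(50, 1)
    expect_equal(cohensD(x, y), -cohensD(y, x))
    expect_equal(cohensD(x + 3, y + 3), cohensD(x, y))
    expect_equal(cohensD(2 * x, 2 * y), cohensD(x, y))
    expect_error(cohensD(rep(1, 5), rep(1, 5)), "zero pooled SD")
    expect_error(cohensD(1, x), "n >= 2")

    a <- rnorm(1e5, 0.5, 1)
    b <- rnorm(1e5, 0, 1)
    expect_equal(cohensD(a, b), 0.5, tolerance = 0.02)
})

test_that("pool comparison recovers planted composition shifts", {
    set.seed(5)
    # identical pools: all d = 0, p ~ 1
    pre <- proteinPool(randomProteins("NNB", 200, 51), "pre")
    rep0 <- comparePools(pre, pre)
    m <- metricsTable(rep0)
    expect_equal(m$cohens_d, rep(0, 3))
    expect_true(all(m$p_value > 0.99))
    expect_false(any(m$flagged))

    # planted hydrophobic shift: estimate the population effect size from a
    # large reference sample, then recover it at n = 1000 within +/- 0.1
    mixProteins <- function(n) {
        base <- randomProteins("NNB", n, 51)
        bias <- randomProteins("NYN", n, 51)
        pick <- runif(n) < 0.3
        ifelse(pick, bias, base)
    }
    refPre <- randomProteins("NNB", 5e4, 51)
    refPost <- mixProteins(5e4)
    dPop <- cohensD(gravy(refPost), gravy(refPre))
    post <- proteinPool(mixProteins(1000), "post")
    pre1k <- proteinPool(randomProteins("NNB", 1000, 51), "pre")
    rep1 <- comparePools(pre1k, post)
    dHat <- metricsTable(rep1)$cohens_d[
        metricsTable(rep1)$metric == "hydrophobicity"]
    expect_gt(dHat, 0)
    expect_equal(dHat, dPop, tolerance = 0.1)

    # unequal design sizes still give well-defined d and p
    small <- proteinPool(randomProteins("NNB", 151, 51), "post")
    big <- proteinPool(randomProteins("NNB", 10000, 51), "pre")
    rep2 <- comparePools(big, small)
    expect_true(all(is.finite(metricsTable(rep2)$cohens_d)))
    expect_true(all(is.finite(metricsTable(rep2)$p_value)))
})

test_that("protein pools enforce the length floor and alphabet", {
    expect_message(p <- proteinPool(c(strrep("M", 31), "MK"), "x"),
                   "dropped")
    expect_equal(length(p), 1)
    expect_error(suppressMessages(proteinPool("MK", minLen = 30)), "empty")
    expect_error(new("ProteinPool", proteins = "MX!",
                     label = "", minLen = 1L))
})
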
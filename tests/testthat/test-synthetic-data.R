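test_that("survival cohort generation is deterministic and validates input", {
    a <- generateSurvivalCohort(nSamples = 30, nGenes = 50,
                                nSignatureGenes = 10, seed = 7)
    b <- generateSurvivalCohort(nSamples = 30, nGenes = 50,
                                nSignatureGenes = 10, seed = 7)
    expect_identical(exprMatrix(a), exprMatrix(b))
    expect_identical(survTime(a), survTime(b))
    expect_identical(cohortTruth(a), cohortTruth(b))
    c2 <- generateSurvivalCohort(nSamples = 30, nGenes = 50,
                                 nSignatureGenes = 10, seed = 8)
    expect_false(identical(exprMatrix(a), exprMatrix(c2)))

    expect_error(generateSurvivalCohort(nSamples = 0, seed = 1), "positive")
    expect_error(generateSurvivalCohort(nSamples = 20, nGenes = 10,
        nSignatureGenes = 20, seed = 1), "exceed")
    expect_error(generateSurvivalCohort(nSamples = 20, censoringRate = 1.2,
                                        seed = 1), "censoringRate")
})

test_that("planted hazard drives survival; null plants nothing", {
    # strong effect: top-quartile factor samples die sooner (Monte-Carlo
    # check of the exponential proportional-hazards construction)
    co <- generateSurvivalCohort(nSamples = 200, nGenes = 20,
        nSignatureGenes = 10, hazardCoefficient = 1, censoringRate = 0,
        seed = 42)
    f <- cohortTruth(co)$factor
    hi <- survTime(co)[f >= quantile(f, 0.75)]
    lo <- survTime(co)[f <= quantile(f, 0.25)]
    expect_lt(mean(hi), mean(lo))

    # hazardCoefficient = 0: factor and survival time unrelated
    pvals <- vapply(1:20, function(s) {
        con <- generateSurvivalCohort(nSamples = 100, nGenes = 5,
            nSignatureGenes = 3, hazardCoefficient = 0, censoringRate = 0,
            seed = 1000 + s)
        spearmanRho(cohortTruth(con)$factor, survTime(con))$p
    }, numeric(1))
    expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("requested censoring fraction is realized at moderate n", {
    for (s in 1:5) {
        co <- generateSurvivalCohort(nSamples = 150, nGenes = 10,
            nSignatureGenes = 5, censoringRate = 0.3, seed = 200 + s)
        expect_lt(abs((1 - mean(survEvent(co))) - 0.3), 0.15)
    }
})

test_that("group separation grows with the planted hazard coefficient", {
    sep <- vapply(c(0, 0.5, 1), function(hc) {
        median(vapply(1:20, function(s) {
            co <- generateSurvivalCohort(nSamples = 100, nGenes = 5,
                nSignatureGenes = 3, hazardCoefficient = hc,
                censoringRate = 0.2, seed = 3000 + s)
            abs(fastStatistic(cohortTruth(co)$factor, survTime(co),
                              survEvent(co)))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(sep) > 0))
})

test_that("batch structure adds gene-wise shifts between batches", {
    co <- generateSurvivalCohort(nSamples = 60, nGenes = 100,
        nSignatureGenes = 10, nBatches = 2, batchShiftSd = 3, noiseSd = 0.5,
        seed = 5)
    b <- sampleBatch(co)
    expect_equal(sort(unique(b)), c(1, 2))
    m <- exprMatrix(co)
    gap <- rowMeans(m[, b == 1]) - rowMeans(m[, b == 2])
    expect_gt(sd(gap), 1)  # shifts of SD 3 dominate noise
})

test_that("gene-set generation honors counts, anchors and frequencies", {
    uni <- sprintf("G%03d", 1:300)
    gs <- generateGeneSetCollection(nSets = 15, hypoxiaSets = 10,
        universe = uni, overlapProfile = c(G001 = 0.5, G002 = 0.1, G003 = 1),
        anchorGene = "VEGFA", seed = 9)
    nm <- names(geneSets(gs))
    hyp <- geneSets(gs)[grepl("HYPOXIA", nm)]
    expect_length(hyp, 10)
    expect_true(all(vapply(hyp, function(s) "VEGFA" %in% s, logical(1))))
    counts <- vapply(c("G001", "G002", "G003"),
        function(g) sum(vapply(hyp, function(s) g %in% s, logical(1))),
        numeric(1))
    expect_equal(unname(counts), c(5, 1, 10))
    expect_error(generateGeneSetCollection(5, 2, universe = character(),
                                           seed = 1), "empty universe")
    # no hypoxia sets -> meta-signature build fails downstream
    gs0 <- generateGeneSetCollection(nSets = 5, hypoxiaSets = 0,
                                     universe = uni, seed = 2)
    expect_error(buildHypoxiaMetasignature(gs0), "no matching sets")
})

test_that("ortholog cohort maps symbols, plants effect, reports fraction", {
    co <- generateSurvivalCohort(nSamples = 40, nGenes = 100,
                                 nSignatureGenes = 30, seed = 21)
    model <- suppressWarnings(discoverSignature(co, keepFraction = 1,
        nPerm = 300, lfdrThreshold = 0.4, seed = 3))$model
    nSig <- length(model@transcriptIds)

    half <- generateOrthologCohort(model, nSamples = 16, mappingRate = 0.5,
                                   effect = 0, seed = 4)
    st <- riskScore(half, model)
    expect_equal(matchedGeneFraction(st), round(0.5 * nSig) / nSig)
    # mouse case convention: title case of the human symbols
    expect_true(all(grepl("^Gene", rownames(half)[seq_len(round(0.5 * nSig))])))

    # no effect: groups indistinguishable in most seeds
    pv <- vapply(1:20, function(s) {
        c0 <- generateOrthologCohort(model, nSamples = 20, mappingRate = 1,
                                     effect = 0, seed = 400 + s)
        sc <- scores(riskScore(c0, model))
        met <- cohortTruth(c0)$metastatic
        mannWhitneyU(sc[met], sc[!met])$p
    }, numeric(1))
    expect_gte(mean(pv > 0.05), 0.9)
    expect_error(generateOrthologCohort(model, mappingRate = 0, seed = 1),
                 "mappingRate")
})

test_that("image stacks are reproducible with controlled area fraction", {
    a <- generateShgStack(width = 64, height = 64, depth = 3,
                          fiberCount = 15, seed = 6)
    b <- generateShgStack(width = 64, height = 64, depth = 3,
                          fiberCount = 15, seed = 6)
    expect_identical(a, b)
    expect_equal(dim(a), c(64, 64, 3))
    expect_true(all(a >= 0 & a <= 1))

    blank <- generateShgStack(width = 32, height = 32, depth = 2,
        fiberCount = 0, backgroundNoiseSd = 0, seed = 1)
    expect_true(all(blank == 0))
    expect_warning(am <- autoMask(maxProjection(blank)), "constant")
    expect_equal(am$areaPercent, 0)

    st <- generateShgStack(width = 96, height = 96, depth = 2,
        fiberCount = 25, areaFractionTarget = 0.2, seed = 8)
    # stack-level foreground fraction (mean over slices) hits the target
    sliceArea <- vapply(1:2, function(s) autoMask(st[, , s])$areaPercent,
                        numeric(1))
    expect_lt(abs(mean(sliceArea) / 100 - 0.2), 0.1)
    expect_error(generateShgStack(width = 0, seed = 1), "zero")
})

test_that("doubling the correlation length slows the autocorrelation decay", {
    decayLen <- function(cl, s) {
        st <- generateShgStack(width = 96, height = 96, depth = 1,
            fiberCount = 20, correlationLengthPx = cl,
            backgroundNoiseSd = 0, seed = s)
        img <- maxProjection(st)
        img <- img - mean(img)
        # empirical horizontal autocorrelation by direct shifting
        ac <- vapply(1:25, function(d) {
            a <- img[, 1:(96 - d)]; b <- img[, (d + 1):96]
            sum(a * b) / sqrt(sum(a^2) * sum(b^2))
        }, numeric(1))
        if (all(ac > 0.5)) 25 else which(ac <= 0.5)[1]
    }
    short <- vapply(1:5, function(s) decayLen(3, 50 + s), numeric(1))
    long <- vapply(1:5, function(s) decayLen(6, 50 + s), numeric(1))
    expect_gt(median(long), median(short))
})
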
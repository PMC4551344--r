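test_that("variance filter keeps the top-variance rows in order", {
    co <- makeToyCohort(nGenes = 10, nSamples = 5)
    expect_identical(exprMatrix(varianceFilter(co, 1)), exprMatrix(co))

    kept <- varianceFilter(co, 0.5)
    v <- apply(exprMatrix(co), 1, var)
    top5 <- names(sort(v, decreasing = TRUE))[1:5]
    expect_setequal(rownames(kept), top5)
    # original order preserved among retained rows
    expect_identical(rownames(kept),
                     rownames(co)[rownames(co) %in% top5])

    # a constant row is never retained while non-constant rows exist
    m <- exprMatrix(co); m["g03", ] <- 5
    co2 <- ExpressionCohort(m, time = survTime(co), event = survEvent(co))
    expect_false("g03" %in% rownames(varianceFilter(co2, 0.9)))
    one <- ExpressionCohort(m[, 1, drop = FALSE], time = 3, event = 1L)
    expect_error(varianceFilter(one, 0.5), "fewer than 2")
})

test_that("probe collapse keeps the highest-variance probe per gene", {
    m <- rbind(p1 = c(1, 2, 3, 4), p2 = c(0, 4, 0, 4), p3 = c(5, 5, 5.5, 5))
    colnames(m) <- paste0("s", 1:4)
    co <- ExpressionCohort(m, time = 1:4, event = c(1, 1, 0, 1),
        probeMap = c(p1 = "GX", p2 = "GX", p3 = "GY"))
    out <- collapseProbes(co)
    expect_setequal(rownames(out), c("GX", "GY"))
    expect_equal(unname(exprMatrix(out)["GX", ]), c(0, 4, 0, 4))  # var 5.33 > 1.67

    # tie in variance -> lexicographically smallest probe id wins
    mt <- rbind(pb = c(0, 1, 0, 1), pa = c(1, 0, 1, 0))
    colnames(mt) <- paste0("s", 1:4)
    cot <- ExpressionCohort(mt, time = 1:4, event = rep(1L, 4),
        probeMap = c(pb = "GZ", pa = "GZ"))
    expect_equal(unname(exprMatrix(collapseProbes(cot))["GZ", ]),
                 c(1, 0, 1, 0))

    # one probe per gene: identity up to renaming; unmapped probes dropped
    co1 <- ExpressionCohort(m, time = 1:4, event = rep(1L, 4),
        probeMap = c(p1 = "A", p2 = "B"))
    expect_message(out1 <- collapseProbes(co1), "1 unmapped")
    expect_equal(unname(exprMatrix(out1)[c("A", "B"), ]), unname(m[1:2, ]))
    expect_error(collapseProbes(makeToyCohort()), "no probe-to-gene map")
})

test_that("FAST statistic equals the Cox score at beta 0 divided by n", {
    expect_equal(fastStatistic(c(4, 3, 2, 1), 1:4, rep(1, 4)),
                 coxScoreOracle(c(4, 3, 2, 1), 1:4, rep(1, 4)),
                 tolerance = 1e-12)
    # exhaustive small-n comparison against the brute-force oracle,
    # including tied times and censoring
    set.seed(31)
    for (rep in 1:60) {
        n <- sample(3:8, 1)
        x <- rnorm(n)
        time <- sample(1:4, n, replace = TRUE)   # forces ties
        event <- rbinom(n, 1, 0.7)
        if (!any(event == 1)) event[1] <- 1L
        expect_equal(fastStatistic(x, time, event),
                     coxScoreOracle(x, time, event), tolerance = 1e-10)
    }
})

test_that("FAST statistic: affine invariance, degenerate inputs", {
    set.seed(5)
    x <- rnorm(12); tm <- rexp(12) + 0.1; ev <- rbinom(12, 1, 0.6)
    ev[1] <- 1L
    expect_equal(fastStatistic(3 * x - 7, tm, ev), fastStatistic(x, tm, ev),
                 tolerance = 1e-12)
    expect_warning(s0 <- fastStatistic(rep(2, 12), tm, ev), "zero-variance")
    expect_identical(s0, 0)
    expect_error(fastStatistic(x, tm, rep(0L, 12)), "no events")
})

test_that("permutation p-values follow the add-one rule on a shared stream", {
    set.seed(8)
    n <- 15
    tm <- rexp(n) + 0.1; ev <- rep(1L, n)
    # a covariate equal to a monotone transform of time beats all permutations
    x <- -rank(tm)
    m <- rbind(a = x, b = x, c = rnorm(n))
    colnames(m) <- paste0("s", 1:n)
    pp <- suppressWarnings(permutationPvalues(m, tm, ev, nPerm = 199,
                                              seed = 2))
    expect_equal(unname(pp$p["a"]), 1 / 200)
    # duplicate rows get identical p-values (shared permutation stream)
    expect_identical(pp$p[["a"]], pp$p[["b"]])
    # p-values live on the add-one grid, never 0
    expect_true(all(pp$p >= 1 / 200 & pp$p <= 1))
    expect_true(all(abs(pp$p * 200 - round(pp$p * 200)) < 1e-9))
    expect_error(permutationPvalues(m, tm, ev, nPerm = 0, seed = 1), "nPerm")
})

test_that("null permutation p-values are close to uniform", {
    set.seed(77)
    n <- 40
    m <- matrix(rnorm(500 * n), 500, n,
                dimnames = list(sprintf("g%03d", 1:500), NULL))
    tm <- rexp(n) + 0.1; ev <- rbinom(n, 1, 0.7); ev[1] <- 1L
    pp <- permutationPvalues(m, tm, ev, nPerm = 400, seed = 3)
    ks <- suppressWarnings(ks.test(pp$p, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("Grenander lfdr matches an independent majorant and behaves", {
    set.seed(12)
    p <- c(rbeta(40, 0.2, 1), runif(360))
    p[p <= 0] <- 1e-6
    gren <- PDACsig:::.grenander(p)
    orc <- lcmOracle(p)
    expect_equal(gren$x, orc$x, tolerance = 1e-12)
    expect_equal(gren$slope, orc$slope, tolerance = 1e-12)

    lf <- localFdr(p)
    expect_true(all(lf >= 0 & lf <= 1))
    # non-decreasing in p (Grenander density is non-increasing)
    ord <- order(p)
    expect_true(all(diff(lf[ord]) > -1e-12))

    # global null: eta0 ~ 1 and lfdr mostly near 1
    set.seed(13)
    pu <- runif(500)
    expect_gte(median(localFdr(pu)), 0.9)

    expect_error(localFdr(runif(20)), "at least 50")
    expect_error(localFdr(c(runif(60), 0)), "\\(0, 1\\]")
})

test_that("PCA metagenes: rank-1 recovery, score identity, SVD agreement", {
    # rank-1 outer product: one component carries all variance
    u <- c(2, -1, 0.5, 1, -2, 0.25); v <- c(1, 2, 3, 4)
    m <- outer(u, v)
    dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:4))
    co <- ExpressionCohort(m, time = 1:4, event = rep(1L, 4))
    pc <- pcaMetagenes(co, nComponents = 1)
    expect_equal(pc$varianceExplained[1], 1, tolerance = 1e-12)

    # definitional identity: scores = t(loadings) %*% centered matrix
    co2 <- makeToyCohort(nGenes = 6, nSamples = 4, seed = 3)
    pc2 <- pcaMetagenes(co2, nComponents = 2)
    mc <- exprMatrix(co2) - rowMeans(exprMatrix(co2))
    expect_equal(pc2$scores, t(pc2$loadings) %*% mc, tolerance = 1e-12)

    # loadings match an independent eigendecomposition up to sign
    ev <- eigen(mc %*% t(mc))
    expect_equal(abs(sum(pc2$loadings[, 1] * ev$vectors[, 1])), 1,
                 tolerance = 1e-8)
    expect_error(pcaMetagenes(co2, nComponents = 5), "rank")
    expect_error(pcaMetagenes(co2, transcripts = rownames(co2)[1:2],
                              nComponents = 3), "fewer")
})

test_that("orientation and signature split are antisymmetric and exhaustive", {
    lo <- c(a = 0.5, b = -0.3, c = 0.1, d = -0.9)
    m1 <- splitSignature(lo, +1)
    m2 <- splitSignature(lo, -1)
    expect_setequal(hazardousSet(m1), c("a", "c"))
    expect_setequal(protectiveSet(m1), c("b", "d"))
    # flipping orientation swaps the sets exactly
    expect_setequal(hazardousSet(m2), protectiveSet(m1))
    expect_setequal(protectiveSet(m2), hazardousSet(m1))
    # exhaustive, disjoint partition is enforced by the class
    expect_setequal(c(hazardousSet(m1), protectiveSet(m1)), names(lo))

    allPos <- splitSignature(c(x = 0.2, y = 0.7), +1)
    expect_length(protectiveSet(allPos), 0)
    expect_warning(splitSignature(c(x = 0.2, y = 0), +1), "zero loading")
    expect_error(splitSignature(lo, 0), "unoriented")
    expect_error(suppressWarnings(orientComponent(c(1, 1, 1, 1), 1:4,
                                                  rep(1L, 4))))
})

test_that("discovery recovers a planted signature", {
    co <- generateSurvivalCohort(nSamples = 100, nGenes = 400,
        nSignatureGenes = 60, hazardCoefficient = 1, seed = 17)
    tr <- cohortTruth(co)
    disc <- suppressWarnings(discoverSignature(co, keepFraction = 0.5,
        nPerm = 500, seed = 18))
    sel <- disc$model@transcriptIds
    jac <- length(intersect(sel, tr$signatureGenes)) /
           length(union(sel, tr$signatureGenes))
    expect_gt(jac, 0.3)
    common <- intersect(sel, tr$signatureGenes)
    r <- cor(signatureLoadings(disc$model)[common] *
             signatureOrientation(disc$model), tr$loadings[common])
    expect_gt(abs(r), 0.7)
    # oriented hazardous set matches planted positive loadings
    planted <- names(tr$loadings)[tr$loadings > 0]
    hazHit <- mean(intersect(planted, sel) %in% hazardousSet(disc$model))
    expect_gt(hazHit, 0.8)
    # oriented scores track the planted factor, hazard-positively
    expect_gt(cor(scores(disc$scores), tr$factor), 0.9)
})

test_that("LOO-CV scores every fold and reports association", {
    co <- generateSurvivalCohort(nSamples = 40, nGenes = 150,
        nSignatureGenes = 40, hazardCoefficient = 1.5, seed = 23)
    lo <- suppressWarnings(suppressMessages(evaluateComponentsLoocv(co,
        nPermFold = 150, nPermScore = 499, seed = 29)))
    expect_equal(sum(!is.na(lo$oofScores[, 1])) + length(lo$skippedFolds),
                 ncol(co))
    expect_lt(lo$p[1], 0.05)
    expect_gt(lo$statistic[1], 0)
    expect_error(evaluateComponentsLoocv(co[, 1:5], seed = 1), "at least 10")
})
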
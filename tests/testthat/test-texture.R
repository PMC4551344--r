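test_that("maximum projection is the pixelwise maximum", {
    set.seed(14)
    st <- array(runif(8 * 8 * 8), c(8, 8, 8))
    proj <- maxProjection(st)
    # brute-force per-pixel loop oracle
    for (r in 1:8) for (cc in 1:8)
        expect_equal(proj[r, cc], max(st[r, cc, ]))
    one <- st[, , 1]
    expect_identical(maxProjection(array(one, c(8, 8, 1))), one)
    expect_identical(maxProjection(array(c(one, one * 2), c(8, 8, 2))),
                     one * 2)
    expect_error(maxProjection(array(0, c(4, 4, 0))), "empty")
})

test_that("Otsu mask separates a bimodal image and reports area", {
    img <- matrix(0, 20, 20); img[, 11:20] <- 1
    am <- autoMask(img)
    expect_equal(am$areaPercent, 50)
    expect_true(all(am$mask[, 11:20]) && !any(am$mask[, 1:10]))
    expect_warning(blank <- autoMask(matrix(0.3, 5, 5)), "constant")
    expect_equal(blank$areaPercent, 0)
})

test_that("GLCM counts match brute-force pair enumeration", {
    # hand-enumerated 4x4 two-level toy image, distance 1, direction 0
    img <- matrix(c(0, 0, 1, 1,
                    0, 0, 1, 1,
                    0, 1, 1, 0,
                    1, 1, 0, 0), 4, 4, byrow = TRUE)
    mask <- matrix(TRUE, 4, 4)
    P <- PDACsig:::.glcmMatrix(PDACsig:::.quantizeLevels(img, mask, 2),
                               mask, 2L, 0, 1)
    # horizontal neighbor pairs: (0,0)x3, (1,1)x4, mixed x5; symmetrized
    expect_equal(P, matrix(c(6, 5, 5, 8), 2, 2) / 24)

    # exhaustive oracle comparison on random small images, all 4 directions
    set.seed(15)
    off <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
    for (rep in 1:6) {
        n <- sample(6:16, 1)
        im <- matrix(sample(0:255, n * n, replace = TRUE), n, n)
        mk <- matrix(runif(n * n) > 0.2, n, n)
        if (!any(mk)) next
        q <- PDACsig:::.quantizeLevels(im, mk, 8)
        for (d in 1:3) for (o in off) {
            got <- PDACsig:::.glcmMatrix(q, mk, 8L, o[1] * d, o[2] * d)
            want <- glcmOracle(im, mk, 8, o[1] * d, o[2] * d)
            if (is.null(want)) expect_null(got)
            else expect_equal(got, want, tolerance = 1e-12)
        }
    }
})

test_that("Haralick parameters behave on degenerate and periodic images", {
    # constant foreground: contrast 0, energy 1, homogeneity 1
    img <- matrix(0.7, 12, 12)
    mask <- matrix(TRUE, 12, 12)
    grid <- glcmProfile(img, mask, distances = 1:4, levels = 8)
    for (p in c("contrast", "energy", "homogeneity")) {
        v <- grid$value[grid$parameter == p]
        expect_equal(v, rep(if (p == "contrast") 0 else 1, length(v)))
    }
    expect_true(all(grid$value[grid$parameter == "entropy"] == 0))

    # period-2 horizontal stripes: horizontal contrast maximal at d = 1,
    # zero at d = 2 (pairs identical)
    stripes <- matrix(rep(c(0, 1), 8), 16, 16)  # alternating rows
    g2 <- glcmProfile(stripes, matrix(TRUE, 16, 16), distances = 1:2,
                      levels = 2)
    vert <- function(d) g2$value[g2$parameter == "contrast" &
                                 g2$direction == 90 & g2$distance == d]
    expect_gt(vert(1), 0.9)     # all vertical pairs differ
    expect_equal(vert(2), 0)    # two rows apart: identical levels

    # invariants: energy in (0, 1], entropy >= 0, contrast >= 0
    set.seed(16)
    im <- matrix(runif(400), 20, 20)
    g3 <- glcmProfile(im, matrix(TRUE, 20, 20), distances = 1:6, levels = 16)
    expect_true(all(g3$value[g3$parameter == "energy"] > 0 &
                    g3$value[g3$parameter == "energy"] <= 1))
    expect_true(all(g3$value[g3$parameter == "entropy"] >= 0))
    expect_true(all(g3$value[g3$parameter == "contrast"] >= 0))
    expect_error(glcmProfile(im, distances = 1:30), "smaller")
})

test_that("rotating the image by 90 degrees permutes direction channels", {
    set.seed(17)
    im <- matrix(runif(18 * 18), 18, 18)
    mask <- matrix(TRUE, 18, 18)
    g <- glcmProfile(im, mask, distances = 1:5, levels = 8)
    rot <- t(im)[, nrow(im):1]   # 90-degree rotation
    gr <- glcmProfile(rot, matrix(TRUE, 18, 18), distances = 1:5, levels = 8)
    # direction-averaged curves are unchanged
    cu <- decayCurves(g); cur <- decayCurves(gr)
    for (p in names(cu))
        expect_equal(cu[[p]]$value, cur[[p]]$value, tolerance = 1e-10)
    # 0 <-> 90 swap for one parameter as a direct channel check
    h0 <- g$value[g$parameter == "contrast" & g$direction == 0]
    h90r <- gr$value[gr$parameter == "contrast" & gr$direction == 90]
    expect_equal(h0, h90r, tolerance = 1e-10)
})

test_that("decay fit recovers analytic weighted mean decay distances", {
    d <- 1:60
    # degenerate double exponential: single scale 5
    f1 <- decayFit(3 * exp(-d / 5), d, seed = 2)
    expect_equal(f1$weightedMeanDecayDistance, 5, tolerance = 0.01)
    # two components 2 and 10 with equal amplitude: weighted mean 6
    f2 <- decayFit(exp(-d / 2) + exp(-d / 10), d, seed = 3)
    expect_equal(f2$weightedMeanDecayDistance, 6, tolerance = 0.06)
    expect_lte(f2$lambda1, f2$lambda2)
    expect_true(all(c(f2$A1, f2$A2) >= 0))
    # with mild noise the recovery stays within 15% (median over seeds)
    set.seed(18)
    wm <- vapply(1:20, function(s) {
        y <- exp(-d / 2) + exp(-d / 10) + rnorm(60, 0, 0.01 * 2)
        decayFit(y, d, seed = s)$weightedMeanDecayDistance
    }, numeric(1))
    expect_lt(abs(median(wm) - 6) / 6, 0.15)
    expect_error(decayFit(c(1, 2, 3), 1:3, seed = 1), "at least 8")
})

test_that("depth profile counts foreground per slice and in total", {
    st <- array(0, c(10, 10, 2))
    st[1:5, 1:2, 1] <- 1    # 10 px  = 10%
    st[, 1:3, 2] <- 1       # 30 px  = 30%
    dp <- depthProfile(st, rule = "fixed", threshold = 0.5)
    expect_equal(dp$percent, c(10, 30))
    expect_equal(dp$totalForeground, sum(dp$count))
    expect_equal(dp$count, c(10, 30))
    # uniform foreground: 100% at every depth under a fixed rule
    uni <- array(1, c(4, 4, 3))
    expect_equal(depthProfile(uni, rule = "fixed", threshold = 0.5)$percent,
                 rep(100, 3))
    expect_error(depthProfile(array(0, c(2, 2, 0))), "empty")
})

test_that("full stack analysis produces finite decay distances", {
    st <- generateShgStack(width = 96, height = 96, depth = 2,
        fiberCount = 25, correlationLengthPx = 4, seed = 19)
    tp <- analyzeStack(st, distances = 1:24, levels = 16, seed = 1)
    expect_s4_class(tp, "TextureProfile")
    expect_equal(nrow(textureValues(tp)), 5 * 4 * 24)
    expect_gt(areaPercent(tp), 5)
    wm <- meanDecayDistance(tp)[["correlation"]]
    expect_true(is.finite(wm) && wm > 0)
})
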
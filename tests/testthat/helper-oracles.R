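# Independent oracles used to validate the package's own implementations.
# Each is a deliberately naive, brute-force computation.

# Cox partial-likelihood score at beta = 0 for a standardized covariate,
# divided by n (risk set = {j : t_j >= t_i}, ties included).
coxScoreOracle <- function(x, time, event) {
    z <- (x - mean(x)) / sd(x)
    s <- 0
    for (i in seq_along(time)) {
        if (event[i] == 1) {
            rs <- which(time >= time[i])
            s <- s + z[i] - mean(z[rs])
        }
    }
    s / length(time)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws of the query from the universe.
hypergeomOracle <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    inSet <- seq_len(K)
    hits <- apply(draws, 2, function(d) sum(d %in% inSet))
    mean(hits >= k)
}

# Symmetric normalized co-occurrence matrix by a double loop over all
# pixels; independent quantization included.
glcmOracle <- function(image, mask, levels, dRow, dCol) {
    vals <- image[mask]
    rng <- range(vals)
    q <- matrix(NA_integer_, nrow(image), ncol(image))
    q[mask] <- if (diff(rng) == 0) 1L else
        pmin(levels, 1L + floor((image[mask] - rng[1]) / diff(rng) * levels))
    C <- matrix(0, levels, levels)
    for (r in seq_len(nrow(image))) for (cc in seq_len(ncol(image))) {
        r2 <- r + dRow; c2 <- cc + dCol
        if (r2 < 1 || r2 > nrow(image) || c2 < 1 || c2 > ncol(image)) next
        if (!mask[r, cc] || !mask[r2, c2]) next
        C[q[r, cc], q[r2, c2]] <- C[q[r, cc], q[r2, c2]] + 1
        C[q[r2, c2], q[r, cc]] <- C[q[r2, c2], q[r, cc]] + 1
    }
    if (sum(C) == 0) return(NULL)
    C / sum(C)
}

# Least concave majorant of the p-value ECDF by greedy maximum-slope
# chaining from the origin (quadratic, independent of the stack algorithm).
lcmOracle <- function(p) {
    sp <- sort(unique(p)); m <- length(p)
    x <- c(0, sp); y <- c(0, vapply(sp, function(q) mean(p <= q), 0))
    if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, 1) }
    i <- 1; keep <- 1
    while (i < length(x)) {
        sl <- (y[(i + 1):length(x)] - y[i]) / (x[(i + 1):length(x)] - x[i])
        j <- i + which.max(sl)
        keep <- c(keep, j); i <- j
    }
    list(x = x[keep], slope = diff(y[keep]) / diff(x[keep]))
}

# Product-limit estimator by a hand loop.
kmOracle <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- 1; surv <- numeric(length(ts))
    for (i in seq_along(ts)) {
        nRisk <- sum(time >= ts[i])
        nEv <- sum(time == ts[i] & event == 1)
        s <- s * (1 - nEv / nRisk)
        surv[i] <- s
    }
    list(time = ts, surv = surv)
}

# Mann-Whitney U for x by direct pair counting (ties count 1/2).
uOracle <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# A tiny deterministic cohort for unit tests.
makeToyCohort <- function(nGenes = 60, nSamples = 20, seed = 11) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    ExpressionCohort(m, time = rexp(nSamples, 0.1) + 0.1,
                     event = rbinom(nSamples, 1, 0.7))
}
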
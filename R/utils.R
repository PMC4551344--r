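#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the RNG seeded to \code{seed}, then restores the
#' caller's RNG state, so every stochastic operation in the package is a pure
#' function of its arguments.
#' @keywords internal
.withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Row-standardize a matrix (z-scores across samples)
#'
#' Rows with zero variance are returned as all-zero rows (optionally with a
#' warning); constant expression carries no survival information.
#' @keywords internal
.rowVars <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1L)
}

.rowZ <- function(m, warn = TRUE) {
    mu <- rowMeans(m)
    sd <- sqrt(.rowVars(m))
    zero <- sd == 0 | !is.finite(sd)
    if (any(zero) && warn)
        warning(sum(zero), " zero-variance row(s) set to z = 0")
    sd[zero] <- 1
    z <- (m - mu) / sd
    z[zero, ] <- 0
    z
}

#' Separable Gaussian smoothing of a matrix
#'
#' Band-matrix convolution along rows then columns with kernel weights
#' renormalized at the edges, so mass is conserved on images of any size
#' (including images smaller than the kernel support).
#' @keywords internal
.gaussSmooth <- function(m, sigma) {
    if (sigma <= 0) return(m)
    bandMat <- function(n) {
        K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma)
        K[abs(outer(seq_len(n), seq_len(n), "-")) > ceiling(4 * sigma)] <- 0
        K / rowSums(K)
    }
    bandMat(nrow(m)) %*% m %*% t(bandMat(ncol(m)))
}

#' Format numbers for reproducible text output (10 significant digits)
#' @keywords internal
.fmtNum <- function(x) formatC(x, digits = 10, format = "g")

#' Match gene symbols case-insensitively
#'
#' Returns, for each query symbol, the index of its (first) case-insensitive
#' match in \code{target}, or NA.  Preserves case of both sides; matching is
#' on upper-cased symbols so that human (LOX) and mouse (Lox) conventions
#' align.
#' @keywords internal
.matchSymbols <- function(query, target) {
    match(toupper(query), toupper(target))
}
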
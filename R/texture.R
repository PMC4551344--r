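.glcmDirections <- c(0, 45, 90, 135)
.glcmParameters <- c("contrast", "correlation", "energy", "homogeneity",
                     "entropy")

#' Maximum intensity projection of an image stack
#'
#' @param stack numeric array height x width x depth (a single matrix is
#'   treated as a 1-slice stack).
#' @return matrix of pixelwise maxima.
#' @export
maxProjection <- function(stack) {
    if (is.matrix(stack)) return(stack)
    d <- dim(stack)
    if (length(d) != 3 || d[3] < 1) stop("empty stack")
    out <- stack[, , 1L]
    for (s in seq_len(d[3])[-1L]) out <- pmax(out, stack[, , s])
    out
}

#' Automatic foreground mask by Otsu threshold
#'
#' Thresholds a grayscale image with Otsu's method (on 256 histogram bins
#' over the image range) and reports the percent area covered by the
#' foreground.  The mask restricts the GLCM computation to the signal,
#' removing the background-noise bias.  A constant image yields an empty
#' mask (area 0) with a warning.
#'
#' @param image numeric matrix.
#' @return list with \code{mask} (logical matrix) and \code{areaPercent}.
#' @export
autoMask <- function(image) {
    if (!is.matrix(image)) stop("a grayscale image matrix is required")
    rng <- range(image)
    if (diff(rng) == 0) {
        warning("constant image: empty mask")
        return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                    areaPercent = 0))
    }
    norm <- (image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
    mask <- norm > thr
    list(mask = mask, areaPercent = 100 * mean(mask))
}

#' Quantize in-mask intensities to gray levels
#' @keywords internal
.quantizeLevels <- function(image, mask, levels) {
    vals <- image[mask]
    rng <- range(vals)
    q <- matrix(NA_integer_, nrow(image), ncol(image))
    if (diff(rng) == 0) q[mask] <- 1L
    else q[mask] <- pmin(levels,
        1L + as.integer(floor((image[mask] - rng[1]) / diff(rng) * levels)))
    q
}

#' Co-occurrence counts for one (distance, direction) offset
#'
#' Pairs (i, j) are counted only where both pixels lie in the mask; counts
#' are symmetrized (both pair orders) and normalized to probabilities.
#' Returns NULL when no in-mask pair exists at this offset.
#' @keywords internal
.glcmMatrix <- function(q, mask, levels, dRow, dCol) {
    nr <- nrow(q); nc <- ncol(q)
    r1 <- max(1, 1 - dRow):min(nr, nr - dRow)
    c1 <- max(1, 1 - dCol):min(nc, nc - dCol)
    if (!length(r1) || !length(c1)) return(NULL)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dRow, c1 + dCol, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dRow, c1 + dCol, drop = FALSE]
    if (!any(ok)) return(NULL)
    ai <- a[ok]; bi <- b[ok]
    cnt <- tabulate(ai + levels * (bi - 1L), nbins = levels * levels)
    C <- matrix(cnt, levels, levels)
    C <- C + t(C)
    C / sum(C)
}

#' Haralick parameters of a normalized co-occurrence matrix
#' @keywords internal
.glcmFeatures <- function(P) {
    lv <- nrow(P)
    I <- row(P); J <- col(P)
    mu_i <- sum(P * I); mu_j <- sum(P * J)
    var_i <- sum(P * (I - mu_i)^2); var_j <- sum(P * (J - mu_j)^2)
    corr <- if (var_i > 0 && var_j > 0)
        (sum(P * I * J) - mu_i * mu_j) / sqrt(var_i * var_j) else NA_real_
    pos <- P[P > 0]
    c(contrast = sum(P * (I - J)^2),
      correlation = corr,
      energy = sum(P^2),
      homogeneity = sum(P / (1 + (I - J)^2)),
      entropy = -sum(pos * log(pos)))
}

#' GLCM texture parameter profile over distances and directions
#'
#' For every offset distance (default 1..100 px) and each of the four
#' standard directions (0, 45, 90, 135 degrees), builds the symmetric,
#' normalized gray-level co-occurrence matrix over pixel pairs whose members
#' both lie in the mask, and computes five Haralick texture parameters:
#' contrast, correlation, energy (angular second moment), homogeneity
#' (inverse difference moment) and entropy - a 5 x 4 x D grid of values per
#' image.  Offsets with no in-mask pair are recorded as missing.
#'
#' @param image grayscale matrix (e.g. a maximum projection).
#' @param mask logical matrix; default from \code{\link{autoMask}}.
#' @param distances integer offset distances in pixels.
#' @param levels gray levels for quantization over the in-mask intensity
#'   range (default 64).
#' @return data.frame with columns \code{parameter}, \code{direction},
#'   \code{distance}, \code{value}.
#' @export
glcmProfile <- function(image, mask = NULL, distances = 1:100, levels = 64) {
    if (levels < 2) stop("levels must be >= 2")
    if (max(distances) >= min(dim(image)))
        stop("image smaller than the maximum offset distance")
    if (is.null(mask)) mask <- autoMask(image)$mask
    if (!any(mask)) stop("empty mask")
    q <- .quantizeLevels(image, mask, levels)
    # offsets in (row, col) terms for 0/45/90/135 degrees
    off <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                `135` = c(-1, -1))
    res <- vector("list", length(distances) * 4L)
    k <- 0L
    for (d in distances) for (ang in names(off)) {
        k <- k + 1L
        P <- .glcmMatrix(q, mask, levels, off[[ang]][1] * d, off[[ang]][2] * d)
        f <- if (is.null(P))
            stats::setNames(rep(NA_real_, 5), .glcmParameters)
        else .glcmFeatures(P)
        res[[k]] <- data.frame(parameter = .glcmParameters,
            direction = as.numeric(ang), distance = d, value = unname(f))
    }
    do.call(rbind, res)
}

#' Direction-averaged decay curves from a GLCM grid
#'
#' Averages each texture parameter over the four directions at every
#' distance, giving one value-vs-distance curve per parameter.
#'
#' @param grid data.frame from \code{\link{glcmProfile}}.
#' @return named list of data.frames (\code{distance}, \code{value}).
#' @export
decayCurves <- function(grid) {
    out <- lapply(split(grid, grid$parameter), function(g) {
        ag <- stats::aggregate(value ~ distance, data = g, FUN = mean,
                               na.rm = TRUE, na.action = stats::na.pass)
        ag[order(ag$distance), ]
    })
    out[.glcmParameters]
}

#' Double-exponential decay fit and weighted mean decay distance
#'
#' Least-squares fit of f(d) = A1 exp(-d/lambda1) + A2 exp(-d/lambda2) + c
#' with nonnegative amplitudes and positive decay scales (the offset c is
#' allowed but bounded by the curve range).  Ten multistarts with
#' log-uniform decay scales in [1, max distance] guard against local minima;
#' the best-residual fit is kept and components are ordered so
#' lambda1 <= lambda2.  The weighted mean decay distance is
#' (A1 lambda1 + A2 lambda2) / (A1 + A2) - the amplitude-weighted average
#' of the two scales, the scalar fibrillar-texture score - and is NA when
#' both amplitudes vanish (no decaying component; e.g. a rising curve).
#'
#' @param value,distance the decay curve (>= 8 points, finite values).
#' @param nStarts number of random multistarts.
#' @param seed integer seed for the multistarts.
#' @return list with \code{A1}, \code{lambda1}, \code{A2}, \code{lambda2},
#'   \code{c}, \code{weightedMeanDecayDistance}, \code{sse},
#'   \code{converged}.
#' @examples
#' d <- 1:50
#' decayFit(exp(-d / 2) + exp(-d / 10), d, seed = 1)$weightedMeanDecayDistance
#' @export
decayFit <- function(value, distance, nStarts = 10, seed = 1) {
    ok <- is.finite(value) & is.finite(distance)
    value <- value[ok]; distance <- distance[ok]
    if (length(value) < 8) stop("at least 8 finite curve points required")
    rngY <- range(value); spanY <- diff(rngY)
    if (spanY == 0) spanY <- max(abs(rngY[1]), 1e-12)
    maxD <- max(distance)
    # decay scales beyond the measured distance range are not identifiable
    lower <- c(A1 = 0, l1 = 0.1, A2 = 0, l2 = 0.1, c = rngY[1] - spanY)
    upper <- c(A1 = 10 * spanY, l1 = maxD, A2 = 10 * spanY,
               l2 = maxD, c = rngY[2] + spanY)
    resid <- function(p)
        value - (p[1] * exp(-distance / p[2]) + p[3] * exp(-distance / p[4]) +
                 p[5])
    # moment-style start: distance at which the normalized curve crosses 1/e
    rel <- (value - rngY[1]) / spanY
    l1e <- if (any(rel <= exp(-1))) distance[which(rel <= exp(-1))[1]]
           else maxD / 2
    starts <- list(c(l1e / 2, min(2 * l1e, maxD)),
                   c(l1e, min(4 * l1e, maxD)))
    best <- NULL
    .withSeed(seed, {
        for (s in seq_len(nStarts)) {
            l0 <- if (s <= length(starts)) starts[[s]]
                  else sort(exp(stats::runif(2, log(1), log(maxD))))
            a0 <- max(spanY, 1e-9)
            st <- c(A1 = a0 / 2, l1 = l0[1], A2 = a0 / 2, l2 = l0[2],
                    c = rngY[1])
            fit <- tryCatch(minpack.lm::nls.lm(par = st, fn = resid,
                lower = lower, upper = upper,
                control = minpack.lm::nls.lm.control(maxiter = 200)),
                error = function(e) NULL)
            if (is.null(fit)) next
            sse <- fit$deviance
            if (is.null(best) || sse < best$sse)
                best <- list(par = fit$par, sse = sse)
        }
    })
    if (is.null(best)) stop("decay fit failed for every start")
    p <- best$par
    if (p[["l1"]] > p[["l2"]])
        p[c("A1", "l1", "A2", "l2")] <- p[c("A2", "l2", "A1", "l1")]
    amp <- p[["A1"]] + p[["A2"]]
    wmdd <- if (amp > 1e-9 * spanY)
        (p[["A1"]] * p[["l1"]] + p[["A2"]] * p[["l2"]]) / amp else NA_real_
    list(A1 = p[["A1"]], lambda1 = p[["l1"]], A2 = p[["A2"]],
         lambda2 = p[["l2"]], c = p[["c"]],
         weightedMeanDecayDistance = wmdd, sse = best$sse, converged = TRUE)
}

#' Depth-resolved foreground profile of a stack
#'
#' Binarizes every slice by the chosen threshold rule and reports the
#' per-slice foreground percent and the stack-total foreground pixel count -
#' the depth-resolved fraction of cross-linked (fibrillar) collagen signal.
#' The default rule derives one global Otsu threshold from the pooled stack
#' and applies it to every slice; \code{"slice"} thresholds each slice
#' independently; \code{"fixed"} uses the supplied cutoff.
#'
#' @param stack numeric array height x width x depth.
#' @param rule "global", "slice", or "fixed".
#' @param threshold cutoff for \code{rule = "fixed"}.
#' @return list with \code{slice}, \code{count}, \code{percent},
#'   \code{totalForeground}.
#' @export
depthProfile <- function(stack, rule = c("global", "slice", "fixed"),
                         threshold = NULL) {
    rule <- match.arg(rule)
    if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
    d <- dim(stack)
    if (length(d) != 3 || d[3] < 1) stop("empty stack")
    thrGlobal <- NULL
    if (rule == "global") {
        rng <- range(stack)
        thrGlobal <- if (diff(rng) == 0) Inf
        else rng[1] + diff(rng) * EBImage::otsu(
            EBImage::Image((stack - rng[1]) / diff(rng)), range = c(0, 1),
            levels = 256)
    }
    counts <- vapply(seq_len(d[3]), function(s) {
        sl <- stack[, , s]
        mask <- switch(rule,
            global = sl > thrGlobal,
            slice = autoMask(sl)$mask,
            fixed = sl > threshold)
        sum(mask)
    }, numeric(1))
    list(slice = seq_len(d[3]), count = counts,
         percent = 100 * counts / (d[1] * d[2]),
         totalForeground = sum(counts))
}

#' Full texture analysis of an image stack
#'
#' Maximum projection, Otsu mask and area percent, GLCM parameter grid over
#' the requested distances and four directions, direction-averaged decay
#' curves, and a double-exponential decay fit per parameter.  The headline
#' weighted mean decay distance is taken from the Haralick correlation
#' parameter, whose curve decays from ~1 on the scale of the spatial
#' correlation length of the fibrillar signal; parameters whose curves do
#' not decay (e.g. contrast, which rises with offset distance) yield NA.
#'
#' @param stack numeric array height x width x depth.
#' @param distances GLCM offset distances (default 1..100 px).
#' @param levels gray levels (default 64).
#' @param seed integer seed for the fit multistarts.
#' @return a \linkS4class{TextureProfile}.
#' @export
analyzeStack <- function(stack, distances = 1:100, levels = 64, seed = 1) {
    proj <- maxProjection(stack)
    am <- autoMask(proj)
    grid <- glcmProfile(proj, am$mask, distances = distances, levels = levels)
    curves <- decayCurves(grid)
    fits <- lapply(curves, function(cu) {
        tryCatch(decayFit(cu$value, cu$distance, seed = seed),
                 error = function(e) NULL)
    })
    wmdd <- vapply(fits, function(f)
        if (is.null(f)) NA_real_ else f$weightedMeanDecayDistance, numeric(1))
    methods::new("TextureProfile", values = grid,
        fits = fits, meanDecayDistance = wmdd,
        areaPercent = am$areaPercent, levels = as.integer(levels))
}
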
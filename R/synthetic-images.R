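#' Simulate an SHG-like fibrillar collagen image stack
#'
#' Generates a depth stack of grayscale slices whose foreground consists of
#' oriented, anti-aliased fiber segments convolved with a Gaussian of scale
#' \code{correlationLengthPx}, giving the image a controllable spatial
#' autocorrelation length - the quantity the GLCM decay-distance analysis is
#' designed to recover.  Foreground is set by thresholding the blurred fiber
#' field at the pooled intensity quantile that realizes
#' \code{areaFractionTarget}, so the stack-level foreground area fraction
#' matches the target; Gaussian background noise is added on top.  This is a
#' statistical stand-in for second harmonic generation acquisitions, not an
#' optics model.
#'
#' @param width,height,depth stack dimensions in pixels / slices.
#' @param fiberCount fiber segments drawn per slice (0 gives a blank stack).
#' @param fiberWidthPx approximate fiber width before correlation smoothing.
#' @param correlationLengthPx Gaussian smoothing scale; the planted texture
#'   decay scale.
#' @param areaFractionTarget target foreground area fraction in (0, 1).
#' @param backgroundNoiseSd SD of additive background noise (intensity units,
#'   image range is [0, 1]).
#' @param bitDepth 8 or 16; recorded for TIFF serialization.
#' @param seed integer seed.
#' @return numeric array \code{height x width x depth} with values in
#'   [0, 1] and attribute \code{bitDepth}.
#' @examples
#' st <- generateShgStack(width = 64, height = 64, depth = 2,
#'                        fiberCount = 10, seed = 1)
#' dim(st)
#' @export
generateShgStack <- function(width = 256, height = 256, depth = 8,
        fiberCount = 40, fiberWidthPx = 2, correlationLengthPx = 6,
        areaFractionTarget = 0.2, backgroundNoiseSd = 0.01, bitDepth = 16,
        seed) {
    if (width < 1 || height < 1 || depth < 1) stop("zero stack dimensions")
    if (!bitDepth %in% c(8, 16)) stop("bitDepth must be 8 or 16")
    if (areaFractionTarget <= 0 || areaFractionTarget >= 1)
        stop("areaFractionTarget must lie in (0, 1)")
    .withSeed(seed, {
        field <- array(0, c(height, width, depth))
        for (s in seq_len(depth)) {
            sl <- matrix(0, height, width)
            for (f in seq_len(fiberCount)) {
                x0 <- stats::runif(1, 1, width); y0 <- stats::runif(1, 1, height)
                th <- stats::runif(1, 0, pi)
                len <- stats::runif(1, 0.3, 0.8) * min(width, height)
                tt <- seq(0, len, by = 0.35)
                xs <- x0 + tt * cos(th); ys <- y0 + tt * sin(th)
                ok <- xs >= 1 & xs <= width & ys >= 1 & ys <= height
                if (!any(ok)) next
                # bilinear splat for anti-aliasing
                xs <- xs[ok]; ys <- ys[ok]
                xf <- floor(xs); yf <- floor(ys)
                fx <- xs - xf; fy <- ys - yf
                for (dxy in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
                    cx <- pmin(xf + dxy[1], width)
                    cy <- pmin(yf + dxy[2], height)
                    w <- (if (dxy[1]) fx else 1 - fx) *
                         (if (dxy[2]) fy else 1 - fy)
                    idx <- cbind(cy, cx)
                    sl[idx] <- sl[idx] + w
                }
            }
            if (fiberWidthPx > 0.5)
                sl <- .gaussSmooth(sl, fiberWidthPx / 2)
            if (correlationLengthPx > 0)
                sl <- .gaussSmooth(sl, correlationLengthPx)
            field[, , s] <- sl
        }
        out <- array(0, c(height, width, depth))
        if (max(field) > 0) {
            thr <- stats::quantile(field, 1 - areaFractionTarget, names = FALSE)
            fg <- field > thr
            norm <- field / max(field)
            out[fg] <- 0.4 + 0.6 * norm[fg]
        }
        if (backgroundNoiseSd > 0)
            out <- out + array(stats::rnorm(length(out), 0, backgroundNoiseSd),
                               dim(out))
        out <- pmin(pmax(out, 0), 1)
        # quantize to the target bit depth so serialization round-trips
        scale <- 2^bitDepth - 1
        out <- round(out * scale) / scale
        attr(out, "bitDepth") <- bitDepth
        out
    })
}
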
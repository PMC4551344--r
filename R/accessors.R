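#' Construct an ExpressionCohort
#'
#' @param exprs numeric matrix, rows = probes/genes (rownames required),
#'   columns = samples (colnames required); log-scale expression.
#' @param time,event optional numeric vectors: survival time in months
#'   (strictly positive) and 0/1 event indicator.
#' @param batch optional per-sample batch label.
#' @param probeMap optional named character vector mapping row id -> gene
#'   symbol (names = row ids).  Rows absent from the map are treated as
#'   unmapped by \code{\link{collapseProbes}}.
#' @param metadata list of free-form metadata (e.g. simulation ground truth).
#' @return An \linkS4class{ExpressionCohort}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ExpressionCohort(m, time = 1:5, event = c(1, 0, 1, 1, 0))
#' @export
ExpressionCohort <- function(exprs, time = NULL, event = NULL, batch = NULL,
                             probeMap = NULL, metadata = list()) {
    exprs <- as.matrix(exprs)
    cd <- DataFrame(row.names = colnames(exprs))
    if (!is.null(time)) {
        stopifnot(length(time) == ncol(exprs), length(event) == ncol(exprs))
        cd$time <- as.numeric(time)
        cd$event <- as.integer(event)
    }
    if (!is.null(batch)) cd$batch <- batch
    rd <- DataFrame(row.names = rownames(exprs))
    if (!is.null(probeMap))
        rd$gene <- unname(probeMap[rownames(exprs)])
    se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd,
                               rowData = rd, metadata = metadata)
    methods::new("ExpressionCohort", se)
}

#' Accessors for ExpressionCohort
#'
#' \code{exprMatrix} returns the expression matrix; \code{survTime} and
#' \code{survEvent} the survival annotations (error if absent);
#' \code{sampleBatch} the batch labels or NULL; \code{probeMap} the named
#' probe-to-gene map or NULL; \code{cohortTruth} the simulation ground truth
#' stored by the generators, or NULL for real data.
#'
#' @param x an \linkS4class{ExpressionCohort}.
#' @return See description.
#' @name cohort-accessors
#' @aliases exprMatrix survTime survEvent sampleBatch probeMap cohortTruth
NULL

#' @rdname cohort-accessors
#' @export
exprMatrix <- function(x) assay(x, "exprs")

#' @rdname cohort-accessors
#' @export
survTime <- function(x) {
    if (!"time" %in% colnames(colData(x)))
        stop("cohort carries no survival annotations")
    colData(x)$time
}

#' @rdname cohort-accessors
#' @export
survEvent <- function(x) {
    if (!"event" %in% colnames(colData(x)))
        stop("cohort carries no survival annotations")
    colData(x)$event
}

#' @rdname cohort-accessors
#' @export
sampleBatch <- function(x) {
    if ("batch" %in% colnames(colData(x))) colData(x)$batch else NULL
}

#' @rdname cohort-accessors
#' @export
probeMap <- function(x) {
    g <- rowData(x)$gene
    if (is.null(g)) return(NULL)
    stats::setNames(g, rownames(x))
}

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(x) metadata(x)$groundTruth

#' Replace the expression matrix of a cohort, keeping annotations
#' @param x an ExpressionCohort
#' @param m replacement matrix whose columns match \code{colnames(x)}
#' @keywords internal
.replaceMatrix <- function(x, m) {
    pm <- probeMap(x)
    ExpressionCohort(m,
        time = if ("time" %in% colnames(colData(x))) colData(x)$time,
        event = if ("event" %in% colnames(colData(x))) colData(x)$event,
        batch = sampleBatch(x),
        probeMap = if (!is.null(pm)) pm[intersect(names(pm), rownames(m))],
        metadata = as.list(metadata(x)))
}

#' Accessors for SignatureModel and ScoreTable
#'
#' @param x a \linkS4class{SignatureModel} or \linkS4class{ScoreTable}.
#' @return \code{signatureLoadings}: named numeric loadings;
#'   \code{hazardousSet}/\code{protectiveSet}: transcript id vectors;
#'   \code{signatureOrientation}: +1/-1; \code{scores}: named numeric
#'   per-sample scores; \code{scoreStrata}: named stratum labels;
#'   \code{matchedGeneFraction}: scalar fraction in (0, 1].
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
signatureLoadings <- function(x) stats::setNames(x@loadings, x@transcriptIds)

#' @rdname model-accessors
#' @export
hazardousSet <- function(x) x@hazardousSet

#' @rdname model-accessors
#' @export
protectiveSet <- function(x) x@protectiveSet

#' @rdname model-accessors
#' @export
signatureOrientation <- function(x) x@orientation

#' @rdname model-accessors
#' @export
scores <- function(x) stats::setNames(x@score, x@sampleIds)

#' @rdname model-accessors
#' @export
scoreStrata <- function(x) stats::setNames(x@stratum, x@sampleIds)

#' @rdname model-accessors
#' @export
matchedGeneFraction <- function(x) x@matchedGeneFraction

#' Accessors for GeneSetCollection
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @return \code{geneSets}: the named list of member vectors;
#'   \code{setUniverse}: the universe (possibly empty).
#' @name geneset-accessors
NULL

#' @rdname geneset-accessors
#' @export
geneSets <- function(x) x@sets

#' @rdname geneset-accessors
#' @export
setUniverse <- function(x) x@universe

#' Accessors for TextureProfile
#'
#' @param x a \linkS4class{TextureProfile}.
#' @return \code{textureValues}: long data.frame of raw GLCM parameter
#'   values; \code{decayFits}: per-parameter fit results;
#'   \code{meanDecayDistance}: named weighted mean decay distances in px;
#'   \code{areaPercent}: thresholded foreground area percent.
#' @name texture-accessors
NULL

#' @rdname texture-accessors
#' @export
textureValues <- function(x) x@values

#' @rdname texture-accessors
#' @export
decayFits <- function(x) x@fits

#' @rdname texture-accessors
#' @export
meanDecayDistance <- function(x) x@meanDecayDistance

#' @rdname texture-accessors
#' @export
areaPercent <- function(x) x@areaPercent
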
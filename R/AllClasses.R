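#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   colData<- rowData<-
NULL

#' Expression cohort with survival annotations
#'
#' An \code{ExpressionCohort} holds a log-scale expression matrix (rows =
#' probes or genes, columns = samples) together with per-sample survival
#' annotations (follow-up time in months and a 0/1 event indicator), an
#' optional batch label and an optional probe-to-gene map.  It extends
#' \linkS4class{SummarizedExperiment}: the matrix lives in the \code{"exprs"}
#' assay, survival annotations in \code{colData}, and the probe map in
#' \code{rowData$gene}.
#'
#' Validity requires a numeric matrix without missing values, unique row
#' identifiers, and (when survival columns are present) strictly positive
#' times and events in \{0, 1\}.  Cohorts with a binary outcome instead of
#' survival (for example cross-species metastasis cohorts) simply omit the
#' \code{time}/\code{event} columns.
#'
#' @seealso \code{\link{ExpressionCohort}} for the constructor,
#'   \code{\link{exprMatrix}}, \code{\link{survTime}}, \code{\link{survEvent}},
#'   \code{\link{probeMap}}.
#' @name ExpressionCohort-class
#' @exportClass ExpressionCohort
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- assay(object, "exprs")
        if (!is.numeric(m)) msg <- c(msg, "'exprs' must be numeric")
        if (anyNA(m) || any(!is.finite(m)))
            msg <- c(msg, "'exprs' must not contain missing or non-finite values")
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "row identifiers must be present and unique")
    }
    cd <- colData(object)
    if ("time" %in% colnames(cd)) {
        if (anyNA(cd$time) || any(cd$time <= 0))
            msg <- c(msg, "'time' must be positive")
        if (!"event" %in% colnames(cd) || !all(cd$event %in% c(0L, 1L)))
            msg <- c(msg, "'event' must accompany 'time' and lie in {0, 1}")
    }
    if (length(msg)) msg else TRUE
})

#' Fitted survival-signature model
#'
#' Artifact of signature discovery: the selected transcripts, their
#' first-component (or chosen-component) loadings, the orientation chosen so
#' that a higher score means higher hazard, and the resulting partition into
#' hazardous (oriented loading > 0) and protective transcripts.
#'
#' @slot transcriptIds character, the selected transcripts.
#' @slot loadings named numeric, one loading per transcript.
#' @slot componentIndex integer, which principal component the model uses.
#' @slot orientation +1 or -1; \code{orientation * loadings} is hazard-positive.
#' @slot hazardousSet,protectiveSet character; disjoint, exhaustive partition.
#' @slot trainingSummary list of training diagnostics (cross-validated
#'   association statistic and p-value, variance explained, selection size).
#' @name SignatureModel-class
#' @exportClass SignatureModel
setClass("SignatureModel",
    representation(transcriptIds = "character", loadings = "numeric",
        componentIndex = "integer", orientation = "numeric",
        hazardousSet = "character", protectiveSet = "character",
        trainingSummary = "list"))

setValidity("SignatureModel", function(object) {
    msg <- character()
    if (length(object@loadings) != length(object@transcriptIds))
        msg <- c(msg, "one loading per transcript required")
    if (!identical(sort(c(object@hazardousSet, object@protectiveSet)),
                   sort(object@transcriptIds)))
        msg <- c(msg, "hazardous/protective sets must partition the transcripts")
    if (length(intersect(object@hazardousSet, object@protectiveSet)))
        msg <- c(msg, "hazardous and protective sets must be disjoint")
    if (!object@orientation %in% c(-1, 1))
        msg <- c(msg, "orientation must be +1 or -1")
    or <- object@orientation * object@loadings
    if (any(or[object@transcriptIds %in% object@hazardousSet] <= 0))
        msg <- c(msg, "hazardous transcripts must have positive oriented loading")
    if (length(msg)) msg else TRUE
})

#' Named gene-set collection
#'
#' Thin S4 container for a GMT-style collection: a named list of character
#' member vectors plus an optional universe.  Set names must be unique and
#' members non-empty.
#'
#' @slot sets named list of character vectors.
#' @slot universe optional character vector of all scoreable genes.
#' @name GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
    representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (is.null(nm) || anyDuplicated(nm)) msg <- c(msg, "set names must be unique")
    if (any(lengths(object@sets) == 0)) msg <- c(msg, "sets must be non-empty")
    if (!all(vapply(object@sets, is.character, logical(1))))
        msg <- c(msg, "set members must be character vectors")
    if (length(msg)) msg else TRUE
})

#' Per-sample score table
#'
#' Scalar per-sample scores (risk or hypoxia) together with the fraction of
#' signature genes that matched the cohort and optional stratum labels.
#'
#' @slot sampleIds character sample identifiers.
#' @slot score numeric, one finite score per sample; because every gene is
#'   centered across samples before weighting, scores sum to (numerically)
#'   zero within a cohort.
#' @slot matchedGeneFraction fraction of signature genes found in the cohort.
#' @slot stratum character labels ("low"/"mid"/"high", ...) or NA before
#'   stratification.
#' @name ScoreTable-class
#' @exportClass ScoreTable
setClass("ScoreTable",
    representation(sampleIds = "character", score = "numeric",
        matchedGeneFraction = "numeric", stratum = "character"))

setValidity("ScoreTable", function(object) {
    msg <- character()
    n <- length(object@sampleIds)
    if (length(object@score) != n || length(object@stratum) != n)
        msg <- c(msg, "score and stratum must match sampleIds in length")
    if (any(!is.finite(object@score))) msg <- c(msg, "scores must be finite")
    f <- object@matchedGeneFraction
    if (length(f) != 1 || is.na(f) || f <= 0 || f > 1)
        msg <- c(msg, "matchedGeneFraction must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' GLCM texture profile of an image
#'
#' Raw gray-level co-occurrence texture parameter values indexed by
#' (parameter, direction, distance), together with the direction-averaged
#' decay curves, double-exponential fits per parameter, the weighted mean
#' decay distance of the headline parameter, and the foreground area percent.
#'
#' @slot values data.frame with columns parameter, direction (degrees),
#'   distance (px), value.
#' @slot fits named list of decay-fit results (see \code{\link{decayFit}}).
#' @slot meanDecayDistance named numeric, weighted mean decay distance (px)
#'   per parameter (NA where the decay model does not apply).
#' @slot areaPercent foreground area of the thresholded max projection, in
#'   percent.
#' @slot levels number of gray levels used for quantization.
#' @name TextureProfile-class
#' @exportClass TextureProfile
setClass("TextureProfile",
    representation(values = "data.frame", fits = "list",
        meanDecayDistance = "numeric", areaPercent = "numeric",
        levels = "integer"))

setMethod("show", "ExpressionCohort", function(object) {
    cat("ExpressionCohort:", nrow(object), "features x", ncol(object),
        "samples\n")
    cd <- colData(object)
    if ("time" %in% colnames(cd))
        cat(sprintf("  survival: median time %.1f, %d events / %d samples\n",
            stats::median(cd$time), sum(cd$event), ncol(object)))
    if ("batch" %in% colnames(cd))
        cat("  batches:", length(unique(cd$batch)), "\n")
    if (!is.null(rowData(object)$gene))
        cat("  probe->gene map present\n")
})

setMethod("show", "SignatureModel", function(object) {
    cat("SignatureModel: component", object@componentIndex, "with",
        length(object@transcriptIds), "transcripts\n")
    cat("  hazardous:", length(object@hazardousSet),
        " protective:", length(object@protectiveSet),
        " orientation:", object@orientation, "\n")
    ts <- object@trainingSummary
    if (length(ts))
        cat("  training:", paste(names(ts), vapply(ts, function(x)
            paste(format(x, digits = 4), collapse = ","), ""), sep = "=",
            collapse = "  "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "sets, ",
        length(unique(unlist(object@sets))), "distinct genes\n")
})

setMethod("show", "ScoreTable", function(object) {
    cat("ScoreTable:", length(object@sampleIds), "samples; matched gene",
        sprintf("fraction %.3f\n", object@matchedGeneFraction))
    if (!all(is.na(object@stratum)))
        print(table(object@stratum, useNA = "no"))
})

setMethod("show", "TextureProfile", function(object) {
    cat("TextureProfile:", nrow(object@values), "parameter values;",
        sprintf("area %.1f%%\n", object@areaPercent))
    md <- object@meanDecayDistance
    cat("  weighted mean decay distance (px):",
        paste(names(md), format(md, digits = 4), sep = "=", collapse = "  "),
        "\n")
})
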
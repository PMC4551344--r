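#' Risk-score a cohort with a fitted signature
#'
#' Expression of each signature transcript found in the cohort is
#' mean-centered across samples and scaled to unit variance; the per-sample
#' risk score is the sum over matched transcripts of the standardized value
#' multiplied by the transcript's (oriented) signature loading.  Symbols are
#' matched case-insensitively (optionally through a user-supplied ortholog
#' table), so a human signature can score mouse cohorts; unmatched
#' transcripts are dropped and the matched fraction is reported.  Matched
#' genes with zero variance in the target cohort are dropped with a warning.
#'
#' @param cohort an \linkS4class{ExpressionCohort} with at least 2 samples.
#' @param signature a \linkS4class{SignatureModel}.
#' @param orthologTable optional 2-column data.frame (from, to) translating
#'   signature symbols before matching.
#' @return a \linkS4class{ScoreTable}; scores sum to (numerically) zero
#'   across the cohort because every gene is centered.
#' @export
riskScore <- function(cohort, signature, orthologTable = NULL) {
    m <- exprMatrix(cohort)
    if (ncol(m) < 2) stop("risk scoring needs at least 2 samples")
    ids <- signature@transcriptIds
    w <- signature@orientation * signature@loadings
    lookup <- ids
    if (!is.null(orthologTable)) {
        hit <- .matchSymbols(lookup, orthologTable[[1]])
        lookup[!is.na(hit)] <- orthologTable[[2]][hit[!is.na(hit)]]
    }
    idx <- .matchSymbols(lookup, rownames(m))
    matched <- !is.na(idx)
    if (!any(matched)) stop("no signature gene matches the cohort")
    sub <- m[idx[matched], , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " matched gene(s) with zero variance dropped")
        sub <- sub[sds > 0, , drop = FALSE]
        wUse <- w[matched][sds > 0]
        if (!nrow(sub)) stop("no scoreable signature gene left")
    } else wUse <- w[matched]
    z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
    sc <- drop(crossprod(z, wUse))
    methods::new("ScoreTable", sampleIds = colnames(m), score = unname(sc),
        matchedGeneFraction = mean(matched),
        stratum = rep(NA_character_, ncol(m)))
}

#' Build a hypoxia meta-signature from a gene-set collection
#'
#' Selects the collection's sets whose names contain \code{nameToken}
#' (case-insensitive) and returns the genes present in strictly more than
#' \code{minFraction} of them, together with the number of matching sets and
#' the size of their gene union.  With a curated pathway collection and the
#' default token this reproduces the construction that yields a compact
#' hypoxia meta-signature from the pool of hypoxia-named sets.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param nameToken token identifying hypoxia sets (default "HYPOXIA").
#' @param minFraction membership-fraction cutoff; strict ">" is used, so a
#'   gene in exactly 20\% of the sets is excluded at the default 0.20.
#' @return list with \code{genes}, \code{nSets}, \code{unionSize}.
#' @export
buildHypoxiaMetasignature <- function(collection, nameToken = "HYPOXIA",
                                      minFraction = 0.20) {
    sets <- geneSets(collection)
    hyp <- sets[grepl(nameToken, names(sets), ignore.case = TRUE)]
    if (!length(hyp)) stop("no matching sets for token '", nameToken, "'")
    uni <- unique(unlist(hyp))
    cnt <- table(unlist(lapply(hyp, unique)))
    genes <- names(cnt)[cnt / length(hyp) > minFraction]
    list(genes = sort(genes), nSets = length(hyp), unionSize = length(uni))
}

#' Score samples on a hypoxia meta-signature by PCA
#'
#' Restricts the cohort to the meta-signature genes (case-insensitive
#' match), mean-centers each gene across samples, and computes the first
#' principal axis of the centered matrix.  Per-sample scores are the sample
#' coordinates on that axis; the gene-side weights carry the sign rule: if
#' the anchor gene's weight is negative the whole component (weights and
#' scores) is flipped, so increased anchor expression (VEGFA, a canonical
#' hypoxia-induced transcript) always increases the score.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param metasignature character vector of meta-signature genes (or the
#'   list from \code{\link{buildHypoxiaMetasignature}}).
#' @param anchorGene gene anchoring the sign (default "VEGFA"); an error is
#'   raised if it is absent from the cohort or the meta-signature, since the
#'   sign rule cannot be applied.
#' @return a \linkS4class{ScoreTable} with attribute \code{"geneWeights"}
#'   (the oriented gene-side weights).
#' @export
hypoxiaScore <- function(cohort, metasignature, anchorGene = "VEGFA") {
    if (is.list(metasignature)) metasignature <- metasignature$genes
    if (is.na(.matchSymbols(anchorGene, metasignature)))
        stop("anchor gene '", anchorGene, "' is not in the meta-signature")
    m <- exprMatrix(cohort)
    idx <- .matchSymbols(metasignature, rownames(m))
    present <- metasignature[!is.na(idx)]
    if (length(present) < 2) stop("fewer than 2 meta-signature genes present")
    if (is.na(.matchSymbols(anchorGene, present)))
        stop("anchor gene '", anchorGene, "' is absent from the cohort")
    sub <- m[idx[!is.na(idx)], , drop = FALSE]
    mc <- sub - rowMeans(sub)
    sv <- svd(mc, nu = 1, nv = 1)
    wts <- stats::setNames(drop(sv$u), present)
    sc <- drop(crossprod(mc, sv$u))
    aw <- wts[[which(!is.na(.matchSymbols(present, anchorGene)))[1]]]
    if (aw < 0) { wts <- -wts; sc <- -sc }
    st <- methods::new("ScoreTable", sampleIds = colnames(m),
        score = unname(sc),
        matchedGeneFraction = length(present) / length(metasignature),
        stratum = rep(NA_character_, ncol(m)))
    attr(st, "geneWeights") <- wts
    st
}

#' Stratify scores into labelled groups
#'
#' Assigns stratum labels by empirical quantiles (type-7, the linear
#' interpolation default).  Schemes: \code{"tertile"} (low/mid/high by
#' thirds), \code{"quartile_extremes"} (top and bottom quartile, middle
#' half labelled "mid"), \code{"quantile_extremes"} with explicit
#' \code{qLow}/\code{qHigh}, and \code{"median"} (low/high split).  "mid"
#' samples are intended to be excluded from two-group comparisons.
#'
#' @param scoreTable a \linkS4class{ScoreTable}.
#' @param scheme one of "tertile", "quartile_extremes", "quantile_extremes",
#'   "median".
#' @param qLow,qHigh quantile bounds for \code{"quantile_extremes"}.
#' @return the \linkS4class{ScoreTable} with stratum labels filled in.
#' @export
stratifyScores <- function(scoreTable,
        scheme = c("tertile", "quartile_extremes", "quantile_extremes",
                   "median"), qLow = 0.25, qHigh = 0.75) {
    scheme <- match.arg(scheme)
    s <- scoreTable@score
    nGroups <- if (scheme == "median") 2 else 3
    if (length(s) < nGroups) stop("fewer samples than groups")
    if (length(unique(s)) == 1) stop("degenerate quantiles: all scores equal")
    lab <- switch(scheme,
        tertile = {
            q <- stats::quantile(s, c(1, 2) / 3, type = 7, names = FALSE)
            ifelse(s <= q[1], "low", ifelse(s > q[2], "high", "mid"))
        },
        quartile_extremes = ,
        quantile_extremes = {
            if (scheme == "quartile_extremes") { qLow <- 0.25; qHigh <- 0.75 }
            q <- stats::quantile(s, c(qLow, qHigh), type = 7, names = FALSE)
            ifelse(s <= q[1], "low", ifelse(s > q[2], "high", "mid"))
        },
        median = {
            qm <- stats::quantile(s, 0.5, type = 7, names = FALSE)
            ifelse(s <= qm, "low", "high")
        })
    if (length(unique(lab[lab != "mid"])) < 2)
        stop("degenerate quantiles: a stratum is empty")
    methods::initialize(scoreTable, stratum = lab)
}
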
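#' Simulate a survival cohort with planted metagene structure
#'
#' Generates a post-normalization, log-scale expression cohort carrying a
#' latent-factor structure and exponential proportional-hazards survival, the
#' statistical setting assumed by the metagene discovery pipeline.  A set of
#' \code{nSignatureGenes} "signature" genes loads on latent factor 1; the
#' per-sample hazard is \code{baselineHazard * exp(hazardCoefficient * f1)}
#' with \code{f1 ~ N(0, 1)}, so \code{hazardCoefficient} is the log-hazard
#' per SD of the planted factor.  Additional latent factors (2..latentDim)
#' load on random gene subsets and create correlated but survival-neutral
#' background structure.  Censoring is independent exponential, with its rate
#' solved numerically so that the expected censored fraction equals
#' \code{censoringRate} given the realized hazards.  Optional batches add
#' gene-wise constant shifts, mimicking residual array batch structure after
#' normalization.
#'
#' Defaults emulate a resected-PDAC microarray cohort: 73 patients, a few
#' thousand variance-filtered transcripts, a baseline hazard giving a median
#' survival of about 18 months, and roughly 30\% censoring.
#'
#' The simulation ground truth (signature gene ids, their factor-1 loadings
#' and the per-sample latent factor) is stored in the cohort metadata and
#' retrieved with \code{\link{cohortTruth}}; parameter-recovery tests compare
#' pipeline output against it.
#'
#' @param nSamples,nGenes,nSignatureGenes cohort dimensions;
#'   \code{nSignatureGenes <= nGenes}.
#' @param latentDim number of latent factors (factor 1 carries the hazard).
#' @param loadingScale SD of the non-zero factor loadings.
#' @param hazardCoefficient log-hazard ratio per SD of factor 1 (0 = null).
#' @param baselineHazard baseline event rate per month.
#' @param censoringRate target censored fraction in [0, 1].
#' @param nBatches,batchShiftSd number of batches and SD of the gene-wise
#'   additive batch shifts (0 disables batch structure).
#' @param noiseSd SD of i.i.d. Gaussian measurement noise.
#' @param probesPerGene if > 1, each gene is emitted as this many probe rows
#'   (independent noise per probe) plus a probe-to-gene map, to exercise
#'   probe collapsing.
#' @param seed integer; the generator is a pure function of its arguments
#'   including the seed.
#' @return An \linkS4class{ExpressionCohort} with survival annotations and
#'   ground truth in \code{metadata}.
#' @examples
#' co <- generateSurvivalCohort(nSamples = 40, nGenes = 200,
#'                              nSignatureGenes = 30, seed = 1)
#' str(cohortTruth(co)$signatureGenes)
#' @export
generateSurvivalCohort <- function(nSamples = 73, nGenes = 2000,
        nSignatureGenes = 300, latentDim = 3, loadingScale = 1,
        hazardCoefficient = 1, baselineHazard = log(2) / 18,
        censoringRate = 0.3, nBatches = 1, batchShiftSd = 0, noiseSd = 1,
        probesPerGene = 1, seed) {
    if (nSamples < 2 || nGenes < 1 || nSignatureGenes < 1 || latentDim < 1)
        stop("dimensions must be positive (and nSamples >= 2)")
    if (nSignatureGenes > nGenes)
        stop("nSignatureGenes must not exceed nGenes")
    if (censoringRate < 0 || censoringRate >= 1)
        stop("censoringRate must lie in [0, 1)")
    if (baselineHazard <= 0 || noiseSd <= 0 || loadingScale <= 0)
        stop("baselineHazard, noiseSd and loadingScale must be positive")
    .withSeed(seed, {
        genes <- sprintf("GENE%04d", seq_len(nGenes))
        samples <- sprintf("S%03d", seq_len(nSamples))
        fac <- matrix(stats::rnorm(latentDim * nSamples), latentDim, nSamples)
        sig <- sort(sample.int(nGenes, nSignatureGenes))
        L <- matrix(0, nGenes, latentDim)
        L[sig, 1L] <- stats::rnorm(nSignatureGenes, 0, loadingScale)
        if (latentDim > 1) for (k in 2:latentDim)
            L[sample.int(nGenes, nSignatureGenes), k] <-
                stats::rnorm(nSignatureGenes, 0, loadingScale)
        expr <- L %*% fac
        batch <- NULL
        if (nBatches > 1) {
            batch <- rep_len(seq_len(nBatches), nSamples)
            shifts <- matrix(stats::rnorm(nGenes * nBatches, 0, batchShiftSd),
                             nGenes, nBatches)
            expr <- expr + shifts[, batch]
        }
        haz <- baselineHazard * exp(hazardCoefficient * fac[1L, ])
        tEvent <- stats::rexp(nSamples, haz)
        if (censoringRate > 0) {
            # solve E[c / (c + h)] = censoringRate for the censoring rate c
            f <- function(lc) mean(exp(lc) / (exp(lc) + haz)) - censoringRate
            lc <- stats::uniroot(f, lower = log(baselineHazard) - 20,
                                 upper = log(baselineHazard) + 20)$root
            tCens <- stats::rexp(nSamples, exp(lc))
        } else tCens <- rep(Inf, nSamples)
        time <- pmin(tEvent, tCens)
        event <- as.integer(tEvent <= tCens)
        if (probesPerGene > 1) {
            rows <- rep(seq_len(nGenes), each = probesPerGene)
            probeIds <- sprintf("%s_P%d", genes[rows],
                                rep(seq_len(probesPerGene), nGenes))
            m <- expr[rows, , drop = FALSE] +
                matrix(stats::rnorm(length(rows) * nSamples, 0, noiseSd),
                       length(rows), nSamples)
            dimnames(m) <- list(probeIds, samples)
            pm <- stats::setNames(genes[rows], probeIds)
        } else {
            m <- expr + matrix(stats::rnorm(nGenes * nSamples, 0, noiseSd),
                               nGenes, nSamples)
            dimnames(m) <- list(genes, samples)
            pm <- NULL
        }
        truth <- list(signatureGenes = genes[sig],
            loadings = stats::setNames(L[sig, 1L], genes[sig]),
            factor = stats::setNames(fac[1L, ], samples),
            params = list(hazardCoefficient = hazardCoefficient,
                baselineHazard = baselineHazard,
                censoringRate = censoringRate, seed = seed))
        ExpressionCohort(m, time = time, event = event, batch = batch,
            probeMap = pm, metadata = list(groundTruth = truth))
    })
}

#' Simulate a second-species cohort scored against a fitted signature
#'
#' Emulates applying a human tumor signature to mouse tumor expression
#' profiles with a binary metastasis outcome.  Signature gene symbols are
#' carried over under the other species' case convention (title case), a
#' random \code{1 - mappingRate} fraction is dropped (no ortholog), and
#' hazardous-set genes are shifted upward by \code{effect} SD units in
#' metastatic samples; protective genes and background genes are untouched.
#'
#' @param signature a \linkS4class{SignatureModel}.
#' @param nSamples number of tumors.
#' @param mappingRate fraction of signature genes with an ortholog, in
#'   (0, 1].
#' @param effect shift (in SD units, the per-gene noise SD is 1) applied to
#'   hazardous genes in metastatic samples.
#' @param metastaticFraction fraction of samples labelled metastatic.
#' @param nBackgroundGenes unrelated genes added to the matrix.
#' @param seed integer seed.
#' @return An \linkS4class{ExpressionCohort} without survival columns; the
#'   metastasis label is in \code{colData(x)$metastatic} and the ground truth
#'   (mapped genes, labels) in \code{metadata}.
#' @export
generateOrthologCohort <- function(signature, nSamples = 20, mappingRate = 1,
        effect = 0, metastaticFraction = 0.5, nBackgroundGenes = 100, seed) {
    if (!length(signature@transcriptIds)) stop("empty signature")
    if (mappingRate <= 0 || mappingRate > 1)
        stop("mappingRate must lie in (0, 1]")
    .withSeed(seed, {
        ids <- signature@transcriptIds
        nKeep <- round(mappingRate * length(ids))
        if (nKeep < 1) stop("mappingRate keeps no signature genes")
        kept <- sort(sample.int(length(ids), nKeep))
        # title-case the symbols, mimicking mouse gene nomenclature
        mouse <- paste0(toupper(substr(ids[kept], 1, 1)),
                        tolower(substring(ids[kept], 2)))
        bg <- sprintf("Bgene%04d", seq_len(nBackgroundGenes))
        samples <- sprintf("M%03d", seq_len(nSamples))
        met <- rep(FALSE, nSamples)
        met[sample.int(nSamples, round(metastaticFraction * nSamples))] <- TRUE
        m <- matrix(stats::rnorm((nKeep + nBackgroundGenes) * nSamples),
                    nKeep + nBackgroundGenes, nSamples,
                    dimnames = list(c(mouse, bg), samples))
        hazIdx <- which(ids[kept] %in% signature@hazardousSet)
        if (length(hazIdx) && any(met))
            m[hazIdx, met] <- m[hazIdx, met] + effect
        co <- ExpressionCohort(m, metadata = list(groundTruth = list(
            mappedGenes = ids[kept], mouseSymbols = mouse,
            metastatic = stats::setNames(met, samples),
            params = list(mappingRate = mappingRate, effect = effect,
                          seed = seed))))
        colData(co)$metastatic <- met
        methods::validObject(co)
        co
    })
}
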
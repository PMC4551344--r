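#' Variance filter
#'
#' Retains the \code{keepFraction} of rows with the highest across-sample
#' variance, preserving the original row order of the retained rows.
#'
#' @param cohort an \linkS4class{ExpressionCohort} with at least 2 samples.
#' @param keepFraction fraction of rows to keep, in (0, 1].
#' @return filtered \linkS4class{ExpressionCohort}.
#' @export
varianceFilter <- function(cohort, keepFraction = 0.5) {
    if (keepFraction <= 0 || keepFraction > 1)
        stop("keepFraction must lie in (0, 1]")
    m <- exprMatrix(cohort)
    if (ncol(m) < 2) stop("variance undefined with fewer than 2 samples")
    if (keepFraction == 1) return(cohort)
    v <- .rowVars(m)
    nKeep <- max(1L, floor(keepFraction * nrow(m)))
    keep <- sort(order(v, decreasing = TRUE)[seq_len(nKeep)])
    .replaceMatrix(cohort, m[keep, , drop = FALSE])
}

#' Collapse probes to genes by highest-variance probe
#'
#' For each gene in the probe-to-gene map, keeps the probe with the highest
#' across-sample variance and renames the row to the gene symbol.  Variance
#' ties are broken toward the lexicographically smallest probe id.  Probes
#' absent from the map are dropped with a message reporting the count.
#'
#' @param cohort an \linkS4class{ExpressionCohort} whose \code{probeMap} is
#'   set.
#' @return a gene-level \linkS4class{ExpressionCohort} (no probe map).
#' @export
collapseProbes <- function(cohort) {
    pm <- probeMap(cohort)
    if (is.null(pm) || !length(pm)) stop("cohort has no probe-to-gene map")
    m <- exprMatrix(cohort)
    mapped <- rownames(m)[!is.na(pm[rownames(m)])]
    nDropped <- nrow(m) - length(mapped)
    if (nDropped > 0)
        message(nDropped, " unmapped probe(s) dropped")
    if (!length(mapped)) stop("no probe maps to a gene")
    m <- m[mapped, , drop = FALSE]
    v <- .rowVars(m)
    # stable pick: order by gene, then decreasing variance, then probe id
    ord <- order(pm[mapped], -v, mapped)
    pick <- ord[!duplicated(pm[mapped][ord])]
    out <- m[pick, , drop = FALSE]
    rownames(out) <- unname(pm[mapped][pick])
    co <- ExpressionCohort(out,
        time = if ("time" %in% colnames(colData(cohort))) survTime(cohort),
        event = if ("event" %in% colnames(colData(cohort))) survEvent(cohort),
        batch = sampleBatch(cohort), metadata = as.list(metadata(cohort)))
    co
}

#' Survival-screening weights shared by all transcripts
#'
#' The FAST statistic is linear in the standardized expression vector:
#' s = z . v / n, where v depends only on (time, event).  Computing v once
#' lets the permutation screen reuse one permutation stream across all
#' transcripts as a single matrix product.
#' @keywords internal
.fastWeights <- function(time, event) {
    n <- length(time)
    stopifnot(length(event) == n)
    if (!any(event == 1)) stop("no events: screening statistic undefined")
    v <- numeric(n)
    for (i in which(event == 1)) {
        risk <- time >= time[i]   # ties stay in the risk set (Breslow)
        v[i] <- v[i] + 1
        v[risk] <- v[risk] - 1 / sum(risk)
    }
    v
}

#' FAST univariate survival-screening statistic
#'
#' For standardized expression z (mean 0, SD 1 across samples), returns
#' (1/n) * sum over event times t_i of (z_i - mean of z over the risk set
#' \{j : t_j >= t_i\}).  This equals the Cox partial-likelihood score at
#' beta = 0 for the standardized covariate, divided by n; positive values
#' mean higher expression is hazardous.  Constant expression returns 0 with
#' a warning (the z-score is undefined, and a constant carries no survival
#' information).
#'
#' @param x numeric expression vector, one value per sample.
#' @param time,event survival times (months) and 0/1 event indicators.
#' @return scalar statistic.
#' @examples
#' fastStatistic(c(4, 3, 2, 1), time = 1:4, event = rep(1, 4))
#' @export
fastStatistic <- function(x, time, event) {
    n <- length(x)
    stopifnot(length(time) == n, length(event) == n)
    v <- .fastWeights(time, event)
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
        warning("zero-variance expression: statistic defined as 0")
        return(0)
    }
    z <- (x - mean(x)) / s
    sum(z * v) / n
}

#' Permutation p-values for the FAST screen
#'
#' Jointly permutes the (time, event) pairs against the samples and
#' recomputes the statistic for every transcript under each permutation; the
#' same permutation stream is shared across transcripts, so duplicate rows
#' receive identical p-values.  Two-sided add-one p-values:
#' p = (1 + #\{|s*| >= |s_obs|\}) / (nPerm + 1), never zero.
#'
#' @param mat numeric matrix, transcripts x samples.
#' @param time,event survival annotations.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return list with \code{statistic} (observed per transcript) and \code{p}.
#' @export
permutationPvalues <- function(mat, time, event, nPerm = 10000, seed) {
    if (nPerm < 1) stop("nPerm must be at least 1")
    n <- ncol(mat)
    stopifnot(length(time) == n, length(event) == n)
    v <- .fastWeights(time, event)
    Z <- .rowZ(mat, warn = TRUE)
    obs <- drop(Z %*% v) / n
    absObs <- abs(obs)
    cnt <- integer(nrow(mat))
    .withSeed(seed, {
        chunk <- 2000L
        done <- 0L
        while (done < nPerm) {
            b <- min(chunk, nPerm - done)
            P <- vapply(seq_len(b), function(i) v[sample.int(n)], numeric(n))
            S <- abs(Z %*% P) / n
            cnt <- cnt + rowSums(S >= absObs)
            done <- done + b
        }
    })
    list(statistic = stats::setNames(obs, rownames(mat)),
         p = stats::setNames((1 + cnt) / (nPerm + 1), rownames(mat)))
}

#' Local false discovery rate from p-values
#'
#' Semi-parametric two-component mixture estimate: the marginal p-value
#' density is estimated by the Grenander (monotone non-increasing) estimator,
#' i.e. the left slope of the least concave majorant of the empirical CDF on
#' [0, 1], and the null proportion eta0 from the flat tail
#' (\code{mean(p > 0.8) / 0.2}, capped at 1).  The local FDR at p is
#' \code{eta0 / fhat(p)}, clipped to [0, 1]; it is non-decreasing in p by
#' construction.
#'
#' @param p p-values in (0, 1]; at least 50 are required for the density
#'   estimate to carry mass.
#' @return numeric lfdr vector aligned with \code{p}.
#' @export
localFdr <- function(p) {
    if (length(p) < 50) stop("at least 50 p-values required")
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    eta0 <- min(1, mean(p > 0.8) / 0.2)
    gren <- .grenander(p)
    # density on (x[i], x[i+1]] is the LCM slope of that interval
    fhat <- gren$slope[findInterval(p, gren$x, left.open = TRUE)]
    pmin(1, pmax(0, eta0 / fhat))
}

#' Least concave majorant slopes of the p-value ECDF
#'
#' Returns knots x (starting at 0, ending at 1) and the LCM slope of each
#' interval (x[i], x[i+1]] (length = knots - 1).  Stack-based upper-hull
#' construction over the points (0,0), (p_(i), i/m), (1, 1).
#' @keywords internal
.grenander <- function(p) {
    sp <- sort(unique(p))
    m <- length(p)
    Fy <- vapply(sp, function(q) sum(p <= q), numeric(1)) / m
    x <- c(0, sp); y <- c(0, Fy)
    if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, 1) }
    keep <- integer(0)
    for (i in seq_along(x)) {
        while (length(keep) >= 2) {
            a <- keep[length(keep) - 1]; b <- keep[length(keep)]
            s1 <- (y[b] - y[a]) / (x[b] - x[a])
            s2 <- (y[i] - y[b]) / (x[i] - x[b])
            if (s2 > s1) keep <- keep[-length(keep)] else break
        }
        keep <- c(keep, i)
    }
    xs <- x[keep]; ys <- y[keep]
    list(x = xs, slope = diff(ys) / diff(xs))
}

#' Screen transcripts for univariate survival association
#'
#' Runs the permutation FAST screen on every row of the cohort, estimates
#' local FDRs from the permutation p-values, and selects transcripts with
#' \code{lfdr < lfdrThreshold}.
#'
#' @param cohort an \linkS4class{ExpressionCohort} with survival annotations.
#' @param nPerm permutations for the screen.
#' @param lfdrThreshold selection threshold on the local FDR (default 0.15).
#' @param seed integer seed.
#' @return \link[S4Vectors]{DataFrame} with columns \code{statistic},
#'   \code{p}, \code{lfdr}, \code{selected}, row names = transcript ids.
#' @export
screenTranscripts <- function(cohort, nPerm = 10000, lfdrThreshold = 0.15,
                              seed) {
    perm <- permutationPvalues(exprMatrix(cohort), survTime(cohort),
                               survEvent(cohort), nPerm = nPerm, seed = seed)
    lf <- localFdr(perm$p)
    DataFrame(statistic = unname(perm$statistic), p = unname(perm$p),
              lfdr = unname(lf), selected = unname(lf < lfdrThreshold),
              row.names = rownames(cohort))
}

#' PCA metagene decomposition
#'
#' Mean-centers each selected transcript across samples and decomposes the
#' centered matrix by singular value decomposition.  Component k's transcript
#' loadings are the k-th left singular vector (unit norm); sample scores are
#' the loading-weighted sums of centered expression, so
#' \code{scores = t(loadings) \%*\% centered}.  Components are ordered by
#' explained variance.  Signs are arbitrary at this stage; they are fixed by
#' the hazard-positive orientation step (see \code{\link{orientComponent}}).
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param transcripts transcript ids to decompose (default: all rows).
#' @param nComponents number of metagenes, \code{>= 1} and at most the
#'   matrix rank.
#' @return list with \code{loadings} (transcripts x components),
#'   \code{scores} (components x samples), \code{varianceExplained},
#'   \code{center} (per-transcript means, needed to score new samples).
#' @export
pcaMetagenes <- function(cohort, transcripts = rownames(cohort),
                         nComponents = 1) {
    m <- exprMatrix(cohort)[transcripts, , drop = FALSE]
    if (nComponents < 1) stop("nComponents must be >= 1")
    if (nrow(m) < nComponents)
        stop("fewer selected transcripts than components")
    ctr <- rowMeans(m)
    mc <- m - ctr
    sv <- svd(mc, nu = nComponents, nv = nComponents)
    if (nComponents > sum(sv$d > max(dim(mc)) * .Machine$double.eps * sv$d[1]))
        stop("nComponents exceeds matrix rank")
    load <- sv$u
    dimnames(load) <- list(transcripts, paste0("PC", seq_len(nComponents)))
    sc <- t(load) %*% mc
    colnames(sc) <- colnames(m)
    list(loadings = load, scores = sc,
         varianceExplained = sv$d^2 / sum(svd(mc, nu = 0, nv = 0)$d^2),
         center = ctr)
}

#' Hazard-positive orientation of a metagene
#'
#' Chooses the component sign so that higher scores associate with higher
#' hazard: the orientation is the sign of the FAST statistic of the sample
#' scores (error if the statistic is exactly zero, in which case the
#' component is unoriented).
#'
#' @param componentScores numeric per-sample scores of one component.
#' @param time,event survival annotations.
#' @return +1 or -1.
#' @export
orientComponent <- function(componentScores, time, event) {
    s <- fastStatistic(componentScores, time, event)
    if (s == 0) stop("component cannot be oriented (zero score-survival association)")
    sign(s)
}

#' Partition a metagene into hazardous and protective transcript sets
#'
#' After hazard-positive orientation, transcripts with oriented loading > 0
#' form the hazardous set (higher expression, worse prognosis) and those
#' with oriented loading < 0 the protective set.  Zero loadings are assigned
#' to the protective set with a warning.
#'
#' @param loadings named numeric loadings of one component.
#' @param orientation +1 or -1 from \code{\link{orientComponent}}.
#' @param componentIndex which component this is (bookkeeping).
#' @param trainingSummary optional list of training diagnostics.
#' @return a \linkS4class{SignatureModel}.
#' @export
splitSignature <- function(loadings, orientation, componentIndex = 1L,
                           trainingSummary = list()) {
    if (!orientation %in% c(-1, 1)) stop("component is unoriented")
    ids <- names(loadings)
    if (is.null(ids)) stop("loadings must be named by transcript")
    orl <- orientation * loadings
    if (any(orl == 0))
        warning(sum(orl == 0), " zero loading(s) assigned to the protective set")
    methods::new("SignatureModel", transcriptIds = ids,
        loadings = unname(loadings), componentIndex = as.integer(componentIndex),
        orientation = orientation,
        hazardousSet = ids[orl > 0], protectiveSet = ids[orl <= 0],
        trainingSummary = trainingSummary)
}

#' Full signature discovery pipeline
#'
#' Variance filter, probe collapse (when a probe map is present), FAST
#' permutation screen, local-FDR selection, PCA metagene decomposition of the
#' selected transcripts, hazard-positive orientation, and the
#' hazardous/protective partition of component \code{componentIndex}.
#'
#' @param cohort an \linkS4class{ExpressionCohort} with survival annotations.
#' @param keepFraction variance-filter fraction.
#' @param nPerm screening permutations.
#' @param lfdrThreshold local-FDR selection threshold.
#' @param nComponents metagenes to extract.
#' @param componentIndex which component becomes the signature (default 1).
#' @param seed integer seed.
#' @return list with \code{model} (\linkS4class{SignatureModel}),
#'   \code{screen} (the screening DataFrame), \code{pca} (the decomposition),
#'   \code{scores} (oriented component scores as a
#'   \linkS4class{ScoreTable}).
#' @export
discoverSignature <- function(cohort, keepFraction = 0.5, nPerm = 10000,
        lfdrThreshold = 0.15, nComponents = 1, componentIndex = 1L, seed) {
    co <- varianceFilter(cohort, keepFraction)
    if (!is.null(probeMap(co))) co <- collapseProbes(co)
    screen <- screenTranscripts(co, nPerm = nPerm,
                                lfdrThreshold = lfdrThreshold, seed = seed)
    sel <- rownames(screen)[screen$selected]
    if (length(sel) < nComponents)
        stop("screen selected too few transcripts (", length(sel), ")")
    pca <- pcaMetagenes(co, sel, nComponents = nComponents)
    sc <- pca$scores[componentIndex, ]
    orient <- orientComponent(sc, survTime(co), survEvent(co))
    model <- splitSignature(stats::setNames(pca$loadings[, componentIndex],
                                            sel),
        orient, componentIndex = componentIndex,
        trainingSummary = list(
            nSelected = length(sel),
            varianceExplained = pca$varianceExplained[componentIndex],
            scoreStatistic = fastStatistic(orient * sc, survTime(co),
                                           survEvent(co))))
    st <- methods::new("ScoreTable", sampleIds = colnames(co),
        score = unname(orient * (sc - mean(sc))), matchedGeneFraction = 1,
        stratum = rep(NA_character_, ncol(co)))
    list(model = model, screen = screen, pca = pca, scores = st)
}

#' Leave-one-out cross-validated metagene evaluation
#'
#' For each held-out sample the entire discovery pipeline (variance filter,
#' probe collapse, permutation screen, local-FDR selection, PCA, orientation)
#' is rerun on the remaining samples and the held-out sample is scored on the
#' training loadings (centered by the training means).  The association of
#' the out-of-fold score vector with survival is then summarized per
#' component as its FAST statistic and a permutation p-value.  Folds whose
#' screen selects no transcript are reported and skipped.
#'
#' Screening inside each fold uses a reduced permutation count
#' (\code{nPermFold}); the final out-of-fold association p-value uses
#' \code{nPermScore} permutations of the single score vector.
#'
#' @param cohort an \linkS4class{ExpressionCohort} with survival annotations
#'   and at least 10 samples.
#' @param keepFraction,lfdrThreshold,nComponents as in
#'   \code{\link{discoverSignature}}.
#' @param nPermFold screening permutations per fold (default 1000).
#' @param nPermScore permutations for the out-of-fold association p.
#' @param seed integer seed (per-fold streams are derived from it).
#' @return list with \code{oofScores} (samples x components, NA for skipped
#'   folds), \code{statistic} and \code{p} per component, and
#'   \code{skippedFolds}.
#' @export
evaluateComponentsLoocv <- function(cohort, keepFraction = 0.5,
        lfdrThreshold = 0.15, nComponents = 1, nPermFold = 1000,
        nPermScore = 9999, seed) {
    n <- ncol(cohort)
    if (n < 10) stop("LOO-CV requires at least 10 samples")
    time <- survTime(cohort); event <- survEvent(cohort)
    oof <- matrix(NA_real_, n, nComponents,
                  dimnames = list(colnames(cohort),
                                  paste0("PC", seq_len(nComponents))))
    skipped <- character(0)
    for (i in seq_len(n)) {
        train <- cohort[, -i]
        fold <- tryCatch({
            co <- varianceFilter(train, keepFraction)
            if (!is.null(probeMap(co))) co <- collapseProbes(co)
            screen <- suppressWarnings(screenTranscripts(co, nPerm = nPermFold,
                lfdrThreshold = lfdrThreshold, seed = seed + i))
            sel <- rownames(screen)[screen$selected]
            if (length(sel) < nComponents) stop("no transcripts selected")
            pca <- pcaMetagenes(co, sel, nComponents = nComponents)
            held <- exprMatrix(cohort)[sel, i] - pca$center
            vapply(seq_len(nComponents), function(k) {
                orient <- orientComponent(pca$scores[k, ], time[-i], event[-i])
                orient * sum(pca$loadings[, k] * held)
            }, numeric(1))
        }, error = function(e) e)
        if (inherits(fold, "error")) {
            skipped <- c(skipped, colnames(cohort)[i])
            message("fold ", i, " skipped: ", conditionMessage(fold))
        } else oof[i, ] <- fold
    }
    use <- !is.na(oof[, 1L])
    if (sum(use) < 3) stop("too few scored folds to evaluate")
    stat <- p <- numeric(nComponents)
    for (k in seq_len(nComponents)) {
        pk <- permutationPvalues(matrix(oof[use, k], nrow = 1), time[use],
                                 event[use], nPerm = nPermScore,
                                 seed = seed + 100003L + k)
        stat[k] <- unname(pk$statistic); p[k] <- unname(pk$p)
    }
    list(oofScores = oof, statistic = stat, p = p, skippedFolds = skipped)
}
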
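#' Read an expression matrix TSV
#'
#' Tab-separated, UTF-8, first column = row (probe/gene) identifiers, header
#' = sample identifiers.  Duplicate row ids and non-numeric cells are
#' rejected; missing cells are rejected unless \code{missingPolicy =
#' "drop-row"}, which drops every row containing a missing value.
#'
#' @param path TSV file path.
#' @param missingPolicy "error" (default) or "drop-row".
#' @return numeric matrix with dimnames.
#' @export
readExpression <- function(path, missingPolicy = c("error", "drop-row")) {
    missingPolicy <- match.arg(missingPolicy)
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate row id(s): ", paste(unique(dup), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cell in ", path)
    rownames(m) <- ids
    if (anyNA(m)) {
        if (missingPolicy == "error")
            stop("missing cells in ", path, " (use missingPolicy='drop-row')")
        m <- m[stats::complete.cases(m), , drop = FALSE]
    }
    m
}

#' Read a clinical annotation TSV
#'
#' Columns: \code{sample_id}, \code{time_months}, \code{event} (0/1) and
#' optionally \code{batch}.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readClinical <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "time_months", "event")
    if (!all(need %in% colnames(df)))
        stop("clinical table must have columns ", paste(need, collapse = ", "))
    df
}

#' Read a probe-to-gene map TSV (columns probe_id, gene_symbol)
#' @param path TSV file path.
#' @return named character vector (probe id -> gene symbol).
#' @export
readProbeMap <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("probe map needs 2 columns")
    stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Assemble an ExpressionCohort from expression + clinical files
#'
#' @param exprPath expression matrix TSV.
#' @param clinicalPath clinical TSV (see \code{\link{readClinical}}).
#' @param probeMapPath optional probe-map TSV.
#' @param missingPolicy forwarded to \code{\link{readExpression}}.
#' @return an \linkS4class{ExpressionCohort} with samples ordered as in the
#'   expression matrix.
#' @export
readExpressionCohort <- function(exprPath, clinicalPath,
                                 probeMapPath = NULL,
                                 missingPolicy = "error") {
    m <- readExpression(exprPath, missingPolicy)
    cl <- readClinical(clinicalPath)
    idx <- match(colnames(m), cl$sample_id)
    if (anyNA(idx)) stop("clinical table misses sample(s): ",
                         paste(colnames(m)[is.na(idx)], collapse = ", "))
    cl <- cl[idx, ]
    ExpressionCohort(m, time = cl$time_months, event = cl$event,
        batch = if ("batch" %in% colnames(cl)) cl$batch,
        probeMap = if (!is.null(probeMapPath)) readProbeMap(probeMapPath))
}

#' Write an ExpressionCohort as paired TSVs
#'
#' Writes the matrix (row ids in the first column, 10 significant digits)
#' and a clinical table with columns sample_id, time_months, event and,
#' when present, batch.  Unix newlines, UTF-8.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param exprPath,clinicalPath output paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionCohort <- function(cohort, exprPath, clinicalPath) {
    m <- exprMatrix(cohort)
    df <- data.frame(id = rownames(m),
                     apply(m, 2, .fmtNum), check.names = FALSE)
    colnames(df) <- c("id", colnames(m))
    utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    cl <- data.frame(sample_id = colnames(m),
                     time_months = .fmtNum(survTime(cohort)),
                     event = survEvent(cohort))
    if (!is.null(sampleBatch(cohort))) cl$batch <- sampleBatch(cohort)
    utils::write.table(cl, clinicalPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(c(exprPath, clinicalPath))
}

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line, tab-separated name, description and
#' members.  Duplicate members are deduplicated; malformed lines (fewer than
#' 3 columns) and empty sets are reported with their line number.
#'
#' @param path GMT file path.
#' @param universe optional universe to attach.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, universe = character()) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("malformed GMT line ", i, ": fewer than 3 columns")
        members <- unique(f[-(1:2)])
        members <- members[nzchar(members)]
        if (!length(members)) stop("empty set at GMT line ", i)
        sets[[f[1]]] <- members
    }
    methods::new("GeneSetCollection", sets = sets,
                 universe = as.character(universe))
}

#' Write a GeneSetCollection as GMT
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @param descriptions optional named descriptions (default "na").
#' @return invisibly, the path.
#' @export
writeGmt <- function(collection, path, descriptions = NULL) {
    sets <- geneSets(collection)
    lines <- vapply(names(sets), function(nm) {
        desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
            descriptions[[nm]] else "na"
        paste(c(nm, desc, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path, sep = "\n")
    invisible(path)
}

#' Serialize / deserialize a SignatureModel as JSON
#'
#' Loadings are written as decimal strings (10 significant digits) so the
#' file round-trips reproducibly across platforms.
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param path JSON path.
#' @return \code{writeSignatureModel}: invisibly, the path;
#'   \code{readSignatureModel}: the model.
#' @name signature-io
NULL

#' @rdname signature-io
#' @export
writeSignatureModel <- function(model, path) {
    obj <- list(transcript_ids = model@transcriptIds,
        loadings = .fmtNum(model@loadings),
        component_index = model@componentIndex,
        orientation = model@orientation,
        hazardous_set = model@hazardousSet,
        protective_set = model@protectiveSet,
        training_summary = model@trainingSummary)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname signature-io
#' @param path JSON path.
#' @export
readSignatureModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("SignatureModel",
        transcriptIds = as.character(obj$transcript_ids),
        loadings = as.numeric(obj$loadings),
        componentIndex = as.integer(obj$component_index),
        orientation = as.numeric(obj$orientation),
        hazardousSet = as.character(obj$hazardous_set),
        protectiveSet = as.character(obj$protective_set),
        trainingSummary = as.list(obj$training_summary))
}

#' Write a ScoreTable as TSV (sample_id, score, stratum)
#' @param scoreTable a \linkS4class{ScoreTable}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeScoreTable <- function(scoreTable, path) {
    df <- data.frame(sample_id = scoreTable@sampleIds,
                     score = .fmtNum(scoreTable@score),
                     stratum = scoreTable@stratum)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(path)
}

#' Read / write grayscale image stacks as multi-page TIFF
#'
#' Stacks are numeric arrays (height x width x depth) with values in
#' [0, 1]; the bit depth attribute (8 or 16) controls the sample format on
#' disk.
#'
#' @param stack numeric array with optional \code{bitDepth} attribute.
#' @param path TIFF path.
#' @return \code{writeStack}: invisibly, the path; \code{readStack}: the
#'   array with \code{bitDepth} attribute.
#' @name stack-io
NULL

#' @rdname stack-io
#' @export
writeStack <- function(stack, path) {
    bd <- attr(stack, "bitDepth")
    if (is.null(bd)) bd <- 16L
    if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
    pages <- lapply(seq_len(dim(stack)[3]), function(s) stack[, , s])
    tiff::writeTIFF(pages, path, bits.per.sample = bd)
    invisible(path)
}

#' @rdname stack-io
#' @param path TIFF path.
#' @export
readStack <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
    if (is.matrix(pages)) pages <- list(pages)
    out <- array(0, c(dim(pages[[1]]), length(pages)))
    for (s in seq_along(pages)) out[, , s] <- pages[[s]]
    attr(out, "bitDepth") <- 16L
    out
}

#' Run the transcriptomic analysis pipeline end to end
#'
#' Executes discovery, scoring and (optionally) over-representation on files
#' referenced by a configuration list, writing every intermediate artifact
#' (screen TSV, signature JSON, score TSV, ORA TSV) plus a JSON manifest
#' recording the package version, seed, parameters and the stages executed.
#' All inputs are checked before any stage runs; rerunning the same
#' configuration reproduces all numeric outputs byte-identically.
#'
#' @param config list with entries \code{exprPath}, \code{clinicalPath},
#'   optional \code{probeMapPath} and \code{gmtPath}, parameters
#'   \code{keepFraction}, \code{nPerm}, \code{lfdrThreshold},
#'   \code{minFraction}, \code{alpha}, \code{scheme}, \code{seed}, and
#'   \code{outDir}.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
    need <- c("exprPath", "clinicalPath", "seed", "outDir")
    miss <- setdiff(need, names(config))
    if (length(miss)) stop("config misses: ", paste(miss, collapse = ", "))
    paths <- unlist(config[intersect(names(config),
        c("exprPath", "clinicalPath", "probeMapPath", "gmtPath"))])
    for (p in paths) if (!file.exists(p)) stop("missing input file: ", p)
    cfg <- utils::modifyList(list(keepFraction = 0.5, nPerm = 10000,
        lfdrThreshold = 0.15, minFraction = 0.20, alpha = 0.05,
        scheme = "tertile"), config)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    stages <- character(0)
    out <- function(f) file.path(cfg$outDir, f)

    cohort <- readExpressionCohort(cfg$exprPath, cfg$clinicalPath,
                                   cfg$probeMapPath)
    stages <- c(stages, "read")
    disc <- discoverSignature(cohort, keepFraction = cfg$keepFraction,
        nPerm = cfg$nPerm, lfdrThreshold = cfg$lfdrThreshold, seed = cfg$seed)
    stages <- c(stages, "discover")
    utils::write.table(data.frame(transcript = rownames(disc$screen),
        statistic = .fmtNum(disc$screen$statistic),
        p = .fmtNum(disc$screen$p), lfdr = .fmtNum(disc$screen$lfdr),
        selected = disc$screen$selected),
        out("screen.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeSignatureModel(disc$model, out("signature.json"))
    sc <- stratifyScores(riskScore(cohort, disc$model), scheme = cfg$scheme)
    writeScoreTable(sc, out("risk_scores.tsv"))
    stages <- c(stages, "score")
    grp <- scoreStrata(sc)
    keep <- grp != "mid"
    lr <- logrankTest(survTime(cohort)[keep], survEvent(cohort)[keep],
                      grp[keep])
    stages <- c(stages, "survtest")
    oraFile <- NULL
    if (!is.null(cfg$gmtPath)) {
        gs <- readGmt(cfg$gmtPath, universe = rownames(cohort))
        ora <- hypergeomOra(intersect(disc$model@hazardousSet,
                                      rownames(cohort)), gs,
                            universe = rownames(cohort), alpha = cfg$alpha)
        utils::write.table(data.frame(set = rownames(ora),
            k = ora$k, n = ora$n, K = ora$K, N = ora$N,
            p = .fmtNum(ora$p), p_adj = .fmtNum(ora$pAdjusted),
            significant = ora$significant),
            out("ora.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        stages <- c(stages, "ora")
        oraFile <- "ora.tsv"
    }
    manifest <- list(
        package = "PDACsig",
        version = as.character(utils::packageVersion("PDACsig")),
        seed = cfg$seed,
        parameters = cfg[c("keepFraction", "nPerm", "lfdrThreshold",
                           "minFraction", "alpha", "scheme")],
        stages = stages,
        logrank = list(chisq = lr$chisq, p = lr$p),
        outputs = c("screen.tsv", "signature.json", "risk_scores.tsv",
                    oraFile))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
}
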
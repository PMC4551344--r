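#' Hypergeometric over-representation analysis
#'
#' Tests each set of a collection for over-representation of a query gene
#' list.  Every set is intersected with the universe before testing; the
#' query must be a subset of the universe.  With N = universe size, K = set
#' size, n = query size and k = overlap, the p-value is the upper tail
#' P(X >= k) under Hypergeometric(N, K, n).  P-values are corrected across
#' all tested sets by the Benjamini-Yekutieli procedure, and sets are called
#' significant when the adjusted p is strictly below \code{alpha}.  Sets
#' with no member in the universe are skipped (the test is undefined).
#'
#' @param query character vector of genes (subset of the universe).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of testable genes; defaults to the
#'   collection's universe.
#' @param alpha significance level on the BY-adjusted p (default 0.05).
#' @return \link[S4Vectors]{DataFrame} with one row per tested set:
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{p}, \code{pAdjusted},
#'   \code{significant}.
#' @examples
#' gs <- methods::new("GeneSetCollection",
#'     sets = list(A = c("g1", "g2", "g3"), B = c("g4", "g5")),
#'     universe = paste0("g", 1:10))
#' hypergeomOra(c("g1", "g2", "g4"), gs)
#' @export
hypergeomOra <- function(query, collection, universe = setUniverse(collection),
                         alpha = 0.05) {
    if (!length(universe)) stop("empty universe")
    if (!length(query)) stop("empty query")
    universe <- unique(universe)
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    sets <- lapply(geneSets(collection), function(s) intersect(s, universe))
    sets <- sets[lengths(sets) > 0]
    if (!length(sets)) stop("no set overlaps the universe")
    N <- length(universe); n <- length(query)
    K <- lengths(sets)
    k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    padj <- byAdjust(p)
    DataFrame(k = unname(k), n = n, K = unname(K), N = N, p = unname(p),
              pAdjusted = unname(padj), significant = unname(padj < alpha),
              row.names = names(sets))
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up false discovery rate control valid under arbitrary dependence:
#' the Benjamini-Hochberg adjustment multiplied by the harmonic factor
#' c(m) = sum(1/i, i = 1..m), with monotonicity enforced and values capped
#' at 1.  Delegates to \code{stats::p.adjust(method = "BY")}.
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values, elementwise >= the input.
#' @export
byAdjust <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BY")
}
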
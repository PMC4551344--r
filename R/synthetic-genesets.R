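#' Simulate a gene-set collection with named hypoxia sets
#'
#' Builds a GMT-like collection emulating a curated pathway database in which
#' a subset of set names contain the token "HYPOXIA".  An anchor gene
#' (VEGFA by default) is made a member of every hypoxia set, matching its
#' role as the sign anchor of the hypoxia meta-signature.  Per-gene hypoxia
#' membership frequencies can be requested exactly: a gene with frequency
#' \code{f} is placed in \code{round(f * hypoxiaSets)} randomly chosen
#' hypoxia sets (and removed from the rest), so the strict more-than-20\%
#' meta-signature rule can be tested against known counts.
#'
#' @param nSets total number of sets.
#' @param hypoxiaSets how many set names carry the "HYPOXIA" token
#'   (\code{<= nSets}).
#' @param universe character vector of gene symbols to draw members from.
#' @param overlapProfile optional named numeric vector of per-gene hypoxia
#'   membership frequencies in [0, 1].
#' @param anchorGene gene forced into every hypoxia set.
#' @param setSizeRange integer range of set sizes.
#' @param seed integer seed.
#' @return A \linkS4class{GeneSetCollection} whose universe is
#'   \code{universe}.
#' @examples
#' gs <- generateGeneSetCollection(10, 4, universe = paste0("G", 1:200),
#'                                 seed = 1)
#' grep("HYPOXIA", names(geneSets(gs)), value = TRUE)
#' @export
generateGeneSetCollection <- function(nSets = 30, hypoxiaSets = 22,
        universe, overlapProfile = NULL, anchorGene = "VEGFA",
        setSizeRange = c(30L, 120L), seed) {
    if (!length(universe)) stop("empty universe")
    if (hypoxiaSets > nSets) stop("hypoxiaSets must not exceed nSets")
    if (!anchorGene %in% universe)
        universe <- c(anchorGene, universe)
    .withSeed(seed, {
        sizes <- sample(seq(setSizeRange[1], setSizeRange[2]), nSets,
                        replace = TRUE)
        sizes <- pmin(sizes, length(universe))
        nm <- character(nSets)
        if (hypoxiaSets > 0)
            nm[seq_len(hypoxiaSets)] <-
                sprintf("MODULE_%02d_HYPOXIA_UP", seq_len(hypoxiaSets))
        if (nSets > hypoxiaSets)
            nm[(hypoxiaSets + 1):nSets] <-
                sprintf("PATHWAY_%02d_SIGNALING", seq_len(nSets - hypoxiaSets))
        sets <- lapply(sizes, function(s) sample(universe, s))
        names(sets) <- nm
        hypIdx <- seq_len(hypoxiaSets)
        for (i in hypIdx)
            sets[[i]] <- union(sets[[i]], anchorGene)
        if (!is.null(overlapProfile) && hypoxiaSets > 0) {
            for (g in names(overlapProfile)) {
                k <- round(overlapProfile[[g]] * hypoxiaSets)
                inSets <- if (k > 0) sample(hypIdx, k) else integer()
                for (i in hypIdx) {
                    sets[[i]] <- setdiff(sets[[i]], g)
                    if (i %in% inSets) sets[[i]] <- c(sets[[i]], g)
                }
            }
        }
        methods::new("GeneSetCollection", sets = sets,
                     universe = as.character(universe))
    })
}
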
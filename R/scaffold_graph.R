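# Link-count-thresholded scaffolding graph and its connected components.

#' Default link-count threshold
#'
#' The 10\% quantile (lower interpolation on the sorted values) of the
#' non-zero per-pair link counts, floored at 2 so a single chimeric read can
#' never create an edge. Practitioners may instead supply an explicit
#' threshold (a value between 0.25x and 0.5x the read coverage is a sensible
#' range); the explicit value then takes precedence in
#' \code{\link{buildGraph}} callers.
#'
#' @param linkCounts integer vector of per-pair link counts.
#' @param probs quantile level (default 0.1).
#' @param floor minimum returned threshold (default 2).
#' @return integer threshold.
#' @examples
#' defaultThreshold(c(1:10))   # lower 10% quantile 1, floored to 2
#' @export
defaultThreshold <- function(linkCounts, probs = 0.1, floor = 2) {
    nz <- linkCounts[linkCounts > 0]
    if (!length(nz)) stop("no linking evidence: all pair link counts are zero")
    s <- sort(nz)
    idx <- base::floor((length(s) - 1) * probs) + 1   # lower interpolation
    max(floor, s[idx])
}

#' Build the scaffolding graph
#'
#' Tallies per unordered contig pair the orientation votes \code{a}
#' (\code{d = +1}) and \code{b} (\code{d = -1}) and keeps an edge when
#' \code{a + b >= threshold}. Links on dropped edges take no further part in
#' scaffolding.
#'
#' @param links link data.frame.
#' @param contigIds all contig ids (isolated contigs become singleton
#'   components downstream).
#' @param threshold minimum link count; when \code{NULL} the
#'   \code{\link{defaultThreshold}} of the observed counts is used.
#' @return a \linkS4class{ScaffoldGraph}.
#' @export
buildGraph <- function(links, contigIds, threshold = NULL) {
    if (nrow(links)) {
        key <- pairKey(links$i, links$j)
        a <- tapply(links$d == 1L, key, sum)
        b <- tapply(links$d == -1L, key, sum)
        cnt <- as.integer(a + b)
        if (is.null(threshold)) threshold <- defaultThreshold(cnt)
        keep <- cnt >= threshold
        parts <- strsplit(names(a)[keep], "\r", fixed = TRUE)
        edges <- data.frame(
            i = vapply(parts, `[[`, character(1), 1L),
            j = vapply(parts, `[[`, character(1), 2L),
            a = as.integer(a[keep]), b = as.integer(b[keep]))
        edges <- edges[order(edges$i, edges$j), , drop = FALSE]
        rownames(edges) <- NULL
    } else {
        if (is.null(threshold)) threshold <- 2
        edges <- data.frame(i = character(), j = character(),
                            a = integer(), b = integer())
    }
    new("ScaffoldGraph", vertices = as.character(contigIds), edges = edges,
        threshold = as.numeric(threshold))
}

# links restricted to pairs that survived thresholding
linksOnGraph <- function(links, graph) {
    if (!nrow(links) || !nrow(graph@edges)) return(links[0L, , drop = FALSE])
    links[pairKey(links$i, links$j) %in%
          pairKey(graph@edges$i, graph@edges$j), , drop = FALSE]
}

#' Connected components of the scaffolding graph
#'
#' Depth-first search with an explicit stack (no recursion limits);
#' singleton contigs come through as single-contig components.
#'
#' @param graph a \linkS4class{ScaffoldGraph}.
#' @return list of character vectors (a partition of the vertices), ordered
#'   by each component's smallest contig id.
#' @export
connectedComponents <- function(graph) {
    orderComponents(dfsComponents(graph@vertices, graph@edges))
}

#' Dump the graph as a tab-separated edge list
#'
#' @param graph a \linkS4class{ScaffoldGraph}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGraphTSV <- function(graph, path) {
    utils::write.table(graph@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
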
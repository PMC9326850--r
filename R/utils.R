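# Small shared helpers: logging, pair keys, link table scaffolding.

ltsLog <- function(fmt, ..., verbose = getOption("ltsScaffold.verbose", FALSE)) {
    if (isTRUE(verbose)) message(sprintf(fmt, ...))
    invisible(NULL)
}

# canonical unordered pair key
pairKey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")

#' An empty link table
#'
#' Links are kept in a plain data.frame, one row per read (pair) joining two
#' distinct contigs. Paired rows populate \code{si}/\code{sj} (distance from
#' contig start to the read's outer, fragment-side end, 0-based bp) and
#' \code{gi}/\code{gj} (geometry-normalised strand: +1 when the read points
#' toward the downstream edge of its contig once pair geometry is reduced to
#' the inward convention). TGS rows populate alignment starts on the read
#' (\code{qsi}, \code{qsj}) and on the contigs (\code{csi}, \code{csj}),
#' alignment lengths and stored-frame strands. \code{d} is the relative
#' orientation vote in \{+1, -1\}; \code{F} is the linking distance, filled
#' once orientations are fixed.
#'
#' @param n number of preallocated rows.
#' @return data.frame with the canonical link columns.
#' @export
emptyLinks <- function(n = 0L) {
    data.frame(readId = character(n), i = character(n), j = character(n),
               d = integer(n), lib = character(n), type = character(n),
               si = numeric(n), sj = numeric(n),
               gi = integer(n), gj = integer(n),
               qsi = numeric(n), qsj = numeric(n),
               csi = numeric(n), csj = numeric(n),
               leni = numeric(n), lenj = numeric(n),
               qaleni = numeric(n), qalenj = numeric(n), qlen = numeric(n),
               strandi = integer(n), strandj = integer(n),
               F = numeric(n))
}

# fill missing canonical columns with NA
completeLinks <- function(df) {
    tmpl <- emptyLinks()
    for (cn in names(tmpl)) {
        if (is.null(df[[cn]])) df[[cn]] <- rep(tmpl[[cn]][NA], nrow(df))
    }
    df[names(tmpl)]
}

# connected components by iterative depth-first search (explicit stack);
# vertices: character ids, edges: data.frame with columns i, j.
dfsComponents <- function(vertices, edges) {
    n <- length(vertices)
    comp <- integer(n)
    names(comp) <- vertices
    adj <- vector("list", n)
    names(adj) <- vertices
    if (nrow(edges)) {
        ii <- match(edges$i, vertices)
        jj <- match(edges$j, vertices)
        for (k in seq_len(nrow(edges))) {
            adj[[ii[k]]] <- c(adj[[ii[k]]], jj[k])
            adj[[jj[k]]] <- c(adj[[jj[k]]], ii[k])
        }
    }
    cid <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cid <- cid + 1L
        stack <- s
        comp[s] <- cid
        while (length(stack)) {
            v <- stack[length(stack)]
            stack <- stack[-length(stack)]
            for (u in adj[[v]]) {
                if (comp[u] == 0L) {
                    comp[u] <- cid
                    stack <- c(stack, u)
                }
            }
        }
    }
    unname(split(vertices, comp))
}

# deterministic ordering of components: by smallest member id
orderComponents <- function(comps) {
    comps[order(vapply(comps, min, character(1)))]
}
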
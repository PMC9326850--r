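# Contig orientation per component: minimise the Ising-type energy
#   H(D) = - sum_over_edges J_ij D_i D_j,   J_ij = (a_ij - b_ij)/2,
# where a_ij / b_ij count links voting the pair co- / anti-oriented. The sum
# runs once per unordered edge (the ordered double sum merely doubles H and
# leaves the argmin unchanged). The ground-state search is heuristic:
# a weight-decreasing spanning-tree initialisation followed by
# best-improvement single-spin flips.

#' Orientation couplings for one component
#'
#' @param graph a \linkS4class{ScaffoldGraph}.
#' @param component character vector of contig ids (one connected
#'   component).
#' @return list with \code{vertices} (sorted ids) and \code{edges}
#'   (data.frame \code{i}, \code{j}, \code{J} with \code{J = (a - b)/2}).
#' @export
couplings <- function(graph, component = graphVertices(graph)) {
    e <- graph@edges
    e <- e[e$i %in% component & e$j %in% component, , drop = FALSE]
    list(vertices = sort(unique(component)),
         edges = data.frame(i = e$i, j = e$j, J = (e$a - e$b) / 2))
}

#' Orientation energy
#'
#' @param problem couplings list from \code{\link{couplings}}.
#' @param D named orientation vector over the problem's vertices.
#' @return the energy \code{H(D)}; invariant under the global flip
#'   \code{D -> -D}.
#' @export
orientationEnergy <- function(problem, D) {
    e <- problem$edges
    if (!nrow(e)) return(0)
    -sum(e$J * D[e$i] * D[e$j])
}

#' Assign orientations by heuristic energy minimisation
#'
#' Initialisation grows a maximum-\code{|J|} spanning forest from a root,
#' always following the heaviest available tree edge and setting each
#' newly reached vertex to agree with \code{sign(J) x} its parent's state;
#' zero-coupling edges carry no information and are skipped. Refinement
#' repeatedly applies the single flip that most decreases the energy (ties
#' to the smallest vertex id) until no flip helps, then attempts a
#' Kernighan-Lin sweep (a best-prefix sequence of one-time flips) to
#' escape shallow local minima on frustrated instances. The search also
#' restarts from trees rooted at up to \code{maxStarts} different vertices
#' (chosen by decreasing incident coupling mass) and keeps the lowest
#' energy; everything is deterministic, and the returned assignment is
#' renormalised so the anchor (first vertex) is +1 and certified to be a
#' single-flip local minimum.
#'
#' @param problem couplings list from \code{\link{couplings}}.
#' @param maxStarts number of deterministic restarts (default 8).
#' @return named orientation vector \code{D} in \{+1, -1\} with the anchor
#'   entry +1.
#' @export
orient <- function(problem, maxStarts = 8L) {
    v <- problem$vertices
    m <- length(v)
    if (m <= 1L) return(stats::setNames(rep(1, m), v))
    e <- problem$edges[problem$edges$J != 0, , drop = FALSE]
    if (!nrow(e)) return(stats::setNames(rep(1, m), v))
    e <- e[order(-abs(e$J), e$i, e$j), , drop = FALSE]
    mass <- tapply(c(abs(e$J), abs(e$J)), c(e$i, e$j), sum)
    roots <- names(sort(mass, decreasing = TRUE))
    roots <- unique(c(v[1L], roots))[seq_len(min(maxStarts, m))]
    best <- NULL
    bestH <- Inf
    for (root in roots) {
        D <- treeInit(v, e, root)
        D <- refineOrientation(problem, D)
        H <- orientationEnergy(problem, D)
        if (H < bestH - 1e-12) {
            bestH <- H
            best <- D
        }
    }
    best
}

# weight-decreasing spanning-forest initialisation from one root
treeInit <- function(v, e, root) {
    D <- stats::setNames(rep(1, length(v)), v)
    visited <- stats::setNames(rep(FALSE, length(v)), v)
    visited[root] <- TRUE
    repeat {
        touch <- xor(visited[e$i], visited[e$j])
        if (!any(touch)) break
        k <- which(touch)[1L]               # heaviest frontier edge
        parent <- if (visited[e$i[k]]) e$i[k] else e$j[k]
        child <- if (visited[e$i[k]]) e$j[k] else e$i[k]
        D[child] <- sign(e$J[k]) * D[parent]
        visited[child] <- TRUE
    }
    D
}

# best-improvement single-spin descent with Kernighan-Lin escape sweeps:
# after a single-flip minimum, flip vertices one by one in best-marginal
# order (each at most once, worsening moves allowed) and keep the best
# prefix; accepted sweeps loop back into the descent. Deterministic; ties
# to the smallest vertex id; the returned state is a single-flip local
# minimum with the anchor renormalised to +1.
refineOrientation <- function(problem, D) {
    v <- problem$vertices
    e <- problem$edges
    if (!nrow(e)) return(D)
    ii <- match(e$i, v); jj <- match(e$j, v)
    m <- length(v)
    Dv <- as.numeric(D[v])
    deltas <- function(Dv) {
        # flipping vertex x changes H by 2 * sum of J D_i D_j over its edges
        contrib <- e$J * Dv[ii] * Dv[jj]
        delta <- 2 * tapply(c(contrib, contrib), c(ii, jj), sum)
        dAll <- numeric(m)
        dAll[as.integer(names(delta))] <- as.numeric(delta)
        dAll
    }
    energyOf <- function(Dv) -sum(e$J * Dv[ii] * Dv[jj])
    repeat {
        repeat {
            dAll <- deltas(Dv)
            best <- which.min(dAll)         # ties: smallest index = smallest id
            if (dAll[best] >= -1e-12) break
            Dv[best] <- -Dv[best]
        }
        H0 <- energyOf(Dv)
        cur <- Dv
        locked <- rep(FALSE, m)
        Hcur <- H0
        bestH <- H0
        bestDv <- Dv
        for (s in seq_len(m)) {
            dAll <- deltas(cur)
            dAll[locked] <- Inf
            u <- which.min(dAll)
            cur[u] <- -cur[u]
            Hcur <- Hcur + dAll[u]
            locked[u] <- TRUE
            if (Hcur < bestH - 1e-12) {
                bestH <- Hcur
                bestDv <- cur
            }
        }
        if (bestH < H0 - 1e-12) Dv <- bestDv else break
    }
    if (Dv[1L] < 0) Dv <- -Dv               # anchor renormalisation
    stats::setNames(Dv, v)
}

#' Exhaustive minimum-energy orientation (small components)
#'
#' Enumerates all assignments with the anchor fixed to +1; used as an
#' oracle and for tiny components.
#'
#' @param problem couplings list.
#' @return list with \code{D} and \code{H}.
#' @export
orientExhaustive <- function(problem) {
    v <- problem$vertices
    m <- length(v)
    stopifnot(m <= 20L)
    if (m == 1L) return(list(D = stats::setNames(1, v), H = 0))
    e <- problem$edges
    ii <- match(e$i, v); jj <- match(e$j, v)
    grid <- as.matrix(expand.grid(rep(list(c(1, -1)), m - 1L)))
    best <- NULL; bestH <- Inf
    for (r in seq_len(nrow(grid))) {
        Dv <- c(1, grid[r, ])
        H <- if (nrow(e)) -sum(e$J * Dv[ii] * Dv[jj]) else 0
        if (H < bestH) { bestH <- H; best <- Dv }
    }
    list(D = stats::setNames(best, v), H = bestH)
}

#' Restrict links to orientation-supported ones
#'
#' Keeps exactly the links whose orientation vote matches the assignment:
#' \code{d == D_i D_j}. Downstream coordinate computations treat contigs
#' with \code{D = -1} as reverse-complemented.
#'
#' @param links link data.frame (rows within one component).
#' @param D named orientation vector.
#' @return the supported subset.
#' @export
orientationSupported <- function(links, D) {
    if (!nrow(links)) return(links)
    links[links$d == D[links$i] * D[links$j], , drop = FALSE]
}
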
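# The iterative scaffolding pipeline: graph -> orientation -> clustering ->
# robust regression -> untangling, repeated with super-contigs standing in
# for contigs, remapping link coordinates into the growing frames.

# tally per-pair orientation votes from a link table
tallyCouplings <- function(links, vertices) {
    if (!nrow(links))
        return(list(vertices = sort(vertices),
                    edges = data.frame(i = character(), j = character(),
                                       J = numeric())))
    ci <- pmin(links$i, links$j)
    cj <- pmax(links$i, links$j)
    key <- paste(ci, cj, sep = "\r")
    a <- tapply(links$d == 1L, key, sum)
    b <- tapply(links$d == -1L, key, sum)
    parts <- strsplit(names(a), "\r", fixed = TRUE)
    list(vertices = sort(vertices),
         edges = data.frame(i = vapply(parts, `[[`, character(1), 1L),
                            j = vapply(parts, `[[`, character(1), 2L),
                            J = (as.numeric(a) - as.numeric(b)) / 2))
}

#' Orient and position one component (with re-splitting)
#'
#' Runs orientation, orientation-supported link selection, distance
#' clustering and the trimming regression for a component; when trimming
#' disconnects the component the parts re-enter the same procedure, so the
#' return value is a list of layouts.
#'
#' @param component contig ids.
#' @param links preprocessed links restricted to the current unit set.
#' @param libraries named list of \linkS4class{SeqLibrary}.
#' @param contigLengths named numeric vector over the current units.
#' @param maxError residual bound (bp) for this pipeline iteration.
#' @param clusterArgs list of extra arguments for
#'   \code{\link{clusterObservations}} (kernel, merge rules,
#'   \code{multiMode}).
#' @return list of \linkS4class{LayoutEstimate}.
#' @export
fitComponent <- function(component, links, libraries, contigLengths,
                         maxError = 100, clusterArgs = list()) {
    queue <- list(as.character(component))
    layouts <- list()
    while (length(queue)) {
        comp <- queue[[1L]]
        queue <- queue[-1L]
        if (length(comp) == 1L) {
            layouts[[length(layouts) + 1L]] <- singletonLayout(comp, maxError)
            next
        }
        lk <- links[links$i %in% comp & links$j %in% comp, , drop = FALSE]
        problem <- tallyCouplings(lk, comp)
        D <- orient(problem)
        sup <- orientationSupported(lk, D)
        sup <- linkDistances(sup, D, contigLengths, libraries)
        obs <- do.call(clusterObservations,
                       c(list(links = sup, libraries = libraries),
                         clusterArgs))
        system <- buildSystem(comp, obs)
        if (is.null(system$X)) {
            # no observations survive: dissolve into singletons
            queue <- c(queue, as.list(comp))
            next
        }
        # the observation graph may be sparser than the link graph
        obsComps <- dfsComponents(system$contigs,
                                  system$obs[, c("i", "j"), drop = FALSE])
        if (length(obsComps) > 1L) {
            queue <- c(queue, orderComponents(obsComps))
            next
        }
        fit <- wlts(system, maxError)
        if (isTRUE(fit$converged)) {
            layouts[[length(layouts) + 1L]] <-
                layoutFromFit(system, D, fit, maxError)
        } else {
            queue <- c(queue, fit$components)
        }
    }
    layouts
}

singletonLayout <- function(id, maxError) {
    obs <- data.frame(i = character(), j = character(), lib = character(),
                      Y = numeric(), n = integer(), w = numeric(),
                      sigma = numeric(), resid = numeric(),
                      selected = logical())
    new("LayoutEstimate", contigs = id, D = stats::setNames(1, id),
        beta = stats::setNames(0, id), observations = obs,
        cov = matrix(0, 1, 1, dimnames = list(id, id)), sigma2 = NA_real_,
        modelVariance = FALSE, iterations = 0, maxError = maxError)
}

# contig -> (unit, offset, orientation, unitLength) map from SuperContigs
unitMap <- function(units) {
    rows <- lapply(units, function(u) {
        p <- u@placements
        L <- unitLength(u)
        data.frame(contig = p$contig, unit = u@id, offset = p$start,
                   orientation = p$orientation, contigLength = p$length,
                   unitLength = L)
    })
    do.call(rbind, rows)
}

unitLength <- function(u) {
    p <- u@placements
    max(p$start + p$length)
}

# remap original links into the current unit frames; intra-unit links drop
remapLinks <- function(links, map) {
    if (!nrow(links)) return(links)
    idx <- match(links$i, map$contig)
    jdx <- match(links$j, map$contig)
    ok <- !is.na(idx) & !is.na(jdx)
    links <- links[ok, , drop = FALSE]
    idx <- idx[ok]; jdx <- jdx[ok]
    newI <- map$unit[idx]; newJ <- map$unit[jdx]
    keep <- newI != newJ
    links <- links[keep, , drop = FALSE]
    if (!nrow(links)) return(links)
    newI <- newI[keep]; newJ <- newJ[keep]
    idx <- idx[keep]; jdx <- jdx[keep]
    ei <- map$orientation[idx]; ej <- map$orientation[jdx]
    offI <- map$offset[idx]; offJ <- map$offset[jdx]
    Li <- map$contigLength[idx]; Lj <- map$contigLength[jdx]
    paired <- links$type == "paired"
    if (any(paired)) {
        p <- which(paired)
        links$si[p] <- ifelse(ei[p] > 0, offI[p] + links$si[p],
                              offI[p] + Li[p] - links$si[p])
        links$sj[p] <- ifelse(ej[p] > 0, offJ[p] + links$sj[p],
                              offJ[p] + Lj[p] - links$sj[p])
        links$gi[p] <- links$gi[p] * ei[p]
        links$gj[p] <- links$gj[p] * ej[p]
        links$d[p] <- -(links$gi[p] * links$gj[p])
    }
    if (any(!paired)) {
        t <- which(!paired)
        links$csi[t] <- ifelse(ei[t] > 0, offI[t] + links$csi[t],
                               offI[t] + Li[t] - links$csi[t] - links$leni[t])
        links$csj[t] <- ifelse(ej[t] > 0, offJ[t] + links$csj[t],
                               offJ[t] + Lj[t] - links$csj[t] - links$lenj[t])
        links$strandi[t] <- links$strandi[t] * ei[t]
        links$strandj[t] <- links$strandj[t] * ej[t]
        links$d[t] <- links$strandi[t] * links$strandj[t]
    }
    links$i <- newI
    links$j <- newJ
    links
}

# place the contigs of unit u into a parent frame
transformUnit <- function(u, start, orientation) {
    p <- u@placements
    L <- unitLength(u)
    if (orientation > 0) {
        p$start <- start + p$start
    } else {
        p$start <- start + (L - (p$start + p$length))
        p$orientation <- -p$orientation
    }
    g <- u@gaps
    if (orientation < 0 && nrow(g)) {
        g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
        tmp <- g$left; g$left <- g$right; g$right <- tmp
        tmp <- g$trimLeft; g$trimLeft <- g$trimRight; g$trimRight <- tmp
    }
    p <- p[order(p$start), , drop = FALSE]
    list(placements = p, gaps = g)
}

#' Run the full scaffolding pipeline
#'
#' Executes \code{iterations} rounds of graph construction, orientation,
#' distance clustering, trimmed regression and untangling, replacing the
#' current units by the resulting super-contigs each round (link
#' coordinates are remapped into the new frames; reversed units reflect
#' coordinates and strands). MaxError follows
#' \code{\link{maxErrorSchedule}}. The loop stops early when a round merges
#' nothing.
#'
#' @param contigs \code{DNAStringSet} or named numeric lengths of the
#'   preliminary contigs.
#' @param links preprocessed link data.frame.
#' @param libraries named list of \linkS4class{SeqLibrary} (final insert
#'   models).
#' @param iterations number of pipeline rounds \code{k} (default 3).
#' @param threshold link-count threshold; \code{NULL} for the 10\%-quantile
#'   default, recomputed each round.
#' @param maxErrorBase base MaxError in bp (default 100).
#' @param overlapTolerance passed to \code{\link{untangle}}.
#' @param level confidence level for gap intervals.
#' @param clusterArgs extra arguments for \code{\link{clusterObservations}}.
#' @return list with \code{superContigs} (list of \linkS4class{SuperContig}
#'   over the original contigs), \code{layouts} (final round's layouts over
#'   units), \code{rounds} (rounds actually run).
#' @export
scaffoldPipeline <- function(contigs, links, libraries, iterations = 3,
                             threshold = NULL, maxErrorBase = 100,
                             overlapTolerance = 200, level = 0.95,
                             clusterArgs = list()) {
    stopifnot(iterations >= 1)
    lens <- contigLengths(contigs)
    units <- lapply(names(lens), function(id) {
        newSuperContig(id, data.frame(contig = id, orientation = 1,
                                      start = 0, length = lens[[id]]))
    })
    names(units) <- names(lens)
    layouts <- list()
    rounds <- 0L
    for (r in seq_len(iterations)) {
        rounds <- r
        maxError <- maxErrorSchedule(maxErrorBase, r - 1L)
        map <- unitMap(units)
        curLinks <- remapLinks(links, map)
        unitLens <- stats::setNames(
            vapply(units, unitLength, numeric(1)), names(units))
        graph <- buildGraph(curLinks, names(units), threshold = threshold)
        curLinks <- linksOnGraph(curLinks, graph)
        comps <- connectedComponents(graph)
        layouts <- list()
        chainsOut <- list()
        for (comp in comps) {
            ls <- fitComponent(comp, curLinks, libraries, unitLens,
                               maxError = maxError,
                               clusterArgs = clusterArgs)
            layouts <- c(layouts, ls)
            for (lay in ls)
                chainsOut <- c(chainsOut,
                               untangle(lay, unitLens,
                                        overlapTolerance = overlapTolerance,
                                        level = level,
                                        idPrefix = sprintf("r%d", r)))
        }
        merged <- any(vapply(chainsOut,
                             function(sc) nrow(sc@placements) > 1L,
                             logical(1)))
        newUnits <- list()
        for (ci in seq_along(chainsOut)) {
            sc <- chainsOut[[ci]]
            up <- sc@placements
            allP <- list(); allG <- list()
            for (q in seq_len(nrow(up))) {
                u <- units[[up$contig[q]]]
                tr <- transformUnit(u, up$start[q], up$orientation[q])
                allP[[q]] <- tr$placements
                if (nrow(tr$gaps)) allG[[length(allG) + 1L]] <- tr$gaps
                if (q < nrow(up)) {
                    gRow <- sc@gaps[q, , drop = FALSE]
                    # junction between boundary contigs of adjacent units
                    leftUnitP <- tr$placements
                    gRow$left <- leftUnitP$contig[nrow(leftUnitP)]
                    nxt <- transformUnit(units[[up$contig[q + 1L]]],
                                         up$start[q + 1L],
                                         up$orientation[q + 1L])
                    gRow$right <- nxt$placements$contig[1L]
                    allG[[length(allG) + 1L]] <- gRow
                }
            }
            plc <- do.call(rbind, allP)
            plc <- plc[order(plc$start), , drop = FALSE]
            gp <- if (length(allG)) do.call(rbind, allG) else NULL
            if (!is.null(gp)) {
                # order gap rows along the final placement
                gp <- gp[match(plc$contig[-nrow(plc)], gp$left), ,
                         drop = FALSE]
                rownames(gp) <- NULL
            }
            id <- sprintf("scaffold_%d", ci)
            newUnits[[id]] <- newSuperContig(id, plc, gp)
        }
        units <- newUnits
        if (!merged) {
            ltsLog("round %d merged nothing; stopping early", r)
            break
        }
    }
    names(units) <- NULL
    list(superContigs = units, layouts = layouts, rounds = rounds)
}
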
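# Untangling layouts into super-contigs, overlap polishing and
# residual-based assessment of existing scaffolds.

# total selected link support between a pair, from a layout's observations
pairSupport <- function(obs, a, b) {
    sum(obs$n[obs$selected & obs$i == pmin(a, b) & obs$j == pmax(a, b)])
}

#' Untangle a layout into super-contigs
#'
#' Contigs are walked in order of estimated position. When the next contig
#' would overlap the chain's last contig by more than
#' \code{overlapTolerance}, the placement is tangled (typically collapsed
#' repeats): among the contending contigs, the one with the most supporting
#' links (cluster sizes of trimmed-in observations) to the current contig
#' continues the chain — ties broken toward the smaller estimated overlap —
#' and the others each seed a new super-contig, to be reconsidered in later
#' pipeline iterations.
#'
#' @param layout a \linkS4class{LayoutEstimate}.
#' @param contigLengths named numeric vector.
#' @param overlapTolerance maximum tolerated adjacent overlap in bp
#'   (default 200).
#' @param level confidence level for gap intervals.
#' @param idPrefix prefix for generated super-contig ids.
#' @return list of \linkS4class{SuperContig}, each with gap CIs from the
#'   layout covariance.
#' @export
untangle <- function(layout, contigLengths, overlapTolerance = 200,
                     level = 0.95, idPrefix = "scaffold") {
    b <- layout@beta
    ids <- names(sort(b))
    m <- length(ids)
    obs <- layout@observations
    if (m == 1L) {
        sc <- newSuperContig(paste0(idPrefix, "_1"),
                             data.frame(contig = ids, orientation = layout@D[ids],
                                        start = 0,
                                        length = contigLengths[ids]))
        return(list(sc))
    }
    chains <- list()
    cur <- ids[1L]
    k <- 2L
    while (k <= m) {
        last <- cur[length(cur)]
        lastEnd <- b[last] + contigLengths[last]
        # run of contigs overlapping `last` beyond the tolerance
        run <- integer(0)
        while (k <= m && b[ids[k]] < lastEnd - overlapTolerance) {
            run <- c(run, k)
            k <- k + 1L
        }
        if (!length(run)) {
            cur <- c(cur, ids[k])
            k <- k + 1L
            next
        }
        cand <- ids[run]
        support <- vapply(cand, function(cc) pairSupport(obs, last, cc),
                          numeric(1))
        # ties toward the smaller estimated overlap, i.e. the larger start
        best <- cand[order(-support, -b[cand])][1L]
        cur <- c(cur, best)
        for (loser in setdiff(cand, best))
            chains[[length(chains) + 1L]] <- loser
    }
    chains <- c(list(cur), chains)
    z <- stats::qnorm(1 - (1 - level) / 2)
    out <- vector("list", length(chains))
    for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        start <- b[ch] - b[ch[1L]]
        plc <- data.frame(contig = ch, orientation = layout@D[ch],
                          start = as.numeric(start),
                          length = as.numeric(contigLengths[ch]))
        gp <- NULL
        if (length(ch) >= 2L) {
            left <- ch[-length(ch)]; right <- ch[-1L]
            gap <- b[right] - b[left] - contigLengths[left]
            v <- diag(layout@cov)[right] + diag(layout@cov)[left] -
                2 * layout@cov[cbind(right, left)]
            se <- sqrt(pmax(0, v))
            ncl <- vapply(seq_along(left), function(q) {
                sum(obs$selected & obs$i == pmin(left[q], right[q]) &
                    obs$j == pmax(left[q], right[q]))
            }, integer(1))
            gp <- data.frame(left = left, right = right,
                             gap = as.numeric(gap),
                             lo = as.numeric(gap - z * se),
                             hi = as.numeric(gap + z * se),
                             nClusters = ncl, merged = FALSE,
                             trimLeft = 0, trimRight = 0)
        }
        out[[ci]] <- newSuperContig(sprintf("%s_%d", idPrefix, ci), plc, gp)
    }
    out
}

#' Polish scaffolds by merging overlapping adjacent contigs
#'
#' For each adjacent pair whose estimated gap is negative (an estimated
#' overlap of at most \code{maxOverlapCheck} bp), the 3' end of the left
#' contig is locally aligned against the 5' end of the right one over a
#' window of the estimated overlap plus three standard errors. When the
#' alignment reaches the junction with identity at least \code{minIdentity}
#' the contigs are merged, spliced at the alignment midpoint; otherwise the
#' junction is kept with a 1 bp gap.
#'
#' @param supercontigs list of \linkS4class{SuperContig}.
#' @param contigs \code{DNAStringSet} of contig sequences.
#' @param maxOverlapCheck largest estimated overlap considered (default
#'   2000 bp).
#' @param minIdentity minimum alignment identity (default 0.95).
#' @return the list with merge annotations filled in the gap tables.
#' @export
polish <- function(supercontigs, contigs, maxOverlapCheck = 2000,
                   minIdentity = 0.95) {
    lapply(supercontigs, function(sc) {
        g <- sc@gaps
        if (!nrow(g)) return(sc)
        p <- sc@placements
        for (k in seq_len(nrow(g))) {
            if (!(g$gap[k] < 0 && -g$gap[k] <= maxOverlapCheck)) next
            ovlEst <- -g$gap[k]
            se <- if (is.finite(g$hi[k]) && is.finite(g$lo[k]))
                (g$hi[k] - g$lo[k]) / (2 * stats::qnorm(0.975)) else 50
            win <- ceiling(ovlEst + 3 * max(se, 10))
            leftSeq <- orientedSeq(contigs, g$left[k],
                                   p$orientation[p$contig == g$left[k]])
            rightSeq <- orientedSeq(contigs, g$right[k],
                                    p$orientation[p$contig == g$right[k]])
            wL <- min(win, nchar(leftSeq))
            wR <- min(win, nchar(rightSeq))
            endL <- substr(leftSeq, nchar(leftSeq) - wL + 1L, nchar(leftSeq))
            startR <- substr(rightSeq, 1L, wR)
            aln <- Biostrings::pairwiseAlignment(endL, startR, type = "local")
            alnLen <- Biostrings::nchar(aln)
            if (alnLen < max(10L, floor(ovlEst / 2))) next
            ident <- Biostrings::pid(aln, type = "PID1") / 100
            pStart <- IRanges::start(Biostrings::pattern(aln))
            pEnd <- IRanges::end(Biostrings::pattern(aln))
            sStart <- IRanges::start(Biostrings::subject(aln))
            sEnd <- IRanges::end(Biostrings::subject(aln))
            reachesJunction <- (wL - pEnd) <= 3L && (sStart - 1L) <= 3L
            if (ident >= minIdentity && reachesJunction) {
                ovl <- round(((wL - pStart + 1L) + sEnd) / 2)
                g$merged[k] <- TRUE
                g$gap[k] <- -ovl
                g$trimLeft[k] <- floor(ovl / 2)
                g$trimRight[k] <- ovl - floor(ovl / 2)
            } else {
                g$gap[k] <- max(g$gap[k], -maxOverlapCheck)  # kept, floored later
            }
        }
        methods::initialize(sc, gaps = g)
    })
}

orientedSeq <- function(contigs, id, orientation) {
    s <- getContigSeq(contigs, id)
    if (orientation < 0) s <- Biostrings::reverseComplement(s)
    as.character(s)
}

#' Assess an existing scaffold by regression residuals
#'
#' Plugs the scaffold's contig positions into the linear model, recomputes
#' compressed observations from the links, and reports observations with
#' residuals above \code{maxError} as outliers. If removing the flagged
#' observations disconnects the link graph over the scaffold's contigs,
#' each adjacent placement pair spanning two of the resulting components is
#' reported as a suspicious junction.
#'
#' @param supercontig a \linkS4class{SuperContig} (or anything with
#'   placements).
#' @param links preprocessed link data.frame restricted to the assembly.
#' @param libraries named list of \linkS4class{SeqLibrary}.
#' @param maxError residual bound in bp (default 100).
#' @param ... passed to \code{\link{clusterObservations}}.
#' @return list with \code{outliers} (flagged observation rows with
#'   residuals), \code{observations} (all rows) and \code{suspicious}
#'   (data.frame of junctions \code{left}, \code{right}).
#' @export
assessScaffold <- function(supercontig, links, libraries, maxError = 100,
                           ...) {
    p <- supercontig@placements
    beta <- stats::setNames(p$start, p$contig)
    D <- stats::setNames(p$orientation, p$contig)
    lens <- stats::setNames(p$length, p$contig)
    lk <- links[links$i %in% p$contig & links$j %in% p$contig, , drop = FALSE]
    lk <- orientationSupported(lk, D)
    lk <- linkDistances(lk, D, lens, libraries)
    obs <- clusterObservations(lk, libraries, ...)
    if (!nrow(obs))
        return(list(outliers = obs, observations = obs,
                    suspicious = data.frame(left = character(),
                                            right = character())))
    obs$resid <- (beta[obs$j] - beta[obs$i]) - obs$Y
    obs$flagged <- abs(obs$resid) > maxError
    keptEdges <- obs[!obs$flagged, c("i", "j"), drop = FALSE]
    comps <- dfsComponents(p$contig, keptEdges)
    suspicious <- data.frame(left = character(), right = character())
    if (length(comps) > 1L) {
        compOf <- stats::setNames(rep(seq_along(comps),
                                      lengths(comps)), unlist(comps))
        adjL <- p$contig[-nrow(p)]
        adjR <- p$contig[-1L]
        bad <- compOf[adjL] != compOf[adjR]
        suspicious <- data.frame(left = adjL[bad], right = adjR[bad],
                                 row.names = NULL)
    }
    list(outliers = obs[obs$flagged, , drop = FALSE], observations = obs,
         suspicious = suspicious)
}
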
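# Linking distances and their per-pair, per-library clustering.
#
# Once orientations are fixed, every supported link measures the difference
# between its two contigs' start coordinates. For a paired read with insert
# mean mu and outer-end mapping coordinates s_i, s_j (measured in the
# oriented contig frames), the linking distance is
#   F = mu + s_i - s_j      when contig i is upstream,
#   F = -(mu - s_i + s_j)   otherwise;
# for a long read it is F = qs_j - qs_i + cs_i - cs_j from the alignment
# starts on the read (qs) and on the contigs (cs). Distances for one contig
# pair and library are then clustered by a kernel density with bandwidth
# sigma_b / 2 so that multi-modal evidence (e.g. around tandem repeats)
# yields several observations instead of one corrupted average. Each
# cluster is compressed to its median, whose sampling error follows the
# median central limit theorem: sd = sqrt(pi / (2 n)) * sigma_b.

#' Linking distance of paired links
#'
#' @param mu library insert mean (bp).
#' @param si,sj outer-end mapping coordinates in the oriented contig frames.
#' @param iUpstream logical; is contig i upstream of contig j?
#' @return observed \code{beta_j - beta_i} in bp.
#' @export
pairedDistance <- function(mu, si, sj, iUpstream) {
    ifelse(iUpstream, mu + si - sj, -(mu - si + sj))
}

#' Linking distance of TGS links
#'
#' @param qsi,qsj alignment starts on the long read.
#' @param csi,csj alignment starts on the (oriented) contigs.
#' @return observed \code{beta_j - beta_i} in bp.
#' @export
tgsDistance <- function(qsi, qsj, csi, csj) {
    qsj - qsi + csi - csj
}

#' Fill linking distances for a table of orientation-supported links
#'
#' Remaps coordinates of contigs assigned \code{D = -1} by reflection
#' (\code{s -> L - s}; alignment intervals likewise) before applying the
#' distance formulas. Reads traversing the layout in reverse (TGS only) are
#' first reflected into their reverse-complement frame.
#'
#' @param links orientation-supported link data.frame.
#' @param D named orientation vector.
#' @param contigLengths named numeric vector.
#' @param libraries named list of \linkS4class{SeqLibrary}.
#' @return \code{links} with the \code{F} column filled.
#' @export
linkDistances <- function(links, D, contigLengths, libraries) {
    if (!nrow(links)) return(links)
    Li <- contigLengths[links$i]; Lj <- contigLengths[links$j]
    Di <- D[links$i]; Dj <- D[links$j]
    paired <- links$type == "paired"
    if (any(paired)) {
        p <- which(paired)
        si <- ifelse(Di[p] > 0, links$si[p], Li[p] - links$si[p])
        sj <- ifelse(Dj[p] > 0, links$sj[p], Lj[p] - links$sj[p])
        gi <- links$gi[p] * Di[p]
        mu <- vapply(links$lib[p], function(l) insertMean(libraries[[l]]),
                     numeric(1))
        links$F[p] <- pairedDistance(mu, si, sj, iUpstream = gi > 0)
    }
    if (any(!paired)) {
        t <- which(!paired)
        csi <- ifelse(Di[t] > 0, links$csi[t],
                      Li[t] - links$csi[t] - links$leni[t])
        csj <- ifelse(Dj[t] > 0, links$csj[t],
                      Lj[t] - links$csj[t] - links$lenj[t])
        sp <- links$strandi[t] * Di[t]      # traversal strand in layout frame
        qsi <- links$qsi[t]; qsj <- links$qsj[t]
        rev <- sp < 0 & !is.na(links$qlen[t])
        qsi[rev] <- links$qlen[t][rev] - (links$qsi[t][rev] + links$qaleni[t][rev])
        qsj[rev] <- links$qlen[t][rev] - (links$qsj[t][rev] + links$qalenj[t][rev])
        links$F[t] <- tgsDistance(qsi, qsj, csi, csj)
    }
    links
}

#' Cluster one pair's linking distances by kernel density
#'
#' A kernel density with bandwidth \code{sigma/2} is evaluated on a grid of
#' step \code{sigma/20} padded \code{3 sigma} beyond the data range; local
#' maxima are candidate modes. Peaks are merged when closer than
#' \code{mergeDistance} (default \code{2 sigma}) or when the saddle between
#' them stays above \code{saddleRatio} (default 0.6) of the lower peak —
#' the operational meaning of "well separated". Every distance is assigned
#' to its nearest surviving peak, and clusters whose medians still fall
#' within \code{mergeDistance} of each other are collapsed, which keeps
#' the mode structure stable across kernels.
#'
#' @param distances numeric vector of linking distances (one contig pair,
#'   one library).
#' @param sigma the library insert SD (bp); for TGS pairs a pseudo-sigma.
#' @param kernel density kernel: \code{"gaussian"} (default),
#'   \code{"epanechnikov"} or \code{"rectangular"} (tophat).
#' @param mergeDistance,saddleRatio peak-separation parameters.
#' @param minPeakMass smallest share of the pair's links a separate mode
#'   may carry (default 0.1); smaller clumps are folded into the nearest
#'   cluster.
#' @param minClusterSize clusters smaller than this are dropped (default 1,
#'   i.e. keep all; the graph link-count threshold already guards noise).
#' @param multiMode set \code{FALSE} to force a single cluster (the
#'   single-median compression baseline used for comparison).
#' @return list with \code{assignment} (cluster index per distance) and
#'   \code{peaks} (cluster centres: member medians, ascending).
#' @export
clusterPair <- function(distances, sigma, kernel = "gaussian",
                        mergeDistance = 2 * sigma, saddleRatio = 0.6,
                        minPeakMass = 0.1, minClusterSize = 1L,
                        multiMode = TRUE) {
    n <- length(distances)
    stopifnot(n >= 1L)
    if (!multiMode || n == 1L || diff(range(distances)) < .Machine$double.eps)
        return(list(assignment = rep(1L, n), peaks = stats::median(distances)))
    step <- sigma / 20
    lo <- min(distances) - 3 * sigma
    hi <- max(distances) + 3 * sigma
    npts <- max(32L, ceiling((hi - lo) / step) + 1L)
    den <- stats::density(distances, bw = sigma / 2, kernel = kernel,
                          from = lo, to = hi, n = npts)
    x <- den$x; y <- den$y
    k <- length(y)
    isPeak <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] &
                       y[2:(k - 1)] >= y[3:k], FALSE)
    pk <- which(isPeak)
    # finite-support kernels leave numerically-zero ripples in the padded
    # tails; they are not modes
    pk <- pk[y[pk] >= 1e-3 * max(y)]
    if (!length(pk)) pk <- which.max(y)
    # merge insufficiently separated peaks, closest-in-density first
    repeat {
        if (length(pk) <= 1L) break
        merged <- FALSE
        for (a in seq_len(length(pk) - 1L)) {
            p1 <- pk[a]; p2 <- pk[a + 1L]
            saddle <- min(y[p1:p2])
            lower <- min(y[p1], y[p2])
            if ((x[p2] - x[p1]) < mergeDistance || saddle > saddleRatio * lower) {
                pk <- pk[-(if (y[p1] < y[p2]) a else a + 1L)]
                merged <- TRUE
                break
            }
        }
        if (!merged) break
    }
    peaks <- x[pk]
    assignment <- vapply(distances,
                         function(d) which.min(abs(peaks - d)), integer(1))
    if (minClusterSize > 1L) {
        sizes <- tabulate(assignment, nbins = length(peaks))
        keep <- which(sizes >= minClusterSize)
        if (!length(keep)) keep <- which.max(sizes)
        peaks <- peaks[keep]
        assignment <- vapply(distances,
                             function(d) which.min(abs(peaks - d)), integer(1))
    }
    # rougher kernels (tophat, epanechnikov) can shatter one mode into
    # several nearby maxima; clusters whose medians are closer than the
    # merge distance are collapsed so the mode structure is kernel-robust
    repeat {
        meds <- vapply(split(distances, assignment), stats::median,
                       numeric(1))
        if (length(meds) <= 1L) break
        ord <- order(meds)
        gapsBetween <- diff(meds[ord])
        k <- which.min(gapsBetween)
        if (gapsBetween[k] >= mergeDistance) break
        from <- as.integer(names(meds)[ord][k + 1L])
        into <- as.integer(names(meds)[ord][k])
        assignment[assignment == from] <- into
    }
    # a mode must carry a non-negligible share of the pair's links;
    # stray clumps below minPeakMass are folded into the nearest cluster
    repeat {
        tab <- table(assignment)
        if (length(tab) <= 1L) break
        frac <- tab / length(distances)
        if (min(frac) >= minPeakMass) break
        meds <- vapply(split(distances, assignment), stats::median,
                       numeric(1))
        small <- names(frac)[which.min(frac)]
        others <- setdiff(names(meds), small)
        tgt <- others[which.min(abs(meds[others] - meds[small]))]
        assignment[assignment == as.integer(small)] <- as.integer(tgt)
    }
    peaks <- vapply(split(distances, assignment), stats::median, numeric(1))
    ord <- order(peaks)
    assignment <- match(assignment, as.integer(names(peaks)[ord]))
    list(assignment = assignment, peaks = unname(peaks[ord]))
}

#' Compress one cluster of linking distances into an observation
#'
#' The observation is the member median; its weight is
#' \code{n / variance-basis}, where the variance basis is the member sample
#' variance when the cluster holds more than 6 links (and that variance is
#' positive) and the library variance \code{sigma^2} otherwise.
#'
#' @param members linking distances of one cluster.
#' @param sigma library insert SD (bp).
#' @param useSampleVar use the member sample variance for clusters larger
#'   than 6 (default). \code{FALSE} always trusts \code{sigma^2}, which is
#'   how single-observation-per-pair scaffolders weight their compressed
#'   link bundles; the single-median baseline mode uses it.
#' @return list with \code{Y} (median), \code{n}, \code{w} (1/bp^2) and
#'   \code{varBasis}.
#' @export
compressCluster <- function(members, sigma, useSampleVar = TRUE) {
    n <- length(members)
    stopifnot(n >= 1L)
    v <- if (n > 1L) stats::var(members) else 0
    varBasis <- if (useSampleVar && n > 6L && v > 0) v else sigma^2
    list(Y = stats::median(members), n = n, w = n / varBasis,
         varBasis = varBasis)
}

#' Two-SD residual bound for a compressed observation
#'
#' The median central limit theorem gives a compressed observation the
#' standard deviation \code{sqrt(pi / (2 n)) * sigma}; the default residual
#' bound of the trimming loop is derived from the two-SD value of a typical
#' cluster (n = 150, sigma = 500), about 102.33 bp, rounded down to 100.
#'
#' @param n cluster size (links).
#' @param sigma insert SD (bp).
#' @param z multiplier (default 2).
#' @return \code{z * sqrt(pi / (2 n)) * sigma} in bp.
#' @examples
#' medianErrorBound(150, 500)   # ~102.33
#' @export
medianErrorBound <- function(n, sigma, z = 2) {
    z * sqrt(pi / (2 * n)) * sigma
}

#' Compressed observations for a set of supported links
#'
#' Groups links by (contig pair, library), clusters each group's linking
#' distances and compresses every cluster to a weighted median observation.
#' Paired groups use the library insert SD; TGS groups use a pseudo-sigma
#' equal to the MAD-SD of the group's distances, floored at
#' \code{tgsSigmaFloor}.
#'
#' @param links link data.frame with \code{F} filled.
#' @param libraries named list of \linkS4class{SeqLibrary}.
#' @param tgsSigmaFloor floor for the TGS pseudo-sigma (default 50 bp).
#' @param useSampleVar passed to \code{\link{compressCluster}}; set
#'   \code{FALSE} together with \code{multiMode = FALSE} for the
#'   single-median baseline.
#' @param ... passed to \code{\link{clusterPair}} (kernel, merge rules,
#'   \code{multiMode}).
#' @return data.frame with columns \code{i}, \code{j}, \code{lib},
#'   \code{Y}, \code{n}, \code{w}, \code{sigma} and a list column
#'   \code{members}.
#' @export
clusterObservations <- function(links, libraries, tgsSigmaFloor = 50,
                                useSampleVar = TRUE, ...) {
    empty <- data.frame(i = character(), j = character(), lib = character(),
                        Y = numeric(), n = integer(), w = numeric(),
                        sigma = numeric())
    empty$members <- list()
    if (!nrow(links)) return(empty)
    # canonical direction: i < j; F measures beta_j - beta_i in that order
    ci <- pmin(links$i, links$j)
    cj <- pmax(links$i, links$j)
    Fc <- ifelse(links$i <= links$j, links$F, -links$F)
    key <- paste(ci, cj, links$lib, sep = "\r")
    out <- list()
    for (grp in split(seq_len(nrow(links)), key)) {
        one <- links[grp[1L], ]
        d <- Fc[grp]
        sigma <- if (one$type == "tgs") {
            max(tgsSigmaFloor, stats::mad(d))
        } else {
            insertSd(libraries[[one$lib]])
        }
        cl <- clusterPair(d, sigma, ...)
        for (k in sort(unique(cl$assignment))) {
            mem <- d[cl$assignment == k]
            cp <- compressCluster(mem, sigma, useSampleVar = useSampleVar)
            row <- data.frame(i = ci[grp[1L]], j = cj[grp[1L]],
                              lib = one$lib, Y = cp$Y, n = cp$n,
                              w = cp$w, sigma = sigma)
            row$members <- list(mem)
            out[[length(out) + 1L]] <- row
        }
    }
    res <- do.call(rbind, out)
    res <- res[order(res$i, res$j, res$lib, res$Y), , drop = FALSE]
    rownames(res) <- NULL
    res
}
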
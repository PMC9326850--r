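# Alignment filtering and per-library insert-model re-estimation.
#
# Three filters run before the scaffolding graph is built: ambiguous
# (multi-mapped) reads are removed entirely, links whose reads fall in
# high-coverage (collapsed-repeat) intervals are dropped, and paired links
# mapping too far from the joining contig edge (beyond mu + 3 sigma) are
# discarded. Insert models are re-estimated robustly from read pairs mapped
# to the same long contig.

#' Insert-size model re-estimated from same-contig pairs
#'
#' @slot libraryId library the model belongs to.
#' @slot insertMean,insertSd robust estimates in bp.
#' @slot nPairsUsed number of same-contig pairs behind the estimate; 0 when
#'   the nominal configuration values were kept.
#' @export
setClass("InsertModel", representation(
    libraryId = "character",
    insertMean = "numeric",
    insertSd = "numeric",
    nPairsUsed = "numeric"
))

setValidity("InsertModel", function(object) {
    if (!isTRUE(object@insertSd > 0)) "insertSd must be > 0" else TRUE
})

setMethod("show", "InsertModel", function(object) {
    cat(sprintf("InsertModel '%s': %.1f +/- %.1f bp (%d pairs)\n",
                object@libraryId, object@insertMean, object@insertSd,
                as.integer(object@nPairsUsed)))
})

#' Re-estimate a library's insert model from same-contig pairs
#'
#' Only pairs mapped inside contigs longer than \code{minContigLength}
#' (default 10 kb) are used, so that the observed spans are not truncated by
#' contig ends. Location is estimated by the median and scale by
#' 1.4826 x MAD, which chimeric pairs cannot break. When fewer than
#' \code{minPairs} usable pairs exist the nominal model is kept, with a
#' warning.
#'
#' @param sameContig data.frame from \code{\link{readAlignments}} with
#'   columns \code{lib}, \code{contig}, \code{contigLength}, \code{insert}.
#' @param library a \linkS4class{SeqLibrary} holding the nominal model.
#' @param minContigLength contigs at or below this length are excluded.
#' @param minPairs minimum usable pairs before the estimate replaces the
#'   nominal model (default 100).
#' @return an \linkS4class{InsertModel}.
#' @export
estimateInsert <- function(sameContig, library, minContigLength = 10000,
                           minPairs = 100) {
    obs <- sameContig$insert[sameContig$lib == libId(library) &
                             sameContig$contigLength > minContigLength]
    if (length(obs) < minPairs) {
        warning(sprintf(
            "library '%s': only %d same-contig pairs on long contigs; keeping nominal insert model",
            libId(library), length(obs)))
        return(new("InsertModel", libraryId = libId(library),
                   insertMean = insertMean(library),
                   insertSd = insertSd(library), nPairsUsed = 0))
    }
    mu <- stats::median(obs)
    sg <- stats::mad(obs)          # 1.4826 * MAD
    if (sg <= 0) sg <- insertSd(library)
    new("InsertModel", libraryId = libId(library), insertMean = mu,
        insertSd = sg, nPairsUsed = length(obs))
}

#' Fold an insert model back into its library
#'
#' @param library a \linkS4class{SeqLibrary}.
#' @param model an \linkS4class{InsertModel} for the same library.
#' @return the updated \linkS4class{SeqLibrary}.
#' @export
applyInsertModel <- function(library, model) {
    stopifnot(libId(library) == model@libraryId)
    library@insertMean <- model@insertMean
    library@insertSd <- model@insertSd
    library@nPairsUsed <- model@nPairsUsed
    library
}

#' Mask high-coverage intervals
#'
#' Returns, per contig, maximal runs of coverage bins whose mean coverage
#' exceeds \code{max(2 x assembly-wide median, median + 3 x MAD-SD)}; such
#' intervals flag collapsed repeats whose links are untrustworthy.
#'
#' @param coverage binned coverage track from \code{\link{readAlignments}}
#'   (list per contig, \code{attr(, "bin")} bin width).
#' @param medianFactor multiplier on the assembly-wide median (default 2).
#' @param madFactor multiplier on the MAD-SD (default 3).
#' @return named list of data.frames with 0-based half-open \code{start},
#'   \code{end} columns.
#' @export
markHighCoverage <- function(coverage, medianFactor = 2, madFactor = 3) {
    bin <- attr(coverage, "bin")
    all <- unlist(coverage, use.names = FALSE)
    out <- lapply(coverage, function(x) data.frame(start = numeric(),
                                                   end = numeric()))
    if (!length(all)) return(out)
    med <- stats::median(all)
    cutoff <- max(medianFactor * med, med + madFactor * stats::mad(all))
    for (cn in names(coverage)) {
        hi <- coverage[[cn]] > cutoff
        if (!any(hi)) next
        r <- rle(hi)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        w <- which(r$values)
        out[[cn]] <- data.frame(start = (starts[w] - 1L) * bin,
                                end = ends[w] * bin)
    }
    out
}

#' Drop links touching masked intervals
#'
#' A paired link is removed when either read's outer end lies inside a
#' masked high-coverage interval; a TGS link when either alignment start
#' does.
#'
#' @param links link data.frame.
#' @param mask per-contig interval list from \code{\link{markHighCoverage}}.
#' @return filtered link data.frame.
#' @export
dropMaskedLinks <- function(links, mask) {
    if (!nrow(links)) return(links)
    inMask <- function(contig, pos) {
        bad <- logical(length(contig))
        ok <- !is.na(pos)
        for (cn in unique(contig[ok])) {
            m <- mask[[cn]]
            if (is.null(m) || !nrow(m)) next
            idx <- which(contig == cn & ok)
            for (r in seq_len(nrow(m)))
                bad[idx] <- bad[idx] | (pos[idx] >= m$start[r] &
                                        pos[idx] < m$end[r])
        }
        bad
    }
    paired <- links$type == "paired"
    posI <- ifelse(paired, links$si, links$csi)
    posJ <- ifelse(paired, links$sj, links$csj)
    drop <- inMask(links$i, posI) | inMask(links$j, posJ)
    ltsLog("high-coverage mask dropped %d of %d links", sum(drop), nrow(links))
    links[!drop, , drop = FALSE]
}

#' Remove ambiguous (multi-mapped) reads from a link table
#'
#' Any read id contributing more than one link row is taken as multi-mapped
#' and removed entirely. (SAM input already removes reads with secondary or
#' duplicated primary records at parse time; this guard also covers the TSV
#' dialect.)
#'
#' @param links link data.frame.
#' @return filtered link data.frame.
#' @export
dropAmbiguous <- function(links) {
    if (!nrow(links)) return(links)
    paired <- links[links$type == "paired", , drop = FALSE]
    dupIds <- unique(paired$readId[duplicated(paired$readId)])
    keep <- !(links$type == "paired" & links$readId %in% dupIds)
    ltsLog("ambiguity filter dropped %d of %d links", sum(!keep), nrow(links))
    links[keep, , drop = FALSE]
}

#' Contig-edge filter on paired links
#'
#' A paired read whose fragment must extend past the contig edge by more
#' than \code{mu + 3 sigma} cannot belong to a genuine link; such links are
#' removed. The relevant distance is from the read's outer end to the edge
#' the fragment points across: the downstream edge for a rightward-pointing
#' read (\code{L - s}) and the upstream edge for a leftward-pointing one
#' (\code{s}). The bound is inclusive (distance equal to \code{mu + 3 sigma}
#' is kept). TGS links pass through untouched.
#'
#' @param links link data.frame.
#' @param libraries named list of \linkS4class{SeqLibrary} with final insert
#'   models.
#' @param contigLengths named numeric vector of contig lengths.
#' @return filtered link data.frame.
#' @export
edgeFilter <- function(links, libraries, contigLengths) {
    if (!nrow(links)) return(links)
    paired <- links$type == "paired"
    if (!any(paired)) return(links)
    mu <- vapply(links$lib, function(l) insertMean(libraries[[l]]), numeric(1))
    sg <- vapply(links$lib, function(l) insertSd(libraries[[l]]), numeric(1))
    bound <- mu + 3 * sg
    Li <- contigLengths[links$i]
    Lj <- contigLengths[links$j]
    edgeI <- ifelse(links$gi > 0, Li - links$si, links$si)
    edgeJ <- ifelse(links$gj > 0, Lj - links$sj, links$sj)
    keep <- !paired | (edgeI <= bound & edgeJ <= bound)
    ltsLog("edge filter dropped %d of %d links", sum(!keep), nrow(links))
    links[keep, , drop = FALSE]
}
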
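#' @import methods
#' @importFrom stats median mad density qnorm quantile rnorm runif sd var setNames
#' @importFrom utils head read.table write.table
NULL

#' Sequencing library description
#'
#' Holds the per-library insert model used throughout scaffolding. Paired
#' kinds (\code{"PE"}, \code{"MP"}) carry an insert mean \code{insertMean}
#' and standard deviation \code{insertSd} in base pairs; third-generation
#' (\code{"TGS"}) libraries carry no insert model. \code{alreadyFlipped}
#' marks a mate-pair library whose aligner pipeline already reoriented
#' reads into paired-end (inward) geometry.
#'
#' @slot id single library identifier.
#' @slot kind one of \code{"PE"}, \code{"MP"}, \code{"TGS"}.
#' @slot insertMean,insertSd insert-size model in bp (\code{NA} for TGS).
#' @slot readLength informational read length in bp.
#' @slot alreadyFlipped logical; MP geometry already converted to PE.
#' @slot nPairsUsed number of same-contig pairs behind the current insert
#'   model; 0 means nominal (configured) values.
#' @export
setClass("SeqLibrary", representation(
    id = "character",
    kind = "character",
    insertMean = "numeric",
    insertSd = "numeric",
    readLength = "numeric",
    alreadyFlipped = "logical",
    nPairsUsed = "numeric"
))

setValidity("SeqLibrary", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (!object@kind %in% c("PE", "MP", "TGS"))
        msg <- c(msg, "'kind' must be one of PE, MP, TGS")
    if (object@kind %in% c("PE", "MP")) {
        if (!isTRUE(object@insertMean > 0))
            msg <- c(msg, "paired library needs insertMean > 0")
        if (!isTRUE(object@insertSd > 0))
            msg <- c(msg, "paired library needs insertSd > 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SeqLibrary
#'
#' @param id library identifier.
#' @param kind \code{"PE"} (short-insert, inward-facing pairs), \code{"MP"}
#'   (long-insert, outward-facing pairs) or \code{"TGS"} (long reads).
#' @param insertMean,insertSd nominal insert model in bp (paired kinds only).
#' @param readLength read length in bp (informational).
#' @param alreadyFlipped for MP libraries whose reads were already flipped
#'   into PE geometry by the aligner pipeline.
#' @return a \linkS4class{SeqLibrary}.
#' @examples
#' Library("pe1", "PE", insertMean = 800, insertSd = 80, readLength = 100)
#' @export
Library <- function(id, kind = c("PE", "MP", "TGS"), insertMean = NA_real_,
                    insertSd = NA_real_, readLength = 100,
                    alreadyFlipped = FALSE) {
    kind <- match.arg(kind)
    new("SeqLibrary", id = as.character(id), kind = kind,
        insertMean = as.numeric(insertMean), insertSd = as.numeric(insertSd),
        readLength = as.numeric(readLength),
        alreadyFlipped = isTRUE(alreadyFlipped), nPairsUsed = 0)
}

setMethod("show", "SeqLibrary", function(object) {
    cat(sprintf("SeqLibrary '%s' [%s]", object@id, object@kind))
    if (object@kind != "TGS")
        cat(sprintf(" insert %.0f +/- %.0f bp", object@insertMean,
                    object@insertSd))
    if (object@nPairsUsed > 0)
        cat(sprintf(" (re-estimated from %d pairs)", as.integer(object@nPairsUsed)))
    cat("\n")
})

#' @rdname accessors
#' @param x an object of the documented classes.
#' @export
setGeneric("libId", function(x) standardGeneric("libId"))
#' @rdname accessors
#' @export
setMethod("libId", "SeqLibrary", function(x) x@id)
#' @rdname accessors
#' @export
setGeneric("libKind", function(x) standardGeneric("libKind"))
#' @rdname accessors
#' @export
setMethod("libKind", "SeqLibrary", function(x) x@kind)
#' @rdname accessors
#' @export
setGeneric("insertMean", function(x) standardGeneric("insertMean"))
#' @rdname accessors
#' @export
setMethod("insertMean", "SeqLibrary", function(x) x@insertMean)
#' @rdname accessors
#' @export
setGeneric("insertSd", function(x) standardGeneric("insertSd"))
#' @rdname accessors
#' @export
setMethod("insertSd", "SeqLibrary", function(x) x@insertSd)

#' Scaffolding graph over contigs
#'
#' Contigs are vertices; an edge joins two contigs when the number of links
#' between them reaches the link-count threshold. Per edge the counts
#' \code{a} (links voting the two contigs co-oriented) and \code{b} (links
#' voting them anti-oriented) are tallied.
#'
#' @slot vertices character vector of contig ids.
#' @slot edges data.frame with columns \code{i}, \code{j}, \code{a}, \code{b};
#'   one row per unordered pair, \code{i < j} lexicographically.
#' @slot threshold the minimum link count an edge had to reach.
#' @export
setClass("ScaffoldGraph", representation(
    vertices = "character",
    edges = "data.frame",
    threshold = "numeric"
))

setValidity("ScaffoldGraph", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("i", "j", "a", "b") %in% names(e)))
        msg <- c(msg, "edges need columns i, j, a, b")
    else {
        if (any(e$i == e$j)) msg <- c(msg, "self-edges are not allowed")
        if (!all(c(e$i, e$j) %in% object@vertices))
            msg <- c(msg, "edge endpoints must be vertices")
        if (nrow(e) && any(e$a + e$b < object@threshold))
            msg <- c(msg, "every retained edge must meet the link-count threshold")
        if (anyDuplicated(paste(pmin(e$i, e$j), pmax(e$i, e$j))))
            msg <- c(msg, "edges must be stored once per unordered pair")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ScaffoldGraph", function(object) {
    cat(sprintf("ScaffoldGraph: %d contigs, %d edges (link threshold %g)\n",
                length(object@vertices), nrow(object@edges), object@threshold))
})

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setMethod("graphEdges", "ScaffoldGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setGeneric("graphVertices", function(x) standardGeneric("graphVertices"))
#' @rdname accessors
#' @export
setMethod("graphVertices", "ScaffoldGraph", function(x) x@vertices)

#' Per-component layout estimate
#'
#' The result of orienting and positioning one connected component: an
#' orientation vector \code{D} (anchor fixed to +1), estimated start
#' coordinates \code{beta} (anchor at 0), the compressed observations with
#' residuals and the trimmed-in subset, and the covariance machinery needed
#' for gap confidence intervals.
#'
#' @slot contigs contig ids in the component.
#' @slot D named orientation vector in \{+1, -1\}.
#' @slot beta named start coordinates (bp), anchor exactly 0.
#' @slot observations data.frame of compressed observations (columns
#'   \code{i}, \code{j}, \code{lib}, \code{Y}, \code{n}, \code{w},
#'   \code{resid}, \code{selected}).
#' @slot cov covariance matrix of \code{beta} (anchor row/col zero).
#' @slot sigma2 residual scale estimate used for \code{cov}.
#' @slot modelVariance TRUE when no residual degrees of freedom were
#'   available and the weight-based model variance was used instead.
#' @slot iterations trimming iterations performed.
#' @slot maxError the residual bound the fit converged under (bp).
#' @export
setClass("LayoutEstimate", representation(
    contigs = "character",
    D = "numeric",
    beta = "numeric",
    observations = "data.frame",
    cov = "matrix",
    sigma2 = "numeric",
    modelVariance = "logical",
    iterations = "numeric",
    maxError = "numeric"
))

setValidity("LayoutEstimate", function(object) {
    msg <- character()
    if (length(object@D) != length(object@contigs) ||
        length(object@beta) != length(object@contigs))
        msg <- c(msg, "D and beta must cover the component")
    if (length(object@D) && !all(object@D %in% c(-1, 1)))
        msg <- c(msg, "D entries must be +1/-1")
    if (length(object@beta) && min(abs(object@beta)) > 1e-9)
        msg <- c(msg, "the anchor contig's beta must be exactly 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LayoutEstimate", function(object) {
    nsel <- sum(object@observations$selected)
    cat(sprintf(paste0("LayoutEstimate: %d contigs, %d/%d observations kept",
                       " (MaxError %g bp, %d trimming iterations)\n"),
                length(object@contigs), nsel, nrow(object@observations),
                object@maxError, as.integer(object@iterations)))
})

#' @rdname accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))
#' @rdname accessors
#' @export
setMethod("orientations", "LayoutEstimate", function(x) x@D)
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "LayoutEstimate", function(x) x@beta)
#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @rdname accessors
#' @export
setMethod("observations", "LayoutEstimate", function(x) x@observations)

#' A super-contig: linearly placed, oriented contigs with estimated gaps
#'
#' @slot id scaffold identifier.
#' @slot placements data.frame with columns \code{contig}, \code{orientation}
#'   (+1/-1), \code{start} (bp on the scaffold axis), \code{length} (bp),
#'   sorted by \code{start}.
#' @slot gaps data.frame with one row per adjacent pair: \code{left},
#'   \code{right}, \code{gap}, \code{lo}, \code{hi}, \code{nClusters},
#'   \code{merged}, \code{trimLeft}, \code{trimRight}. Negative \code{gap}
#'   means estimated overlap; merged junctions record how many bases are
#'   spliced off each side.
#' @slot sequence \code{DNAString} after polishing/rendering (may be empty
#'   until sequences are attached).
#' @export
setClass("SuperContig", representation(
    id = "character",
    placements = "data.frame",
    gaps = "data.frame",
    sequence = "ANY"
))

setValidity("SuperContig", function(object) {
    p <- object@placements
    msg <- character()
    if (!all(c("contig", "orientation", "start", "length") %in% names(p)))
        msg <- c(msg, "placements need contig/orientation/start/length")
    else {
        if (is.unsorted(p$start)) msg <- c(msg, "placements must be sorted by start")
        if (anyDuplicated(p$contig)) msg <- c(msg, "a contig may appear only once")
    }
    if (nrow(object@gaps) && nrow(object@gaps) != nrow(p) - 1L)
        msg <- c(msg, "one gap row per adjacent placement pair")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SuperContig", function(object) {
    cat(sprintf("SuperContig '%s': %d contigs", object@id,
                nrow(object@placements)))
    if (nrow(object@gaps))
        cat(sprintf(", gaps %s bp",
                    paste(round(object@gaps$gap), collapse = "/")))
    cat("\n")
})

#' @rdname accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))
#' @rdname accessors
#' @export
setMethod("placements", "SuperContig", function(x) x@placements)
#' @rdname accessors
#' @export
setGeneric("gaps", function(x) standardGeneric("gaps"))
#' @rdname accessors
#' @export
setMethod("gaps", "SuperContig", function(x) x@gaps)

# internal constructor; gaps filled with defaults where absent
newSuperContig <- function(id, placements, gaps = NULL, sequence = NULL) {
    placements <- placements[order(placements$start), , drop = FALSE]
    rownames(placements) <- NULL
    if (is.null(gaps)) {
        n <- nrow(placements)
        if (n >= 2L) {
            gap <- placements$start[-1L] -
                (placements$start[-n] + placements$length[-n])
            gaps <- data.frame(left = placements$contig[-n],
                               right = placements$contig[-1L],
                               gap = gap, lo = NA_real_, hi = NA_real_,
                               nClusters = NA_integer_, merged = FALSE,
                               trimLeft = 0, trimRight = 0)
        } else {
            gaps <- emptyGapTable()
        }
    }
    new("SuperContig", id = as.character(id), placements = placements,
        gaps = gaps, sequence = sequence)
}

emptyGapTable <- function() {
    data.frame(left = character(), right = character(), gap = numeric(),
               lo = numeric(), hi = numeric(), nClusters = integer(),
               merged = logical(), trimLeft = numeric(), trimRight = numeric())
}
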
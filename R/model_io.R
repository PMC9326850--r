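# Readers and writers for the standard formats the scaffolder touches:
# contig FASTA, SAM/BAM paired alignments, PAF long-read alignments, a TSV
# link dialect (the simulator's native output), AGP v2.1 and the gap report.
# All internal coordinates are 0-based half-open; SAM/AGP 1-based coordinates
# are converted at the boundary.

#' Read contigs from FASTA
#'
#' @param path FASTA file of preliminary contigs.
#' @return a \code{\link[Biostrings]{DNAStringSet}}; names are the first
#'   whitespace-delimited header token, sequences upper-cased.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 descr", "acgtacgtac", ">c2", "ACGT"), fa)
#' ctg <- readContigs(fa)
#' width(ctg)
#' @export
readContigs <- function(path) {
    if (!file.exists(path)) stop("no such FASTA file: ", path)
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L) stop("empty FASTA: ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate contig id(s) in ", path, ": ",
             paste(dup, collapse = ", "))
    names(seqs) <- ids
    # normalise case; width is preserved
    Biostrings::DNAStringSet(toupper(seqs))
}

#' Read a library configuration (YAML)
#'
#' The file holds a top-level \code{libraries:} list, each entry with fields
#' \code{id}, \code{kind} (PE/MP/TGS), \code{mean}, \code{sd},
#' \code{read_length} and optional \code{already_flipped}.
#'
#' @param path YAML file.
#' @return named list of \linkS4class{SeqLibrary} objects.
#' @export
readLibraryConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    entries <- cfg$libraries
    if (is.null(entries)) stop("config has no 'libraries' section: ", path)
    libs <- lapply(entries, function(e) {
        Library(id = e$id, kind = e$kind,
                insertMean = if (is.null(e$mean)) NA_real_ else e$mean,
                insertSd = if (is.null(e$sd)) NA_real_ else e$sd,
                readLength = if (is.null(e$read_length)) 100 else e$read_length,
                alreadyFlipped = isTRUE(e$already_flipped))
    })
    names(libs) <- vapply(libs, libId, character(1))
    if (anyDuplicated(names(libs))) stop("duplicate library ids in config")
    libs
}

# reference-consumed width from a CIGAR string (M/D/N/=/X)
cigarRefWidth <- function(cigar) {
    vapply(cigar, function(cg) {
        if (is.na(cg) || cg == "*") return(NA_real_)
        ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
        lens <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
        num <- as.numeric(sub("[MIDNSHP=X]$", "", lens))
        op <- sub("^\\d+", "", lens)
        sum(num[op %in% c("M", "D", "N", "=", "X")])
    }, numeric(1), USE.NAMES = FALSE)
}

#' Read alignments and extract inter-contig links
#'
#' Dispatches on the file extension: \code{.sam}/\code{.bam} are read as
#' paired SGS alignments, \code{.paf} as TGS long-read alignments and
#' \code{.links.tsv}/\code{.tsv} as the package's own link dialect (written
#' by the simulator and by \code{\link{writeLinksTSV}}).
#'
#' Paired records on two distinct contigs become links; pairs mapped to one
#' contig are routed to insert-size estimation. Multi-mapped reads (SAM
#' secondary records, or duplicated primary read ids) are removed entirely,
#' both mates. Mate-pair geometry is reduced to the inward (paired-end)
#' convention unless the library is marked \code{alreadyFlipped}, in which
#' case records are taken as inward already.
#'
#' @param path alignment file.
#' @param libraries named list of \linkS4class{SeqLibrary}.
#' @param contigs \code{DNAStringSet} of contigs, or a named numeric vector
#'   of contig lengths.
#' @param libraryId library the file belongs to (required for SAM/PAF; the
#'   TSV dialect carries its own \code{lib} column).
#' @param minAligned minimum aligned length (bp) for a TGS local alignment
#'   to count (default 500).
#' @param covBin coverage-track bin width in bp.
#' @return list with elements \code{links} (link data.frame, see
#'   \code{\link{emptyLinks}}), \code{sameContig} (data.frame of same-contig
#'   pair observations: \code{lib}, \code{contig}, \code{contigLength},
#'   \code{insert}), \code{coverage} (per-contig binned mean coverage) and
#'   \code{counters} (named counts of skipped records).
#' @export
readAlignments <- function(path, libraries, contigs, libraryId = NULL,
                           minAligned = 500, covBin = 200L) {
    lens <- contigLengths(contigs)
    ext <- tolower(sub(".*\\.", "", path))
    if (ext %in% c("sam", "bam")) {
        if (is.null(libraryId)) stop("libraryId is required for SAM/BAM input")
        lib <- libraries[[libraryId]]
        if (is.null(lib)) stop("unknown library id: ", libraryId)
        readSamPairs(path, lib, lens, covBin = covBin)
    } else if (ext == "paf") {
        if (is.null(libraryId)) stop("libraryId is required for PAF input")
        lib <- libraries[[libraryId]]
        if (is.null(lib)) stop("unknown library id: ", libraryId)
        if (libKind(lib) != "TGS") stop("PAF input expects a TGS library")
        readPafLinks(path, lib, lens, minAligned = minAligned, covBin = covBin)
    } else {
        lk <- readLinksTSV(path)
        unknown <- setdiff(unique(lk$lib), names(libraries))
        if (length(unknown))
            stop("unknown library id(s) in ", path, ": ",
                 paste(unknown, collapse = ", "))
        list(links = lk, sameContig = emptySameContig(),
             coverage = emptyCoverage(lens, covBin), counters = c(records = nrow(lk)))
    }
}

#' Contig lengths from a DNAStringSet or named numeric vector
#'
#' @param contigs \code{DNAStringSet} or named numeric vector of lengths.
#' @return named numeric vector of lengths in bp.
#' @export
contigLengths <- function(contigs) {
    if (methods::is(contigs, "DNAStringSet"))
        return(stats::setNames(as.numeric(Biostrings::width(contigs)),
                               names(contigs)))
    if (is.null(names(contigs))) stop("contig lengths must be named")
    stats::setNames(as.numeric(contigs), names(contigs))
}

emptySameContig <- function() {
    data.frame(lib = character(), contig = character(),
               contigLength = numeric(), insert = numeric())
}

emptyCoverage <- function(lens, covBin) {
    cov <- lapply(lens, function(L) numeric(max(1L, ceiling(L / covBin))))
    attr(cov, "bin") <- covBin
    cov
}

# accumulate alignment footprints onto the binned coverage track
addCoverage <- function(cov, contig, pos, width) {
    bin <- attr(cov, "bin")
    if (!length(pos)) return(cov)
    mid <- pmax(0, pos + width / 2)
    sp <- split(width, contig)
    spm <- split(mid, contig)
    for (cn in names(sp)) {
        if (is.null(cov[[cn]])) next
        b <- pmin(length(cov[[cn]]), floor(spm[[cn]] / bin) + 1L)
        tab <- tapply(sp[[cn]], b, sum)
        idx <- as.integer(names(tab))
        cov[[cn]][idx] <- cov[[cn]][idx] + as.numeric(tab) / bin
    }
    cov
}

readSamPairs <- function(path, lib, lens, covBin = 200L) {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(path, destination = dest,
                                overwrite = TRUE, indexDestination = FALSE)
    }
    what <- c("qname", "flag", "rname", "strand", "pos", "cigar",
              "mrnm", "mpos")
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
    flag <- res$flag
    counters <- c(records = length(flag), unmappedMate = 0L,
                  multiMapped = 0L, unpaired = 0L)
    keep <- !bitwAnd(flag, 4L)                      # mapped
    primary <- !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
    # reads with any secondary/supplementary record, or duplicated primary
    # records, are ambiguous: remove both mates (drop_ambiguous)
    mateOrd <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)
    key <- paste(res$qname, mateOrd)
    ambig <- unique(res$qname[!primary | duplicated(key) & primary])
    ambig <- unique(c(ambig, res$qname[primary][duplicated(key[primary])]))
    counters["multiMapped"] <- length(ambig)
    sel <- keep & primary & !(res$qname %in% ambig)
    qname <- res$qname[sel]; flag <- res$flag[sel]
    rname <- as.character(res$rname[sel]); pos <- res$pos[sel]
    strand <- ifelse(bitwAnd(flag, 16L) > 0L, -1L, 1L)
    rw <- cigarRefWidth(res$cigar[sel])
    pos0 <- pos - 1                                  # SAM is 1-based
    cov <- emptyCoverage(lens, covBin)
    cov <- addCoverage(cov, rname, pos0, rw)
    mateUnmapped <- bitwAnd(flag, 8L) > 0L
    counters["unmappedMate"] <- sum(mateUnmapped)
    ok <- !mateUnmapped
    qname <- qname[ok]; rname <- rname[ok]; pos0 <- pos0[ok]
    strand <- strand[ok]; rw <- rw[ok]
    mateOrd <- ifelse(bitwAnd(res$flag[sel][ok], 64L) > 0L, 1L, 2L)
    unknown <- setdiff(unique(rname), names(lens))
    if (length(unknown))
        stop("alignment references unknown contig(s): ",
             paste(unknown, collapse = ", "))
    ord <- order(qname, mateOrd)
    qname <- qname[ord]; rname <- rname[ord]; pos0 <- pos0[ord]
    strand <- strand[ord]; rw <- rw[ord]
    first <- !duplicated(qname)
    paired <- qname %in% qname[duplicated(qname)]
    counters["unpaired"] <- sum(first & !paired)
    i1 <- which(first & paired)
    i2 <- i1 + 1L
    geom <- pairGeometry(lib,
                         contig1 = rname[i1], pos1 = pos0[i1], width1 = rw[i1],
                         strand1 = strand[i1],
                         contig2 = rname[i2], pos2 = pos0[i2], width2 = rw[i2],
                         strand2 = strand[i2], readId = qname[i1])
    list(links = geom$links, sameContig = sameContigTable(geom, lib, lens),
         coverage = cov, counters = counters)
}

# reduce raw mate geometry to links + same-contig insert observations.
# Outer (fragment-side) ends: for inward (PE) geometry the forward read's
# outer end is its leftmost coordinate and the reverse read's its rightmost;
# an un-flipped MP library is the mirror image and is reduced to the inward
# convention by negating strands.
pairGeometry <- function(lib, contig1, pos1, width1, strand1,
                         contig2, pos2, width2, strand2, readId) {
    g1 <- strand1; g2 <- strand2
    if (libKind(lib) == "MP" && !lib@alreadyFlipped) {
        g1 <- -g1; g2 <- -g2
    }
    outer1 <- ifelse(g1 > 0L, pos1, pos1 + width1)
    outer2 <- ifelse(g2 > 0L, pos2, pos2 + width2)
    same <- contig1 == contig2
    lk <- emptyLinks(sum(!same))
    if (any(!same)) {
        w <- which(!same)
        lk$readId <- readId[w]
        lk$i <- contig1[w]; lk$j <- contig2[w]
        lk$d <- -(g1[w] * g2[w])
        lk$lib <- libId(lib); lk$type <- "paired"
        lk$si <- outer1[w]; lk$sj <- outer2[w]
        lk$gi <- g1[w]; lk$gj <- g2[w]
    }
    list(links = lk,
         sameIdx = which(same),
         sameContig = contig1[same],
         sameInsert = abs(outer2[same] - outer1[same]))
}

sameContigTable <- function(geom, lib, lens) {
    if (!length(geom$sameContig)) return(emptySameContig())
    data.frame(lib = libId(lib), contig = geom$sameContig,
               contigLength = as.numeric(lens[geom$sameContig]),
               insert = geom$sameInsert)
}

readPafLinks <- function(path, lib, lens, minAligned = 500, covBin = 200L) {
    cols <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                              fill = TRUE, header = FALSE)[, 1:12]
    names(cols) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                     "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
    unknown <- setdiff(unique(cols$tname), names(lens))
    if (length(unknown))
        stop("alignment references unknown contig(s): ",
             paste(unknown, collapse = ", "))
    cov <- emptyCoverage(lens, covBin)
    cov <- addCoverage(cov, cols$tname, cols$tstart, cols$tend - cols$tstart)
    cols <- cols[cols$qend - cols$qstart >= minAligned, , drop = FALSE]
    links <- emptyLinks(0L)
    counters <- c(records = nrow(cols))
    if (nrow(cols)) {
        byq <- split(cols, cols$qname)
        out <- list()
        for (rec in byq) {
            tab <- table(rec$tname)
            usable <- names(tab)[tab == 1L]        # exactly one alignment per contig
            rec <- rec[rec$tname %in% usable, , drop = FALSE]
            if (nrow(rec) < 2L) next
            rec <- rec[order(rec$qstart), , drop = FALSE]
            cmb <- utils::combn(nrow(rec), 2L)
            for (cix in seq_len(ncol(cmb))) {
                a <- rec[cmb[1L, cix], ]; b <- rec[cmb[2L, cix], ]
                lk <- emptyLinks(1L)
                lk$readId <- a$qname; lk$i <- a$tname; lk$j <- b$tname
                si <- if (a$strand == "+") 1L else -1L
                sj <- if (b$strand == "+") 1L else -1L
                lk$d <- si * sj
                lk$lib <- libId(lib); lk$type <- "tgs"
                lk$qsi <- a$qstart; lk$qsj <- b$qstart
                lk$csi <- a$tstart; lk$csj <- b$tstart
                lk$leni <- a$tend - a$tstart; lk$lenj <- b$tend - b$tstart
                lk$qaleni <- a$qend - a$qstart; lk$qalenj <- b$qend - b$qstart
                lk$qlen <- a$qlen
                lk$strandi <- si; lk$strandj <- sj
                out[[length(out) + 1L]] <- lk
            }
        }
        if (length(out)) links <- do.call(rbind, out)
    }
    list(links = links, sameContig = emptySameContig(), coverage = cov,
         counters = counters)
}

#' Write / read the TSV link dialect
#'
#' A flat tab-separated serialisation of the canonical link table (the
#' simulator's native output, also accepted by \code{\link{readAlignments}}).
#'
#' @param links link data.frame.
#' @param path file path.
#' @return \code{readLinksTSV} returns the link data.frame.
#' @export
writeLinksTSV <- function(links, path) {
    utils::write.table(completeLinks(links), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeLinksTSV
#' @export
readLinksTSV <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(readId = "character",
                                           i = "character", j = "character",
                                           lib = "character",
                                           type = "character"))
    completeLinks(df)
}

#' Write scaffolds: FASTA, AGP v2.1 and the gap report
#'
#' Gap runs are rendered as N stretches of length \code{max(gap, 1)}; a
#' merged junction (resolved overlap) is written as two adjacent W lines
#' whose component spans drop the spliced bases. The gap report is
#' tab-separated with columns scaffold, left contig, right contig, gap
#' estimate, CI low, CI high and supporting-cluster count.
#'
#' @param supercontigs list of \linkS4class{SuperContig}.
#' @param contigs \code{DNAStringSet} of contig sequences.
#' @param fastaPath,agpPath,gapReportPath output paths.
#' @return invisibly, the rendered \code{DNAStringSet}.
#' @export
writeScaffolds <- function(supercontigs, contigs, fastaPath, agpPath,
                           gapReportPath) {
    if (!length(supercontigs))
        warning("no scaffolds to write; emitting empty files")
    seqs <- character(0)
    agp <- character(0)
    gapRows <- list()
    agp <- c(agp, "##agp-version\t2.1")
    for (sc in supercontigs) {
        r <- renderSuperContig(sc, contigs)
        seqs[sc@id] <- r$sequence
        agp <- c(agp, r$agp)
        if (nrow(sc@gaps)) {
            g <- sc@gaps
            gapRows[[length(gapRows) + 1L]] <-
                data.frame(scaffold = sc@id, left = g$left, right = g$right,
                           gap = round(g$gap, 2), ci_low = round(g$lo, 2),
                           ci_high = round(g$hi, 2), n_clusters = g$nClusters)
        }
    }
    out <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(out, fastaPath)
    writeLines(agp, agpPath)
    gapTab <- if (length(gapRows)) do.call(rbind, gapRows) else
        data.frame(scaffold = character(), left = character(),
                   right = character(), gap = numeric(), ci_low = numeric(),
                   ci_high = numeric(), n_clusters = integer())
    utils::write.table(gapTab, gapReportPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}

# render one super-contig: spliced sequence + AGP rows (1-based, v2.1)
renderSuperContig <- function(sc, contigs) {
    p <- sc@placements
    g <- sc@gaps
    parts <- character(0)
    agp <- character(0)
    cursor <- 0          # 0-based object cursor
    part <- 0L
    for (k in seq_len(nrow(p))) {
        L <- p$length[k]
        trimL <- if (k > 1L && nrow(g)) g$trimRight[k - 1L] else 0
        trimR <- if (k < nrow(p) && nrow(g) && isTRUE(g$merged[k])) g$trimLeft[k] else 0
        cb <- trimL + 1L                 # component_beg, 1-based
        ce <- L - trimR                  # component_end
        seqk <- as.character(getContigSeq(contigs, p$contig[k]))
        if (p$orientation[k] < 0)
            seqk <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(seqk)))
        seqk <- substr(seqk, cb, ce)
        part <- part + 1L
        agp <- c(agp, paste(sc@id, cursor + 1L, cursor + (ce - cb + 1L), part,
                            "W", p$contig[k], cb, ce,
                            if (p$orientation[k] > 0) "+" else "-",
                            sep = "\t"))
        parts <- c(parts, seqk)
        cursor <- cursor + (ce - cb + 1L)
        if (k < nrow(p) && nrow(g)) {
            if (isTRUE(g$merged[k])) next
            glen <- max(1L, round(g$gap[k]))
            part <- part + 1L
            agp <- c(agp, paste(sc@id, cursor + 1L, cursor + glen, part, "N",
                                glen, "scaffold", "yes", "paired-ends",
                                sep = "\t"))
            parts <- c(parts, strrep("N", glen))
            cursor <- cursor + glen
        }
    }
    list(sequence = paste(parts, collapse = ""), agp = agp)
}

getContigSeq <- function(contigs, id) {
    if (!id %in% names(contigs)) stop("missing sequence for contig ", id)
    contigs[[id]]
}

#' Read scaffold structure back from AGP
#'
#' Reconstructs placements (contig, orientation, start of the full contig
#' frame on the object) and gap sizes from W/N rows.
#'
#' @param path AGP v2.1 file.
#' @return list of \linkS4class{SuperContig} (without sequences).
#' @export
readAGP <- function(path) {
    ln <- readLines(path)
    ln <- ln[!grepl("^#", ln) & nzchar(ln)]
    if (!length(ln)) return(list())
    fld <- strsplit(ln, "\t")
    bad <- which(vapply(fld, length, integer(1)) < 8L)
    if (length(bad))
        stop("malformed AGP at line ", bad[1L], ": ", ln[bad[1L]])
    obj <- vapply(fld, `[[`, character(1), 1L)
    out <- list()
    for (id in unique(obj)) {
        rows <- fld[obj == id]
        plc <- list(); gp <- list()
        lastContig <- NA_character_
        pendingGap <- NA_real_
        for (f in rows) {
            if (f[[5]] == "W") {
                cb <- as.numeric(f[[7]]); ce <- as.numeric(f[[8]])
                ob <- as.numeric(f[[2]]) - 1
                ori <- if (f[[9]] == "-") -1 else 1
                start <- if (ori > 0) ob - (cb - 1) else ob  # full-frame start
                plc[[length(plc) + 1L]] <-
                    data.frame(contig = f[[6]], orientation = ori,
                               start = start, length = ce)
                if (!is.na(lastContig)) {
                    gp[[length(gp) + 1L]] <-
                        data.frame(left = lastContig, right = f[[6]],
                                   gap = if (is.na(pendingGap)) 0 else pendingGap,
                                   lo = NA_real_, hi = NA_real_,
                                   nClusters = NA_integer_,
                                   merged = is.na(pendingGap),
                                   trimLeft = 0, trimRight = 0)
                }
                lastContig <- f[[6]]
                pendingGap <- NA_real_
            } else if (f[[5]] %in% c("N", "U")) {
                pendingGap <- as.numeric(f[[6]])
            } else {
                stop("malformed AGP component type '", f[[5]], "' in ", path)
            }
        }
        pl <- do.call(rbind, plc)
        gg <- if (length(gp)) do.call(rbind, gp) else emptyGapTable()
        out[[id]] <- new("SuperContig", id = id, placements = pl, gaps = gg,
                         sequence = NULL)
    }
    out
}
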
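# Alignment-level simulator: planted genomes, fragmented contigs and links
# with the statistical structure the scaffolder assumes — normal insert
# sizes, optional short-insert contamination (bimodal libraries), and
# repeat-induced mis-mapping of edge reads (the false-cluster mechanism).
# Links are emitted directly at the alignment level (no FASTQ, no mapper),
# so every pipeline stage can be scored against the planted truth.

#' Generate a random genome with planted tandem repeats
#'
#' i.i.d. uniform ACGT background; each repeat specification inserts an
#' exact tandem block (\code{copies} identical \code{unitLength}-mers) at
#' \code{position} by overwriting the background.
#'
#' @param length genome length in bp.
#' @param repeats list of lists with fields \code{unitLength},
#'   \code{copies}, \code{position} (0-based start).
#' @param seed RNG seed (deterministic output per seed).
#' @return a character string of length \code{length}.
#' @export
makeGenome <- function(length, repeats = list(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    bases <- c("A", "C", "G", "T")
    g <- sample(bases, length, replace = TRUE)
    for (rp in repeats) {
        u <- rp$unitLength
        block <- rep(sample(bases, u, replace = TRUE), rp$copies)
        stopifnot(rp$position + length(block) <= length)
        g[(rp$position + 1L):(rp$position + length(block))] <- block
    }
    paste(g, collapse = "")
}

#' Fragment a genome into contigs with planted truth
#'
#' Contigs are genome substrings. Either explicit \code{breaks} (list of
#' 0-based half-open \code{c(start, end)} intervals) or an even layout of
#' \code{nContigs} contigs separated by \code{gapLength} is used. Intervals
#' overlapping a \code{dropIntervals} entry are trimmed (simulating
#' unassembled regions such as a missing repeat copy); contigs listed in
#' \code{revComp} are stored reverse-complemented, with the truth table
#' recording orientation -1.
#'
#' @param genome character string from \code{\link{makeGenome}}.
#' @param nContigs,gapLength even-layout parameters.
#' @param breaks explicit contig intervals (overrides the even layout).
#' @param dropIntervals list of \code{c(start, end)} genome intervals to
#'   exclude from contigs (edge trims).
#' @param revComp integer indices of contigs to reverse-complement.
#' @param idPrefix contig id prefix.
#' @return list with \code{contigs} (\code{DNAStringSet}) and \code{truth}
#'   (data.frame \code{contig}, \code{start}, \code{length},
#'   \code{orientation}).
#' @export
fragmentGenome <- function(genome, nContigs = NULL, gapLength = 0,
                           breaks = NULL, dropIntervals = NULL,
                           revComp = integer(0), idPrefix = "ctg") {
    G <- nchar(genome)
    if (is.null(breaks)) {
        stopifnot(!is.null(nContigs))
        clen <- floor((G - (nContigs - 1) * gapLength) / nContigs)
        starts <- (seq_len(nContigs) - 1L) * (clen + gapLength)
        breaks <- lapply(starts, function(s) c(s, s + clen))
    }
    for (dr in dropIntervals) {
        breaks <- lapply(breaks, function(iv) {
            if (dr[2] <= iv[1] || dr[1] >= iv[2]) return(iv)   # no overlap
            left <- c(iv[1], max(iv[1], dr[1]))
            right <- c(min(iv[2], dr[2]), iv[2])
            if (diff(left) >= diff(right)) left else right      # keep larger side
        })
    }
    n <- length(breaks)
    ids <- sprintf("%s%03d", idPrefix, seq_len(n))
    seqs <- vapply(breaks, function(iv) substr(genome, iv[1] + 1L, iv[2]),
                   character(1))
    ori <- rep(1L, n)
    ori[revComp] <- -1L
    seqs <- ifelse(ori > 0, seqs, vapply(seqs, function(s)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
        character(1)))
    contigs <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    truth <- data.frame(contig = ids,
                        start = vapply(breaks, `[`, numeric(1), 1L),
                        length = vapply(breaks, function(iv) diff(iv),
                                        numeric(1)),
                        orientation = ori)
    list(contigs = contigs, truth = truth)
}

# place a read span on the planted contigs; NA when not fully inside one
placeRead <- function(truth, gleft, gright) {
    idx <- rep(NA_integer_, length(gleft))
    for (k in seq_len(nrow(truth))) {
        s <- truth$start[k]; e <- s + truth$length[k]
        hit <- is.na(idx) & gleft >= s & gright <= e
        idx[hit] <- k
    }
    idx
}

#' Simulate paired links against planted contigs
#'
#' Fragment starts are uniform on the genome; insert sizes are
#' \code{N(mu, sigma^2)} truncated at twice the read length, with a
#' \code{contamination} fraction drawn instead from the short-insert
#' distribution (defaults 300/30 bp) — the bimodal PE-contaminated library
#' model. Reads whose locus falls in a \code{relocations} source interval
#' (a dropped repeat copy) are moved by that row's \code{offset} to a
#' surviving homologous copy with probability \code{mismapRate}, else left
#' unmapped; this reproduces the repeat-edge false-cluster mechanism.
#' Pairs with both reads on one contig are routed to same-contig insert
#' observations; pairs with an unmapped read are dropped.
#'
#' @param truth planted truth table from \code{\link{fragmentGenome}}.
#' @param genomeLength genome length in bp.
#' @param library a \linkS4class{SeqLibrary} (PE or MP).
#' @param coverage read coverage to simulate.
#' @param contamination fraction of short-insert pairs (default 0).
#' @param shortInsertMean,shortInsertSd contaminant insert model.
#' @param mismapRate probability that a read in a relocation source
#'   interval is mis-mapped instead of unmapped.
#' @param relocations data.frame with columns \code{start}, \code{end},
#'   \code{offset} (genome bp).
#' @param seed RNG seed.
#' @return list with \code{links}, \code{sameContig}, \code{counters}.
#' @export
simulatePairedLinks <- function(truth, genomeLength, library, coverage,
                                contamination = 0, shortInsertMean = 300,
                                shortInsertSd = 30, mismapRate = 0,
                                relocations = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(coverage > 0)
    rl <- library@readLength
    mu <- insertMean(library); sg <- insertSd(library)
    npairs <- round(coverage * genomeLength / (2 * rl))
    contaminated <- stats::runif(npairs) < contamination
    ins <- ifelse(contaminated,
                  stats::rnorm(npairs, shortInsertMean, shortInsertSd),
                  stats::rnorm(npairs, mu, sg))
    ins <- pmax(round(ins), 2 * rl)
    p <- floor(stats::runif(npairs) * pmax(1, genomeLength - ins))
    # genome spans; left read and right read of the fragment
    l1 <- p; r1 <- p + rl
    l2 <- p + ins - rl; r2 <- p + ins
    tau1 <- rep(1L, npairs); tau2 <- rep(-1L, npairs)       # PE geometry
    if (libKind(library) == "MP" && !library@alreadyFlipped) {
        tau1 <- -tau1; tau2 <- -tau2                        # outward pairs
    }
    drop <- rep(FALSE, npairs)
    if (!is.null(relocations) && nrow(relocations)) {
        if (is.null(relocations$rate)) relocations$rate <- mismapRate
        if (is.null(relocations$unmappedOtherwise))
            relocations$unmappedOtherwise <- TRUE
        shiftRead <- function(l, r) {
            shift <- numeric(length(l))
            dead <- rep(FALSE, length(l))
            for (q in seq_len(nrow(relocations))) {
                inSrc <- l >= relocations$start[q] & r <= relocations$end[q]
                mis <- inSrc & stats::runif(length(l)) < relocations$rate[q]
                shift[mis] <- relocations$offset[q]
                if (relocations$unmappedOtherwise[q])
                    dead[inSrc & !mis] <- TRUE
            }
            list(shift = shift, dead = dead)
        }
        s1 <- shiftRead(l1, r1); s2 <- shiftRead(l2, r2)
        l1 <- l1 + s1$shift; r1 <- r1 + s1$shift
        l2 <- l2 + s2$shift; r2 <- r2 + s2$shift
        drop <- s1$dead | s2$dead
    }
    k1 <- placeRead(truth, l1, r1)
    k2 <- placeRead(truth, l2, r2)
    ok <- !drop & !is.na(k1) & !is.na(k2)
    counters <- c(pairs = npairs, unplaced = sum(!ok))
    k1 <- k1[ok]; k2 <- k2[ok]
    l1 <- l1[ok]; r1 <- r1[ok]; l2 <- l2[ok]; r2 <- r2[ok]
    tau1 <- tau1[ok]; tau2 <- tau2[ok]
    # contig-frame coordinates and strands
    toContig <- function(kk, gl, gr, tau) {
        o <- truth$orientation[kk]
        s <- truth$start[kk]; L <- truth$length[kk]
        pos <- ifelse(o > 0, gl - s, (s + L) - gr)
        list(pos = pos, strand = tau * o)
    }
    c1 <- toContig(k1, l1, r1, tau1)
    c2 <- toContig(k2, l2, r2, tau2)
    geom <- pairGeometry(library,
                         contig1 = truth$contig[k1], pos1 = c1$pos,
                         width1 = rep(rl, length(k1)), strand1 = c1$strand,
                         contig2 = truth$contig[k2], pos2 = c2$pos,
                         width2 = rep(rl, length(k2)), strand2 = c2$strand,
                         readId = sprintf("%s_p%07d", libId(library),
                                          which(ok)))
    lens <- stats::setNames(truth$length, truth$contig)
    list(links = geom$links,
         sameContig = sameContigTable(geom, library, lens),
         counters = counters)
}

#' Simulate TGS links against planted contigs
#'
#' Error-free geometric simulation: read spans are uniform; for every pair
#' of contigs a read overlaps by at least \code{minAligned} bp, one TGS
#' link is emitted with alignment coordinates derived from the planted
#' truth.
#'
#' @param truth planted truth table.
#' @param genomeLength genome length in bp.
#' @param library a TGS \linkS4class{SeqLibrary}.
#' @param readLength long-read length in bp (fixed).
#' @param coverage coverage to simulate (0 gives an empty table).
#' @param minAligned minimum aligned length per contig (default 500).
#' @param seed RNG seed.
#' @return link data.frame.
#' @export
simulateTgsLinks <- function(truth, genomeLength, library, readLength,
                             coverage, minAligned = 500, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    out <- list()
    nreads <- round(coverage * genomeLength / readLength)
    if (nreads < 1L) return(emptyLinks(0L))
    p <- floor(stats::runif(nreads) * max(1, genomeLength - readLength))
    for (r in seq_len(nreads)) {
        gl <- p[r]; gr <- p[r] + readLength
        aln <- list()
        for (k in seq_len(nrow(truth))) {
            s <- truth$start[k]; e <- s + truth$length[k]
            a <- max(gl, s); b <- min(gr, e)
            if (b - a < minAligned) next
            o <- truth$orientation[k]
            cs <- if (o > 0) a - s else e - b
            aln[[length(aln) + 1L]] <-
                data.frame(k = k, qs = a - gl, cs = cs, len = b - a,
                           strand = o)
        }
        if (length(aln) < 2L) next
        aln <- do.call(rbind, aln)
        cmb <- utils::combn(nrow(aln), 2L)
        for (cx in seq_len(ncol(cmb))) {
            a1 <- aln[cmb[1L, cx], ]; a2 <- aln[cmb[2L, cx], ]
            lk <- emptyLinks(1L)
            lk$readId <- sprintf("%s_t%06d", libId(library), r)
            lk$i <- truth$contig[a1$k]; lk$j <- truth$contig[a2$k]
            lk$d <- a1$strand * a2$strand
            lk$lib <- libId(library); lk$type <- "tgs"
            lk$qsi <- a1$qs; lk$qsj <- a2$qs
            lk$csi <- a1$cs; lk$csj <- a2$cs
            lk$leni <- a1$len; lk$lenj <- a2$len
            lk$qaleni <- a1$len; lk$qalenj <- a2$len
            lk$qlen <- readLength
            lk$strandi <- a1$strand; lk$strandj <- a2$strand
            out[[length(out) + 1L]] <- lk
        }
    }
    if (!length(out)) return(emptyLinks(0L))
    do.call(rbind, out)
}

#' Simulate a complete planted assembly scenario
#'
#' Convenience wrapper: genome, evenly fragmented contigs and links from a
#' set of libraries, all deterministic per seed. Used throughout the test
#' suite and by the acceptance checks.
#'
#' @param genomeLength,nContigs,gapLength genome layout.
#' @param libraries named list of \linkS4class{SeqLibrary}.
#' @param coverages named numeric vector (per library id).
#' @param contamination named numeric vector of contamination fractions
#'   (default 0 for every library).
#' @param revComp indices of contigs stored reverse-complemented.
#' @param seed RNG seed.
#' @return list with \code{genome}, \code{contigs}, \code{truth},
#'   \code{links}, \code{sameContig}.
#' @export
simulateAssembly <- function(genomeLength = 200000, nContigs = 40,
                             gapLength = 200, libraries, coverages,
                             contamination = NULL, revComp = integer(0),
                             seed = 1) {
    genome <- makeGenome(genomeLength, seed = seed)
    fr <- fragmentGenome(genome, nContigs = nContigs, gapLength = gapLength,
                         revComp = revComp)
    links <- emptyLinks(0L)
    same <- emptySameContig()
    for (q in seq_along(libraries)) {
        lib <- libraries[[q]]
        cont <- if (is.null(contamination)) 0 else
            contamination[[libId(lib)]]
        if (is.null(cont) || is.na(cont)) cont <- 0
        if (libKind(lib) == "TGS") {
            lk <- simulateTgsLinks(fr$truth, genomeLength, lib,
                                   readLength = 8000,
                                   coverage = coverages[[libId(lib)]],
                                   seed = seed + 1000L * q)
            links <- rbind(links, lk)
        } else {
            sim <- simulatePairedLinks(fr$truth, genomeLength, lib,
                                       coverage = coverages[[libId(lib)]],
                                       contamination = cont,
                                       seed = seed + 1000L * q)
            links <- rbind(links, sim$links)
            same <- rbind(same, sim$sameContig)
        }
    }
    list(genome = genome, contigs = fr$contigs, truth = fr$truth,
         links = links, sameContig = same)
}

#' The tandem-repeat false-cluster scenario
#'
#' A genome carrying a tandem repeat block is cut into three contigs with
#' the first repeat copy trimmed off the middle contig's upstream edge
#' (unassembled). Reads whose true locus lies in the missing copy are
#' mis-mapped to the surviving homologous copy one unit downstream with
#' probability \code{mismapRate} (and left unmapped otherwise), producing a
#' false linking-distance cluster offset by one repeat unit between the
#' flanking contig and the middle contig. The short-insert library's
#' geometry concentrates its links on the junction, so within that library
#' the false cluster dominates; the long-insert library spans the short
#' middle contig and supplies the global (first-to-third contig) evidence
#' that lets the trimming regression discard the false mode.
#'
#' @param unitLength repeat unit (default 600 bp).
#' @param copies tandem copies (default 4).
#' @param mismapRate mis-mapping probability for reads in the dropped copy
#'   (default 0.9; a perfect homologous copy exists, so most such reads
#'   find an "optimal" alignment there).
#' @param coverageShort,coverageLong coverages of the two libraries.
#' @param seed RNG seed.
#' @return list with \code{contigs}, \code{truth}, \code{links},
#'   \code{libraries}, \code{trueGaps} (named by left contig id),
#'   \code{genomeLength}, \code{unitLength}.
#' @export
simulateTandemRepeatScenario <- function(unitLength = 600, copies = 4,
                                         mismapRate = 0.95,
                                         coverageShort = 50,
                                         coverageLong = 12, seed = 1) {
    # layout: ctgA [0, 6000) | gap 100 | repeat block | tail | gap | ctgC
    G <- 16000
    rpStart <- 6100
    blockLen <- unitLength * copies
    genome <- makeGenome(G, repeats = list(list(unitLength = unitLength,
                                                copies = copies,
                                                position = rpStart)),
                         seed = seed)
    bEnd <- rpStart + blockLen              # middle contig: pure repeat, copies 2..4
    cStart <- bEnd + 100
    breaks <- list(c(0, 6000), c(rpStart, bEnd), c(cStart, G))
    drops <- list(c(rpStart, rpStart + unitLength))  # first copy unassembled
    fr <- fragmentGenome(genome, breaks = breaks, dropIntervals = drops)
    libShort <- Library("pes", "PE", insertMean = 1200, insertSd = 100,
                        readLength = 100)
    libLong <- Library("mpl", "MP", insertMean = 5000, insertSd = 150,
                       readLength = 100)
    reloc <- data.frame(start = rpStart, end = rpStart + unitLength,
                        offset = unitLength)
    simS <- simulatePairedLinks(fr$truth, G, libShort,
                                coverage = coverageShort,
                                mismapRate = mismapRate,
                                relocations = reloc, seed = seed + 7L)
    simL <- simulatePairedLinks(fr$truth, G, libLong,
                                coverage = coverageLong,
                                mismapRate = mismapRate,
                                relocations = reloc, seed = seed + 13L)
    trueGaps <- stats::setNames(
        c(fr$truth$start[2] - (fr$truth$start[1] + fr$truth$length[1]),
          fr$truth$start[3] - (fr$truth$start[2] + fr$truth$length[2])),
        fr$truth$contig[1:2])
    list(contigs = fr$contigs, truth = fr$truth,
         links = rbind(simS$links, simL$links),
         libraries = stats::setNames(list(libShort, libLong),
                                     c(libId(libShort), libId(libLong))),
         trueGaps = trueGaps, genomeLength = G, unitLength = unitLength)
}
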
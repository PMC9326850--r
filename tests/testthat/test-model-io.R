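# FASTA / SAM / TSV / AGP readers and writers.

writeFasta <- function(lines) {
    fa <- tempfile(fileext = ".fa")
    writeLines(lines, fa)
    fa
}

test_that("readContigs parses, normalises and validates", {
    fa <- writeFasta(c(">c1 some description", "ACGTACGTAC",
                       ">c2", paste(rep("acgt", 5), collapse = "")))
    ctg <- readContigs(fa)
    expect_equal(length(ctg), 2L)
    expect_equal(unname(Biostrings::width(ctg)), c(10L, 20L))
    expect_equal(names(ctg), c("c1", "c2"))
    # lowercase input upper-cased, length preserved
    expect_equal(as.character(ctg[["c2"]]), strrep("ACGT", 5))

    dupfa <- writeFasta(c(">c1 a", "ACGT", ">c1 b", "GGCC"))
    expect_error(readContigs(dupfa), "duplicate.*c1")
    emptyfa <- writeFasta(character(0))
    expect_error(readContigs(emptyfa))
})

samFixture <- function(records) {
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 "@SQ\tSN:A\tLN:5000",
                 "@SQ\tSN:B\tLN:5000",
                 records), sam)
    sam
}

samLine <- function(qname, flag, rname, pos, mrnm = "=", mpos = 1) {
    paste(qname, flag, rname, pos, 60, "100M", mrnm, mpos, 0,
          strrep("A", 100), "*", sep = "\t")
}

test_that("SAM pairs on two contigs become links with the inward convention", {
    lib <- list(pe1 = Library("pe1", "PE", 3000, 300, 100))
    lens <- c(A = 5000, B = 5000)
    # d must equal -strand1*strand2 for PE geometry: enumerate all four
    # strand combinations (flag 16 = reverse; 64/128 mark mates)
    combos <- list(c(1L + 64L, 1L + 128L + 16L, +1L),        # + -  -> d=+1
                   c(1L + 64L + 16L, 1L + 128L, +1L),        # - +  -> d=+1
                   c(1L + 64L, 1L + 128L, -1L),              # + +  -> d=-1
                   c(1L + 64L + 16L, 1L + 128L + 16L, -1L))  # - -  -> d=-1
    for (cb in combos) {
        sam <- samFixture(c(samLine("r1", cb[1L], "A", 101, "B", 201),
                            samLine("r1", cb[2L], "B", 201, "A", 101)))
        al <- readAlignments(sam, lib, lens, libraryId = "pe1")
        expect_equal(nrow(al$links), 1L)
        expect_equal(al$links$d, cb[3L])
        expect_equal(al$links$type, "paired")
    }
    # outer ends: forward read outer = 0-based pos; reverse = pos + width
    sam <- samFixture(c(samLine("r1", 65L, "A", 101, "B", 201),
                        samLine("r1", 145L, "B", 201, "A", 101)))
    al <- readAlignments(sam, lib, lens, libraryId = "pe1")
    expect_equal(al$links$si, 100)
    expect_equal(al$links$sj, 300)
})

test_that("same-contig SAM pairs feed insert estimation, not links", {
    lib <- list(pe1 = Library("pe1", "PE", 3000, 300, 100))
    lens <- c(A = 5000, B = 5000)
    sam <- samFixture(c(samLine("r1", 65L, "A", 101, "=", 3001),
                        samLine("r1", 145L, "A", 3001, "=", 101)))
    al <- readAlignments(sam, lib, lens, libraryId = "pe1")
    expect_equal(nrow(al$links), 0L)
    expect_equal(nrow(al$sameContig), 1L)
    # outer ends 100 and 3100 -> insert 3000
    expect_equal(al$sameContig$insert, 3000)
    expect_error(readAlignments(sam, lib, lens, libraryId = "nope"),
                 "unknown library")
})

test_that("multi-mapped reads are removed entirely at SAM parse time", {
    lib <- list(pe1 = Library("pe1", "PE", 3000, 300, 100))
    lens <- c(A = 5000, B = 5000)
    sam <- samFixture(c(samLine("r1", 65L, "A", 101, "B", 201),
                        samLine("r1", 145L, "B", 201, "A", 101),
                        samLine("r1", 65L + 256L, "B", 901, "B", 201)))
    al <- readAlignments(sam, lib, lens, libraryId = "pe1")
    expect_equal(nrow(al$links), 0L)
    expect_gte(al$counters[["multiMapped"]], 1)
})

test_that("PAF long-read alignments become TGS links carrying coordinates", {
    lib <- list(tgs1 = Library("tgs1", "TGS"))
    lens <- c(A = 5000, B = 5000)
    paf <- tempfile(fileext = ".paf")
    writeLines(c(paste("read1", 8000, 1000, 2000, "+", "A", 5000, 200, 1200,
                       1000, 1000, 60, sep = "\t"),
                 paste("read1", 8000, 4000, 5000, "+", "B", 5000, 300, 1300,
                       1000, 1000, 60, sep = "\t")),
               paf)
    al <- readAlignments(paf, lib, lens, libraryId = "tgs1")
    expect_equal(nrow(al$links), 1L)
    expect_equal(al$links$qsi, 1000)
    expect_equal(al$links$qsj, 4000)
    expect_equal(al$links$csi, 200)
    expect_equal(al$links$csj, 300)
    expect_equal(al$links$d, 1L)
    # alignments shorter than minAligned are ignored
    al2 <- readAlignments(paf, lib, lens, libraryId = "tgs1",
                          minAligned = 1500)
    expect_equal(nrow(al2$links), 0L)
})

test_that("the TSV link dialect round-trips", {
    lk <- emptyLinks(2L)
    lk$readId <- c("r1", "r2"); lk$i <- "a"; lk$j <- "b"
    lk$d <- c(1L, -1L); lk$lib <- "pe1"; lk$type <- "paired"
    lk$si <- c(10, 20); lk$sj <- c(30, 40); lk$gi <- 1L; lk$gj <- -1L
    p <- tempfile(fileext = ".tsv")
    writeLinksTSV(lk, p)
    back <- readLinksTSV(p)
    expect_equal(back$readId, lk$readId)
    expect_equal(back$si, lk$si)
    expect_equal(back$d, lk$d)
    libs <- list(pe1 = Library("pe1", "PE", 3000, 300))
    al <- readAlignments(p, libs, c(a = 100, b = 100))
    expect_equal(nrow(al$links), 2L)
})

test_that("scaffold FASTA/AGP writing and AGP re-reading round-trip", {
    plc <- data.frame(contig = c("c1", "c2"), orientation = c(1, -1),
                      start = c(0, 150), length = c(100, 100))
    sc <- ltsScaffold:::newSuperContig("s1", plc)
    expect_equal(sc@gaps$gap, 50)
    contigs <- Biostrings::DNAStringSet(c(c1 = strrep("ACGTT", 20),
                                          c2 = strrep("GATCA", 20)))
    fa <- tempfile(fileext = ".fa"); agp <- tempfile(fileext = ".agp")
    rep <- tempfile(fileext = ".tsv")
    out <- writeScaffolds(list(sc), contigs, fa, agp, rep)
    expect_equal(unname(Biostrings::width(out)), 250L)
    # N gap run of 50 between the contigs
    expect_equal(as.character(Biostrings::subseq(out[[1L]], 101, 150)),
                 strrep("N", 50))
    # second contig written reverse-complemented
    expect_equal(as.character(Biostrings::subseq(out[[1L]], 151, 250)),
                 as.character(Biostrings::reverseComplement(contigs[["c2"]])))
    agpLines <- readLines(agp)
    expect_match(agpLines[1L], "agp-version")
    types <- vapply(strsplit(agpLines[-1L], "\t"), `[[`, character(1), 5L)
    expect_equal(types, c("W", "N", "W"))
    back <- readAGP(agp)
    expect_equal(length(back), 1L)
    expect_equal(placements(back[["s1"]])$contig, plc$contig)
    expect_equal(placements(back[["s1"]])$orientation, plc$orientation)
    expect_equal(placements(back[["s1"]])$start, plc$start)
    expect_equal(gaps(back[["s1"]])$gap, 50)
    gapTab <- read.table(rep, header = TRUE, sep = "\t")
    expect_equal(gapTab$gap, 50)
    # empty scaffold set still writes valid empty files
    expect_warning(writeScaffolds(list(), contigs, fa, agp, rep), "no scaffolds")
})

test_that("non-positive gaps are floored to 1 bp in rendered output", {
    plc <- data.frame(contig = c("c1", "c2"), orientation = c(1, 1),
                      start = c(0, 95), length = c(100, 100))
    sc <- ltsScaffold:::newSuperContig("s1", plc)
    contigs <- Biostrings::DNAStringSet(c(c1 = strrep("A", 100),
                                          c2 = strrep("G", 100)))
    fa <- tempfile(); agp <- tempfile(); rep <- tempfile()
    out <- writeScaffolds(list(sc), contigs, fa, agp, rep)
    expect_equal(unname(Biostrings::width(out)), 201L)
})

test_that("malformed AGP is rejected with the offending line", {
    agp <- tempfile()
    writeLines(c("s1\t1\t100\t1\tW\tc1\t1\t100\t+", "s1\tbroken"), agp)
    expect_error(readAGP(agp), "line 2")
})

test_that("library YAML config reads into SeqLibrary objects", {
    y <- tempfile(fileext = ".yaml")
    writeLines(c("libraries:",
                 "  - id: pe1", "    kind: PE", "    mean: 800",
                 "    sd: 80", "    read_length: 100",
                 "  - id: mp1", "    kind: MP", "    mean: 5000",
                 "    sd: 500", "    already_flipped: true",
                 "  - id: t1", "    kind: TGS"), y)
    libs <- readLibraryConfig(y)
    expect_equal(names(libs), c("pe1", "mp1", "t1"))
    expect_equal(insertMean(libs$pe1), 800)
    expect_true(libs$mp1@alreadyFlipped)
    expect_equal(libKind(libs$t1), "TGS")
})
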
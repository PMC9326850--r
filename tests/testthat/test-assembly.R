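# Untangling, iteration, polishing and scaffold assessment.

mkLayout <- function(ids, beta, D = NULL, obs = NULL) {
    if (is.null(D)) D <- stats::setNames(rep(1, length(ids)), ids)
    if (is.null(obs))
        obs <- data.frame(i = character(), j = character(), lib = character(),
                          Y = numeric(), n = integer(), w = numeric(),
                          sigma = numeric(), resid = numeric(),
                          selected = logical())
    new("LayoutEstimate", contigs = ids, D = D,
        beta = stats::setNames(beta - beta[1L], ids), observations = obs,
        cov = matrix(0, length(ids), length(ids),
                     dimnames = list(ids, ids)),
        sigma2 = 1, modelVariance = FALSE, iterations = 0, maxError = 100)
}

test_that("untangle keeps tolerable overlaps in one chain", {
    lens <- c(a = 1000, b = 1000, c = 500)
    lay <- mkLayout(c("a", "b", "c"), c(0, 950, 2000))
    sc <- untangle(lay, lens, overlapTolerance = 100)
    expect_equal(length(sc), 1L)
    expect_equal(placements(sc[[1L]])$contig, c("a", "b", "c"))
    expect_equal(gaps(sc[[1L]])$gap, c(-50, 50))
})

test_that("branches resolve to the most-linked neighbour", {
    lens <- c(A = 2000, B = 500, C = 500, D = 1000)
    # B and C both sit inside A's span; B has more supporting links to A
    obs <- data.frame(i = c("A", "A", "B"), j = c("B", "C", "D"),
                      lib = "x", Y = 0, n = c(40L, 5L, 20L),
                      w = 1, sigma = 10, resid = 0, selected = TRUE)
    lay <- mkLayout(c("A", "B", "C", "D"), c(0, 800, 900, 2600), obs = obs)
    sc <- untangle(lay, lens, overlapTolerance = 200)
    chains <- lapply(sc, function(s) placements(s)$contig)
    main <- chains[[1L]]
    expect_true(all(c("A", "B", "D") %in% main))
    expect_false("C" %in% main)
    expect_equal(sort(unlist(chains)), sort(names(lens)))  # conservation
    # a single contig stays a single placement
    single <- untangle(mkLayout("z", 0), c(z = 700))
    expect_equal(nrow(placements(single[[1L]])), 1L)
})

test_that("untangle conserves contigs on random layouts", {
    set.seed(60)
    for (trial in 1:10) {
        m <- sample(4:12, 1)
        ids <- sprintf("u%02d", 1:m)
        lens <- stats::setNames(sample(500:2000, m, TRUE), ids)
        beta <- cumsum(c(0, sample(c(-300, 200, 800, 1500), m - 1, TRUE)))
        lay <- mkLayout(ids, beta - min(beta))
        sc <- untangle(lay, lens, overlapTolerance = 200)
        expect_equal(sort(unlist(lapply(sc, function(s)
            placements(s)$contig))), sort(ids))
    }
})

test_that("one pipeline round equals the k = 1 base case and iteration helps", {
    libs <- testLibraries()
    sim <- simulateAssembly(60000, 12, 200, libraries = libs,
                            coverages = c(pe1 = 30, mp1 = 15), seed = 61)
    r1 <- scaffoldPipeline(sim$contigs, sim$links, libs, iterations = 1,
                           threshold = 8)
    r3 <- scaffoldPipeline(sim$contigs, sim$links, libs, iterations = 3,
                           threshold = 8)
    expect_equal(r1$rounds, 1L)
    # early stop: once nothing merges the loop ends before k
    expect_lte(r3$rounds, 3L)
    expect_lte(length(r3$superContigs), length(r1$superContigs))
})

test_that("polish merges genuine overlaps and leaves the rest alone", {
    set.seed(62)
    base <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    left <- substr(base, 1, 1020)
    right <- substr(base, 1001, 2000)    # true 20 bp overlap
    contigs <- Biostrings::DNAStringSet(c(L = left, R = right))
    plc <- data.frame(contig = c("L", "R"), orientation = c(1, 1),
                      start = c(0, 998), length = c(1020, 1000))
    g <- data.frame(left = "L", right = "R", gap = -22, lo = -60, hi = 20,
                    nClusters = 2L, merged = FALSE, trimLeft = 0,
                    trimRight = 0)
    sc <- new("SuperContig", id = "s1", placements = plc, gaps = g,
              sequence = NULL)
    out <- polish(list(sc), contigs)[[1L]]
    expect_true(gaps(out)$merged)
    expect_equal(gaps(out)$gap, -20)
    fa <- tempfile(); agp <- tempfile(); repf <- tempfile()
    seqs <- writeScaffolds(list(out), contigs, fa, agp, repf)
    expect_equal(unname(Biostrings::width(seqs)), 2000L)
    expect_equal(as.character(seqs[[1L]]), base)
    # unrelated junction sequences are not merged
    contigs2 <- Biostrings::DNAStringSet(c(
        L = left, R = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                            collapse = "")))
    out2 <- polish(list(sc), contigs2)[[1L]]
    expect_false(gaps(out2)$merged)
    # positive gap estimates stay untouched
    g3 <- transform(g, gap = 150)
    sc3 <- new("SuperContig", id = "s1", placements = plc, gaps = g3,
               sequence = NULL)
    expect_false(gaps(polish(list(sc3), contigs)[[1L]])$merged)
    expect_equal(gaps(polish(list(sc3), contigs)[[1L]])$gap, 150)
})

test_that("assessment flags displaced clusters and planted misjoins", {
    libs <- testLibraries()
    # contigs of ~8 kb: the 5 kb insert cannot span a whole contig, so no
    # truncation-biased skip-pair clusters arise in the clean fixture
    sim <- simulateAssembly(82000, 10, 200, libraries = libs,
                            coverages = c(pe1 = 30, mp1 = 15), seed = 63)
    tr <- sim$truth
    plc <- data.frame(contig = tr$contig, orientation = 1,
                      start = tr$start, length = tr$length)
    sc <- new("SuperContig", id = "s", placements = plc,
              gaps = ltsScaffold:::emptyGapTable(), sequence = NULL)
    # truth positions, clean links: nothing flagged
    a <- assessScaffold(sc, sim$links, libs, maxError = 150)
    expect_equal(nrow(a$outliers), 0L)
    expect_equal(nrow(a$suspicious), 0L)
    # displace one contig by 5 kb: its observations are flagged
    plc2 <- plc
    plc2$start[5] <- plc2$start[5] + 5000
    plc2 <- plc2[order(plc2$start), ]
    sc2 <- new("SuperContig", id = "s", placements = plc2,
               gaps = ltsScaffold:::emptyGapTable(), sequence = NULL)
    a2 <- assessScaffold(sc2, sim$links, libs, maxError = 150)
    expect_gt(nrow(a2$outliers), 0L)
    expect_true(all(a2$outliers$i == tr$contig[5] |
                    a2$outliers$j == tr$contig[5] |
                    abs(a2$outliers$resid) > 150))
    # planted misjoin: two unlinked halves concatenated in one scaffold
    simB <- simulateAssembly(82000, 10, 200, libraries = libs,
                             coverages = c(pe1 = 30, mp1 = 15), seed = 64)
    trB <- simB$truth
    trB$contig <- sub("ctg", "alt", trB$contig)
    lkB <- simB$links
    lkB$i <- sub("ctg", "alt", lkB$i)
    lkB$j <- sub("ctg", "alt", lkB$j)
    joined <- data.frame(
        contig = c(tr$contig, trB$contig), orientation = 1,
        start = c(tr$start, max(tr$start + tr$length) + 500 + trB$start),
        length = c(tr$length, trB$length))
    scM <- new("SuperContig", id = "m", placements = joined,
               gaps = ltsScaffold:::emptyGapTable(), sequence = NULL)
    aM <- assessScaffold(scM, rbind(sim$links, lkB), libs, maxError = 150)
    expect_equal(nrow(aM$suspicious), 1L)
    expect_equal(aM$suspicious$left, tr$contig[10])
    expect_equal(aM$suspicious$right, trB$contig[1])
})

test_that("the command-line front end runs the pipeline end to end", {
    script <- system.file("scripts", "ltsscaffold.R",
                          package = "ltsScaffold")
    expect_true(nzchar(script))
    rscript <- file.path(R.home("bin"), "Rscript")
    tmp <- tempfile()
    dir.create(tmp)
    status <- system2(rscript, c(script, "simulate", "--out",
                                 shQuote(file.path(tmp, "sim")),
                                 "--genome-length", "40000",
                                 "--n-contigs", "8", "--seed", "4"),
                      stdout = FALSE, stderr = FALSE)
    expect_equal(status, 0L)
    expect_true(file.exists(file.path(tmp, "sim", "links.tsv")))
    out <- file.path(tmp, "out")
    status2 <- system2(rscript, c(
        script, "scaffold",
        "--contigs", shQuote(file.path(tmp, "sim", "contigs.fasta")),
        "--config", shQuote(file.path(tmp, "sim", "libraries.yaml")),
        "--alignments", shQuote(file.path(tmp, "sim", "links.tsv")),
        "--threshold", "8", "--out", shQuote(out)),
        stdout = FALSE, stderr = FALSE)
    expect_equal(status2, 0L)
    expect_true(file.exists(file.path(out, "scaffolds.fasta")))
    expect_true(file.exists(file.path(out, "scaffolds.agp")))
    expect_true(file.exists(file.path(out, "gaps.tsv")))
    agp <- readAGP(file.path(out, "scaffolds.agp"))
    expect_gte(length(agp), 1L)
})
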
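# System assembly, weighted least squares, the trimming loop and gap
# confidence intervals.

test_that("buildSystem anchors the smallest contig and indexes rows", {
    obs <- makeObs(c("1", "2", "1"), c("2", "3", "3"), c(100, 50, 160))
    sys <- buildSystem(c("1", "2", "3"), obs)
    expect_equal(sys$anchor, "1")
    expect_equal(dim(sys$X), c(3L, 2L))
    # duplicate clusters for one pair stay separate rows
    obs2 <- makeObs(c("1", "1"), c("2", "2"), c(100, 700))
    expect_equal(nrow(buildSystem(c("1", "2"), obs2)$obs), 2L)
    # single contig: passthrough
    expect_null(buildSystem("1", obs[0L, ])$X)
})

test_that("wlsSolve matches hand-solved normal equations", {
    obs <- makeObs(c("1", "2", "1"), c("2", "3", "3"), c(100, 50, 160))
    fit <- wlsSolve(buildSystem(c("1", "2", "3"), obs))
    expect_equal(unname(fit$beta), c(0, 310 / 3, 470 / 3), tolerance = 1e-9)
    # single-row exact fit
    one <- makeObs("1", "2", 100)
    f1 <- wlsSolve(buildSystem(c("1", "2"), one))
    expect_equal(unname(f1$beta), c(0, 100))
    expect_equal(f1$residuals, 0)
    # weighted mean with weights 10 and 2
    two <- makeObs(c("1", "1"), c("2", "2"), c(100, 700), w = c(10, 2))
    f2 <- wlsSolve(buildSystem(c("1", "2"), two))
    expect_equal(unname(f2$beta)[2L], 200)
    # disconnected rows are refused
    disc <- makeObs(c("1", "3"), c("2", "4"), c(10, 10))
    expect_error(wlsSolve(buildSystem(c("1", "2", "3", "4"), disc)),
                 "split required")
})

test_that("the MaxError schedule adds 50 bp per outer iteration", {
    expect_equal(maxErrorSchedule(100, 0), 100)
    expect_equal(maxErrorSchedule(100, 2), 200)
    expect_equal(maxErrorSchedule(150, 1), 200)
    expect_error(maxErrorSchedule(100, -1))
})

test_that("the trimming loop follows the hand trace", {
    # two observations on one pair: initial weighted fit at 200, worst
    # residual 500 -> the light outlying row is dropped, fit lands at 100
    obs <- makeObs(c("1", "1"), c("2", "2"), c(100, 700), w = c(10, 2))
    sys <- buildSystem(c("1", "2"), obs)
    r <- wlts(sys, maxError = 100)
    expect_true(r$converged)
    expect_equal(unname(r$beta)[2L], 100)
    expect_equal(r$selected, 1L)
    # already-converged system: zero iterations, everything kept
    ok <- makeObs(c("1", "2"), c("2", "3"), c(100, 50))
    r2 <- wlts(buildSystem(c("1", "2", "3"), ok), maxError = 100)
    expect_equal(r2$iterations, 0L)
    expect_equal(r2$selected, c(1L, 2L))
})

test_that("disconnected evidence is signalled for component splitting", {
    # rows that do not span the component cannot be fitted; the solver
    # signals the split instead of producing an arbitrary layout
    disc <- makeObs(c("1", "3"), c("2", "4"), c(10, 10))
    sys <- buildSystem(c("1", "2", "3", "4"), disc)
    expect_error(wlsSolve(sys), "split required")
    # fitComponent re-queues the parts when the observation graph does
    # not span the component: vertex z9 has no links at all
    lk <- emptyLinks(4L)
    lk$readId <- sprintf("r%d", 1:4)
    lk$i <- c("a1", "a1", "a2", "a2")
    lk$j <- c("a2", "a2", "a3", "a3")
    lk$d <- 1L; lk$lib <- "pe1"; lk$type <- "paired"
    lk$si <- c(900, 910, 905, 915); lk$sj <- c(120, 130, 110, 100)
    lk$gi <- 1L; lk$gj <- -1L
    libs <- list(pe1 = Library("pe1", "PE", 500, 50, 100))
    lens <- c(a1 = 1000, a2 = 1000, a3 = 1000, z9 = 800)
    lay <- fitComponent(c("a1", "a2", "a3", "z9"), lk, libs, lens,
                        maxError = 100)
    sizes <- sort(vapply(lay, function(l) length(l@contigs), integer(1)))
    expect_equal(sizes, c(1L, 3L))
})

test_that("beta is equivariant and row order never matters", {
    set.seed(50)
    m <- 6
    v <- as.character(1:m)
    obs <- makeObs(v[c(1, 2, 3, 4, 5, 1, 2)], v[c(2, 3, 4, 5, 6, 3, 4)],
                   c(100, 120, 90, 110, 105, 225, 200) + rnorm(7, 0, 1))
    sys <- buildSystem(v, obs)
    r <- wlts(sys, maxError = 100)
    perm <- sample(nrow(obs))
    rp <- wlts(buildSystem(v, obs[perm, ]), maxError = 100)
    expect_equal(rp$beta, r$beta, tolerance = 1e-9)
    expect_equal(sort(perm[rp$selected]), r$selected)
    # adding c to each chain observation shifts beta by c * (index - 1)
    chain <- makeObs(v[1:5], v[2:6], rep(100, 5))
    bshift <- wlts(buildSystem(v, transform(chain, Y = Y + 7)), 100)$beta
    expect_equal(unname(bshift), (0:5) * 107, tolerance = 1e-9)
})

test_that("WLTS survives 30% gross outliers where WLS breaks down", {
    # every contig pair keeps its true cluster; 30% of the rows are false
    # clusters of smaller size offset by +5000 (the minority-mode regime
    # that mis-mapping produces)
    set.seed(51)
    obs <- breakdownSystem(m = 20, nRows = 200, outFrac = 0.3)
    contigs <- sprintf("c%02d", 1:20)
    beta <- (0:19) * 1000
    sys <- buildSystem(contigs, obs$obs)
    wls <- wlsSolve(sys)
    r <- wlts(sys, maxError = 100)
    expect_true(r$converged)
    expect_equal(sort(setdiff(seq_len(nrow(obs$obs)), r$selected)),
                 sort(obs$outliers))
    lay <- ltsScaffold:::layoutFromFit(
        sys, stats::setNames(rep(1, 20), contigs), r, 100)
    se <- sqrt(diag(lay@cov))[-1L]
    rmseT <- sqrt(mean((r$beta - beta)^2))
    rmseW <- sqrt(mean((wls$beta - beta)^2))
    expect_lt(rmseT, 3 * mean(se))
    expect_gt(rmseW, 10 * rmseT)
})

test_that("greedy trimming matches the exhaustive subset oracle", {
    set.seed(52)
    equal <- 0L
    trials <- 0L
    for (q in 1:20) {
        m <- 4
        cg <- sprintf("g%d", 1:m)
        b <- c(0, 500, 900, 1500)
        nr <- 8
        ii <- sample(1:(m - 1), nr, replace = TRUE)
        jj <- pmin(m, ii + sample(1:2, nr, replace = TRUE))
        Y <- b[jj] - b[ii] + rnorm(nr, 0, 5)
        nout <- sample(0:2, 1)
        outidx <- if (nout) sample(nr, nout) else integer(0)
        Y[outidx] <- Y[outidx] + 5000
        obs <- makeObs(cg[ii], cg[jj], Y, w = 5 / 1e4, n = 5L, sigma = 100)
        if (length(ufComponents(cg, obs[, c("i", "j")])) > 1) next
        sys <- buildSystem(cg, obs)
        r <- wlts(sys, maxError = 100)
        if (!r$converged) next
        trials <- trials + 1L
        og <- wltsObjective(sys, r$selected)
        oracle <- exhaustiveTrim(obs, cg)
        expect_lte(og, 1.05 * oracle$objective)
        if (abs(og - oracle$objective) < 1e-9) equal <- equal + 1L
    }
    expect_gte(trials, 10L)
    # gross planted outliers: the greedy subset is almost always the
    # exhaustive optimum, and never more than 5% above it
    expect_gte(equal, 0.8 * trials)
})

test_that("local optimality: no single-row swap improves the objective", {
    set.seed(53)
    m <- 4
    cg <- sprintf("g%d", 1:m)
    b <- c(0, 400, 900, 1300)
    obs <- makeObs(cg[c(1, 2, 3, 1, 2, 1)], cg[c(2, 3, 4, 3, 4, 2)],
                   c(402, 498, 405, 903, 898, 5400), w = 5 / 1e4, n = 5L,
                   sigma = 100)
    sys <- buildSystem(cg, obs)
    r <- wlts(sys, maxError = 100)
    expect_true(r$converged)
    og <- wltsObjective(sys, r$selected)
    nr <- nrow(obs)
    for (drop in r$selected) {
        for (add in setdiff(seq_len(nr), r$selected)) {
            cand <- sort(c(setdiff(r$selected, drop), add))
            if (length(ufComponents(cg, obs[cand, c("i", "j")])) > 1) next
            expect_gte(wltsObjective(sys, cand), og - 1e-9)
        }
    }
})

test_that("gap confidence intervals use the layout covariance", {
    # one supporting cluster of 150 links at sigma 500: without residual
    # degrees of freedom the weight-based model SE applies and the two-SD
    # interval half-width is the median-CLT bound (~102.33)
    obs <- makeObs("1", "2", 5000, w = 150 / 500^2, n = 150L, sigma = 500)
    sys <- buildSystem(c("1", "2"), obs)
    r <- wlts(sys, maxError = 200)
    lay <- ltsScaffold:::layoutFromFit(sys, c("1" = 1, "2" = 1), r, 200)
    expect_true(lay@modelVariance)
    ci <- gapConfidence(lay, c("1" = 4000, "2" = 4000), level = 0.9545)
    expect_equal(ci$gap, 1000)
    expect_equal(ci$hi - ci$gap, medianErrorBound(150, 500), tolerance = 0.01)
    expect_true(ci$modelVariance)
})

test_that("nominal gap CI coverage is honest on simulated layouts", {
    set.seed(54)
    m <- 10
    v <- sprintf("c%02d", 1:m)
    lens <- stats::setNames(rep(900, m), v)
    beta <- (0:(m - 1)) * 1000
    nlink <- 40L
    sigma <- 300
    hit <- 0L
    reps <- 400
    for (q in seq_len(reps)) {
        ii <- c(1:(m - 1), sample(1:(m - 2), 30, replace = TRUE))
        jj <- c(2:m, pmin(m, ii[-(1:(m - 1))] + 2L))
        noise <- rnorm(length(ii), 0, sqrt(pi / (2 * nlink)) * sigma)
        obs <- makeObs(v[ii], v[jj], beta[jj] - beta[ii] + noise,
                       w = nlink / sigma^2, n = nlink, sigma = sigma)
        sys <- buildSystem(v, obs)
        # a residual bound of ~4 observation SDs keeps trimming inactive on
        # clean data, so pure interval calibration is measured
        r <- wlts(sys, maxError = 250)
        lay <- ltsScaffold:::layoutFromFit(
            sys, stats::setNames(rep(1, m), v), r, 250)
        ci <- gapConfidence(lay, lens, level = 0.95)
        trueGap <- 100
        hit <- hit + sum(ci$lo <= trueGap & trueGap <= ci$hi)
    }
    coverage <- hit / (reps * (m - 1))
    expect_gte(coverage, 0.93)
    expect_lte(coverage, 0.97)
})
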
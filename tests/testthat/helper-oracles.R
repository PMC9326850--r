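# Independent oracles used across the suite. These deliberately avoid the
# package's own graph / regression / search code paths: components via
# union-find, trimmed least squares via exhaustive subset enumeration with
# base lm.wfit, and orientation via full enumeration of assignments.

# union-find connected components
ufComponents <- function(vertices, edges) {
    parent <- stats::setNames(seq_along(vertices), vertices)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    if (nrow(edges)) {
        for (k in seq_len(nrow(edges))) {
            ri <- find(match(edges$i[k], vertices))
            rj <- find(match(edges$j[k], vertices))
            if (ri != rj) parent[ri] <- rj
        }
    }
    roots <- vapply(seq_along(vertices), function(x) find(x), numeric(1))
    unname(split(vertices, roots))
}

# exhaustive minimiser of the trimmed-squares objective over all connected
# row subsets; base-R weighted least squares per subset
exhaustiveTrim <- function(obs, contigs) {
    nr <- nrow(obs)
    stopifnot(nr <= 12)
    free <- contigs[-1]
    best <- Inf
    bestRows <- NULL
    for (msk in seq_len(2^nr - 1)) {
        rows <- which(bitwAnd(msk, 2^(seq_len(nr) - 1)) > 0)
        sub <- obs[rows, , drop = FALSE]
        if (length(ufComponents(contigs, sub[, c("i", "j")])) > 1) next
        X <- matrix(0, length(rows), length(free))
        for (q in seq_along(rows)) {
            if (sub$i[q] %in% free) X[q, match(sub$i[q], free)] <- -1
            if (sub$j[q] %in% free) X[q, match(sub$j[q], free)] <- 1
        }
        f <- stats::lm.wfit(X, sub$Y, sub$w)
        o <- sum(sub$w * f$residuals^2) + (nr - length(rows))
        if (o < best) {
            best <- o
            bestRows <- rows
        }
    }
    list(objective = best, rows = bestRows)
}

# exhaustive ground-state search of the orientation energy (anchor = +1)
enumOrientation <- function(problem) {
    v <- problem$vertices
    m <- length(v)
    stopifnot(m <= 16)
    e <- problem$edges
    ii <- match(e$i, v)
    jj <- match(e$j, v)
    grid <- as.matrix(expand.grid(rep(list(c(1, -1)), m - 1L)))
    H <- apply(grid, 1L, function(g) {
        Dv <- c(1, g)
        if (nrow(e)) -sum(e$J * Dv[ii] * Dv[jj]) else 0
    })
    k <- which.min(H)
    list(H = H[k], D = stats::setNames(c(1, grid[k, ]), v))
}

# build an observation table with the canonical columns
makeObs <- function(i, j, Y, w = 1, n = 10L, sigma = 100, lib = "x") {
    data.frame(i = i, j = j, lib = lib, Y = Y,
               n = rep_len(n, length(Y)), w = rep_len(w, length(Y)),
               sigma = rep_len(sigma, length(Y)))
}

# random coupled orientation problem on m vertices
randomProblem <- function(m, pEdge = 0.5, Jmax = 3L) {
    v <- sprintf("v%02d", seq_len(m))
    pairs <- utils::combn(m, 2L)
    keep <- stats::runif(ncol(pairs)) < pEdge
    pairs <- pairs[, keep, drop = FALSE]
    J <- sample(seq(-Jmax, Jmax), ncol(pairs), replace = TRUE)
    nz <- J != 0
    list(vertices = v,
         edges = data.frame(i = v[pairs[1L, nz]], j = v[pairs[2L, nz]],
                            J = J[nz]))
}

# breakdown fixture: a 20-contig chain where every adjacent / skip pair
# keeps true compressed observations (clusters of 30 links) and outFrac of
# the rows are false clusters (10 links each) displaced by +5000 bp —
# the minority-mode structure repeat mis-mapping produces
breakdownSystem <- function(m = 20, nRows = 200, outFrac = 0.3,
                            sigma = 30, offset = 5000) {
    contigs <- sprintf("c%02d", seq_len(m))
    beta <- (seq_len(m) - 1) * 1000
    pairsI <- c(1:(m - 1), 1:(m - 2))
    pairsJ <- c(2:m, 3:m)
    nOut <- round(outFrac * nRows)
    nTrue <- nRows - nOut
    extra <- sample(seq_along(pairsI), nTrue - length(pairsI), replace = TRUE)
    ti <- c(seq_along(pairsI), extra)
    nT <- 30L
    Yt <- beta[pairsJ[ti]] - beta[pairsI[ti]] +
        rnorm(length(ti), 0, sqrt(pi / (2 * nT)) * sigma)
    oi <- sample(seq_along(pairsI), nOut, replace = TRUE)
    nO <- 10L
    Yo <- beta[pairsJ[oi]] - beta[pairsI[oi]] + offset +
        rnorm(nOut, 0, sqrt(pi / (2 * nO)) * sigma)
    obs <- makeObs(contigs[c(pairsI[ti], pairsI[oi])],
                   contigs[c(pairsJ[ti], pairsJ[oi])],
                   c(Yt, Yo),
                   w = c(rep(nT, nTrue), rep(nO, nOut)) / sigma^2,
                   n = c(rep(nT, nTrue), rep(nO, nOut)), sigma = sigma)
    list(obs = obs, outliers = nTrue + seq_len(nOut))
}

# default two-library setup used by planted-genome tests
testLibraries <- function() {
    list(pe1 = Library("pe1", "PE", insertMean = 800, insertSd = 80,
                       readLength = 100),
         mp1 = Library("mp1", "MP", insertMean = 5000, insertSd = 500,
                       readLength = 100))
}
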
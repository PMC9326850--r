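# Global position estimation. Every compressed observation Y_ijk is an
# observation on beta_j - beta_i, giving the linear model Y = X beta + eps
# whose design rows carry -1 at i(k) and +1 at j(k). The anchor contig
# (smallest id, beta = 0) is enforced by eliminating its column, so
# X^T W X is the weighted graph Laplacian over the free contigs. Positions
# are estimated by weighted least trimmed squares: iteratively re-select
# the rows with the smallest absolute residuals (one fewer per iteration,
# re-chosen from the full sample space so a removed row may re-enter) until
# every selected residual is below MaxError; if the selected rows no longer
# connect the component, it is split and the parts are re-oriented.

#' Build the regression system for one component
#'
#' @param component character vector of contig ids.
#' @param observations compressed observations
#'   (\code{\link{clusterObservations}} output restricted to the component).
#' @return list with \code{contigs} (sorted ids), \code{anchor} (smallest
#'   id), \code{obs} (observation data.frame) and the sparse free-column
#'   design \code{X}; \code{NULL} for a single-contig passthrough with no
#'   observations.
#' @export
buildSystem <- function(component, observations) {
    contigs <- sort(unique(as.character(component)))
    obs <- observations[observations$i %in% contigs &
                        observations$j %in% contigs, , drop = FALSE]
    rownames(obs) <- NULL
    if (length(contigs) == 1L || !nrow(obs)) {
        return(list(contigs = contigs, anchor = contigs[1L],
                    obs = obs[0L, , drop = FALSE], X = NULL))
    }
    anchor <- contigs[1L]
    free <- contigs[-1L]
    n <- nrow(obs)
    ii <- match(obs$i, free)        # NA for anchor
    jj <- match(obs$j, free)
    rows <- c(which(!is.na(ii)), which(!is.na(jj)))
    cols <- c(ii[!is.na(ii)], jj[!is.na(jj)])
    vals <- c(rep(-1, sum(!is.na(ii))), rep(1, sum(!is.na(jj))))
    X <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                              dims = c(n, length(free)))
    list(contigs = contigs, anchor = anchor, obs = obs, X = X)
}

#' Weighted least squares on a row subset
#'
#' Solves the sparse normal equations \code{(X^T W X) beta = X^T W Y} on
#' the given rows and returns the full coordinate vector (anchor at 0) plus
#' residuals for \emph{all} observations of the system.
#'
#' @param system from \code{\link{buildSystem}}.
#' @param rows integer row subset (default: all).
#' @return list with \code{beta} (named, over all contigs), \code{residuals}
#'   (all rows), and \code{XtWX} (the normal matrix on the subset).
#' @export
wlsSolve <- function(system, rows = seq_len(nrow(system$obs))) {
    if (is.null(system$X)) {
        beta <- stats::setNames(numeric(length(system$contigs)),
                                system$contigs)
        return(list(beta = beta, residuals = numeric(0), XtWX = NULL))
    }
    if (!rowsConnect(system, rows))
        stop("split required: selected rows do not connect the component")
    Xs <- system$X[rows, , drop = FALSE]
    w <- system$obs$w[rows]
    y <- system$obs$Y[rows]
    XtW <- Matrix::t(Xs * w)
    A <- XtW %*% Xs
    bfree <- as.numeric(Matrix::solve(A, XtW %*% y))
    beta <- stats::setNames(c(0, bfree), system$contigs)
    res <- as.numeric(system$X %*% bfree) - system$obs$Y
    list(beta = beta, residuals = res, XtWX = A)
}

# do the rows' edges connect all contigs of the system?
rowsConnect <- function(system, rows) {
    comps <- dfsComponents(system$contigs,
                           system$obs[rows, c("i", "j"), drop = FALSE])
    length(comps) == 1L
}

#' MaxError schedule across pipeline iterations
#'
#' The default base of 100 bp comes from the two-SD bound of a typical
#' compressed observation (\code{\link{medianErrorBound}}); because cluster
#' sizes shrink as super-contigs grow, the bound is raised by 50 bp in each
#' outer iteration.
#'
#' @param base base MaxError in bp (default 100).
#' @param outerIteration 0-based pipeline iteration index.
#' @return MaxError in bp.
#' @examples
#' maxErrorSchedule(100, 0)  # 100
#' maxErrorSchedule(100, 2)  # 200
#' @export
maxErrorSchedule <- function(base = 100, outerIteration = 0) {
    stopifnot(outerIteration >= 0)
    base + 50 * outerIteration
}

#' Weighted least trimmed squares (the trimming loop)
#'
#' Iteration t fits WLS on the current subset, computes residuals for every
#' observation, and re-selects from the full sample space the (n - t) rows
#' with the smallest absolute residuals (raw residuals in bp; ties broken
#' by row index). The loop stops when every selected residual is at most
#' \code{maxError}. If the re-selected rows disconnect the component, the
#' component is broken up and the sub-components are returned for
#' re-orientation.
#'
#' @param system from \code{\link{buildSystem}}.
#' @param maxError residual bound in bp.
#' @return On convergence, a list with \code{converged = TRUE},
#'   \code{beta}, \code{selected} (row indices), \code{residuals} (all
#'   rows), \code{iterations}, \code{XtWX}. On disconnection, a list with
#'   \code{converged = FALSE} and \code{components} (vertex sets to be sent
#'   back through orientation). A component whose rows are exhausted
#'   dissolves into singletons (with a warning).
#' @export
wlts <- function(system, maxError = 100) {
    n <- nrow(system$obs)
    if (is.null(system$X) || n == 0L) {
        fit <- wlsSolve(system)
        return(list(converged = TRUE, beta = fit$beta, selected = integer(0),
                    residuals = numeric(0), iterations = 0L, XtWX = NULL))
    }
    sel <- seq_len(n)
    t <- 0L
    repeat {
        fit <- wlsSolve(system, sel)
        absres <- abs(fit$residuals)
        if (max(absres[sel]) <= maxError) {
            return(list(converged = TRUE, beta = fit$beta, selected = sel,
                        residuals = fit$residuals, iterations = t,
                        XtWX = fit$XtWX))
        }
        keepN <- n - t
        if (keepN < 1L) {
            warning("trimming exhausted the observations; dissolving component")
            return(list(converged = FALSE,
                        components = as.list(system$contigs)))
        }
        cand <- order(absres)[seq_len(keepN)]      # ties resolved by row index
        if (!rowsConnect(system, cand)) {
            comps <- dfsComponents(system$contigs,
                                   system$obs[cand, c("i", "j"), drop = FALSE])
            return(list(converged = FALSE, components = orderComponents(comps)))
        }
        sel <- sort(cand)
        t <- t + 1L
    }
}

#' The trimmed-squares objective
#'
#' \code{sum_{k in I*} w_k e_k^2 + |I \\ I*|} for a given kept subset; used
#' to compare the greedy trimming against exhaustive subset search.
#'
#' @param system from \code{\link{buildSystem}}.
#' @param rows kept row subset.
#' @return the objective value.
#' @export
wltsObjective <- function(system, rows) {
    fit <- wlsSolve(system, rows)
    sum(system$obs$w[rows] * fit$residuals[rows]^2) +
        (nrow(system$obs) - length(rows))
}

# finalize a converged WLTS fit into a LayoutEstimate
layoutFromFit <- function(system, D, fit, maxError) {
    contigs <- system$contigs
    m <- length(contigs)
    obs <- system$obs
    obs$resid <- if (nrow(obs)) fit$residuals else numeric(0)
    obs$selected <- seq_len(nrow(obs)) %in% fit$selected
    covB <- matrix(0, m, m, dimnames = list(contigs, contigs))
    sigma2 <- NA_real_
    modelVar <- FALSE
    if (!is.null(fit$XtWX)) {
        p <- m - 1L
        dof <- length(fit$selected) - p
        if (dof < 1L) {
            # no residual dof: weight-based model variance. Weights are
            # n/sigma^2 while the median-CLT error variance is
            # (pi/2) sigma^2/n, so the covariance carries the pi/2 factor.
            sigma2 <- pi / 2
            modelVar <- TRUE
        } else {
            sigma2 <- sum(obs$w[fit$selected] *
                          obs$resid[fit$selected]^2) / dof
        }
        covFree <- sigma2 * as.matrix(Matrix::solve(fit$XtWX))
        covB[-1L, -1L] <- covFree
    }
    new("LayoutEstimate", contigs = contigs,
        D = D[contigs], beta = fit$beta[contigs], observations = obs,
        cov = covB, sigma2 = sigma2, modelVariance = modelVar,
        iterations = as.numeric(fit$iterations), maxError = maxError)
}

#' Gap estimates with confidence intervals
#'
#' Adjacency is taken from the sorted positions; for each adjacent pair,
#' \code{gap = beta_j - beta_i - length_i} and the variance of
#' \code{beta_j - beta_i} comes from the weighted-least-squares covariance
#' (inverse normal matrix scaled by the weighted residual mean square; the
#' weight-based model variance, flagged via the layout's
#' \code{modelVariance}, when no residual degrees of freedom were left).
#'
#' @param layout a \linkS4class{LayoutEstimate}.
#' @param contigLengths named numeric vector.
#' @param level confidence level (default 0.95).
#' @return data.frame with \code{left}, \code{right}, \code{gap}, \code{se},
#'   \code{lo}, \code{hi}, \code{nClusters}, \code{modelVariance}.
#' @export
gapConfidence <- function(layout, contigLengths, level = 0.95) {
    b <- sort(layout@beta)
    ids <- names(b)
    if (length(ids) < 2L)
        return(data.frame(left = character(), right = character(),
                          gap = numeric(), se = numeric(), lo = numeric(),
                          hi = numeric(), nClusters = integer(),
                          modelVariance = logical()))
    z <- stats::qnorm(1 - (1 - level) / 2)
    left <- ids[-length(ids)]
    right <- ids[-1L]
    gap <- b[right] - b[left] - contigLengths[left]
    v <- diag(layout@cov)[right] + diag(layout@cov)[left] -
        2 * layout@cov[cbind(right, left)]
    se <- sqrt(pmax(0, v))
    obs <- layout@observations
    ncl <- vapply(seq_along(left), function(k) {
        sum(obs$selected & obs$i == pmin(left[k], right[k]) &
            obs$j == pmax(left[k], right[k]))
    }, integer(1))
    data.frame(left = left, right = right, gap = as.numeric(gap),
               se = as.numeric(se), lo = as.numeric(gap - z * se),
               hi = as.numeric(gap + z * se), nClusters = ncl,
               modelVariance = layout@modelVariance, row.names = NULL)
}
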
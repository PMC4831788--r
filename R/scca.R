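#' @include AllClasses.R
NULL

#' Sparse CCA configuration
#'
#' Settings for the rank-1 penalised fit.  The L1 budgets `cU`, `cV` control
#' the sparsity of the canonical vectors (`c = 1` forces a single nonzero
#' entry; `c = sqrt(k)` deactivates the penalty).  `weakness` is the
#' randomised-Lasso weakness: per-variable penalty factors are drawn
#' uniformly from `[weakness, 1]` in each stability iteration, and
#' `weakness = 1` recovers the plain Lasso penalty.  The defaults were
#' calibrated once on synthetic panels at study scale (about 450 available
#' edges, 17 subjects) so that a single fit selects about 20 structural
#' edges, and are held fixed across all bootstrap iterations and indices.
#'
#' @param cU,cV L1 budgets for u and v, in `[1, sqrt(k)]`.
#' @param weakness randomised-Lasso weakness in (0, 1].
#' @param maxIter maximum alternating iterations.
#' @param tol convergence tolerance on the canonical vectors.
#' @param restarts number of extra deterministic coordinate initialisations
#'   (beyond the leading singular pair); the alternation is non-convex and
#'   multi-starting guards against local optima at small L1 budgets.
#' @return a list of class `sccaConfig`.
#' @export
sccaConfig <- function(cU = 2.4, cV = 2.4, weakness = 0.6, maxIter = 200L,
                       tol = 1e-6, restarts = 4L) {
  if (cU < 1 || cV < 1) stop("L1 budgets must be >= 1")
  if (weakness <= 0 || weakness > 1) stop("weakness must lie in (0, 1]")
  if (restarts < 0L) stop("restarts must be >= 0")
  structure(list(cU = cU, cV = cV, weakness = weakness,
                 maxIter = as.integer(maxIter), tol = tol,
                 restarts = as.integer(restarts)),
            class = "sccaConfig")
}

#' Soft-thresholding operator
#'
#' `sign(a) * max(|a| - lam, 0)`, applied elementwise.
#'
#' @param a numeric vector.
#' @param lam threshold(s), >= 0.
#' @return the shrunk vector.
#' @export
softThreshold <- function(a, lam) {
  if (any(lam < 0)) stop("threshold must be non-negative")
  sign(a) * pmax(abs(a) - lam, 0)
}

#' Maximise a linear form under unit-L2 and weighted-L1 constraints
#'
#' Solves `argmax u' a` subject to `||u||_2 <= 1` and
#' `sum(w_j |u_j|) <= c` by soft-thresholding `a` at level `delta * w` and
#' bisecting on `delta >= 0` until the weighted-L1 constraint is active (or
#' `delta = 0` already satisfies it).  This is the workhorse update of the
#' penalised rank-1 decomposition behind sparse CCA.
#'
#' @param a numeric vector (nonzero).
#' @param c L1 budget in `[1, sqrt(length(a))]`.
#' @param w per-variable penalty factors in (0, 1]; scalar 1 recycled.
#' @param tol bisection tolerance on the weighted L1 norm.
#' @return unit-L2 vector satisfying the weighted-L1 budget.
#' @export
unitL1Constrained <- function(a, c, w = 1, tol = 1e-8) {
  if (all(a == 0)) stop("cannot maximise a zero linear form")
  w <- rep_len(w, length(a))
  absA <- abs(a)
  nrm <- sqrt(sum(absA * absA))
  if (sum(w * absA) / nrm <= c + tol) return(a / nrm)
  # bisect the threshold level; only magnitudes matter until the end
  lo <- 0
  hi <- max(absA / w)
  for (iter in seq_len(120L)) {
    mid <- (lo + hi) / 2
    s <- absA - mid * w
    s[s < 0] <- 0
    l1 <- sum(w * s) / sqrt(sum(s * s))
    if (l1 > c) {
      lo <- mid
    } else {
      hi <- mid
      if (c - l1 < 1e-9 * max(1, c)) break
    }
    if (hi - lo < 1e-13 * max(1, hi)) break
  }
  s <- absA - hi * w
  s[s < 0] <- 0
  ns <- sqrt(sum(s * s))
  if (ns == 0) {
    # degenerate tie at the top: fall back to the 1-sparse maximiser
    j <- which.max(absA)
    u <- numeric(length(a))
    u[j] <- sign(a[j])
    return(u)
  }
  sign(a) * s / ns
}

#' Randomised-Lasso penalty factors
#'
#' Independent per-variable factors drawn uniformly from `[weakness, 1]`.
#' Multiplying the penalty level by these factors perturbs which variables
#' the Lasso favours, which decorrelates selections across bootstrap
#' iterations and improves sparse support recovery.  `weakness = 1` returns
#' all-ones (plain Lasso).  Draws use the session RNG, so they are
#' reproducible under `set.seed()`.
#'
#' @param p number of variables.
#' @param weakness weakness parameter in (0, 1].
#' @return numeric vector of length `p` with entries in `[weakness, 1]`.
#' @export
randomizedWeights <- function(p, weakness) {
  if (weakness <= 0 || weakness > 1) stop("weakness must lie in (0, 1]")
  if (weakness == 1) return(rep(1, p))
  stats::runif(p, weakness, 1)
}

## Leading singular pair of X %*% t(Y) without forming the k_x x k_y
## cross-product: both panels have rank <= m, so a QR factorisation of each
## reduces the problem to an m x m SVD.
.leadingCrossPair <- function(X, Y) {
  qx <- qr(X)
  qy <- qr(Y)
  r <- min(ncol(X), nrow(X))
  small <- qr.R(qx) %*% t(qr.R(qy))
  sv <- svd(small, nu = 1L, nv = 1L)
  list(u = as.vector(qr.Q(qx) %*% sv$u),
       v = as.vector(qr.Q(qy) %*% sv$v),
       d = sv$d[1L])
}

#' Rank-1 sparse canonical correlation analysis
#'
#' Finds sparse canonical vectors `u` (over structural edges) and `v` (over
#' functional edges) maximising `u' X Y' v` subject to unit-L2 and
#' (weighted) L1 constraints, by alternating the closed-form constrained
#' updates of [unitL1Constrained()]:
#' `u <- unitL1Constrained(X Y' v, cU, wU)` and
#' `v <- unitL1Constrained(Y X' u, cV, wV)`, initialised at the leading
#' singular pair of `X Y'`.  With standardised panels the cross-product is
#' (m - 1) times the between-set correlation, so the diagonal-covariance
#' canonical pair is recovered: the within-set covariances are not inverted,
#' which is the standard remedy when subjects are far fewer than edges.
#'
#' @param X structural panel: a standardised [ConnectomePanel-class] (k_x by
#'   m), or a bare numeric matrix.
#' @param Y functional panel, same subjects in the same order.
#' @param config an [sccaConfig()] list.
#' @param wU,wV per-variable penalty factors (defaults 1 = plain penalty);
#'   draw from [randomizedWeights()] for the randomised variant.
#' @return an [SccaFit-class].  The sign convention makes u's
#'   largest-magnitude entry positive and then flips v if needed so that the
#'   canonical correlation is non-negative.
#' @export
sccaRank1 <- function(X, Y, config = sccaConfig(), wU = 1, wV = 1) {
  xm <- if (is(X, "ConnectomePanel")) {
    if (!isTRUE(X@standardized)) stop("X panel must be standardised")
    X@values
  } else X
  ym <- if (is(Y, "ConnectomePanel")) {
    if (!isTRUE(Y@standardized)) stop("Y panel must be standardised")
    Y@values
  } else Y
  if (ncol(xm) != ncol(ym))
    stop("X and Y must have the same subjects")
  if (!is.null(colnames(xm)) && !is.null(colnames(ym)) &&
      !identical(colnames(xm), colnames(ym)))
    stop("X and Y subject columns must match in order")
  if (config$cU > sqrt(nrow(xm)) + 1e-9 || config$cV > sqrt(nrow(ym)) + 1e-9)
    stop("L1 budget exceeds sqrt(k)")
  wU <- rep_len(wU, nrow(xm))
  wV <- rep_len(wV, nrow(ym))

  alternate <- function(v0) {
    u <- NULL
    v <- v0
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      uNew <- unitL1Constrained(as.vector(xm %*% crossprod(ym, v)),
                                config$cU, wU)
      vNew <- unitL1Constrained(as.vector(ym %*% crossprod(xm, uNew)),
                                config$cV, wV)
      delta <- if (is.null(u)) Inf
               else max(max(abs(uNew - u)), max(abs(vNew - v)))
      u <- uNew
      v <- vNew
      if (delta < config$tol) {
        converged <- TRUE
        break
      }
      if (iter >= config$maxIter) break
    }
    list(u = u, v = v, iter = iter, converged = converged,
         objective = as.numeric(u %*% xm %*% crossprod(ym, v)))
  }

  init <- .leadingCrossPair(xm, ym)
  starts <- list(init$v)
  restarts <- min(config$restarts %||% 0L, nrow(ym))
  if (restarts > 0L) {
    # coordinate starts at the functional edges with the largest
    # cross-product column norms: ||Z e_j||^2 = y_j' (X'X) y_j
    g <- crossprod(xm)               # m x m Gram over subjects
    colNorm2 <- rowSums((ym %*% g) * ym)
    for (j in utils::head(order(colNorm2, decreasing = TRUE), restarts)) {
      e <- numeric(nrow(ym))
      e[j] <- 1
      starts[[length(starts) + 1L]] <- e
    }
  }
  best <- NULL
  for (v0 in starts) {
    cand <- alternate(v0)
    if (is.null(best) || cand$objective > best$objective + 1e-12)
      best <- cand
  }
  u <- best$u
  v <- best$v
  iter <- best$iter
  converged <- best$converged

  # sign convention
  jmax <- which.max(abs(u))
  if (length(jmax) && u[jmax] < 0) {
    u <- -u
    v <- -v
  }
  px <- as.vector(crossprod(xm, u))
  py <- as.vector(crossprod(ym, v))
  rho <- if (stats::sd(px) == 0 || stats::sd(py) == 0) NA_real_
         else stats::cor(px, py)
  if (!is.na(rho) && rho < 0) {
    v <- -v
    rho <- -rho
  }
  names(u) <- rownames(xm)
  names(v) <- rownames(ym)
  new("SccaFit", u = u, v = v, rho = rho, iterations = iter,
      converged = converged,
      objective = as.vector(u %*% xm %*% crossprod(ym, v)))
}
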
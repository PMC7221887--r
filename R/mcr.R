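# Multivariate curve resolution - alternating least squares.
#
# The bilinear model X = A %*% BT + E (generalized Lambert-Beer: each mixture
# spectrum is a concentration-weighted sum of pure component spectra) is fit
# by alternating non-negative least squares on A (samples x k concentration
# profiles) and BT (k x buckets pure spectra).  Rows of BT are kept at unit
# Euclidean norm with the scale folded into A, which together with the
# component ordering (descending total concentration) resolves the bilinear
# scale/permutation ambiguity.

# Multi-RHS NNLS: minimize ||Y - D %*% Z|| column-wise over Z >= 0, where D is
# the common design matrix.  Fast path: the unconstrained normal-equations
# solution; columns that come out infeasible fall back to Lawson-Hanson
# (pracma::lsqnonneg).
nnls_multi <- function(D, Y, nonneg = TRUE) {
  Z <- tryCatch({
    G <- crossprod(D)
    solve(G, crossprod(D, Y))
  }, error = function(e) NULL)
  if (!nonneg) {
    if (is.null(Z))
      stop("design matrix is rank deficient; unconstrained solve failed",
           call. = FALSE)
    return(Z)
  }
  if (ncol(D) <= 2L) return(nnls_multi_k2(D, Y, Z))
  G <- crossprod(D)
  FF <- crossprod(D, Y)
  if (is.null(Z)) {
    Z <- matrix(0, ncol(D), ncol(Y))
    needs <- seq_len(ncol(Y))
  } else {
    needs <- which(apply(Z, 2L, function(z) any(z < 0)))
    Z[, needs] <- 0
  }
  if (!length(needs)) return(Z)
  if (ncol(D) <= 6L) Z[, needs] <- nnls_enum(G, FF[, needs, drop = FALSE])
  else for (j in needs) Z[, j] <- nnls_gram(G, FF[, j])
  Z
}

# Exact NNLS for small k by support enumeration, vectorized over right-hand
# sides: the NNLS optimum is the least-squares solution on its own support,
# so among all supports whose LS solution is feasible the one with the
# largest objective reduction f'z wins.
nnls_enum <- function(G, FF) {
  k <- nrow(FF); m <- ncol(FF)
  best <- matrix(0, k, m)
  best_red <- numeric(m)  # support {} gives z = 0, reduction 0
  for (code in seq_len(2^k - 1L)) {
    p <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    sol <- tryCatch(
      solve(G[p, p, drop = FALSE], FF[p, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(sol)) next
    feas <- colSums(sol < 0) == 0L
    red <- colSums(sol * FF[p, , drop = FALSE])
    take <- feas & red > best_red
    if (any(take)) {
      best[, take] <- 0
      best[p, take] <- sol[, take]
      best_red[take] <- red[take]
    }
  }
  best
}

# Lawson-Hanson active-set NNLS on the normal equations: minimize
# ||y - D z||^2 over z >= 0 given G = D'D and f = D'y.  Working on the k x k
# Gram system keeps the cost independent of the number of rows of D, which
# is what makes the ALS half-steps cheap.
nnls_gram <- function(G, f) {
  k <- length(f)
  passive <- rep(FALSE, k)
  z <- numeric(k)
  w <- f
  tol <- 1e-12 * max(abs(f), 1)
  for (outer in seq_len(30L * k)) {
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(k)
      sol <- tryCatch(solve(G[passive, passive, drop = FALSE], f[passive]),
                      error = function(e) NULL)
      if (is.null(sol)) {  # degenerate subproblem: drop the newest variable
        passive[which(passive)[sum(passive)]] <- FALSE
        if (!any(passive)) return(numeric(k))
        next
      }
      s[passive] <- sol
      if (all(s[passive] > 0)) { z <- s; break }
      q <- passive & s <= 0
      alpha <- min(z[q] / (z[q] - s[q]))
      z <- z + alpha * (s - z)
      passive <- passive & z > tol
      z[!passive] <- 0
    }
    w <- f - as.vector(G %*% z)
  }
  z
}

# Exact NNLS for one or two columns of D, vectorized over all right-hand
# sides by enumerating the candidate support sets (the unconstrained
# solution if feasible, else the best single-component fit).
nnls_multi_k2 <- function(D, Y, Z_ols) {
  DtY <- crossprod(D, Y)                     # k x m
  dn <- colSums(D^2)
  if (ncol(D) == 1L)
    return(matrix(pmax(DtY[1L, ] / dn[1L], 0), 1L))
  single <- pmax(DtY / dn, 0)                # best per-component fits, 2 x m
  gain <- single * DtY                       # objective decrease vs z = 0
  pick1 <- gain[1L, ] >= gain[2L, ]
  Z <- rbind(ifelse(pick1, single[1L, ], 0), ifelse(pick1, 0, single[2L, ]))
  if (!is.null(Z_ols)) {
    ok <- Z_ols[1L, ] >= 0 & Z_ols[2L, ] >= 0
    Z[, ok] <- Z_ols[, ok]
  }
  Z
}

# Frobenius RSS as a percentage of the total sum of squares of X.
rel_rss <- function(X, A, BT) 100 * sum((X - A %*% BT)^2) / sum(X^2)

# Evaluate a function with a temporary RNG state derived from `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Initial pure-spectra estimates for MCR-ALS
#'
#' `purest_variables` performs a deterministic greedy selection of `k`
#' mutually dissimilar high-intensity bucket columns (pick the column of X
#' with the largest Euclidean norm, then repeatedly the column whose maximum
#' cosine similarity to the already-chosen columns is smallest), uses the
#' selected columns as initial concentration profiles, and lifts them to
#' initial spectra by one non-negative least-squares solve.  This mirrors
#' purest-variable (SIMPLISMA-style) initialization.  `random_uniform` draws
#' i.i.d. uniform(0, 1) rows under `seed`.  Rows are returned at unit norm.
#'
#' @param X A [bucket_set()] or numeric matrix (samples x buckets).
#' @param k Number of components.
#' @param method `"purest_variables"` (deterministic) or `"random_uniform"`.
#' @param seed Integer seed (used by `random_uniform` only).
#' @return k x buckets matrix with unit-norm rows; for `purest_variables`
#'   the chosen bucket-column indices are attached as attribute
#'   `"selected_buckets"`.
#' @export
mcr_initialize <- function(X, k, method = c("purest_variables", "random_uniform"),
                           seed = 0L) {
  method <- match.arg(method)
  M <- as_bucket_matrix(X)
  check_k(k, M)
  nb <- ncol(M)
  if (method == "random_uniform") {
    BT <- with_seed(seed, matrix(stats::runif(k * nb), nrow = k))
    return(BT / sqrt(rowSums(BT^2)))
  }
  norms <- sqrt(colSums(M^2))
  if (all(norms == 0)) stop("matrix is all zero", call. = FALSE)
  U <- sweep(M, 2L, pmax(norms, .Machine$double.xmin), "/")
  sel <- which.max(norms)
  while (length(sel) < k) {
    sim <- abs(crossprod(U[, sel, drop = FALSE], U))  # |cosine| to chosen
    worst <- apply(sim, 2L, max)
    worst[sel] <- Inf
    sel <- c(sel, which.min(worst))
  }
  A0 <- pmax(M[, sel, drop = FALSE], 0)
  BT <- nnls_multi(A0, M)
  BT <- fix_dead_rows(BT, seed = seed + 1L)
  BT <- BT / sqrt(rowSums(BT^2))
  attr(BT, "selected_buckets") <- sel
  BT
}

# Replace all-zero rows by random unit rows (their concentrations are zero,
# so the objective is unchanged but the unit-norm invariant holds).
fix_dead_rows <- function(BT, seed) {
  dead <- rowSums(BT^2) == 0
  if (any(dead))
    BT[dead, ] <- with_seed(seed,
      matrix(stats::runif(sum(dead) * ncol(BT)), nrow = sum(dead)))
  BT
}

check_k <- function(k, M) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 ||
      k > min(dim(M)))
    stop(sprintf("k must be an integer in [1, %d]", min(dim(M))),
         call. = FALSE)
}

# One ALS run from a given BT start.  Returns A, BT, rss path, iterations.
als_run <- function(M, BT, max_iter, tol, nonneg_A, nonneg_BT, seed) {
  rss_path <- numeric(0)
  rss_prev <- Inf
  converged <- FALSE
  A <- NULL
  for (it in seq_len(max_iter)) {
    # concentrations: rows of A solve min ||x_i - a %*% BT||, design t(BT)
    A <- t(nnls_multi(t(BT), t(M), nonneg = nonneg_A))
    # spectra: columns of BT solve min ||X[,j] - A %*% bt_j||, design A
    BT <- nnls_multi(A, M, nonneg = nonneg_BT)
    BT <- fix_dead_rows(BT, seed = seed + 7919L * it)
    s <- sqrt(rowSums(BT^2))
    BT <- BT / s
    A <- sweep(A, 2L, s, "*")
    rss <- rel_rss(M, A, BT)
    rss_path <- c(rss_path, rss)
    if (is.finite(rss_prev) &&
        (rss_prev - rss) < tol * max(rss_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }
  list(A = A, BT = BT, rss = rss_path[length(rss_path)], rss_path = rss_path,
       n_iter = length(rss_path), converged = converged)
}

#' Fit a constrained bilinear MCR-ALS model
#'
#' Alternates non-negative least-squares solves for the concentration matrix
#' A (given the pure spectra) and the pure-spectra matrix BT (given the
#' concentrations), renormalizing BT rows to unit Euclidean norm with the
#' scale folded into A, until the relative change in the residual sum of
#' squares falls below `tol` or `max_iter` is reached.  Among
#' `n_restarts` initializations (one deterministic purest-variables start
#' plus seeded random starts) plus any starts supplied in `extra_inits`, the
#' model with the lowest relative RSS is returned.  Components are ordered by
#' descending total concentration (column sum of A); ties are broken by the
#' descending bucket index of each spectrum's maximum.
#'
#' @param X A [bucket_set()] or numeric matrix (samples x buckets), finite,
#'   not all zero.
#' @param k Number of components, `1 <= k <= min(dim(X))`.
#' @param max_iter Maximum ALS iterations per restart.
#' @param tol Convergence tolerance on the relative change of the relative
#'   RSS between iterations.
#' @param n_restarts Number of standard initializations (the first is
#'   purest-variables, the rest random-uniform).  May be 0 if `extra_inits`
#'   is supplied.
#' @param seed Integer seed controlling the random restarts (run is
#'   bit-reproducible given the seed).
#' @param nonneg Which factors are constrained non-negative: a subset of
#'   `c("A", "BT")` (default both, the standard MCR-ALS constraint set under
#'   the Lambert-Beer interpretation), or `character(0)` for an
#'   unconstrained bilinear fit.
#' @param extra_inits Optional list of additional starting BT matrices
#'   (k x buckets); used e.g. to nest the solution at k-1 into the scan at k.
#' @return An object of class `mcr_model` with elements `k`, `A`, `BT`, `E`
#'   (`= X - A %*% BT`), `rss_relative`, `ess_relative` (percent), `n_iter`,
#'   `converged`, `seed`, `restarts`, `rss_path` and `init` (which start won).
#' @examples
#' a <- c(1, 2, 4); b <- c(0, 1, 3, 2)
#' m <- mcr_als_fit(outer(a, b), k = 1, n_restarts = 2)
#' m$rss_relative  # ~0: exact rank-1 data
#' @export
mcr_als_fit <- function(X, k, max_iter = 500L, tol = 1e-8, n_restarts = 10L,
                        seed = 0L, nonneg = c("A", "BT"), extra_inits = NULL) {
  M <- as_bucket_matrix(X)
  if (!all(is.finite(M)))
    stop("X contains non-finite values", call. = FALSE)
  if (all(M == 0))
    stop("X is all zero: the bilinear model has no defined scale",
         call. = FALSE)
  check_k(k, M)
  stopifnot(max_iter >= 1, tol >= 0, n_restarts >= 0)
  if (length(nonneg) && !all(nonneg %in% c("A", "BT")))
    stop("nonneg must be a subset of c('A', 'BT')", call. = FALSE)
  nonneg_A <- "A" %in% nonneg
  nonneg_BT <- "BT" %in% nonneg
  starts <- list()
  labels <- character(0)
  if (n_restarts >= 1L) {
    starts <- c(starts, list(mcr_initialize(M, k, "purest_variables")))
    labels <- c(labels, "purest_variables")
  }
  if (n_restarts >= 2L) {
    for (r in 2:n_restarts) {
      starts <- c(starts, list(
        mcr_initialize(M, k, "random_uniform", seed = seed + 1000L * r)))
      labels <- c(labels, sprintf("random_uniform_%d", r - 1L))
    }
  }
  if (!is.null(extra_inits)) {
    for (i in seq_along(extra_inits)) {
      B0 <- as.matrix(extra_inits[[i]])
      if (!all(dim(B0) == c(k, ncol(M))))
        stop("extra_inits matrices must be k x n_buckets", call. = FALSE)
      B0 <- fix_dead_rows(B0, seed = seed + 31L * i)
      starts <- c(starts, list(B0 / sqrt(rowSums(B0^2))))
      labels <- c(labels, sprintf("supplied_%d", i))
    }
  }
  if (!length(starts))
    stop("no initializations: n_restarts is 0 and extra_inits is empty",
         call. = FALSE)
  best <- NULL
  for (i in seq_along(starts)) {
    run <- als_run(M, starts[[i]], max_iter = max_iter, tol = tol,
                   nonneg_A = nonneg_A, nonneg_BT = nonneg_BT,
                   seed = seed + 104729L * i)
    if (is.null(best) || run$rss < best$rss) { best <- run; best$init <- labels[i] }
  }
  # resolve permutation ambiguity: order by descending total concentration,
  # tie-break by descending argmax bucket of the spectrum
  tot <- colSums(best$A)
  ord <- order(-tot, -apply(best$BT, 1L, which.max))
  A <- best$A[, ord, drop = FALSE]
  BT <- best$BT[ord, , drop = FALSE]
  comp <- sprintf("Macro %d", seq_len(k))
  dimnames(A) <- list(rownames(M), comp)
  dimnames(BT) <- list(comp, colnames(M))
  E <- M - A %*% BT
  rss <- 100 * sum(E^2) / sum(M^2)
  structure(list(k = as.integer(k), A = A, BT = BT, E = E,
                 rss_relative = rss, ess_relative = 100 - rss,
                 n_iter = best$n_iter, converged = best$converged,
                 seed = as.integer(seed), restarts = length(starts),
                 rss_path = best$rss_path, init = best$init,
                 nonneg = nonneg),
            class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf(
    "<mcr_model> k = %d: relative RSS %.4g%% (ESS %.4g%%), %d iteration(s), %s (%d start(s), init %s)\n",
    x$k, x$rss_relative, x$ess_relative, x$n_iter,
    if (x$converged) "converged" else "max_iter reached",
    x$restarts, x$init))
  invisible(x)
}

#' Freeze the pure-spectra matrix of a fitted model as a component library
#'
#' @param model An `mcr_model`.
#' @param grid The [bucket_grid()] the model was fit on.
#' @param labels Optional component labels.
#' @return A [component_library()].
#' @export
freeze_library <- function(model, grid,
                           labels = sprintf("Macro %d", seq_len(model$k))) {
  stopifnot(inherits(model, "mcr_model"))
  # clamp rounding negatives from the unconstrained mode guard
  S <- pmax(model$BT, 0)
  S <- S / sqrt(rowSums(S^2))
  component_library(S, grid, labels = labels)
}
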
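# Binomial-moment solution of the promoter-modulated birth-death CME.

lambda_diag_of <- function(Lambda, n) {
  ld <- if (is.matrix(Lambda)) {
    if (any(Lambda[row(Lambda) != col(Lambda)] != 0))
      stop("Lambda must be diagonal")
    diag(Lambda)
  } else Lambda
  if (length(ld) != n) stop("Lambda dimension must match A")
  if (any(ld < 0)) stop("Lambda diagonal must be nonnegative")
  ld
}

check_generator <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  n <- nrow(A)
  offdiag <- A[row(A) != col(A)]
  if (any(offdiag < 0)) stop("A has negative off-diagonal entries")
  if (max(abs(colSums(A))) > 1e-8 * max(1, max(abs(A))))
    stop("columns of A must sum to zero (probability conservation)")
  # strong connectivity of the jump graph (edge j -> i iff A[i, j] > 0)
  adj <- A > 0
  diag(adj) <- TRUE
  reach <- adj
  for (i in seq_len(n)) reach <- (reach %*% adj) > 0
  if (!all(reach))
    stop("promoter chain is reducible; disconnected states: ",
         paste(which(!apply(reach, 2, all)), collapse = ", "))
  invisible(n)
}

#' Stationary law of the promoter chain
#'
#' Normalized null vector of a proper generator `A` (columns summing to
#' zero); errors if the chain is reducible.
#'
#' @param A Generator matrix, `A[i, j]` the rate from `j` to `i`.
#' @return Probability vector `b0` with `A %*% b0 = 0`, `sum(b0) = 1`.
#' @examples
#' gp <- config_generator(loop_config("side_by_side", d1 = 300, k1 = 1, k2 = 1))
#' stationary_probs(gp$A)
#' @export
stationary_probs <- function(A) {
  n <- check_generator(A)
  M <- rbind(A[-n, , drop = FALSE], rep(1, n))
  p <- solve(M, c(rep(0, n - 1), 1))
  p[p < 0 & p > -1e-14] <- 0
  setNames(p, colnames(A))
}

#' Stationary binomial moments of the mRNA copy number
#'
#' Solves the steady-state recursion
#' \eqn{(k \delta I - A) b_k = \Lambda b_{k-1}} with \eqn{b_0} the
#' stationary promoter law, for `k = 1..K`.  `B_k = sum_i b_k^{(i)}` is the
#' k-th binomial moment (k-th factorial moment over `k!`) of the stationary
#' copy-number distribution.  Computation runs in compensated double-double
#' arithmetic so the moments can feed the alternating-sum distribution
#' reconstruction without precision loss.
#'
#' @param A Promoter generator (any number of states).
#' @param Lambda Diagonal transcription matrix or its diagonal vector.
#' @param delta Degradation rate, `> 0`.
#' @param K Truncation order; default `max(50, ceiling(4 * max(Lambda) / delta))`.
#' @return An object of class `moment_sequence`: list with `totals`
#'   (`B_0..B_K`), `per_state` (`(K+1) x N` matrix of `b_k^{(i)}`), `K`,
#'   `delta`, and the inputs (used by [reconstruct_distribution()] to rerun
#'   the recursion at higher order when needed).
#' @examples
#' gp <- config_generator(loop_config("alternating", d1 = 300, k1 = 0.5, k2 = 0.5))
#' mom <- solve_moments(gp$A, gp$Lambda)
#' mom$totals[2]  # mean copy number
#' @export
solve_moments <- function(A, Lambda, delta = 1, K = NULL) {
  n <- check_generator(A)
  ld <- lambda_diag_of(Lambda, n)
  if (delta <= 0) stop("delta must be > 0")
  if (is.null(K)) K <- max(50, ceiling(4 * max(ld) / delta))
  if (K < 1) stop("K must be >= 1")
  res <- .bm_core_dd(A, ld, delta, as.integer(K), -1L)
  structure(list(totals = setNames(res$totals, paste0("B", 0:K)),
                 per_state = res$per_state, K = as.integer(K), delta = delta,
                 A = A, lambda_diag = ld), class = "moment_sequence")
}

#' @export
print.moment_sequence <- function(x, ...) {
  cat(sprintf("<moment_sequence> N=%d states, K=%d, delta=%g\n",
              ncol(x$per_state), x$K, x$delta))
  cat("  B1 (mean) =", format(x$totals[["B1"]]), " B2 =",
      format(x$totals[["B2"]]), "\n")
  invisible(x)
}

#' Time evolution of the binomial moments
#'
#' Integrates the lower-block-triangular linear system
#' \eqn{db_k/dt = (A - k \delta I) b_k + \Lambda b_{k-1}} from an initial
#' promoter law with zero transcripts (so `b_k(0) = 0` for `k >= 1`).
#'
#' @inheritParams solve_moments
#' @param K Truncation order.
#' @param initial_state Initial promoter probability vector (default: all
#'   mass in state 1, i.e. OFF1).
#' @param t_grid Increasing times starting at 0.
#' @param rtol,atol Integrator tolerances (deSolve::lsoda).
#' @return Class `moment_dynamics`: list with `t`, `totals` (length(t) x
#'   (K+1) matrix of `B_k(t)`) and `per_state` (length(t) x N(K+1)).
#' @examples
#' gp <- config_generator(loop_config("alternating", d1 = 300, k1 = 0.5, k2 = 0.5))
#' dyn <- evolve_moments(gp$A, gp$Lambda, K = 2, t_grid = seq(0, 5, 0.5))
#' dyn$totals[, "B1"]  # mean trajectory from zero
#' @export
evolve_moments <- function(A, Lambda, delta = 1, K = 4,
                           initial_state = NULL, t_grid,
                           rtol = 1e-10, atol = 1e-12) {
  n <- check_generator(A)
  ld <- lambda_diag_of(Lambda, n)
  if (delta <= 0) stop("delta must be > 0")
  if (is.null(initial_state)) initial_state <- c(1, rep(0, n - 1))
  if (length(initial_state) != n || any(initial_state < 0) ||
      abs(sum(initial_state) - 1) > 1e-10)
    stop("initial_state must be a probability vector over the promoter states")
  if (length(t_grid) < 1 || t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing and start at 0")
  big <- matrix(0, n * (K + 1), n * (K + 1))
  for (k in 0:K) {
    idx <- k * n + seq_len(n)
    big[idx, idx] <- A - k * delta * diag(n)
    if (k >= 1) big[idx, idx - n] <- diag(ld, n)
  }
  y0 <- c(initial_state, rep(0, n * K))
  sol <- deSolve::lsoda(y0, t_grid, function(t, y, p) list(big %*% y),
                        parms = NULL, rtol = rtol, atol = atol)
  ys <- sol[, -1, drop = FALSE]
  totals <- sapply(0:K, function(k) rowSums(ys[, k * n + seq_len(n), drop = FALSE]))
  totals <- matrix(totals, nrow = length(t_grid),
                   dimnames = list(NULL, paste0("B", 0:K)))
  structure(list(t = t_grid, totals = totals, per_state = ys,
                 K = as.integer(K), delta = delta), class = "moment_dynamics")
}

#' Reconstruct the stationary mRNA distribution from binomial moments
#'
#' Evaluates \eqn{P(m) = \sum_{k \ge m} (-1)^{k-m} \binom{k}{m} B_k} in
#' compensated double-double arithmetic.  The truncation order is grown
#' automatically until the last retained alternating term is below
#' `1e-13`; if the cancellation error bound cannot meet the tolerance the
#' function stops and points to [fsp_steady_state()] as the fallback path.
#'
#' @param moments A `moment_sequence` from [solve_moments()].
#' @param M Support cap; default from mean + 12 standard deviations.
#' @param K_cap Largest truncation order tried before giving up.
#' @return An `mrna_pmf` with `method_tag = "reconstruction"`.
#' @examples
#' gp <- config_generator(loop_config("nested", d1 = 300))
#' pmf <- reconstruct_distribution(solve_moments(gp$A, gp$Lambda))
#' pmf_mean(pmf)
#' @export
reconstruct_distribution <- function(moments, M = NULL, K_cap = 600L) {
  stopifnot(inherits(moments, "moment_sequence"))
  B1 <- moments$totals[["B1"]]
  B2 <- moments$totals[["B2"]]
  v <- max(2 * B2 + B1 - B1^2, B1, 1e-12)
  if (is.null(M)) M <- ceiling(B1 + 12 * sqrt(v)) + 10
  K <- max(moments$K, M + 25)
  repeat {
    res <- .bm_core_dd(moments$A, moments$lambda_diag, moments$delta,
                       as.integer(K), as.integer(M))
    if (res$tail_term < 1e-13) break
    if (K >= K_cap)
      stop("reconstruction truncation not converged at K = ", K,
           " (last term ", format(res$tail_term),
           "); use fsp_steady_state() instead")
    K <- min(K_cap, ceiling(K * 1.5) + 10)
  }
  # double-double carries ~31 digits; refuse output when cancellation has
  # eaten through the precision budget
  if (res$max_term * 1e-31 > 1e-10)
    stop("alternating-sum cancellation beyond precision budget (max term ",
         format(res$max_term), "); use fsp_steady_state() instead")
  probs <- res$probs
  # trim the requested support to where mass lives, keep tail < 1e-10
  new_pmf(probs, "reconstruction")
}

#' Stationary distribution by finite state projection
#'
#' Independent deterministic oracle for the same chemical master equation:
#' solves the truncated stationary CME on promoter states x copy numbers
#' `{0..M}` directly as one sparse linear system (reflecting boundary at
#' `M`).  `M` is grown until the probability on the boundary level is below
#' `tail_tol`.
#'
#' @inheritParams solve_moments
#' @param M Initial truncation level (auto-grown); default from moment
#'   estimates.
#' @param tail_tol Acceptable boundary-mass (default 1e-12).
#' @param M_cap Hard cap on truncation growth.
#' @return An `mrna_pmf` with `method_tag = "fsp"`; the per-promoter-state
#'   joint distribution is attached as attribute `"per_state"` (N x (M+1)).
#' @examples
#' gp <- config_generator(loop_config("nested", d1 = 300))
#' fsp <- fsp_steady_state(gp$A, gp$Lambda)
#' pmf_noise(fsp)
#' @export
fsp_steady_state <- function(A, Lambda, delta = 1, M = NULL,
                             tail_tol = 1e-12, M_cap = 5000L) {
  n <- check_generator(A)
  ld <- lambda_diag_of(Lambda, n)
  if (delta <= 0) stop("delta must be > 0")
  if (is.null(M)) {
    b0 <- stationary_probs(A)
    mean_hat <- sum(ld * b0) / delta
    M <- ceiling(mean_hat + 12 * sqrt(mean_hat + 1)) + 15
  }
  repeat {
    S <- n * (M + 1)
    idx <- function(i, m) (m) * n + i  # 1-based block per copy level
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    add <- function(i, j, v) {
      ii[[length(ii) + 1]] <<- i; jj[[length(jj) + 1]] <<- j
      xx[[length(xx) + 1]] <<- v
    }
    # promoter switching within each copy level
    nz <- which(A != 0, arr.ind = TRUE)
    for (m in 0:M) {
      for (r in seq_len(nrow(nz)))
        add(idx(nz[r, 1], m), idx(nz[r, 2], m), A[nz[r, 1], nz[r, 2]])
      for (i in seq_len(n)) {
        birth <- if (m < M) ld[i] else 0  # reflecting boundary
        death <- delta * m
        add(idx(i, m), idx(i, m), -(birth + death))
        if (m < M) add(idx(i, m + 1), idx(i, m), ld[i])
        if (m > 0) add(idx(i, m - 1), idx(i, m), delta * m)
      }
    }
    Q <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(S, S))
    Q[S, ] <- 1  # replace last balance equation by normalization
    rhs <- c(rep(0, S - 1), 1)
    p <- as.numeric(Matrix::solve(Q, rhs))
    per_state <- matrix(p, nrow = n)
    probs <- colSums(per_state)
    if (probs[M + 1] < tail_tol) {
      probs[probs < 0 & probs > -1e-12] <- 0
      pmf <- new_pmf(probs, "fsp")
      attr(pmf, "per_state") <- per_state
      return(pmf)
    }
    if (M >= M_cap)
      stop("FSP truncation cap reached with boundary mass ",
           format(probs[M + 1]))
    M <- min(M_cap, ceiling(M * 1.5) + 10)
  }
}

#' Summary statistics from binomial moments
#'
#' Mean `B_1`, variance `2 B_2 + B_1 - B_1^2`, noise intensity
#' `eta = variance / mean^2`, Fano factor, and (when `K >= 4`) skewness and
#' kurtosis obtained by converting the factorial moments `k! B_k` to raw
#' and then central moments.  Kurtosis is reported plain (not excess).
#'
#' @param moments A `moment_sequence` (or `moment_dynamics` row extracted as
#'   a named vector of `B_k`).
#' @return Class `summary_stats`: list with `mean`, `variance`, `eta`,
#'   `fano`, `skewness`, `kurtosis`.
#' @examples
#' gp <- config_generator(loop_config("nested", d1 = 300))
#' summary_stats(solve_moments(gp$A, gp$Lambda))
#' @export
summary_stats <- function(moments) {
  B <- if (inherits(moments, "moment_sequence")) moments$totals else moments
  if (length(B) < 3) stop("need binomial moments up to order >= 2")
  f <- function(k) factorial(k) * B[[k + 1]]
  m1 <- f(1); m2 <- f(2) + m1
  v <- m2 - m1^2
  eta <- if (m1 > 0) v / m1^2 else NA_real_
  if (m1 == 0) warning("mean is zero; noise intensity undefined")
  sk <- ku <- NA_real_
  if (length(B) >= 5) {
    m3 <- f(3) + 3 * f(2) + m1
    m4 <- f(4) + 6 * f(3) + 7 * f(2) + m1
    c3 <- m3 - 3 * m1 * v - m1^3
    c4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
    sk <- c3 / v^1.5
    ku <- c4 / v^2
  }
  structure(list(mean = m1, variance = v, eta = eta,
                 fano = if (m1 > 0) v / m1 else NA_real_,
                 skewness = sk, kurtosis = ku), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> mean=%.6g var=%.6g eta=%.6g fano=%.6g\n",
              x$mean, x$variance, x$eta, x$fano))
  if (is.finite(x$skewness))
    cat(sprintf("  skewness=%.6g kurtosis=%.6g\n", x$skewness, x$kurtosis))
  invisible(x)
}
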
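# Closed-form hypergeometric stationary distributions used to cross-check
# the binomial-moment solver.

#' Two-state (telegraph-like) stationary mRNA distribution
#'
#' Stationary copy-number law of a promoter switching ON at rate `lam` and
#' OFF at rate `lam_off`, transcribing at rate `mu` while ON (degradation
#' rate 1):
#' \deqn{P(m) = \frac{\mu^m}{m!}
#'   \frac{(\lambda)_m}{(\lambda+\lambda_{off})_m}
#'   {}_1F_1(m+\lambda;\, m+\lambda+\lambda_{off};\, -\mu)}
#' with \eqn{(c)_m} the Pochhammer symbol.  The default `lam_off = lam`
#' is the symmetric case that also arises by exact lumping of the
#' all-equal-rates four-state promoter.  Series are summed with explicit
#' term recurrences in double-double arithmetic.
#'
#' @param lam ON-switching rate, `> 0`.
#' @param mu Transcription rate, `> 0` (in units of the degradation rate).
#' @param M Support cap; default mean + 12 sd.
#' @param lam_off OFF-switching rate (default `lam`).
#' @return An `mrna_pmf` with `method_tag = "analytic"`.
#' @examples
#' telegraph_pmf(0.3, 10)
#' @export
telegraph_pmf <- function(lam, mu, M = NULL, lam_off = lam) {
  if (lam <= 0 || lam_off <= 0 || mu <= 0) stop("lam, lam_off, mu must be > 0")
  if (is.null(M)) {
    mean0 <- mu * lam / (lam + lam_off)
    M <- ceiling(mean0 + 12 * sqrt(mean0 + 1)) + 15
  }
  probs <- .hyper_pmf_dd(mu, lam, lam + lam_off, as.integer(M))
  if (abs(sum(probs) - 1) > 1e-10)
    stop("telegraph pmf mass off by ", format(sum(probs) - 1),
         "; increase M")
  new_pmf(probs, "analytic")
}

#' Two-component 3F3 mixture distribution
#'
#' Stationary distribution of the four-state promoter in its general
#' closed form: a mixture of two confluent-hypergeometric components,
#' \deqn{P(m) = \sum_i w_i \frac{\mu^m}{m!}
#'   \prod_j \frac{(\gamma^{(i)}_j)_m}{(\alpha_j)_m}\,
#'   {}_3F_3(m+\gamma^{(i)};\, m+\alpha;\, -\mu),}
#' where \eqn{-\alpha_j} are the nonzero eigenvalues of the promoter
#' generator.  The numerator parameters are caller-supplied (their symbolic
#' form in terms of the rates is not reproduced here); they can be obtained
#' by eigenvalue bookkeeping or moment matching.
#'
#' @param weights Mixture weights summing to 1.
#' @param gamma_sets List of numeric length-3 vectors, one per component.
#' @param alphas Numeric length-3 vector of denominator parameters
#'   (positive real part).
#' @param mu Effective transcription rate.
#' @param M Support cap.
#' @return An `mrna_pmf` with `method_tag = "analytic"`.
#' @examples
#' # gamma = alpha collapses each component to Poisson(mu)
#' mixture_pmf(1, list(c(1, 2, 3)), c(1, 2, 3), mu = 5, M = 40)
#' @export
mixture_pmf <- function(weights, gamma_sets, alphas, mu, M = NULL) {
  if (!is.list(gamma_sets)) gamma_sets <- list(gamma_sets)
  if (length(weights) != length(gamma_sets))
    stop("one weight per gamma set required")
  if (abs(sum(weights) - 1) > 1e-10) stop("weights must sum to 1")
  if (length(alphas) != 3 || any(vapply(gamma_sets, length, 1L) != 3))
    stop("parameter sets must have length 3")
  if (mu <= 0) stop("mu must be > 0")
  if (is.null(M)) M <- ceiling(mu + 12 * sqrt(mu + 1)) + 15
  probs <- rep(0, M + 1)
  for (i in seq_along(weights))
    probs <- probs + weights[i] *
      .hyper_pmf_dd(mu, gamma_sets[[i]], alphas, as.integer(M))
  new_pmf(probs, "analytic")
}

#' 2F2-form stationary distribution (non-interacting loops)
#'
#' Closed form for the side-by-side special case in which the blue-loop
#' opening rates are a common multiple of the others:
#' \deqn{P(m) = \frac{\tilde\mu^m}{m!}
#'   \frac{(a_1)_m (a_2)_m}{(b_1)_m (b_2)_m}\,
#'   {}_2F_2(m+a;\, m+b;\, -\tilde\mu).}
#'
#' @param mu_tilde Effective transcription scale, `> 0`.
#' @param a_pair,b_pair Numeric length-2 parameter vectors, positive.
#' @param M Support cap.
#' @return An `mrna_pmf` with `method_tag = "analytic"`.
#' @seealso [two_f_two_noise()], [fit_two_f_two()]
#' @export
two_f_two_pmf <- function(mu_tilde, a_pair, b_pair, M = NULL) {
  if (length(a_pair) != 2 || length(b_pair) != 2)
    stop("a_pair and b_pair must have length 2")
  if (mu_tilde <= 0 || any(a_pair <= 0) || any(b_pair <= 0))
    stop("parameters must be positive")
  if (is.null(M)) {
    mean0 <- mu_tilde * prod(a_pair) / prod(b_pair)
    M <- ceiling(mean0 + 12 * sqrt(mean0 + 1)) + 15
  }
  probs <- .hyper_pmf_dd(mu_tilde, a_pair, b_pair, as.integer(M))
  new_pmf(probs, "analytic")
}

#' Noise intensity of the 2F2-form distribution
#'
#' Two readings of the printed noise formula are carried side by side.
#' The `"consistent"` reading,
#' \deqn{\eta = \frac{b_1 b_2}{a_1 a_2}\left[
#'   \frac{(1+a_1)(1+a_2)}{(1+b_1)(1+b_2)} + \frac{1}{\tilde\mu}\right] - 1,}
#' agrees exactly with the variance/mean^2 of [two_f_two_pmf()] (it follows
#' from the distribution's binomial moments
#' \eqn{B_k = \tilde\mu^k (a_1)_k (a_2)_k / (k! (b_1)_k (b_2)_k)}).  The
#' `"literal"` reading keeps the typeset grouping with \eqn{\tilde\mu}
#' inside the outer factor,
#' \eqn{[\cdot]\, b_1 b_2 / (\tilde\mu a_1 a_2) - 1}, and does not
#' reproduce the distribution's own noise except at measure-zero parameter
#' sets; it is retained so the discrepancy is documented rather than
#' silently corrected.
#'
#' @inheritParams two_f_two_pmf
#' @param reading `"consistent"` (default) or `"literal"`.
#' @return Noise intensity (variance over squared mean).
#' @export
two_f_two_noise <- function(mu_tilde, a_pair, b_pair,
                            reading = c("consistent", "literal")) {
  reading <- match.arg(reading)
  a1 <- a_pair[1]; a2 <- a_pair[2]; b1 <- b_pair[1]; b2 <- b_pair[2]
  bracket <- (1 + a1) * (1 + a2) / ((1 + b1) * (1 + b2)) + 1 / mu_tilde
  switch(reading,
    consistent = bracket * b1 * b2 / (a1 * a2) - 1,
    literal = bracket * b1 * b2 / (mu_tilde * a1 * a2) - 1)
}

#' Recover 2F2 parameters from binomial moments
#'
#' For a distribution of the 2F2 form the ratio
#' \eqn{R(k) = (k+1) B_{k+1} / B_k =
#'   \tilde\mu (a_1+k)(a_2+k) / ((b_1+k)(b_2+k))}
#' is a rational function of `k` whose coefficients are linear in
#' \eqn{(b_1+b_2,\; b_1 b_2,\; \tilde\mu,\; \tilde\mu(a_1+a_2),\;
#' \tilde\mu a_1 a_2)}; five ratio values pin them down exactly, replacing
#' a nonlinear fit by one 5x5 linear solve plus two quadratics.
#'
#' @param moments A `moment_sequence` with `K >= 5` (only `B_0..B_5` used).
#' @return List with `mu_tilde`, `a_pair`, `b_pair`.  Complex quadratic
#'   roots signal that the distribution is not of 2F2 form; an error is
#'   raised in that case.
#' @export
fit_two_f_two <- function(moments) {
  B <- if (inherits(moments, "moment_sequence")) moments$totals else moments
  if (length(B) < 6) stop("need binomial moments up to order 5")
  k <- 0:4
  R <- (k + 1) * B[k + 2] / B[k + 1]
  # R(k)(k^2 + s_b k + p_b) = mt k^2 + q1 k + q0
  Mlin <- cbind(R * k, R, -k^2, -k, -1)
  rhs <- -R * k^2
  x <- solve(Mlin, rhs)
  s_b <- x[1]; p_b <- x[2]; mt <- x[3]; q1 <- x[4]; q0 <- x[5]
  quad_roots <- function(s, p) {
    disc <- s^2 - 4 * p
    if (disc < -1e-8 * max(1, s^2))
      stop("complex parameters: distribution is not of 2F2 form")
    disc <- max(disc, 0)
    c((s - sqrt(disc)) / 2, (s + sqrt(disc)) / 2)
  }
  list(mu_tilde = unname(mt),
       a_pair = unname(quad_roots(q1 / mt, q0 / mt)),
       b_pair = unname(quad_roots(s_b, p_b)))
}
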
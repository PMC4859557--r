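#' mRNA copy-number distributions
#'
#' Finite distributions over copy numbers `m = 0..M` are represented by the
#' lightweight class `mrna_pmf`: a probability vector plus a tag recording
#' how it was obtained (`"reconstruction"`, `"fsp"`, `"analytic"` or
#' `"empirical"`).
#'
#' @param probs Nonnegative vector, `probs[m + 1] = P(m)`.
#' @param method_tag Provenance tag.
#' @param normalize Renormalize after clipping tiny negatives (default TRUE).
#' @param tol Clipping tolerance for negatives introduced by round-off.
#' @return An `mrna_pmf` object.
#' @export
new_pmf <- function(probs, method_tag = c("reconstruction", "fsp", "analytic",
                                          "empirical"),
                    normalize = TRUE, tol = 1e-12) {
  method_tag <- match.arg(method_tag)
  if (any(probs < -tol))
    stop("pmf has negative mass beyond tolerance (min ", min(probs), ")")
  probs[probs < 0] <- 0
  s <- sum(probs)
  if (abs(s - 1) > 1e-8)
    stop(sprintf("pmf normalization off by %.3g (method %s)", s - 1, method_tag))
  if (normalize) probs <- probs / s
  structure(list(probs = probs, M = length(probs) - 1L,
                 method_tag = method_tag), class = "mrna_pmf")
}

#' @export
print.mrna_pmf <- function(x, ...) {
  cat(sprintf("<mrna_pmf> method=%s support=0..%d mean=%.4f var=%.4f\n",
              x$method_tag, x$M, pmf_mean(x), pmf_var(x)))
  invisible(x)
}

#' Moments and noise of a pmf
#'
#' @param pmf An `mrna_pmf`.
#' @return `pmf_mean`: the mean; `pmf_var`: the variance; `pmf_noise`: the
#'   noise intensity (variance over squared mean); `pmf_fano`: the Fano
#'   factor.
#' @export
pmf_mean <- function(pmf) sum((0:pmf$M) * pmf$probs)

#' @rdname pmf_mean
#' @export
pmf_var <- function(pmf) {
  m <- 0:pmf$M
  mu <- pmf_mean(pmf)
  sum((m - mu)^2 * pmf$probs)
}

#' @rdname pmf_mean
#' @export
pmf_noise <- function(pmf) pmf_var(pmf) / pmf_mean(pmf)^2

#' @rdname pmf_mean
#' @export
pmf_fano <- function(pmf) pmf_var(pmf) / pmf_mean(pmf)

#' Total-variation distance between two pmfs
#'
#' Supports of different lengths are zero-padded.
#'
#' @param p,q `mrna_pmf` objects (or bare probability vectors).
#' @return Total variation distance in `[0, 1]`.
#' @export
tv_dist <- function(p, q) {
  pv <- if (inherits(p, "mrna_pmf")) p$probs else p
  qv <- if (inherits(q, "mrna_pmf")) q$probs else q
  n <- max(length(pv), length(qv))
  pv <- c(pv, rep(0, n - length(pv)))
  qv <- c(qv, rep(0, n - length(qv)))
  0.5 * sum(abs(pv - qv))
}

#' Sup-norm distance between two pmfs
#'
#' @inheritParams tv_dist
#' @return Maximum absolute pointwise difference.
#' @export
sup_dist <- function(p, q) {
  pv <- if (inherits(p, "mrna_pmf")) p$probs else p
  qv <- if (inherits(q, "mrna_pmf")) q$probs else q
  n <- max(length(pv), length(qv))
  pv <- c(pv, rep(0, n - length(pv)))
  qv <- c(qv, rep(0, n - length(qv)))
  max(abs(pv - qv))
}
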
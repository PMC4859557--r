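#' Looping rate as a function of loop length
#'
#' Empirical law \eqn{k_{loop}(d) = k_{Ron} \exp(-u/d - v \ln d + w d + z)}
#' for the rate at which a pair of DNA elements separated by contour
#' distance `d` forms a loop.  The `-u/d` term suppresses very short loops
#' (stiffness), the `-v ln d` term long ones (dilution), and the weak
#' `+w d` term eventually dominates at very large `d`; the competition
#' creates an interior maximum near `d` of a few tens and a minimum near a
#' couple of thousand.
#'
#' @param d Loop length(s), `> 0` (vectorized).
#' @param params A [loop_params()] object.
#' @return Looping rate(s), strictly positive.
#' @examples
#' looping_rate(c(100, 1500))
#' @export
looping_rate <- function(d, params = loop_params()) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0))
    stop("looping_rate: d must be finite and > 0")
  params$kRon * exp(-params$u / d - params$v * log(d) + params$w * d + params$z)
}

#' Loop-interaction factor for a connection pattern
#'
#' Multiplier applied to the looping rate of one loop once the partner loop
#' has formed: nested loops assist (`4 exp(-0.5 d) + 1`, in `(1, 5]`),
#' side-by-side loops do not interact (`1`), alternating loops interfere
#' (`0.5`).
#'
#' @param pattern `"side_by_side"`, `"nested"` or `"alternating"`.
#' @param d Loop length the nested factor is evaluated at (ignored for the
#'   other two patterns).
#' @return Dimensionless factor.
#' @examples
#' interaction_factor("nested", 2)
#' interaction_factor("alternating", 100)
#' @export
interaction_factor <- function(pattern, d = NULL) {
  pattern <- match.arg(pattern, .patterns)
  switch(pattern,
    side_by_side = 1,
    alternating = 0.5,
    nested = {
      if (is.null(d) || !is.numeric(d) || any(d <= 0))
        stop("interaction_factor: nested pattern needs d > 0")
      4 * exp(-0.5 * d) + 1
    })
}

#' Facilitated-tracking rate increment
#'
#' Under facilitated tracking a loop element slides along the DNA towards
#' its partner, adding \eqn{\Delta = r d} to the looping rate; \eqn{r = 0} recovers
#' direct looping.
#'
#' @param r Tracking ratio, `>= 0`.
#' @param d Loop length, `> 0`.
#' @return The increment \eqn{r d}.
#' @examples
#' tracking_increment(0.15, 1500)
#' @export
tracking_increment <- function(r, d) {
  if (!is.numeric(r) || any(r < 0)) stop("tracking_increment: r must be >= 0")
  if (!is.numeric(d) || any(d <= 0)) stop("tracking_increment: d must be > 0")
  r * d
}

#' Assemble the eight promoter switching rates from a configuration
#'
#' Computes the looping rates from the loop lengths via [looping_rate()],
#' adds the tracking increments \eqn{r d_1} and \eqn{r d_2}, resolves the
#' interaction factors, and derives `lam23 = k1 * lam14` and
#' `lam43 = k2 * lam12`.  With `tracking_in_derived = FALSE` in the config,
#' the derived rates use the natural (untracked) looping rates instead.
#'
#' @param config A [loop_config()].
#' @return An object of class `rate_set`: the eight transition rates plus
#'   the resolved numeric `k1`, `k2`.
#' @examples
#' build_rate_set(loop_config("alternating", d1 = 300, k1 = 0.5, k2 = 0.5))
#' @export
build_rate_set <- function(config) {
  validate_config(config)
  lp <- config$looping_params
  nat14 <- looping_rate(config$d1, lp)
  nat12 <- looping_rate(config$d2, lp)
  lam14 <- nat14 + tracking_increment(config$r, config$d1)
  lam12 <- nat12 + tracking_increment(config$r, config$d2)
  ks <- resolve_k(config)
  base14 <- if (config$tracking_in_derived) lam14 else nat14
  base12 <- if (config$tracking_in_derived) lam12 else nat12
  structure(list(
    lam14 = lam14, lam41 = config$lam41,
    lam12 = lam12, lam21 = config$lam21,
    lam23 = ks[["k1"]] * base14, lam32 = config$lam32,
    lam43 = ks[["k2"]] * base12, lam34 = config$lam34,
    k1 = ks[["k1"]], k2 = ks[["k2"]]), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>\n")
  cat(sprintf("  lam14=%.6g lam41=%.6g | lam12=%.6g lam21=%.6g\n",
              x$lam14, x$lam41, x$lam12, x$lam21))
  cat(sprintf("  lam23=%.6g lam32=%.6g | lam43=%.6g lam34=%.6g  (k1=%.4g k2=%.4g)\n",
              x$lam23, x$lam32, x$lam43, x$lam34, x$k1, x$k2))
  invisible(x)
}

#' Build the promoter generator and transcription matrix
#'
#' Assembles the continuous-time generator `A` on the state order
#' (OFF1, OFF2, ON1, ON2) = (1, 2, 3, 4), with `A[i, j]` the rate from
#' state `j` to state `i`, and the diagonal transcription matrix
#' `Lambda = diag(0, 0, mu1, mu2)`.  The promoter topology is the square
#' cycle OFF1-OFF2-ON2-ON1: direct OFF1-ON2 and OFF2-ON1 transitions are
#' structurally absent.
#'
#' @param rates A `rate_set` from [build_rate_set()], or any list carrying
#'   the eight `lamXY` entries.
#' @param mu1,mu2 Transcription rates in ON1 and ON2.
#' @return An object of class `generator_pair`: list with 4x4 matrices `A`
#'   and `Lambda`.
#' @examples
#' gp <- build_generator(build_rate_set(loop_config("nested", d1 = 300)), 10, 10)
#' colSums(gp$A)  # all zero
#' @export
build_generator <- function(rates, mu1, mu2) {
  need <- c("lam14", "lam41", "lam12", "lam21", "lam23", "lam32", "lam43", "lam34")
  v <- unlist(rates[need])
  if (length(v) != 8 || any(!is.finite(v)) || any(v < 0))
    stop("build_generator: rates must contain the eight nonnegative lamXY entries")
  if (any(!is.finite(c(mu1, mu2))) || mu1 < 0 || mu2 < 0)
    stop("build_generator: mu1, mu2 must be >= 0")
  r <- as.list(v)
  A <- matrix(0, 4, 4, dimnames = list(
    c("OFF1", "OFF2", "ON1", "ON2"), c("OFF1", "OFF2", "ON1", "ON2")))
  A[1, ] <- c(-(r$lam14 + r$lam12), r$lam21, r$lam41, 0)
  A[2, ] <- c(r$lam12, -(r$lam21 + r$lam23), 0, r$lam32)
  A[3, ] <- c(r$lam14, 0, -(r$lam41 + r$lam43), r$lam34)
  A[4, ] <- c(0, r$lam23, r$lam43, -(r$lam32 + r$lam34))
  structure(list(A = A, Lambda = diag(c(0, 0, mu1, mu2))),
            class = "generator_pair")
}

#' Generator pair for a full configuration
#'
#' Convenience wrapper: [build_rate_set()] followed by [build_generator()].
#'
#' @param config A [loop_config()].
#' @return A `generator_pair`.
#' @export
config_generator <- function(config) {
  build_generator(build_rate_set(config), config$mu1, config$mu2)
}
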
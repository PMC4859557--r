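# Exact stochastic simulation of the four-state promoter plus mRNA
# birth-death, used as the independent stochastic oracle.

#' Simulation plan
#'
#' @param t_end Duration of each cell's trajectory.
#' @param burn_in Initial window discarded from stationary averages;
#'   `0 <= burn_in < t_end`.
#' @param n_cells Number of independent replicate cells.
#' @param seed Base seed; cell `i` runs under seed `seed + i - 1`.
#' @return Class `sim_plan`.
#' @export
sim_plan <- function(t_end, burn_in = 0, n_cells = 1L, seed = 1L) {
  if (t_end <= 0 || burn_in < 0 || burn_in >= t_end)
    stop("need 0 <= burn_in < t_end")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(list(t_end = t_end, burn_in = burn_in,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "sim_plan")
}

rates8_of <- function(rates) {
  need <- c("lam14", "lam12", "lam21", "lam23", "lam32", "lam43", "lam34", "lam41")
  v <- unlist(rates[need])
  if (length(v) != 8 || any(!is.finite(v)) || any(v < 0))
    stop("rates must contain the eight nonnegative lamXY entries")
  v
}

config_hash_of <- function(rates8, mu1, mu2, delta) {
  paste0("rates=", paste(signif(rates8, 10), collapse = ","),
         ";mu=", mu1, ",", mu2, ";delta=", delta)
}

#' Gillespie simulation of the two-loop promoter model
#'
#' Direct-method stochastic simulation: propensities are the eight
#' state-dependent switching rates, transcription `mu1`/`mu2` in the two ON
#' states and degradation `delta * m`.  Trajectories are statistically
#' exact samples of the chemical master equation; identical seeds give
#' identical event lists.
#'
#' @param rates A `rate_set` (or list with the eight `lamXY` rates).
#' @param mu1,mu2 Transcription rates in ON1/ON2.
#' @param delta Degradation rate.
#' @param plan A [sim_plan()].
#' @param init_state Initial promoter state (1 = OFF1, ..., 4 = ON2).
#' @param init_count Initial mRNA copy number.
#' @param record Keep full event lists (times, states, counts); turn off
#'   for large ensembles where only time-averaged summaries are needed.
#' @param probe_times Optional times at which the instantaneous copy number
#'   is sampled (for ensemble dynamics).
#' @return A list of class `ssa_ensemble`: per-cell trajectories (class
#'   `ssa_trajectory`, each with `times`, `states`, `counts`, `seed`,
#'   `config_hash`, time-weighted summaries) plus the plan.
#' @examples
#' rs <- build_rate_set(loop_config("alternating", d1 = 300, k1 = 0.5, k2 = 0.5))
#' sim <- ssa_simulate(rs, 10, 10, 1, sim_plan(20, 5, n_cells = 2, seed = 7))
#' sim$cells[[1]]$counts[1:5]
#' @export
ssa_simulate <- function(rates, mu1, mu2, delta = 1, plan,
                         init_state = 1L, init_count = 0L,
                         record = TRUE, probe_times = numeric()) {
  stopifnot(inherits(plan, "sim_plan"))
  r8 <- rates8_of(rates)
  if (delta <= 0) stop("delta must be > 0")
  hash <- config_hash_of(r8, mu1, mu2, delta)
  cells <- vector("list", plan$n_cells)
  for (i in seq_len(plan$n_cells)) {
    set.seed(plan$seed + i - 1L)
    res <- .ssa_run_cpp(r8, mu1, mu2, delta, plan$t_end, plan$burn_in,
                        as.integer(init_state), as.integer(init_count),
                        record, as.numeric(probe_times))
    res$seed <- plan$seed + i - 1L
    res$config_hash <- hash
    class(res) <- "ssa_trajectory"
    cells[[i]] <- res
  }
  structure(list(cells = cells, plan = plan, mu1 = mu1, mu2 = mu2,
                 delta = delta, config_hash = hash), class = "ssa_ensemble")
}

#' Time-weighted stationary histogram from simulated trajectories
#'
#' Pools the post-burn-in, time-weighted copy-number occupancy across cells
#' into an empirical pmf; per-bin standard errors come from across-cell
#' variation of the per-cell occupancy fractions.
#'
#' @param sim An `ssa_ensemble` from [ssa_simulate()].
#' @return An `mrna_pmf` with `method_tag = "empirical"`; attributes `"se"`
#'   (per-bin standard errors), `"mean"`, `"mean_se"`, `"eta"`, `"eta_se"`
#'   (jackknife over cells).
#' @export
stationary_histogram <- function(sim) {
  stopifnot(inherits(sim, "ssa_ensemble"))
  cells <- sim$cells
  ncell <- length(cells)
  lens <- vapply(cells, function(c) length(c$hist), 1L)
  L <- max(lens)
  H <- matrix(0, ncell, L)
  for (i in seq_len(ncell)) H[i, seq_len(lens[i])] <- cells[[i]]$hist
  t_obs <- vapply(cells, function(c) c$t_obs, 1)
  if (any(t_obs <= 0)) stop("empty post-burn-in window")
  probs <- colSums(H) / sum(t_obs)
  frac <- H / t_obs  # per-cell occupancy fractions
  se <- if (ncell > 1) apply(frac, 2, stats::sd) / sqrt(ncell) else rep(NA_real_, L)
  # pooled mean/noise with jackknife standard errors over cells
  S1 <- vapply(cells, function(c) c$sum_m, 1)
  S2 <- vapply(cells, function(c) c$sum_m2, 1)
  Ttot <- sum(t_obs)
  mean_hat <- sum(S1) / Ttot
  m2_hat <- sum(S2) / Ttot
  eta_hat <- (m2_hat - mean_hat^2) / mean_hat^2
  if (ncell > 1) {
    mean_i <- (sum(S1) - S1) / (Ttot - t_obs)
    m2_i <- (sum(S2) - S2) / (Ttot - t_obs)
    eta_i <- (m2_i - mean_i^2) / mean_i^2
    jk <- function(theta_i, theta) sqrt((ncell - 1) / ncell *
                                          sum((theta_i - mean(theta_i))^2))
    mean_se <- jk(mean_i, mean_hat)
    eta_se <- jk(eta_i, eta_hat)
  } else mean_se <- eta_se <- NA_real_
  pmf <- new_pmf(probs, "empirical")
  attr(pmf, "se") <- se
  attr(pmf, "mean") <- mean_hat
  attr(pmf, "mean_se") <- mean_se
  attr(pmf, "eta") <- eta_hat
  attr(pmf, "eta_se") <- eta_se
  pmf
}

#' Empirical binomial moments of a pmf
#'
#' \eqn{B_k = \sum_m \binom{m}{k} P(m)} applied to (empirical or exact)
#' frequencies.
#'
#' @param pmf An `mrna_pmf` or bare probability vector.
#' @param K Highest order.
#' @return Vector `B_0..B_K`.
#' @examples
#' empirical_binomial_moments(c(0, 0, 1), K = 2)  # point mass at 2: (1, 2, 1)
#' @export
empirical_binomial_moments <- function(pmf, K) {
  pv <- if (inherits(pmf, "mrna_pmf")) pmf$probs else pmf
  m <- seq_along(pv) - 1
  vapply(0:K, function(k) sum(choose(m, k) * pv), 1.0)
}
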
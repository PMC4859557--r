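# Plain-text writers with provenance headers.

header_lines <- function(kind, config = NULL, seed = NULL, extra = NULL) {
  h <- c(paste0("# loopnoise ", kind),
         paste0("# date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  if (!is.null(config)) {
    ks <- resolve_k(config)
    h <- c(h, sprintf(
      "# config: pattern=%s d1=%g d2=%g r=%g k1=%.8g k2=%.8g lam21=%g lam32=%g lam34=%g lam41=%g mu1=%g mu2=%g delta=%g tracking_in_derived=%s",
      config$pattern, config$d1, config$d2, config$r, ks[["k1"]], ks[["k2"]],
      config$lam21, config$lam32, config$lam34, config$lam41,
      config$mu1, config$mu2, config$delta, config$tracking_in_derived))
  }
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  c(h, extra)
}

write_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distribution, moment sequence, trajectory or sweep to disk
#'
#' Tab-separated plain text with `#`-prefixed header lines recording the
#' configuration and seed.
#'
#' @param pmf,moments,traj,df The object to write.
#' @param path Output file path.
#' @param config Optional [loop_config()] echoed into the header.
#' @param seed Optional seed echoed into the header.
#' @return The path, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path, config = NULL, seed = NULL) {
  stopifnot(inherits(pmf, "mrna_pmf"))
  df <- data.frame(m = 0:pmf$M, probability = pmf$probs)
  se <- attr(pmf, "se")
  if (!is.null(se)) df$se <- se
  write_with_header(df, path,
                    header_lines(paste0("pmf (", pmf$method_tag, ")"),
                                 config, seed))
}

#' @rdname write_pmf_tsv
#' @export
write_moments_tsv <- function(moments, path, config = NULL, seed = NULL) {
  stopifnot(inherits(moments, "moment_sequence"))
  df <- data.frame(k = 0:moments$K, B = unname(moments$totals))
  ps <- moments$per_state
  colnames(ps) <- paste0("b_state", seq_len(ncol(ps)))
  df <- cbind(df, ps)
  write_with_header(df, path,
                    header_lines(sprintf("binomial moments (delta=%g)",
                                         moments$delta), config, seed))
}

#' @rdname write_pmf_tsv
#' @export
write_trajectory_tsv <- function(traj, path, config = NULL) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  if (is.null(traj$times))
    stop("trajectory was simulated with record = FALSE; no event list")
  df <- data.frame(time = traj$times, state = traj$states,
                   count = traj$counts)
  write_with_header(df, path,
                    header_lines("SSA trajectory", config, traj$seed,
                                 paste0("# config_hash: ", traj$config_hash)))
}

#' @rdname write_pmf_tsv
#' @export
write_sweep_tsv <- function(df, path, config = NULL, seed = NULL) {
  write_with_header(df, path, header_lines("sweep table", config, seed))
}
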
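#' Empirical looping-rate fit constants
#'
#' Constants of the empirical looping-rate law
#' \eqn{k_{loop}(d) = k_{Ron} \exp(-u/d - v \ln d + w d + z)}, obtained
#' elsewhere by fitting measured looping rates against inter-operator
#' distance.  The defaults are used throughout unless overridden.
#'
#' @param u,v,w,z Fit constants (defaults 140.6, 2.52, 0.0014, 19.9).
#' @param kRon Overall rate scale (default 1).
#' @return An object of class `loop_params`.
#' @examples
#' looping_rate(1500, loop_params())
#' @export
loop_params <- function(u = 140.6, v = 2.52, w = 0.0014, z = 19.9, kRon = 1) {
  vals <- c(u = u, v = v, w = w, z = z, kRon = kRon)
  if (!all(is.finite(vals))) stop("loop_params: all constants must be finite")
  if (kRon <= 0) stop("loop_params: kRon must be > 0")
  structure(as.list(vals), class = "loop_params")
}

.patterns <- c("side_by_side", "nested", "alternating")

#' Full parameterization of a two-loop promoter model
#'
#' Bundles the geometry (loop lengths `d1`, `d2`), the connection pattern,
#' the communication form (tracking ratio `r`), the loop-interaction factors
#' `k1`/`k2`, the four unlooping rates, the transcription and degradation
#' rates, and the looping-rate fit constants.
#'
#' `k1` and `k2` may be plain positive numbers, the string `"preset"`
#' (resolved as [interaction_factor()] of the configured pattern at the
#' designated distance `k1_dist`/`k2_dist`), or `"nested:d1"` / `"nested:d2"`
#' (the nested-form factor evaluated at that distance regardless of pattern,
#' as some figure-style parameter bundles prescribe).
#'
#' @param pattern Connection pattern: `"side_by_side"`, `"nested"` or
#'   `"alternating"`.
#' @param d1 Enhancer-promoter ("blue") loop length along the DNA,
#'   dimensionless as in the looping-rate fit.
#' @param d2 Insulator-pair ("green") loop length.
#' @param r Tracking ratio in `[0, 1]`; \eqn{r = 0} is direct looping.
#' @param k1 Interaction factor on blue looping given the green loop
#'   (number or spec string, see Details).
#' @param k2 Interaction factor on green looping given the blue loop.
#' @param k1_dist,k2_dist Which distance (`"d1"` or `"d2"`) a `"preset"`
#'   factor is evaluated at.
#' @param lam21,lam32,lam34,lam41 Unlooping (reverse) rates; default 0.3.
#' @param mu1,mu2 Transcription rates in the two active states; default 10.
#' @param delta mRNA degradation rate; default 1 (time unit).
#' @param looping_params A [loop_params()] object.
#' @param tracking_in_derived Logical; if `TRUE` (default) the derived rates
#'   `lam23 = k1 * lam14` and `lam43 = k2 * lam12` are built from the
#'   tracking-augmented looping rates, if `FALSE` from the natural
#'   (untracked) ones.  The alternative reading exists because the source
#'   description of which rates the tracking increment modifies is
#'   ambiguous; [validation_report()] reports both.
#' @return An object of class `loop_config`.
#' @examples
#' cfg <- loop_config("nested", d1 = 300)
#' build_rate_set(cfg)
#' @export
loop_config <- function(pattern = "side_by_side", d1, d2 = 1500, r = 0,
                        k1 = "preset", k2 = "preset",
                        k1_dist = "d1", k2_dist = "d2",
                        lam21 = 0.3, lam32 = 0.3, lam34 = 0.3, lam41 = 0.3,
                        mu1 = 10, mu2 = 10, delta = 1,
                        looping_params = loop_params(),
                        tracking_in_derived = TRUE) {
  pattern <- match.arg(pattern, .patterns)
  cfg <- structure(list(
    pattern = pattern, d1 = d1, d2 = d2, r = r,
    k1 = k1, k2 = k2, k1_dist = k1_dist, k2_dist = k2_dist,
    lam21 = lam21, lam32 = lam32, lam34 = lam34, lam41 = lam41,
    mu1 = mu1, mu2 = mu2, delta = delta,
    looping_params = looping_params,
    tracking_in_derived = isTRUE(tracking_in_derived)), class = "loop_config")
  validate_config(cfg)
  cfg
}

#' Validate a loop_config
#'
#' Checks all invariants of a model configuration and stops with a message
#' listing every offending field.
#'
#' @param cfg A `loop_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  bad <- character()
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$d1) || cfg$d1 <= 0) bad <- c(bad, "d1 (must be > 0)")
  if (!num1(cfg$d2) || cfg$d2 <= 0) bad <- c(bad, "d2 (must be > 0)")
  if (!num1(cfg$r) || cfg$r < 0 || cfg$r > 1) bad <- c(bad, "r (must be in [0, 1])")
  for (nm in c("lam21", "lam32", "lam34", "lam41", "mu1", "mu2"))
    if (!num1(cfg[[nm]]) || cfg[[nm]] < 0) bad <- c(bad, paste0(nm, " (must be >= 0)"))
  if (!num1(cfg$delta) || cfg$delta <= 0) bad <- c(bad, "delta (must be > 0)")
  for (nm in c("k1", "k2")) {
    k <- cfg[[nm]]
    okstr <- is.character(k) && length(k) == 1 &&
      k %in% c("preset", "nested:d1", "nested:d2")
    if (!(okstr || (num1(k) && k >= 0))) bad <- c(bad, paste0(nm, " (number >= 0 or spec string)"))
  }
  for (nm in c("k1_dist", "k2_dist"))
    if (!cfg[[nm]] %in% c("d1", "d2")) bad <- c(bad, paste0(nm, " (must be 'd1' or 'd2')"))
  if (!inherits(cfg$looping_params, "loop_params")) bad <- c(bad, "looping_params")
  if (length(bad))
    stop("invalid loop_config: ", paste(bad, collapse = "; "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.loop_config <- function(x, ...) {
  cat("<loop_config>", x$pattern,
      sprintf("d1=%g d2=%g r=%g", x$d1, x$d2, x$r), "\n")
  ks <- resolve_k(x)
  cat(sprintf("  k1=%s (%.6g)  k2=%s (%.6g)\n",
              format(x$k1), ks[1], format(x$k2), ks[2]))
  cat(sprintf("  unlooping: lam21=%g lam32=%g lam34=%g lam41=%g\n",
              x$lam21, x$lam32, x$lam34, x$lam41))
  cat(sprintf("  mu1=%g mu2=%g delta=%g  tracking_in_derived=%s\n",
              x$mu1, x$mu2, x$delta, x$tracking_in_derived))
  invisible(x)
}

# numeric (k1, k2) for a config
resolve_k <- function(cfg) {
  one <- function(k, dist_field) {
    d <- cfg[[dist_field]]
    if (is.numeric(k)) return(k)
    if (k == "preset") return(interaction_factor(cfg$pattern, d))
    if (k == "nested:d1") return(interaction_factor("nested", cfg$d1))
    if (k == "nested:d2") return(interaction_factor("nested", cfg$d2))
    stop("unrecognized interaction-factor spec: ", k)
  }
  c(k1 = one(cfg$k1, cfg$k1_dist), k2 = one(cfg$k2, cfg$k2_dist))
}

#' Named figure-style parameter bundles
#'
#' Returns ready-made configurations matching the parameter bundles used in
#' the loop-length and tracking studies: `"fig3"` (blue-length scan,
#' `d2 = 1500`, \eqn{r = 0}, `k2 = 0.5`, `k1` pattern-resolved at `d1`),
#' `"fig4ab"` (alternating, `k1 = 0.5`, `k2` nested-form of `d2`,
#' \eqn{r = 0.1}), `"fig4cd"` (alternating, `k1 = k2 = 0.5`), `"fig5ab"`
#' (nested, `k1 = k2` nested-form of `d2`, \eqn{r = 0.1}), `"fig5cd"` (nested,
#' `k1 = k2` nested-form of `d1`), `"fig6alt"` (alternating,
#' `k1 = k2 = 0.5`, \eqn{r = 0.15}) and `"fig6nested"` (nested, `k1 = k2`
#' nested-form of `d2`, \eqn{r = 0.15}).
#'
#' @param name Bundle name.
#' @param pattern Optional pattern override (used by `"fig3"` which is run
#'   once per pattern).
#' @param d1,d2 Optional geometry overrides.
#' @param r Optional tracking-ratio override.
#' @return A [loop_config()].
#' @examples
#' fig_preset("fig6alt", d2 = 1500)
#' @export
fig_preset <- function(name = c("fig3", "fig4ab", "fig4cd", "fig5ab",
                                "fig5cd", "fig6alt", "fig6nested"),
                       pattern = NULL, d1 = NULL, d2 = NULL, r = NULL) {
  name <- match.arg(name)
  args <- switch(name,
    fig3 = list(pattern = pattern %||% "side_by_side", d1 = d1 %||% 300,
                d2 = d2 %||% 1500, r = r %||% 0,
                k1 = "preset", k1_dist = "d1", k2 = 0.5),
    fig4ab = list(pattern = "alternating", d1 = d1 %||% 1500,
                  d2 = d2 %||% 1500, r = r %||% 0.1,
                  k1 = 0.5, k2 = "nested:d2"),
    fig4cd = list(pattern = "alternating", d1 = d1 %||% 1500,
                  d2 = d2 %||% 1500, r = r %||% 0.1, k1 = 0.5, k2 = 0.5),
    fig5ab = list(pattern = "nested", d1 = d1 %||% 1500, d2 = d2 %||% 1500,
                  r = r %||% 0.1, k1 = "nested:d2", k2 = "nested:d2"),
    fig5cd = list(pattern = "nested", d1 = d1 %||% 1500, d2 = d2 %||% 1500,
                  r = r %||% 0.1, k1 = "nested:d1", k2 = "nested:d1"),
    fig6alt = list(pattern = "alternating", d1 = d1 %||% 1500,
                   d2 = d2 %||% 1500, r = r %||% 0.15, k1 = 0.5, k2 = 0.5),
    fig6nested = list(pattern = "nested", d1 = d1 %||% 1500,
                      d2 = d2 %||% 1500, r = r %||% 0.15,
                      k1 = "nested:d2", k2 = "nested:d2"))
  do.call(loop_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model configuration from a JSON file
#'
#' Keys mirror the [loop_config()] argument names; unspecified keys take the
#' blue-length-scan defaults (`lam21 = lam32 = lam34 = lam41 = 0.3`,
#' `mu1 = mu2 = 10`, `delta = 1`, \eqn{r = 0}, `d2 = 1500`).
#'
#' @param path Path to a JSON file.
#' @return A [loop_config()].
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(loop_config))
  extra <- setdiff(names(raw), c(known, "looping_params"))
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (!is.null(raw$looping_params))
    raw$looping_params <- do.call(loop_params, as.list(raw$looping_params))
  if (is.null(raw$d1)) stop("config must provide d1")
  do.call(loop_config, raw)
}
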
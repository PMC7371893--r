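#' Model parameters for the instance-based learning model
#'
#' Bundles the four fitted scalars of the declarative-memory model --
#' latency factor `F`, latency exponent `f`, base-level decay `d` and
#' activation noise scale `s` -- together with the mismatch penalty weight
#' `P`, an optional retrieval threshold `tau`, and the fixed per-item
#' non-retrieval overhead (encoding + response time) in seconds.
#'
#' Admissible ranges follow the model's normal ranges: `F` and `f` in
#' \[0, 1\], `d` and `s` in \[0, 10\].  The decay default of 0.5 is the
#' ACT-R architecture default; fitted values may lie anywhere in \[0, 10\].
#'
#' @param F Latency factor, seconds; scales retrieval time. In \[0, 1\].
#' @param f Latency exponent (unitless); steepness of the latency law. In \[0, 1\].
#' @param d Base-level decay (unitless). In \[0, 10\].
#' @param s Logistic activation-noise scale (unitless). In \[0, 10\]; `s = 0`
#'   disables noise.
#' @param P Mismatch penalty weight per probe slot (unitless, `>= 0`).
#' @param tau Optional retrieval threshold in activation units; retrieval
#'   fails when no instance reaches it. `NULL` (the default) disables
#'   retrieval failure.
#' @param t_nonretrieval Fixed per-item overhead in seconds added to every
#'   item's retrieval latency.
#'
#' @return An object of class `ibl_params`: a named list of the validated
#'   parameters.
#' @examples
#' model_params(f = 0.005, d = 4, s = 2)
#' @export
model_params <- function(F = 1, f = 0.003, d = 0.5, s = 0, P = 1,
                         tau = NULL, t_nonretrieval = 0) {
  chk_range <- function(x, nm, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop(sprintf("`%s` must be a single number in [%g, %g]", nm, lo, hi),
           call. = FALSE)
    }
    as.numeric(x)
  }
  p <- list(
    F = chk_range(F, "F", 0, 1),
    f = chk_range(f, "f", 0, 1),
    d = chk_range(d, "d", 0, 10),
    s = chk_range(s, "s", 0, 10),
    P = chk_range(P, "P", 0, Inf),
    tau = if (is.null(tau)) NULL else chk_range(tau, "tau", -Inf, Inf),
    t_nonretrieval = chk_range(t_nonretrieval, "t_nonretrieval", 0, Inf)
  )
  structure(p, class = "ibl_params")
}

#' @export
print.ibl_params <- function(x, ...) {
  cat("<ibl_params>\n")
  cat(sprintf("  F = %g  f = %g  d = %g  s = %g\n", x$F, x$f, x$d, x$s))
  cat(sprintf("  P = %g  tau = %s  t_nonretrieval = %g s\n",
              x$P, if (is.null(x$tau)) "unset" else format(x$tau),
              x$t_nonretrieval))
  invisible(x)
}

#' Published group-level parameter sets
#'
#' The fitted parameter rows for the control and DMD (Dp140 negative)
#' groups: `F = 1` for both; control `f = 0.003`, `d = 5`, `s = 2`; DMD
#' `f = 0.005`, `d = 4`, `s = 2`.
#'
#' @param group `"control"` or `"dmd"`.
#' @param ... Overrides passed on to [model_params()] (e.g. `P`,
#'   `t_nonretrieval`).
#' @return An `ibl_params` object.
#' @examples
#' group_params("control")
#' @export
group_params <- function(group = c("control", "dmd"), ...) {
  group <- match.arg(group)
  if (group == "control") {
    model_params(F = 1, f = 0.003, d = 5, s = 2, ...)
  } else {
    model_params(F = 1, f = 0.005, d = 4, s = 2, ...)
  }
}
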
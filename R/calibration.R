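#' Probe calibration for dual-excitation roGFP
#'
#' A calibration maps the oxidized fraction of the probe pool to expected
#' emissions under 405 nm and 488 nm excitation. Oxidation-dependent
#' disulfide formation raises 405-excited emission and lowers 488-excited
#' emission, so the 405/488 emission ratio increases monotonically with
#' oxidation.
#'
#' @param a_red_405,a_ox_405 emission coefficients (arbitrary units, > 0) of
#'   the fully reduced / fully oxidized probe under 405 nm excitation.
#' @param a_red_488,a_ox_488 same under 488 nm excitation.
#' @param f_baseline resting oxidized fraction in untreated cells, in
#'   \code{[0, 1]}. The default \code{NULL} solves \code{ratio(f) = 0.5}
#'   by root-finding, the control-cell convention of the assay.
#' @return An object of class \code{probe_calibration}.
#'
#' @details The default coefficients give a fully-oxidized ratio of about
#'   2.2 (about 4.4-fold over the 0.5 control ratio), inside the 3--5 fold
#'   dynamic-range envelope the assay exhibits between mock-treated and
#'   strongly pro-apoptotic conditions.
#' @examples
#' cal <- probe_calibration()
#' probe_ratio(cal$f_baseline, cal) # 0.5
#' @export
probe_calibration <- function(a_red_405 = 1.0, a_ox_405 = 3.5,
                              a_red_488 = 4.0, a_ox_488 = 1.6,
                              f_baseline = NULL) {
  stopifnot(a_red_405 > 0, a_ox_405 > 0, a_red_488 > 0, a_ox_488 > 0)
  if (!(a_ox_405 > a_red_405))
    stop("invalid calibration: need a_ox_405 > a_red_405 (oxidation must raise 405-excited emission)")
  if (!(a_ox_488 < a_red_488))
    stop("invalid calibration: need a_ox_488 < a_red_488 (oxidation must lower 488-excited emission)")
  cal <- structure(list(a_red_405 = a_red_405, a_ox_405 = a_ox_405,
                        a_red_488 = a_red_488, a_ox_488 = a_ox_488,
                        f_baseline = NA_real_),
                   class = "probe_calibration")
  if (is.null(f_baseline)) {
    r0 <- probe_ratio(0, cal); r1 <- probe_ratio(1, cal)
    if (r0 >= 0.5 || r1 <= 0.5)
      stop("calibration cannot reach the 0.5 control ratio within [0, 1]")
    f_baseline <- stats::uniroot(function(f) probe_ratio(f, cal) - 0.5,
                                 c(0, 1), tol = 1e-12)$root
  }
  stopifnot(f_baseline >= 0, f_baseline <= 1)
  cal$f_baseline <- f_baseline
  cal
}

#' Expected emissions of the probe at a given oxidized fraction
#'
#' Linear two-state blend of the fully reduced and fully oxidized probe
#' spectra: \code{em405 = (1-f) a_red_405 + f a_ox_405} and analogously for
#' 488 nm excitation.
#'
#' @param f oxidized fraction(s) in \code{[0, 1]}.
#' @param cal a \code{\link{probe_calibration}}.
#' @return A list with numeric components \code{em405} and \code{em488}.
#' @export
probe_response <- function(f, cal) {
  stopifnot(inherits(cal, "probe_calibration"))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("oxidized fraction f must lie in [0, 1]")
  list(em405 = (1 - f) * cal$a_red_405 + f * cal$a_ox_405,
       em488 = (1 - f) * cal$a_red_488 + f * cal$a_ox_488)
}

#' 405/488 emission ratio at a given oxidized fraction
#'
#' @inheritParams probe_response
#' @return Numeric ratio(s), strictly increasing in \code{f}.
#' @export
probe_ratio <- function(f, cal) {
  em <- probe_response(f, cal)
  em$em405 / em$em488
}

#' Oxidized fraction that produces a given 405/488 ratio
#'
#' Closed-form inverse of \code{\link{probe_ratio}}; used by the synthetic
#' generators to render kinetic trajectories specified on the ratio scale.
#'
#' @param r ratio value(s) within \code{[probe_ratio(0, cal), probe_ratio(1, cal)]}.
#' @param cal a \code{\link{probe_calibration}}.
#' @return Oxidized fraction(s) in \code{[0, 1]}.
#' @export
oxidized_fraction_for_ratio <- function(r, cal) {
  stopifnot(inherits(cal, "probe_calibration"))
  lo <- probe_ratio(0, cal); hi <- probe_ratio(1, cal)
  if (any(r < lo - 1e-12) || any(r > hi + 1e-12))
    stop(sprintf("ratio outside the calibration's dynamic range [%.4g, %.4g]", lo, hi))
  f <- (r * cal$a_red_488 - cal$a_red_405) /
    ((cal$a_ox_405 - cal$a_red_405) + r * (cal$a_red_488 - cal$a_ox_488))
  pmin(1, pmax(0, f))
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat("roGFP probe calibration\n")
  cat(sprintf("  405 nm: reduced %.3g, oxidized %.3g\n", x$a_red_405, x$a_ox_405))
  cat(sprintf("  488 nm: reduced %.3g, oxidized %.3g\n", x$a_red_488, x$a_ox_488))
  cat(sprintf("  baseline oxidized fraction %.4f (ratio %.3f)\n",
              x$f_baseline, probe_ratio(x$f_baseline, x)))
  cat(sprintf("  dynamic range: ratio %.3f (reduced) to %.3f (oxidized)\n",
              probe_ratio(0, x), probe_ratio(1, x)))
  invisible(x)
}
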
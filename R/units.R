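## Internal unit system: SI (Pa, m^3, s).  Clinical I/O uses mmHg, mL, ms.

#' Unit conversion constants
#'
#' The simulator works internally in SI units (Pa, m^3, s) because the
#' material constants of the passive laws are given in Pa.  Clinical
#' quantities (pressures in mmHg, volumes in mL, times in ms) are converted
#' at the I/O boundary with these constants.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{mmHg}{Pascals per mmHg (133.322...).}
#'   \item{mL}{Cubic metres per millilitre (1e-6).}
#'   \item{ms}{Seconds per millisecond (1e-3).}
#' }
#' @export
lv_units <- list(
  mmHg = 133.322387415,
  mL   = 1e-6,
  ms   = 1e-3
)

#' Convert pressure between Pa and mmHg
#'
#' @param x numeric vector of pressures.
#' @param to either "mmHg" (from Pa) or "Pa" (from mmHg).
#' @return converted numeric vector.
#' @export
convert_pressure <- function(x, to = c("mmHg", "Pa")) {
  to <- match.arg(to)
  if (to == "mmHg") x / lv_units$mmHg else x * lv_units$mmHg
}

#' Convert volume between m^3 and mL
#'
#' @param x numeric vector of volumes.
#' @param to either "mL" (from m^3) or "m3" (from mL).
#' @return converted numeric vector.
#' @export
convert_volume <- function(x, to = c("mL", "m3")) {
  to <- match.arg(to)
  if (to == "mL") x / lv_units$mL else x * lv_units$mL
}
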
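#' Stable-isotope delta notation
#'
#' Per-mil deviation of a sample's heavy/light isotope ratio from a
#' standard: \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000}.
#' For carbon the conventional standard is Pee Dee Belemnite (VPDB), for
#' nitrogen atmospheric air; the standard's ratio is a parameter here, so
#' no reference values are hardcoded.
#'
#' @param ratio_sample,ratio_standard Positive isotope ratios (heavy over
#'   light); vectorized.
#' @return Delta value(s) in per mil.
#' @examples
#' delta_value(0.0112372, 0.0112372)   # the standard itself: 0
#' delta_value(1.01 * 0.0112372, 0.0112372) # +10 per mil
#' @export
delta_value <- function(ratio_sample, ratio_standard) {
  if (any(!is.finite(ratio_sample)) || any(!is.finite(ratio_standard)) ||
      any(ratio_sample <= 0) || any(ratio_standard <= 0)) {
    abort("isotope ratios must be positive and finite")
  }
  (ratio_sample / ratio_standard - 1) * 1000
}
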
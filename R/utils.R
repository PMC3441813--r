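`%||%` <- function(x, y) if (is.null(x)) y else x

stop_rhmap <- function(msg, class = "rhmap_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rhmap_error", "error", "condition")))
}

warn_rhmap <- function(msg, class = "rhmap_warning") {
  warning(warningCondition(msg, class = c(class, "rhmap_warning", "warning", "condition")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

#' Convert a breakage fraction to a centiray distance
#'
#' The RH map distance between two markers with breakage fraction
#' `theta` is `-100 * log(1 - theta)` centirays, capped so the result stays
#' finite as `theta` approaches 1.
#'
#' @param theta breakage fraction(s) in `[0, 1]`.
#' @param max_distance cap in cR applied when `theta` is close to 1.
#' @return numeric vector of distances in cR.
#' @examples
#' theta_to_cr(1 - exp(-1))  # 100 cR
#' @export
theta_to_cr <- function(theta, max_distance = 300) {
  stopifnot(is_prob(theta), max_distance > 0)
  pmin(-100 * log1p(-pmin(theta, 1 - 1e-6)), max_distance)
}
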
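#' Caliper tumor volume
#'
#' Converts a bidirectional caliper measurement into a tumor volume using the
#' standard ellipsoid approximation \eqn{V = (L \times W^2)/2}, with the
#' smaller of the two caliper readings treated as the width regardless of the
#' order in which the dimensions were recorded. This normalization makes the
#' computation symmetric in its arguments, so inconsistently recorded
#' length/width pairs yield identical volumes.
#'
#' @param length_mm,width_mm Caliper readings in mm. Vectorized; both must be
#'   strictly positive (use `NA` for unmeasured dead animals).
#' @return Numeric vector of tumor volumes in mm^3.
#' @examples
#' compute_volume(10, 10)  # 500
#' compute_volume(20, 10)  # 1000
#' compute_volume(10, 20)  # 1000 (order immaterial)
#' @export
compute_volume <- function(length_mm, width_mm) {
  if (length(length_mm) != length(width_mm)) {
    stop("`length_mm` and `width_mm` must have the same length", call. = FALSE)
  }
  bad <- which(!is.na(length_mm) & !is.na(width_mm) &
                 (length_mm <= 0 | width_mm <= 0))
  if (length(bad) > 0) {
    stop("invalid measurement: non-positive caliper dimension at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  l <- pmax(length_mm, width_mm)
  w <- pmin(length_mm, width_mm)
  (l * w^2) / 2
}
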
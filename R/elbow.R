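#' Elbow selection on a non-increasing curve
#'
#' Picks the "elbow" of a scree-like curve (explained variances, k-means
#' inertias) as the point with maximal perpendicular distance to the chord
#' joining the first and last points. Ties break toward the smaller index.
#' An exactly linear (collinear) curve has no elbow: index 1 is returned
#' with the `ambiguous` attribute set.
#'
#' @param values numeric vector, length >= 3, non-increasing.
#' @return integer index (1-based) with attribute `ambiguous` (logical).
#' @examples
#' choose_elbow(c(10, 9, 1, 0.9, 0.8))   # 3
#' @export
choose_elbow <- function(values) {
  n <- length(values)
  if (n < 3L) abort("elbow selection needs at least 3 values")
  if (any(diff(values) > 1e-9 * max(abs(values), 1))) {
    warn("elbow curve is not non-increasing")
  }
  x <- seq_len(n)
  x1 <- 1; y1 <- values[1]; x2 <- n; y2 <- values[n]
  d <- abs((y2 - y1) * x - (x2 - x1) * values + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  scale <- max(abs(values), 1)
  if (max(d) <= 1e-9 * scale) {
    return(structure(1L, ambiguous = TRUE))
  }
  structure(which.max(d), ambiguous = FALSE)
}
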
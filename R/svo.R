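#' SVO Slider primary item endpoints
#'
#' Endpoint allocations (self, other) of the six primary items of the
#' SVO Slider Measure instrument; each item offers nine evenly spaced
#' allocations along the segment between its two endpoints.  Shipped as
#' instrument constants.
#'
#' @return data.frame with one row per item: `item`, `self_start`,
#'   `other_start`, `self_end`, `other_end`.
#' @export
svo_slider_items <- function() {
  data.frame(
    item = 1:6,
    self_start = c(85, 85, 50, 50, 100, 100),
    other_start = c(85, 15, 100, 100, 50, 50),
    self_end = c(85, 100, 85, 100, 50, 85),
    other_end = c(15, 50, 85, 50, 100, 85)
  )
}

#' SVO angle from slider allocations
#'
#' The social value orientation angle, in degrees, of six (self, other)
#' allocation pairs:
#' \deqn{\theta = \arctan\frac{\bar{A}_o - 50}{\bar{A}_s - 50},}
#' where \eqn{\bar{A}_s} and \eqn{\bar{A}_o} are the mean allocations to
#' self and other.  Higher angles reflect a more prosocial orientation.
#' When the mean self allocation equals the 50-point origin the angle is
#' +/- 90 degrees by the sign of the other-allocation deviation (flagged
#' with a warning).
#'
#' @param self,other numeric vectors of the six allocations to self and
#'   to the other.
#' @return Angle in degrees.
#' @export
svo_angle <- function(self, other) {
  if (length(self) != length(other) || length(self) == 0L) {
    stop("svo_angle: 'self' and 'other' must be equal-length, non-empty",
         call. = FALSE)
  }
  ds <- mean(self) - 50
  do <- mean(other) - 50
  if (abs(ds) < .Machine$double.eps) {
    if (abs(do) < .Machine$double.eps) return(0)
    warning("svo_angle: mean self allocation at the 50-point origin; ",
            "angle set to +/-90 by sign convention", call. = FALSE)
    return(90 * sign(do))
  }
  atan2(do, ds) * 180 / pi
}

#' Trait-group assignment from SVO angles
#'
#' Classifies each subject as proself (angle strictly below
#' `mean - k * sd`), prosocial (strictly above `mean + k * sd`) or
#' intermediate (everything else, including angles exactly at a cutoff).
#'
#' @param angles numeric vector of SVO angles in degrees (>= 3 subjects).
#' @param k SD multiplier for the cutoffs (default 1).
#' @return list with `group` (character vector), `cutoffs` (named lower /
#'   upper), `mean`, `sd`.
#' @export
classify_svo <- function(angles, k = 1) {
  if (length(angles) < 3L) stop("classify_svo: need >= 3 subjects",
                                call. = FALSE)
  m <- mean(angles)
  s <- stats::sd(angles)
  if (s == 0) {
    warning("classify_svo: zero SD; everyone classified intermediate",
            call. = FALSE)
  }
  lo <- m - k * s
  hi <- m + k * s
  group <- ifelse(angles < lo, "proself",
                  ifelse(angles > hi, "prosocial", "intermediate"))
  list(group = group, cutoffs = c(lower = lo, upper = hi),
       mean = m, sd = s)
}
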
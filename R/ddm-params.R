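#' Drift diffusion model parameters for one condition
#'
#' Bundles the four free parameters of the two-boundary Wiener diffusion
#' model used throughout the package, plus the fixed noise scale.  The
#' accumulator starts at `a * (1 - z)` and drifts with rate `v` toward the
#' upper boundary `a` (defection); absorption at the lower boundary 0 is a
#' cooperation decision.  `z` therefore measures the prosocial
#' (cooperation-ward) starting-point bias: larger `z` means a start closer
#' to the cooperation boundary and a lower defection probability.
#'
#' @param v drift rate toward the defection boundary (evidence/s).
#' @param a boundary separation (evidence units, > 0).
#' @param z starting-point fraction in (0, 1); prosocial bias.
#' @param t_er non-decision time in seconds (>= 0), added to every
#'   first-passage time.
#' @param s diffusion noise scale (evidence/sqrt(s)).  The conventional
#'   value 1 is the default; the alternative 0.1 convention is a pure
#'   rescaling of `v` and `a`.
#'
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' p <- ddm_params(v = 1, a = 1.5, z = 0.4)
#' choice_probability(p)
#' @export
ddm_params <- function(v, a, z, t_er = 0, s = 1) {
  for (nm in c("v", "a", "z", "t_er", "s")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("ddm_params: '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (a <= 0) stop("ddm_params: boundary separation 'a' must be > 0",
                   call. = FALSE)
  if (z <= 0 || z >= 1) stop("ddm_params: bias 'z' must lie in (0, 1)",
                             call. = FALSE)
  if (t_er < 0) stop("ddm_params: non-decision time 't_er' must be >= 0",
                     call. = FALSE)
  if (s <= 0) stop("ddm_params: noise scale 's' must be > 0", call. = FALSE)
  structure(list(v = v, a = a, z = z, t_er = t_er, s = s),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM parameters: v = %.4g, a = %.4g, z = %.4g, t_er = %.4g s (s = %g)\n",
    x$v, x$a, x$z, x$t_er, x$s))
  cat(sprintf("  start = a*(1-z) = %.4g; P(defect) = %.4f\n",
              x$a * (1 - x$z), choice_probability(x)))
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(ddm_params(v = x$v, a = x$a, z = x$z,
                      t_er = if (is.null(x$t_er)) 0 else x$t_er,
                      s = if (is.null(x$s)) 1 else x$s))
  }
  stop("cannot interpret object as ddm_params", call. = FALSE)
}
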
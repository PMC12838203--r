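#' Closed-form defection probability
#'
#' Probability that the accumulator is absorbed at the upper (defection)
#' boundary, for a constant-drift Wiener process with noise scale `s`
#' started at `a * (1 - z)`:
#' \deqn{P(\mathrm{defect}) = \frac{1 - e^{-2 v a (1-z)/s^2}}
#'                                 {1 - e^{-2 v a / s^2}},}
#' with the driftless limit \eqn{1 - z}.  Increasing the prosocial bias
#' `z` strictly decreases the defection probability.
#'
#' @param params a [ddm_params()] object.
#' @return Probability of a defection decision, in (0, 1).
#' @export
choice_probability <- function(params) {
  params <- as_ddm_params(params)
  cpp_choice_prob(params$v, params$a, params$z, params$s)
}

#' First-passage-time density at one boundary
#'
#' Defective density of the decision time at the named boundary (the two
#' boundary densities jointly integrate to 1).  Evaluated with the
#' standard small-time/large-time series pair; for each `t` the expansion
#' needing fewer terms at the target truncation error (`err`, default
#' 1e-7 on the scaled-density scale) is used.  The density is over
#' *decision* time; `t` does not include the non-decision time.
#'
#' @param params a [ddm_params()] object.
#' @param t vector of decision times in seconds, all > 0.
#' @param boundary `"defect"` (upper) or `"cooperate"` (lower).
#' @param err series truncation error target.
#' @return Vector of density values (>= 0).
#' @export
fpt_density <- function(params, t, boundary = c("defect", "cooperate"),
                        err = 1e-7) {
  params <- as_ddm_params(params)
  boundary <- match.arg(boundary)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop("fpt_density: 't' must be finite and > 0", call. = FALSE)
  }
  cpp_fpt_density(t, params$v, params$a, params$z, params$s,
                  boundary == "defect", err)
}

#' First-passage-time distribution function at one boundary
#'
#' Defective CDF \eqn{P(T \le t, \mathrm{boundary})} of the decision time,
#' computed from the analytically integrated large-time series (an
#' exponential tail sum), clamped into \eqn{[0, P(\mathrm{boundary})]}.
#'
#' @inheritParams fpt_density
#' @return Vector of defective CDF values.
#' @export
fpt_cdf <- function(params, t, boundary = c("defect", "cooperate")) {
  params <- as_ddm_params(params)
  boundary <- match.arg(boundary)
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("fpt_cdf: 't' must be finite", call. = FALSE)
  }
  cpp_fpt_cdf(t, params$v, params$a, params$z, params$s,
              boundary == "defect")
}

#' Boundary-conditional RT quantiles
#'
#' Quantiles of the response-time distribution conditional on the named
#' response, shifted by the non-decision time `t_er`.  Inverted by
#' bisection on the conditional CDF.
#'
#' @inheritParams fpt_density
#' @param probs strictly increasing probabilities in (0, 1); the
#'   conventional quantile-probability summary uses
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @return Vector of RT quantiles in seconds (strictly increasing).
#' @export
rt_quantiles <- function(params, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         boundary = c("defect", "cooperate")) {
  params <- as_ddm_params(params)
  boundary <- match.arg(boundary)
  if (length(probs) == 0L) stop("rt_quantiles: 'probs' is empty", call. = FALSE)
  if (any(probs <= 0) || any(probs >= 1) || any(diff(probs) <= 0)) {
    stop("rt_quantiles: 'probs' must be strictly increasing in (0, 1)",
         call. = FALSE)
  }
  params$t_er + cpp_fpt_quantile(probs, params$v, params$a, params$z,
                                 params$s, boundary == "defect")
}

#' Simulate diffusion trials
#'
#' Euler-Maruyama simulation of the accumulator: Gaussian increments with
#' mean `v * dt` and standard deviation `s * sqrt(dt)` from the start
#' point `a * (1 - z)` until a boundary is crossed.  Reported RT is the
#' crossing time plus `t_er`.  Deterministic for a fixed `seed`.
#'
#' @param params a [ddm_params()] object.
#' @param n number of trials (>= 1).
#' @param dt Euler step in seconds (default 1e-4).
#' @param seed integer seed for the simulator's own RNG stream (does not
#'   touch R's global RNG).
#' @return A data.frame with columns `choice` (factor,
#'   defect/cooperate) and `rt` (seconds).
#' @export
simulate_trials <- function(params, n, dt = 1e-4, seed) {
  params <- as_ddm_params(params)
  if (!is.numeric(n) || n < 1) stop("simulate_trials: n must be >= 1",
                                    call. = FALSE)
  if (dt <= 0) stop("simulate_trials: dt must be > 0", call. = FALSE)
  if (missing(seed)) stop("simulate_trials: an explicit 'seed' is required",
                          call. = FALSE)
  res <- cpp_simulate(as.integer(n), params$v, params$a, params$z,
                      params$s, params$t_er, dt, as.double(seed))
  data.frame(
    choice = factor(ifelse(res$choice == 1L, "defect", "cooperate"),
                    levels = c("defect", "cooperate")),
    rt = res$rt
  )
}
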
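#' Differential evolution settings
#'
#' Control object for the global optimizer used by [fit_subject()].
#' Defaults: rand/1/bin strategy, population `pop_factor * dim`,
#' differential weight `F = 0.8`, crossover `CR = 0.9`, at most
#' `maxiter` generations, stopping early once the population objective
#' spread falls below `tol` (relative).
#'
#' @param pop_factor population size per free parameter.
#' @param F differential weight in (0, 2].
#' @param CR crossover probability in (0, 1].
#' @param maxiter maximum number of generations.
#' @param tol relative convergence tolerance on the population objective
#'   spread.
#' @return A list of class `de_control`.
#' @export
de_control <- function(pop_factor = 15, F = 0.8, CR = 0.9,
                       maxiter = 300, tol = 1e-8) {
  stopifnot(pop_factor >= 4, F > 0, F <= 2, CR > 0, CR <= 1,
            maxiter >= 1, tol >= 0)
  structure(list(pop_factor = pop_factor, F = F, CR = CR,
                 maxiter = maxiter, tol = tol),
            class = "de_control")
}

# Elitist rand/1/bin differential evolution over box bounds.
# `fn` is a batch objective: matrix (rows = candidates) -> numeric vector.
# Uses R's RNG under an isolated seed; the caller's RNG state is restored.
de_optimize <- function(fn, lower, upper, control = de_control(), seed) {
  dim <- length(lower)
  stopifnot(length(upper) == dim, all(upper > lower))
  if (missing(seed)) stop("de_optimize: an explicit 'seed' is required",
                          call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  np <- max(4L, as.integer(round(control$pop_factor * dim)))
  pop <- matrix(runif(np * dim, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
  fit <- fn(pop)
  iter <- 0L
  converged <- FALSE
  while (iter < control$maxiter) {
    iter <- iter + 1L
    # rand/1 mutation
    r <- t(vapply(seq_len(np), function(i) sample(seq_len(np)[-i], 3L),
                  integer(3L)))
    mutant <- pop[r[, 1L], , drop = FALSE] +
      control$F * (pop[r[, 2L], , drop = FALSE] - pop[r[, 3L], , drop = FALSE])
    # binomial crossover with a guaranteed mutant coordinate
    cross <- matrix(runif(np * dim) < control$CR, nrow = np)
    jrand <- cbind(seq_len(np), sample.int(dim, np, replace = TRUE))
    cross[jrand] <- TRUE
    trial <- pop
    trial[cross] <- mutant[cross]
    # reflect out-of-bounds coordinates back into the box
    for (j in seq_len(dim)) {
      bad_lo <- trial[, j] < lower[j]
      bad_hi <- trial[, j] > upper[j]
      trial[bad_lo, j] <- pmin(upper[j], 2 * lower[j] - trial[bad_lo, j])
      trial[bad_hi, j] <- pmax(lower[j], 2 * upper[j] - trial[bad_hi, j])
      trial[, j] <- pmin(pmax(trial[, j], lower[j]), upper[j])
    }
    f_trial <- fn(trial)
    better <- f_trial <= fit          # elitist: best member never worsens
    pop[better, ] <- trial[better, , drop = FALSE]
    fit[better] <- f_trial[better]
    spread <- max(fit) - min(fit)
    if (is.finite(spread) && spread <= control$tol * max(1, abs(min(fit)))) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], iterations = iter,
       converged = converged, seed = as.integer(seed))
}
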
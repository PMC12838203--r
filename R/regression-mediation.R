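#' Linear and quadratic SVO regressions
#'
#' Fits `outcome ~ SVO` and `outcome ~ SVO + SVO^2` by OLS, with SVO
#' standardized (z-scored) *before* squaring, so the quadratic
#' coefficient measures curvature over the standardized trait scale.  A
#' negative quadratic coefficient is an inverted-U relationship.
#'
#' @param svo SVO angles (degrees; standardized internally).
#' @param outcome per-subject outcome (bias variation, rate variation,
#'   EOD, ...).
#' @return list of class `quad_fit` with components `linear` and
#'   `quadratic`, each holding `coef`, `ci` (95%), `adj_r_squared`, `F`,
#'   `p_model`; plus `n` and `degenerate`.
#' @export
quad_regression <- function(svo, outcome) {
  n <- length(svo)
  if (n < 10L) stop("quad_regression: need >= 10 subjects", call. = FALSE)
  if (stats::sd(outcome) == 0) {
    warning("quad_regression: constant outcome; degenerate fit",
            call. = FALSE)
  }
  s <- as.numeric(scale(svo))
  dat <- data.frame(y = outcome, s = s, s2 = s^2)
  pack <- function(fit) {
    sm <- summary(fit)
    fstat <- sm$fstatistic
    list(coef = stats::coef(fit), ci = stats::confint(fit),
         coef_p = sm$coefficients[, 4],
         adj_r_squared = sm$adj.r.squared, r_squared = sm$r.squared,
         F = unname(fstat[1]),
         p_model = stats::pf(fstat[1], fstat[2], fstat[3],
                             lower.tail = FALSE))
  }
  lin <- stats::lm(y ~ s, data = dat)
  quad <- stats::lm(y ~ s + s2, data = dat)
  structure(list(linear = pack(lin), quadratic = pack(quad), n = n,
                 degenerate = stats::sd(outcome) == 0),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  fmt <- function(m, nm) {
    cat(" ", nm, "model: adj R^2 =", sprintf("%.3f", m$adj_r_squared),
        ", F =", sprintf("%.3f", m$F), "\n")
    for (i in seq_along(m$coef)) {
      cat(sprintf("    %-11s %8.4f  [%.4f, %.4f]\n", names(m$coef)[i],
                  m$coef[i], m$ci[i, 1], m$ci[i, 2]))
    }
  }
  cat("Quadratic SVO regression (n =", x$n, ")\n")
  fmt(x$linear, "linear")
  fmt(x$quadratic, "quadratic")
  invisible(x)
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval.  The bias correction `z0` is
#' the normal quantile of the bootstrap CDF at the point estimate; the
#' acceleration comes from the jackknife skewness.  A degenerate
#' bootstrap distribution (all draws equal, or z0 undefined) falls back
#' to the percentile interval with a warning.
#'
#' @param boot_stats numeric vector of bootstrap replicates (>= 1000 for
#'   production use).
#' @param point the point estimate on the original sample.
#' @param jack_stats jackknife leave-one-out estimates.
#' @param level confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
bca_interval <- function(boot_stats, point, jack_stats, level = 0.95) {
  boot_stats <- boot_stats[is.finite(boot_stats)]
  alpha <- (1 - level) / 2
  if (length(unique(boot_stats)) < 2L) {
    warning("bca_interval: degenerate bootstrap distribution; ",
            "percentile fallback", call. = FALSE)
    return(stats::quantile(boot_stats, c(alpha, 1 - alpha), names = FALSE))
  }
  # tie-aware bootstrap CDF at the point estimate
  prop <- (sum(boot_stats < point) + 0.5 * sum(boot_stats == point)) /
    length(boot_stats)
  if (prop <= 0 || prop >= 1) {
    warning("bca_interval: point estimate outside the bootstrap ",
            "distribution; percentile fallback", call. = FALSE)
    return(stats::quantile(boot_stats, c(alpha, 1 - alpha), names = FALSE))
  }
  z0 <- stats::qnorm(prop)
  jm <- mean(jack_stats)
  num <- sum((jm - jack_stats)^3)
  den <- 6 * sum((jm - jack_stats)^2)^1.5
  acc <- if (den == 0) 0 else num / den
  adj <- function(z_alpha) {
    stats::pnorm(z0 + (z0 + z_alpha) / (1 - acc * (z0 + z_alpha)))
  }
  stats::quantile(boot_stats,
                  c(adj(stats::qnorm(alpha)), adj(stats::qnorm(1 - alpha))),
                  names = FALSE)
}

# product-of-coefficients decomposition of the squared-SVO effect
mediation_effects <- function(s, s2, m, y) {
  med_fit <- stats::lm(m ~ s + s2)
  out_fit <- stats::lm(y ~ s + s2 + m)
  tot_fit <- stats::lm(y ~ s + s2)
  a2 <- stats::coef(med_fit)[["s2"]]
  b <- stats::coef(out_fit)[["m"]]
  c(direct = stats::coef(out_fit)[["s2"]],
    indirect = a2 * b,
    total = stats::coef(tot_fit)[["s2"]])
}

#' Mediation of the quadratic SVO effect through bias variation
#'
#' Tests whether the quadratic (inverted-U) relation between SVO and
#' defection-rate variation is carried by the prosocial-bias variation.
#' The treatment is the squared standardized SVO with the linear term as
#' covariate in both models; effects are the OLS product-of-coefficients
#' decomposition (mediator model `dz ~ SVO + SVO^2`, outcome model
#' `dp ~ SVO + SVO^2 + dz`), for which direct + indirect = total holds
#' exactly.  Confidence intervals are BCa over nonparametric subject
#' resampling with jackknife acceleration; the bootstrap is
#' deterministic for a fixed `seed`.
#'
#' @param svo SVO angles (standardized internally).
#' @param mediator per-subject bias variation (e.g. `z_D - z_U`).
#' @param outcome per-subject defection-rate variation.
#' @param n_boot bootstrap replicates (>= 1000; default 5000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list of class `mediation_result`: `effects` (direct,
#'   indirect, total), `ci` (3 x 2 matrix), `proportion_mediated`,
#'   `proportion_unstable` (TRUE when the total effect is near zero),
#'   `n_boot`, `seed`.
#' @export
mediate_quadratic <- function(svo, mediator, outcome, n_boot = 5000L,
                              seed, level = 0.95) {
  if (missing(seed)) stop("mediate_quadratic: 'seed' is required",
                          call. = FALSE)
  if (n_boot < 1000L) stop("mediate_quadratic: n_boot >= 1000 required",
                           call. = FALSE)
  ok <- stats::complete.cases(svo, mediator, outcome)
  svo <- svo[ok]; mediator <- mediator[ok]; outcome <- outcome[ok]
  n <- length(svo)
  s <- as.numeric(scale(svo))
  point <- mediation_effects(s, s^2, mediator, outcome)

  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sb <- as.numeric(scale(svo[idx]))
      mediation_effects(sb, sb^2, mediator[idx], outcome[idx])
    }, numeric(3)))
  })
  jack <- t(vapply(seq_len(n), function(i) {
    sj <- as.numeric(scale(svo[-i]))
    mediation_effects(sj, sj^2, mediator[-i], outcome[-i])
  }, numeric(3)))
  ci <- t(vapply(1:3, function(j) {
    bca_interval(boot[, j], point[j], jack[, j], level)
  }, numeric(2)))
  dimnames(ci) <- list(names(point), c("lower", "upper"))
  unstable <- abs(point[["total"]]) < 1e-8
  if (unstable) {
    warning("mediate_quadratic: total effect ~ 0; proportion mediated ",
            "is unstable", call. = FALSE)
  }
  structure(list(effects = point, ci = ci,
                 proportion_mediated = point[["indirect"]] / point[["total"]],
                 proportion_unstable = unstable,
                 n = n, n_boot = n_boot, seed = as.integer(seed)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation of the quadratic SVO effect (n =", x$n, ",",
      x$n_boot, "bootstrap draws)\n")
  for (nm in names(x$effects)) {
    cat(sprintf("  %-8s %8.4f  BCa 95%% CI [%.4f, %.4f]\n", nm,
                x$effects[[nm]], x$ci[nm, 1], x$ci[nm, 2]))
  }
  cat(sprintf("  proportion mediated: %.1f%%%s\n",
              100 * x$proportion_mediated,
              if (x$proportion_unstable) " [unstable]" else ""))
  invisible(x)
}
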
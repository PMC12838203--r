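#' Per-subject, per-condition defection rates
#'
#' @param trials multi-subject trial table.
#' @return data.frame: `subject_id`, `p_def_U`, `p_def_D`, `p_def_C`.
#'   Subjects missing a condition are dropped with a warning.
#' @export
defection_rates <- function(trials) {
  trials <- normalize_trials(trials)
  if (!"subject_id" %in% names(trials)) trials$subject_id <- "S1"
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$subject_id == id, ]
    if (!all(CONDITIONS %in% sub$condition)) return(NULL)
    rates <- vapply(CONDITIONS, function(cond) {
      sel <- sub$condition == cond
      mean(sub$choice[sel] == "defect")
    }, numeric(1))
    data.frame(subject_id = id, p_def_U = rates[["U"]],
               p_def_D = rates[["D"]], p_def_C = rates[["C"]])
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning("defection_rates: dropping ", sum(dropped),
            " subject(s) missing a condition", call. = FALSE)
  }
  kept <- rows[!dropped]
  if (!length(kept)) {
    return(data.frame(subject_id = character(), p_def_U = numeric(),
                      p_def_D = numeric(), p_def_C = numeric()))
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

#' Effect size of the disjunction effect (EOD)
#'
#' \deqn{EOD = (p_D + p_C)/2 - p_U}: the mean defection rate under the
#' two known conditions minus the rate under uncertainty.  Positive
#' values mean behavior under uncertainty deviates toward cooperation.
#' With `p_u = 0` (the default) the same formula turns per-condition
#' *variations* (`p_D - p_U`, `p_C - p_U`) into the EOD directly.
#'
#' @param p_d,p_c defection rates (or rate variations) under the
#'   defector-known and cooperator-known conditions.
#' @param p_u defection rate under uncertainty (default 0, for inputs
#'   already expressed as variations).
#' @return Numeric vector of EOD values.
#' @export
eod <- function(p_d, p_c, p_u = 0) {
  (p_d + p_c) / 2 - p_u
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA on a subjects x conditions matrix,
#' computed from the explicit sum-of-squares decomposition.  The
#' Greenhouse-Geisser epsilon comes from the eigenvalues of the
#' orthonormally contrasted sample covariance of the condition scores;
#' when active, both degrees of freedom are multiplied by epsilon.
#' Partial eta-squared is `SS_effect / (SS_effect + SS_error)`.  With
#' `gg = "auto"` the correction is applied when a Mauchly sphericity
#' check rejects at 0.05.
#'
#' @param values numeric matrix (or data.frame), subjects in rows,
#'   conditions in columns (complete cases required).
#' @param gg `"auto"`, `"on"`, or `"off"`.
#' @return list of class `rm_anova` with `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`, `gg_epsilon`, `gg_applied`, `mauchly`,
#'   `pairwise` (see [bonferroni_pairwise()]), `degenerate`.
#' @export
rm_anova <- function(values, gg = c("auto", "on", "off")) {
  gg <- match.arg(gg)
  values <- as.matrix(values)
  n <- nrow(values)
  kk <- ncol(values)
  if (n < 3L || kk < 2L) stop("rm_anova: need >= 3 subjects and >= 2 ",
                              "conditions", call. = FALSE)
  if (any(!is.finite(values))) stop("rm_anova: complete cases required",
                                    call. = FALSE)
  gm <- mean(values)
  ss_cond <- n * sum((colMeans(values) - gm)^2)
  ss_subj <- kk * sum((rowMeans(values) - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj

  # GG epsilon and Mauchly check via the orthonormally contrasted covariance
  C <- qr.Q(qr(stats::contr.helmert(kk)))            # k x (k-1), orthonormal
  A <- t(C) %*% stats::cov(values) %*% C
  eig <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  eig <- pmax(eig, 0)
  eps <- if (sum(eig^2) > 0) sum(eig)^2 / ((kk - 1) * sum(eig^2)) else 1
  eps <- min(max(eps, 1 / (kk - 1)), 1)
  mauchly <- list(W = NA_real_, chisq = NA_real_, df = NA_real_,
                  p = NA_real_)
  if (all(eig > 0)) {
    W <- prod(eig) / (mean(eig))^(kk - 1)
    cc <- 1 - (2 * (kk - 1)^2 + (kk - 1) + 2) / (6 * (kk - 1) * (n - 1))
    chisq <- -(n - 1) * cc * log(W)
    dfm <- kk * (kk - 1) / 2 - 1
    mauchly <- list(W = W, chisq = chisq, df = dfm,
                    p = stats::pchisq(chisq, dfm, lower.tail = FALSE))
  }
  gg_applied <- switch(gg, on = TRUE, off = FALSE,
                       auto = is.finite(mauchly$p) && mauchly$p < 0.05)

  degenerate <- ss_err < 1e-12
  df1 <- kk - 1
  df2 <- (n - 1) * (kk - 1)
  if (gg_applied) {
    df1 <- df1 * eps
    df2 <- df2 * eps
  }
  F_stat <- if (ss_cond < 1e-12) 0
            else (ss_cond / (kk - 1)) / (ss_err / ((n - 1) * (kk - 1)))
  p <- if (degenerate && ss_cond >= 1e-12) 0
       else stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  eta <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0
  structure(list(F = F_stat, df1 = df1, df2 = df2, p = p,
                 partial_eta_sq = eta, gg_epsilon = eps,
                 gg_applied = gg_applied, mauchly = mauchly,
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err),
                 pairwise = bonferroni_pairwise(values),
                 degenerate = degenerate),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g, etaP2 = %.3f\n",
    x$df1, x$df2, x$F, x$p, x$partial_eta_sq))
  cat(sprintf("  GG epsilon = %.3f (%s); Mauchly p = %.4g\n", x$gg_epsilon,
              if (x$gg_applied) "applied" else "not applied", x$mauchly$p))
  if (x$degenerate) cat("  [degenerate: zero error variance]\n")
  print(x$pairwise)
  invisible(x)
}

#' Bonferroni-adjusted pairwise paired t tests
#'
#' All pairwise paired t tests over the columns of `values`; p values are
#' multiplied by the number of comparisons and capped at 1.  A
#' zero-variance difference yields an infinite (or zero) t and is flagged.
#'
#' @param values subjects x conditions matrix.
#' @return data.frame: `pair`, `t`, `df`, `p`, `p_bonferroni`,
#'   `zero_variance`.
#' @export
bonferroni_pairwise <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  cols <- colnames(values)
  if (is.null(cols)) cols <- paste0("c", seq_len(ncol(values)))
  idx <- utils::combn(ncol(values), 2)
  m <- ncol(idx)
  rows <- lapply(seq_len(m), function(j) {
    d <- values[, idx[1, j]] - values[, idx[2, j]]
    sd_d <- stats::sd(d)
    zero_var <- sd_d == 0
    t_stat <- if (zero_var) {
      if (mean(d) == 0) 0 else Inf * sign(mean(d))
    } else mean(d) / (sd_d / sqrt(n))
    p <- if (zero_var) as.numeric(mean(d) != 0) * 0 + (mean(d) == 0)
         else 2 * stats::pt(-abs(t_stat), n - 1)
    data.frame(pair = paste(cols[idx[1, j]], cols[idx[2, j]], sep = "-"),
               t = t_stat, df = n - 1, p = p,
               p_bonferroni = min(1, m * p), zero_variance = zero_var)
  })
  do.call(rbind, rows)
}

#' One-sample t statistic from summary statistics
#'
#' `t = M / (SD / sqrt(n))` with `df = n - 1`; the form used for paired
#' difference scores reported as mean and SD.
#'
#' @param M mean of the difference scores.
#' @param SD their standard deviation (> 0; `SD = 0` is flagged).
#' @param n sample size (>= 2).
#' @return data.frame: `t`, `df`, `p`, `flagged`.
#' @export
t_from_summary <- function(M, SD, n) {
  stopifnot(n >= 2)
  flagged <- SD <= 0
  t_stat <- ifelse(flagged, ifelse(M == 0, 0, Inf * sign(M)),
                   M / (SD / sqrt(n)))
  data.frame(t = t_stat, df = n - 1,
             p = ifelse(is.finite(t_stat),
                        2 * stats::pt(-abs(t_stat), n - 1), 0),
             flagged = flagged)
}

#' Logit transform for bounded bias values
#'
#' `log(z / (1 - z))`, with values at 0 or 1 clamped to `eps` /
#' `1 - eps` (with a warning).  Used to re-run the bias ANOVA on an
#' unbounded scale.
#'
#' @param z values in (0, 1).
#' @param eps clamping margin.
#' @return Transformed values.
#' @export
logit_transform <- function(z, eps = 1e-6) {
  if (any(z < 0 | z > 1)) stop("logit_transform: z outside [0, 1]",
                               call. = FALSE)
  if (any(z <= 0 | z >= 1)) {
    warning("logit_transform: values at 0/1 clamped at eps", call. = FALSE)
    z <- pmin(pmax(z, eps), 1 - eps)
  }
  log(z / (1 - z))
}

#' Build the per-subject effect table
#'
#' Joins defection rates, the EOD, the DDM parameter variations
#' (D - U and C - U differences of `a`, `v`, `z`), the SVO angle and the
#' trait group into the table all downstream analyses consume.
#'
#' @param trials multi-subject trial table.
#' @param fits fits table from [fit_experiment()] (long: subject x
#'   condition rows).
#' @param svo data.frame with `subject_id` and `svo_angle` (degrees).
#' @param k SD multiplier for trait grouping.
#' @return data.frame: `subject_id`, `svo_angle`, `group`,
#'   `p_def_U/D/C`, `eod`, `da_d`, `da_c`, `dv_d`, `dv_c`, `dz_d`,
#'   `dz_c`, plus the per-condition fitted `z_U/z_D/z_C`, `v_U/v_D/v_C`,
#'   `a_U/a_D/a_C`.
#' @export
effect_table <- function(trials, fits, svo, k = 1) {
  rates <- defection_rates(trials)
  wide <- stats::reshape(
    fits[, c("subject_id", "condition", "v", "a", "z")],
    direction = "wide", idvar = "subject_id", timevar = "condition",
    sep = "_")
  names(wide) <- sub("^(v|a|z)_(U|D|C)$", "\\1_\\2", names(wide))
  tab <- merge(rates, wide, by = "subject_id")
  tab <- merge(tab, svo[, c("subject_id", "svo_angle")], by = "subject_id")
  tab$group <- classify_svo(tab$svo_angle, k = k)$group
  tab$eod <- eod(tab$p_def_D, tab$p_def_C, tab$p_def_U)
  tab$da_d <- tab$a_D - tab$a_U
  tab$da_c <- tab$a_C - tab$a_U
  tab$dv_d <- tab$v_D - tab$v_U
  tab$dv_c <- tab$v_C - tab$v_U
  tab$dz_d <- tab$z_D - tab$z_U
  tab$dz_c <- tab$z_C - tab$z_U
  tab
}
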
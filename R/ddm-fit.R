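CONDITIONS <- c("U", "D", "C")
QP_PROBS <- c(0.1, 0.3, 0.5, 0.7, 0.9)

# Accept either analysis-style (rt) or file-style (rt_s) trial tables.
normalize_trials <- function(trials) {
  trials <- as.data.frame(trials)
  if (!"rt" %in% names(trials) && "rt_s" %in% names(trials)) {
    trials$rt <- trials$rt_s
  }
  need <- c("condition", "choice", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trials$condition <- as.character(trials$condition)
  trials$choice <- as.character(trials$choice)
  bad <- !trials$condition %in% CONDITIONS
  if (any(bad)) stop("unknown condition code(s): ",
                     paste(unique(trials$condition[bad]), collapse = ", "),
                     call. = FALSE)
  bad <- !trials$choice %in% c("defect", "cooperate")
  if (any(bad)) stop("unknown choice code(s): ",
                     paste(unique(trials$choice[bad]), collapse = ", "),
                     call. = FALSE)
  trials
}

#' Quantile-probability summary of a trial table
#'
#' Summarizes one subject's trials per (condition, response) by the
#' response proportion, the RT quantiles at `probs` (type-7 order-statistic
#' interpolation), and the trial count.  Cells with fewer than
#' `min_count` trials are flagged `degraded`: their quantiles are the best
#' available order statistics and are not trustworthy summaries.
#'
#' @param trials data.frame with columns `condition` (U/D/C), `choice`
#'   (defect/cooperate) and `rt` (or `rt_s`) in seconds.
#' @param probs quantile probabilities (strictly increasing, in (0,1)).
#' @param min_count minimum trials for a non-degraded quantile cell.
#' @return A data.frame of class `qp_summary` (one row per condition x
#'   response) with a `rts` attribute holding the sorted per-cell RTs.
#' @export
compute_qp <- function(trials, probs = QP_PROBS, min_count = 5L) {
  trials <- normalize_trials(trials)
  if (nrow(trials) == 0L) stop("compute_qp: empty trial table", call. = FALSE)
  conds <- intersect(CONDITIONS, unique(trials$condition))
  rows <- list()
  rts <- list()
  for (cond in conds) {
    sub <- trials[trials$condition == cond, ]
    n_cond <- nrow(sub)
    for (resp in c("defect", "cooperate")) {
      x <- sort(sub$rt[sub$choice == resp])
      key <- paste(cond, resp, sep = ".")
      rts[[key]] <- x
      qs <- if (length(x)) stats::quantile(x, probs, type = 7, names = FALSE)
            else rep(NA_real_, length(probs))
      rows[[key]] <- data.frame(
        condition = cond, response = resp,
        proportion = length(x) / n_cond, n = length(x),
        degraded = length(x) < min_count,
        t(stats::setNames(qs, paste0("q", probs * 100)))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rts") <- rts
  attr(out, "probs") <- probs
  class(out) <- c("qp_summary", class(out))
  out
}

#' Quantile-probability chi-square statistic
#'
#' Chi-square distance between an observed quantile-probability summary
#' and the predictions of condition-wise DDM parameters sharing one
#' non-decision time.  For each (condition, response) the observed trial
#' counts are cut at the model-predicted RT quantiles, giving bins with
#' expected masses 0.1, 0.2, 0.2, 0.2, 0.2, 0.1 of the predicted response
#' probability; a response-proportion cell is added per response.  Cells
#' whose response has fewer than `min_count` observed trials contribute
#' the proportion cell only.  Expected counts are floored at 1e-10 (with a
#' warning when an occupied cell has essentially zero expectation).
#'
#' @param observed a [compute_qp()] summary (its attached raw RTs are
#'   used for the bin counts).
#' @param params named list of [ddm_params()] per condition present in
#'   `observed` (e.g. `list(U = ..., D = ..., C = ...)`); their `t_er`
#'   entries must agree (the shared non-decision time).
#' @param min_count see [compute_qp()].
#' @return The chi-square statistic (>= 0).
#' @export
qp_chisq <- function(observed, params, min_count = 5L) {
  if (!inherits(observed, "qp_summary")) {
    stop("qp_chisq: 'observed' must come from compute_qp()", call. = FALSE)
  }
  rts <- attr(observed, "rts")
  probs <- attr(observed, "probs")
  conds <- intersect(CONDITIONS, unique(observed$condition))
  if (!all(conds %in% names(params))) {
    stop("qp_chisq: 'params' must cover conditions ",
         paste(conds, collapse = ", "), call. = FALSE)
  }
  params <- lapply(params, as_ddm_params)
  ters <- vapply(params[conds], function(p) p$t_er, numeric(1))
  if (diff(range(ters)) > 1e-12) {
    stop("qp_chisq: all conditions must share one t_er", call. = FALSE)
  }
  ss <- vapply(params[conds], function(p) p$s, numeric(1))
  if (diff(range(ss)) > 1e-12) {
    stop("qp_chisq: all conditions must share one noise scale s", call. = FALSE)
  }
  par_row <- c(unlist(lapply(params[conds],
                             function(p) c(p$v, p$a, p$z)), use.names = FALSE),
               ters[[1L]])
  def_rts <- lapply(conds, function(cn) rts[[paste0(cn, ".defect")]])
  coop_rts <- lapply(conds, function(cn) rts[[paste0(cn, ".cooperate")]])
  # warn on occupied cells with vanishing expectation
  for (i in seq_along(conds)) {
    p_def <- choice_probability(params[[conds[i]]])
    if (length(def_rts[[i]]) > 0 && p_def < 1e-10 ||
        length(coop_rts[[i]]) > 0 && 1 - p_def < 1e-10) {
      warning("qp_chisq: occupied response cell with ~zero expected count; ",
              "expected floored at 1e-10", call. = FALSE)
    }
  }
  as.numeric(cpp_qp_obj(matrix(par_row, nrow = 1L), def_rts, coop_rts,
                        probs, ss[[1L]], as.integer(min_count)))
}

#' Parameter bounds for subject fitting
#'
#' Box bounds for the 10-dimensional search: per-condition (v, a, z) plus
#' one shared non-decision time.  The `t_er` upper bound defaults to the
#' subject's minimum RT minus `eps` (set at fit time when `NA`).
#'
#' @param v,a,z,t_er length-2 numeric ranges.
#' @param eps safety margin below the minimum RT for the `t_er` upper
#'   bound.
#' @return A list of class `fit_bounds`.
#' @export
fit_bounds <- function(v = c(-5, 5), a = c(0.3, 4), z = c(0.05, 0.95),
                       t_er = c(0.1, NA), eps = 1e-3) {
  structure(list(v = v, a = a, z = z, t_er = t_er, eps = eps),
            class = "fit_bounds")
}

#' Fit the DDM to one subject by quantile-probability chi-square
#'
#' Estimates condition-specific drift `v`, boundary `a` and prosocial bias
#' `z`, together with one non-decision time shared across the three
#' conditions, by minimizing the quantile-probability chi-square of
#' [qp_chisq()] with elitist rand/1/bin differential evolution.  The fit
#' is deterministic for a fixed `seed`.
#'
#' @param trials one subject's trial table (all of U, D, C present).
#' @param probs quantile probabilities of the QP summary.
#' @param bounds a [fit_bounds()] object.
#' @param control a [de_control()] object.
#' @param seed integer seed for the optimizer.
#' @param min_trials minimum trials required per condition.
#' @param min_count minimum per-response trials for quantile cells.
#' @param s fixed diffusion noise scale.
#' @param polish run a deterministic Nelder-Mead refinement from the DE
#'   optimum (recommended: the global search locates the basin, the
#'   simplex finishes the descent).
#' @return An object of class `subject_fit`: per-condition
#'   [ddm_params()], shared `t_er`, objective value and optimizer
#'   metadata.
#' @export
fit_subject <- function(trials, probs = QP_PROBS, bounds = fit_bounds(),
                        control = de_control(), seed, min_trials = 10L,
                        min_count = 5L, s = 1, polish = TRUE) {
  trials <- normalize_trials(trials)
  if (missing(seed)) stop("fit_subject: an explicit 'seed' is required",
                          call. = FALSE)
  counts <- table(factor(trials$condition, levels = CONDITIONS))
  if (any(counts < min_trials)) {
    stop("fit_subject: every condition needs >= ", min_trials, " trials",
         call. = FALSE)
  }
  z_bounds <- bounds$z
  for (cond in CONDITIONS) {
    ch <- trials$choice[trials$condition == cond]
    if (length(unique(ch)) < 2L) {
      warning("fit_subject: condition ", cond,
              " has zero response variability; widening z bounds",
              call. = FALSE)
      z_bounds <- c(min(0.01, z_bounds[1]), max(0.99, z_bounds[2]))
    }
  }
  ter_hi <- bounds$t_er[2]
  if (is.na(ter_hi)) ter_hi <- min(trials$rt) - bounds$eps
  if (ter_hi <= bounds$t_er[1]) ter_hi <- bounds$t_er[1] + bounds$eps

  obs <- compute_qp(trials, probs, min_count)
  rts <- attr(obs, "rts")
  def_rts <- lapply(CONDITIONS, function(cn) rts[[paste0(cn, ".defect")]])
  coop_rts <- lapply(CONDITIONS, function(cn) rts[[paste0(cn, ".cooperate")]])
  fn <- function(par_mat) {
    cpp_qp_obj(par_mat, def_rts, coop_rts, probs, s, as.integer(min_count))
  }
  lower <- c(rep(c(bounds$v[1], bounds$a[1], z_bounds[1]), 3L), bounds$t_er[1])
  upper <- c(rep(c(bounds$v[2], bounds$a[2], z_bounds[2]), 3L), ter_hi)
  opt <- de_optimize(fn, lower, upper, control, seed)
  if (polish) {
    pen_fn <- function(p) {
      if (any(p < lower) || any(p > upper)) return(1e10)
      fn(matrix(p, nrow = 1L))
    }
    nm <- stats::optim(opt$par, pen_fn, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    if (is.finite(nm$value) && nm$value <= opt$value) {
      opt$par <- nm$par
      opt$value <- nm$value
    }
  }

  ter <- opt$par[10L]
  pars <- stats::setNames(lapply(seq_along(CONDITIONS), function(i) {
    ddm_params(v = opt$par[3 * i - 2], a = opt$par[3 * i - 1],
               z = opt$par[3 * i], t_er = ter, s = s)
  }), CONDITIONS)
  structure(list(params = pars, t_er = ter, objective = opt$value,
                 iterations = opt$iterations, converged = opt$converged,
                 seed = opt$seed,
                 n_trials = as.integer(counts)[match(CONDITIONS, names(counts))]),
            class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  cat("Quantile-probability DDM fit (shared t_er =",
      sprintf("%.3f s", x$t_er), ")\n")
  for (cond in names(x$params)) {
    p <- x$params[[cond]]
    cat(sprintf("  %s: v = %6.3f, a = %5.3f, z = %5.3f\n",
                cond, p$v, p$a, p$z))
  }
  cat(sprintf("  objective = %.3f; %d generations; converged: %s\n",
              x$objective, x$iterations, x$converged))
  invisible(x)
}

#' @export
as.data.frame.subject_fit <- function(x, ..., subject_id = NA) {
  do.call(rbind, lapply(names(x$params), function(cond) {
    p <- x$params[[cond]]
    data.frame(subject_id = subject_id, condition = cond,
               v = p$v, a = p$a, z = p$z, t_er = x$t_er,
               objective = x$objective, converged = x$converged)
  }))
}

#' Predicted-vs-empirical quantile diagnostic
#'
#' For every (condition, response) cell of a fitted subject, tabulates the
#' observed RT quantiles against the model-implied quantiles at the same
#' probabilities — the standard graphical fit check.
#'
#' @param fit a [fit_subject()] result.
#' @param trials the subject's trial table used in the fit.
#' @param probs quantile probabilities.
#' @return A data.frame with one row per condition x response x
#'   probability: `condition`, `response`, `n`, `prob`, `observed`,
#'   `predicted`.
#' @export
fit_report <- function(fit, trials, probs = QP_PROBS) {
  stopifnot(inherits(fit, "subject_fit"))
  obs <- compute_qp(trials, probs)
  out <- list()
  for (i in seq_len(nrow(obs))) {
    row <- obs[i, ]
    if (row$n == 0L) next
    pred <- rt_quantiles(fit$params[[row$condition]], probs,
                         boundary = row$response)
    qcols <- paste0("q", probs * 100)
    out[[length(out) + 1L]] <- data.frame(
      condition = row$condition, response = row$response, n = row$n,
      prob = probs, observed = as.numeric(row[1, qcols]), predicted = pred)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit every subject of an experiment
#'
#' Applies [fit_subject()] independently to each subject of a multi-subject
#' trial table (the design's explicit choice: no hierarchical pooling).
#' Per-subject optimizer seeds are derived deterministically from `seed`.
#'
#' @param trials trial table with a `subject_id` column.
#' @param seed master seed.
#' @param ... passed on to [fit_subject()].
#' @return A data.frame in the fits schema: one row per subject x
#'   condition with columns `subject_id`, `condition`, `v`, `a`, `z`,
#'   `t_er`, `objective`, `converged`.
#' @export
fit_experiment <- function(trials, seed, ...) {
  trials <- as.data.frame(trials)
  if (!"subject_id" %in% names(trials)) {
    stop("fit_experiment: trials need a 'subject_id' column", call. = FALSE)
  }
  ids <- unique(trials$subject_id)
  out <- lapply(seq_along(ids), function(i) {
    sub_seed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
    fit <- fit_subject(trials[trials$subject_id == ids[i], ],
                       seed = sub_seed, ...)
    as.data.frame(fit, subject_id = ids[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
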
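# Deterministic sub-seed derivation so that every stage of a generated
# experiment is reproducible from one master seed (kept below 2^31).
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Default prototype Prisoner's Dilemma payoff matrix
#'
#' A reconstruction chosen so that jittered matrices reproduce the
#' published mean payoff gaps (T-R about 19, R-P about 12, P-S about 18
#' points); the original prototype cell values were not published in the
#' main text.
#'
#' @return Named list with integer `T`, `R`, `P`, `S`, satisfying
#'   T > R > P > S.
#' @export
default_payoff_prototype <- function() {
  list(T = 59L, R = 40L, P = 28L, S = 10L)
}

#' Generate jittered Prisoner's Dilemma payoff matrices
#'
#' Adds an independent uniform random integer in `[-jitter, +jitter]` to
#' each cell of the prototype and rejects any draw violating the canonical
#' ordering T > R > P > S, until `n` valid matrices are collected.  The
#' game is symmetric: the column player's payoffs mirror the row player's.
#'
#' @param prototype list/row with `T`, `R`, `P`, `S` (must satisfy the
#'   ordering).
#' @param jitter maximum absolute integer jitter per cell.
#' @param n number of matrices.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `T`, `R`, `P`, `S`.
#' @export
generate_payoff_matrices <- function(prototype = default_payoff_prototype(),
                                     jitter = 10L, n = 150L, seed) {
  if (missing(seed)) stop("generate_payoff_matrices: 'seed' is required",
                          call. = FALSE)
  proto <- unlist(prototype[c("T", "R", "P", "S")])
  if (any(diff(proto) >= 0)) {
    stop("prototype must satisfy T > R > P > S", call. = FALSE)
  }
  with_seed(seed, {
    out <- matrix(NA_integer_, nrow = 0L, ncol = 4L)
    tried <- 0L
    while (nrow(out) < n) {
      batch <- max(64L, 2L * (n - nrow(out)))
      jit <- matrix(sample.int(2L * jitter + 1L, batch * 4L, replace = TRUE) -
                      jitter - 1L, ncol = 4L)
      cand <- sweep(jit, 2L, proto, "+")
      ok <- cand[, 1] > cand[, 2] & cand[, 2] > cand[, 3] & cand[, 3] > cand[, 4]
      tried <- tried + batch
      out <- rbind(out, cand[ok, , drop = FALSE])
      if (tried >= 1000L && nrow(out) / tried < 0.01) {
        stop("payoff acceptance rate below 1%; widen the prototype gaps ",
             "relative to the jitter range", call. = FALSE)
      }
    }
    out <- out[seq_len(n), , drop = FALSE]
    data.frame(id = seq_len(n), T = out[, 1], R = out[, 2],
               P = out[, 3], S = out[, 4])
  })
}

#' Summarize payoff gaps across matrices
#'
#' Mean and SD of the gaps (T-R), (R-P), (P-S) and (T-S).  By
#' construction the (T-S) mean equals the sum of the other three means.
#'
#' @param matrices data.frame with columns `T`, `R`, `P`, `S`.
#' @return data.frame with columns `gap`, `mean`, `sd`.
#' @export
payoff_gap_summary <- function(matrices) {
  if (nrow(matrices) < 2L) stop("need >= 2 matrices", call. = FALSE)
  gaps <- data.frame(`T-R` = matrices$T - matrices$R,
                     `R-P` = matrices$R - matrices$P,
                     `P-S` = matrices$P - matrices$S,
                     `T-S` = matrices$T - matrices$S,
                     check.names = FALSE)
  data.frame(gap = names(gaps),
             mean = vapply(gaps, mean, numeric(1)),
             sd = vapply(gaps, stats::sd, numeric(1)),
             row.names = NULL)
}

#' Default group-level generating parameters
#'
#' Group means and SDs of the condition-dependent DDM parameters used by
#' [generate_population()].  The starting-point shifts encode the
#' heterogeneity the generator is built to emulate: the U-to-D prosocial
#' bias drop is largest for intermediate-SVO subjects
#' (mean -0.147 on the z scale, vs -0.060 proself and -0.050 prosocial),
#' the U-to-C shift is near zero except for a positive proself shift,
#' drift is lower under uncertainty (U) than under the known conditions,
#' and the boundary separation does not vary across conditions.  Baseline
#' `z_U` rises with the trait group, giving the positive trait/bias
#' association.
#'
#' @return data.frame, one row per group, with `*_mean` / `*_sd` columns
#'   for `z_U`, `dz_D`, `dz_C`, `v_U`, `dv_D`, `dv_C`, `a`, `t_er`.
#' @export
group_param_defaults <- function() {
  data.frame(
    group = c("proself", "intermediate", "prosocial"),
    z_U_mean = c(0.42, 0.50, 0.58),   z_U_sd = c(0.08, 0.08, 0.08),
    dz_D_mean = c(-0.060, -0.147, -0.050), dz_D_sd = c(0.099, 0.080, 0.087),
    dz_C_mean = c(0.097, -0.012, -0.017),  dz_C_sd = c(0.137, 0.089, 0.076),
    v_U_mean = c(0.40, 0.40, 0.40),   v_U_sd = c(0.30, 0.30, 0.30),
    dv_D_mean = c(0.15, 0.15, 0.15),  dv_D_sd = c(0.20, 0.20, 0.20),
    dv_C_mean = c(0.15, 0.15, 0.15),  dv_C_sd = c(0.20, 0.20, 0.20),
    a_mean = c(1.5, 1.5, 1.5),        a_sd = c(0.15, 0.15, 0.15),
    t_er_mean = c(0.35, 0.35, 0.35),  t_er_sd = c(0.05, 0.05, 0.05)
  )
}

#' Generate a cohort of SVO-heterogeneous synthetic subjects
#'
#' Draws SVO angles from Normal(`svo_mean`, `svo_sd`), assigns trait
#' groups by the mean +/- `k` SD rule on the *realized* sample, then draws
#' each subject's condition-specific true DDM parameters around their
#' group's means (see [group_param_defaults()]).  Boundary separation and
#' non-decision time are drawn once per subject and shared across
#' conditions.  Parameters are clamped to a safe interior range
#' (z in [0.05, 0.95], a >= 0.5, t_er >= 0.15).
#'
#' @param n_subjects cohort size (>= 6; the study's size is 72).
#' @param svo_mean,svo_sd SVO angle distribution in degrees (defaults:
#'   mean 20.86, SD 8).
#' @param config group-level parameter table as in
#'   [group_param_defaults()].
#' @param k SD multiplier of the grouping rule.
#' @param seed integer seed.
#' @return data.frame, one row per subject: `subject_id`, `svo_angle`,
#'   `group`, true `v_U/v_D/v_C`, `z_U/z_D/z_C`, `a`, `t_er`.
#' @export
generate_population <- function(n_subjects = 72L, svo_mean = 20.86,
                                svo_sd = 8, config = group_param_defaults(),
                                k = 1, seed) {
  if (missing(seed)) stop("generate_population: 'seed' is required",
                          call. = FALSE)
  if (n_subjects < 6L) stop("n_subjects < 6 makes the M +/- SD grouping ",
                            "degenerate", call. = FALSE)
  with_seed(seed, {
    svo <- stats::rnorm(n_subjects, svo_mean, svo_sd)
    grp <- classify_svo(svo, k = k)$group
    idx <- match(grp, config$group)
    draw <- function(base) {
      stats::rnorm(n_subjects, config[[paste0(base, "_mean")]][idx],
                   config[[paste0(base, "_sd")]][idx])
    }
    z_U <- draw("z_U")
    z_D <- z_U + draw("dz_D")
    z_C <- z_U + draw("dz_C")
    v_U <- draw("v_U")
    v_D <- v_U + draw("dv_D")
    v_C <- v_U + draw("dv_C")
    a <- pmax(draw("a"), 0.5)
    t_er <- pmax(draw("t_er"), 0.15)
    clamp_z <- function(z) pmin(pmax(z, 0.05), 0.95)
    data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
               svo_angle = svo, group = grp,
               v_U = v_U, v_D = v_D, v_C = v_C,
               z_U = clamp_z(z_U), z_D = clamp_z(z_D), z_C = clamp_z(z_C),
               a = a, t_er = t_er)
  })
}

#' Simulate a full Prisoner's Dilemma experiment
#'
#' For each subject, simulates `n_trials_per_condition` diffusion trials
#' per condition from the subject's true condition parameters, assigns
#' payoff matrices (the matrix pool is split at random into three
#' equal-sized condition sets, as in the experimental design), and
#' interleaves the conditions in randomized trial order.
#'
#' @param population a [generate_population()] table.
#' @param matrices a payoff matrix table ([generate_payoff_matrices()]).
#' @param n_trials_per_condition trials per condition (design: 50).
#' @param dt Euler step for the trial simulator (seconds).  The
#'   experiment generator defaults to 1e-3 to keep cohort-scale
#'   simulation cheap; the per-trial discretization bias at this step is
#'   negligible relative to trial noise.
#' @param seed integer seed.
#' @return Trial table: `subject_id`, `trial_index`, `condition`,
#'   `choice`, `rt_s`, `matrix_id`.
#' @export
generate_experiment <- function(population, matrices,
                                n_trials_per_condition = 50L, dt = 1e-3,
                                seed) {
  if (missing(seed)) stop("generate_experiment: 'seed' is required",
                          call. = FALSE)
  n_cond_mat <- nrow(matrices) %/% 3L
  if (n_cond_mat < 1L) stop("need at least 3 payoff matrices", call. = FALSE)
  assign_mat <- with_seed(derive_seed(seed, 0), {
    ids <- sample(matrices$id)
    stats::setNames(split(ids[seq_len(3L * n_cond_mat)],
                          rep(CONDITIONS, each = n_cond_mat)), CONDITIONS)
  })
  out <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    subj <- population[i, ]
    rows <- lapply(seq_along(CONDITIONS), function(ci) {
      cond <- CONDITIONS[ci]
      p <- ddm_params(v = subj[[paste0("v_", cond)]], a = subj$a,
                      z = subj[[paste0("z_", cond)]], t_er = subj$t_er)
      sim <- simulate_trials(p, n_trials_per_condition, dt = dt,
                             seed = derive_seed(seed, 10 * i + ci))
      mat_ids <- with_seed(derive_seed(seed, 10 * i + ci + 5), {
        sample(assign_mat[[cond]], n_trials_per_condition,
               replace = n_trials_per_condition > n_cond_mat)
      })
      data.frame(subject_id = subj$subject_id, condition = cond,
                 choice = as.character(sim$choice), rt_s = sim$rt,
                 matrix_id = mat_ids)
    })
    tab <- do.call(rbind, rows)
    ord <- with_seed(derive_seed(seed, 10 * i + 9), sample(nrow(tab)))
    tab <- tab[ord, ]
    tab$trial_index <- seq_len(nrow(tab))
    out[[i]] <- tab[, c("subject_id", "trial_index", "condition", "choice",
                        "rt_s", "matrix_id")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quality-control subject exclusion
#'
#' Flags subjects with abnormally high response consistency (the modal
#' response's share over all trials strictly above
#' `consistency_threshold`, so a threshold of 1 excludes nobody) or
#' abnormally fast responding (the fraction of RTs at or above
#' `fast_rt_threshold_s` falls strictly below `min_valid_fraction`).
#'
#' @param trials trial table (multi-subject).
#' @param consistency_threshold modal response share triggering
#'   exclusion (in (0, 1]).
#' @param fast_rt_threshold_s RT below which a trial counts as a fast
#'   guess (seconds).
#' @param min_valid_fraction minimum fraction of non-fast trials
#'   required to keep a subject (in (0, 1]).
#' @return list with `kept` (the filtered trial table) and `exclusions`
#'   (data.frame `subject_id`, `rule`, `value`).
#' @export
apply_qc_filters <- function(trials, consistency_threshold = 0.98,
                             fast_rt_threshold_s = 0.2,
                             min_valid_fraction = 0.9) {
  if (consistency_threshold <= 0 || consistency_threshold > 1 ||
      min_valid_fraction <= 0 || min_valid_fraction > 1 ||
      fast_rt_threshold_s < 0) {
    stop("apply_qc_filters: thresholds out of range", call. = FALSE)
  }
  trials <- as.data.frame(trials)
  rt <- if ("rt_s" %in% names(trials)) trials$rt_s else trials$rt
  log <- list()
  for (id in unique(trials$subject_id)) {
    sel <- trials$subject_id == id
    share <- max(table(trials$choice[sel])) / sum(sel)
    valid <- mean(rt[sel] >= fast_rt_threshold_s)
    if (share > consistency_threshold) {
      log[[length(log) + 1L]] <- data.frame(
        subject_id = id, rule = "response_consistency", value = share)
    }
    if (valid < min_valid_fraction) {
      log[[length(log) + 1L]] <- data.frame(
        subject_id = id, rule = "fast_rt", value = 1 - valid)
    }
  }
  exclusions <- if (length(log)) do.call(rbind, log) else
    data.frame(subject_id = character(), rule = character(),
               value = numeric())
  list(kept = trials[!trials$subject_id %in% exclusions$subject_id, ],
       exclusions = exclusions)
}
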
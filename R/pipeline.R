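#' Pipeline configuration
#'
#' All knobs of the end-to-end synthetic pipeline, every stochastic stage
#' with an explicit seed derived from `seed`.  The configuration
#' round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param seed master seed.
#' @param n_subjects cohort size (study design: 72).
#' @param n_trials_per_condition trials per condition (design: 50).
#' @param svo_mean,svo_sd SVO angle distribution (degrees).
#' @param n_matrices,jitter payoff-matrix pool size and cell jitter.
#' @param qc list of QC thresholds (see [apply_qc_filters()]).
#' @param de [de_control()] settings for the fitter.
#' @param bounds [fit_bounds()] for the fitter.
#' @param n_boot mediation bootstrap replicates.
#' @param dt_experiment Euler step for trial simulation (s).
#' @param group_config group-level generating parameters
#'   ([group_param_defaults()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 72L,
                            n_trials_per_condition = 50L,
                            svo_mean = 20.86, svo_sd = 8,
                            n_matrices = 150L, jitter = 10L,
                            qc = list(consistency_threshold = 0.98,
                                      fast_rt_threshold_s = 0.2,
                                      min_valid_fraction = 0.9),
                            de = de_control(),
                            bounds = fit_bounds(),
                            n_boot = 5000L,
                            dt_experiment = 1e-3,
                            group_config = group_param_defaults()) {
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 svo_mean = svo_mean, svo_sd = svo_sd,
                 n_matrices = as.integer(n_matrices),
                 jitter = as.integer(jitter), qc = qc,
                 de = unclass(de), bounds = unclass(bounds),
                 n_boot = as.integer(n_boot), dt_experiment = dt_experiment,
                 group_config = group_config),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  # revalidate through the constructors, stored unclassed as in the original
  cfg$de <- unclass(do.call(de_control, as.list(cfg$de)))
  cfg$bounds <- unclass(do.call(fit_bounds, lapply(cfg$bounds, function(x)
    if (is.list(x)) unlist(x) else x)))
  cfg
}

# ---------------------------------------------------------------------------
# file formats
# ---------------------------------------------------------------------------

check_columns <- function(df, required, path, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(what, " file '", path, "' has unknown column(s) (ignored): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
}

#' Trial table files
#'
#' CSV schema: `subject_id`, `trial_index`, `condition` (U/D/C),
#' `choice` (defect/cooperate), `rt_s` (seconds), `matrix_id`.  Invalid
#' condition or choice codes are fatal, reported with the offending file
#' line numbers (header = line 1).
#'
#' @param path CSV path.
#' @return The validated trial table.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "trial_index", "condition", "choice",
                      "rt_s", "matrix_id"), path, "trials")
  bad <- which(!df$condition %in% CONDITIONS)
  if (length(bad)) {
    stop("trials file '", path, "': invalid condition at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " (allowed: U, D, C)", call. = FALSE)
  }
  bad <- which(!df$choice %in% c("defect", "cooperate"))
  if (length(bad)) {
    stop("trials file '", path, "': invalid choice at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " (allowed: defect, cooperate)", call. = FALSE)
  }
  bad <- which(!is.finite(df$rt_s) | df$rt_s <= 0)
  if (length(bad)) {
    stop("trials file '", path, "': nonpositive RT at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_trials
#' @param trials trial table to write.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, c("subject_id", "trial_index", "condition",
                              "choice", "rt_s", "matrix_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Payoff matrix files
#'
#' Two dialects are accepted: wide (`id`, `T`, `R`, `P`, `S` columns) and
#' long per-cell (`id`, `cell`, `value` with cell in T/R/P/S).  Both
#' parse to the same wide table; every matrix must satisfy T > R > P > S.
#'
#' @param path CSV path.
#' @return data.frame `id`, `T`, `R`, `P`, `S`.
#' @export
read_payoffs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("cell", "value") %in% names(df))) {
    check_columns(df, c("id", "cell", "value"), path, "payoffs")
    bad <- which(!df$cell %in% c("T", "R", "P", "S"))
    if (length(bad)) {
      stop("payoffs file '", path, "': invalid cell label at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
    }
    wide <- stats::reshape(df, direction = "wide", idvar = "id",
                           timevar = "cell")
    names(wide) <- sub("^value\\.", "", names(wide))
    df <- wide[order(wide$id), c("id", "T", "R", "P", "S")]
    rownames(df) <- NULL
  } else {
    check_columns(df, c("id", "T", "R", "P", "S"), path, "payoffs")
  }
  bad <- !(df$T > df$R & df$R > df$P & df$P > df$S)
  if (any(bad)) {
    stop("payoffs file '", path, "': ", sum(bad),
         " matrix(es) violate T > R > P > S", call. = FALSE)
  }
  df
}

#' @rdname read_payoffs
#' @param matrices payoff table to write (wide dialect).
#' @export
write_payoffs <- function(matrices, path) {
  utils::write.csv(matrices[, c("id", "T", "R", "P", "S")], path,
                   row.names = FALSE)
  invisible(path)
}

#' SVO files
#'
#' Accepts either precomputed angles (`subject_id`, `svo_angle_deg`) or
#' raw slider allocations (`subject_id`, `self_1`..`self_6`,
#' `other_1`..`other_6`), in which case angles are computed with
#' [svo_angle()].
#'
#' @param path CSV path.
#' @return data.frame `subject_id`, `svo_angle`.
#' @export
read_svo <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("svo_angle_deg" %in% names(df)) {
    check_columns(df, c("subject_id", "svo_angle_deg"), path, "SVO")
    return(data.frame(subject_id = df$subject_id,
                      svo_angle = df$svo_angle_deg))
  }
  alloc_cols <- c(paste0("self_", 1:6), paste0("other_", 1:6))
  check_columns(df, c("subject_id", alloc_cols), path, "SVO")
  ang <- vapply(seq_len(nrow(df)), function(i) {
    svo_angle(as.numeric(df[i, paste0("self_", 1:6)]),
              as.numeric(df[i, paste0("other_", 1:6)]))
  }, numeric(1))
  data.frame(subject_id = df$subject_id, svo_angle = ang)
}

#' Fitted-parameter files
#'
#' CSV schema: `subject_id`, `condition`, `v`, `a`, `z`, `t_er`,
#' `objective`, `converged` — one row per subject and condition.
#'
#' @param path CSV path.
#' @return The fits table.
#' @export
read_fits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "condition", "v", "a", "z", "t_er",
                      "objective", "converged"), path, "fits")
  df
}

#' @rdname read_fits
#' @param fits fits table to write.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# analysis bundle
# ---------------------------------------------------------------------------

# drop classes / matrices so jsonlite serializes deterministically
plain <- function(x) {
  if (is.matrix(x)) {
    return(stats::setNames(lapply(seq_len(nrow(x)), function(i)
      as.list(x[i, ])), rownames(x)))
  }
  if (is.list(x)) return(lapply(unclass(x), plain))
  x
}

anova_bundle <- function(values, gg = "auto") {
  res <- rm_anova(values, gg = gg)
  list(F = res$F, df1 = res$df1, df2 = res$df2, p = res$p,
       partial_eta_sq = res$partial_eta_sq, gg_epsilon = res$gg_epsilon,
       gg_applied = res$gg_applied, mauchly_p = res$mauchly$p,
       pairwise = res$pairwise)
}

decomposition_bundle <- function(et, suffix) {
  dp <- et$p_def_U * 0 + et[[paste0("p_def_", toupper(suffix))]] - et$p_def_U
  da <- et[[paste0("da_", suffix)]]
  dv <- et[[paste0("dv_", suffix)]]
  dz <- et[[paste0("dz_", suffix)]]
  reg <- variation_regression(dp, da, dv, dz)
  X <- cbind(da = da, dv = dv, dz = dz)
  pm <- pmvd_shares(X, dp)
  lm_ <- lmg_shares(X, dp)
  list(beta = as.list(reg$beta), beta_p = as.list(reg$p),
       r_squared = reg$r_squared, F = reg$F, p_model = reg$p_model,
       pmvd_pct = as.list(100 * pm$shares),
       lmg_pct = as.list(100 * lm_$shares))
}

quad_bundle <- function(svo, outcome) {
  q <- quad_regression(svo, outcome)
  pack <- function(m) list(coef = as.list(m$coef), ci = plain(m$ci),
                           coef_p = as.list(m$coef_p),
                           adj_r_squared = m$adj_r_squared,
                           F = m$F, p_model = m$p_model)
  list(linear = pack(q$linear), quadratic = pack(q$quadratic))
}

#' Full statistical analysis of one experiment
#'
#' Runs the complete analysis stack on an effect table: condition-level
#' rate and parameter ANOVAs (with the logit-bias robustness rerun),
#' the parameter-variation decomposition with PMVD/LMG shares for both
#' D-U and C-U variations, linear/quadratic SVO regressions for the bias
#' variations (both sign conventions for the C-U block), the rate
#' variations and the EOD, and the BCa mediation analyses.
#'
#' @param et an [effect_table()].
#' @param n_boot mediation bootstrap replicates.
#' @param seed seed for the mediation bootstrap.
#' @return Nested list of plain (JSON-serializable) results.
#' @export
analyze_experiment <- function(et, n_boot = 5000L, seed) {
  if (missing(seed)) stop("analyze_experiment: 'seed' is required",
                          call. = FALSE)
  rates <- as.matrix(et[, c("p_def_U", "p_def_D", "p_def_C")])
  zmat <- as.matrix(et[, c("z_U", "z_D", "z_C")])
  group_stats <- function(v) {
    ag <- stats::aggregate(v, list(group = et$group),
                           function(x) c(mean = mean(x), sd = stats::sd(x),
                                         n = length(x)))
    stats::setNames(lapply(seq_len(nrow(ag)), function(i) as.list(ag$x[i, ])),
                    ag$group)
  }
  list(
    rates = list(
      mean_p_def = as.list(colMeans(rates)),
      mean_eod = mean(et$eod),
      eod_by_group = group_stats(et$eod),
      dp_d_by_group = group_stats(et$p_def_D - et$p_def_U),
      dp_c_by_group = group_stats(et$p_def_C - et$p_def_U),
      dz_d_by_group = group_stats(et$dz_d),
      dz_c_by_group = group_stats(et$dz_c)
    ),
    anova = list(
      defection_rates = anova_bundle(rates),
      threshold = anova_bundle(as.matrix(et[, c("a_U", "a_D", "a_C")])),
      drift = anova_bundle(as.matrix(et[, c("v_U", "v_D", "v_C")])),
      bias = anova_bundle(zmat),
      bias_logit = anova_bundle(apply(zmat, 2, logit_transform))
    ),
    decomposition = list(D = decomposition_bundle(et, "d"),
                         C = decomposition_bundle(et, "c")),
    svo_regressions = list(
      dz_d = quad_bundle(et$svo_angle, et$dz_d),
      dz_c = quad_bundle(et$svo_angle, et$dz_c),
      dz_c_reversed = quad_bundle(et$svo_angle, -et$dz_c),
      dp_d = quad_bundle(et$svo_angle, et$p_def_D - et$p_def_U),
      dp_c = quad_bundle(et$svo_angle, et$p_def_C - et$p_def_U),
      eod = quad_bundle(et$svo_angle, et$eod)
    ),
    mediation = list(
      D = plain(mediate_quadratic(et$svo_angle, et$dz_d,
                                  et$p_def_D - et$p_def_U,
                                  n_boot = n_boot,
                                  seed = derive_seed(seed, 41))),
      C = plain(mediate_quadratic(et$svo_angle, et$dz_c,
                                  et$p_def_C - et$p_def_U,
                                  n_boot = n_boot,
                                  seed = derive_seed(seed, 42)))
    )
  )
}

# ---------------------------------------------------------------------------
# report
# ---------------------------------------------------------------------------

render_report <- function(results, config, path) {
  ln <- character()
  add <- function(...) ln <<- c(ln, paste0(...))
  fmtn <- function(x, d = 3) formatC(x, digits = d, format = "f")
  add("# Disjunction-effect DDM pipeline report")
  add("")
  add("Seed: ", config$seed, "; subjects: ", config$n_subjects,
      "; trials/condition: ", config$n_trials_per_condition)
  add("")
  add("## Defection rates and EOD")
  r <- results$rates
  add("")
  add("Mean defection rates: U = ", fmtn(r$mean_p_def$p_def_U),
      ", D = ", fmtn(r$mean_p_def$p_def_D),
      ", C = ", fmtn(r$mean_p_def$p_def_C),
      "; mean EOD = ", fmtn(r$mean_eod))
  add("")
  add("| group | EOD mean | EOD sd | n |")
  add("|---|---|---|---|")
  for (g in names(r$eod_by_group)) {
    e <- r$eod_by_group[[g]]
    add("| ", g, " | ", fmtn(e$mean), " | ", fmtn(e$sd), " | ", e$n, " |")
  }
  anova_block <- function(title, a) {
    add("")
    add("## ANOVA: ", title)
    add("")
    add("F(", fmtn(a$df1, 2), ", ", fmtn(a$df2, 2), ") = ", fmtn(a$F),
        ", p = ", format.pval(a$p, digits = 3), ", etaP2 = ",
        fmtn(a$partial_eta_sq), " (GG epsilon = ", fmtn(a$gg_epsilon),
        if (a$gg_applied) ", applied)" else ", not applied)")
    add("")
    add("| pair | t | df | p (Bonferroni) |")
    add("|---|---|---|---|")
    pw <- a$pairwise
    for (i in seq_len(nrow(pw))) {
      add("| ", pw$pair[i], " | ", fmtn(pw$t[i]), " | ", pw$df[i], " | ",
          format.pval(pw$p_bonferroni[i], digits = 3), " |")
    }
  }
  anova_block("defection rates", results$anova$defection_rates)
  anova_block("boundary separation (threshold)", results$anova$threshold)
  anova_block("drift rate", results$anova$drift)
  anova_block("prosocial bias", results$anova$bias)
  anova_block("prosocial bias (logit transformed)", results$anova$bias_logit)
  add("")
  add("## Parameter-variation decomposition")
  for (blk in c("D", "C")) {
    d <- results$decomposition[[blk]]
    add("")
    add("Outcome: p(Defect|", blk, ") - p(Defect|U);  R^2 = ",
        fmtn(d$r_squared), ", F = ", fmtn(d$F))
    add("")
    add("| predictor | beta | p | PMVD % | LMG % |")
    add("|---|---|---|---|---|")
    for (nm in names(d$beta)) {
      add("| ", nm, " | ", fmtn(d$beta[[nm]]), " | ",
          format.pval(d$beta_p[[nm]], digits = 3), " | ",
          fmtn(d$pmvd_pct[[nm]], 1), " | ", fmtn(d$lmg_pct[[nm]], 1), " |")
    }
  }
  quad_block <- function(title, q) {
    add("")
    add("### ", title)
    add("")
    add("| model | term | coef | 95% CI | adj R^2 |")
    add("|---|---|---|---|---|")
    for (mn in c("linear", "quadratic")) {
      m <- q[[mn]]
      for (nm in names(m$coef)) {
        add("| ", mn, " | ", nm, " | ", fmtn(m$coef[[nm]]), " | [",
            fmtn(m$ci[[nm]][[1]]), ", ", fmtn(m$ci[[nm]][[2]]), "] | ",
            fmtn(m$adj_r_squared), " |")
      }
    }
  }
  add("")
  add("## SVO and bias variation")
  quad_block("z_D - z_U", results$svo_regressions$dz_d)
  quad_block("z_C - z_U", results$svo_regressions$dz_c)
  quad_block("z_U - z_C (reversed sign)", results$svo_regressions$dz_c_reversed)
  add("")
  add("## SVO and defection-rate variation")
  quad_block("p(Defect|D) - p(Defect|U)", results$svo_regressions$dp_d)
  quad_block("p(Defect|C) - p(Defect|U)", results$svo_regressions$dp_c)
  quad_block("EOD", results$svo_regressions$eod)
  add("")
  add("## Mediation of the quadratic SVO effect")
  add("")
  add("| outcome | effect | estimate | BCa 95% CI |")
  add("|---|---|---|---|")
  for (blk in c("D", "C")) {
    m <- results$mediation[[blk]]
    for (nm in names(m$effects)) {
      add("| ", blk, "-U | ", nm, " | ", fmtn(m$effects[[nm]]), " | [",
          fmtn(m$ci[[nm]]$lower), ", ", fmtn(m$ci[[nm]]$upper), "] |")
    }
    add("| ", blk, "-U | proportion mediated | ",
        fmtn(100 * m$proportion_mediated, 1), "% | |")
  }
  writeLines(ln, path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' simulate -> qc -> fit -> effect table -> ANOVA -> decomposition ->
#' regression/mediation, writing every intermediate file (trials,
#' payoffs, SVO, fits, effect table CSVs), the results JSON and a
#' markdown report into `out_dir`.  Idempotent: the same config produces
#' byte-identical result files.  A stage failure halts with a
#' stage-tagged error; files written by earlier stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `matrices`, `population`, `trials`,
#'   `qc`, `fits`, `effect_table`, `results`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (missing(out_dir)) stop("run_pipeline: 'out_dir' is required",
                             call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  p <- function(f) file.path(out_dir, f)
  seed <- config$seed

  matrices <- stage("simulate", {
    m <- generate_payoff_matrices(jitter = config$jitter,
                                  n = config$n_matrices,
                                  seed = derive_seed(seed, 1))
    write_payoffs(m, p("payoffs.csv"))
    m
  })
  population <- stage("simulate", {
    pop <- generate_population(config$n_subjects, config$svo_mean,
                               config$svo_sd, config$group_config,
                               seed = derive_seed(seed, 2))
    utils::write.csv(pop, p("population_true_params.csv"), row.names = FALSE)
    utils::write.csv(data.frame(subject_id = pop$subject_id,
                                svo_angle_deg = pop$svo_angle),
                     p("svo.csv"), row.names = FALSE)
    pop
  })
  trials <- stage("simulate", {
    tr <- generate_experiment(population, matrices,
                              config$n_trials_per_condition,
                              dt = config$dt_experiment,
                              seed = derive_seed(seed, 3))
    write_trials(tr, p("trials.csv"))
    tr
  })
  qc <- stage("qc", {
    res <- do.call(apply_qc_filters, c(list(trials), config$qc))
    utils::write.csv(res$exclusions, p("qc_exclusions.csv"),
                     row.names = FALSE)
    res
  })
  fits <- stage("fit", {
    f <- fit_experiment(qc$kept, seed = derive_seed(seed, 4),
                        bounds = do.call(fit_bounds,
                                         config$bounds[c("v", "a", "z",
                                                         "t_er", "eps")]),
                        control = do.call(de_control,
                                          config$de[c("pop_factor", "F", "CR",
                                                      "maxiter", "tol")]))
    write_fits(f, p("fits.csv"))
    f
  })
  et <- stage("analyze", {
    svo <- read_svo(p("svo.csv"))
    tab <- effect_table(qc$kept, fits, svo)
    utils::write.csv(tab, p("effect_table.csv"), row.names = FALSE)
    tab
  })
  results <- stage("analyze", {
    res <- analyze_experiment(et, n_boot = config$n_boot,
                              seed = derive_seed(seed, 5))
    jsonlite::write_json(res, p("results.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res
  })
  stage("report", {
    write_config(config, p("config.json"))
    render_report(results, config, p("report.md"))
  })
  invisible(list(matrices = matrices, population = population,
                 trials = trials, qc = qc, fits = fits, effect_table = et,
                 results = results,
                 paths = stats::setNames(
                   file.path(out_dir, c("payoffs.csv", "trials.csv",
                                        "svo.csv", "fits.csv",
                                        "effect_table.csv", "results.json",
                                        "report.md", "config.json")),
                   c("payoffs", "trials", "svo", "fits", "effect_table",
                     "results", "report", "config"))))
}
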
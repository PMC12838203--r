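# Shared fixtures: small synthetic subjects and trial tables built in code.

# canonical parameter set used across the numerics tests
fix_params <- function(t_er = 0) ddm_params(v = 1, a = 1.5, z = 0.4,
                                            t_er = t_er)

# one subject's trials simulated at known condition parameters
make_subject_trials <- function(n = 50, seed = 100, dt = 1e-3,
                                true = NULL) {
  if (is.null(true)) {
    true <- list(U = ddm_params(0.4, 1.5, 0.50, 0.35),
                 D = ddm_params(0.55, 1.5, 0.353, 0.35),
                 C = ddm_params(0.55, 1.5, 0.49, 0.35))
  }
  do.call(rbind, lapply(names(true), function(cn) {
    sim <- simulate_trials(true[[cn]], n, dt = dt,
                           seed = seed + match(cn, names(true)))
    data.frame(subject_id = "S1", condition = cn,
               choice = as.character(sim$choice), rt = sim$rt)
  }))
}

# evaluate expr under a local seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# tiny deterministic trial table for counting tests
make_count_trials <- function() {
  data.frame(
    subject_id = rep("S1", 12),
    condition = rep(c("U", "D", "C"), each = 4),
    choice = c("defect", "defect", "cooperate", "cooperate",   # U: 2/4
               "defect", "defect", "defect", "cooperate",      # D: 3/4
               "defect", "cooperate", "cooperate", "cooperate"), # C: 1/4
    rt = seq(0.5, 1.6, by = 0.1)
  )
}
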
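# All permutations of 1..p (p small; p! enumerated exactly).
all_orderings <- function(p) {
  if (p == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_orderings(p - 1L)
  do.call(rbind, lapply(seq_len(p), function(j) {
    rest <- seq_len(p)[-j]
    cbind(j, matrix(rest[sub], nrow(sub), p - 1L))
  }))
}

# R^2 of y on every subset of the columns of X, via the correlation matrix.
# Returns a numeric vector indexed by the subset bitmask (1..2^p - 1).
subset_r2 <- function(X, y) {
  p <- ncol(X)
  R <- stats::cor(cbind(X, y))
  rxx <- R[seq_len(p), seq_len(p), drop = FALSE]
  rxy <- R[seq_len(p), p + 1L]
  out <- numeric(2^p - 1L)
  for (m in seq_len(2^p - 1L)) {
    s <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    out[m] <- drop(crossprod(rxy[s], solve(rxx[s, s, drop = FALSE], rxy[s])))
  }
  out
}

mask_of <- function(s) sum(bitwShiftL(1L, s - 1L))

#' Multiple regression of defection-rate variation on parameter variations
#'
#' Ordinary least squares on standardized (z-scored) outcome and
#' predictors, the convention under which coefficients are comparable
#' across predictors.
#'
#' @param dp outcome: per-subject defection-rate variation.
#' @param da,dv,dz predictors: boundary, drift and bias variations.
#' @return list of class `variation_regression`: standardized `beta`
#'   (named), `se`, `t`, `p`, `r_squared`, `F`, `df`, `p_model`, `n`.
#' @export
variation_regression <- function(dp, da, dv, dz) {
  n <- length(dp)
  if (n < 10L) stop("variation_regression: need >= 10 subjects",
                    call. = FALSE)
  X <- cbind(da = da, dv = dv, dz = dz)
  Xs <- scale(X)
  if (kappa(crossprod(Xs), exact = TRUE) > 1e8) {
    stop("variation_regression: predictors are (near-)collinear",
         call. = FALSE)
  }
  dat <- data.frame(dp = as.numeric(scale(dp)), Xs)
  fit <- stats::lm(dp ~ da + dv + dz, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients[-1L, , drop = FALSE]
  fstat <- sm$fstatistic
  structure(list(beta = co[, 1], se = co[, 2], t = co[, 3], p = co[, 4],
                 r_squared = sm$r.squared, F = unname(fstat[1]),
                 df = unname(fstat[2:3]),
                 p_model = stats::pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE),
                 n = n),
            class = "variation_regression")
}

#' PMVD relative-importance shares
#'
#' Proportional marginal variance decomposition: each predictor ordering
#' contributes its sequential R-squared increments, and orderings are
#' weighted data-dependently, with weight proportional to
#' \deqn{L(r) = \prod_{i=1}^{p-1}
#'   \left[R^2_{\mathrm{full}} - R^2(r_1, \dots, r_i)\right]^{-1},}
#' so that orderings leaving little unexplained variance early dominate.
#' This gives PMVD its exclusion property: a predictor with a zero
#' population coefficient receives a vanishing share.  Orderings are
#' enumerated exactly (p <= 6).
#'
#' @param X numeric matrix of predictors (n x p, p <= 6).
#' @param y outcome vector.
#' @return list of class `importance_result`: `shares` (fractions of the
#'   full-model R-squared, summing to 1), `raw` (summing to R-squared),
#'   `r_squared`, `orderings` (ordering x weight table), `method`.
#' @export
pmvd_shares <- function(X, y) {
  importance_shares(X, y, method = "pmvd")
}

#' LMG relative-importance shares (diagnostic comparator)
#'
#' The unweighted average over predictor orderings of sequential
#' R-squared increments.  Equals PMVD for mutually orthogonal predictors.
#'
#' @inheritParams pmvd_shares
#' @return As [pmvd_shares()].
#' @export
lmg_shares <- function(X, y) {
  importance_shares(X, y, method = "lmg")
}

importance_shares <- function(X, y, method = c("pmvd", "lmg")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 6L) stop("importance shares: p <= 6 required (orderings are ",
                   "enumerated exactly)", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  r2 <- subset_r2(X, y)
  full <- r2[2^p - 1L]
  if (!is.finite(full) || full <= 0) {
    warning("importance shares: full-model R^2 is 0; shares undefined",
            call. = FALSE)
    return(structure(list(shares = rep(NA_real_, p), raw = rep(NA_real_, p),
                          r_squared = full, orderings = NULL,
                          method = method),
                     class = "importance_result"))
  }
  perms <- all_orderings(p)
  nperm <- nrow(perms)
  weights <- numeric(nperm)
  contrib <- matrix(0, nperm, p)
  for (r in seq_len(nperm)) {
    ord <- perms[r, ]
    prev <- 0
    mask <- 0L
    logw <- 0
    for (i in seq_len(p)) {
      mask <- mask + bitwShiftL(1L, ord[i] - 1L)
      cur <- r2[mask]
      contrib[r, ord[i]] <- cur - prev
      if (method == "pmvd" && i < p) {
        logw <- logw - log(max(full - cur, 1e-12))
      }
      prev <- cur
    }
    weights[r] <- logw
  }
  weights <- if (method == "pmvd") {
    w <- exp(weights - max(weights))
    w / sum(w)
  } else rep(1 / nperm, nperm)
  raw <- drop(crossprod(weights, contrib))
  names(raw) <- colnames(X)
  structure(list(shares = raw / full, raw = raw, r_squared = full,
                 orderings = data.frame(
                   ordering = apply(perms, 1, function(o)
                     paste(colnames(X)[o], collapse = " -> ")),
                   weight = weights),
                 method = method),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(toupper(x$method), "relative importance (R^2 =",
      sprintf("%.3f", x$r_squared), ")\n")
  for (nm in names(x$shares)) {
    cat(sprintf("  %-6s %6.1f%% of R^2\n", nm, 100 * x$shares[[nm]]))
  }
  invisible(x)
}
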
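#' Simulation-based residual diagnostics
#'
#' Randomized quantile residuals computed by simulation: `n_sim` response
#' vectors are drawn from the fitted model (re-drawing the random
#' intercepts), and the scaled residual of each observation is its
#' quantile position within its own simulated values, randomized at ties.
#' For a correctly specified model the scaled residuals are standard
#' uniform, which a Kolmogorov-Smirnov test checks.  The dispersion ratio
#' compares the observed Pearson statistic against the mean simulated one.
#'
#' @param fit A [fit_glmm()] result.
#' @param n_sim Number of simulated response vectors (>= 20; default 250).
#' @param seed Integer seed for the simulations (scoped).
#' @return A `residual_diagnostic`: list with `residuals` (in \[0, 1\]),
#'   `ks_stat`, `ks_p`, `dispersion_ratio`, `n_sim`.
#' @export
simulate_residual_check <- function(fit, n_sim = 250, seed = 1L) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (n_sim < 20) {
    stop("n_sim must be >= 20: quantile ranks are unstable below that",
         call. = FALSE)
  }
  y <- fit$frame$value
  sims <- simulate(fit, nsim = n_sim, seed = seed)
  u <- local_seed(split_seed(seed, "ties"), {
    vapply(seq_along(y), function(i) {
      below <- sum(sims[i, ] < y[i])
      ties <- sum(sims[i, ] == y[i])
      (below + runif(1) * (ties + 1)) / (n_sim + 1)
    }, numeric(1))
  })
  ks <- suppressWarnings(ks.test(u, "punif"))
  mu0 <- as.vector(fit$X %*% fit$beta)
  pearson_stat <- function(yy) {
    if (fit$family == "gamma_log") {
      mu <- exp(mu0)
      sum(((yy - mu) / mu)^2)
    } else {
      sum((yy - mu0)^2)
    }
  }
  disp <- pearson_stat(y) / mean(apply(sims, 2, pearson_stat))
  structure(list(residuals = u, ks_stat = as.numeric(ks$statistic),
                 ks_p = ks$p.value, dispersion_ratio = disp,
                 n_sim = n_sim),
            class = "residual_diagnostic")
}

#' @export
print.residual_diagnostic <- function(x, ...) {
  cat(sprintf(
    "Simulation-based residual check (%d simulations)\n  KS uniformity: D = %.4f, p = %.4g\n  dispersion ratio = %.3f\n",
    x$n_sim, x$ks_stat, x$ks_p, x$dispersion_ratio))
  invisible(x)
}
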
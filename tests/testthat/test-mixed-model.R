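# Small balanced half-life tables for model tests.
sim_hl <- function(medians, n_blocks = 4, n_rep = 3, cv = 0.15,
                   sd_block = 0, sd_rep = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(block = LETTERS[seq_len(n_blocks)],
                      replicate = seq_len(n_rep),
                      strain = names(medians),
                      stringsAsFactors = FALSE)
  bB <- setNames(rnorm(n_blocks, 0, sd_block), LETTERS[seq_len(n_blocks)])
  brk <- unique(grid[c("block", "replicate")])
  bR <- setNames(rnorm(nrow(brk), 0, sd_rep),
                 paste(brk$block, brk$replicate))
  mu <- log(unlist(medians)[grid$strain]) + bB[grid$block] +
    bR[paste(grid$block, grid$replicate)]
  shape <- 1 / cv^2
  grid$value <- rgamma(nrow(grid), shape = shape, rate = shape / exp(mu))
  tibble::as_tibble(grid)
}

test_that("near-constant responses collapse to a degenerate fit", {
  d <- sim_hl(c(A = 2, B = 2))
  set.seed(2)
  d$value <- 3.7 * exp(rnorm(nrow(d), 0, 1e-3))
  fit <- suppressWarnings(fit_glmm(d))
  expect_equal(unname(fit$beta[1]), log(3.7), tolerance = 5e-3)
  expect_lt(abs(fit$beta[2]), 5e-3)
  expect_lt(fit$var_block + fit$var_rep, 1e-6)

  # exactly constant data: the Gamma shape likelihood is unbounded and the
  # fit honestly reports non-convergence
  d$value <- 3.7
  fit0 <- suppressWarnings(fit_glmm(d))
  expect_false(fit0$converged)
})

test_that("the variance-pinned mixed model is a gamma log-link GLM", {
  d <- sim_hl(c(A = 0.8, B = 1.6, C = 3.1), cv = 0.2, seed = 4)
  fit <- fit_glmm(d, fix_variance_zero = TRUE)
  oracle <- glm(value ~ strain, family = Gamma(link = "log"), data = d)
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
  # gamma log-link GLM property: fitted group means are sample means
  means <- exp(c(fit$beta[1], fit$beta[1] + fit$beta[-1]))
  sample_means <- tapply(d$value, d$strain, mean)
  expect_equal(unname(means), as.vector(sample_means), tolerance = 1e-6)
  # letting the variance components free never lowers the likelihood
  free <- fit_glmm(d)
  expect_gte(free$loglik, fit$loglik - 1e-6)
})

test_that("rescaling responses shifts only the intercept", {
  d <- sim_hl(c(A = 1, B = 2.5, C = 4), sd_block = 0.15, sd_rep = 0.1,
              seed = 6)
  f1 <- fit_glmm(d)
  d2 <- d
  d2$value <- d$value * 3
  f2 <- fit_glmm(d2)
  expect_equal(unname(f2$beta[1] - f1$beta[1]), log(3), tolerance = 1e-4)
  expect_equal(f2$beta[-1], f1$beta[-1], tolerance = 1e-4)
  c1 <- tukey_contrasts(marginal_means(f1))
  c2 <- tukey_contrasts(marginal_means(f2))
  expect_equal(c2$log_ratio, c1$log_ratio, tolerance = 1e-4)
})

test_that("Wald machinery matches its algebraic special cases", {
  d <- sim_hl(c(A = 1.5, B = 2.2), seed = 8)
  fit <- fit_glmm(d)
  w <- wald_test_term(fit, "strain")
  z2 <- (fit$beta[2] / sqrt(fit$vcov_beta[2, 2]))^2
  expect_equal(w$statistic, unname(z2))
  expect_equal(w$df, 1L)
  expect_error(wald_test_term(fit, "environment"), "unknown term")

  lrt <- wald_test_term(fit, "strain", method = "lrt")
  expect_equal(lrt$df, 1L)
  expect_gt(lrt$statistic, 0)

  # strong separation is detected
  d2 <- sim_hl(c(A = 1, B = exp(2)), cv = 0.05, seed = 9)
  expect_lt(wald_test_term(fit_glmm(d2), "strain")$p, 1e-6)
})

test_that("marginal means reproduce one-factor predictions and emmeans", {
  d <- sim_hl(c(A = 1.5, B = 2.2, C = 3.4), sd_block = 0.1, seed = 12)
  fit <- fit_glmm(d)
  mm <- marginal_means(fit)
  expect_equal(mm$emmean,
               unname(c(fit$beta[1], fit$beta[1] + fit$beta[-1])))
  em <- as.data.frame(emmeans::emmeans(fit$model, "strain"))
  expect_equal(mm$emmean, em$emmean, tolerance = 1e-8)
  expect_equal(mm$se, em$SE, tolerance = 1e-6)
})

test_that("two-factor marginal means average equally over the other factor", {
  set.seed(14)
  d <- sim_hl(c(A = 1.5, B = 3), seed = 14)
  d$environment <- rep(c("20C", "25C"), length.out = nrow(d))
  d$value <- d$value * ifelse(d$environment == "25C", 1.4, 1)
  fit <- fit_glmm(d, glmm_spec("strain*environment"))
  mm_s <- marginal_means(fit, by = "strain")
  grid_pred <- function(s) {
    g <- data.frame(strain = factor(s, c("A", "B")),
                    environment = factor(c("20C", "25C")))
    X <- model.matrix(~ strain * environment, g)
    mean(X %*% fit$beta)
  }
  expect_equal(mm_s$emmean, c(grid_pred("A"), grid_pred("B")))
  em <- as.data.frame(emmeans::emmeans(fit$model, "strain"))
  expect_equal(mm_s$emmean, em$emmean, tolerance = 1e-8)

  # conditioned contrasts: one pair per stratum, family of one
  mm_full <- marginal_means(fit, by = c("strain", "environment"))
  ctr <- tukey_contrasts(mm_full, by = "strain")
  expect_equal(nrow(ctr), 2L)
  expect_equal(ctr$p_adj, ctr$p_raw)
  em_ctr <- summary(emmeans::emmeans(
    fit$model, pairwise ~ environment | strain, adjust = "tukey"))$contrasts
  expect_equal(ctr$log_ratio, em_ctr$estimate, tolerance = 1e-8)
})

test_that("pairwise contrasts are antisymmetric and Tukey-adjusted", {
  d <- sim_hl(c(A = 1.2, B = 2, C = 2.4, D = 4), sd_block = 0.1,
              sd_rep = 0.1, seed = 16)
  fit <- fit_glmm(d)
  mm <- marginal_means(fit)
  ctr <- tukey_contrasts(mm)
  expect_equal(nrow(ctr), 6L)
  ab <- ctr[ctr$level_a == "A" & ctr$level_b == "B", ]
  expect_equal(ab$log_ratio, mm$emmean[1] - mm$emmean[2])
  expect_true(all(ctr$p_adj >= ctr$p_raw))
  expect_true(all(ctr$p_adj >= 0 & ctr$p_adj <= 1))

  # two levels: the family is a single contrast, no adjustment
  d2 <- sim_hl(c(A = 1.5, B = 2.1), seed = 17)
  ctr2 <- tukey_contrasts(marginal_means(fit_glmm(d2)))
  expect_equal(ctr2$p_adj, ctr2$p_raw)
})

test_that("data problems are reported before fitting", {
  d <- sim_hl(c(A = 1.5, B = 2.5), seed = 20)
  bad <- d
  bad$value[1] <- -0.5
  expect_error(fit_glmm(bad), "strictly positive")

  one_level <- d[d$strain == "A", ]
  expect_error(fit_glmm(one_level), ">= 2 levels")

  # censored estimates are excluded and counted
  cens <- d
  cens$status <- "interpolated"
  cens$status[1:2] <- "censored"
  cens$value[1:2] <- NA
  fit <- fit_glmm(cens)
  expect_equal(fit$n_censored, 2L)
  expect_equal(fit$n_obs, nrow(d) - 2L)
})

test_that("strains confined to one block are excluded by default", {
  d <- sim_hl(c(A = 1.5, B = 2.5, C = 3.5), seed = 22)
  d <- d[!(d$strain == "C" & d$block != "A"), ]
  fit <- fit_glmm(d)
  expect_false("strainC" %in% names(fit$beta))
  fit_all <- fit_glmm(d, include_singleton_strains = TRUE)
  expect_true("strainC" %in% names(fit_all$beta))
})

test_that("single-block data drop the block intercept", {
  d <- sim_hl(c(A = 1.5, B = 2.5), n_blocks = 1, n_rep = 6, seed = 24)
  fit <- fit_glmm(d)
  expect_true(fit$single_block)
  expect_equal(fit$var_block, 0)
})

test_that("residual diagnostics are bounded, calibrated and sensitive", {
  d <- sim_hl(c(A = 1.5, B = 2.5, C = 3.5), sd_block = 0.15, sd_rep = 0.1,
              cv = 0.1, seed = 30)
  fit <- fit_glmm(d)
  diag <- simulate_residual_check(fit, n_sim = 100, seed = 2)
  expect_true(all(diag$residuals >= 0 & diag$residuals <= 1))
  expect_gt(diag$dispersion_ratio, 0)
  expect_error(simulate_residual_check(fit, n_sim = 10), ">= 20")
  # identical seed, identical diagnostic
  diag2 <- simulate_residual_check(fit, n_sim = 100, seed = 2)
  expect_identical(diag$residuals, diag2$residuals)

  # gross misspecification: heavy right-tailed data under a gaussian fit
  set.seed(31)
  heavy <- d
  heavy$value <- exp(rnorm(nrow(d), 0, 1.2))
  gfit <- suppressWarnings(
    fit_glmm(heavy, glmm_spec("strain", family = "gaussian_identity")))
  ps <- vapply(1:10, function(s) {
    simulate_residual_check(gfit, n_sim = 100, seed = s)$ks_p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.5)
})
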
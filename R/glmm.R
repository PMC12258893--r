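#' Specification of a half-life mixed model
#'
#' The analysis model for half-life values: fixed effects for strain (and
#' optionally environment with interaction), random intercepts for block
#' and for replicate nested in block, and a Gamma distribution with log
#' link (half-lives are positive and block/replicate variation acts
#' multiplicatively).  A Gaussian identity-link variant is available for
#' sensitivity analyses.
#'
#' @param fixed One of `"strain"`, `"strain*environment"` or
#'   `"strain+environment"`.
#' @param family `"gamma_log"` (default) or `"gaussian_identity"`.
#' @return A `glmm_spec` (a named list).
#' @export
glmm_spec <- function(fixed = "strain",
                      family = c("gamma_log", "gaussian_identity")) {
  fixed <- gsub(" ", "", fixed)
  allowed <- c("strain", "strain*environment", "strain+environment",
               "environment")
  if (!fixed %in% allowed) {
    stop("fixed must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  family <- match.arg(family)
  factors <- unique(strsplit(fixed, "[*+]")[[1]])
  structure(list(fixed = fixed, factors = factors, family = family),
            class = "glmm_spec")
}

#' Fit the Gamma log-link mixed model to half-life values
#'
#' Fits `value ~ <fixed> + (1|block) + (1|block:replicate)` by maximum
#' likelihood with a Laplace approximation to the marginal likelihood.
#' When the data contain a single block, the block intercept is dropped
#' and only the replicate-in-block intercept is kept.  Censored half-life
#' estimates carry no value and are excluded before fitting (their count
#' is recorded on the fit).  Strains observed in only one block are
#' excluded from strain-effect fits by default, since their strain effect
#' would be confounded with that block.
#'
#' @param data A half-life table (see [half_life_table()]): columns
#'   `block`, `strain`, `replicate`, `value`, and `environment` / `status`
#'   as needed.
#' @param spec A [glmm_spec()].
#' @param include_singleton_strains Keep strains observed in a single
#'   block (default FALSE).
#' @param fix_variance_zero Pin both random-intercept variances at zero
#'   (the generalized-linear-model limit of the mixed model).
#' @return A `glmm_fit`: list with `beta` (link-scale fixed effects),
#'   `vcov_beta`, `var_block`, `var_rep`, `shape` (Gamma shape, or
#'   residual variance under the Gaussian family), `loglik`, `converged`,
#'   `n_obs`, `n_groups`, `n_censored`, plus the model frame and engine
#'   fit.
#' @export
fit_glmm <- function(data, spec = glmm_spec(),
                     include_singleton_strains = FALSE,
                     fix_variance_zero = FALSE) {
  stopifnot(inherits(spec, "glmm_spec"))
  data <- tibble::as_tibble(data)
  need <- c("block", "replicate", "value", spec$factors)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("half-life data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_censored <- 0L
  if ("status" %in% names(data)) {
    n_censored <- sum(data$status == "censored")
    data <- data[data$status != "censored", , drop = FALSE]
  }
  if (any(is.na(data$value))) stop("missing half-life values", call. = FALSE)
  if (spec$family == "gamma_log" && any(data$value <= 0)) {
    stop("Gamma family requires strictly positive half-life values",
         call. = FALSE)
  }
  if ("strain" %in% spec$factors && !include_singleton_strains &&
      length(unique(data$block)) > 1) {
    blocks_per_strain <- tapply(data$block, data$strain,
                                function(b) length(unique(b)))
    singletons <- names(blocks_per_strain)[blocks_per_strain < 2]
    data <- data[!data$strain %in% singletons, , drop = FALSE]
  }
  for (f in spec$factors) {
    data[[f]] <- factor(data[[f]], levels = sort(unique(data[[f]])))
    if (nlevels(data[[f]]) < 2) {
      stop(sprintf("factor '%s' needs >= 2 levels after filtering", f),
           call. = FALSE)
    }
  }
  data$block <- factor(data$block)
  data$replicate <- factor(data$replicate)

  fixed_formula <- as.formula(paste("value ~", spec$fixed))
  X <- model.matrix(fixed_formula, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  single_block <- nlevels(data$block) < 2
  random_terms <- if (single_block) "(1 | block:replicate)" else
    "(1 | block) + (1 | block:replicate)"
  full_formula <- as.formula(paste("value ~", spec$fixed, "+", random_terms))
  fam <- if (spec$family == "gamma_log") Gamma(link = "log") else
    stats::gaussian()

  args <- list(formula = full_formula, data = data, family = fam)
  if (fix_variance_zero) {
    n_theta <- if (single_block) 1L else 2L
    args$start <- list(theta = rep(-12, n_theta))
    args$map <- list(theta = factor(rep(NA, n_theta)))
  }
  model <- suppressWarnings(do.call(glmmTMB::glmmTMB, args))

  vc <- glmmTMB::VarCorr(model)$cond
  var_block <- if (single_block || fix_variance_zero) 0 else
    as.numeric(vc$block[1, 1])
  var_rep <- if (fix_variance_zero) 0 else
    as.numeric(vc$`block:replicate`[1, 1])
  disp <- sigma(model)
  shape <- if (spec$family == "gamma_log") 1 / disp^2 else disp^2
  converged <- isTRUE(model$fit$convergence == 0) &&
    isTRUE(model$sdr$pdHess %||% TRUE)

  structure(list(
    beta = glmmTMB::fixef(model)$cond,
    vcov_beta = as.matrix(vcov(model)$cond),
    var_block = var_block,
    var_rep = var_rep,
    shape = shape,
    loglik = as.numeric(logLik(model)),
    converged = converged,
    n_obs = nrow(data),
    n_groups = c(block = nlevels(data$block),
                 replicate = nlevels(droplevels(
                   interaction(data$block, data$replicate)))),
    n_censored = n_censored,
    family = spec$family,
    spec = spec,
    fixed_formula = fixed_formula,
    single_block = single_block,
    frame = data,
    X = X,
    model = model
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Half-life mixed model (%s, Laplace ML)\n", x$family))
  cat(sprintf("  fixed: value ~ %s;  random: %s\n", x$spec$fixed,
              if (x$single_block) "(1|block:replicate)" else
                "(1|block) + (1|block:replicate)"))
  cat(sprintf("  n = %d (censored excluded: %d), logLik = %.3f%s\n",
              x$n_obs, x$n_censored, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  var(block) = %.4g, var(block:replicate) = %.4g, %s = %.4g\n",
              x$var_block, x$var_rep,
              if (x$family == "gamma_log") "Gamma shape" else "resid var",
              x$shape))
  print(round(x$beta, 4))
  invisible(x)
}

#' Omnibus test of a fixed-effect term
#'
#' Wald chi-square test of all coefficients belonging to one factor (or
#' interaction) against zero, using the asymptotic normal reference; a
#' likelihood-ratio variant refits the model without the term.
#'
#' @param fit A [fit_glmm()] result.
#' @param term Term label, e.g. `"strain"` or `"strain:environment"`.
#' @param method `"wald"` (default) or `"lrt"`.
#' @return A tibble with columns `term`, `statistic`, `df`, `p`.
#' @export
wald_test_term <- function(fit, term, method = c("wald", "lrt")) {
  method <- match.arg(method)
  labels <- attr(terms(fit$fixed_formula), "term.labels")
  if (!term %in% labels) {
    stop(sprintf("unknown term '%s' (model terms: %s)", term,
                 paste(labels, collapse = ", ")), call. = FALSE)
  }
  assign <- attr(fit$X, "assign")
  idx <- which(assign == match(term, labels))
  if (method == "wald") {
    b <- fit$beta[idx]
    V <- fit$vcov_beta[idx, idx, drop = FALSE]
    stat <- as.numeric(t(b) %*% solve(V, b))
    df <- length(idx)
  } else {
    reduced <- drop_term_refit(fit, term)
    stat <- 2 * (fit$loglik - reduced$loglik)
    df <- length(fit$beta) - length(reduced$beta)
  }
  tibble::tibble(term = term, statistic = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE))
}

drop_term_refit <- function(fit, term) {
  reduced_fixed <- switch(
    fit$spec$fixed,
    "strain" = if (term == "strain") "1" else NULL,
    "strain+environment" = setdiff(fit$spec$factors, term),
    "strain*environment" = if (term == "strain:environment")
      "strain+environment" else NULL
  )
  if (is.null(reduced_fixed) || length(reduced_fixed) == 0) {
    stop("cannot drop term '", term, "' from fixed part '",
         fit$spec$fixed, "' (marginality)", call. = FALSE)
  }
  reduced_fixed <- paste(reduced_fixed, collapse = "+")
  random_terms <- if (fit$single_block) "(1 | block:replicate)" else
    "(1 | block) + (1 | block:replicate)"
  fam <- if (fit$family == "gamma_log") Gamma(link = "log") else
    stats::gaussian()
  m <- suppressWarnings(glmmTMB::glmmTMB(
    as.formula(paste("value ~", reduced_fixed, "+", random_terms)),
    data = fit$frame, family = fam))
  list(beta = glmmTMB::fixef(m)$cond, loglik = as.numeric(logLik(m)))
}

#' Simulate responses from a fitted half-life model
#'
#' Draws new response vectors from the fitted model, re-drawing the block
#' and replicate random intercepts from their estimated distributions
#' (unconditional simulation), as used by the residual diagnostics.
#'
#' @param object A [fit_glmm()] result.
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed (scoped; the caller's RNG state is preserved).
#' @param ... Unused.
#' @return A numeric matrix, `n_obs` rows by `nsim` columns.
#' @export
simulate.glmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu0 <- as.vector(object$X %*% object$beta)
  frame <- object$frame
  block <- frame$block
  brep <- droplevels(interaction(frame$block, frame$replicate))
  n <- nrow(frame)
  draw_all <- function() {
    out <- matrix(NA_real_, n, nsim)
    for (s in seq_len(nsim)) {
      eta <- mu0
      if (object$var_block > 0) {
        b <- rnorm(nlevels(block), 0, sqrt(object$var_block))
        eta <- eta + b[as.integer(block)]
      }
      if (object$var_rep > 0) {
        b <- rnorm(nlevels(brep), 0, sqrt(object$var_rep))
        eta <- eta + b[as.integer(brep)]
      }
      if (object$family == "gamma_log") {
        mu <- exp(eta)
        out[, s] <- rgamma(n, shape = object$shape,
                           rate = object$shape / mu)
      } else {
        out[, s] <- rnorm(n, eta, sqrt(object$shape))
      }
    }
    out
  }
  if (is.null(seed)) draw_all() else local_seed(seed, draw_all())
}
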
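# Independent oracles used across the suite.  These re-derive the bracket
# selection and half-life by exhaustive enumeration, sharing no code with
# the package implementation (the interpolation formula itself is the
# estimator's definition and is common to both).

oracle_bracket <- function(values, threshold = 50) {
  n <- length(values)
  is_above <- vapply(seq_len(n), function(i) values[i] >= threshold,
                     logical(1))
  if (sum(is_above) == 0) return(list(signal = "censored"))
  if (sum(is_above) == n) return(list(signal = "left_anchored"))
  if (!is_above[n]) return(list(signal = "censored"))
  crossings <- 0
  for (i in seq_len(n - 1)) {
    if (is_above[i] != is_above[i + 1]) crossings <- crossings + 1
  }
  if (crossings == 1) {
    # exhaustive search: the below point minimizing (threshold - value) and
    # the above point minimizing (value - threshold), first index on ties;
    # the pair is only valid when the below point precedes the above point
    cb <- ca <- 0
    for (i in seq_len(n)) {
      # below ties resolve to the latest point, above ties to the earliest
      if (!is_above[i] &&
          (cb == 0 || threshold - values[i] <= threshold - values[cb])) {
        cb <- i
      }
      if (is_above[i] &&
          (ca == 0 || values[i] - threshold < values[ca] - threshold)) {
        ca <- i
      }
    }
    if (cb < ca) {
      return(list(signal = "bracket", below = cb, above = ca,
                  smoothing = FALSE))
    }
  }
  # smoothing: scan from the end for the start of the sustained recovery
  a <- n
  while (a >= 2 && is_above[a - 1]) a <- a - 1
  b <- a - 1
  while (b >= 1 && is_above[b]) b <- b - 1
  list(signal = "bracket", below = b, above = a, smoothing = TRUE)
}

oracle_half_life <- function(values, coords, threshold = 50) {
  sel <- oracle_bracket(values, threshold)
  if (sel$signal == "censored") {
    return(list(value = NA_real_, status = "censored", smoothing = FALSE))
  }
  if (sel$signal == "left_anchored") {
    x_b <- 0; v_b <- 0
    x_a <- coords[1]; v_a <- values[1]
    status <- "left_anchored"
    smoothing <- FALSE
  } else {
    x_b <- coords[sel$below]; v_b <- values[sel$below]
    x_a <- coords[sel$above]; v_a <- values[sel$above]
    status <- if (coords[sel$below] == 0) "left_anchored" else "interpolated"
    smoothing <- sel$smoothing
  }
  list(value = x_b + (threshold - v_b) * (x_a - x_b) / (v_a - v_b),
       status = status, smoothing = smoothing)
}

# A random noisy logistic trajectory on generations 0..n_gen (G0 forced to
# 0% ON), scored with n individuals per point.
random_logistic_trajectory <- function(n_gen = 8, n = 100) {
  h <- runif(1, 0.5, n_gen - 1)
  k <- runif(1, 0.8, 3)
  g <- 0:n_gen
  p <- c(0, expected_on_probability(seq_len(n_gen), h, k))
  pct <- 100 * rbinom(length(g), n, p) / n
  tibble::tibble(generation = g, day = g * 3.5, pct_on = pct)
}

# Small scoring fixture: 2 strains x 1 block x `n_rep` replicates.
tiny_scoring_table <- function(n_rep = 2, generations = 1:5) {
  rows <- list()
  for (strain in c("A", "B")) {
    for (r in seq_len(n_rep)) {
      for (g in c(0, generations)) {
        on <- if (strain == "A") min(25 * g, 100) else min(12 * g, 100)
        rows[[length(rows) + 1]] <- data.frame(
          block = "C", strain = strain, environment = "20C_OP50",
          replicate = r, generation = g,
          n_off = 100 - on - min(10, 100 - on), n_dim = min(10, 100 - on),
          n_on = on)
      }
    }
  }
  scoring_table(do.call(rbind, rows))
}

default_design_halflives <- c(JU1171 = 0.7, N2 = 1.5, JU1395 = 3.0,
                              XZ1514 = 5.5)

# Population half-life value: the chord-interpolated 50% crossing of the
# noiseless logistic trajectory with the fully silenced G0 anchor.  This is
# the estimand the interpolation procedure defines (distinct from the
# latent logistic midpoint because the chord is not the curve).
population_halflife <- function(h, slope = 1.5, generations = 1:8) {
  pct <- c(0, 100 * expected_on_probability(generations, h, slope))
  oracle_half_life(pct, c(0, generations))$value
}

# Brute-force Monte-Carlo oracle for the pairwise log half-life ratio the
# mixed model estimates under the default generative design:
#   E_b[ log m_a(b) - log m_b(b) ],
# with b the (shared) block+replicate log-scale intercept, and m_s(b) the
# mean estimable half-life of strain s under binomial scoring noise at
# n = 100, computed with the exhaustive-search interpolator above.
estimand_log_ratio_oracle <- function(halflives, nb, nn, seed,
                                      slope = 1.5, generations = 1:8,
                                      n = 100, sd_total = sqrt(0.15^2 + 0.1^2)) {
  set.seed(seed)
  b <- rnorm(nb, 0, sd_total)
  inner_mean <- function(hl) {
    p <- c(0, expected_on_probability(generations, hl, slope))
    vals <- vapply(seq_len(nn), function(i) {
      pct <- 100 * rbinom(length(p), n, p) / n
      oracle_half_life(pct, c(0, generations))$value
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  logm <- sapply(halflives, function(h) {
    vapply(h * exp(b), inner_mean, numeric(1))
  })
  pairs <- utils::combn(sort(names(halflives)), 2)
  out <- apply(pairs, 2, function(pr) {
    mean(log(logm[, pr[1]]) - log(logm[, pr[2]]), na.rm = TRUE)
  })
  names(out) <- paste(pairs[1, ], pairs[2, ], sep = "-")
  out
}
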
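#' Environment scenario for a simulated memory assay
#'
#' Bundles an environment label with the generation schedule used to place
#' scoring points on a day axis and an optional multiplicative effect on the
#' strain half-life (e.g. a temperature that prolongs silencing memory).
#'
#' @param id Environment label, e.g. `"20C_OP50"`, `"25C"`, `"L1_arrest"`,
#'   `"dauer"`.
#' @param temperature Temperature label; must be a name of
#'   `schedule$base_days`.
#' @param schedule A [generation_schedule()].
#' @param halflife_multiplier Multiplies every strain half-life (> 0) under
#'   this environment; 1 means no effect.
#' @return An `environment_scenario` (a named list).
#' @export
environment_scenario <- function(id = "20C_OP50", temperature = "20C",
                                 schedule = generation_schedule(),
                                 halflife_multiplier = 1) {
  stopifnot(is.character(id), length(id) == 1)
  if (!temperature %in% names(schedule$base_days)) {
    stop(sprintf("temperature '%s' has no entry in the schedule's base_days",
                 temperature), call. = FALSE)
  }
  if (!is.numeric(halflife_multiplier) || halflife_multiplier <= 0) {
    stop("halflife_multiplier must be > 0", call. = FALSE)
  }
  structure(list(id = id, temperature = temperature, schedule = schedule,
                 halflife_multiplier = halflife_multiplier),
            class = "environment_scenario")
}

#' Design of a synthetic silencing-memory experiment
#'
#' Describes the full generative model for a multigenerational desilencing
#' assay.  Each strain has a latent half-life `H` (in generations); the
#' probability that a scored individual is GFP-positive ("ON") at
#' generation `g` follows the logistic recovery curve
#' `p(g) = 1 / (1 + exp(-k (g - H)))`.  Block and replicate random
#' intercepts act additively on `log H` — the same scale on which the
#' Gamma log-link analysis model operates — and scored counts are drawn
#' binomially from ~`n_scored` individuals, with a fixed fraction of
#' non-ON individuals scored as DIM.
#'
#' The defaults emulate the study conditions of a four-block wild-isolate
#' assay: blocks lettered C-F, three replicates per strain per block,
#' around 100 individuals scored per time point, scoring at generations
#' 1-8 after trigger removal, and strain half-lives spanning a
#' no-transmission isolate (0.7 generations) to a long-memory isolate
#' (5.5 generations).
#'
#' @param strain_halflives Named numeric vector of latent half-lives in
#'   generations (> 0), one per strain.
#' @param slope Logistic steepness `k` (per generation, > 0).
#' @param sd_block,sd_replicate Standard deviations of the Normal block and
#'   replicate-in-block random intercepts on log half-life (>= 0).
#' @param dim_fraction Probability that a non-ON individual is scored DIM.
#' @param n_scored Individuals scored per time point.
#' @param n_blocks,n_replicates Design sizes; blocks are lettered from "C".
#' @param generations Ordered trigger-free scoring generations (G0 is always
#'   emitted in addition).
#' @param environments List of [environment_scenario()] objects.
#' @param g0_leak Probability of an ON individual at G0 (0 emulates full
#'   silencing at trigger removal; > 0 emulates partially refractory
#'   strains).
#' @param seed Integer master seed for the hierarchical random streams.
#' @return A `simulation_design` (a named list).
#' @export
simulation_design <- function(
    strain_halflives = c(JU1171 = 0.7, N2 = 1.5, JU1395 = 3.0, XZ1514 = 5.5),
    slope = 1.5,
    sd_block = 0.15,
    sd_replicate = 0.10,
    dim_fraction = 0.2,
    n_scored = 100L,
    n_blocks = 4L,
    n_replicates = 3L,
    generations = 1:8,
    environments = list(environment_scenario()),
    g0_leak = 0,
    seed = 1L) {
  if (length(strain_halflives) == 0 || is.null(names(strain_halflives)) ||
      any(names(strain_halflives) == "")) {
    stop("strain_halflives must be a non-empty named vector", call. = FALSE)
  }
  if (any(strain_halflives <= 0)) stop("half-lives must be > 0", call. = FALSE)
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (sd_block < 0 || sd_replicate < 0) {
    stop("random-effect standard deviations must be >= 0", call. = FALSE)
  }
  if (dim_fraction < 0 || dim_fraction > 1) {
    stop("dim_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (g0_leak < 0 || g0_leak > 1) stop("g0_leak must lie in [0, 1]",
                                       call. = FALSE)
  if (n_scored < 1 || n_blocks < 1 || n_replicates < 1) {
    stop("design sizes must be positive", call. = FALSE)
  }
  generations <- as.integer(generations)
  if (any(generations < 1) || is.unsorted(generations, strictly = TRUE)) {
    stop("generations must be strictly increasing integers >= 1",
         call. = FALSE)
  }
  if (!all(vapply(environments, inherits, logical(1),
                  "environment_scenario"))) {
    stop("environments must be a list of environment_scenario objects",
         call. = FALSE)
  }
  ids <- vapply(environments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate environment ids", call. = FALSE)
  structure(list(
    strain_halflives = strain_halflives, slope = slope,
    sd_block = sd_block, sd_replicate = sd_replicate,
    dim_fraction = dim_fraction, n_scored = as.integer(n_scored),
    n_blocks = as.integer(n_blocks), n_replicates = as.integer(n_replicates),
    generations = generations, environments = environments,
    g0_leak = g0_leak, seed = as.integer(seed)
  ), class = "simulation_design")
}

design_blocks <- function(design) {
  LETTERS[seq(3, length.out = design$n_blocks)]
}

#' Logistic desilencing curve
#'
#' Probability that a scored individual is GFP-positive at generation `g`
#' given a latent half-life `H` and slope `k`:
#' `p(g) = 1 / (1 + exp(-k (g - H)))`.  At `g = H` the probability is
#' exactly 0.5, identifying `H` with the 50% crossing of the noiseless
#' trajectory up to chord-interpolation bias.
#'
#' @param g Generation index (vectorized).
#' @param halflife Latent half-life `H` in generations (> 0).
#' @param slope Steepness `k` per generation (> 0).
#' @return Probabilities in (0, 1), strictly increasing in `g`.
#' @examples
#' expected_on_probability(2, halflife = 3, slope = 1.5)
#' @export
expected_on_probability <- function(g, halflife, slope) {
  if (!is.numeric(halflife) || any(halflife <= 0)) {
    stop("halflife must be > 0", call. = FALSE)
  }
  if (!is.numeric(slope) || any(slope <= 0)) {
    stop("slope must be > 0", call. = FALSE)
  }
  1 / (1 + exp(-slope * (g - halflife)))
}

#' Draw a latent half-life with block and replicate effects
#'
#' Block and replicate random intercepts are Normal on the log-half-life
#' scale, matching the Gamma log-link analysis model:
#' `H = exp(log(h_strain) + b_block + b_replicate)`.
#'
#' @param h_strain Strain-level half-life (> 0).
#' @param sd_block,sd_replicate Random-intercept standard deviations.
#' @param seed Optional integer; when given, draws are made under this seed
#'   without disturbing the caller's RNG state.
#' @return A list with elements `halflife`, `b_block`, `b_replicate`.
#' @export
draw_latent_halflife <- function(h_strain, sd_block = 0, sd_replicate = 0,
                                 seed = NULL) {
  if (h_strain <= 0) stop("h_strain must be > 0", call. = FALSE)
  draw <- function() {
    b_block <- if (sd_block > 0) rnorm(1, 0, sd_block) else 0
    b_rep <- if (sd_replicate > 0) rnorm(1, 0, sd_replicate) else 0
    list(halflife = exp(log(h_strain) + b_block + b_rep),
         b_block = b_block, b_replicate = b_rep)
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Draw OFF/DIM/ON counts for one scoring time point
#'
#' `n_on ~ Binomial(n, p_on)`; among the remaining individuals each is DIM
#' with probability `dim_fraction`, else OFF.  Counts always sum to `n`.
#'
#' @param p_on Probability of scoring ON.
#' @param dim_fraction Probability a non-ON individual scores DIM.
#' @param n Number of scored individuals.
#' @param seed Optional integer for a scoped draw.
#' @return Named integer vector `c(n_off, n_dim, n_on)`.
#' @export
simulate_counts <- function(p_on, dim_fraction, n, seed = NULL) {
  if (p_on < 0 || p_on > 1 || dim_fraction < 0 || dim_fraction > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  draw <- function() {
    n_on <- rbinom(1, n, p_on)
    n_dim <- rbinom(1, n - n_on, dim_fraction)
    c(n_off = n - n_on - n_dim, n_dim = n_dim, n_on = n_on)
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Simulate a full silencing-memory experiment
#'
#' Emits one scoring record per environment x block x strain x replicate x
#' generation, plus a G0 record per series (fully silenced by default, or
#' leaky via `g0_leak`).  Random streams are split hierarchically by group
#' key, so adding a strain or environment to the design never perturbs the
#' draws of existing groups, and block/replicate intercepts are shared
#' across strains and environments exactly as the analysis model assumes.
#'
#' @param design A [simulation_design()].
#' @return A [scoring_table()].
#' @examples
#' design <- simulation_design(strain_halflives = c(N2 = 1.5, JU1395 = 3),
#'                             n_blocks = 2, seed = 42)
#' tbl <- simulate_experiment(design)
#' head(tbl)
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  blocks <- design_blocks(design)
  strains <- names(design$strain_halflives)
  rows <- list()
  for (env in design$environments) {
    for (block in blocks) {
      b_block <- if (design$sd_block > 0) {
        local_seed(split_seed(design$seed, "block", block),
                   rnorm(1, 0, design$sd_block))
      } else 0
      for (strain in strains) {
        h_env <- design$strain_halflives[[strain]] * env$halflife_multiplier
        for (rep in seq_len(design$n_replicates)) {
          b_rep <- if (design$sd_replicate > 0) {
            local_seed(split_seed(design$seed, "replicate", block, rep),
                       rnorm(1, 0, design$sd_replicate))
          } else 0
          h_lat <- exp(log(h_env) + b_block + b_rep)
          p <- c(design$g0_leak,
                 expected_on_probability(design$generations, h_lat,
                                         design$slope))
          counts <- local_seed(
            split_seed(design$seed, "counts", env$id, block, strain, rep), {
              n_on <- rbinom(length(p), design$n_scored, p)
              n_dim <- rbinom(length(p), design$n_scored - n_on,
                              design$dim_fraction)
              list(n_on = n_on, n_dim = n_dim,
                   n_off = design$n_scored - n_on - n_dim)
            })
          rows[[length(rows) + 1]] <- tibble::tibble(
            block = block, strain = strain, environment = env$id,
            replicate = rep, generation = c(0L, design$generations),
            n_off = counts$n_off, n_dim = counts$n_dim, n_on = counts$n_on
          )
        }
      }
    }
  }
  scoring_table(dplyr::bind_rows(rows),
                metadata = list(generator = "rnaimem::simulate_experiment",
                                seed = design$seed))
}
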
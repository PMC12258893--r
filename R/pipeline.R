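#' Run configuration
#'
#' Bundles everything one analysis run needs: the input source (a
#' [simulation_design()] or a scoring CSV), the environment scenarios
#' (schedules), the half-life and model settings, the output directory and
#' the master seed.  Exactly one input source must be given.
#'
#' @param design A [simulation_design()] (for simulated input), or NULL.
#' @param scoring_path Path to a scoring CSV (for file input), or NULL.
#' @param environments List of [environment_scenario()]s; defaults to the
#'   design's environments when simulating.
#' @param axes Character vector among `"generations"`, `"days"`.
#' @param threshold Percent threshold for the half-life (default 50).
#' @param fixed,family Passed to [glmm_spec()].
#' @param contrast_by Optional stratifying factor for the pairwise
#'   contrasts (e.g. `"strain"` to compare environments within strain).
#' @param diagnostics Run the simulation-based residual check.
#' @param n_sim Simulations for the residual check.
#' @param include_singleton_strains Passed to [fit_glmm()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed; every source of randomness in the run
#'   derives from it.
#' @param verbose Print stage progress.
#' @return A `run_config` (a named list).
#' @export
run_config <- function(design = NULL, scoring_path = NULL,
                       environments = NULL,
                       axes = "generations", threshold = 50,
                       fixed = "strain", family = "gamma_log",
                       contrast_by = NULL,
                       diagnostics = FALSE, n_sim = 250,
                       include_singleton_strains = FALSE,
                       outdir = tempfile("rnaimem_run_"), seed = 1L,
                       verbose = FALSE) {
  if (is.null(design) == is.null(scoring_path)) {
    stop("exactly one input source: give either design or scoring_path",
         call. = FALSE)
  }
  if (is.null(environments)) {
    if (!is.null(design)) {
      environments <- design$environments
    } else {
      environments <- list(environment_scenario())
    }
  }
  axes <- match.arg(axes, c("generations", "days"), several.ok = TRUE)
  structure(list(
    design = design, scoring_path = scoring_path,
    environments = environments, axes = axes, threshold = threshold,
    spec = glmm_spec(fixed = fixed, family = family),
    contrast_by = contrast_by, diagnostics = diagnostics, n_sim = n_sim,
    include_singleton_strains = include_singleton_strains,
    outdir = outdir, seed = as.integer(seed), verbose = verbose
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [run_config()]; `design` holds [simulation_design()] fields
#' (with `strain_halflives` as a map) and `environments` a list of
#' scenario entries with `id`, `temperature`, `base_days` (map),
#' `halflife_multiplier` and `arrests` (list of `generation`/`extra_days`
#' pairs).
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed to [run_config()] (e.g. `seed`, `outdir`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  parse_env <- function(e) {
    arrests <- if (!is.null(e$arrests)) {
      do.call(rbind, lapply(e$arrests, as.data.frame))
    }
    environment_scenario(
      id = e$id, temperature = e$temperature %||% "20C",
      schedule = generation_schedule(
        base_days = unlist(e$base_days %||% c("20C" = 3.5, "25C" = 2.5)),
        arrests = arrests),
      halflife_multiplier = e$halflife_multiplier %||% 1
    )
  }
  envs <- if (!is.null(raw$environments)) lapply(raw$environments, parse_env)
  design <- NULL
  if (!is.null(raw$design)) {
    d <- raw$design
    args <- d[setdiff(names(d), "environments")]
    args$strain_halflives <- unlist(d$strain_halflives)
    if (!is.null(envs)) args$environments <- envs
    design <- do.call(simulation_design, args)
  }
  overrides <- list(...)
  args <- raw[intersect(names(raw),
                        setdiff(names(formals(run_config)),
                                c("design", "environments")))]
  args$design <- design
  args$environments <- envs
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

#' Run the full silencing-memory analysis
#'
#' Orchestrates simulate/read -> trajectories -> half-lives -> mixed model
#' -> contrasts (-> residual diagnostics), writing every artifact plus a
#' manifest with checksums into `config$outdir`.  The run is deterministic
#' for a fixed configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of run artifacts (tables, fits, file paths).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[rnaimem] ", ...)
  files <- character()
  art <- list(config = config)

  # --- input stage ---
  if (!is.null(config$design)) {
    say("simulate: generating scoring table")
    design <- config$design
    design$seed <- config$seed
    table <- tryCatch(simulate_experiment(design),
                      error = function(e) stop_stage("simulate",
                                                     conditionMessage(e)))
  } else {
    say("read: ", config$scoring_path)
    table <- tryCatch(read_scoring_table(config$scoring_path),
                      error = function(e) stop_stage("read",
                                                     conditionMessage(e)))
  }
  scoring_file <- file.path(config$outdir, "scoring.csv")
  write_scoring_table(table, scoring_file)
  files <- c(files, scoring_file)
  art$scoring <- table

  # --- trajectory stage ---
  say("trajectories: summarizing replicates")
  traj <- tryCatch(trajectory_summary(table, config$environments),
                   error = function(e) stop_stage("trajectory",
                                                  conditionMessage(e)))
  traj_file <- file.path(config$outdir, "trajectory_summary.csv")
  readr::write_csv(traj, traj_file, progress = FALSE)
  files <- c(files, traj_file)
  art$trajectory_summary <- traj

  art$halflife <- list()
  art$fit <- list()
  art$contrasts <- list()
  art$diagnostics <- list()
  for (axis in config$axes) {
    say("halflife: axis = ", axis)
    hl <- tryCatch(
      half_life_table(table, config$environments, axis = axis,
                      threshold = config$threshold),
      error = function(e) stop_stage("halflife", conditionMessage(e)))
    hl_file <- file.path(config$outdir, paste0("halflife_", axis, ".csv"))
    readr::write_csv(hl, hl_file, progress = FALSE)
    files <- c(files, hl_file)
    art$halflife[[axis]] <- hl

    say("fit: ", config$spec$fixed, " (", config$spec$family, "), axis = ",
        axis)
    fit <- tryCatch(
      fit_glmm(hl, config$spec,
               include_singleton_strains = config$include_singleton_strains),
      error = function(e) stop_stage("fit", conditionMessage(e)))
    art$fit[[axis]] <- fit
    tests <- dplyr::bind_rows(lapply(
      attr(terms(fit$fixed_formula), "term.labels"),
      function(tm) wald_test_term(fit, tm)))
    fit_file <- file.path(config$outdir, paste0("fit_", axis, ".json"))
    jsonlite::write_json(list(
      family = fit$family, fixed = fit$spec$fixed,
      single_block = fit$single_block,
      coefficients = as.list(round(fit$beta, 10)),
      se = as.list(round(sqrt(diag(fit$vcov_beta)), 10)),
      var_block = fit$var_block, var_rep = fit$var_rep,
      shape = fit$shape, loglik = fit$loglik, converged = fit$converged,
      n_obs = fit$n_obs, n_censored = fit$n_censored,
      term_tests = tests
    ), fit_file, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    files <- c(files, fit_file)

    say("contrasts: axis = ", axis)
    mm_by <- if (!is.null(config$contrast_by)) fit$spec$factors else
      fit$spec$factors[1]
    mm <- marginal_means(fit, by = mm_by)
    ctr <- tukey_contrasts(mm, by = config$contrast_by)
    ctr_file <- file.path(config$outdir, paste0("contrasts_", axis, ".csv"))
    readr::write_csv(ctr, ctr_file, progress = FALSE)
    files <- c(files, ctr_file)
    art$contrasts[[axis]] <- ctr

    if (isTRUE(config$diagnostics)) {
      say("diagnostics: axis = ", axis)
      diag <- simulate_residual_check(fit, n_sim = config$n_sim,
                                      seed = split_seed(config$seed,
                                                        "diagnostics", axis))
      diag_file <- file.path(config$outdir,
                             paste0("diagnostics_", axis, ".json"))
      jsonlite::write_json(list(
        n_sim = diag$n_sim, ks_stat = diag$ks_stat, ks_p = diag$ks_p,
        dispersion_ratio = diag$dispersion_ratio
      ), diag_file, auto_unbox = TRUE, digits = 10)
      files <- c(files, diag_file)
      art$diagnostics[[axis]] <- diag
    }
  }

  manifest <- list(
    package = "rnaimem",
    version = as.character(utils::packageVersion("rnaimem")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(
      files = {
        tf <- tempfile(); writeLines(deparse(config[setdiff(
          names(config), "outdir")]), tf); tf
      })),
    files = lapply(setNames(basename(files), basename(files)),
                   function(f) unname(tools::md5sum(
                     file.path(config$outdir, f))))
  )
  manifest_file <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE)
  art$files <- c(files, manifest_file)
  say("done: ", length(art$files), " artifacts in ", config$outdir)
  invisible(art)
}

#' Human-readable run report
#'
#' Summarizes the artifacts of a completed run: per-strain half-life
#' medians and spreads, censored counts, omnibus term tests and the
#' pairwise contrasts.  Deterministic for given artifacts, so a
#' regenerated report is identical.
#'
#' @param outdir Output directory of a completed [run_analysis()].
#' @return Invisibly, the report lines; also printed.
#' @export
run_report <- function(outdir) {
  need <- file.path(outdir, "manifest.json")
  if (!file.exists(need)) {
    stop("missing artifact: ", need, " (run_analysis first?)",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(need)
  lines <- c("== rnaimem run report ==",
             sprintf("seed: %s  (package %s)", manifest$seed,
                     manifest$version))
  for (axis in c("generations", "days")) {
    hl_file <- file.path(outdir, paste0("halflife_", axis, ".csv"))
    if (!file.exists(hl_file)) next
    hl <- readr::read_csv(hl_file, show_col_types = FALSE, progress = FALSE)
    lines <- c(lines, "", sprintf("-- half-lives (%s axis) --", axis))
    ok <- hl[hl$status != "censored", ]
    med <- dplyr::summarise(
      dplyr::group_by(ok, .data$strain, .data$environment),
      median = median(.data$value), iqr = stats::IQR(.data$value),
      n = dplyr::n(), .groups = "drop")
    lines <- c(lines, sprintf(
      "  %-10s %-12s median %6.3f  IQR %6.3f  (n=%d)",
      med$strain, med$environment, med$median, med$iqr, med$n))
    n_cens <- sum(hl$status == "censored")
    n_left <- sum(hl$status == "left_anchored")
    lines <- c(lines, sprintf(
      "  censored replicates (excluded from model): %d; left-anchored: %d",
      n_cens, n_left))
    fit_file <- file.path(outdir, paste0("fit_", axis, ".json"))
    if (file.exists(fit_file)) {
      fit <- jsonlite::read_json(fit_file)
      for (tt in fit$term_tests) {
        lines <- c(lines, sprintf(
          "  %s effect (%s): Wald chi-sq = %.2f, df = %d, p = %.3g",
          tt$term, fit$family, tt$statistic, tt$df, tt$p))
      }
    }
    ctr_file <- file.path(outdir, paste0("contrasts_", axis, ".csv"))
    if (file.exists(ctr_file)) {
      ctr <- readr::read_csv(ctr_file, show_col_types = FALSE,
                             progress = FALSE)
      ctr <- ctr[order(ctr$p_adj), ]
      top <- head(ctr, 6)
      lines <- c(lines, "  top pairwise contrasts (link scale):",
                 sprintf("    %s - %s: log-ratio %6.3f +/- %.3f, p_adj = %.3g",
                         top$level_a, top$level_b, top$log_ratio, top$se,
                         top$p_adj))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
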
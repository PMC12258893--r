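#' Generation schedule: mapping generations to days
#'
#' A schedule converts generation indices into days since trigger removal
#' (G0 = day 0).  Each temperature has a base generation time in days;
#' developmental arrests (L1 starvation, dauer diapause) insert extra days
#' at a given generation, delaying that generation's scoring point and all
#' later ones.
#'
#' @param base_days Named numeric vector of days per generation by
#'   temperature label (> 0).  Defaults: 3.5 d at 20C, 2.5 d at 25C.
#' @param arrests Optional data frame with columns `generation` (index at
#'   which the arrest occurs, >= 1) and `extra_days` (>= 0), e.g. a 6-day
#'   L1 arrest at G1 or a 5-day dauer diapause at G2.
#' @return A `generation_schedule` (a named list).
#' @examples
#' sched <- generation_schedule(
#'   arrests = data.frame(generation = 1, extra_days = 6)
#' )
#' day_of_generation(sched, 0:3, "20C")
#' @export
generation_schedule <- function(base_days = c("20C" = 3.5, "25C" = 2.5),
                                arrests = NULL) {
  if (is.null(names(base_days)) || any(names(base_days) == "") ||
      any(base_days <= 0)) {
    stop("base_days must be a named vector of positive day counts",
         call. = FALSE)
  }
  if (is.null(arrests)) {
    arrests <- data.frame(generation = integer(), extra_days = numeric())
  }
  arrests <- as.data.frame(arrests)
  if (!all(c("generation", "extra_days") %in% names(arrests))) {
    stop("arrests needs columns 'generation' and 'extra_days'",
         call. = FALSE)
  }
  if (nrow(arrests) > 0 &&
      (any(arrests$generation < 1) || any(arrests$extra_days < 0))) {
    stop("arrests must have generation >= 1 and extra_days >= 0",
         call. = FALSE)
  }
  structure(list(base_days = base_days, arrests = arrests),
            class = "generation_schedule")
}

#' @param schedule A [generation_schedule()].
#' @param g Generation index (vectorized, >= 0).
#' @param temperature Temperature label naming an entry of `base_days`.
#' @return Days since G0, strictly increasing in `g`.
#' @rdname generation_schedule
#' @export
day_of_generation <- function(schedule, g, temperature) {
  stopifnot(inherits(schedule, "generation_schedule"))
  if (!temperature %in% names(schedule$base_days)) {
    stop(sprintf("unknown temperature label '%s' (schedule defines: %s)",
                 temperature,
                 paste(names(schedule$base_days), collapse = ", ")),
         call. = FALSE)
  }
  if (any(g < 0)) stop("generation index must be >= 0", call. = FALSE)
  base <- schedule$base_days[[temperature]]
  extra <- vapply(g, function(gi) {
    sum(schedule$arrests$extra_days[schedule$arrests$generation <= gi])
  }, numeric(1))
  g * base + extra
}

#' Percent GFP-positive individuals
#'
#' OFF and DIM individuals both count as GFP-negative: DIM animals are
#' considered to still inherit the silencing signal, so only fully ON
#' animals count toward desilencing.
#'
#' @param n_off,n_dim,n_on Scored counts (vectorized).
#' @return Percent ON in \[0, 100\].
#' @export
pct_gfp_positive <- function(n_off, n_dim = 0, n_on) {
  total <- n_off + n_dim + n_on
  if (any(total < 1)) {
    stop("percent undefined: no scored individuals", call. = FALSE)
  }
  100 * n_on / total
}

#' Build a per-replicate desilencing trajectory
#'
#' Converts the scoring records of one (block, strain, environment,
#' replicate) series into an ordered trajectory of
#' (generation, day, percent GFP-positive) points.  Records at generation
#' -1 (trigger generation) are dropped; a G0 record, when present, is kept
#' as the first point.
#'
#' @param records Scoring records sharing a single group key.
#' @param schedule A [generation_schedule()].
#' @param temperature Temperature label for the day axis.
#' @return A `trajectory`: a tibble with columns `generation`, `day`,
#'   `pct_on` and a `key` attribute.
#' @export
build_trajectory <- function(records, schedule = generation_schedule(),
                             temperature = "20C") {
  records <- tibble::as_tibble(records)
  key <- unique(records[c("block", "strain", "environment", "replicate")])
  if (nrow(key) != 1) {
    stop("records span more than one (block, strain, environment, ",
         "replicate) group", call. = FALSE)
  }
  records <- records[records$generation >= 0, , drop = FALSE]
  records <- records[order(records$generation), , drop = FALSE]
  if (nrow(records) == 0) stop("no records at generation >= 0",
                               call. = FALSE)
  out <- tibble::tibble(
    generation = records$generation,
    day = day_of_generation(schedule, records$generation, temperature),
    pct_on = pct_gfp_positive(records$n_off, records$n_dim, records$n_on)
  )
  structure(out, key = as.list(key), class = c("trajectory", class(out)))
}

#' Select the two scoring points bracketing the 50% threshold
#'
#' Implements the half-life bracket rule: by default the below point is the
#' scored value closest below the threshold and the above point the value
#' closest at-or-above it.  When the series oscillates around the threshold
#' (more than one crossing, or a misordered default pair) a smoothing rule
#' picks points further apart: the above point is the first point from
#' which the series stays at-or-above the threshold, and the below point is
#' the last sub-threshold point before it.  A value exactly at the
#' threshold counts as "above"; equally close candidate points resolve
#' toward the crossing (latest below, earliest above).
#'
#' @param values Percent-ON values in scoring order.
#' @param threshold Percent threshold (default 50).
#' @return A list with `signal` (`"bracket"`, `"left_anchored"` — every
#'   value at or above the threshold — or `"censored"` — the series never
#'   reaches, or does not end at or above, the threshold), indices `below`
#'   and `above` into `values`, and `smoothing_applied`.
#' @examples
#' select_bracket(c(10, 40, 80, 100))
#' select_bracket(c(10, 60, 40, 80, 95))  # oscillation: smoothing fires
#' @export
select_bracket <- function(values, threshold = 50) {
  n <- length(values)
  if (n < 1) stop("at least one point is required", call. = FALSE)
  above <- values >= threshold
  if (!any(above)) {
    return(list(signal = "censored", below = NA_integer_,
                above = NA_integer_, smoothing_applied = FALSE))
  }
  if (all(above)) {
    return(list(signal = "left_anchored", below = NA_integer_,
                above = NA_integer_, smoothing_applied = FALSE))
  }
  if (!above[n]) {
    # oscillates back below the threshold at the end: no sustained recovery
    return(list(signal = "censored", below = NA_integer_,
                above = NA_integer_, smoothing_applied = FALSE))
  }
  crossings <- sum(diff(above) != 0)
  if (crossings == 1) {
    # ties in distance-to-threshold resolve toward the crossing: the latest
    # of equally close below points, the earliest of equally close above
    # points (on a monotone series this is the adjacent crossing pair)
    d_b <- threshold - values[!above]
    i_below <- which(!above)[max(which(d_b == min(d_b)))]
    i_above <- which(above)[which.min(values[above] - threshold)]
    if (i_below < i_above) {
      return(list(signal = "bracket", below = i_below, above = i_above,
                  smoothing_applied = FALSE))
    }
  }
  # smoothing: first point of the sustained recovery and the last
  # sub-threshold point before it
  i_above <- max(which(!above)) + 1L
  i_below <- max(which(!above[seq_len(i_above - 1L)]))
  list(signal = "bracket", below = i_below, above = i_above,
       smoothing_applied = TRUE)
}

#' Half-life of silencing memory
#'
#' The half-life is the interpolated coordinate at which the percent of
#' GFP-positive individuals crosses the threshold (default 50%): the two
#' bracketing scoring points define a line and the half-life is where that
#' line meets the threshold.  Trajectories already at or above the
#' threshold at their first scored point are anchored against full
#' silencing at G0 (0% at coordinate 0) unless an observed G0 point is
#' present; trajectories that never (or not durably) reach the threshold
#' are right-censored and carry no value.
#'
#' @param trajectory A [build_trajectory()] result (or a tibble with
#'   columns `generation`, `day`, `pct_on`).
#' @param axis `"generations"` or `"days"`: the coordinate on which to
#'   interpolate.
#' @param threshold Percent threshold (default 50).
#' @return A `halflife_estimate`: list with `value` (NA when censored),
#'   `axis`, `status` (`"interpolated"`, `"left_anchored"` or
#'   `"censored"`), `bracket` (two-row tibble of the points used),
#'   `smoothing_applied` and the group `key`.
#' @examples
#' traj <- tibble::tibble(generation = 0:3, day = c(0, 3.5, 7, 10.5),
#'                        pct_on = c(0, 20, 80, 100))
#' half_life(traj)$value  # 1.5: the 20 -> 80 chord crosses 50% midway
#' @export
half_life <- function(trajectory, axis = c("generations", "days"),
                      threshold = 50) {
  axis <- match.arg(axis)
  pts <- tibble::as_tibble(trajectory)
  if (nrow(pts) == 0) stop("empty trajectory", call. = FALSE)
  coord <- if (axis == "generations") pts$generation else pts$day
  sel <- select_bracket(pts$pct_on, threshold)
  key <- attr(trajectory, "key")
  if (sel$signal == "censored") {
    return(structure(list(
      value = NA_real_, axis = axis, status = "censored",
      bracket = NULL, smoothing_applied = sel$smoothing_applied,
      threshold = threshold, key = key), class = "halflife_estimate"))
  }
  if (sel$signal == "left_anchored") {
    bracket <- tibble::tibble(
      generation = c(0, pts$generation[1]),
      coordinate = c(0, coord[1]),
      pct_on = c(0, pts$pct_on[1])
    )
    status <- "left_anchored"
    smoothing <- FALSE
  } else {
    bracket <- tibble::tibble(
      generation = pts$generation[c(sel$below, sel$above)],
      coordinate = coord[c(sel$below, sel$above)],
      pct_on = pts$pct_on[c(sel$below, sel$above)]
    )
    status <- if (bracket$generation[1] == 0) "left_anchored" else
      "interpolated"
    smoothing <- sel$smoothing_applied
  }
  x_b <- bracket$coordinate[1]; v_b <- bracket$pct_on[1]
  x_a <- bracket$coordinate[2]; v_a <- bracket$pct_on[2]
  value <- x_b + (threshold - v_b) * (x_a - x_b) / (v_a - v_b)
  structure(list(value = value, axis = axis, status = status,
                 bracket = bracket, smoothing_applied = smoothing,
                 threshold = threshold, key = key),
            class = "halflife_estimate")
}

#' @export
print.halflife_estimate <- function(x, ...) {
  if (x$status == "censored") {
    cat(sprintf("half-life: censored (never reached %g%% ON)\n",
                x$threshold))
  } else {
    cat(sprintf("half-life: %.4g %s (%s%s)\n", x$value, x$axis, x$status,
                if (x$smoothing_applied) ", smoothed" else ""))
  }
  invisible(x)
}

#' Half-life table for a whole scoring table
#'
#' Runs the bracket-and-interpolate half-life estimator on every
#' (block, strain, environment, replicate) series of a scoring table.
#'
#' @param table A [scoring_table()].
#' @param environments List of [environment_scenario()] objects supplying
#'   the schedule and temperature of every environment label appearing in
#'   the table.
#' @param axis `"generations"` or `"days"`.
#' @param threshold Percent threshold (default 50).
#' @return A tibble with columns `block`, `strain`, `environment`,
#'   `replicate`, `axis`, `value`, `status`, `g_below`, `g_above`,
#'   `smoothing`.
#' @export
half_life_table <- function(table, environments = list(environment_scenario()),
                            axis = "generations", threshold = 50) {
  table <- as_scoring_table(table)
  env_ids <- vapply(environments, `[[`, character(1), "id")
  names(environments) <- env_ids
  present <- unique(table$environment)
  unknown <- setdiff(present, env_ids)
  if (length(unknown) > 0) {
    stop_stage("schedule", "no environment scenario for label(s): ",
               paste(unknown, collapse = ", "))
  }
  groups <- group_replicates(table)
  keys <- attr(groups, "keys")
  n <- length(groups)
  value <- g_below <- g_above <- rep(NA_real_, n)
  status <- character(n)
  smoothing <- logical(n)
  for (i in seq_len(n)) {
    g <- groups[[i]]
    env <- environments[[g$environment[1]]]
    traj <- build_trajectory(g, env$schedule, env$temperature)
    est <- half_life(traj, axis = axis, threshold = threshold)
    value[i] <- est$value
    status[i] <- est$status
    smoothing[i] <- est$smoothing_applied
    if (!is.null(est$bracket)) {
      g_below[i] <- est$bracket$generation[1]
      g_above[i] <- est$bracket$generation[2]
    }
  }
  dplyr::bind_cols(keys, tibble::tibble(
    axis = axis, value = value, status = status,
    g_below = g_below, g_above = g_above, smoothing = smoothing))
}

#' Summarize replicate trajectories
#'
#' Pointwise mean and sample standard deviation of percent-ON across the
#' replicates of one strain/environment, the summary drawn as lines with
#' SD error bars in desilencing figures.
#'
#' @param trajectories List of trajectories sharing a generation grid.
#' @return A tibble with columns `generation`, `day`, `mean_pct`,
#'   `sd_pct`, `n_rep` (SD is 0 for a single replicate).
#' @export
summarize_trajectories <- function(trajectories) {
  if (length(trajectories) < 1) stop("no trajectories", call. = FALSE)
  grids <- lapply(trajectories, function(t) t$generation)
  if (length(unique(lapply(grids, paste, collapse = ","))) != 1) {
    stop("trajectories are scored on different generation grids; ",
         "refusing to align or impute", call. = FALSE)
  }
  pct <- do.call(cbind, lapply(trajectories, function(t) t$pct_on))
  n <- ncol(pct)
  tibble::tibble(
    generation = trajectories[[1]]$generation,
    day = trajectories[[1]]$day,
    mean_pct = rowMeans(pct),
    sd_pct = if (n == 1) rep(0, nrow(pct)) else apply(pct, 1, sd),
    n_rep = n
  )
}

#' Per-strain trajectory summary of a scoring table
#'
#' @param table A [scoring_table()].
#' @param environments List of [environment_scenario()] objects.
#' @return A tibble with columns `block`, `strain`, `environment`,
#'   `generation`, `day`, `mean_pct`, `sd_pct`, `n_rep`: the mean and SD of
#'   the replicates within each block/strain/environment, one summary row
#'   per scored generation.
#' @export
trajectory_summary <- function(table,
                               environments = list(environment_scenario())) {
  table <- as_scoring_table(table)
  env_ids <- vapply(environments, `[[`, character(1), "id")
  names(environments) <- env_ids
  groups <- group_replicates(table)
  keys <- attr(groups, "keys")
  split_key <- paste(keys$block, keys$strain, keys$environment, sep = "\x1f")
  rows <- lapply(split(seq_along(groups), split_key), function(idx) {
    g1 <- groups[[idx[1]]]
    env <- environments[[g1$environment[1]]]
    if (is.null(env)) {
      stop_stage("schedule", "no environment scenario for label: ",
                 g1$environment[1])
    }
    trajs <- lapply(groups[idx], build_trajectory, schedule = env$schedule,
                    temperature = env$temperature)
    out <- summarize_trajectories(trajs)
    tibble::tibble(block = g1$block[1], strain = g1$strain[1],
                   environment = g1$environment[1], out)
  })
  dplyr::bind_rows(rows)
}
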
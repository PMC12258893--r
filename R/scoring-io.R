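#' Scoring tables
#'
#' A scoring table is the long-format record of a GFP silencing-memory assay:
#' one row per block x strain x environment x replicate x generation, holding
#' the number of scored individuals in each of the OFF, DIM and ON
#' fluorescence categories.  Generation 0 is the last generation exposed to
#' the RNAi trigger; generation 1 is the first trigger-free generation.
#' Rows at generation -1 (the first trigger generation) are accepted but
#' ignored by all analysis stages.
#'
#' @param x A data frame with columns `block`, `strain`, `environment`,
#'   `replicate`, `generation`, `n_off`, `n_on` and optionally `n_dim`
#'   (missing `n_dim` is treated as 0, for assays scored ON/OFF only).
#' @param metadata Optional named list of free-form provenance (block
#'   letters, dates, bacterial clone, ...).
#' @return A `scoring_table`: a tibble with the canonical columns in
#'   canonical order and a `metadata` attribute.
#' @examples
#' tbl <- scoring_table(data.frame(
#'   block = "C", strain = "N2", environment = "20C_OP50", replicate = 1L,
#'   generation = 1L, n_off = 90L, n_dim = 5L, n_on = 5L
#' ))
#' pct_gfp_positive(tbl$n_off, tbl$n_dim, tbl$n_on)
#' @export
scoring_table <- function(x, metadata = list()) {
  x <- as.data.frame(x)
  if (!"n_dim" %in% names(x)) x$n_dim <- 0L
  missing <- setdiff(scoring_columns(), names(x))
  if (length(missing) > 0) {
    stop("scoring table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[scoring_columns()]
  x$block <- as.character(x$block)
  x$strain <- as.character(x$strain)
  x$environment <- as.character(x$environment)
  out <- tibble::as_tibble(x)
  validate_scoring_table(out)
  for (col in c("replicate", "generation", "n_off", "n_dim", "n_on")) {
    out[[col]] <- as.integer(out[[col]])
  }
  structure(out, metadata = metadata,
            class = c("scoring_table", class(out)))
}

scoring_columns <- function() {
  c("block", "strain", "environment", "replicate", "generation",
    "n_off", "n_dim", "n_on")
}

validate_scoring_table <- function(x) {
  for (col in c("replicate", "generation", "n_off", "n_dim", "n_on")) {
    v <- x[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
      bad <- which(!is.finite(v) | is.na(v) | v != floor(v))[1]
      stop(sprintf("column '%s' must be integer-valued (row %d)", col,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  counts <- c("n_off", "n_dim", "n_on")
  for (col in counts) {
    if (any(x[[col]] < 0)) {
      stop(sprintf("negative count in column '%s' (row %d)", col,
                   which(x[[col]] < 0)[1]), call. = FALSE)
    }
  }
  total <- x$n_off + x$n_dim + x$n_on
  if (any(total < 1)) {
    stop(sprintf("no scored individuals at row %d (counts sum to zero)",
                 which(total < 1)[1]), call. = FALSE)
  }
  if (any(x$replicate < 1)) {
    stop(sprintf("replicate must be a positive integer (row %d)",
                 which(x$replicate < 1)[1]), call. = FALSE)
  }
  if (any(x$generation < -1)) {
    stop(sprintf("generation index below -1 at row %d",
                 which(x$generation < -1)[1]), call. = FALSE)
  }
  key <- paste(x$block, x$strain, x$environment, x$replicate, x$generation,
               sep = "\x1f")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf(
      "duplicate scoring key at rows %d and %d (%s / %s / %s / rep %s / G%s)",
      match(key[d], key), d, x$block[d], x$strain[d], x$environment[d],
      x$replicate[d], x$generation[d]), call. = FALSE)
  }
  invisible(x)
}

#' Read and write scoring tables
#'
#' The canonical on-disk dialect is UTF-8 CSV with header
#' `block,strain,environment,replicate,generation,n_off,n_dim,n_on`.
#' The `n_dim` column may be absent for two-category (ON/OFF) assays and is
#' then read as 0.  Row order is preserved; duplicate
#' (block, strain, environment, replicate, generation) keys are rejected.
#'
#' @param path Path to a CSV file.
#' @return `read_scoring_table()` returns a [scoring_table()];
#'   `write_scoring_table()` returns `path` invisibly.
#' @export
read_scoring_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- setdiff(scoring_columns(), "n_dim")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("scoring file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"n_dim" %in% names(raw)) raw$n_dim <- "0"
  for (col in c("replicate", "generation", "n_off", "n_dim", "n_on")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (nrow(raw) > 0 && any(is.na(v))) {
      stop(sprintf("column '%s' is not numeric at row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    }
    raw[[col]] <- v
  }
  scoring_table(raw)
}

#' @param table A [scoring_table()].
#' @rdname read_scoring_table
#' @export
write_scoring_table <- function(table, path) {
  table <- as_scoring_table(table)
  readr::write_csv(tibble::as_tibble(table)[scoring_columns()], path,
                   progress = FALSE)
  invisible(path)
}

as_scoring_table <- function(x) {
  if (inherits(x, "scoring_table")) return(x)
  scoring_table(x)
}

#' Split a scoring table into replicate series
#'
#' Partitions the table into one group per
#' (block, strain, environment, replicate) and sorts each group by
#' generation, the unit on which a half-life is estimated.
#'
#' @param table A [scoring_table()].
#' @return A named list of tibbles (one per group, sorted by generation)
#'   with a `keys` attribute holding the group keys as a tibble.
#' @export
group_replicates <- function(table) {
  table <- as_scoring_table(table)
  tbl <- tibble::as_tibble(table)
  if (nrow(tbl) == 0) {
    out <- list()
    attr(out, "keys") <- tibble::tibble(block = character(),
                                        strain = character(),
                                        environment = character(),
                                        replicate = integer())
    return(out)
  }
  tbl <- dplyr::arrange(tbl, .data$block, .data$strain, .data$environment,
                        .data$replicate, .data$generation)
  keys <- dplyr::distinct(tbl, .data$block, .data$strain, .data$environment,
                          .data$replicate)
  groups <- dplyr::group_split(
    dplyr::group_by(tbl, .data$block, .data$strain, .data$environment,
                    .data$replicate),
    .keep = TRUE
  )
  names(groups) <- vapply(groups, function(g) {
    paste(g$block[1], g$strain[1], g$environment[1], g$replicate[1],
          sep = "/")
  }, character(1))
  out <- as.list(groups)
  attr(out, "keys") <- keys
  out
}
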
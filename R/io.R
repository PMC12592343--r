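#' Read / write trajectory CSV files
#'
#' The on-disk schema is `agent_id,t,col,row` (integers; `t` in seconds,
#' multiples of the 5-s tick) or `agent_id,t,x_m,y_m` (continuous meters,
#' converted with [point_to_cell()] on read).
#'
#' @param path CSV file path.
#' @param grid A [grid_spec()] (used for validation / coordinate conversion).
#' @param dt Sampling interval in seconds.
#' @return A `trajectory_table`.
#' @export
read_trajectory_csv <- function(path, grid, dt = 5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("agent_id", "t", "col", "row") %in% names(df))) {
    trajectory_table(df$agent_id, df$t, df$col, df$row, grid, dt)
  } else if (all(c("agent_id", "t", "x_m", "y_m") %in% names(df))) {
    cells <- point_to_cell(df$x_m, df$y_m, grid)
    trajectory_table(df$agent_id, df$t, cells$col, cells$row, grid, dt)
  } else {
    stop("trajectory CSV needs columns agent_id,t,col,row or agent_id,t,x_m,y_m",
         call. = FALSE)
  }
}

#' @rdname read_trajectory_csv
#' @param table A `trajectory_table` to write.
#' @export
write_trajectory_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("agent_id", "t", "col", "row")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a corpus as plain text, one document per line
#'
#' @param corpus List of documents (from [build_corpus()]).
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, `[[`, character(1L), "text"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @param cfg The [corpus_config()] the corpus was built with (needed to
#'   recover role spans from the raw text).
#' @export
read_corpus <- function(path, cfg) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    words <- strsplit(trimws(l), "\\s+")[[1L]]
    roles <- ifelse(words == cfg$eos_token, "eos", substr(words, 1L, 1L))
    new_document(words, roles)
  })
}

#' Read a YAML run configuration
#'
#' Resolves the named model preset (if any) and builds the component config
#' objects. Recognised top-level blocks: `grid`, `corpus`, `model`, `train`,
#' `simulation`, `world`, `seed`.
#'
#' @param path YAML file path.
#' @return A list with any of `grid`, `corpus`, `model`, `train`,
#'   `simulation`, `world_args`, `seed` that the file defines.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  out <- list(seed = y$seed %||% 1L)
  if (!is.null(y$grid)) out$grid <- grid_from_config(y$grid)
  if (!is.null(y$corpus))
    out$corpus <- corpus_config(k = y$corpus$k %||% 2L,
                                absent_token = y$corpus$absent_token %||% "none",
                                eos_token = y$corpus$eos_token %||% "Z")
  if (!is.null(y$model)) {
    preset <- y$model$preset
    args <- y$model[setdiff(names(y$model), "preset")]
    out$model <- do.call(model_config, c(list(preset = preset), args))
  }
  if (!is.null(y$train)) out$train <- do.call(train_config, y$train)
  if (!is.null(y$simulation)) out$simulation <- do.call(simulation_config,
                                                        y$simulation)
  if (!is.null(y$world)) out$world_args <- y$world
  out
}

write_jsonl_log <- function(path, record) {
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}
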
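#' Corpus configuration
#'
#' Controls how multi-agent trajectory tables are serialised into symbolic
#' documents. Each timestep of a focal customer becomes `1 + k` role-prefixed
#' tokens: the focal position (prefix `"S"`) followed by the positions of its
#' `k` nearest neighbours in rank order (prefixes `"O"`, `"T"`, `"U"`). A
#' neighbour slot with no agent present carries the placeholder body
#' (`absent_token`), so frame arity is constant. `k = 0` yields the
#' non-interactive variant: documents contain only focal tokens.
#'
#' @param k Number of referenced neighbours, 0..3.
#' @param role_prefixes Ordered single-character prefixes, focal first.
#' @param absent_token Placeholder body for a missing neighbour; the whole
#'   word (prefix + body) is kept atomic by the sub-token codec.
#' @param eos_token Reserved end-of-trajectory word.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(k = 2L,
                          role_prefixes = c("S", "O", "T", "U")[seq_len(k + 1L)],
                          absent_token = "none",
                          eos_token = "Z") {
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > 3L)
    stop("`k` must be in 0..3", call. = FALSE)
  if (length(role_prefixes) != k + 1L || anyDuplicated(role_prefixes))
    stop("`role_prefixes` must be ", k + 1L, " distinct prefixes", call. = FALSE)
  if (any(nchar(role_prefixes) != 1L) || any(role_prefixes %in% letters))
    stop("role prefixes must be single characters outside the a-z code alphabet",
         call. = FALSE)
  structure(
    list(k = k, role_prefixes = role_prefixes,
         absent_token = absent_token, eos_token = eos_token),
    class = "corpus_config"
  )
}

#' Assemble and validate a trajectory table
#'
#' The canonical in-memory container: one row per (agent, tick) observation
#' with columns `agent_id`, `t` (seconds, multiples of the 5-s sampling
#' interval), `col`, `row` (0-based cell indices). Per agent, ticks must be
#' strictly increasing with no gaps.
#'
#' @param agent_id Vector of agent identifiers.
#' @param t Observation times in seconds.
#' @param col,row Cell indices.
#' @param grid Optional [grid_spec()]; if given, cells are range-checked.
#' @param dt Sampling interval in seconds (default 5).
#' @return A data.frame of class `trajectory_table` with attribute `dt`.
#' @export
trajectory_table <- function(agent_id, t, col, row, grid = NULL, dt = 5) {
  tab <- data.frame(agent_id = agent_id, t = as.numeric(t),
                    col = as.integer(col), row = as.integer(row))
  tab <- tab[order(tab$agent_id, tab$t), , drop = FALSE]
  rownames(tab) <- NULL
  if (any(tab$t %% dt != 0))
    stop("`t` values must be multiples of the sampling interval", call. = FALSE)
  by_gap <- tapply(tab$t, tab$agent_id, function(ts) {
    length(ts) > 1L && any(diff(ts) != dt)
  })
  if (any(unlist(by_gap)))
    stop("per-agent times must be consecutive multiples of dt (no gaps)",
         call. = FALSE)
  if (!is.null(grid) &&
      any(tab$col < 0L | tab$col >= grid$n_cols |
          tab$row < 0L | tab$row >= grid$n_rows))
    stop("cell index out of range for the grid", call. = FALSE)
  attr(tab, "dt") <- dt
  class(tab) <- c("trajectory_table", "data.frame")
  tab
}

table_dt <- function(table) {
  dt <- attr(table, "dt")
  if (is.null(dt)) 5 else dt
}

#' Resample raw timestamped points onto the regular tick grid
#'
#' Raw positioning records rarely land exactly on the sampling grid. Each tick
#' takes the nearest-in-time raw point; a tick with no point within `dt/2`
#' ends the trajectory. Time ties between two raw points are broken toward the
#' earlier point.
#'
#' @param raw A data.frame with columns `agent_id`, `t` (seconds), `col`,
#'   `row` (or `x_m`, `y_m`, converted via [point_to_cell()]).
#' @param grid A [grid_spec()].
#' @param dt Sampling interval in seconds.
#' @return A `trajectory_table`.
#' @export
resample_trajectory <- function(raw, grid, dt = 5) {
  if (nrow(raw) == 0L)
    return(trajectory_table(character(0), numeric(0), integer(0), integer(0),
                            grid, dt))
  if (!"col" %in% names(raw)) {
    cells <- point_to_cell(raw$x_m, raw$y_m, grid)
    raw$col <- cells$col; raw$row <- cells$row
  }
  out <- lapply(split(raw, raw$agent_id), function(a) {
    a <- a[order(a$t), , drop = FALSE]
    t0 <- max(0, round(min(a$t) / dt)) * dt
    ticks <- numeric(0); cols <- integer(0); rows <- integer(0)
    tt <- t0
    repeat {
      d <- abs(a$t - tt)
      i <- which.min(d)  # which.min takes the first minimum: earlier point wins ties
      if (d[i] > dt || tt > max(a$t) + dt / 2) break
      ticks <- c(ticks, tt); cols <- c(cols, a$col[i]); rows <- c(rows, a$row[i])
      tt <- tt + dt
    }
    data.frame(agent_id = rep(a$agent_id[1L], length(ticks)),
               t = ticks, col = cols, row = rows)
  })
  out <- do.call(rbind, out)
  trajectory_table(out$agent_id, out$t, out$col, out$row, grid, dt)
}

#' Rank an agent's nearest neighbours within one frame
#'
#' Neighbours are ordered by Euclidean distance between cell centers
#' (ascending, in meters); distance ties are broken by ascending `agent_id`.
#' If fewer than `k` other agents are present, trailing entries are `NA`
#' (absent markers).
#'
#' @param frame A data.frame of all agents present at one tick, with columns
#'   `agent_id`, `col`, `row`.
#' @param focal The focal `agent_id` (must be present in `frame`).
#' @param k Number of neighbours to return.
#' @param grid A [grid_spec()].
#' @return A data.frame with `k` rows: `agent_id`, `col`, `row`, `dist_m`
#'   (`NA` rows mark absent neighbours).
#' @export
nearest_neighbors <- function(frame, focal, k, grid) {
  i <- which(frame$agent_id == focal)
  if (length(i) != 1L)
    stop("focal agent not present (exactly once) in frame", call. = FALSE)
  out <- data.frame(agent_id = rep(NA_character_, k),
                    col = rep(NA_integer_, k), row = rep(NA_integer_, k),
                    dist_m = rep(NA_real_, k))
  if (k == 0L) return(out)
  others <- frame[-i, , drop = FALSE]
  if (nrow(others) > 0L) {
    d <- sqrt((others$col - frame$col[i])^2 +
              (others$row - frame$row[i])^2) * grid$cell_size_m
    ord <- order(d, as.character(others$agent_id))
    m <- min(k, nrow(others))
    sel <- ord[seq_len(m)]
    out$agent_id[seq_len(m)] <- as.character(others$agent_id[sel])
    out$col[seq_len(m)] <- others$col[sel]
    out$row[seq_len(m)] <- others$row[sel]
    out$dist_m[seq_len(m)] <- d[sel]
  }
  out
}

#' Build the symbolic document of one focal customer
#'
#' Per tick the focal position is emitted as `S<code>`, followed by the
#' neighbour positions in rank order (`O<code>`, `T<code>`, ...; absent slots
#' as e.g. `Onone`). The end-of-trajectory word is appended after the last
#' tick. Character spans per token are recorded so the loss mask can be
#' projected onto any sub-tokenisation.
#'
#' @param focal Focal `agent_id`.
#' @param table A `trajectory_table` containing the focal agent (and any
#'   others, used as neighbour context).
#' @param cfg A [corpus_config()].
#' @param grid A [grid_spec()].
#' @return An object of class `document`: list with `text`, `spans` (a
#'   data.frame `role`, `start_char`, `end_char`, 1-based inclusive),
#'   `agent_id`, and `words`.
#' @export
build_document <- function(focal, table, cfg, grid) {
  rows <- table[table$agent_id == focal, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("focal agent not present in table", call. = FALSE)
  rows <- rows[order(rows$t), , drop = FALSE]
  words <- character(0); roles <- character(0)
  for (j in seq_len(nrow(rows))) {
    frame <- table[table$t == rows$t[j], , drop = FALSE]
    words <- c(words, paste0(cfg$role_prefixes[1L],
                             encode_cell(rows$col[j], rows$row[j], grid)))
    roles <- c(roles, cfg$role_prefixes[1L])
    if (cfg$k > 0L) {
      nb <- nearest_neighbors(frame, focal, cfg$k, grid)
      for (q in seq_len(cfg$k)) {
        body <- if (is.na(nb$col[q])) cfg$absent_token else
          encode_cell(nb$col[q], nb$row[q], grid)
        words <- c(words, paste0(cfg$role_prefixes[q + 1L], body))
        roles <- c(roles, cfg$role_prefixes[q + 1L])
      }
    }
  }
  words <- c(words, cfg$eos_token)
  roles <- c(roles, "eos")
  new_document(words, roles, focal)
}

new_document <- function(words, roles, agent_id = NA_character_) {
  ends <- cumsum(nchar(words) + 1L) - 1L  # +1 for the separating space
  starts <- ends - nchar(words) + 1L
  structure(
    list(text = paste(words, collapse = " "),
         words = words,
         spans = data.frame(role = roles, start_char = starts, end_char = ends),
         agent_id = agent_id),
    class = "document"
  )
}

#' @export
print.document <- function(x, ...) {
  cat(sprintf("<document> agent %s, %d words\n%s\n", x$agent_id,
              length(x$words),
              if (nchar(x$text) > 120) paste0(substr(x$text, 1, 117), "...") else x$text))
  invisible(x)
}

#' Build documents for every agent in a table
#'
#' @inheritParams build_document
#' @param agents Optional subset of agent ids; defaults to all.
#' @return A list of [build_document()] documents.
#' @export
build_corpus <- function(table, cfg, grid, agents = NULL) {
  if (is.null(agents)) agents <- unique(table$agent_id)
  # index frames once: splitting by t dominates cost for large tables
  lapply(agents, function(a) build_document(a, table, cfg, grid))
}

#' Parse a document's text back into per-frame cell codes
#'
#' Inverse of [build_document()] at the symbolic level; used to check the
#' document grammar (every document splits into `1 + k` word frames plus the
#' final end word).
#'
#' @param text Document text (whitespace-separated words).
#' @param cfg A [corpus_config()].
#' @return A list with `frames` (character matrix, one row per tick, columns
#'   in role order; absent slots `NA`) and `has_eos`.
#' @export
parse_document <- function(text, cfg) {
  words <- strsplit(trimws(text), "\\s+")[[1L]]
  has_eos <- length(words) > 0L && words[length(words)] == cfg$eos_token
  if (has_eos) words <- words[-length(words)]
  arity <- cfg$k + 1L
  if (length(words) %% arity != 0L)
    stop("word count not a multiple of frame arity", call. = FALSE)
  n <- length(words) %/% arity
  m <- matrix(NA_character_, nrow = n, ncol = arity)
  for (q in seq_len(arity)) {
    w <- words[seq(q, length(words), by = arity)]
    pref <- substr(w, 1L, 1L)
    if (any(pref != cfg$role_prefixes[q]))
      stop("role prefix out of order at slot ", q, call. = FALSE)
    body <- substr(w, 2L, nchar(w))
    body[body == cfg$absent_token] <- NA_character_
    m[, q] <- body
  }
  list(frames = m, has_eos = has_eos)
}
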
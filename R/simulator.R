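#' Simulation configuration
#'
#' Settings for the agent-based generation loop. The store is populated by an
#' arrival process (fixed-interval by default, Poisson optionally); every
#' arriving agent is seeded with the first three positions of a donor
#' trajectory from `seed_pool`, then moves autoregressively under the trained
#' model, with the nearest-neighbour context recomputed from the live
#' simulation at every tick. The eight benchmark arrival rates are 0.15,
#' 0.30, 0.60, 1.20, 2.40, 4.00, 6.00 and 12.00 persons/min (9 to 720 per
#' hour).
#'
#' @param arrival_rate Persons per minute (> 0).
#' @param duration Minutes during which arrivals are admitted.
#' @param arrival_mode `"fixed"` (deterministic spacing) or `"poisson"`.
#' @param max_steps Maximum ticks an agent may stay before forced retirement;
#'   default: the longest stay the model can condition on given its context
#'   window.
#' @param temperature,top_k Sampling settings passed to [next_focal_token()].
#' @param seed Integer seed; every stochastic choice in the run derives from
#'   it (per-agent substreams make the result independent of agent iteration
#'   order).
#' @param warmup Warm-up policy for [equilibrium_window()]: `"auto"` or a
#'   fixed number of minutes.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(arrival_rate, duration,
                              arrival_mode = c("fixed", "poisson"),
                              max_steps = NULL, temperature = 1, top_k = 0L,
                              seed = 1L, warmup = "auto") {
  if (arrival_rate <= 0) stop("arrival_rate must be > 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  structure(
    list(arrival_rate = arrival_rate, duration = duration,
         arrival_mode = match.arg(arrival_mode),
         max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
         temperature = temperature, top_k = as.integer(top_k),
         seed = as.integer(seed), warmup = warmup),
    class = "simulation_config"
  )
}

#' Schedule customer arrivals
#'
#' Fixed-interval mode places one entry every `1/rate` minutes starting at
#' half an interval, rounded to the 5-s tick grid, producing exactly
#' `rate * duration` arrivals. Poisson mode draws exponential inter-arrival
#' times at the same rate.
#'
#' @param cfg A [simulation_config()].
#' @param dt Tick length in seconds.
#' @return Integer vector of entry ticks (0-based).
#' @export
schedule_arrivals <- function(cfg, dt = 5) {
  ticks_per_min <- 60 / dt
  if (cfg$arrival_mode == "fixed") {
    n <- floor(cfg$arrival_rate * cfg$duration + 1e-9)
    if (n < 1L) {
      warning("rate * duration < 1: empty arrival schedule")
      return(integer(0))
    }
    interval <- 1 / cfg$arrival_rate
    times_min <- interval / 2 + interval * (seq_len(n) - 1L)
    as.integer(round(times_min * ticks_per_min))
  } else {
    set.seed(cfg$seed)
    times <- cumsum(stats::rexp(ceiling(cfg$arrival_rate * cfg$duration * 3) + 10,
                                rate = cfg$arrival_rate))
    times <- times[times < cfg$duration]
    if (length(times) == 0L) warning("empty arrival schedule")
    as.integer(round(times * ticks_per_min))
  }
}

#' Sample a seed trajectory head from a donor pool
#'
#' Arriving agents are initialised with the first three observed positions of
#' a uniformly sampled donor trajectory (donors shorter than three ticks are
#' excluded).
#'
#' @param pool A `trajectory_table` of donor trajectories.
#' @param grid A [grid_spec()].
#' @return A data.frame of 3 rows (`col`, `row`).
#' @export
seed_agent <- function(pool, grid) {
  lens <- table(pool$agent_id)
  donors <- names(lens)[lens >= 3L]
  if (length(donors) == 0L)
    stop("seed pool has no trajectory of length >= 3", call. = FALSE)
  a <- donors[sample.int(length(donors), 1L)]
  rows <- pool[pool$agent_id == a, , drop = FALSE]
  rows <- rows[order(rows$t), , drop = FALSE][1:3, ]
  data.frame(col = rows$col, row = rows$row)
}

# per-agent RNG substream helpers: snapshot/restore .Random.seed so that
# results do not depend on the order agents are processed within a tick
with_agent_rng <- function(agent, expr) {
  old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", agent$rng, envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  res <- force(expr)
  agent$rng <- get(".Random.seed", envir = globalenv())
  res
}

new_sim_agent <- function(ckpt, id, entry_tick, seed_cells, stream_seed) {
  ag <- new.env(parent = emptyenv())
  ag$id <- id
  ag$entry_tick <- entry_tick
  ag$seed_cells <- seed_cells
  ag$history <- data.frame(col = integer(0), row = integer(0))
  ag$ids <- integer(0)          # the agent's full symbolic context so far
  ag$frame_starts <- integer(0) # id offsets where each frame begins
  ag$st <- decode_state(ckpt)
  ag$status <- "seeded"
  ag$reason <- NA_character_
  set.seed(stream_seed)
  ag$rng <- get(".Random.seed", envir = globalenv())
  ag
}

# append one frame (self + neighbour words) to an agent's context and cache
agent_append_frame <- function(ckpt, ag, self_code, nb_codes, append_self = TRUE) {
  cfg <- ckpt$corpus_config; codec <- ckpt$codec
  words <- character(0)
  if (append_self)
    words <- paste0(cfg$role_prefixes[1L], self_code)
  if (cfg$k > 0L) {
    for (q in seq_len(cfg$k)) {
      body <- if (is.na(nb_codes[q])) cfg$absent_token else nb_codes[q]
      words <- c(words, paste0(cfg$role_prefixes[q + 1L], body))
    }
  }
  ids <- unlist(lapply(words, encode_word, codec = codec), use.names = FALSE)
  if (append_self)
    ag$frame_starts <- c(ag$frame_starts, length(ag$ids) + 1L)
  if (length(ids) > 0L) {
    ensure_context_room(ckpt, ag, length(ids) + 8L)
    decode_append(ckpt, ag$st, ids)
    ag$ids <- c(ag$ids, ids)
  }
}

# head-truncate in whole frames and rebuild the cache when the context
# window would overflow
ensure_context_room <- function(ckpt, ag, needed) {
  Lmax <- ckpt$model_config$context_length
  if (length(ag$ids) + needed <= Lmax) return(invisible())
  target <- max(1L, length(ag$ids) + needed - Lmax %/% 2L)
  cut_at <- ag$frame_starts[ag$frame_starts >= target][1L]
  if (is.na(cut_at)) cut_at <- target
  ag$ids <- ag$ids[-seq_len(cut_at - 1L)]
  ag$frame_starts <- ag$frame_starts[ag$frame_starts >= cut_at] - cut_at + 1L
  ag$st <- decode_state(ckpt)
  if (length(ag$ids) > 0L) decode_append(ckpt, ag$st, ag$ids)
  invisible()
}

#' Run the agent-based simulation
#'
#' The synchronous generation loop: at each 5-s tick, (1) scheduled arrivals
#' enter (replaying their three seed positions over their first three ticks);
#' (2) every post-seed agent samples its next position — or the
#' end-of-trajectory token — from the model, conditioned on its own stored
#' context; (3) all staged moves are applied simultaneously, so no agent's
#' new position influences another agent's decision within the same tick;
#' (4) the new positions plus freshly ranked neighbour context are appended
#' to every active agent's context (each past frame keeps the neighbour
#' tokens that were actually in effect at that tick); (5) agents that emitted
#' EOS or hit `max_steps` retire into the completed table.
#'
#' @param cfg A [simulation_config()].
#' @param ckpt A trained [train_model()] checkpoint (carries codec, corpus
#'   config and grid).
#' @param seed_pool A `trajectory_table` of donor trajectories.
#' @param quiet Suppress progress messages.
#' @param collect_contexts Also return every completed agent's symbolic
#'   context (sub-token ids) for inspection; contexts may have been
#'   head-truncated if an agent outstayed the context window.
#' @return A list of class `sim_result`: `table` (completed
#'   `trajectory_table`), `log` (per-tick `active_counts`, `departures` by
#'   reason, arrival count, warm-up window), `config`, and optionally
#'   `contexts`.
#' @export
run_simulation <- function(cfg, ckpt, seed_pool, quiet = TRUE,
                           collect_contexts = FALSE) {
  grid <- ckpt$grid
  ccfg <- ckpt$corpus_config
  dt <- 5
  trie <- focal_token_trie(ckpt)
  subtok_per_word <- mean(rowSums(!is.na(trie$seqs)))
  max_steps <- cfg$max_steps %||% max(
    3L, floor(ckpt$model_config$context_length /
                ((1L + ccfg$k) * subtok_per_word)))

  set.seed(cfg$seed)
  arrivals <- schedule_arrivals(cfg, dt)
  seeds_heads <- lapply(seq_along(arrivals), function(i) seed_agent(seed_pool, grid))

  active <- list()
  completed <- list()
  contexts <- list()
  active_counts <- integer(0)
  dep_reasons <- c(eos = 0L, max_length = 0L)
  tick <- 0L
  next_arrival <- 1L
  hard_cap <- as.integer(cfg$duration * 60 / dt) + max_steps * 3L + 10L

  repeat {
    # (1) admissions
    while (next_arrival <= length(arrivals) && arrivals[next_arrival] <= tick) {
      id <- sprintf("sim_%05d", next_arrival)
      ag <- new_sim_agent(ckpt, id, tick, seeds_heads[[next_arrival]],
                          stream_seed = (cfg$seed * 10007L + next_arrival * 97L) %% 2147483629L + 1L)
      active[[id]] <- ag
      next_arrival <- next_arrival + 1L
    }

    # (2) decide moves from the pre-move snapshot; stage them
    staged <- list()
    for (id in names(active)) {
      ag <- active[[id]]
      age <- tick - ag$entry_tick   # 0-based tick index within the stay
      if (age < 3L) {
        staged[[id]] <- list(col = ag$seed_cells$col[age + 1L],
                             row = ag$seed_cells$row[age + 1L], eos = FALSE)
      } else {
        res <- with_agent_rng(ag, {
          ensure_context_room(ckpt, ag, 8L)
          next_focal_token(ckpt, ag$st, trie, cfg$temperature, cfg$top_k)
        })
        ag$ids <- c(ag$ids, res$ids)
        ag$frame_starts <- c(ag$frame_starts, length(ag$ids) - length(res$ids) + 1L)
        if (res$eos) {
          staged[[id]] <- list(eos = TRUE)
        } else {
          cell <- decode_code(res$code, grid)
          staged[[id]] <- list(col = cell$col, row = cell$row, eos = FALSE)
        }
      }
    }

    # (3) apply all moves simultaneously; retire EOS agents
    for (id in names(staged)) {
      ag <- active[[id]]
      s <- staged[[id]]
      if (isTRUE(s$eos)) {
        dep_reasons["eos"] <- dep_reasons["eos"] + 1L
        completed[[id]] <- retire_agent(ag, dt)
        if (collect_contexts) contexts[[id]] <- ag$ids
        active[[id]] <- NULL
      } else {
        ag$history <- rbind(ag$history, data.frame(col = s$col, row = s$row))
        ag$status <- "active"
      }
    }

    # (4) append the post-move frame (self + live neighbour context)
    if (length(active) > 0L) {
      snap <- data.frame(
        agent_id = names(active),
        col = vapply(active, function(a) a$history$col[nrow(a$history)], integer(1L)),
        row = vapply(active, function(a) a$history$row[nrow(a$history)], integer(1L)))
      for (id in names(active)) {
        ag <- active[[id]]
        self_code <- encode_cell(snap$col[snap$agent_id == id],
                                 snap$row[snap$agent_id == id], grid)
        nb_codes <- rep(NA_character_, max(1L, ccfg$k))
        if (ccfg$k > 0L) {
          nb <- nearest_neighbors(snap, id, ccfg$k, grid)
          ok <- !is.na(nb$col)
          nb_codes[ok] <- encode_cell(nb$col[ok], nb$row[ok], grid)
        }
        # the sampled self word is already in the context for generating
        # agents; seeded ticks still need it appended
        age <- tick - ag$entry_tick
        agent_append_frame(ckpt, ag, self_code, nb_codes,
                           append_self = age < 3L)
      }
    }

    # the recorded count makes agent a active at tick t iff
    # entry_tick(a) <= t <= last history tick of a
    active_counts <- c(active_counts, length(active))

    # (5) retire agents that have exhausted their stay budget
    for (id in names(active)) {
      ag <- active[[id]]
      if (nrow(ag$history) >= max_steps) {
        dep_reasons["max_length"] <- dep_reasons["max_length"] + 1L
        completed[[id]] <- retire_agent(ag, dt)
        if (collect_contexts) contexts[[id]] <- ag$ids
        active[[id]] <- NULL
      }
    }
    tick <- tick + 1L
    done_arrivals <- next_arrival > length(arrivals)
    past_duration <- tick * dt / 60 >= cfg$duration
    if (done_arrivals && past_duration && length(active) == 0L) break
    if (tick >= hard_cap) {
      if (length(active) > 0L) {
        warning(sprintf("hard cap reached with %d agents active; force-retiring",
                        length(active)))
        for (id in names(active)) {
          dep_reasons["max_length"] <- dep_reasons["max_length"] + 1L
          completed[[id]] <- retire_agent(active[[id]], dt)
          if (collect_contexts) contexts[[id]] <- active[[id]]$ids
          active[[id]] <- NULL
        }
      }
      break
    }
    if (!quiet && tick %% 120L == 0L)
      message(sprintf("tick %d: %d active, %d completed", tick,
                      length(active), length(completed)))
  }

  tab <- if (length(completed) > 0L) {
    all <- do.call(rbind, completed)
    trajectory_table(all$agent_id, all$t, all$col, all$row, grid, dt)
  } else {
    trajectory_table(character(0), numeric(0), integer(0), integer(0), grid, dt)
  }
  out <- list(table = tab,
              log = list(active_counts = active_counts,
                         departures = as.list(dep_reasons),
                         n_arrivals = length(arrivals),
                         equilibrium = if (length(active_counts))
                           equilibrium_window(active_counts) else NULL),
              config = cfg)
  if (collect_contexts) out$contexts <- contexts
  structure(out, class = "sim_result")
}

#' Generate a single focal agent against a recorded background
#'
#' The controlled-ablation mode: one model-driven focal agent moves through a
#' store whose other occupants replay a recorded trajectory table, so
#' interaction-aware and non-interactive models can be compared under
#' identical realistic densities without compounding model errors.
#'
#' @param ckpt A trained checkpoint.
#' @param background A `trajectory_table` replayed as the other agents.
#' @param entry_tick Tick (0-based) at which the focal agent enters.
#' @param seed_cells Data.frame of 3 rows (`col`, `row`): the replayed
#'   initial positions.
#' @param max_steps Maximum focal stay in ticks.
#' @param temperature,top_k Sampling settings.
#' @param seed Integer seed.
#' @return A data.frame `t`, `col`, `row` of the focal trajectory.
#' @export
replay_generate <- function(ckpt, background, entry_tick = 0L, seed_cells,
                            max_steps = 60L, temperature = 1, top_k = 0L,
                            seed = 1L) {
  grid <- ckpt$grid; ccfg <- ckpt$corpus_config
  dt <- 5
  stopifnot(nrow(seed_cells) == 3L)
  trie <- focal_token_trie(ckpt)
  set.seed(as.integer(seed))
  ag <- new_sim_agent(ckpt, "focal", entry_tick, seed_cells,
                      stream_seed = as.integer(seed) * 7919L %% 2147483629L + 1L)
  cols <- integer(0); rows <- integer(0)
  age <- 0L
  repeat {
    tick <- entry_tick + age
    if (age < 3L) {
      pos <- c(ag$seed_cells$col[age + 1L], ag$seed_cells$row[age + 1L])
    } else {
      res <- with_agent_rng(ag, {
        ensure_context_room(ckpt, ag, 8L)
        next_focal_token(ckpt, ag$st, trie, temperature, top_k)
      })
      ag$ids <- c(ag$ids, res$ids)
      ag$frame_starts <- c(ag$frame_starts,
                           length(ag$ids) - length(res$ids) + 1L)
      if (res$eos) break
      cell <- decode_code(res$code, grid)
      pos <- c(cell$col, cell$row)
    }
    cols <- c(cols, pos[1L]); rows <- c(rows, pos[2L])
    bg <- background[background$t == tick * dt,
                     c("agent_id", "col", "row"), drop = FALSE]
    snap <- rbind(data.frame(agent_id = "focal", col = pos[1L], row = pos[2L]),
                  bg)
    nb_codes <- rep(NA_character_, max(1L, ccfg$k))
    if (ccfg$k > 0L) {
      nb <- nearest_neighbors(snap, "focal", ccfg$k, grid)
      ok <- !is.na(nb$col)
      nb_codes[ok] <- encode_cell(nb$col[ok], nb$row[ok], grid)
    }
    agent_append_frame(ckpt, ag, encode_cell(pos[1L], pos[2L], grid),
                       nb_codes, append_self = age < 3L)
    age <- age + 1L
    if (age >= max_steps) break
  }
  data.frame(t = (entry_tick + seq_along(cols) - 1L) * dt,
             col = cols, row = rows)
}

retire_agent <- function(ag, dt) {
  n <- nrow(ag$history)
  if (n == 0L) return(NULL)
  data.frame(agent_id = ag$id, t = (ag$entry_tick + seq_len(n) - 1L) * dt,
             col = ag$history$col, row = ag$history$row)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d agents, %d ticks, departures eos=%d max_length=%d\n",
              length(unique(x$table$agent_id)), length(x$log$active_counts),
              x$log$departures$eos, x$log$departures$max_length))
  invisible(x)
}

#' Detect the post-warm-up equilibrium window
#'
#' Analyses exclude the initial transient before the active-agent count
#' stabilises. Default policy: the smallest tick from which the 10-minute
#' rolling mean of the active count stays within +/-10% of the mean over the
#' remainder of the run. If the series never stabilises, a fallback window
#' starting at twice the mean observed stay duration is returned with a
#' warning flag.
#'
#' @param active_counts Integer vector of per-tick active-agent counts.
#' @param dt Tick length in seconds.
#' @param window_min Rolling-window length in minutes.
#' @param tol Relative tolerance around the remaining-run mean.
#' @param mean_stay_ticks Mean stay in ticks (used by the fallback; default:
#'   a quarter of the series length).
#' @return A list with `start_tick`, `end_tick` (0-based, inclusive) and
#'   `stabilised` (logical).
#' @export
equilibrium_window <- function(active_counts, dt = 5, window_min = 10,
                               tol = 0.10, mean_stay_ticks = NULL) {
  n <- length(active_counts)
  if (n == 0L) stop("empty series", call. = FALSE)
  w <- min(n, max(1L, as.integer(round(window_min * 60 / dt))))
  roll <- stats::filter(active_counts, rep(1 / w, w), sides = 1)
  roll <- as.numeric(roll)
  roll[seq_len(min(w - 1L, n))] <- cumsum(active_counts)[seq_len(min(w - 1L, n))] /
    seq_len(min(w - 1L, n))
  # a window that only covers the tail (e.g. the drain-out after arrivals
  # stop) is not an equilibrium; require it to span at least half the run
  for (s in seq_len(max(1L, n %/% 2L))) {
    rest_mean <- mean(active_counts[s:n])
    band <- tol * max(rest_mean, 1e-9)
    if (all(abs(roll[s:n] - rest_mean) <= band + 1e-12))
      return(list(start_tick = s - 1L, end_tick = n - 1L, stabilised = TRUE))
  }
  fallback <- if (is.null(mean_stay_ticks)) max(1L, n %/% 4L)
  else as.integer(2L * mean_stay_ticks)
  list(start_tick = min(fallback, n - 1L), end_tick = n - 1L,
       stabilised = FALSE)
}

#' Restrict a trajectory table to an equilibrium window
#'
#' Keeps agents whose entire stay falls inside `[start_tick, end_tick]`.
#'
#' @param table A `trajectory_table`.
#' @param win A window from [equilibrium_window()].
#' @param dt Tick seconds.
#' @return A filtered `trajectory_table`.
#' @export
filter_equilibrium <- function(table, win, dt = 5) {
  lo <- win$start_tick * dt; hi <- win$end_tick * dt
  by_agent <- tapply(table$t, table$agent_id, function(ts)
    min(ts) >= lo && max(ts) <= hi)
  keep <- names(by_agent)[unlist(by_agent)]
  out <- table[table$agent_id %in% keep, , drop = FALSE]
  attr(out, "dt") <- attr(table, "dt")
  class(out) <- class(table)
  out
}
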
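#' World configuration for the rule-based synthetic crowd generator
#'
#' The generator stands in for unavailable real indoor-positioning data: it
#' produces 5-s-sampled, goal-directed shopping trajectories with three
#' planted, labelled interaction effects — proximity-triggered slowdown,
#' proximity-triggered rerouting, and density-triggered early disengagement —
#' so that downstream models have a known, recoverable social signal. It is
#' deliberately a simple cellular rule system, mechanically unrelated to the
#' transformer it generates training data for, so model-vs-truth agreement is
#' a genuine recovery test.
#'
#' Defaults define the "desk" world: a 16 x 16 grid of 0.5-m cells with the
#' entrance/exit at the bottom edge, agents visiting 1-3 goal cells at about
#' one cell per tick (0.1 m/s), halving their move probability when another
#' agent is within 1 m, detouring orthogonally with probability 0.3 under the
#' same proximity, and abandoning remaining goals with probability 0.05 per
#' tick when the local 3x3 density reaches 3.
#'
#' @param grid A [grid_spec()].
#' @param entry_cells Data.frame (`col`, `row`) of entrance cells.
#' @param exit_cells Data.frame of exit cells (defaults to the entrances).
#' @param n_goals_range Integer range of goal cells per agent.
#' @param move_prob Base probability of stepping (vs browsing in place).
#' @param r_slow_m Slowdown radius in meters (0 disables).
#' @param slow_factor Multiplier on `move_prob` when a neighbour is within
#'   `r_slow_m`; in (0, 1].
#' @param r_turn_m Reroute radius in meters (0 disables).
#' @param p_turn Probability of replacing the goal-directed step by an
#'   orthogonal detour when a neighbour is within `r_turn_m`.
#' @param disengage_density 3x3 local-density threshold (>= 2) that can
#'   trigger early disengagement (0 disables).
#' @param p_disengage Per-tick probability of dropping all remaining goals at
#'   or above the threshold.
#' @param arrival_rate Persons per minute.
#' @param arrival_mode `"poisson"` (default: the real process being emulated)
#'   or `"fixed"`.
#' @param n_agents Total agents to generate.
#' @param step_noise Probability a step goes to a uniformly random adjacent
#'   cell instead of the greedy goal-directed one.
#' @param max_stay_ticks Safety cap on stay length.
#' @param seed Integer seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(grid = grid_spec(depth = 4L, cell_size_m = 0.5),
                         entry_cells = data.frame(col = 7:8, row = 0L),
                         exit_cells = entry_cells,
                         n_goals_range = c(1L, 3L),
                         move_prob = 0.9,
                         r_slow_m = 1.0, slow_factor = 0.5,
                         r_turn_m = 1.0, p_turn = 0.3,
                         disengage_density = 3L, p_disengage = 0.05,
                         arrival_rate = 1.0,
                         arrival_mode = c("poisson", "fixed"),
                         n_agents = 100L, step_noise = 0.1,
                         max_stay_ticks = 120L, seed = 1L) {
  stopifnot(r_slow_m >= 0, r_turn_m >= 0, slow_factor > 0, slow_factor <= 1,
            p_turn >= 0, p_turn <= 1, p_disengage >= 0, p_disengage <= 1,
            move_prob > 0, move_prob <= 1, arrival_rate >= 0, n_agents >= 0)
  structure(
    list(grid = grid, entry_cells = entry_cells, exit_cells = exit_cells,
         n_goals_range = as.integer(n_goals_range), move_prob = move_prob,
         r_slow_m = r_slow_m, slow_factor = slow_factor, r_turn_m = r_turn_m,
         p_turn = p_turn, disengage_density = as.integer(disengage_density),
         p_disengage = p_disengage, arrival_rate = arrival_rate,
         arrival_mode = match.arg(arrival_mode), n_agents = as.integer(n_agents),
         step_noise = step_noise, max_stay_ticks = as.integer(max_stay_ticks),
         seed = as.integer(seed)),
    class = "world_config"
  )
}

clampi <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic ground-truth crowd
#'
#' Runs the rule-based world tick by tick. Each agent enters at an entry
#' cell, walks greedily (8-neighbourhood, with tie-break noise) through its
#' sampled goal cells, then heads to an exit cell and leaves. Per tick, in
#' order: early disengagement (local 3x3 density at or above the threshold
#' drops remaining goals with probability `p_disengage`), slowdown (a
#' neighbour within `r_slow_m` reduces the move probability by
#' `slow_factor`), reroute (a neighbour within `r_turn_m` replaces the step
#' with an orthogonal detour with probability `p_turn`). Every tick carries
#' exactly one rule label: `free`, `slowed`, `rerouted` or `disengaged`.
#'
#' @param cfg A [world_config()].
#' @return A list of class `world`: `table` (a `trajectory_table`), `labels`
#'   (data.frame `agent_id`, `t`, `rule`), `config`.
#' @export
generate_world <- function(cfg) {
  grid <- cfg$grid
  set.seed(cfg$seed)
  dt <- 5
  if (cfg$n_agents == 0L || cfg$arrival_rate == 0)
    return(structure(list(
      table = trajectory_table(character(0), numeric(0), integer(0),
                               integer(0), grid, dt),
      labels = data.frame(agent_id = character(0), t = numeric(0),
                          rule = character(0)),
      config = cfg), class = "world"))

  ticks_per_min <- 60 / dt
  inter <- if (cfg$arrival_mode == "fixed")
    rep(1 / cfg$arrival_rate, cfg$n_agents)
  else stats::rexp(cfg$n_agents, rate = cfg$arrival_rate)
  entry_ticks <- as.integer(round(cumsum(inter) * ticks_per_min))

  interior <- expand.grid(col = 1:(grid$n_cols - 2L), row = 2:(grid$n_rows - 2L))
  agents <- lapply(seq_len(cfg$n_agents), function(i) {
    ng <- sample(cfg$n_goals_range[1L]:cfg$n_goals_range[2L], 1L)
    gix <- sample(nrow(interior), ng)
    e <- cfg$entry_cells[sample(nrow(cfg$entry_cells), 1L), ]
    x <- cfg$exit_cells[sample(nrow(cfg$exit_cells), 1L), ]
    list(id = sprintf("gt_%05d", i), entry = entry_ticks[i],
         col = as.integer(e$col), row = as.integer(e$row),
         goals = interior[gix, , drop = FALSE],
         exit = data.frame(col = as.integer(x$col), row = as.integer(x$row)),
         hist_col = integer(0), hist_row = integer(0), labels = character(0),
         alive = FALSE, done = FALSE)
  })
  names(agents) <- vapply(agents, `[[`, character(1L), "id")

  pending <- order(entry_ticks)
  next_in <- 1L
  active_ids <- character(0)
  tick <- 0L
  max_tick <- max(entry_ticks) + cfg$max_stay_ticks * 3L + 10L
  r_slow_c <- cfg$r_slow_m / grid$cell_size_m
  r_turn_c <- cfg$r_turn_m / grid$cell_size_m

  while ((next_in <= length(pending) || length(active_ids) > 0L) &&
         tick <= max_tick) {
    while (next_in <= length(pending) &&
           agents[[pending[next_in]]]$entry <= tick) {
      ai <- pending[next_in]
      agents[[ai]]$alive <- TRUE
      agents[[ai]]$hist_col <- agents[[ai]]$col
      agents[[ai]]$hist_row <- agents[[ai]]$row
      agents[[ai]]$labels <- "free"
      active_ids <- c(active_ids, agents[[ai]]$id)
      next_in <- next_in + 1L
    }
    if (length(active_ids) == 0L) { tick <- tick + 1L; next }

    cols <- vapply(agents[active_ids], `[[`, integer(1L), "col")
    rows <- vapply(agents[active_ids], `[[`, integer(1L), "row")
    departures <- character(0)
    for (j in seq_along(active_ids)) {
      id <- active_ids[j]
      ag <- agents[[id]]
      if (length(ag$hist_col) == 0L || tick == ag$entry) { next }  # entry tick already logged
      # neighbour geometry from the synchronous snapshot
      label <- "free"
      nd <- if (length(active_ids) > 1L)
        min(sqrt((cols[-j] - ag$col)^2 + (rows[-j] - ag$row)^2)) else Inf
      dens <- sum(abs(cols - ag$col) <= 1L & abs(rows - ag$row) <= 1L)
      # early disengagement: drop remaining goals, head for the exit
      if (cfg$disengage_density > 0L && nrow(ag$goals) > 0L &&
          dens >= cfg$disengage_density &&
          stats::runif(1) < cfg$p_disengage) {
        ag$goals <- ag$goals[0L, , drop = FALSE]
        label <- "disengaged"
      }
      target <- if (nrow(ag$goals) > 0L) ag$goals[1L, ] else ag$exit
      p_move <- cfg$move_prob
      slowed <- FALSE
      if (cfg$r_slow_m > 0 && nd <= r_slow_c + 1e-9) {
        p_move <- p_move * cfg$slow_factor
        slowed <- TRUE
      }
      if (stats::runif(1) < p_move) {
        dc <- sign(target$col - ag$col); dr <- sign(target$row - ag$row)
        if (cfg$r_turn_m > 0 && nd <= r_turn_c + 1e-9 &&
            stats::runif(1) < cfg$p_turn && (dc != 0L || dr != 0L)) {
          # orthogonal detour: rotate the intended step by 90 degrees
          rot <- if (stats::runif(1) < 0.5) c(-dr, dc) else c(dr, -dc)
          dc <- rot[1L]; dr <- rot[2L]
          if (label == "free") label <- "rerouted"
        } else if (stats::runif(1) < cfg$step_noise) {
          dc <- sample(-1:1, 1L); dr <- sample(-1:1, 1L)
        }
        ag$col <- as.integer(clampi(ag$col + dc, 0L, grid$n_cols - 1L))
        ag$row <- as.integer(clampi(ag$row + dr, 0L, grid$n_rows - 1L))
      } else if (slowed && label == "free") {
        label <- "slowed"
      }
      # goal bookkeeping
      if (nrow(ag$goals) > 0L && ag$col == ag$goals$col[1L] &&
          ag$row == ag$goals$row[1L])
        ag$goals <- ag$goals[-1L, , drop = FALSE]
      at_exit <- nrow(ag$goals) == 0L &&
        any(ag$col == cfg$exit_cells$col & ag$row == cfg$exit_cells$row)
      ag$hist_col <- c(ag$hist_col, ag$col)
      ag$hist_row <- c(ag$hist_row, ag$row)
      ag$labels <- c(ag$labels, label)
      if (at_exit || length(ag$hist_col) >= cfg$max_stay_ticks) {
        ag$done <- TRUE
        departures <- c(departures, id)
      }
      agents[[id]] <- ag
    }
    active_ids <- setdiff(active_ids, departures)
    tick <- tick + 1L
  }

  rows_out <- lapply(agents, function(ag) {
    n <- length(ag$hist_col)
    if (n == 0L) return(NULL)
    data.frame(agent_id = ag$id, t = (ag$entry + seq_len(n) - 1L) * dt,
               col = ag$hist_col, row = ag$hist_row, rule = ag$labels)
  })
  all <- do.call(rbind, rows_out)
  structure(
    list(table = trajectory_table(all$agent_id, all$t, all$col, all$row,
                                  grid, dt),
         labels = data.frame(agent_id = all$agent_id, t = all$t,
                             rule = all$rule),
         config = cfg),
    class = "world"
  )
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("<world> %d agents, %d observations; rules: %s\n",
              length(unique(x$table$agent_id)), nrow(x$table),
              paste(names(table(x$labels$rule)), table(x$labels$rule),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Split a trajectory table by agent
#'
#' Disjoint, seeded split into train / validation / seed-pool tables.
#'
#' @param table A `trajectory_table`.
#' @param fractions Numeric length-3 vector summing to 1.
#' @param seed Integer seed.
#' @return A list of three `trajectory_table`s: `train`, `validation`,
#'   `seed_pool`.
#' @export
split_corpus <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must be 3 non-negative numbers summing to 1",
         call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sample(unique(table$agent_id))
  n <- length(ids)
  n1 <- round(fractions[1L] * n)
  n2 <- round(fractions[2L] * n)
  grp <- list(train = ids[seq_len(n1)],
              validation = if (n2 > 0L) ids[n1 + seq_len(min(n2, n - n1))] else character(0),
              seed_pool = if (n1 + n2 < n) ids[(n1 + n2 + 1L):n] else character(0))
  pick <- function(sel) {
    out <- table[table$agent_id %in% sel, , drop = FALSE]
    attr(out, "dt") <- attr(table, "dt")
    class(out) <- class(table)
    out
  }
  lapply(grp, pick)
}
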
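#' Per-tick active-agent counts of a trajectory table
#'
#' @param table A `trajectory_table`.
#' @return Integer vector indexed by tick (from tick 0 to the last observed).
#' @export
active_count_series <- function(table) {
  dt <- table_dt(table)
  if (nrow(table) == 0L) return(integer(0))
  ticks <- table$t / dt
  tabulate(ticks + 1L, nbins = max(ticks) + 1L)
}

# crowding-stay quadratic over per-agent responses pooled across several
# tables (each table's concurrent counts are computed separately, so tables
# from different runs never alias each other's clocks)
pooled_crowding <- function(tables, grid) {
  do.call(rbind, lapply(tables, crowding_response, grid = grid))
}

#' Summary statistics of one simulated condition
#'
#' Means of in-store count, travel distance, stay duration and velocity over
#' an (equilibrium-filtered) trajectory table; the per-condition summary used
#' to compare crowding conditions.
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @return A one-row data.frame: `avg_count`, `distance_m`, `stay_min`,
#'   `speed_ms`, `n_agents`.
#' @export
condition_summary <- function(table, grid) {
  sd_tab <- stay_and_distance(table, grid)
  counts <- active_count_series(table)
  data.frame(avg_count = mean(counts[counts > 0]),
             distance_m = mean(sd_tab$distance_m),
             stay_min = mean(sd_tab$stay_min),
             speed_ms = mean(sd_tab$speed_ms, na.rm = TRUE),
             n_agents = nrow(sd_tab))
}

equilibrium_filter <- function(table) {
  if (nrow(table) == 0L) return(table)
  win <- equilibrium_window(active_count_series(table))
  filter_equilibrium(table, win)
}

#' End-to-end behaviour-recovery experiment
#'
#' The full pipeline at CPU scale on the synthetic desk world: generate
#' ground truth with the planted slowdown / reroute / disengagement rules,
#' build interaction-aware (`k = 2`) and non-interactive (`k = 0`) corpora
#' from the same trajectories, train one model per corpus, simulate both
#' models across arrival-rate conditions, and measure whether the simulated
#' crowds reproduce the planted effects:
#'
#' * `speed_density`: mean simulated speed by local density — congestion
#'   should slow agents down (density >= 3 slower than density 1);
#' * `turn_ratio`: big-turn ratio near (< 1 m) vs far (>= 2 m) from the
#'   nearest agent — evasive turning should be proximity-linked;
#' * `rmse_stay` for both models against ground truth — the interaction-aware
#'   model should track the crowding-stay curve better than the
#'   non-interactive one.
#'
#' @param seed Integer master seed; all world, split, training and simulation
#'   seeds derive from it.
#' @param n_train_agents Ground-truth agents per training arrival-rate
#'   condition.
#' @param train_rates Arrival rates (persons/min) of the training worlds.
#' @param sim_rates Arrival-rate conditions to simulate and compare.
#' @param sim_agents Approximate arrivals per simulated condition (sets each
#'   condition's duration to `sim_agents / rate`).
#' @param gt_agents Hold-out ground-truth agents per condition for the
#'   comparison tables.
#' @param mc A [model_config()] without `vocab_size` (filled from the codec).
#' @param tc_args Overrides for the desk [train_config()] recipe.
#' @param vocab_budget Sub-token vocabulary size.
#' @param temperature Sampling temperature for simulation.
#' @param quiet Suppress progress messages.
#' @return A list with `signs` (logical: `speed_density`, `turn_ratio`,
#'   `rmse_order`), `stats` (the named numbers behind them), `summaries`
#'   (per-condition [condition_summary()] rows for the k = 2 model),
#'   `checkpoints` (k2/k0), `sims`, `gt`.
#' @export
recovery_experiment <- function(seed = 1L,
                                n_train_agents = 40L,
                                train_rates = c(0.3, 1.2, 2.4),
                                sim_rates = c(0.3, 2.4),
                                sim_agents = c(30L, 60L),
                                gt_agents = 60L,
                                mc = model_config("desk"),
                                tc_args = list(),
                                vocab_budget = 200L,
                                temperature = 1,
                                quiet = TRUE) {
  seed <- as.integer(seed)
  grid <- grid_spec(depth = 4L, cell_size_m = 0.5)
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- ground truth: training worlds across crowding conditions ------------
  train_worlds <- lapply(seq_along(train_rates), function(i) {
    w <- generate_world(world_config(grid = grid, arrival_rate = train_rates[i],
                                     n_agents = n_train_agents,
                                     seed = seed * 131L + i))
    # distinct worlds must not share agent ids once tables are pooled
    w$table$agent_id <- paste0("r", i, "_", w$table$agent_id)
    w$labels$agent_id <- paste0("r", i, "_", w$labels$agent_id)
    w
  })
  splits <- lapply(seq_along(train_worlds), function(i)
    split_corpus(train_worlds[[i]]$table, c(0.85, 0, 0.15),
                 seed = seed * 17L + i))
  seed_pool <- do.call(rbind, lapply(splits, function(s)
    as.data.frame(s$seed_pool)))
  seed_pool <- trajectory_table(seed_pool$agent_id, seed_pool$t,
                                seed_pool$col, seed_pool$row, grid)

  # --- corpora and codec (shared word alphabet across k) -------------------
  cfgs <- list(k2 = corpus_config(k = 2L), k0 = corpus_config(k = 0L))
  corpora <- lapply(cfgs, function(cc)
    unlist(lapply(splits, function(s)
      build_corpus(s$train, cc, grid)), recursive = FALSE))
  say("corpus: %d documents per k", length(corpora$k2))
  codecs <- lapply(names(cfgs), function(nm)
    train_codec(corpora[[nm]], vocab_budget = vocab_budget, cfg = cfgs[[nm]],
                grid = grid))
  names(codecs) <- names(cfgs)

  # --- train one model per context width -----------------------------------
  tc_base <- list(learning_rate = 1e-3, batch_size = 6L, max_epochs = 12L,
                  patience = 2L, val_fraction = 0.12, seed = seed)
  tc_base[names(tc_args)] <- tc_args
  tc <- do.call(train_config, tc_base)
  ckpts <- lapply(names(cfgs), function(nm) {
    mck <- mc; mck$vocab_size <- length(codecs[[nm]]$vocab)
    ex <- lapply(corpora[[nm]], encode_with_mask, codec = codecs[[nm]],
                 cfg = cfgs[[nm]])
    say("training %s ...", nm)
    train_model(ex, mck, tc, codec = codecs[[nm]], cfg = cfgs[[nm]],
                grid = grid, quiet = quiet)
  })
  names(ckpts) <- names(cfgs)

  # --- hold-out ground truth and simulations per condition -----------------
  gt <- lapply(seq_along(sim_rates), function(i)
    equilibrium_filter(generate_world(world_config(
      grid = grid, arrival_rate = sim_rates[i], n_agents = gt_agents,
      seed = seed * 977L + i))$table))
  sims <- lapply(names(ckpts), function(nm) {
    lapply(seq_along(sim_rates), function(i) {
      sc <- simulation_config(
        arrival_rate = sim_rates[i],
        duration = ceiling(sim_agents[min(i, length(sim_agents))] / sim_rates[i]),
        temperature = temperature, seed = seed * 389L + i)
      say("simulating %s at %.2f /min ...", nm, sim_rates[i])
      equilibrium_filter(run_simulation(sc, ckpts[[nm]], seed_pool)$table)
    })
  })
  names(sims) <- names(ckpts)

  # --- planted-effect recovery ---------------------------------------------
  pool_tables <- function(tabs) {
    all <- do.call(rbind, lapply(seq_along(tabs), function(i) {
      d <- as.data.frame(tabs[[i]])
      d$agent_id <- paste0("c", i, "_", d$agent_id)
      d
    }))
    all
  }
  k2_pool <- pool_tables(sims$k2)
  dens_parts <- lapply(sims$k2, speed_by_density, grid = grid)
  dens <- data.frame(
    density = dens_parts[[1L]]$density,
    n_obs = Reduce(`+`, lapply(dens_parts, `[[`, "n_obs")))
  wsum <- Reduce(`+`, lapply(dens_parts, function(d)
    ifelse(d$n_obs > 0, d$mean_speed_ms * d$n_obs, 0)))
  dens$mean_speed_ms <- ifelse(dens$n_obs > 0, wsum / dens$n_obs, NA_real_)
  speed_lo <- dens$mean_speed_ms[1L]
  hi_n <- sum(dens$n_obs[dens$density >= 3L])
  speed_hi <- if (hi_n > 0)
    sum(dens$mean_speed_ms[dens$density >= 3L] * dens$n_obs[dens$density >= 3L],
        na.rm = TRUE) / hi_n else NA_real_

  turn_parts <- lapply(sims$k2, function(tab)
    turn_ratio_by_proximity(tab, grid, bins = c(0, 1, 2, 5)))
  near_big <- sum(vapply(turn_parts, function(tp) tp$by_bin$n_big[1L], numeric(1)))
  near_n <- sum(vapply(turn_parts, function(tp) tp$by_bin$n_turns[1L], numeric(1)))
  far_big <- sum(vapply(turn_parts, function(tp)
    sum(tp$by_bin$n_big[tp$by_bin$bin_lo >= 2]), numeric(1)))
  far_n <- sum(vapply(turn_parts, function(tp)
    sum(tp$by_bin$n_turns[tp$by_bin$bin_lo >= 2]), numeric(1)))
  turn_near <- if (near_n > 0) near_big / near_n else NA_real_
  turn_far <- if (far_n > 0) far_big / far_n else NA_real_

  cr_gt <- pooled_crowding(gt, grid)
  cr_k2 <- pooled_crowding(sims$k2, grid)
  cr_k0 <- pooled_crowding(sims$k0, grid)
  grid_x <- sort(Reduce(intersect, list(unique(cr_gt$crowding),
                                        unique(cr_k2$crowding),
                                        unique(cr_k0$crowding))))
  enough <- function(cr) length(unique(cr$crowding)) >= 3L
  rmse_k2 <- rmse_k0 <- NA_real_
  if (enough(cr_gt) && enough(cr_k2) && enough(cr_k0) && length(grid_x) > 0L) {
    fit_gt <- fit_quadratic(cr_gt$crowding, cr_gt$stay_min)
    rmse_k2 <- rmse_between_fits(fit_gt, fit_quadratic(cr_k2$crowding,
                                                       cr_k2$stay_min), grid_x)
    rmse_k0 <- rmse_between_fits(fit_gt, fit_quadratic(cr_k0$crowding,
                                                       cr_k0$stay_min), grid_x)
  }

  summaries <- do.call(rbind, lapply(seq_along(sim_rates), function(i)
    cbind(data.frame(rate = sim_rates[i]),
          condition_summary(sims$k2[[i]], grid))))

  list(
    signs = list(
      speed_density = isTRUE(speed_hi < speed_lo),
      turn_ratio = isTRUE(turn_near > turn_far),
      rmse_order = isTRUE(rmse_k2 < rmse_k0)),
    stats = list(speed_density1 = speed_lo, speed_density3plus = speed_hi,
                 turn_ratio_near = turn_near, turn_ratio_far = turn_far,
                 rmse_stay_k2 = rmse_k2, rmse_stay_k0 = rmse_k0,
                 crowding_grid = grid_x),
    summaries = summaries,
    checkpoints = ckpts, sims = sims, gt = gt, seed_pool = seed_pool,
    speed_density_table = dens)
}
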
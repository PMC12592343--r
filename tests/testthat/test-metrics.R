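test_that("occupancy counts each observation once and adds over tables", {
  g <- desk_grid()
  parked <- trajectory_table(rep("p", 10), seq(0, 45, 5), rep(3L, 10),
                             rep(7L, 10), g)
  om <- occupancy(parked, g)
  expect_equal(om$freq[8L, 4L], 1)        # row 7, col 3 (1-based matrix)
  expect_equal(sum(om$counts), 10L)

  t2 <- random_table(g, n_agents = 4L, seed = 3)
  both <- rbind(as.data.frame(parked), as.data.frame(t2))
  om_both <- occupancy(both, g)
  expect_equal(om_both$counts, occupancy(parked, g)$counts + occupancy(t2, g)$counts)
  expect_equal(sum(om_both$freq), 1)
})

test_that("long-run random-walk occupancy approaches its stationary law", {
  # independent uniform cell draws: stationary distribution is uniform
  g <- grid_spec(2, cell_size_m = 1)
  set.seed(60)
  n <- 6000L
  tab <- data.frame(agent_id = "w", t = 5 * (0:(n - 1L)),
                    col = sample(0:3, n, TRUE), row = sample(0:3, n, TRUE))
  tab <- trajectory_table(tab$agent_id, tab$t, tab$col, tab$row, g)
  om <- occupancy(tab, g)
  expect_true(max(abs(om$freq - 1 / 16)) < 0.015)
})

test_that("stay, distance and speed follow the worked arithmetic", {
  g <- grid_spec(4, cell_size_m = 0.25)
  # 12 one-cell eastward steps over 12 ticks of 5 s
  tab <- trajectory_table(rep("e", 13), seq(0, 60, 5), 0:12, rep(1L, 13), g)
  sd_ <- stay_and_distance(tab, g)
  expect_equal(sd_$distance_m, 3.0)
  expect_equal(sd_$stay_min, 1.0)
  expect_equal(sd_$speed_ms, 0.05)

  still <- trajectory_table(rep("s", 5), seq(0, 20, 5), rep(2L, 5),
                            rep(2L, 5), g)
  expect_equal(stay_and_distance(still, g)$distance_m, 0)
  one <- trajectory_table("o", 0, 1L, 1L, g)
  sd1 <- stay_and_distance(one, g)
  expect_equal(sd1$stay_min, 0)
  expect_true(is.na(sd1$speed_ms))
})

test_that("distances match a naive per-step oracle on random tables", {
  g <- desk_grid()
  tab <- random_table(g, n_agents = 5L, seed = 14)
  sd_ <- stay_and_distance(tab, g)
  for (a in unique(tab$agent_id)) {
    rows <- tab[tab$agent_id == a, ]
    rows <- rows[order(rows$t), ]
    tot <- 0
    for (j in seq_len(nrow(rows) - 1L))
      tot <- tot + sqrt((rows$col[j + 1] - rows$col[j])^2 +
                        (rows$row[j + 1] - rows$row[j])^2) * g$cell_size_m
    expect_equal(sd_$distance_m[sd_$agent_id == a], tot)
  }
})

test_that("turn ratios hit their closed-form extremes", {
  g <- desk_grid()
  straight <- trajectory_table(rep("s", 8), seq(0, 35, 5), 0:7, rep(1L, 8), g)
  ts <- turn_ratio_by_proximity(straight, g)
  expect_true(all(ts$by_bin$ratio == 0, na.rm = TRUE))
  expect_true(all(is.na(ts$angles$d1)))  # lone agent: no neighbour distance

  zig <- trajectory_table(rep("z", 9), seq(0, 40, 5),
                          rep(c(2L, 3L), length.out = 9), rep(2L, 9), g)
  tz <- turn_ratio_by_proximity(zig, g)
  expect_equal(unique(tz$angles$angle_deg), 180)

  # angles adjacent to a stationary step are skipped
  pause <- trajectory_table(rep("p", 5), seq(0, 20, 5),
                            c(0L, 1L, 1L, 2L, 3L), rep(0L, 5), g)
  tp <- turn_ratio_by_proximity(pause, g)
  expect_equal(nrow(tp$angles), 1L)  # only the fully-moving middle tick
})

test_that("planted near-proximity turns surface only in the near bin", {
  g <- desk_grid()
  # walker A turns 90 degrees exactly when walker B sits one cell away
  rows <- list()
  mk <- function(id, t, col, row) data.frame(agent_id = id, t = t, col = col,
                                             row = row)
  # far phase: B parked far away, A walks straight
  rows[[1]] <- mk("A", seq(0, 25, 5), 0:5, rep(2L, 6))
  rows[[2]] <- mk("B", seq(0, 25, 5), rep(15L, 6), rep(15L, 6))
  # near phase (fresh agents): B adjacent to A's path, A turns each tick
  rows[[3]] <- mk("A2", seq(0, 25, 5), c(8L, 9L, 9L, 10L, 10L, 11L),
                  c(2L, 2L, 3L, 3L, 4L, 4L))
  rows[[4]] <- mk("B2", seq(0, 25, 5), c(9L, 9L, 10L, 10L, 11L, 11L),
                  c(3L, 2L, 3L, 3L, 4L, 4L))
  d <- do.call(rbind, rows)
  tab <- trajectory_table(d$agent_id, d$t, d$col, d$row, g)
  ts <- turn_ratio_by_proximity(tab, g, bins = c(0, 1, 5))
  near <- ts$by_bin$ratio[1L]
  far <- ts$by_bin$ratio[2L]
  expect_gt(near, 0.9)
  expect_equal(far, 0)
})

test_that("empty turn bins report NA, not zero", {
  g <- desk_grid()
  straight <- trajectory_table(rep("s", 6), seq(0, 25, 5), 0:5, rep(1L, 6), g)
  ts <- turn_ratio_by_proximity(straight, g)
  expect_true(all(is.na(ts$by_bin$ratio)))
})

test_that("proximity speed table recovers a planted slowdown rule", {
  g <- desk_grid()
  # focal a moves every other tick while b walks glued 0.5 m away (near
  # phase), then a moves every tick while b is parked far off (far phase)
  near_a <- cumsum(seq_len(20) %% 2L)                  # 1,1,2,2,...,10
  far_a <- 10L + seq_len(20) %% 2L                     # step 1 every tick
  cols_a <- c(near_a, far_a)
  cols_b <- c(near_a, rep(15L, 20))
  rows_b <- c(rep(1L, 20), rep(15L, 20))
  d <- rbind(data.frame(agent_id = "a", t = 5 * (1:40), col = cols_a, row = 0L),
             data.frame(agent_id = "b", t = 5 * (1:40), col = cols_b,
                        row = rows_b))
  tab <- trajectory_table(d$agent_id, d$t, d$col, d$row, g)
  feat <- storesim:::tick_features(tab, g)
  a_rows <- feat[feat$agent_id == "a" & !is.na(feat$speed_ms), ]
  near_speed <- mean(a_rows$speed_ms[a_rows$d1 < 1])
  far_speed <- mean(a_rows$speed_ms[a_rows$d1 >= 1])
  expect_lt(near_speed / far_speed, 0.75)
})

test_that("refining proximity bins and re-aggregating reproduces coarse means", {
  g <- desk_grid()
  tab <- random_table(g, n_agents = 8L, len_range = c(6L, 12L), seed = 9)
  coarse <- speed_by_proximity(tab, g, d1_bins = c(0, 2, 4), d2_bins = c(0, 2, 4))
  fine <- speed_by_proximity(tab, g, d1_bins = seq(0, 4, 1), d2_bins = seq(0, 4, 1))
  for (i in 1:2) for (j in 1:2) {
    ii <- (2 * i - 1):(2 * i); jj <- (2 * j - 1):(2 * j)
    n_f <- fine$n[ii, jj]
    if (sum(n_f) == 0L) {
      expect_equal(coarse$n[i, j], 0L)
    } else {
      agg <- sum(fine$mean_speed[ii, jj] * n_f, na.rm = TRUE) / sum(n_f)
      expect_equal(coarse$mean_speed[i, j], agg, tolerance = 1e-12)
      expect_equal(coarse$n[i, j], sum(n_f))
    }
  }
})

test_that("single-agent tables have no proximity-binned mass", {
  g <- desk_grid()
  lone <- trajectory_table(rep("l", 6), seq(0, 25, 5), 0:5, rep(3L, 6), g)
  st <- speed_by_proximity(lone, g)
  expect_true(all(st$n == 0L))
  expect_true(all(is.na(st$mean_speed)))
})

test_that("local density counts the 3x3 block, focal included", {
  g <- desk_grid()
  lone <- trajectory_table(rep("l", 4), seq(0, 15, 5), 2:5, rep(3L, 4), g)
  expect_true(all(local_density(lone, g)$density == 1L))
  pair <- trajectory_table(c("a", "b"), c(0, 0), c(4L, 5L), c(4L, 4L), g)
  expect_true(all(local_density(pair, g)$density == 2L))
  sdd <- speed_by_density(lone, g)
  expect_equal(sdd$n_obs[1L], 3L)  # 3 outgoing steps, all at density 1
  expect_equal(sum(sdd$n_obs[-1L]), 0L)

  # brute-force block-count oracle on a random configuration
  set.seed(17)
  tab <- random_table(g, n_agents = 10L, seed = 17)
  got <- local_density(tab, g)
  for (r in sample(nrow(got), 25L)) {
    fr <- tab[tab$t == got$t[r], ]
    me <- fr[fr$agent_id == got$agent_id[r], ]
    cnt <- sum(abs(fr$col - me$col) <= 1 & abs(fr$row - me$row) <= 1)
    expect_equal(got$density[r], cnt)
  }
})

test_that("quadratic fits are exact on noiseless quadratics", {
  x <- c(1, 2, 3, 5, 8)
  y <- 2 - 0.5 * x + 0.25 * x^2
  f <- fit_quadratic(x, y)
  expect_equal(f$coef, c(2, -0.5, 0.25), tolerance = 1e-9)
  expect_lt(max(abs(f$predict(x) - y)), 1e-9)
  fc <- fit_quadratic(x, rep(3, 5))
  expect_equal(fc$coef, c(3, 0, 0), tolerance = 1e-9)
  expect_error(fit_quadratic(c(1, 1, 2), c(1, 2, 3)), "distinct")
})

test_that("noisy quadratic fits match the explicit normal equations", {
  set.seed(5)
  x <- runif(100, 0, 10)
  y <- 1 + 0.3 * x - 0.05 * x^2 + rnorm(100, 0, 0.2)
  f <- fit_quadratic(x, y)
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$coef, as.numeric(beta), tolerance = 1e-8)
  # residual orthogonality to the design columns
  r <- y - f$predict(x)
  expect_lt(max(abs(t(X) %*% r)), 1e-8)
})

test_that("RMSE between fits has its closed forms", {
  f1 <- fit_quadratic(1:5, (1:5)^2)
  f2 <- fit_quadratic(1:5, (1:5)^2 + 3)
  grid_x <- 1:5
  expect_equal(rmse_between_fits(f1, f1, grid_x), 0)
  expect_equal(rmse_between_fits(f1, f2, grid_x), 3)
  # arbitrary pair: pointwise evaluation oracle
  f3 <- fit_quadratic(1:5, c(2, 1, 4, 9, 16))
  want <- sqrt(mean((f1$predict(grid_x) - f3$predict(grid_x))^2))
  expect_equal(rmse_between_fits(f1, f3, grid_x), want)
  expect_error(rmse_between_fits(f1, f2, numeric(0)), "empty")
})

test_that("stay summary splits by concurrent-count class", {
  g <- desk_grid()
  set.seed(8)
  # crowd of 8 overlapping agents (high class) + 2 lone late agents
  mk <- function(id, t0, len, col0) data.frame(
    agent_id = id, t = t0 + 5 * (0:(len - 1L)),
    col = pmin(15L, col0 + 0:(len - 1L)), row = 3L)
  crowd <- do.call(rbind, lapply(1:8, function(i) mk(paste0("c", i), 0, 10, 1L)))
  late <- do.call(rbind, lapply(1:2, function(i)
    mk(paste0("l", i), 300 + 200 * i, 4, 2L)))
  d <- rbind(crowd, late)
  tab <- trajectory_table(d$agent_id, d$t, d$col, d$row, g)
  ss <- stay_summary(tab, g, split_at = 6L)
  expect_equal(sort(ss$class), c("n<6", "n>=6"))
  expect_equal(ss$n[ss$class == "n>=6"], 8L)
  cr <- crowding_response(tab, g)
  expect_true(all(cr$crowding[startsWith(as.character(cr$agent_id), "c")] == 8L))
  expect_true(all(cr$crowding[startsWith(as.character(cr$agent_id), "l")] == 1L))
})

test_that("metric functions are pure: identical inputs give identical outputs", {
  g <- desk_grid()
  tab <- random_table(g, n_agents = 6L, seed = 77)
  expect_identical(turn_ratio_by_proximity(tab, g), turn_ratio_by_proximity(tab, g))
  expect_identical(speed_by_density(tab, g), speed_by_density(tab, g))
  expect_identical(occupancy(tab, g), occupancy(tab, g))
})

test_that("the full report wires the six metrics together", {
  g <- desk_grid()
  real <- random_table(g, n_agents = 12L, len_range = c(6L, 14L), seed = 1)
  sim <- random_table(g, n_agents = 12L, len_range = c(6L, 14L), seed = 2)
  rep_ <- evaluate_tables(real, sim, g)
  expect_s3_class(rep_, "metrics_report")
  expect_equal(sum(rep_$occupancy$real$freq), 1)
  expect_true(is.finite(rep_$rmse_stay) || is.na(rep_$rmse_stay))
})
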
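#' Cell occupancy map
#'
#' Counts every (agent, tick) observation once and normalises to frequencies;
#' the spatial-density heatmap metric.
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @return A list of class `occupancy_map`: `counts` (n_rows x n_cols integer
#'   matrix, `counts[r+1, c+1]` = visits to cell (c, r)), `freq` (same shape,
#'   sums to 1 over visited cells), `n_obs`.
#' @export
occupancy <- function(table, grid) {
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  if (nrow(table) > 0L) {
    tab <- table(factor(table$row, levels = 0:(grid$n_rows - 1L)),
                 factor(table$col, levels = 0:(grid$n_cols - 1L)))
    counts <- matrix(as.integer(tab), grid$n_rows, grid$n_cols)
  }
  n <- sum(counts)
  structure(list(counts = counts,
                 freq = if (n > 0) counts / n else counts * 0,
                 n_obs = n),
            class = "occupancy_map")
}

#' Per-agent stay duration, travel distance and mean speed
#'
#' Stay is the time between first and last observation (minutes); distance is
#' the summed Euclidean center-to-center step length (meters); speed is
#' distance over stay (m/s). Agents observed for a single tick get stay 0 and
#' an undefined (NA) speed.
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @return A data.frame: `agent_id`, `stay_min`, `distance_m`, `speed_ms`.
#' @export
stay_and_distance <- function(table, grid) {
  if (nrow(table) == 0L)
    return(data.frame(agent_id = character(0), stay_min = numeric(0),
                      distance_m = numeric(0), speed_ms = numeric(0)))
  out <- lapply(split(seq_len(nrow(table)), table$agent_id), function(ix) {
    a <- table[ix, , drop = FALSE]
    a <- a[order(a$t), , drop = FALSE]
    stay_s <- max(a$t) - min(a$t)
    dist <- if (nrow(a) > 1L)
      sum(sqrt(diff(a$col)^2 + diff(a$row)^2)) * grid$cell_size_m else 0
    data.frame(agent_id = a$agent_id[1L], stay_min = stay_s / 60,
               distance_m = dist,
               speed_ms = if (stay_s > 0) dist / stay_s else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# long per-tick view with nearest-neighbour distances (meters) and per-tick
# speed of the outgoing step; the workhorse behind the proximity metrics
tick_features <- function(table, grid, k = 2L) {
  dt <- table_dt(table)
  parts <- lapply(split(seq_len(nrow(table)), table$t), function(ix) {
    fr <- table[ix, , drop = FALSE]
    n <- nrow(fr)
    d1 <- rep(NA_real_, n); d2 <- rep(NA_real_, n)
    if (n > 1L) {
      dx <- outer(fr$col, fr$col, `-`); dy <- outer(fr$row, fr$row, `-`)
      D <- sqrt(dx^2 + dy^2) * grid$cell_size_m
      diag(D) <- Inf
      for (i in seq_len(n)) {
        s <- sort(D[i, ])
        d1[i] <- s[1L]
        if (n > 2L) d2[i] <- s[2L]
      }
    }
    data.frame(agent_id = fr$agent_id, t = fr$t, col = fr$col, row = fr$row,
               d1 = d1, d2 = d2)
  })
  feat <- do.call(rbind, parts)
  feat <- feat[order(feat$agent_id, feat$t), , drop = FALSE]
  # outgoing displacement per agent
  nxt <- c(feat$agent_id[-1L], NA)
  same <- !is.na(nxt) & nxt == feat$agent_id
  feat$step_m <- NA_real_
  ix <- which(same)
  feat$step_m[ix] <- sqrt((feat$col[ix + 1L] - feat$col[ix])^2 +
                          (feat$row[ix + 1L] - feat$row[ix])^2) * grid$cell_size_m
  feat$speed_ms <- feat$step_m / dt
  rownames(feat) <- NULL
  feat
}

#' Big-turn ratio by proximity to the nearest agent
#'
#' The turning angle at tick t is the angle between the displacement
#' (t-1 -> t) and (t -> t+1); angles adjacent to a stationary step are
#' skipped. Each angle is assigned to the distance bin of the focal agent's
#' nearest-agent distance at tick t; the big-turn ratio per bin is the share
#' of angles of at least `threshold` degrees. An empty bin yields `NA`, never
#' zero.
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @param bins Distance bin edges in meters (default 0 to 5 by 0.5).
#' @param threshold Big-turn threshold in degrees.
#' @return A list of class `turn_stats`: `angles` (data.frame `agent_id`,
#'   `t`, `angle_deg`, `d1`), `by_bin` (data.frame `bin_lo`, `bin_hi`,
#'   `n_turns`, `n_big`, `ratio`).
#' @export
turn_ratio_by_proximity <- function(table, grid, bins = seq(0, 5, by = 0.5),
                                    threshold = 90) {
  feat <- tick_features(table, grid)
  rows <- lapply(split(seq_len(nrow(feat)), feat$agent_id), function(ix) {
    a <- feat[ix, , drop = FALSE]
    n <- nrow(a)
    if (n < 3L) return(NULL)
    vx <- diff(a$col); vy <- diff(a$row)
    out <- NULL
    for (j in 2L:(n - 1L)) {
      v1 <- c(vx[j - 1L], vy[j - 1L]); v2 <- c(vx[j], vy[j])
      if (all(v1 == 0) || all(v2 == 0)) next
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      out <- rbind(out, data.frame(agent_id = a$agent_id[1L], t = a$t[j],
                                   angle_deg = ang, d1 = a$d1[j]))
    }
    out
  })
  angles <- do.call(rbind, rows)
  if (is.null(angles))
    angles <- data.frame(agent_id = character(0), t = numeric(0),
                         angle_deg = numeric(0), d1 = numeric(0))
  lo <- bins[-length(bins)]; hi <- bins[-1L]
  by_bin <- data.frame(bin_lo = lo, bin_hi = hi, n_turns = 0L, n_big = 0L,
                       ratio = NA_real_)
  ok <- !is.na(angles$d1)
  if (any(ok)) {
    b <- findInterval(angles$d1[ok], bins, rightmost.closed = FALSE)
    inb <- b >= 1L & b <= length(lo)
    tt <- tapply(rep(1L, sum(inb)), factor(b[inb], levels = seq_along(lo)), sum)
    bg <- tapply(angles$angle_deg[ok][inb] >= threshold,
                 factor(b[inb], levels = seq_along(lo)), sum)
    by_bin$n_turns <- as.integer(ifelse(is.na(tt), 0L, tt))
    by_bin$n_big <- as.integer(ifelse(is.na(bg), 0L, bg))
    by_bin$ratio <- ifelse(by_bin$n_turns > 0L, by_bin$n_big / by_bin$n_turns,
                           NA_real_)
  }
  structure(list(angles = angles, by_bin = by_bin, threshold = threshold),
            class = "turn_stats")
}

#' Mean speed by distances to the nearest and second-nearest agents
#'
#' Per-tick speed (outgoing step length over the 5-s interval) binned by the
#' pair of distances to the nearest and second-nearest agent at the step's
#' starting tick. Ticks with fewer than two other agents present fall in the
#' absent margins. Empty cells are `NA`.
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @param d1_bins,d2_bins Bin edges in meters.
#' @return A list of class `speed_table`: `mean_speed` (matrix, rows = d1
#'   bins, cols = d2 bins), `n` (observation counts), bin edges.
#' @export
speed_by_proximity <- function(table, grid, d1_bins = seq(0, 5, by = 0.5),
                               d2_bins = seq(0, 5, by = 0.5)) {
  feat <- tick_features(table, grid)
  feat <- feat[!is.na(feat$speed_ms), , drop = FALSE]
  n1 <- length(d1_bins) - 1L; n2 <- length(d2_bins) - 1L
  M <- matrix(NA_real_, n1, n2); N <- matrix(0L, n1, n2)
  ok <- !is.na(feat$d1) & !is.na(feat$d2)
  if (any(ok)) {
    b1 <- findInterval(feat$d1[ok], d1_bins)
    b2 <- findInterval(feat$d2[ok], d2_bins)
    sp <- feat$speed_ms[ok]
    inb <- b1 >= 1L & b1 <= n1 & b2 >= 1L & b2 <= n2
    if (any(inb)) {
      key <- (b1[inb] - 1L) * n2 + b2[inb]
      sums <- tapply(sp[inb], key, sum)
      cnts <- tapply(rep(1L, sum(inb)), key, sum)
      for (kk in names(sums)) {
        k <- as.integer(kk)
        i <- (k - 1L) %/% n2 + 1L; j <- (k - 1L) %% n2 + 1L
        N[i, j] <- cnts[[kk]]
        M[i, j] <- sums[[kk]] / cnts[[kk]]
      }
    }
  }
  structure(list(mean_speed = M, n = N, d1_bins = d1_bins, d2_bins = d2_bins),
            class = "speed_table")
}

#' Mean speed by local density
#'
#' Local density at a tick is the number of agents — including the focal one,
#' so the minimum is 1 — inside the 3x3-cell block centered on the focal
#' agent's cell (clipped at the store edge). Mean outgoing-step speed is
#' reported per density class 1..5, with densities above 5 pooled into the
#' top class.
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @param max_density Top (pooled) density class.
#' @return A data.frame: `density`, `n_obs`, `mean_speed_ms`.
#' @export
speed_by_density <- function(table, grid, max_density = 5L) {
  feat <- tick_features(table, grid)
  dens <- local_density(table, grid)
  feat <- merge(feat, dens, by = c("agent_id", "t"), sort = FALSE)
  feat <- feat[!is.na(feat$speed_ms), , drop = FALSE]
  cls <- pmin(feat$density, max_density)
  out <- data.frame(density = seq_len(max_density), n_obs = 0L,
                    mean_speed_ms = NA_real_)
  if (nrow(feat) > 0L) {
    sums <- tapply(feat$speed_ms, factor(cls, levels = seq_len(max_density)), sum)
    cnts <- tapply(rep(1L, nrow(feat)), factor(cls, levels = seq_len(max_density)), sum)
    out$n_obs <- as.integer(ifelse(is.na(cnts), 0L, cnts))
    out$mean_speed_ms <- ifelse(out$n_obs > 0L, sums / cnts, NA_real_)
  }
  out
}

#' Local 3x3 density per (agent, tick)
#'
#' @inheritParams speed_by_density
#' @return A data.frame: `agent_id`, `t`, `density` (>= 1, includes focal).
#' @export
local_density <- function(table, grid) {
  parts <- lapply(split(seq_len(nrow(table)), table$t), function(ix) {
    fr <- table[ix, , drop = FALSE]
    d <- vapply(seq_len(nrow(fr)), function(i) {
      sum(abs(fr$col - fr$col[i]) <= 1L & abs(fr$row - fr$row[i]) <= 1L)
    }, integer(1L))
    data.frame(agent_id = fr$agent_id, t = fr$t, density = d)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares quadratic fit
#'
#' Degree-2 polynomial fit of a response on a crowding level, used for the
#' crowding-stay and crowding-distance curves.
#'
#' @param x Crowding levels (needs >= 3 distinct values).
#' @param y Responses.
#' @return A list of class `fit_curve`: `coef` (c0, c1, c2), `predict`
#'   (function of x), `x_range`.
#' @export
fit_quadratic <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3L)
    stop("need >= 3 distinct x values for a quadratic fit", call. = FALSE)
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  structure(
    list(coef = cf,
         predict = function(xx) cf[1L] + cf[2L] * xx + cf[3L] * xx^2,
         x_range = range(x)),
    class = "fit_curve"
  )
}

#' RMSE between two fitted curves
#'
#' Root mean squared difference of the two quadratic fits evaluated on a
#' shared grid of crowding levels.
#'
#' @param a,b `fit_curve` objects.
#' @param grid_x Numeric evaluation points (the shared crowding levels).
#' @return Scalar RMSE.
#' @export
rmse_between_fits <- function(a, b, grid_x) {
  if (length(grid_x) == 0L) stop("empty evaluation grid", call. = FALSE)
  sqrt(mean((a$predict(grid_x) - b$predict(grid_x))^2))
}

#' Per-agent crowding level and stay/distance responses
#'
#' Operationalises "crowding experienced by an agent" as the mean number of
#' concurrently present agents over the agent's visit, rounded to an integer
#' class. These are the points the crowding-response quadratics are fitted
#' to.
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @return A data.frame: `agent_id`, `crowding`, `stay_min`, `distance_m`.
#' @export
crowding_response <- function(table, grid) {
  sd_tab <- stay_and_distance(table, grid)
  if (nrow(sd_tab) == 0L) {
    sd_tab$crowding <- integer(0)
    return(sd_tab[, c("agent_id", "crowding", "stay_min", "distance_m")])
  }
  counts <- tapply(table$agent_id, table$t, function(a) length(unique(a)))
  count_at <- stats::setNames(as.integer(counts), names(counts))
  crowd <- vapply(split(table$t, table$agent_id), function(ts) {
    mean(count_at[as.character(ts)])
  }, numeric(1L))
  sd_tab$crowding <- round(crowd[as.character(sd_tab$agent_id)])
  sd_tab[, c("agent_id", "crowding", "stay_min", "distance_m")]
}

#' Stay-duration summary by crowding class
#'
#' Quartiles of per-agent stay under low vs high concurrent in-store count
#' (default split at 6, the congestion threshold used in the dwell-time
#' comparison).
#'
#' @param table A `trajectory_table`.
#' @param grid A [grid_spec()].
#' @param split_at Class boundary: low is `crowding < split_at`.
#' @return A data.frame with one row per class: `class`, `n`, `q1`, `median`,
#'   `q3`.
#' @export
stay_summary <- function(table, grid, split_at = 6L) {
  cr <- crowding_response(table, grid)
  cls <- ifelse(cr$crowding < split_at, sprintf("n<%d", split_at),
                sprintf("n>=%d", split_at))
  out <- lapply(split(cr$stay_min, cls), function(s) {
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(s), q1 = q[1L], median = q[2L], q3 = q[3L])
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(class = rownames(res)), res)
  rownames(res) <- NULL
  res
}

#' Full six-metric comparison report
#'
#' Computes the whole evaluation suite on a ground-truth and a simulated
#' trajectory table: occupancy maps, stay/distance/speed summaries, big-turn
#' ratios by proximity, speed by proximity pair, speed by local density, and
#' the RMSE between fitted crowding-stay and crowding-distance quadratics.
#'
#' @param real,sim `trajectory_table`s to compare.
#' @param grid A [grid_spec()].
#' @param bins Distance bin edges in meters for the proximity metrics.
#' @return A list of class `metrics_report`; see elements `occupancy`,
#'   `stay_distance`, `turns`, `speed_proximity`, `speed_density`,
#'   `rmse_stay`, `rmse_distance`.
#' @export
evaluate_tables <- function(real, sim, grid, bins = seq(0, 5, by = 0.5)) {
  rep_ <- list(
    occupancy = list(real = occupancy(real, grid), sim = occupancy(sim, grid)),
    stay_distance = list(real = stay_and_distance(real, grid),
                         sim = stay_and_distance(sim, grid)),
    turns = list(real = turn_ratio_by_proximity(real, grid, bins),
                 sim = turn_ratio_by_proximity(sim, grid, bins)),
    speed_proximity = list(real = speed_by_proximity(real, grid, bins, bins),
                           sim = speed_by_proximity(sim, grid, bins, bins)),
    speed_density = list(real = speed_by_density(real, grid),
                         sim = speed_by_density(sim, grid)))
  cr_r <- crowding_response(real, grid)
  cr_s <- crowding_response(sim, grid)
  shared <- intersect(unique(cr_r$crowding), unique(cr_s$crowding))
  rep_$crowding_grid <- sort(shared)
  rep_$rmse_stay <- rep_$rmse_distance <- NA_real_
  ok <- length(unique(cr_r$crowding)) >= 3L &&
    length(unique(cr_s$crowding)) >= 3L && length(shared) > 0L
  if (ok) {
    rep_$rmse_stay <- rmse_between_fits(
      fit_quadratic(cr_r$crowding, cr_r$stay_min),
      fit_quadratic(cr_s$crowding, cr_s$stay_min), sort(shared))
    rep_$rmse_distance <- rmse_between_fits(
      fit_quadratic(cr_r$crowding, cr_r$distance_m),
      fit_quadratic(cr_s$crowding, cr_s$distance_m), sort(shared))
  }
  structure(rep_, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> rmse_stay=%.3f min, rmse_distance=%.3f m\n",
              x$rmse_stay, x$rmse_distance))
  invisible(x)
}
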
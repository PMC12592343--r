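# Shared fixtures and independent oracles, all built in code at test time.

desk_grid <- function() grid_spec(depth = 4L, cell_size_m = 0.5)

# random gap-free multi-agent table on a given grid
random_table <- function(grid, n_agents = 6L, len_range = c(4L, 12L),
                         seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_agents), function(a) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    t0 <- sample(0:6, 1L) * 5
    col <- sample(0:(grid$n_cols - 1L), 1L)
    row <- sample(0:(grid$n_rows - 1L), 1L)
    cols <- integer(len); rws <- integer(len)
    for (j in seq_len(len)) {
      col <- min(grid$n_cols - 1L, max(0L, col + sample(-1:1, 1L)))
      row <- min(grid$n_rows - 1L, max(0L, row + sample(-1:1, 1L)))
      cols[j] <- col; rws[j] <- row
    }
    data.frame(agent_id = sprintf("a%02d", a), t = t0 + 5 * (seq_len(len) - 1L),
               col = cols, row = rws)
  })
  d <- do.call(rbind, rows)
  trajectory_table(d$agent_id, d$t, d$col, d$row, grid)
}

# independent Morton-order oracle: enumerate cells in z-order and read codes
# off the enumeration index, without using the packaged bit logic
morton_code_oracle <- function(col, row, depth) {
  code <- character(0)
  size <- 2^depth
  for (level in seq_len(depth)) {
    half <- size / 2
    q <- 0
    if (col >= half) { q <- q + 1; col <- col - half }
    if (row >= half) { q <- q + 2; row <- row - half }
    code <- c(code, letters[4 * (level - 1) + q + 1])
    size <- half
  }
  paste(code, collapse = "")
}

# brute-force O(n^2) neighbour ranking oracle
nn_oracle <- function(frame, focal, k, grid) {
  i <- which(frame$agent_id == focal)
  others <- frame[-i, , drop = FALSE]
  if (nrow(others) == 0L) return(rep(NA_character_, k))
  d <- sqrt((others$col - frame$col[i])^2 + (others$row - frame$row[i])^2) *
    grid$cell_size_m
  ord <- order(d, as.character(others$agent_id))
  out <- as.character(others$agent_id)[ord]
  length(out) <- k
  out
}

# BFS shortest-path distance on the open 8-connected grid
bfs_dist_oracle <- function(from, to, grid) {
  n <- grid$n_cols
  dist <- matrix(NA_integer_, n, n)
  dist[from[1] + 1, from[2] + 1] <- 0L
  queue <- list(from)
  while (length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    d0 <- dist[cur[1] + 1, cur[2] + 1]
    for (dc in -1:1) for (dr in -1:1) {
      if (dc == 0 && dr == 0) next
      cc <- cur[1] + dc; rr <- cur[2] + dr
      if (cc < 0 || rr < 0 || cc >= n || rr >= n) next
      if (is.na(dist[cc + 1, rr + 1])) {
        dist[cc + 1, rr + 1] <- d0 + 1L
        queue[[length(queue) + 1L]] <- c(cc, rr)
      }
    }
  }
  dist[to[1] + 1, to[2] + 1]
}

# independent oracle: project the target mask from character intervals.
# A sub-token stream position i is masked in iff the character interval of
# the NEXT sub-token lies inside an S-role span (or is the end word).
mask_oracle <- function(doc, codec, cfg) {
  enc <- encode_words(doc$words, codec)
  syms <- codec$vocab[enc$ids]
  word_start <- doc$spans$start_char
  off <- integer(length(syms))
  pos_in_word <- 0L
  for (i in seq_along(syms)) {
    w <- enc$word_of[i]
    if (i == 1L || enc$word_of[i - 1L] != w) pos_in_word <- 0L
    off[i] <- word_start[w] + pos_in_word
    pos_in_word <- pos_in_word + nchar(syms[i])
  }
  in_S <- vapply(seq_along(syms), function(i) {
    w <- enc$word_of[i]
    sp <- doc$spans[w, ]
    (sp$role == cfg$role_prefixes[1L] || sp$role == "eos") &&
      off[i] >= sp$start_char &&
      off[i] + nchar(syms[i]) - 1L <= sp$end_char
  }, logical(1L))
  c(in_S[-1L], FALSE)
}

# a tiny untrained checkpoint: enough structure for the simulator plumbing
untrained_checkpoint <- function(grid = desk_grid(), k = 2L, seed = 1L,
                                 corpus_seed = 2L) {
  cfg <- corpus_config(k = k)
  tab <- random_table(grid, n_agents = 6L, seed = corpus_seed)
  corpus <- build_corpus(tab, cfg, grid)
  codec <- train_codec(corpus, vocab_budget = 120L, cfg = cfg, grid = grid)
  mc <- model_config(preset = NULL, n_layers = 1L, n_heads = 2L,
                     hidden_size = 32L, context_length = 512L,
                     vocab_size = length(codec$vocab))
  structure(
    list(params = init_params(mc, seed = seed), model_config = mc,
         train_config = train_config(), codec = codec, corpus_config = cfg,
         grid = grid, history = data.frame(), best_epoch = 0L),
    class = "checkpoint"
  )
}
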
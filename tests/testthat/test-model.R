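tiny_mc <- function(V = 12L) {
  model_config(preset = NULL, n_layers = 2L, n_heads = 2L, hidden_size = 8L,
               context_length = 32L, vocab_size = V)
}

test_that("masked loss has its closed forms", {
  V <- 7L
  logits <- matrix(0, 4, V)  # uniform scores
  labels <- c(3L, 1L, 5L, 2L)
  mask <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(masked_loss(logits, labels, mask), log(V))
  # perturbing a masked-out position leaves the loss unchanged
  logits2 <- logits
  logits2[2L, ] <- rnorm(V) * 100
  expect_identical(masked_loss(logits2, labels, mask),
                   masked_loss(logits, labels, mask))
  expect_error(masked_loss(logits, labels, rep(FALSE, 4)), "all-false")
})

test_that("masked loss equals the per-position hand-summed oracle", {
  set.seed(8)
  for (rep in 1:10) {
    L <- sample(3:12, 1L); V <- sample(4:9, 1L)
    logits <- matrix(rnorm(L * V), L, V)
    labels <- sample(V, L, replace = TRUE)
    mask <- sample(c(TRUE, FALSE), L, replace = TRUE)
    if (!any(mask)) mask[1L] <- TRUE
    oracle <- {
      tot <- 0; n <- 0
      for (i in seq_len(L)) if (mask[i]) {
        p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
        tot <- tot - log(p[labels[i]]); n <- n + 1
      }
      tot / n
    }
    expect_equal(masked_loss(logits, labels, mask), oracle, tolerance = 1e-10)
  }
})

test_that("gradients vanish exactly at masked-out positions and match finite differences", {
  set.seed(21)
  mc <- tiny_mc()
  p <- init_params(mc, seed = 4L)
  ids <- sample(mc$vocab_size, 9L, replace = TRUE)
  labels <- c(ids[-1L], 1L)
  mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  fwd <- transformer_forward(p, mc, ids, keep_cache = TRUE)
  dlog <- masked_loss_grad(fwd$logits, labels, mask)
  # exact zero rows at masked-out positions: the masking contract
  expect_true(all(dlog[!mask, ] == 0))
  expect_true(any(dlog[mask, ] != 0))
  gr <- transformer_backward(p, mc, fwd, dlog)
  lossfun <- function(pp)
    masked_loss(transformer_forward(pp, mc, ids)$logits, labels, mask)
  eps <- 1e-4
  for (nm in c("tok_emb", "pos_emb", "attn_w_1", "attn_b_2", "proj_w_1",
               "mlp_w1_2", "mlp_w2_1", "ln1_g_1", "ln2_b_2", "lnf_g")) {
    idx <- sample(length(p[[nm]]), 3L)
    for (i in idx) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("causality: logits at position i ignore later tokens", {
  mc <- tiny_mc()
  p <- init_params(mc, seed = 9L)
  ids <- sample(mc$vocab_size, 8L, replace = TRUE)
  full <- transformer_forward(p, mc, ids)$logits
  head5 <- transformer_forward(p, mc, ids[1:5])$logits
  expect_equal(full[1:5, ], head5, tolerance = 1e-10)
})

test_that("incremental decoding with a KV cache matches the full forward pass", {
  mc <- tiny_mc()
  p <- init_params(mc, seed = 2L)
  ck <- list(params = p, model_config = mc)
  ids <- sample(mc$vocab_size, 12L, replace = TRUE)
  st <- decode_state(ck)
  decode_append(ck, st, ids[1:7])   # prefill in a block
  for (i in 8:12) decode_append(ck, st, ids[i])  # then token by token
  full <- transformer_forward(p, mc, ids)$logits
  expect_equal(st$logits, unname(full[12L, ]), tolerance = 1e-10)
})

test_that("head truncation keeps whole recent frames", {
  ex <- structure(list(
    ids = 1:20, target_mask = rep(TRUE, 20), roles = rep("S", 20),
    word_of = rep(1:5, each = 4L), frame_starts = c(1L, 5L, 9L, 13L, 17L)),
    class = "masked_example")
  tr <- storesim:::truncate_example(ex, 10L)
  expect_equal(tr$ids, 13:20)          # whole frames only, most recent kept
  expect_equal(tr$frame_starts, c(1L, 5L))
})

test_that("a smoke training run improves validation loss", {
  grid <- desk_grid()
  cfg <- corpus_config(k = 1L)
  tab <- random_table(grid, n_agents = 24L, len_range = c(4L, 8L), seed = 40)
  corpus <- build_corpus(tab, cfg, grid)
  codec <- train_codec(corpus, vocab_budget = 100L, cfg = cfg)
  ex <- lapply(corpus, encode_with_mask, codec = codec, cfg = cfg)
  mc <- model_config(preset = NULL, n_layers = 1L, n_heads = 2L,
                     hidden_size = 32L, context_length = 128L,
                     vocab_size = length(codec$vocab))
  tc <- train_config(learning_rate = 3e-3, batch_size = 6L, max_epochs = 3L,
                     patience = 3L, seed = 11L)
  ck <- train_model(ex, mc, tc, codec = codec, cfg = cfg, grid = grid,
                    quiet = TRUE)
  h <- ck$history
  expect_equal(nrow(h), 3L)
  expect_lt(min(h$val_loss), h$val_loss[1L])
  expect_equal(ck$best_epoch, which.min(h$val_loss))
})

test_that("longer patience never worsens the best validation loss", {
  grid <- desk_grid()
  cfg <- corpus_config(k = 0L)
  tab <- random_table(grid, n_agents = 12L, len_range = c(3L, 6L), seed = 41)
  corpus <- build_corpus(tab, cfg, grid)
  codec <- train_codec(corpus, vocab_budget = 60L, cfg = cfg)
  ex <- lapply(corpus, encode_with_mask, codec = codec, cfg = cfg)
  mc <- model_config(preset = NULL, n_layers = 1L, n_heads = 1L,
                     hidden_size = 16L, context_length = 64L,
                     vocab_size = length(codec$vocab))
  run <- function(pat) train_model(
    ex, mc, train_config(learning_rate = 3e-3, batch_size = 4L,
                         max_epochs = 8L, patience = pat, seed = 3L),
    quiet = TRUE)
  best1 <- min(run(1L)$history$val_loss, na.rm = TRUE)
  best2 <- min(run(2L)$history$val_loss, na.rm = TRUE)
  expect_lte(best2, best1)
})

test_that("a memorised trajectory is regenerated greedily end to end", {
  grid <- desk_grid()
  cfg <- corpus_config(k = 0L)
  tab <- trajectory_table(rep("m", 6), seq(0, 25, by = 5),
                          c(3L, 4L, 5L, 5L, 6L, 7L),
                          c(1L, 2L, 3L, 4L, 4L, 5L), grid)
  doc <- build_document("m", tab, cfg, grid)
  codec <- train_codec(list(doc), vocab_budget = 40L, cfg = cfg, grid = grid)
  ex <- encode_with_mask(doc, codec, cfg)
  mc <- model_config(preset = NULL, n_layers = 1L, n_heads = 2L,
                     hidden_size = 32L, context_length = 128L,
                     vocab_size = length(codec$vocab))
  tc <- train_config(learning_rate = 1e-2, batch_size = 1L, max_epochs = 120L,
                     patience = 120L, val_fraction = 0, seed = 6L)
  ck <- train_model(list(ex), mc, tc, codec = codec, cfg = cfg, grid = grid,
                    quiet = TRUE)
  # masked-in perplexity approaches 1 on the memorised language
  final <- storesim:::example_loss(ck$params, mc, ex)
  expect_lt(exp(final$loss), 1.1)
  trie <- focal_token_trie(ck)
  st <- decode_state(ck)
  first <- encode_words(doc$words[1L], codec)$ids
  decode_append(ck, st, first)
  got <- character(0)
  for (i in 1:10) {
    res <- next_focal_token(ck, st, trie, temperature = 0)
    if (res$eos) break
    got <- c(got, res$code)
  }
  expect_true(res$eos)
  expect_equal(got, encode_cell(tab$col, tab$row, grid)[-1L])
})

test_that("constrained sampling from an untrained model always parses", {
  ck <- untrained_checkpoint(seed = 14L)
  trie <- focal_token_trie(ck)
  grid <- ck$grid
  set.seed(31)
  n_eos <- 0L
  for (rep in 1:60) {
    st <- decode_state(ck)
    ctx <- encode_words(paste0("S", encode_cell(sample(0:15, 1), sample(0:15, 1),
                                                grid)), ck$codec)$ids
    decode_append(ck, st, ctx)
    res <- next_focal_token(ck, st, trie, temperature = 1.5)
    if (res$eos) { n_eos <- n_eos + 1L; next }
    expect_true(validate_code(res$code, grid))
  }
  expect_lt(n_eos, 60L)
})

test_that("sampling is reproducible given seed and context", {
  ck <- untrained_checkpoint(seed = 5L)
  trie <- focal_token_trie(ck)
  ctx <- encode_words("Saeim", ck$codec)$ids
  draw <- function() {
    st <- decode_state(ck)
    decode_append(ck, st, ctx)
    set.seed(123)
    next_focal_token(ck, st, trie, temperature = 1)
  }
  expect_identical(draw(), draw())
})

test_that("checkpoints round-trip through disk including generation", {
  ck <- untrained_checkpoint(seed = 77L)
  dir <- withr::local_tempdir()
  save_checkpoint(ck, dir)
  back <- load_checkpoint(dir)
  expect_equal(back$model_config$hidden_size, ck$model_config$hidden_size)
  expect_identical(back$codec$vocab, ck$codec$vocab)
  gen <- function(c_) {
    trie <- focal_token_trie(c_)
    st <- decode_state(c_)
    decode_append(c_, st, encode_words("Saeim", c_$codec)$ids)
    set.seed(9)
    next_focal_token(c_, st, trie)
  }
  expect_identical(gen(ck), gen(back))
})

test_that("model configuration guards hold", {
  expect_error(model_config(preset = NULL, n_layers = 1L, n_heads = 3L,
                            hidden_size = 8L, context_length = 16L),
               "divisible")
  mcp <- model_config("full")
  expect_equal(c(mcp$n_layers, mcp$n_heads, mcp$hidden_size,
                 mcp$context_length), c(12L, 12L, 768L, 6144L))
  mcd <- model_config("desk")
  expect_equal(c(mcd$n_layers, mcd$n_heads, mcd$hidden_size,
                 mcd$context_length), c(2L, 4L, 128L, 768L))
  expect_error(train_config(learning_rate = 0), "learning_rate")
})
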
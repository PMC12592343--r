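#' Training configuration
#'
#' Optimisation settings for [train_model()]. Defaults mirror the reference
#' recipe: AdamW (decoupled weight decay) with learning rate 3e-4 and batch
#' size 32, a linear warmup-decay schedule, and early stopping on validation
#' loss. The train/validation split is by document, never by window.
#'
#' @param learning_rate Peak learning rate.
#' @param batch_size Documents per optimiser update (gradient accumulation).
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @param val_fraction Fraction of documents held out for validation.
#' @param weight_decay Decoupled weight decay applied to weight matrices
#'   (not to biases, layer norms or embeddings).
#' @param warmup_frac Fraction of planned optimiser steps spent in linear
#'   warmup before the linear decay.
#' @param seed Seed controlling the split, shuffling and initialisation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 32L,
                         max_epochs = 20L, patience = 3L, val_fraction = 0.1,
                         weight_decay = 0.01, warmup_frac = 0.1, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         val_fraction = val_fraction, weight_decay = weight_decay,
         warmup_frac = warmup_frac, seed = as.integer(seed)),
    class = "train_config"
  )
}

# drop oldest whole frames until the example fits the context window
truncate_example <- function(ex, context_length) {
  n <- length(ex$ids)
  if (n <= context_length) return(ex)
  cut_at <- ex$frame_starts[ex$frame_starts > n - context_length][1L]
  if (is.na(cut_at)) cut_at <- n - context_length + 1L
  keep <- cut_at:n
  ex$ids <- ex$ids[keep]
  ex$target_mask <- ex$target_mask[keep]
  ex$roles <- ex$roles[keep]
  ex$word_of <- ex$word_of[keep]
  ex$frame_starts <- ex$frame_starts[ex$frame_starts >= cut_at] - cut_at + 1L
  ex
}

example_loss <- function(params, mc, ex, with_grad = FALSE) {
  ids <- ex$ids
  L <- length(ids)
  labels <- c(ids[-1L], NA_integer_)
  mask <- ex$target_mask & !is.na(labels)
  if (!any(mask)) return(NULL)
  fwd <- transformer_forward(params, mc, ids, keep_cache = with_grad)
  labels[!mask] <- 1L  # placeholder; masked positions never read
  loss <- masked_loss(fwd$logits, labels, mask)
  out <- list(loss = loss, n_targets = sum(mask))
  if (with_grad) {
    dlogits <- masked_loss_grad(fwd$logits, labels, mask)
    out$grads <- transformer_backward(params, mc, fwd, dlogits)
  }
  out
}

adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  decayed <- vapply(names(params), function(nm) {
    is.matrix(params[[nm]]) && !nm %in% c("tok_emb", "pos_emb")
  }, logical(1L))
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (decayed[[nm]]) upd <- upd + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

lr_at <- function(step, total_steps, peak, warmup_frac) {
  w <- max(1, round(warmup_frac * total_steps))
  if (step <= w) return(peak * step / w)
  frac <- (step - w) / max(1, total_steps - w)
  peak * max(0.1, 1 - 0.9 * frac)  # linear decay to 10% of peak
}

#' Train the trajectory transformer
#'
#' Splits the corpus into train/validation by document, optimises the masked
#' cross-entropy with AdamW under a linear warmup-decay schedule, and returns
#' the checkpoint with the best validation loss (early stopping). Examples
#' longer than the context window are truncated from the head in whole-frame
#' units so the most recent context is kept.
#'
#' @param examples List of [encode_with_mask()] examples.
#' @param mc A [model_config()] (its `vocab_size` must match the codec).
#' @param tc A [train_config()].
#' @param codec The [train_codec()] codec (stored in the checkpoint).
#' @param cfg The [corpus_config()] (stored in the checkpoint).
#' @param grid The [grid_spec()] (stored in the checkpoint).
#' @param quiet Suppress per-epoch messages.
#' @return An object of class `checkpoint`: `params`, `model_config`,
#'   `train_config`, `codec`, `corpus_config`, `grid`, `history` (data.frame
#'   epoch/train_loss/val_loss), `best_epoch`.
#' @export
train_model <- function(examples, mc, tc = train_config(), codec = NULL,
                        cfg = NULL, grid = NULL, quiet = FALSE) {
  if (length(examples) == 0L) stop("empty corpus", call. = FALSE)
  examples <- lapply(examples, truncate_example, context_length = mc$context_length)
  keep <- vapply(examples, function(e) any(e$target_mask[-length(e$target_mask)]),
                 logical(1L))
  examples <- examples[keep]
  if (length(examples) == 0L)
    stop("no example has a masked-in target", call. = FALSE)

  set.seed(tc$seed)
  n <- length(examples)
  n_val <- max(if (n > 1L) 1L else 0L, round(tc$val_fraction * n))
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0L) { train_idx <- val_idx }

  params <- init_params(mc, seed = tc$seed)
  state <- list(t = 0L,
                m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  steps_per_epoch <- max(1L, ceiling(length(train_idx) / tc$batch_size))
  total_steps <- steps_per_epoch * tc$max_epochs

  val_loss_of <- function(p) {
    tot <- 0; cnt <- 0
    for (i in val_idx) {
      r <- example_loss(p, mc, examples[[i]])
      if (is.null(r)) next
      tot <- tot + r$loss * r$n_targets; cnt <- cnt + r$n_targets
    }
    if (cnt == 0) NA_real_ else tot / cnt
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  step <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample(train_idx)
    ep_tot <- 0; ep_cnt <- 0
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    for (b in batches) {
      acc <- NULL; bn <- 0L
      for (i in b) {
        r <- example_loss(params, mc, examples[[i]], with_grad = TRUE)
        if (is.null(r)) next
        ep_tot <- ep_tot + r$loss * r$n_targets; ep_cnt <- ep_cnt + r$n_targets
        if (is.null(acc)) acc <- r$grads
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + r$grads[[nm]]
        bn <- bn + 1L
      }
      if (bn == 0L) next
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / bn
      step <- step + 1L
      lr <- lr_at(step, total_steps, tc$learning_rate, tc$warmup_frac)
      upd <- adamw_step(params, acc, state, lr, tc$weight_decay)
      params <- upd$params; state <- upd$state
    }
    tl <- if (ep_cnt > 0) ep_tot / ep_cnt else NA_real_
    vl <- if (length(val_idx) > 0L) val_loss_of(params) else tl
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         val_loss = vl))
    if (!quiet)
      message(sprintf("epoch %d: train %.4f  val %.4f", epoch, tl, vl))
    if (!is.na(vl) && vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= tc$patience) break
    }
  }

  structure(
    list(params = best$params, model_config = mc, train_config = tc,
         codec = codec, corpus_config = cfg, grid = grid,
         history = history, best_epoch = best$epoch),
    class = "checkpoint"
  )
}

#' @export
print.checkpoint <- function(x, ...) {
  cat(sprintf(
    "<checkpoint> %d layers, hidden %d, vocab %s; best epoch %d (val %.4f)\n",
    x$model_config$n_layers, x$model_config$hidden_size,
    x$model_config$vocab_size, x$best_epoch,
    if (nrow(x$history)) min(x$history$val_loss, na.rm = TRUE) else NA))
  invisible(x)
}

#' Save / load a checkpoint directory
#'
#' Writes `config.json` (model, training, corpus and grid configs),
#' `codec.json`, `history.jsonl` (one epoch per line) and `params.rds`.
#'
#' @param ckpt A `checkpoint`.
#' @param dir Directory path (created if needed).
#' @export
save_checkpoint <- function(ckpt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- list(model_config = unclass(ckpt$model_config),
               train_config = unclass(ckpt$train_config),
               corpus_config = unclass(ckpt$corpus_config),
               grid = unclass(ckpt$grid),
               best_epoch = ckpt$best_epoch)
  jsonlite::write_json(cfgs, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(ckpt$codec)) write_codec(ckpt$codec, file.path(dir, "codec.json"))
  writeLines(
    vapply(seq_len(nrow(ckpt$history)), function(i)
      jsonlite::toJSON(as.list(ckpt$history[i, ]), auto_unbox = TRUE, digits = NA),
      character(1L)),
    file.path(dir, "history.jsonl"))
  saveRDS(ckpt$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfgs <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  mc <- cfgs$model_config
  mc <- model_config(preset = NULL, n_layers = mc$n_layers,
                     n_heads = mc$n_heads, hidden_size = mc$hidden_size,
                     context_length = mc$context_length,
                     vocab_size = mc$vocab_size, use_pos_emb = mc$use_pos_emb)
  tc <- do.call(train_config, as.list(cfgs$train_config))
  cc <- if (!is.null(cfgs$corpus_config))
    corpus_config(k = cfgs$corpus_config$k,
                  role_prefixes = cfgs$corpus_config$role_prefixes,
                  absent_token = cfgs$corpus_config$absent_token,
                  eos_token = cfgs$corpus_config$eos_token) else NULL
  grid <- if (!is.null(cfgs$grid))
    grid_spec(depth = cfgs$grid$depth, cell_size_m = cfgs$grid$cell_size_m)
  else NULL
  codec_path <- file.path(dir, "codec.json")
  codec <- if (file.exists(codec_path)) read_codec(codec_path) else NULL
  hist_lines <- readLines(file.path(dir, "history.jsonl"))
  history <- do.call(rbind, lapply(hist_lines, function(l)
    as.data.frame(jsonlite::fromJSON(l))))
  structure(
    list(params = readRDS(file.path(dir, "params.rds")), model_config = mc,
         train_config = tc, codec = codec, corpus_config = cc, grid = grid,
         history = history, best_epoch = cfgs$best_epoch),
    class = "checkpoint"
  )
}
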
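#' Initialise an incremental decoding state
#'
#' Generation during simulation appends a handful of sub-tokens per tick to a
#' long-lived context, so the model keeps a per-sequence key/value cache and
#' only ever computes attention for new positions against cached keys.
#'
#' @param ckpt A trained [train_model()] checkpoint.
#' @return A mutable decode state (environment).
#' @export
decode_state <- function(ckpt) {
  mc <- ckpt$model_config
  st <- new.env(parent = emptyenv())
  st$pos <- 0L
  st$Lmax <- mc$context_length
  st$K <- vector("list", mc$n_layers)
  st$V <- vector("list", mc$n_layers)
  for (l in seq_len(mc$n_layers)) {
    st$K[[l]] <- matrix(0, st$Lmax, mc$hidden_size)
    st$V[[l]] <- matrix(0, st$Lmax, mc$hidden_size)
  }
  st$logits <- NULL
  st
}

#' Append ids to a decode state and return last-position logits
#'
#' @param ckpt Checkpoint.
#' @param st A [decode_state()].
#' @param ids Integer ids to append (must fit in the remaining context).
#' @return The logits row (numeric vector length V) at the final position;
#'   also stored in `st$logits`.
#' @export
decode_append <- function(ckpt, st, ids) {
  params <- ckpt$params; mc <- ckpt$model_config
  n <- length(ids)
  if (n == 0L) return(st$logits)
  if (st$pos + n > st$Lmax)
    stop("decode state overflow: truncate the context first", call. = FALSE)
  h <- mc$hidden_size; H <- mc$n_heads; dh <- h %/% H
  pos <- st$pos + seq_len(n)
  x <- params$tok_emb[ids, , drop = FALSE]
  if (mc$use_pos_emb) x <- x + params$pos_emb[pos, , drop = FALSE]
  total <- st$pos + n
  neg <- matrix(0, n, total)
  # new position i (global st$pos+i) may attend to global positions <= st$pos+i
  for (i in seq_len(n)) if (st$pos + i < total)
    neg[i, (st$pos + i + 1L):total] <- -Inf
  for (l in seq_len(mc$n_layers)) {
    ln1 <- layernorm_fwd(x, params[[paste0("ln1_g_", l)]],
                         params[[paste0("ln1_b_", l)]])
    qkv <- ln1$y %*% params[[paste0("attn_w_", l)]] +
      matrix(params[[paste0("attn_b_", l)]], n, 3L * h, byrow = TRUE)
    st$K[[l]][pos, ] <- qkv[, h + seq_len(h), drop = FALSE]
    st$V[[l]][pos, ] <- qkv[, 2L * h + seq_len(h), drop = FALSE]
    O <- matrix(0, n, h)
    for (hd in seq_len(H)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      Q <- qkv[, cols, drop = FALSE]
      K <- st$K[[l]][seq_len(total), cols, drop = FALSE]
      V <- st$V[[l]][seq_len(total), cols, drop = FALSE]
      S <- tcrossprod(Q, K) / sqrt(dh) + neg
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      O[, cols] <- A %*% V
    }
    x1 <- x + O %*% params[[paste0("proj_w_", l)]] +
      matrix(params[[paste0("proj_b_", l)]], n, h, byrow = TRUE)
    ln2 <- layernorm_fwd(x1, params[[paste0("ln2_g_", l)]],
                         params[[paste0("ln2_b_", l)]])
    u <- ln2$y %*% params[[paste0("mlp_w1_", l)]] +
      matrix(params[[paste0("mlp_b1_", l)]], n, 4L * h, byrow = TRUE)
    x <- x1 + gelu_fwd(u) %*% params[[paste0("mlp_w2_", l)]] +
      matrix(params[[paste0("mlp_b2_", l)]], n, h, byrow = TRUE)
  }
  st$pos <- total
  lnf <- layernorm_fwd(x[n, , drop = FALSE], params$lnf_g, params$lnf_b)
  st$logits <- as.numeric(tcrossprod(lnf$y, params$tok_emb))
  st$logits
}

#' Prefix trie over the valid focal words
#'
#' Enumerates the sub-token id sequences of every admissible next word — the
#' focal word `S<code>` for every grid cell, plus the end-of-trajectory word —
#' so that constrained sampling can only ever emit well-formed tokens.
#'
#' @param ckpt Checkpoint (codec, grid, corpus config all come from it).
#' @return A list with `seqs` (integer matrix padded with NA, one row per
#'   word), `codes` (the cell code per row, NA for the end word), `eos_row`.
#' @export
focal_token_trie <- function(ckpt) {
  grid <- ckpt$grid; cfg <- ckpt$corpus_config; codec <- ckpt$codec
  cells <- expand.grid(col = 0:(grid$n_cols - 1L), row = 0:(grid$n_rows - 1L))
  codes <- encode_cell(cells$col, cells$row, grid)
  words <- c(paste0(cfg$role_prefixes[1L], codes), cfg$eos_token)
  enc <- lapply(words, encode_word, codec = codec)
  w <- max(lengths(enc))
  seqs <- matrix(NA_integer_, length(enc), w)
  for (i in seq_along(enc)) seqs[i, seq_along(enc[[i]])] <- enc[[i]]
  list(seqs = seqs, codes = c(codes, NA_character_), eos_row = length(words))
}

sample_from_logits <- function(logits, allowed, temperature = 1, top_k = 0L) {
  lg <- logits[allowed]
  if (temperature <= 1e-6) return(allowed[which.max(lg)])
  lg <- lg / temperature
  if (top_k > 0L && top_k < length(lg)) {
    keep <- order(lg, decreasing = TRUE)[seq_len(top_k)]
    allowed <- allowed[keep]; lg <- lg[keep]
  }
  p <- exp(lg - max(lg)); p <- p / sum(p)
  allowed[sample.int(length(allowed), 1L, prob = p)]
}

#' Sample the next focal position under the token-validity constraint
#'
#' Sub-tokens are sampled autoregressively, at every step restricted to
#' continuations that can still complete to a valid focal word or the
#' end-of-trajectory word, so the output is a well-formed cell code or EOS by
#' construction. The caller's context must end at a frame boundary.
#'
#' @param ckpt Checkpoint.
#' @param st A [decode_state()] whose logits are current (after
#'   [decode_append()] of the context). The sampled sub-tokens are appended
#'   to the state.
#' @param trie A [focal_token_trie()] (precompute once per checkpoint).
#' @param temperature Softmax temperature; 0 gives greedy argmax.
#' @param top_k Restrict sampling to the `top_k` allowed continuations
#'   (0 = no restriction).
#' @return A list: `code` (cell code, or `NA` for EOS), `eos` (logical),
#'   `ids` (the sampled sub-token ids).
#' @export
next_focal_token <- function(ckpt, st, trie, temperature = 1, top_k = 0L) {
  # Codes are fixed-length and decoding is injective, so no word's id
  # sequence is a strict prefix of another's: a word is complete exactly when
  # the surviving row's sequence ends, and it is then unique.
  live <- seq_len(nrow(trie$seqs))
  sampled <- integer(0)
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- trie$seqs[live, step]
    allowed <- sort(unique(cand[!is.na(cand)]))
    stopifnot(length(allowed) > 0L)  # trie dead-end is impossible by construction
    id <- sample_from_logits(st$logits, allowed, temperature, top_k)
    sampled <- c(sampled, id)
    live <- live[!is.na(cand) & cand == id]
    decode_append(ckpt, st, id)
    finished <- step == ncol(trie$seqs) |
      is.na(trie$seqs[live, min(step + 1L, ncol(trie$seqs))])
    if (any(finished)) {
      row <- live[finished]
      stopifnot(length(row) == 1L, length(live) == 1L)
      return(list(code = trie$codes[row], eos = row == trie$eos_row,
                  ids = sampled))
    }
  }
}
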
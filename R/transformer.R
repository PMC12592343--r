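#' Model configuration for the trajectory transformer
#'
#' A GPT-2-style decoder-only architecture: learned token and positional
#' embeddings, pre-layer-norm blocks of causal multi-head self-attention and a
#' GELU MLP (expansion 4), a final layer norm, and an output head tied to the
#' token embedding. Two named presets are provided: `"full"` mirrors the
#' full-scale configuration (12 layers, 12 heads, hidden 768, context 6144),
#' `"desk"` is a CPU-trainable reduction (2 layers, 4 heads, hidden 128,
#' context 768).
#'
#' @param preset `"desk"`, `"full"`, or `NULL` for fully manual fields.
#' @param n_layers,n_heads,hidden_size,context_length Architecture sizes;
#'   override the preset when supplied.
#' @param vocab_size Sub-token vocabulary size (set from the codec).
#' @param use_pos_emb Add learned positional embeddings.
#' @return An object of class `model_config`.
#' @export
model_config <- function(preset = c("desk", "full"), n_layers = NULL,
                         n_heads = NULL, hidden_size = NULL,
                         context_length = NULL, vocab_size = NULL,
                         use_pos_emb = TRUE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    p <- switch(preset,
      full = list(n_layers = 12L, n_heads = 12L, hidden_size = 768L,
                   context_length = 6144L),
      desk  = list(n_layers = 2L, n_heads = 4L, hidden_size = 128L,
                   context_length = 768L))
  } else {
    p <- list(n_layers = NULL, n_heads = NULL, hidden_size = NULL,
              context_length = NULL)
  }
  mc <- list(
    n_layers = as.integer(n_layers %||% p$n_layers),
    n_heads = as.integer(n_heads %||% p$n_heads),
    hidden_size = as.integer(hidden_size %||% p$hidden_size),
    context_length = as.integer(context_length %||% p$context_length),
    vocab_size = if (is.null(vocab_size)) NA_integer_ else as.integer(vocab_size),
    use_pos_emb = isTRUE(use_pos_emb))
  if (anyNA(unlist(mc[c("n_layers", "n_heads", "hidden_size", "context_length")])))
    stop("incomplete model configuration", call. = FALSE)
  if (mc$hidden_size %% mc$n_heads != 0L)
    stop("hidden_size must be divisible by n_heads", call. = FALSE)
  structure(mc, class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialise transformer parameters
#'
#' Weights are drawn N(0, 0.02^2); layer-norm gains start at 1, all biases at
#' 0. The output head shares the token embedding matrix.
#'
#' @param mc A [model_config()] with `vocab_size` set.
#' @param seed Integer seed for the initial draw.
#' @return A named list of parameter matrices/vectors.
#' @export
init_params <- function(mc, seed = 1L) {
  if (is.na(mc$vocab_size)) stop("vocab_size not set", call. = FALSE)
  set.seed(as.integer(seed))
  h <- mc$hidden_size
  rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  p <- list(tok_emb = rmat(mc$vocab_size, h))
  if (mc$use_pos_emb) p$pos_emb <- rmat(mc$context_length, h)
  for (l in seq_len(mc$n_layers)) {
    p[[paste0("ln1_g_", l)]] <- rep(1, h)
    p[[paste0("ln1_b_", l)]] <- rep(0, h)
    p[[paste0("attn_w_", l)]] <- rmat(h, 3L * h)
    p[[paste0("attn_b_", l)]] <- rep(0, 3L * h)
    # residual projections scaled down with depth, as in GPT-2
    p[[paste0("proj_w_", l)]] <- rmat(h, h, 0.02 / sqrt(2 * mc$n_layers))
    p[[paste0("proj_b_", l)]] <- rep(0, h)
    p[[paste0("ln2_g_", l)]] <- rep(1, h)
    p[[paste0("ln2_b_", l)]] <- rep(0, h)
    p[[paste0("mlp_w1_", l)]] <- rmat(h, 4L * h)
    p[[paste0("mlp_b1_", l)]] <- rep(0, 4L * h)
    p[[paste0("mlp_w2_", l)]] <- rmat(4L * h, h, 0.02 / sqrt(2 * mc$n_layers))
    p[[paste0("mlp_b2_", l)]] <- rep(0, h)
  }
  p$lnf_g <- rep(1, h)
  p$lnf_b <- rep(0, h)
  p
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

gelu_fwd <- function(u) u * stats::pnorm(u)
gelu_grad <- function(u) stats::pnorm(u) + u * stats::dnorm(u)

#' Transformer forward pass
#'
#' Runs the model over one id sequence and returns per-position logits; with
#' `keep_cache = TRUE` all intermediates needed by [transformer_backward()]
#' are retained.
#'
#' @param params Parameter list from [init_params()].
#' @param mc The [model_config()].
#' @param ids Integer sub-token ids (length <= `context_length`).
#' @param keep_cache Retain intermediates for the backward pass.
#' @return A list with `logits` (L x V) and, if requested, `cache`.
#' @export
transformer_forward <- function(params, mc, ids, keep_cache = FALSE) {
  L <- length(ids)
  if (L < 1L) stop("empty id sequence", call. = FALSE)
  if (L > mc$context_length)
    stop("sequence longer than context_length; truncate first", call. = FALSE)
  h <- mc$hidden_size; H <- mc$n_heads; dh <- h %/% H
  x <- params$tok_emb[ids, , drop = FALSE]
  if (mc$use_pos_emb) x <- x + params$pos_emb[seq_len(L), , drop = FALSE]
  neg <- matrix(0, L, L)
  neg[upper.tri(neg)] <- -Inf  # position i attends to positions <= i
  cache <- if (keep_cache) list(ids = ids, L = L) else NULL
  for (l in seq_len(mc$n_layers)) {
    ln1 <- layernorm_fwd(x, params[[paste0("ln1_g_", l)]],
                         params[[paste0("ln1_b_", l)]])
    qkv <- ln1$y %*% params[[paste0("attn_w_", l)]] +
      matrix(params[[paste0("attn_b_", l)]], L, 3L * h, byrow = TRUE)
    O <- matrix(0, L, h)
    heads <- if (keep_cache) vector("list", H) else NULL
    for (hd in seq_len(H)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      Q <- qkv[, cols, drop = FALSE]
      K <- qkv[, h + cols, drop = FALSE]
      V <- qkv[, 2L * h + cols, drop = FALSE]
      S <- tcrossprod(Q, K) / sqrt(dh) + neg
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      O[, cols] <- A %*% V
      if (keep_cache) heads[[hd]] <- list(A = A, Q = Q, K = K, V = V)
    }
    attn_out <- O %*% params[[paste0("proj_w_", l)]] +
      matrix(params[[paste0("proj_b_", l)]], L, h, byrow = TRUE)
    x1 <- x + attn_out
    ln2 <- layernorm_fwd(x1, params[[paste0("ln2_g_", l)]],
                         params[[paste0("ln2_b_", l)]])
    u <- ln2$y %*% params[[paste0("mlp_w1_", l)]] +
      matrix(params[[paste0("mlp_b1_", l)]], L, 4L * h, byrow = TRUE)
    gact <- gelu_fwd(u)
    x2 <- x1 + gact %*% params[[paste0("mlp_w2_", l)]] +
      matrix(params[[paste0("mlp_b2_", l)]], L, h, byrow = TRUE)
    if (keep_cache)
      cache[[paste0("layer_", l)]] <- list(
        x_in = x, ln1 = ln1, a = ln1$y, heads = heads, O = O, x1 = x1,
        ln2 = ln2, m = ln2$y, u = u, gact = gact)
    x <- x2
  }
  lnf <- layernorm_fwd(x, params$lnf_g, params$lnf_b)
  logits <- tcrossprod(lnf$y, params$tok_emb)
  if (keep_cache) {
    cache$x_final <- x
    cache$lnf <- lnf
    cache$f <- lnf$y
  }
  list(logits = logits, cache = cache)
}

#' Masked cross-entropy loss
#'
#' Mean cross-entropy over masked-in label positions only. Position `i`
#' predicts `labels[i]`; positions with `mask[i] == FALSE` contribute exactly
#' zero to the value and (see [masked_loss_grad()]) to the gradient — this is
#' the asymmetric loss that keeps neighbour context out of the learning
#' signal.
#'
#' @param logits L x V score matrix.
#' @param labels Integer label ids, length L (label for position i).
#' @param mask Logical vector, length L.
#' @return Scalar loss.
#' @export
masked_loss <- function(logits, labels, mask) {
  if (!any(mask)) stop("all-false mask: degenerate batch, skip it", call. = FALSE)
  idx <- which(mask)
  lg <- logits[idx, , drop = FALSE]
  mx <- apply(lg, 1L, max)
  lse <- mx + log(rowSums(exp(lg - mx)))
  picked <- lg[cbind(seq_along(idx), labels[idx])]
  mean(lse - picked)
}

#' Gradient of the masked loss with respect to the logits
#'
#' Rows at masked-out positions are exactly zero.
#'
#' @inheritParams masked_loss
#' @return L x V gradient matrix.
#' @export
masked_loss_grad <- function(logits, labels, mask) {
  d <- matrix(0, nrow(logits), ncol(logits))
  idx <- which(mask)
  if (length(idx) == 0L) return(d)
  lg <- logits[idx, , drop = FALSE]
  mx <- apply(lg, 1L, max)
  E <- exp(lg - mx)
  P <- E / rowSums(E)
  P[cbind(seq_along(idx), labels[idx])] <-
    P[cbind(seq_along(idx), labels[idx])] - 1
  d[idx, ] <- P / length(idx)
  d
}

#' Transformer backward pass
#'
#' Backpropagates a logits gradient through the cached forward pass and
#' returns per-parameter gradients (same names/shapes as the parameter list).
#'
#' @param params Parameter list.
#' @param mc The [model_config()].
#' @param fwd Result of `transformer_forward(..., keep_cache = TRUE)`.
#' @param dlogits Gradient of the loss w.r.t. the logits (L x V).
#' @return Named list of gradients.
#' @export
transformer_backward <- function(params, mc, fwd, dlogits) {
  cache <- fwd$cache
  ids <- cache$ids; L <- cache$L
  h <- mc$hidden_size; H <- mc$n_heads; dh <- h %/% H
  g <- list()
  # output head (tied embedding): logits = f %*% t(tok_emb)
  g$tok_emb <- crossprod(dlogits, cache$f)
  df <- dlogits %*% params$tok_emb
  lb <- layernorm_bwd(df, cache$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx
  for (l in rev(seq_len(mc$n_layers))) {
    cl <- cache[[paste0("layer_", l)]]
    # MLP branch
    dgact <- dx %*% t(params[[paste0("mlp_w2_", l)]])
    g[[paste0("mlp_w2_", l)]] <- crossprod(cl$gact, dx)
    g[[paste0("mlp_b2_", l)]] <- colSums(dx)
    du <- dgact * gelu_grad(cl$u)
    g[[paste0("mlp_w1_", l)]] <- crossprod(cl$m, du)
    g[[paste0("mlp_b1_", l)]] <- colSums(du)
    dm <- du %*% t(params[[paste0("mlp_w1_", l)]])
    lb2 <- layernorm_bwd(dm, cl$ln2, params[[paste0("ln2_g_", l)]])
    g[[paste0("ln2_g_", l)]] <- lb2$dg; g[[paste0("ln2_b_", l)]] <- lb2$db
    dx1 <- dx + lb2$dx
    # attention branch
    dO <- dx1 %*% t(params[[paste0("proj_w_", l)]])
    g[[paste0("proj_w_", l)]] <- crossprod(cl$O, dx1)
    g[[paste0("proj_b_", l)]] <- colSums(dx1)
    dqkv <- matrix(0, L, 3L * h)
    for (hd in seq_len(H)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      hc <- cl$heads[[hd]]
      dOi <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOi, hc$V)
      dV <- crossprod(hc$A, dOi)
      dS <- hc$A * (dA - rowSums(dA * hc$A))
      dqkv[, cols] <- (dS %*% hc$K) / sqrt(dh)
      dqkv[, h + cols] <- crossprod(dS, hc$Q) / sqrt(dh)
      dqkv[, 2L * h + cols] <- dV
    }
    g[[paste0("attn_w_", l)]] <- crossprod(cl$a, dqkv)
    g[[paste0("attn_b_", l)]] <- colSums(dqkv)
    da <- dqkv %*% t(params[[paste0("attn_w_", l)]])
    lb1 <- layernorm_bwd(da, cl$ln1, params[[paste0("ln1_g_", l)]])
    g[[paste0("ln1_g_", l)]] <- lb1$dg; g[[paste0("ln1_b_", l)]] <- lb1$db
    dx <- dx1 + lb1$dx
  }
  # embeddings
  demb <- rowsum(dx, group = ids, reorder = FALSE)
  rows <- as.integer(rownames(demb))
  g$tok_emb[rows, ] <- g$tok_emb[rows, , drop = FALSE] + demb
  if (mc$use_pos_emb) {
    g$pos_emb <- matrix(0, mc$context_length, h)
    g$pos_emb[seq_len(L), ] <- dx
  }
  g
}
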
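# Miniature decoder transformer, written in base R with hand-derived
# backpropagation. Supports the toolkit's ablation axes as configuration:
# causal vs masked (MLM) objectives, four positional-encoding schemes
# (rotary, learnable, fixed sinusoidal, relative shared-bias-per-offset),
# and sliding-window vs dense attention. Pre-LN residual blocks with a
# 4x GELU feed-forward; all forward scores are bit-reproducible on CPU for
# a fixed seed.

#' Model configuration
#'
#' Desk-scale defaults (4 layers x 128 hidden); the production-scale
#' reference point (20 x 1856) is expressible but never required.
#'
#' @param n_layers transformer layers.
#' @param d_model hidden width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param vocab_size token vocabulary size (<= 16).
#' @param context_length maximum context length L in tokens.
#' @param objective `causal` (next-token) or `mlm` (masked, bidirectional).
#' @param mask_rate MLM corruption rate (default 0.15).
#' @param positional_encoding `rotary`, `learnable`, `fixed`, or `relative`.
#' @param attention_window window size w in tokens, or `Inf` for dense.
#'   Causal attention sees the previous `w` slots (self included); MLM sees
#'   slots within `w - 1` of itself on either side. `w = L` reproduces dense
#'   attention exactly.
#' @param ffn_mult feed-forward expansion ratio.
#' @param seed initialization seed.
#' @return A `model_config`.
#' @export
model_config <- function(n_layers = 4L, d_model = 128L, n_heads = 4L,
                         vocab_size = 9L, context_length = 1024L,
                         objective = "causal", mask_rate = 0.15,
                         positional_encoding = "rotary",
                         attention_window = Inf, ffn_mult = 4L, seed = 1L) {
  objective <- match.arg(objective, c("causal", "mlm"))
  positional_encoding <- match.arg(positional_encoding,
                                   c("rotary", "learnable", "fixed", "relative"))
  check_scalar(n_layers, "n_layers", lower = 1, integer = TRUE)
  check_scalar(d_model, "d_model", lower = 2, integer = TRUE)
  check_scalar(n_heads, "n_heads", lower = 1, integer = TRUE)
  if (d_model %% n_heads != 0L)
    fail("d_model (%d) must be divisible by n_heads (%d)", d_model, n_heads)
  check_scalar(vocab_size, "vocab_size", lower = 2, upper = 16, integer = TRUE)
  check_scalar(context_length, "context_length", lower = 2, integer = TRUE)
  if (!(mask_rate > 0 && mask_rate < 1)) fail("mask_rate must be in (0, 1)")
  if (!is.infinite(attention_window)) {
    check_scalar(attention_window, "attention_window", lower = 1, integer = TRUE)
    if (attention_window > context_length)
      fail("attention_window (%d) must not exceed context_length (%d)",
           attention_window, context_length)
  }
  hd <- d_model %/% n_heads
  if (positional_encoding == "rotary" && hd %% 2L != 0L)
    fail("rotary encoding needs an even head dimension (d_model/n_heads = %d)", hd)
  structure(list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads), vocab_size = as.integer(vocab_size),
                 context_length = as.integer(context_length), objective = objective,
                 mask_rate = mask_rate, positional_encoding = positional_encoding,
                 attention_window = attention_window, ffn_mult = as.integer(ffn_mult),
                 seed = as.integer(seed)), class = "model_config")
}

layer_param_names <- function(l) {
  paste0(sprintf("l%02d_", l),
         c("ln1g", "ln1b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "ln2g", "ln2b", "W1", "b1", "W2", "b2"))
}

#' Closed-form parameter count for a model configuration
#' @param config a [model_config()].
#' @return Total number of scalar parameters.
#' @export
count_parameters <- function(config) {
  d <- config$d_model; V <- config$vocab_size; L <- config$context_length
  f <- config$ffn_mult * d
  per_layer <- 2 * d + 4 * (d * d + d) + 2 * d + (d * f + f) + (f * d + d)
  total <- V * d + config$n_layers * per_layer + 2 * d + d * V + V
  if (config$positional_encoding == "learnable") total <- total + L * d
  if (config$positional_encoding == "relative")
    total <- total + config$n_heads * (2 * L - 1)
  total
}

#' Build a model with seeded initialization
#'
#' Weight matrices are drawn N(0, 0.02^2); biases are zero; layer-norm gains
#' start at 1. Identical seeds give identical initial parameters.
#'
#' @param config a [model_config()].
#' @return A `readlm_model`: list with `config`, `params`, `step`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d_model; V <- config$vocab_size; L <- config$context_length
  f <- config$ffn_mult * d
  p <- list()
  with_seed(derive_seed(config$seed, 808L), {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    p$emb <- rn(V, d)
    if (config$positional_encoding == "learnable") p$pos <- rn(L, d)
    if (config$positional_encoding == "relative")
      p$relb <- matrix(0, config$n_heads, 2L * L - 1L)
    for (l in seq_len(config$n_layers)) {
      nm <- layer_param_names(l)
      p[[nm[1]]] <- rep(1, d); p[[nm[2]]] <- rep(0, d)
      p[[nm[3]]] <- rn(d, d); p[[nm[4]]] <- rep(0, d)
      p[[nm[5]]] <- rn(d, d); p[[nm[6]]] <- rep(0, d)
      p[[nm[7]]] <- rn(d, d); p[[nm[8]]] <- rep(0, d)
      p[[nm[9]]] <- rn(d, d) / sqrt(2 * config$n_layers); p[[nm[10]]] <- rep(0, d)
      p[[nm[11]]] <- rep(1, d); p[[nm[12]]] <- rep(0, d)
      p[[nm[13]]] <- rn(d, f); p[[nm[14]]] <- rep(0, f)
      p[[nm[15]]] <- rn(f, d) / sqrt(2 * config$n_layers); p[[nm[16]]] <- rep(0, d)
    }
    p$lnfg <- rep(1, d); p$lnfb <- rep(0, d)
    p$Wout <- rn(d, V); p$bout <- rep(0, V)
  })
  structure(list(config = config, params = p, step = 0L), class = "readlm_model")
}

#' @export
print.readlm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<readlm_model> %d layers x %d hidden, %d heads, %s objective\n",
              cfg$n_layers, cfg$d_model, cfg$n_heads, cfg$objective))
  cat(sprintf("  positional encoding: %s; attention window: %s; context: %d; vocab: %d\n",
              cfg$positional_encoding,
              if (is.infinite(cfg$attention_window)) "dense" else cfg$attention_window,
              cfg$context_length, cfg$vocab_size))
  cat(sprintf("  %s parameters; %d optimizer step(s) taken\n",
              format(count_parameters(cfg), big.mark = ","), x$step))
  invisible(x)
}

#' @export
summary.readlm_model <- function(object, ...) {
  print(object)
  sizes <- vapply(object$params, length, integer(1))
  cat("parameter tensors:\n")
  print(utils::head(sort(sizes, decreasing = TRUE), 10))
  invisible(object)
}

#' @export
coef.readlm_model <- function(object, ...) {
  vapply(object$params, length, integer(1))
}

# ---- numerical primitives ---------------------------------------------------

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

LN_EPS <- 1e-5

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# Small per-session cache for positional tables and attention masks; these
# depend only on (n, d/hd, objective, window) and dominate allocation cost
# when rebuilt per forward pass.
.fwd_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  v <- .fwd_cache[[key]]
  if (is.null(v)) {
    v <- build()
    # keep the cache bounded
    if (length(ls(.fwd_cache)) > 64L) rm(list = ls(.fwd_cache), envir = .fwd_cache)
    .fwd_cache[[key]] <- v
  }
  v
}

sinusoid_pe <- function(n, d) {
  pos <- 0:(n - 1)
  i <- seq_len(d)
  # even columns sine, odd columns cosine, classic 10000^(2k/d) frequencies
  k <- (i - 1) %/% 2
  freq <- 10000^(-2 * k / d)
  ang <- outer(pos, freq)
  pe <- matrix(0, n, d)
  even <- i %% 2L == 1L  # 1-based col 1,3,... take sine
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, !even] <- cos(ang[, !even, drop = FALSE])
  pe
}

rope_tables <- function(n, hd) {
  freq <- 10000^(-(2 * (seq_len(hd %/% 2) - 1)) / hd)
  ang <- outer(0:(n - 1), freq)
  list(cs = cos(ang), sn = sin(ang))
}

rope_apply <- function(X, rt, inverse = FALSE) {
  hd <- ncol(X)
  o <- seq(1L, hd, by = 2L); e <- o + 1L
  sn <- if (inverse) -rt$sn else rt$sn
  X1 <- X[, o, drop = FALSE]; X2 <- X[, e, drop = FALSE]
  Y <- X
  Y[, o] <- X1 * rt$cs - X2 * sn
  Y[, e] <- X1 * sn + X2 * rt$cs
  Y
}

# Visibility mask (TRUE = may attend). Causal: j in (i-w, i]; MLM: |i-j| < w.
attn_mask <- function(n, objective, w) {
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  if (objective == "causal") {
    m <- j <= i
    if (is.finite(w)) m <- m & (j > i - w)
  } else {
    m <- if (is.finite(w)) abs(i - j) < w else matrix(TRUE, n, n)
  }
  m
}

masked_softmax_rows <- function(S, neg) {
  S <- S + neg  # neg is 0 on visible slots, -Inf elsewhere
  # per-row max shift: row i's shift depends only on its own visible slots,
  # which keeps causal outputs bit-identical under perturbation of later
  # slots (max.col is the fastest row-max available in base R)
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# ---- forward / backward -----------------------------------------------------

# Forward pass on one sequence of 1-based token ids. need: "logits" computes
# output projection; collect_layers stores per-block outputs for probing;
# keep_cache retains activations for backprop.
model_forward <- function(params, cfg, ids1, need = "logits",
                          keep_cache = FALSE, collect_layers = FALSE) {
  n <- length(ids1)
  d <- cfg$d_model; H <- cfg$n_heads; hd <- d %/% H
  x <- params$emb[ids1, , drop = FALSE]
  if (cfg$positional_encoding == "learnable")
    x <- x + params$pos[seq_len(n), , drop = FALSE]
  if (cfg$positional_encoding == "fixed")
    x <- x + cached(sprintf("pe_%d_%d", n, d), function() sinusoid_pe(n, d))
  rt <- if (cfg$positional_encoding == "rotary")
    cached(sprintf("rope_%d_%d", n, hd), function() rope_tables(n, hd)) else NULL
  neg <- cached(sprintf("mask_%d_%s_%s", n, cfg$objective, cfg$attention_window),
                function() {
                  m <- attn_mask(n, cfg$objective, cfg$attention_window)
                  nm <- matrix(0, n, n); nm[!m] <- -Inf; nm
                })
  offidx <- if (cfg$positional_encoding == "relative")
    cached(sprintf("off_%d_%d", n, cfg$context_length), function()
      outer(seq_len(n), seq_len(n), function(i, j) i - j + cfg$context_length)) else NULL
  scale <- 1 / sqrt(hd)
  layers_out <- if (collect_layers) list(x) else NULL
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    nm <- layer_param_names(l)
    x_in <- x
    ln1 <- ln_fwd(x_in, params[[nm[1]]], params[[nm[2]]])
    h <- ln1$y
    Q <- h %*% params[[nm[3]]] + rep(params[[nm[4]]], each = n)
    K <- h %*% params[[nm[5]]] + rep(params[[nm[6]]], each = n)
    V <- h %*% params[[nm[7]]] + rep(params[[nm[8]]], each = n)
    O <- matrix(0, n, d)
    As <- if (keep_cache) vector("list", H) else NULL
    Qr <- Q; Kr <- K
    for (hh in seq_len(H)) {
      cols <- (hh - 1L) * hd + seq_len(hd)
      qh <- Q[, cols, drop = FALSE]; kh <- K[, cols, drop = FALSE]
      if (!is.null(rt)) {
        qh <- rope_apply(qh, rt); kh <- rope_apply(kh, rt)
        Qr[, cols] <- qh; Kr[, cols] <- kh
      }
      S <- tcrossprod(qh, kh) * scale
      if (!is.null(offidx)) S <- S + matrix(params$relb[hh, offidx], n, n)
      A <- masked_softmax_rows(S, neg)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      if (keep_cache) As[[hh]] <- A
    }
    attn <- O %*% params[[nm[9]]] + rep(params[[nm[10]]], each = n)
    xmid <- x_in + attn
    ln2 <- ln_fwd(xmid, params[[nm[11]]], params[[nm[12]]])
    U <- ln2$y %*% params[[nm[13]]] + rep(params[[nm[14]]], each = n)
    G <- gelu(U)
    ffn <- G %*% params[[nm[15]]] + rep(params[[nm[16]]], each = n)
    x <- xmid + ffn
    if (collect_layers) layers_out[[l + 1L]] <- x
    if (keep_cache)
      caches[[l]] <- list(x_in = x_in, ln1 = ln1, h = h, Qr = Qr, Kr = Kr, V = V,
                          As = As, O = O, xmid = xmid, ln2 = ln2, U = U, G = G)
  }
  lnf <- ln_fwd(x, params$lnfg, params$lnfb)
  Hf <- lnf$y
  logits <- if (need == "logits") Hf %*% params$Wout + rep(params$bout, each = n) else NULL
  list(logits = logits, Hf = Hf, layers = layers_out,
       cache = if (keep_cache) list(ids1 = ids1, n = n, layers = caches, lnf = lnf,
                                    x_final = x, rt = rt, offidx = offidx,
                                    Hf = Hf) else NULL)
}

# Backward pass. dlogits (n x V) and/or dHf_extra (n x d) seed the gradient;
# returns a named list of gradients matching the parameter layout (missing
# entries are zero tensors).
model_backward <- function(params, cfg, cache, dlogits = NULL, dHf_extra = NULL) {
  n <- cache$n; d <- cfg$d_model; H <- cfg$n_heads; hd <- d %/% H
  scale <- 1 / sqrt(hd)
  g <- list()
  dHf <- if (!is.null(dlogits)) tcrossprod(dlogits, params$Wout) else matrix(0, n, d)
  if (!is.null(dlogits)) {
    g$Wout <- crossprod(cache$Hf, dlogits)
    g$bout <- colSums(dlogits)
  } else {
    g$Wout <- matrix(0, d, cfg$vocab_size); g$bout <- rep(0, cfg$vocab_size)
  }
  if (!is.null(dHf_extra)) dHf <- dHf + dHf_extra
  bf <- ln_bwd(dHf, cache$lnf, params$lnfg)
  g$lnfg <- bf$dg; g$lnfb <- bf$db
  dx <- bf$dx
  if (cfg$positional_encoding == "relative")
    g$relb <- matrix(0, H, 2L * cfg$context_length - 1L)
  for (l in rev(seq_len(cfg$n_layers))) {
    nm <- layer_param_names(l)
    cc <- cache$layers[[l]]
    # FFN block
    dffn <- dx
    g[[nm[15]]] <- crossprod(cc$G, dffn)
    g[[nm[16]]] <- colSums(dffn)
    dG <- tcrossprod(dffn, params[[nm[15]]])
    dU <- dG * gelu_grad(cc$U)
    g[[nm[13]]] <- crossprod(cc$ln2$y, dU)
    g[[nm[14]]] <- colSums(dU)
    dh2 <- tcrossprod(dU, params[[nm[13]]])
    b2 <- ln_bwd(dh2, cc$ln2, params[[nm[11]]])
    g[[nm[11]]] <- b2$dg; g[[nm[12]]] <- b2$db
    dxmid <- dx + b2$dx
    # attention block
    dattn <- dxmid
    g[[nm[9]]] <- crossprod(cc$O, dattn)
    g[[nm[10]]] <- colSums(dattn)
    dO <- tcrossprod(dattn, params[[nm[9]]])
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (hh in seq_len(H)) {
      cols <- (hh - 1L) * hd + seq_len(hd)
      A <- cc$As[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(A * dA))
      if (cfg$positional_encoding == "relative") {
        acc <- rowsum(as.vector(dS), as.vector(cache$offidx))
        g$relb[hh, as.integer(rownames(acc))] <-
          g$relb[hh, as.integer(rownames(acc))] + acc[, 1]
      }
      qh <- cc$Qr[, cols, drop = FALSE]; kh <- cc$Kr[, cols, drop = FALSE]
      dqh <- (dS %*% kh) * scale
      dkh <- (crossprod(dS, qh)) * scale
      if (!is.null(cache$rt)) {
        dqh <- rope_apply(dqh, cache$rt, inverse = TRUE)
        dkh <- rope_apply(dkh, cache$rt, inverse = TRUE)
      }
      dQ[, cols] <- dqh; dK[, cols] <- dkh
    }
    g[[nm[3]]] <- crossprod(cc$h, dQ); g[[nm[4]]] <- colSums(dQ)
    g[[nm[5]]] <- crossprod(cc$h, dK); g[[nm[6]]] <- colSums(dK)
    g[[nm[7]]] <- crossprod(cc$h, dV); g[[nm[8]]] <- colSums(dV)
    dh <- tcrossprod(dQ, params[[nm[3]]]) + tcrossprod(dK, params[[nm[5]]]) +
      tcrossprod(dV, params[[nm[7]]])
    b1 <- ln_bwd(dh, cc$ln1, params[[nm[1]]])
    g[[nm[1]]] <- b1$dg; g[[nm[2]]] <- b1$db
    dx <- dxmid + b1$dx
  }
  # embedding / learnable positional gradients
  ids1 <- cache$ids1
  dEmb <- matrix(0, cfg$vocab_size, d)
  agg <- rowsum(dx, group = ids1)
  dEmb[as.integer(rownames(agg)), ] <- agg
  g$emb <- dEmb
  if (cfg$positional_encoding == "learnable") {
    dP <- matrix(0, cfg$context_length, d)
    dP[seq_len(n), ] <- dx
    g$pos <- dP
  }
  g
}

#' Per-slot logits for a token sequence
#'
#' Runs the forward pass and returns one row of vocabulary scores per input
#' slot. In causal mode the score at slot t depends only on slots <= t; in
#' mlm mode attention is bidirectional. Windowed attention restricts
#' visibility to the `attention_window` most recent visible slots.
#'
#' @param model a `readlm_model`.
#' @param token_ids integer token ids (0-based), length <= context length.
#' @param objective optional override of the model's objective mask.
#' @return A numeric matrix (length(token_ids) x vocab_size) of logits;
#'   column j scores token id j-1.
#' @export
predict_logits <- function(model, token_ids, objective = model$config$objective) {
  cfg <- model$config
  if (length(token_ids) > cfg$context_length)
    fail("sequence of %d tokens exceeds context length %d",
         length(token_ids), cfg$context_length)
  if (any(token_ids < 0L) || any(token_ids >= cfg$vocab_size))
    fail("token id out of range [0, %d]", cfg$vocab_size - 1L)
  cfg2 <- cfg; cfg2$objective <- objective
  model_forward(model$params, cfg2, as.integer(token_ids) + 1L)$logits
}

#' @export
predict.readlm_model <- function(object, newdata, ...) {
  predict_logits(object, newdata)
}

#' Sample nucleotide sequence from a causal model
#'
#' Autoregressive ancestral sampling over nucleotide tokens, starting from
#' BOS; a convenience for inspecting what a trained model has learned.
#'
#' @param object a `readlm_model` with causal objective.
#' @param nsim number of bases to sample.
#' @param seed integer seed.
#' @param ... unused.
#' @return A character string of sampled bases.
#' @export
simulate.readlm_model <- function(object, nsim = 50, seed = 1L, ...) {
  cfg <- object$config
  if (cfg$objective != "causal") fail("simulate() requires a causal model")
  vocab <- build_vocab()
  nuc <- vocab$nucleotide_ids[1:4]
  ids <- vocab$symbol_to_id[["BOS"]]
  with_seed(derive_seed(seed, 909L), {
    for (i in seq_len(nsim)) {
      window <- utils::tail(ids, cfg$context_length)
      lg <- model_forward(object$params, cfg, window + 1L)$logits
      z <- lg[nrow(lg), nuc + 1L]
      p <- exp(z - max(z)); p <- p / sum(p)
      ids <- c(ids, sample(nuc, 1L, prob = p))
    }
  })
  decode_tokens(ids[-1], vocab)
}

#' Corrupt a context for masked-language-model training
#'
#' Selects `round(mask_rate * n_maskable)` loss-masked nucleotide slots
#' (seeded, without replacement) and applies the standard BERT recipe: 80%
#' become MASK, 10% a random nucleotide, 10% stay unchanged. Loss is
#' computed only on the selected slots.
#'
#' @param context a context as returned by [get_context()] (needs
#'   `token_ids` and `loss_mask`).
#' @param config a [model_config()] (supplies `mask_rate`).
#' @param seed integer seed.
#' @return `NULL` (with a warning) if no slot can be masked; otherwise a
#'   list with `token_ids` (corrupted), `target_slots` (1-based slot
#'   indices) and `targets` (original ids at those slots).
#' @export
mlm_corrupt <- function(context, config, seed) {
  vocab <- build_vocab()
  nuc_lo <- vocab$symbol_to_id[["A"]]
  maskable <- which(context$loss_mask & context$token_ids >= nuc_lo)
  n_sel <- round(config$mask_rate * length(maskable))
  if (n_sel < 1L) {
    warning("mlm_corrupt: no maskable slots selected; context skipped", call. = FALSE)
    return(NULL)
  }
  ids <- context$token_ids
  with_seed(derive_seed(seed, 111L), {
    sel <- sort(sample(maskable, n_sel))
    u <- stats::runif(n_sel)
    targets <- ids[sel]
    repl <- ids[sel]
    repl[u < 0.8] <- vocab$symbol_to_id[["MASK"]]
    rand_ix <- which(u >= 0.8 & u < 0.9)
    if (length(rand_ix))
      repl[rand_ix] <- sample(vocab$nucleotide_ids[1:4], length(rand_ix), replace = TRUE)
    ids[sel] <- repl
  })
  list(token_ids = ids, target_slots = sel, targets = targets)
}
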
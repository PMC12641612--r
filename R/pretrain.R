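# Weighted pretraining: next-token or MLM objective, two-phase scheduling
# with corpus mixing, AdamW updates, next-token-accuracy evaluation and the
# ablation-grid runner.

#' Training configuration
#'
#' @param steps_phase1 optimizer steps on corpus A only (reference-genome
#'   phase).
#' @param steps_phase2 optimizer steps of mixed training.
#' @param batch_size contexts per step.
#' @param learning_rate AdamW learning rate (fixed; no schedule).
#' @param mix_ratio fraction r of phase-2 batches drawn from corpus B
#'   (0.5 encodes a 50:50 mix, 0.86 a 14:86 mix).
#' @param subset_fraction fraction of corpus B made available (e.g. 0.15
#'   exposes 15% of the second corpus).
#' @param weight_decay AdamW decoupled weight decay (matrices only).
#' @param seed integer seed governing sampling and MLM corruption.
#' @return A `train_config`.
#' @export
train_config <- function(steps_phase1 = 100L, steps_phase2 = 0L, batch_size = 4L,
                         learning_rate = 1e-3, mix_ratio = 0.5,
                         subset_fraction = 1, weight_decay = 0.01, seed = 1L) {
  check_scalar(steps_phase1, "steps_phase1", lower = 0, integer = TRUE)
  check_scalar(steps_phase2, "steps_phase2", lower = 0, integer = TRUE)
  check_scalar(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_scalar(learning_rate, "learning_rate", lower = 1e-12)
  check_scalar(mix_ratio, "mix_ratio", lower = 0, upper = 1)
  check_scalar(subset_fraction, "subset_fraction", lower = 1e-12, upper = 1)
  structure(list(steps_phase1 = as.integer(steps_phase1),
                 steps_phase2 = as.integer(steps_phase2),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, mix_ratio = mix_ratio,
                 subset_fraction = subset_fraction, weight_decay = weight_decay,
                 seed = as.integer(seed)), class = "train_config")
}

#' Weighted cross-entropy loss
#'
#' `sum(w_i * CE_i) / sum(w_i)` over the scored slots. With uniform weights
#' this equals the plain mean cross-entropy exactly.
#'
#' @param scores numeric matrix of logits (slots x vocab).
#' @param targets integer token ids (0-based), one per row of `scores`.
#' @param weights non-negative weights, one per row.
#' @return Scalar loss.
#' @export
weighted_loss <- function(scores, targets, weights) {
  if (nrow(scores) != length(targets) || length(targets) != length(weights))
    fail("weighted_loss: shapes disagree")
  if (any(weights < 0)) fail("weighted_loss: weights must be non-negative")
  sw <- sum(weights)
  if (sw <= 0) fail("weighted_loss: all weights are zero")
  mx <- scores[cbind(seq_len(nrow(scores)), max.col(scores, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(scores - mx)))
  ce <- lse - scores[cbind(seq_along(targets), targets + 1L)]
  sum(weights * ce) / sw
}

# Softmax-CE gradient wrt logits, scaled by w/sum(w).
ce_grad <- function(scores, targets, weights) {
  mx <- scores[cbind(seq_len(nrow(scores)), max.col(scores, ties.method = "first"))]
  E <- exp(scores - mx)
  P <- E / rowSums(E)
  P[cbind(seq_along(targets), targets + 1L)] <-
    P[cbind(seq_along(targets), targets + 1L)] - 1
  P * (weights / sum(weights))
}

# ---- AdamW ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, weight_decay = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr * gr
    upd <- (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]]))
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, opt = opt)
}

# ---- batch construction -----------------------------------------------------

# Causal batch: slot t is scored when slot t+1 is loss-masked; target is the
# token at t+1 with that slot's weight. Contexts are trimmed to the longest
# non-PAD prefix in the batch (inert under causal masking).
causal_batch_targets <- function(corpus, rows) {
  lapply(rows, function(i) {
    lm <- corpus$loss_mask[i, ]
    t_idx <- which(lm[-1])  # slots 2..L that are targets; predictor slot = t_idx
    list(ids1 = corpus$tokens[i, ] + 1L, slots = t_idx,
         targets = corpus$tokens[i, t_idx + 1L], weights = corpus$weights[i, t_idx + 1L])
  })
}

train_step <- function(params, cfg, opt, corpus, rows, tcfg, step_seed) {
  B <- length(rows)
  grads_sum <- NULL
  loss_sum <- 0; w_batch <- 0
  if (cfg$objective == "causal") {
    items <- causal_batch_targets(corpus, rows)
    kept <- 0L
    for (it in items) {
      if (!length(it$slots) || sum(it$weights) <= 0) next
      kept <- kept + 1L
      n_eff <- min(max(it$slots) + 1L, length(it$ids1))
      fw <- model_forward(params, cfg, it$ids1[seq_len(n_eff)], keep_cache = TRUE)
      dlog <- matrix(0, n_eff, cfg$vocab_size)
      sc <- fw$logits[it$slots, , drop = FALSE]
      loss_sum <- loss_sum + weighted_loss(sc, it$targets, it$weights)
      dlog[it$slots, ] <- ce_grad(sc, it$targets, it$weights)
      gr <- model_backward(params, cfg, fw$cache, dlogits = dlog)
      grads_sum <- if (is.null(grads_sum)) gr else
        mapply(function(a, b) a + b, grads_sum, gr, SIMPLIFY = FALSE)
    }
    B <- max(kept, 1L)
  } else {
    kept <- 0L
    for (j in seq_along(rows)) {
      i <- rows[j]
      ctx <- list(token_ids = corpus$tokens[i, ], loss_mask = corpus$loss_mask[i, ])
      cor <- mlm_corrupt(ctx, cfg, derive_seed(step_seed, j))
      if (is.null(cor)) next
      kept <- kept + 1L
      fw <- model_forward(params, cfg, cor$token_ids + 1L, keep_cache = TRUE)
      w <- corpus$weights[i, cor$target_slots]
      sc <- fw$logits[cor$target_slots, , drop = FALSE]
      loss_sum <- loss_sum + weighted_loss(sc, cor$targets, w)
      dlog <- matrix(0, length(cor$token_ids), cfg$vocab_size)
      dlog[cor$target_slots, ] <- ce_grad(sc, cor$targets, w)
      gr <- model_backward(params, cfg, fw$cache, dlogits = dlog)
      grads_sum <- if (is.null(grads_sum)) gr else
        mapply(function(a, b) a + b, grads_sum, gr, SIMPLIFY = FALSE)
    }
    B <- max(kept, 1L)
  }
  if (is.null(grads_sum)) return(list(params = params, opt = opt, loss = NA_real_))
  grads <- lapply(grads_sum, function(gz) gz / B)
  st <- adam_step(params, grads, opt, tcfg$learning_rate, tcfg$weight_decay)
  list(params = st$params, opt = st$opt, loss = loss_sum / B)
}

#' Two-phase weighted pretraining
#'
#' Phase 1 samples batches from corpus A only (the reference-genome phase);
#' phase 2 draws each batch from corpus B with probability `mix_ratio`, else
#' from A. `subset_fraction` restricts corpus B to a seeded subset before
#' training starts. Fully reproducible per seed; the loss trace records
#' phase boundaries and the per-batch corpus choice.
#'
#' @param model a [build_model()] model.
#' @param corpusA phase-1 `packed_corpus`.
#' @param corpusB second `packed_corpus` (may be `NULL` when
#'   `steps_phase2 = 0` or `mix_ratio = 0`).
#' @param config a [train_config()].
#' @return A `readlm_train` fit: `model` (trained), `trace` (data frame
#'   `step`, `phase`, `corpus`, `loss`), `config`.
#' @export
train_two_phase <- function(model, corpusA, corpusB = NULL, config = train_config()) {
  stopifnot(inherits(model, "readlm_model"), inherits(config, "train_config"))
  cfg <- model$config
  if (n_contexts(corpusA) == 0L) fail("corpus A is empty")
  r <- config$mix_ratio
  if (config$steps_phase2 > 0L && r > 0) {
    if (is.null(corpusB) || n_contexts(corpusB) == 0L)
      fail("phase 2 with mix_ratio > 0 requires a non-empty corpus B")
  }
  params <- model$params
  opt <- if (!is.null(model$opt)) model$opt else adam_init(params)
  n_steps <- config$steps_phase1 + config$steps_phase2
  trace <- data.frame(step = seq_len(n_steps),
                      phase = rep(c(1L, 2L),
                                  c(config$steps_phase1, config$steps_phase2)),
                      corpus = "A", loss = NA_real_, stringsAsFactors = FALSE)
  availB <- integer(0)
  if (!is.null(corpusB) && n_contexts(corpusB) > 0L) {
    nb <- n_contexts(corpusB)
    n_avail <- max(1L, round(config$subset_fraction * nb))
    with_seed(derive_seed(config$seed, 717L),
              availB <- sort(sample.int(nb, n_avail)))
  }
  with_seed(derive_seed(config$seed, 718L), {
    for (s in seq_len(n_steps)) {
      phase2 <- s > config$steps_phase1
      use_B <- phase2 && r > 0 && stats::runif(1) < r
      if (use_B) {
        rows <- availB[sample.int(length(availB), config$batch_size, replace = TRUE)]
        corp <- corpusB
        trace$corpus[s] <- "B"
      } else {
        rows <- sample.int(n_contexts(corpusA), config$batch_size, replace = TRUE)
        corp <- corpusA
      }
      st <- train_step(params, cfg, opt, corp, rows, config,
                       derive_seed(config$seed, 719L, s))
      params <- st$params; opt <- st$opt
      trace$loss[s] <- st$loss
    }
  })
  model$params <- params
  model$opt <- opt
  model$step <- model$step + n_steps
  structure(list(model = model, trace = trace, config = config),
            class = "readlm_train")
}

#' @export
print.readlm_train <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<readlm_train> %d step(s): phase 1 = %d, phase 2 = %d (B fraction %.2f)\n",
              nrow(tr), sum(tr$phase == 1L), sum(tr$phase == 2L),
              if (any(tr$phase == 2L)) mean(tr$corpus[tr$phase == 2L] == "B") else 0))
  lo <- stats::na.omit(tr$loss)
  if (length(lo) > 1)
    cat(sprintf("  loss: %.4f (first) -> %.4f (last)\n", lo[1], lo[length(lo)]))
  invisible(x)
}

#' @export
plot.readlm_train <- function(x, ...) {
  tr <- x$trace
  plot(tr$step, tr$loss, type = "l", xlab = "step", ylab = "weighted loss", ...)
  if (any(tr$phase == 2L))
    graphics::abline(v = min(tr$step[tr$phase == 2L]) - 0.5, lty = 2)
  invisible(x)
}

#' Next-token prediction accuracy
#'
#' For every slot whose successor is loss-masked and a nucleotide, the
#' argmax over nucleotide tokens of the model's scores at that slot is
#' compared with the true successor. Structural successors (PAD, BOS, SEP)
#' are never scored, and structural tokens are excluded from the candidate
#' set.
#'
#' @param model a `readlm_model` with causal objective, or a scorer
#'   function `f(token_ids)` returning a logits matrix (slots x vocab).
#' @param corpus a `packed_corpus`.
#' @param dataset name recorded in the result.
#' @param positions optional data frame (`contig`, `position`) restricting
#'   scoring to slots whose successor sits at one of these genomic
#'   positions (e.g. variant positions).
#' @return An `eval_result`: list with `dataset`, `next_token_accuracy`,
#'   `n_scored_slots`.
#' @export
next_token_accuracy <- function(model, corpus, dataset = "eval", positions = NULL) {
  vocab <- corpus$vocab
  nuc <- vocab$nucleotide_ids[1:4]  # A/C/G/T; N is an ambiguity code, not a call
  scorer <- if (is.function(model)) model else {
    if (model$config$objective != "causal")
      fail("next_token_accuracy requires a causal-objective model")
    function(ids) predict_logits(model, ids)
  }
  poskey <- if (!is.null(positions))
    paste(positions$contig, positions$position) else NULL
  correct <- 0L; scored <- 0L
  for (i in seq_len(n_contexts(corpus))) {
    toks <- corpus$tokens[i, ]
    lm <- corpus$loss_mask[i, ]
    succ_ok <- which(lm[-1] & toks[-1] %in% nuc)  # predictor slots t
    if (!is.null(poskey)) {
      ctg <- corpus$contig_names[corpus$contig[i, succ_ok + 1L]]
      k <- paste(ctg, corpus$pos[i, succ_ok + 1L])
      succ_ok <- succ_ok[k %in% poskey]
    }
    if (!length(succ_ok)) next
    n_eff <- min(max(succ_ok) + 1L, length(toks))
    lg <- scorer(toks[seq_len(n_eff)])
    sc <- lg[succ_ok, nuc + 1L, drop = FALSE]
    pred <- nuc[max.col(sc, ties.method = "first")]
    correct <- correct + sum(pred == toks[succ_ok + 1L])
    scored <- scored + length(succ_ok)
  }
  if (scored == 0L) fail("next_token_accuracy: no scorable slots")
  structure(list(dataset = dataset, next_token_accuracy = correct / scored,
                 n_scored_slots = scored), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: next-token accuracy %.4f (%d slots)\n",
              x$dataset, x$next_token_accuracy, x$n_scored_slots))
  invisible(x)
}

# ---- ablation grid ----------------------------------------------------------

#' Run an ablation grid
#'
#' Trains one seeded model per grid cell and evaluates it on every
#' requested evaluation preparation, mirroring the all-to-all design of the
#' packing/filtration/weighting/attention ablations. Cell failures are
#' recorded and the grid continues.
#'
#' @param axes named list of axis values; supported names: `packing`,
#'   `filtration`, `weighting`, `objective`, `positional_encoding`,
#'   `attention_window`, `n_subjects`, `mix_ratio`.
#' @param base list with components `ref` (reference genome), `reads`
#'   (aligned reads; optional when the `n_subjects` axis resimulates),
#'   `vocab`, `packing` ([packing_config()]), `weighting`
#'   ([weighting_config()]), `model` ([model_config()]), `train`
#'   ([train_config()]), optional `filtration` ([filtration_config()]),
#'   optional `sim` ([sim_config()], needed for `n_subjects`), and
#'   `eval_strategies` (character; default `c(training strategy,
#'   "reference")`).
#' @return A long-format data frame (one row per cell x evaluation set)
#'   with the axis values, `eval_set`, `accuracy`, `n_scored`, `error`.
#' @export
run_ablation_grid <- function(axes, base) {
  supported <- c("packing", "filtration", "weighting", "objective",
                 "positional_encoding", "attention_window", "n_subjects", "mix_ratio")
  if (length(axes) && (is.null(names(axes)) || !all(names(axes) %in% supported)))
    fail("axes must be named with a subset of: %s", paste(supported, collapse = ", "))
  grid <- if (length(axes)) expand.grid(axes, stringsAsFactors = FALSE)
  else data.frame(.dummy = 1)
  out <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- as.list(grid[ci, , drop = FALSE])
    res <- tryCatch(run_grid_cell(cell, base), error = function(e) {
      data.frame(eval_set = NA_character_, accuracy = NA_real_,
                 n_scored = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    ax <- grid[rep(ci, nrow(res)), setdiff(names(grid), ".dummy"), drop = FALSE]
    out[[ci]] <- cbind(ax, res, row.names = NULL)
  }
  do.call(rbind, out)
}

run_grid_cell <- function(cell, base) {
  vocab <- base$vocab
  ref <- base$ref
  reads <- base$reads
  if (!is.null(cell$n_subjects)) {
    sc <- base$sim
    if (is.null(sc)) fail("n_subjects axis requires base$sim")
    sc$n_subjects <- as.integer(cell$n_subjects)
    reads <- cohort_reads(simulate_cohort(ref, sc))
  }
  if (!is.null(cell$filtration) || !is.null(base$filtration)) {
    fc <- if (!is.null(cell$filtration))
      filtration_config(as.integer(cell$filtration)) else base$filtration
    if (fc$reduction_factor > 1L) reads <- filter_reads(reads, ref, fc)
  }
  pcfg <- base$packing
  if (!is.null(cell$packing)) pcfg$strategy <- cell$packing
  corpusB <- pack_reads(reads, vocab, pcfg, ref = ref)
  wcfg <- base$weighting
  if (!is.null(cell$weighting)) wcfg$mode <- cell$weighting
  if (wcfg$mode == "dynamic")
    corpusB <- compute_weights(corpusB, build_pileup(reads, ref), wcfg)
  mcfg <- base$model
  if (!is.null(cell$objective)) mcfg$objective <- cell$objective
  if (!is.null(cell$positional_encoding))
    mcfg$positional_encoding <- cell$positional_encoding
  if (!is.null(cell$attention_window))
    mcfg$attention_window <- cell$attention_window
  tcfg <- base$train
  if (!is.null(cell$mix_ratio)) tcfg$mix_ratio <- cell$mix_ratio
  refcfg <- pcfg; refcfg$strategy <- "reference"
  corpusA <- pack_reference(ref, vocab, refcfg)
  model <- build_model(mcfg)
  fit <- train_two_phase(model, corpusA, corpusB, tcfg)
  evals <- base$eval_strategies
  if (is.null(evals)) evals <- unique(c(pcfg$strategy, "reference"))
  rows <- lapply(evals, function(es) {
    ecfg <- base$packing; ecfg$strategy <- es
    ecorp <- pack_reads(reads, vocab, ecfg, ref = ref)
    if (mcfg$objective != "causal")
      return(data.frame(eval_set = es, accuracy = NA_real_, n_scored = NA_integer_,
                        error = "accuracy defined for causal models",
                        stringsAsFactors = FALSE))
    ev <- next_token_accuracy(fit$model, ecorp, dataset = es)
    data.frame(eval_set = es, accuracy = ev$next_token_accuracy,
               n_scored = ev$n_scored_slots, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a grid result as an axis-by-evaluation-set accuracy matrix
#' @param results a [run_ablation_grid()] data frame.
#' @param axis which axis column labels the rows.
#' @return A numeric matrix (axis values x eval sets).
#' @export
render_grid_matrix <- function(results, axis) {
  stopifnot(axis %in% names(results))
  rows <- unique(as.character(results[[axis]]))
  cols <- unique(results$eval_set[!is.na(results$eval_set)])
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_len(nrow(results))) {
    if (is.na(results$eval_set[i])) next
    m[as.character(results[[axis]][i]), results$eval_set[i]] <- results$accuracy[i]
  }
  m
}
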
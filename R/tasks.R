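# Downstream evaluation: variant-centered classification benchmarks,
# 70/12/18 splitting, classifier-head fine-tuning scored by the Matthews
# correlation coefficient, and per-layer probing with cross-validated
# two-layer MLPs.

#' Split specification
#' @param fractions train/validation/test fractions (default 0.70/0.12/0.18).
#' @param stratified preserve class balance per split.
#' @param seed integer seed.
#' @return A `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.70, validation = 0.12, test = 0.18),
                       stratified = TRUE, seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    fail("fractions must be three positive numbers summing to 1")
  structure(list(fractions = fractions, stratified = isTRUE(stratified),
                 seed = as.integer(seed)), class = "split_spec")
}

new_classification_dataset <- function(df, window) {
  stopifnot(all(c("sequence", "label", "origin") %in% names(df)))
  if (nrow(df) && length(unique(nchar(df$sequence))) != 1L)
    fail("all sequences must have equal length")
  rownames(df) <- NULL
  structure(df, class = c("classification_dataset", "data.frame"), window = window)
}

#' Build a variant-centered classification benchmark
#'
#' One positive record per variant: the reference window centered on the
#' variant position with the alternate allele substituted at the center
#' (windows near contig edges are shifted inward, so every sequence has the
#' same length and no padding symbol leaks label information). Control
#' records are windows centered on seeded random non-variant positions with
#' the reference allele intact. Labels: 0 = control, 1..K = variant classes
#' in sorted label order.
#'
#' @param variants a `variant_table`.
#' @param ref a `reference_genome`.
#' @param window window length in bp (odd recommended; the center is slot
#'   `floor((window-1)/2) + 1`).
#' @param controls number of control records.
#' @param seed integer seed.
#' @return A `classification_dataset` data frame
#'   (`sequence`, `label`, `origin`).
#' @export
build_variant_benchmark <- function(variants, ref, window, controls, seed = 1L) {
  check_scalar(window, "window", lower = 1, integer = TRUE)
  check_scalar(controls, "controls", lower = 0, integer = TRUE)
  if (any(window > nchar(ref$contigs)))
    fail("window (%d) exceeds the smallest contig", window)
  lf <- (window - 1L) %/% 2L
  labs <- sort(unique(variants$label))
  # vectorized window extraction with inward shift at contig edges
  windows_at <- function(contig, pos) {
    clen <- nchar(ref$contigs)[contig]
    s <- pmax(0L, pmin(pos - lf, clen - window))
    list(start = s,
         seq = substring(unlist(ref$contigs)[contig], s + 1L, s + window))
  }
  pos_df <- list()
  if (nrow(variants)) {
    bad <- !(variants$contig %in% names(ref$contigs)) |
      variants$position >= nchar(ref$contigs)[variants$contig]
    if (any(bad))
      fail("variant position %s:%d absent from reference",
           variants$contig[which(bad)[1]], variants$position[which(bad)[1]])
    w <- windows_at(variants$contig, variants$position)
    center <- variants$position - w$start + 1L
    if (any(substring(w$seq, center, center) != variants$ref_allele))
      fail("reference allele mismatch at %s:%d",
           variants$contig[1], variants$position[1])
    sq <- paste0(substring(w$seq, 1L, center - 1L), variants$alt_allele,
                 substring(w$seq, center + 1L, window))
    pos_df$variants <- data.frame(
      sequence = sq, label = match(variants$label, labs),
      origin = sprintf("variant:%s:%d:%s>%s", variants$contig, variants$position,
                       variants$ref_allele, variants$alt_allele),
      stringsAsFactors = FALSE)
  }
  if (controls > 0L) {
    vkey <- paste(variants$contig, variants$position)
    clens <- nchar(ref$contigs)
    with_seed(derive_seed(seed, 121L), {
      ctg <- character(0); pos <- integer(0)
      while (length(pos) < controls) {
        need <- controls - length(pos)
        ci <- sample.int(length(clens), 2L * need + 10L, replace = TRUE, prob = clens)
        pp <- floor(stats::runif(length(ci)) * clens[ci])
        ok <- !(paste(names(clens)[ci], pp) %in% vkey)
        ctg <- c(ctg, names(clens)[ci][ok]); pos <- c(pos, as.integer(pp[ok]))
      }
      ctg <- ctg[seq_len(controls)]; pos <- pos[seq_len(controls)]
      w <- windows_at(ctg, pos)
      pos_df$controls <- data.frame(
        sequence = w$seq, label = 0L,
        origin = sprintf("control:%s:%d", ctg, pos), stringsAsFactors = FALSE)
    })
  }
  df <- if (length(pos_df)) do.call(rbind, pos_df) else
    data.frame(sequence = character(), label = integer(), origin = character())
  rownames(df) <- NULL
  new_classification_dataset(df, window)
}

#' Split a dataset 70/12/18
#'
#' Partition sizes are `round(f * n)` with the remainder assigned to the
#' test set; with stratification the rule applies per class. Partitions are
#' disjoint, their union is the dataset, and the seeded shuffle is
#' reproducible.
#'
#' @param ds a `classification_dataset` (or any data frame with `label`).
#' @param spec a [split_spec()].
#' @return List of data frames `train`, `validation`, `test`.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  n <- nrow(ds)
  if (n < 10L) fail("split_dataset needs at least 10 records")
  f <- spec$fractions
  assign_group <- function(idx) {
    m <- length(idx)
    n_tr <- round(f[1] * m); n_va <- round(f[2] * m)
    if (n_tr < 1L || n_va < 1L || m - n_tr - n_va < 1L)
      fail("a class has too few members (%d) for stratified splitting", m)
    sh <- idx[sample.int(m)]
    list(train = sh[seq_len(n_tr)],
         validation = sh[n_tr + seq_len(n_va)],
         test = sh[(n_tr + n_va + 1L):m])
  }
  with_seed(derive_seed(spec$seed, 131L), {
    parts <- if (spec$stratified) {
      by_class <- split(seq_len(n), ds$label)
      gs <- lapply(by_class, assign_group)
      list(train = sort(unlist(lapply(gs, `[[`, "train"))),
           validation = sort(unlist(lapply(gs, `[[`, "validation"))),
           test = sort(unlist(lapply(gs, `[[`, "test"))))
    } else {
      g <- assign_group(seq_len(n))
      lapply(g, sort)
    }
  })
  lapply(parts, function(ix) ds[ix, , drop = FALSE])
}

#' Matthews correlation coefficient
#'
#' Standard binary MCC from a 2x2 confusion matrix; by convention the value
#' is 0 whenever any denominator factor is zero (e.g. all predictions in
#' one class).
#'
#' @param tp,fp,fn,tn confusion counts; alternatively pass a 2x2 matrix as
#'   `tp` (`matrix[1,1]=TP`, `[1,2]=FN`, `[2,1]=FP`, `[2,2]=TN`).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.matrix(tp)) {
    stopifnot(all(dim(tp) == c(2L, 2L)))
    fn <- tp[1, 2]; fp <- tp[2, 1]; tn <- tp[2, 2]; tp <- tp[1, 1]
  }
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || sum(counts) == 0) fail("mcc: invalid confusion counts")
  tp <- as.numeric(tp); fp <- as.numeric(fp); fn <- as.numeric(fn); tn <- as.numeric(tn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

mcc_from_labels <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  mcc(tp, fp, fn, tn)
}

# Encode fixed-length window sequences as token rows: BOS + bases + SEP,
# PAD-completed to the model context length.
encode_windows <- function(sequences, vocab, L) {
  wl <- unique(nchar(sequences))
  if (length(wl) != 1L) fail("sequences must share one length")
  if (wl + 2L > L) fail("window of %d bp does not fit context length %d", wl, L)
  PAD <- vocab$symbol_to_id[["PAD"]]
  t(vapply(sequences, function(s) {
    c(vocab$symbol_to_id[["BOS"]], encode_tokens(s, vocab),
      vocab$symbol_to_id[["SEP"]], rep(PAD, L - wl - 2L))
  }, integer(L), USE.NAMES = FALSE))
}

# Mean-pooled final-layer embedding (over non-PAD slots) for each row.
pool_final <- function(params, cfg, ids_mat, pad_id) {
  t(vapply(seq_len(nrow(ids_mat)), function(i) {
    ids <- ids_mat[i, ]
    n_eff <- max(which(ids != pad_id))
    fw <- model_forward(params, cfg, ids[seq_len(n_eff)] + 1L, need = "hidden")
    colMeans(fw$Hf)
  }, numeric(cfg$d_model)))
}

#' Fine-tuning configuration
#' @param epochs passes over the training split.
#' @param batch_size records per step.
#' @param learning_rate AdamW learning rate.
#' @param freeze_backbone train the head only, leaving the transformer
#'   untouched.
#' @param seed integer seed.
#' @return A `finetune_config`.
#' @export
finetune_config <- function(epochs = 5L, batch_size = 8L, learning_rate = 1e-3,
                            freeze_backbone = FALSE, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 freeze_backbone = isTRUE(freeze_backbone),
                 seed = as.integer(seed)), class = "finetune_config")
}

#' Fine-tune a classifier head on a benchmark dataset
#'
#' Mean-pooled final-layer embeddings feed a linear head; by default the
#' backbone is unfrozen (full fine-tuning). The model is selected by
#' validation MCC across epochs and the test MCC is reported once. Binary
#' tasks only.
#'
#' @param model a `readlm_model`.
#' @param ds a `classification_dataset` with labels in `{0, 1}`.
#' @param spec a [split_spec()].
#' @param config a [finetune_config()].
#' @return List with `model` (fine-tuned), `head` (`W`, `b`), `val_mcc`
#'   (per epoch), `test_mcc`, `best_epoch`.
#' @export
finetune_classifier <- function(model, ds, spec = split_spec(),
                                config = finetune_config()) {
  cfg <- model$config
  vocab <- build_vocab()
  labs <- sort(unique(ds$label))
  if (!identical(as.integer(labs), c(0L, 1L)))
    fail("finetune_classifier handles binary labels {0, 1}")
  parts <- split_dataset(ds, spec)
  if (length(unique(parts$train$label)) < 2L) fail("training split has one class")
  PAD <- vocab$symbol_to_id[["PAD"]]
  Xtr <- encode_windows(parts$train$sequence, vocab, cfg$context_length)
  ytr <- parts$train$label
  params <- model$params
  d <- cfg$d_model
  with_seed(derive_seed(config$seed, 141L),
            head <- list(W = matrix(stats::rnorm(d * 2, 0, 0.02), d, 2), b = rep(0, 2)))
  all_params <- c(params, list(headW = head$W, headb = head$b))
  opt <- adam_init(all_params)
  eval_mcc <- function(pp, part) {
    X <- encode_windows(part$sequence, vocab, cfg$context_length)
    pool <- pool_final(pp[names(params)], cfg, X, PAD)
    sc <- pool %*% pp$headW + rep(pp$headb, each = nrow(pool))
    mcc_from_labels(part$label, max.col(sc, ties.method = "first") - 1L)
  }
  val_mcc <- numeric(config$epochs)
  best <- list(score = -Inf, params = all_params, epoch = 0L)
  with_seed(derive_seed(config$seed, 142L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        gsum <- NULL
        for (i in bs) {
          ids <- Xtr[i, ]
          n_eff <- max(which(ids != PAD))
          fw <- model_forward(all_params[names(params)], cfg,
                              ids[seq_len(n_eff)] + 1L,
                              need = "hidden", keep_cache = TRUE)
          pool <- colMeans(fw$Hf)
          z <- drop(pool %*% all_params$headW) + all_params$headb
          p <- exp(z - max(z)); p <- p / sum(p)
          dz <- p; dz[ytr[i] + 1L] <- dz[ytr[i] + 1L] - 1
          ghead <- list(headW = outer(pool, dz), headb = dz)
          dpool <- drop(all_params$headW %*% dz)
          dHf <- matrix(dpool / n_eff, n_eff, cfg$d_model, byrow = TRUE)
          gr <- if (config$freeze_backbone) list() else
            model_backward(all_params[names(params)], cfg, fw$cache,
                           dHf_extra = dHf)
          gr <- c(gr, ghead)
          gsum <- if (is.null(gsum)) gr else
            mapply(function(a, b) a + b, gsum, gr[names(gsum)], SIMPLIFY = FALSE)
        }
        gsum <- lapply(gsum, function(gz) gz / length(bs))
        st <- adam_step(all_params, gsum, opt, config$learning_rate)
        all_params <- st$params; opt <- st$opt
      }
      val_mcc[ep] <- eval_mcc(all_params, parts$validation)
      if (val_mcc[ep] > best$score)
        best <- list(score = val_mcc[ep], params = all_params, epoch = ep)
    }
  })
  test_mcc <- eval_mcc(best$params, parts$test)
  model$params <- best$params[names(params)]
  list(model = model, head = list(W = best$params$headW, b = best$params$headb),
       val_mcc = val_mcc, test_mcc = test_mcc, best_epoch = best$epoch)
}

#' Extract mean-pooled embeddings at one layer
#'
#' Layer 0 is the post-embedding representation (token plus positional
#' information, before any transformer block); layer `i` is the output of
#' block `i`. Pooling is the mean over non-PAD slots. The backbone is never
#' modified.
#'
#' @param model a `readlm_model`.
#' @param sequences character vector of equal-length windows.
#' @param layer_index integer in `[0, n_layers]`.
#' @return A numeric matrix (length(sequences) x d_model).
#' @export
extract_layer_embeddings <- function(model, sequences, layer_index) {
  cfg <- model$config
  check_scalar(layer_index, "layer_index", lower = 0, upper = cfg$n_layers,
               integer = TRUE)
  vocab <- build_vocab()
  PAD <- vocab$symbol_to_id[["PAD"]]
  X <- encode_windows(sequences, vocab, cfg$context_length)
  t(vapply(seq_len(nrow(X)), function(i) {
    ids <- X[i, ]
    n_eff <- max(which(ids != PAD))
    fw <- model_forward(model$params, cfg, ids[seq_len(n_eff)] + 1L,
                        need = "hidden", collect_layers = TRUE)
    colMeans(fw$layers[[layer_index + 1L]])
  }, numeric(cfg$d_model)))
}

stratified_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  with_seed(derive_seed(seed, 151L), {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      if (length(ix) < folds)
        fail("class %s has fewer members (%d) than folds (%d)", cl, length(ix), folds)
      fold_of[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
  })
  fold_of
}

#' Probe every layer with a cross-validated MLP
#'
#' For each layer (0 = embeddings, 1..n_layers = block outputs): stratified
#' k-fold cross-validation of a two-layer MLP (single hidden layer of
#' `hidden` units, via `nnet`) on that layer's mean-pooled embeddings, with
#' the per-fold MCC recorded. The backbone is frozen throughout.
#'
#' @param model a `readlm_model`.
#' @param ds a binary `classification_dataset`.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed.
#' @param hidden hidden-layer width of the probe.
#' @return A `probe_report`: numeric matrix `(n_layers + 1) x folds` of MCC
#'   values, rows named `layer0..layerN`.
#' @export
probe_layers <- function(model, ds, folds = 10L, seed = 1L, hidden = 64L) {
  labs <- sort(unique(ds$label))
  if (length(labs) != 2L) fail("probe_layers handles binary labels")
  y <- as.integer(ds$label == labs[2])
  fold_of <- stratified_folds(y, folds, seed)
  nl <- model$config$n_layers
  rep_mat <- matrix(NA_real_, nl + 1L, folds,
                    dimnames = list(paste0("layer", 0:nl), NULL))
  for (li in 0:nl) {
    E <- extract_layer_embeddings(model, ds$sequence, li)
    for (fd in seq_len(folds)) {
      tr <- fold_of != fd
      with_seed(derive_seed(seed, 152L, li, fd), {
        fit <- nnet::nnet(E[tr, , drop = FALSE], class.ind2(y[tr]),
                          size = hidden, softmax = TRUE, trace = FALSE,
                          decay = 1e-3, maxit = 150, MaxNWts = 100000)
      })
      pr <- predict(fit, E[!tr, , drop = FALSE])
      pred <- max.col(pr, ties.method = "first") - 1L
      rep_mat[li + 1L, fd] <- mcc_from_labels(y[!tr], pred)
    }
  }
  structure(rep_mat, class = c("probe_report", "matrix"))
}

# two-column class indicator (nnet::class.ind without requiring factor setup)
class.ind2 <- function(y) {
  m <- matrix(0, length(y), 2)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

#' @export
print.probe_report <- function(x, ...) {
  cat(sprintf("<probe_report> %d layer(s) x %d fold(s); median MCC per layer:\n",
              nrow(x), ncol(x)))
  print(round(apply(unclass(x), 1, stats::median), 3))
  invisible(x)
}

#' Write a classification dataset as TSV
#' @param ds a `classification_dataset`.
#' @param path output path.
#' @export
write_benchmark <- function(ds, path) {
  utils::write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
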
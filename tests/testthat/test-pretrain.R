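vocab <- build_vocab()

make_ref_corpus <- function(len, L, seed = 1) {
  ref <- toy_ref(rand_seq(len, seed = seed))
  pack_reference(ref, vocab, packing_config("reference", L))
}

test_that("weighted_loss follows the stated formula", {
  sc <- rbind(c(2, 0, -1), c(0, 1, 0), c(1, 1, 3))
  tg <- c(0L, 1L, 2L)
  ce <- vapply(1:3, function(i) -log(exp(sc[i, tg[i] + 1]) / sum(exp(sc[i, ]))), 0)
  # uniform = plain mean
  expect_equal(weighted_loss(sc, tg, c(1, 1, 1)), mean(ce))
  # one hot weight picks that slot's cross-entropy
  expect_equal(weighted_loss(sc, tg, c(0, 1, 0)), ce[2])
  # 3-slot hand example with weights (1, 2, 1)
  expect_equal(weighted_loss(sc, tg, c(1, 2, 1)),
               (ce[1] + 2 * ce[2] + ce[3]) / 4)
  expect_error(weighted_loss(sc, tg, c(0, 0, 0)), "all weights are zero")
  expect_error(weighted_loss(sc, tg, c(1, 1)), "shapes disagree")
})

test_that("two-phase scheduling samples corpora as configured", {
  corpA <- make_ref_corpus(300, 34L, seed = 2)
  corpB <- make_ref_corpus(300, 34L, seed = 3)
  mc <- model_config(n_layers = 1, d_model = 8, n_heads = 2, context_length = 34,
                     seed = 1)
  # steps_phase2 = 0 reduces to single-corpus training
  fit0 <- train_two_phase(build_model(mc), corpA, NULL,
                          train_config(steps_phase1 = 3, steps_phase2 = 0,
                                       batch_size = 1, seed = 5))
  expect_equal(nrow(fit0$trace), 3)
  expect_true(all(fit0$trace$phase == 1))
  # r = 0: corpus B never sampled
  fit1 <- train_two_phase(build_model(mc), corpA, corpB,
                          train_config(steps_phase1 = 2, steps_phase2 = 6,
                                       batch_size = 1, mix_ratio = 0, seed = 5))
  expect_true(all(fit1$trace$corpus == "A"))
  # r > 0 with empty corpus B errors
  expect_error(train_two_phase(build_model(mc), corpA, NULL,
                               train_config(steps_phase1 = 1, steps_phase2 = 2,
                                            mix_ratio = 0.5)),
               "corpus B")
})

test_that("phase-2 batches hit corpus B at the configured rate", {
  corpA <- make_ref_corpus(120, 18L, seed = 4)
  corpB <- make_ref_corpus(120, 18L, seed = 5)
  mc <- model_config(n_layers = 1, d_model = 8, n_heads = 2, context_length = 18,
                     seed = 2)
  fit <- train_two_phase(build_model(mc), corpA, corpB,
                         train_config(steps_phase1 = 0, steps_phase2 = 2000,
                                      batch_size = 1, mix_ratio = 0.5,
                                      learning_rate = 1e-4, seed = 6))
  fB <- mean(fit$trace$corpus == "B")
  expect_lt(abs(fB - 0.5), 5 * sqrt(0.25 / 2000))
})

test_that("subset_fraction restricts which corpus-B contexts are ever used", {
  corpA <- make_ref_corpus(60, 18L, seed = 7)
  corpB <- make_ref_corpus(2000, 18L, seed = 8)  # ~125 contexts
  mc <- model_config(n_layers = 1, d_model = 8, n_heads = 2, context_length = 18,
                     seed = 3)
  tc <- train_config(steps_phase1 = 0, steps_phase2 = 40, batch_size = 2,
                     mix_ratio = 1, subset_fraction = 0.15, seed = 9)
  fit <- train_two_phase(build_model(mc), corpA, corpB, tc)
  expect_true(all(fit$trace$corpus == "B"))
  # reproducibility of the whole trace
  fit2 <- train_two_phase(build_model(mc), corpA, corpB, tc)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("training reduces the loss on a small causal run", {
  corp <- make_ref_corpus(2000, 34L, seed = 10)
  mc <- model_config(n_layers = 1, d_model = 16, n_heads = 2, context_length = 34,
                     seed = 4)
  fit <- train_two_phase(build_model(mc), corp, NULL,
                         train_config(steps_phase1 = 60, steps_phase2 = 0,
                                      batch_size = 2, learning_rate = 3e-3,
                                      seed = 11))
  lo <- fit$trace$loss
  expect_lt(mean(tail(lo, 10)), mean(head(lo, 10)))
})

test_that("mlm training runs and reduces the loss", {
  corp <- make_ref_corpus(2000, 34L, seed = 12)
  mc <- model_config(n_layers = 1, d_model = 16, n_heads = 2, context_length = 34,
                     objective = "mlm", seed = 5)
  fit <- train_two_phase(build_model(mc), corp, NULL,
                         train_config(steps_phase1 = 60, steps_phase2 = 0,
                                      batch_size = 2, learning_rate = 3e-3,
                                      seed = 13))
  lo <- fit$trace$loss
  expect_lt(mean(tail(lo, 10)), mean(head(lo, 10)))
})

test_that("next_token_accuracy scores argmax over nucleotides only", {
  corp <- make_ref_corpus(400, 26L, seed = 14)
  # oracle scorer: always puts the true successor on top
  oracle <- function(ids) {
    n <- length(ids)
    m <- matrix(0, n, 9)
    for (t in seq_len(n - 1)) m[t, ids[t + 1] + 1] <- 10
    m
  }
  ev <- next_token_accuracy(oracle, corp, dataset = "oracle")
  expect_equal(ev$next_token_accuracy, 1)
  expect_gt(ev$n_scored_slots, 0)
  # anti-oracle: nucleotide argmax is always wrong
  anti <- function(ids) {
    m <- oracle(ids)
    m[, 5:9] <- -m[, 5:9] + 1e-3  # flip nucleotide preference
    m
  }
  expect_lt(next_token_accuracy(anti, corp)$next_token_accuracy, 0.05)
  # a model whose objective is mlm is rejected
  mm <- build_model(model_config(n_layers = 1, d_model = 8, n_heads = 2,
                                 context_length = 26, objective = "mlm"))
  expect_error(next_token_accuracy(mm, corp), "causal")
})

test_that("a uniform-random scorer sits at chance on a random corpus", {
  corp <- make_ref_corpus(103000, 1024L, seed = 15)
  set.seed(16)
  rand_scorer <- function(ids) matrix(runif(length(ids) * 9), length(ids), 9)
  ev <- next_token_accuracy(rand_scorer, corp, dataset = "random")
  expect_gte(ev$n_scored_slots, 100000)
  expect_lt(abs(ev$next_token_accuracy - 0.25),
            5 * sqrt(0.25 * 0.75 / ev$n_scored_slots))
})

test_that("a singleton ablation grid equals the direct train+eval call", {
  cfg <- sim_config(contig_length = 800, coverage_max = 3, read_length = 30,
                    seed = 17)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(ref, ref, cfg)
  base <- list(ref = ref, reads = reads, vocab = vocab,
               packing = packing_config("consecutive", 64L, seed = 1),
               weighting = weighting_config("uniform"),
               model = model_config(n_layers = 1, d_model = 8, n_heads = 2,
                                    context_length = 64, seed = 6),
               train = train_config(steps_phase1 = 4, steps_phase2 = 2,
                                    batch_size = 1, mix_ratio = 0.5, seed = 18),
               eval_strategies = "consecutive")
  grid <- run_ablation_grid(list(), base)
  expect_equal(nrow(grid), 1)
  # direct path with the same seeds
  corpB <- pack_reads(reads, vocab, base$packing, ref = ref)
  refc <- base$packing; refc$strategy <- "reference"
  corpA <- pack_reference(ref, vocab, refc)
  fit <- train_two_phase(build_model(base$model), corpA, corpB, base$train)
  ev <- next_token_accuracy(fit$model, corpB, dataset = "consecutive")
  expect_equal(grid$accuracy, ev$next_token_accuracy)
  expect_equal(grid$n_scored, ev$n_scored_slots)
})

test_that("the packing axis yields a fully populated all-to-all matrix", {
  cfg <- sim_config(contig_length = 700, coverage_min = 2, coverage_max = 4,
                    read_length = 30, variant_rate = 3e-3, seed = 19)
  ref <- simulate_reference(cfg)
  av <- apply_variants(ref, cfg$variant_rate, 20)
  reads <- simulate_reads(av$donor, ref, cfg)
  strategies <- c("consecutive", "random", "spaced", "overlapping", "reference")
  base <- list(ref = ref, reads = reads, vocab = vocab,
               packing = packing_config("consecutive", 64L, seed = 2),
               weighting = weighting_config("uniform"),
               model = model_config(n_layers = 1, d_model = 8, n_heads = 2,
                                    context_length = 64, seed = 7),
               train = train_config(steps_phase1 = 2, steps_phase2 = 1,
                                    batch_size = 1, mix_ratio = 1, seed = 21),
               eval_strategies = strategies)
  grid <- run_ablation_grid(list(packing = strategies), base)
  expect_equal(nrow(grid), 25)
  m <- render_grid_matrix(grid, "packing")
  expect_equal(dim(m), c(5, 5))
  expect_true(all(is.finite(m)))
  expect_error(run_ablation_grid(list(bogus = 1), base), "axes")
})
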
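test_that("variant benchmarks center the substituted allele", {
  ref <- toy_ref(rand_seq(12000, seed = 1))
  pos <- 5000L
  rs <- substring(ref$contigs[[1]], pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), rs)[1]
  vt <- readlm:::new_variant_table(data.frame(
    contig = "contig01", position = pos, ref_allele = rs, alt_allele = alt,
    label = "case", stringsAsFactors = FALSE))
  ds <- build_variant_benchmark(vt, ref, window = 11L, controls = 0L, seed = 2)
  expect_equal(nrow(ds), 1)
  expect_equal(nchar(ds$sequence), 11)
  expect_equal(ds$sequence,
               paste0(substring(ref$contigs[[1]], 4996, 5000), alt,
                      substring(ref$contigs[[1]], 5002, 5006)))
  expect_equal(ds$label, 1L)

  # ten variants, no controls -> ten records
  av <- apply_variants(ref, 1e-3, 3)
  ds10 <- build_variant_benchmark(av$variants[1:10, ], ref, 21L, 0L, seed = 4)
  expect_equal(nrow(ds10), 10)

  # windows near the contig edge shift inward and keep their length
  vt_edge <- readlm:::new_variant_table(data.frame(
    contig = "contig01", position = 1L,
    ref_allele = substring(ref$contigs[[1]], 2, 2),
    alt_allele = setdiff(c("A", "C", "G", "T"),
                         substring(ref$contigs[[1]], 2, 2))[1],
    label = "edge", stringsAsFactors = FALSE))
  dse <- build_variant_benchmark(vt_edge, ref, 11L, 0L, seed = 5)
  expect_equal(nchar(dse$sequence), 11)
  expect_equal(substring(dse$sequence, 2, 2), vt_edge$alt_allele)

  expect_error(build_variant_benchmark(
    readlm:::new_variant_table(data.frame(contig = "nope", position = 1L,
                                          ref_allele = "A", alt_allele = "C",
                                          label = "x")),
    ref, 11L, 0L), "absent from reference")
})

test_that("the headline benchmark size 612 + 38224 assembles exactly", {
  ref <- simulate_reference(sim_config(contig_length = 60000, seed = 6))
  av <- apply_variants(ref, 0.02, 7, label = "disease")
  expect_gte(nrow(av$variants), 612)
  ds <- build_variant_benchmark(av$variants[seq_len(612), ], ref,
                                window = 25L, controls = 38224L, seed = 8)
  expect_equal(nrow(ds), 38836)
  expect_equal(sum(ds$label == 1), 612)
  expect_equal(sum(ds$label == 0), 38224)
})

test_that("control windows are leak-free reference sequence", {
  ref <- simulate_reference(sim_config(contig_length = 20000, seed = 9))
  av <- apply_variants(ref, 5e-3, 10)
  ds <- build_variant_benchmark(av$variants, ref, 15L, 200L, seed = 11)
  ctrl <- ds[ds$label == 0, ]
  ps <- as.integer(sub("^control:contig01:", "", ctrl$origin))
  # never centered on a variant position
  expect_false(any(ps %in% av$variants$position))
  # sequence equals the untouched reference window
  lf <- (15L - 1L) %/% 2L
  s <- pmax(0L, pmin(ps - lf, 20000L - 15L))
  expect_identical(ctrl$sequence, substring(ref$contigs[[1]], s + 1L, s + 15L))
})

test_that("split_dataset produces exact 70/12/18 partitions", {
  ds <- data.frame(sequence = rep("ACGT", 10000),
                   label = rep(0:1, each = 5000),
                   origin = "x", stringsAsFactors = FALSE)
  sp <- split_dataset(ds, split_spec(seed = 3))
  expect_equal(nrow(sp$train), 7000)
  expect_equal(nrow(sp$validation), 1200)
  expect_equal(nrow(sp$test), 1800)
  # stratified: class balance preserved exactly in every split
  for (part in sp) expect_equal(unname(table(part$label)[1]),
                                unname(table(part$label)[2]))
  # disjoint, union = ds
  ids <- c(rownames(sp$train), rownames(sp$validation), rownames(sp$test))
  expect_equal(anyDuplicated(ids), 0)
  expect_setequal(ids, rownames(ds))
  # same seed, same partitions
  sp2 <- split_dataset(ds, split_spec(seed = 3))
  expect_identical(lapply(sp, rownames), lapply(sp2, rownames))
  # errors
  expect_error(split_dataset(ds[1:5, ], split_spec()), "at least 10")
  tiny <- ds[c(1:20, 5001), ]
  expect_error(split_dataset(tiny, split_spec()), "too few members")
  expect_error(split_spec(fractions = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("mcc matches the closed form and its degenerate conventions", {
  expect_equal(mcc(50, 0, 0, 50), 1)
  expect_equal(mcc(0, 50, 50, 0), -1)
  expect_equal(mcc(60, 40, 0, 0), 0)  # all predictions one class
  expect_equal(mcc(40, 10, 5, 45),
               (40 * 45 - 10 * 5) / sqrt(50 * 45 * 55 * 50))
  expect_equal(mcc(matrix(c(40, 10, 5, 45), 2, 2, byrow = TRUE)),
               mcc(40, 10, 5, 45))
  expect_error(mcc(0, 0, 0, 0), "invalid")
})

test_that("mcc equals the correlation oracle on 1000 random tables", {
  set.seed(12)
  for (i in 1:1000) {
    cts <- rpois(4, 6)  # tp, fp, fn, tn
    if (sum(cts) == 0) next
    truth <- rep(c(1, 0, 1, 0), cts)
    pred <- rep(c(1, 1, 0, 0), cts)
    oracle <- suppressWarnings(cor(truth, pred))
    got <- mcc(cts[1], cts[2], cts[3], cts[4])
    if (is.na(oracle)) expect_equal(got, 0)
    else expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("layer embeddings are deterministic with the documented layer-0", {
  m <- build_model(model_config(n_layers = 2, d_model = 16, n_heads = 2,
                                context_length = 32, seed = 14))
  seqs <- c(rand_seq(20, 1), rand_seq(20, 2), rand_seq(20, 1))
  for (li in 0:2) {
    E <- extract_layer_embeddings(m, seqs, li)
    expect_equal(dim(E), c(3, 16))
    expect_identical(E[1, ], E[3, ])  # identical sequences, identical vectors
    expect_identical(E, extract_layer_embeddings(m, seqs, li))
  }
  # layer 0 is the post-embedding representation: changing every deep
  # parameter must not move it
  m2 <- m
  m2$params$l01_W1 <- m2$params$l01_W1 * 0
  expect_identical(extract_layer_embeddings(m, seqs, 0),
                   extract_layer_embeddings(m2, seqs, 0))
  expect_error(extract_layer_embeddings(m, seqs, 3), "layer_index")
})

separable_ds <- function(n, width = 30, seed = 1) {
  set.seed(seed)
  seqs <- character(n); labs <- integer(n)
  for (i in seq_len(n)) {
    labs[i] <- (i - 1L) %% 2L
    pool <- if (labs[i] == 1L) c("G", "T") else c("A", "C")
    seqs[i] <- paste(sample(pool, width, replace = TRUE), collapse = "")
  }
  readlm:::new_classification_dataset(
    data.frame(sequence = seqs, label = labs, origin = "synthetic",
               stringsAsFactors = FALSE), width)
}

test_that("probing reports per-layer folds and never touches the backbone", {
  m <- build_model(model_config(n_layers = 2, d_model = 16, n_heads = 2,
                                context_length = 40, seed = 15))
  ds <- separable_ds(60, width = 30, seed = 16)
  before <- serialize(m$params, NULL)
  pr <- probe_layers(m, ds, folds = 5, seed = 17, hidden = 8)
  expect_equal(dim(pr), c(3, 5))  # n_layers + 1 rows, fold columns
  expect_true(all(pr >= -1 & pr <= 1))
  expect_identical(serialize(m$params, NULL), before)
  expect_error(probe_layers(m, ds[ds$label == 1, ], folds = 5), "binary")
})

test_that("fine-tuning separates a center-base rule and respects freezing", {
  # label = 1 iff the window's center base is G or T; windows otherwise random
  set.seed(18)
  width <- 11L
  n <- 600L
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""), "")
  center <- substring(seqs, 6, 6)
  ds <- readlm:::new_classification_dataset(
    data.frame(sequence = seqs, label = as.integer(center %in% c("G", "T")),
               origin = "rule", stringsAsFactors = FALSE), width)
  # absolute positions let a small backbone learn to route the center slot
  m <- build_model(model_config(n_layers = 2, d_model = 32, n_heads = 2,
                                context_length = 16,
                                positional_encoding = "learnable", seed = 19))
  ft <- finetune_classifier(m, ds, split_spec(seed = 20),
                            finetune_config(epochs = 8, batch_size = 8,
                                            learning_rate = 3e-3, seed = 21))
  expect_gt(ft$test_mcc, 0.9)
  # full fine-tuning moves backbone parameters
  expect_false(identical(ft$model$params$l01_Wq, m$params$l01_Wq))
  # frozen backbone stays bit-identical
  ff <- finetune_classifier(m, ds, split_spec(seed = 20),
                            finetune_config(epochs = 1, batch_size = 8,
                                            freeze_backbone = TRUE, seed = 22))
  expect_identical(ff$model$params, m$params)
})

test_that("random labels fine-tune to chance-level test MCC", {
  set.seed(23)
  width <- 11L
  seqs <- vapply(seq_len(600), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""), "")
  ds <- readlm:::new_classification_dataset(
    data.frame(sequence = seqs, label = rep(0:1, 300),
               origin = "null", stringsAsFactors = FALSE), width)
  m <- build_model(model_config(n_layers = 2, d_model = 32, n_heads = 2,
                                context_length = 16,
                                positional_encoding = "learnable", seed = 24))
  ft <- finetune_classifier(m, ds, split_spec(seed = 25),
                            finetune_config(epochs = 2, batch_size = 8,
                                            learning_rate = 3e-3, seed = 26))
  expect_lt(abs(ft$test_mcc), 0.15)
})
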
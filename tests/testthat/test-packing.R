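vocab <- build_vocab()
SYM <- vocab$symbol_to_id

test_that("a single 151-bp read lays out as BOS + bases + SEP + PAD", {
  ref <- toy_ref(rand_seq(300, seed = 1))
  reads <- toy_reads(substring(ref$contigs[[1]], 1, 151), 0)
  corp <- pack_consecutive(reads, vocab, packing_config("consecutive", 1024L))
  expect_equal(n_contexts(corp), 1)
  ctx <- get_context(corp, 1)
  expect_length(ctx$token_ids, 1024)
  expect_equal(ctx$token_ids[1], unname(SYM["BOS"]))
  expect_equal(ctx$token_ids[2:152], encode_tokens(reads$bases[1], vocab))
  expect_equal(ctx$token_ids[153], unname(SYM["SEP"]))
  expect_true(all(ctx$token_ids[154:1024] == SYM["PAD"]))
  # loss_mask FALSE exactly on PAD and BOS slots
  expect_identical(which(!ctx$loss_mask), c(1L, 154:1024))
  expect_equal(ctx$positions[2:152], 0:150)
  expect_true(all(is.na(ctx$positions[c(1, 153)])))
  expect_true(all(ctx$weights[ctx$loss_mask] == 1))
  expect_true(all(ctx$weights[!ctx$loss_mask] == 0))
})

test_that("consecutive packing matches a hand-built oracle on 10 reads", {
  ref <- toy_ref(rand_seq(500, seed = 2), rand_seq(500, seed = 3))
  starts <- c(40, 0, 120, 80, 200, 160, 240, 10, 50, 90)
  contigs <- rep(c("contig01", "contig02"), each = 5)
  bases <- vapply(seq_along(starts), function(i)
    substring(ref$contigs[[contigs[i]]], starts[i] + 1, starts[i] + 30), "")
  reads <- toy_reads(bases, starts, contig = contigs)
  L <- 100L
  corp <- pack_consecutive(reads, vocab, packing_config("consecutive", L))
  # oracle: sort by (contig, start), concatenate read tokens + SEP after BOS,
  # flush when the next read does not fit or the contig changes
  ord <- order(contigs, starts)
  expected <- list(); cur <- SYM[["BOS"]]; cur_contig <- contigs[ord[1]]
  for (i in ord) {
    tok <- c(encode_tokens(bases[i], vocab), SYM[["SEP"]])
    if (contigs[i] != cur_contig || length(cur) + length(tok) > L) {
      expected[[length(expected) + 1L]] <- c(cur, rep(SYM[["PAD"]], L - length(cur)))
      cur <- SYM[["BOS"]]; cur_contig <- contigs[i]
    }
    cur <- c(cur, tok)
  }
  expected[[length(expected) + 1L]] <- c(cur, rep(SYM[["PAD"]], L - length(cur)))
  expect_equal(n_contexts(corp), length(expected))
  for (j in seq_along(expected))
    expect_equal(unname(corp$tokens[j, ]), unname(expected[[j]]))
  # contexts never mix contigs
  for (j in seq_len(n_contexts(corp))) {
    cts <- unique(na.omit(corp$contig[j, ]))
    expect_length(cts, 1)
  }
})

test_that("packing conserves the read multiset (consecutive, random, spaced)", {
  cfg <- sim_config(contig_length = 2500, coverage_max = 5, read_length = 40, seed = 7)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(ref, ref, cfg)
  for (strat in c("consecutive", "random", "spaced")) {
    corp <- pack_reads(reads, vocab, packing_config(strat, 128L, seed = 5), ref = ref)
    expect_setequal(unlist(corp$read_ids), reads$read_id)
    expect_length(unlist(corp$read_ids), nrow(reads))
  }
})

test_that("every context has exactly L slots and a BOS/PAD-only mask complement", {
  cfg <- sim_config(contig_length = 1500, coverage_max = 4, read_length = 30, seed = 8)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(ref, ref, cfg)
  for (strat in c("consecutive", "random", "spaced", "overlapping", "reference")) {
    corp <- pack_reads(reads, vocab, packing_config(strat, 90L, seed = 2), ref = ref)
    expect_equal(ncol(corp$tokens), 90)
    off <- corp$tokens == SYM["PAD"] | corp$tokens == SYM["BOS"]
    expect_identical(unname(corp$loss_mask), unname(!off))
  }
})

test_that("oversized items are rejected", {
  reads <- toy_reads(rand_seq(151, seed = 4), 0)
  expect_error(pack_consecutive(reads, vocab, packing_config("consecutive", 100L)),
               "exceeds context capacity")
})

test_that("random packing is seeded and explores both orders of two reads", {
  ref <- toy_ref(rand_seq(300, seed = 5))
  reads <- toy_reads(substring(ref$contigs[[1]], c(1, 101), c(30, 130)), c(0, 100))
  a <- pack_random(reads, vocab, packing_config("random", 80L, seed = 3))
  b <- pack_random(reads, vocab, packing_config("random", 80L, seed = 3))
  expect_identical(a, b)
  orders <- vapply(1:20, function(s) {
    corp <- pack_random(reads, vocab, packing_config("random", 80L, seed = s))
    paste(unlist(corp$read_ids), collapse = ",")
  }, "")
  expect_setequal(unique(orders), c("r001,r002", "r002,r001"))
})

test_that("spaced packing keeps intervals disjoint within each context", {
  ref <- toy_ref(rand_seq(400, seed = 6))
  r2 <- toy_reads(substring(ref$contigs[[1]], c(1, 61), c(30, 90)), c(0, 60))
  corp2 <- pack_spaced(r2, vocab, packing_config("spaced", 80L))
  expect_equal(n_contexts(corp2), 1)  # two disjoint reads share a context

  r3 <- toy_reads(substring(ref$contigs[[1]], c(1, 51), c(100, 150)), c(0, 50))
  corp3 <- pack_spaced(r3, vocab, packing_config("spaced", 300L))
  expect_equal(n_contexts(corp3), 2)  # 50-bp overlap forces separate passes

  # dense fixture: 30 overlapping reads; exhaustive pairwise interval check
  starts <- seq(0, by = 7, length.out = 30)
  rd <- toy_reads(substring(ref$contigs[[1]], starts + 1, starts + 25), starts)
  corp <- pack_spaced(rd, vocab, packing_config("spaced", 120L))
  expect_setequal(unlist(corp$read_ids), rd$read_id)
  for (j in seq_len(n_contexts(corp))) {
    ids <- unlist(corp$read_ids[[j]])
    iv <- cbind(rd$start[match(ids, rd$read_id)],
                rd$start[match(ids, rd$read_id)] + 25)
    if (nrow(iv) > 1)
      for (a in seq_len(nrow(iv) - 1)) for (b in (a + 1):nrow(iv))
        expect_true(iv[a, 2] <= iv[b, 1] || iv[b, 2] <= iv[a, 1])
  }
})

test_that("overlap merging produces majority-consensus contiguous segments", {
  don <- rand_seq(400, seed = 9)
  ref <- toy_ref(don)
  # two agreeing reads overlapping by 10 bp -> one 292-bp segment
  r2 <- toy_reads(substring(don, c(1, 142), c(151, 292)), c(0, 141))
  corp <- pack_overlapping(r2, ref, vocab, packing_config("overlapping", 1024L))
  nuc <- corp$tokens[1, ] >= SYM["A"]
  expect_equal(sum(nuc), 292)
  expect_equal(decode_tokens(corp$tokens[1, nuc], vocab), substring(don, 1, 292))

  # disagreement at one overlap position: 2 reads vs 1 -> majority wins
  b1 <- substring(don, 1, 20); b2 <- substring(don, 11, 30); b3 <- substring(don, 11, 30)
  alt <- setdiff(c("A", "C", "G", "T"), substring(don, 15, 15))[1]
  substring(b2, 5, 5) <- alt; substring(b3, 5, 5) <- alt  # position 14 (0-based)
  rd <- toy_reads(c(b1, b2, b3), c(0, 10, 10))
  corp2 <- pack_overlapping(rd, ref, vocab, packing_config("overlapping", 64L))
  nuc2 <- which(corp2$tokens[1, ] >= SYM["A"])
  merged <- decode_tokens(corp2$tokens[1, nuc2], vocab)
  expect_equal(substring(merged, 15, 15), alt)

  # tie (1 vs 1) resolves to the reference base
  rd3 <- toy_reads(c(b1, b2), c(0, 10))
  corp3 <- pack_overlapping(rd3, ref, vocab, packing_config("overlapping", 64L))
  merged3 <- decode_tokens(corp3$tokens[1, corp3$tokens[1, ] >= SYM["A"]], vocab)
  expect_equal(substring(merged3, 15, 15), substring(don, 15, 15))
})

test_that("a gapless tiling merges into the donor substring", {
  cfg <- sim_config(contig_length = 2000, coverage_min = 2, coverage_max = 4,
                    variant_rate = 2e-3, base_error_rate = 0, seed = 10)
  ref <- simulate_reference(cfg)
  av <- apply_variants(ref, cfg$variant_rate, 11)
  reads <- simulate_reads(av$donor, ref, cfg)
  corp <- pack_overlapping(reads, ref, vocab, packing_config("overlapping", 2048L))
  # reads tile the contig with no gaps: a single merged chain
  covered <- sum(corp$tokens >= SYM["A"])
  expect_equal(n_contexts(corp), 1)
  merged <- decode_tokens(corp$tokens[1, corp$tokens[1, ] >= SYM["A"]], vocab)
  expect_identical(merged, substring(av$donor$contigs[[1]], 1, covered))
})

test_that("reference packing chunks contigs with exact coordinate bookkeeping", {
  ref <- toy_ref(rand_seq(10000, seed = 11))
  corp <- pack_reference(ref, vocab, packing_config("reference", 1024L))
  expect_equal(n_contexts(corp), ceiling(10000 / 1022))
  recon <- paste(vapply(seq_len(n_contexts(corp)), function(j) {
    nuc <- corp$tokens[j, ] >= SYM["A"]
    decode_tokens(corp$tokens[j, nuc], vocab)
  }, ""), collapse = "")
  expect_identical(recon, ref$contigs[[1]])
  # 0-based slot j of the first context holds reference position j - 1
  nuc1 <- which(corp$tokens[1, ] >= SYM["A"])
  expect_equal(corp$pos[1, nuc1], (nuc1 - 1L) - 1L)
})

test_that("consecutive contexts list reads in non-decreasing start order", {
  cfg <- sim_config(contig_length = 3000, coverage_max = 6, read_length = 50, seed = 12)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(ref, ref, cfg)
  corp <- pack_consecutive(reads, vocab, packing_config("consecutive", 256L))
  for (j in seq_len(n_contexts(corp))) {
    st <- reads$start[match(unlist(corp$read_ids[[j]]), reads$read_id)]
    expect_true(all(diff(st) >= 0))
  }
})

test_that("cohort packing never mixes subjects and conserves all reads", {
  cfg <- sim_config(contig_length = 1200, coverage_max = 3, read_length = 40,
                    n_subjects = 3, seed = 13)
  ref <- simulate_reference(cfg)
  co <- simulate_cohort(ref, cfg)
  corp <- pack_cohort(co, vocab, packing_config("consecutive", 128L))
  all_ids <- unlist(corp$read_ids)
  expect_setequal(all_ids, cohort_reads(co)$read_id)
  for (j in seq_len(n_contexts(corp))) {
    subj <- unique(sub(":.*", "", unlist(corp$read_ids[[j]])))
    expect_length(subj, 1)
  }
})
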
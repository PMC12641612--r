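# End-to-end pipeline: simulate -> filter -> pack -> weight -> pretrain ->
# evaluate -> probe, driven by a YAML config, with a manifest of content
# hashes that makes a run reproducible and verifiable.

pipeline_allowed <- list(
  top = c("outdir", "seed", "sim", "filtration", "packing", "weighting",
          "model", "train", "eval", "tasks"),
  sim = c("n_contigs", "contig_length", "read_length", "coverage_min",
          "coverage_max", "variant_rate", "base_error_rate", "quality_mean",
          "quality_sd", "divergence", "n_subjects"),
  filtration = c("reduction_factor", "preserve_variants"),
  packing = c("strategy", "context_length"),
  weighting = c("mode", "alpha", "clip_max", "epsilon"),
  model = c("n_layers", "d_model", "n_heads", "objective", "mask_rate",
            "positional_encoding", "attention_window", "ffn_mult"),
  train = c("steps_phase1", "steps_phase2", "batch_size", "learning_rate",
            "mix_ratio", "subset_fraction", "weight_decay"),
  eval = c("strategies"),
  tasks = c("window", "controls", "folds", "probe", "probe_hidden"))

check_keys <- function(x, section) {
  allowed <- pipeline_allowed[[section]]
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    fail("unknown config key '%s' in section '%s'",
         bad[1], if (section == "top") "(top level)" else section)
}

num_fmt <- function(x) formatC(x, format = "g", digits = 8)

write_matrix_tsv <- function(m, path, digits = FALSE) {
  rows <- apply(m, 1, function(r)
    paste(if (digits) num_fmt(r) else r, collapse = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' Run the full pipeline from a config
#'
#' Executes simulate, filter, pack, weight, pretrain, evaluate and (when
#' configured) benchmark-probing stages in order, writing every intermediate
#' artifact under `outdir` and returning a manifest with a content hash per
#' artifact. Identical config + seed reproduce identical hashes. A stage
#' failure halts the run naming the stage; artifacts produced so far are
#' retained.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Sections: `outdir`, `seed`, `sim`, `filtration`, `packing`,
#'   `weighting`, `model`, `train`, `eval`, `tasks`. Unknown keys raise a
#'   validation error naming the key.
#' @param outdir optional override of the config's output directory.
#' @return A `run_manifest`: list with `config`, `seed`, `artifacts`
#'   (path + md5 per file), `timings`, `results`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cf <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cf, "top")
  for (s in intersect(names(cf), names(pipeline_allowed)[-1])) check_keys(cf[[s]], s)
  out <- outdir %||% cf$outdir %||% fail("config needs an 'outdir'")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cf$seed %||% 1L)
  artifacts <- character(0)
  timings <- list()
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      fail("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  add <- function(path) artifacts <<- c(artifacts, path)

  # -- simulate ---------------------------------------------------------------
  simargs <- cf$sim %||% list()
  simargs$seed <- seed
  sc <- do.call(sim_config, simargs)
  vocab <- build_vocab()
  env <- stage("simulate", {
    ref <- simulate_reference(sc)
    cohort <- simulate_cohort(ref, sc)
    div <- simulate_diverged_genome(ref, sc$divergence, derive_seed(seed, 161L))
    reads <- cohort_reads(cohort)
    vt <- do.call(rbind, lapply(cohort, function(s) {
      v <- as.data.frame(s$variants); if (nrow(v)) v$label <- s$subject_id; v
    }))
    variants <- new_variant_table(vt)
    write_fasta(ref, file.path(out, "reference.fasta")); add(file.path(out, "reference.fasta"))
    write_fasta(div, file.path(out, "diverged.fasta")); add(file.path(out, "diverged.fasta"))
    write_sam(reads, ref, file.path(out, "reads.sam")); add(file.path(out, "reads.sam"))
    write_variants(variants, ref, file.path(out, "variants.vcf")); add(file.path(out, "variants.vcf"))
    list(ref = ref, cohort = cohort, reads = reads, variants = variants)
  })

  # -- filter -----------------------------------------------------------------
  fargs <- cf$filtration %||% list()
  fc <- do.call(filtration_config, fargs)
  filtered <- stage("filter", {
    fr <- filter_reads(env$reads, env$ref, fc)
    write_sam(fr, env$ref, file.path(out, "filtered.sam")); add(file.path(out, "filtered.sam"))
    write_filtration_report(fr, file.path(out, "filtration_report.tsv"))
    add(file.path(out, "filtration_report.tsv"))
    fr
  })
  results$filtration <- as.list(attr(filtered, "report"))

  # -- pack + weight ----------------------------------------------------------
  pargs <- cf$packing %||% list()
  pargs$seed <- derive_seed(seed, 162L)
  pc <- do.call(packing_config, pargs)
  wargs <- cf$weighting %||% list()
  wc <- do.call(weighting_config, wargs)
  corpusB <- stage("pack", {
    cb <- pack_reads(filtered, vocab, pc, ref = env$ref)
    if (wc$mode == "dynamic")
      cb <- compute_weights(cb, build_pileup(filtered, env$ref), wc)
    write_matrix_tsv(cb$tokens, file.path(out, "corpus_tokens.tsv"))
    add(file.path(out, "corpus_tokens.tsv"))
    write_matrix_tsv(cb$weights, file.path(out, "corpus_weights.tsv"), digits = TRUE)
    add(file.path(out, "corpus_weights.tsv"))
    cb
  })
  refcfg <- pc; refcfg$strategy <- "reference"
  corpusA <- pack_reference(env$ref, vocab, refcfg)

  # -- pretrain ---------------------------------------------------------------
  margs <- cf$model %||% list()
  margs$vocab_size <- vocab$size
  margs$context_length <- pc$context_length
  margs$seed <- derive_seed(seed, 163L)
  if (!is.null(margs$attention_window) && identical(margs$attention_window, "dense"))
    margs$attention_window <- Inf
  mc <- do.call(model_config, margs)
  targs <- cf$train %||% list()
  targs$seed <- derive_seed(seed, 164L)
  tc <- do.call(train_config, targs)
  fit <- stage("pretrain", {
    ft <- train_two_phase(build_model(mc), corpusA, corpusB, tc)
    tr <- ft$trace
    writeLines(c("step\tphase\tcorpus\tloss",
                 sprintf("%d\t%d\t%s\t%s", tr$step, tr$phase, tr$corpus,
                         num_fmt(tr$loss))),
               file.path(out, "loss_trace.tsv"))
    add(file.path(out, "loss_trace.tsv"))
    ft
  })

  # -- evaluate ---------------------------------------------------------------
  evs <- (cf$eval %||% list())$strategies %||% c(pc$strategy, "reference")
  results$eval <- stage("eval", {
    rows <- lapply(evs, function(es) {
      ecfg <- pc; ecfg$strategy <- es
      ecorp <- pack_reads(filtered, vocab, ecfg, ref = env$ref)
      ev <- next_token_accuracy(fit$model, ecorp, dataset = es)
      data.frame(eval_set = es, accuracy = ev$next_token_accuracy,
                 n_scored = ev$n_scored_slots)
    })
    df <- do.call(rbind, rows)
    writeLines(c("eval_set\taccuracy\tn_scored",
                 sprintf("%s\t%s\t%d", df$eval_set, num_fmt(df$accuracy), df$n_scored)),
               file.path(out, "eval_results.tsv"))
    add(file.path(out, "eval_results.tsv"))
    df
  })

  # -- tasks ------------------------------------------------------------------
  ta <- cf$tasks
  if (!is.null(ta) && isTRUE(ta$probe)) {
    results$probe <- stage("tasks", {
      bench <- build_variant_benchmark(env$variants, env$ref,
                                      window = as.integer(ta$window %||% 31L),
                                      controls = as.integer(ta$controls %||% 50L),
                                      seed = derive_seed(seed, 165L))
      bench$label <- as.integer(bench$label > 0L)  # binary: variant vs control
      write_benchmark(bench, file.path(out, "benchmark.tsv"))
      add(file.path(out, "benchmark.tsv"))
      pr <- probe_layers(fit$model, bench, folds = as.integer(ta$folds %||% 10L),
                         seed = derive_seed(seed, 166L),
                         hidden = as.integer(ta$probe_hidden %||% 16L))
      write_matrix_tsv(unclass(pr), file.path(out, "probe_report.tsv"), digits = TRUE)
      add(file.path(out, "probe_report.tsv"))
      apply(unclass(pr), 1, stats::median)
    })
  }

  hashes <- tools::md5sum(artifacts)
  manifest <- structure(list(config = cf, seed = seed,
                             artifacts = data.frame(path = names(hashes),
                                                    md5 = unname(hashes),
                                                    stringsAsFactors = FALSE),
                             timings = timings, results = results),
                        class = "run_manifest")
  json <- jsonlite::toJSON(list(seed = seed, config = cf,
                                artifacts = manifest$artifacts),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, file.path(out, "manifest.json"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d artifact(s)\n", x$seed, nrow(x$artifacts)))
  print(x$artifacts)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
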
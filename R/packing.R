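# Read packing: assembling 151-bp reads into fixed-length token contexts.
#
# Context layout: BOS, then each packed item's nucleotide tokens followed by
# one SEP, then PAD to length L. A read that does not fit in the remaining
# space starts the next context; reads are never split (overlap-merged
# segments are the one exception, split at L-2 boundaries). Contexts never
# mix contigs. loss_mask is FALSE exactly on PAD and BOS slots; weights
# default to 1 on loss-masked slots and 0 elsewhere.

#' Packing configuration
#' @param strategy one of `consecutive`, `random`, `spaced`, `overlapping`,
#'   `reference`.
#' @param context_length context length L in token slots (default 1024,
#'   giving ~1000 bp of nucleotide capacity after BOS/SEP overhead).
#' @param seed integer seed (used by the `random` strategy).
#' @return A `packing_config`.
#' @export
packing_config <- function(strategy = "consecutive", context_length = 1024L, seed = 1L) {
  strategy <- match.arg(strategy,
                        c("consecutive", "random", "spaced", "overlapping", "reference"))
  check_scalar(context_length, "context_length", lower = 3, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(strategy = strategy, context_length = as.integer(context_length),
                 seed = as.integer(seed)), class = "packing_config")
}

new_corpus <- function(tokens, contig, pos, loss_mask, weights, read_ids,
                       contig_names, vocab, config) {
  structure(list(tokens = tokens, contig = contig, pos = pos,
                 loss_mask = loss_mask, weights = weights, read_ids = read_ids,
                 contig_names = contig_names, vocab = vocab, config = config),
            class = "packed_corpus")
}

#' @export
print.packed_corpus <- function(x, ...) {
  cat(sprintf("<packed_corpus> %d context(s) x %d slots (%s packing), %d nucleotide token(s)\n",
              nrow(x$tokens), ncol(x$tokens), x$config$strategy,
              sum(x$tokens >= x$vocab$symbol_to_id["A"])))
  invisible(x)
}

#' Number of contexts in a packed corpus
#' @param corpus a `packed_corpus`.
#' @return Integer count.
#' @export
n_contexts <- function(corpus) nrow(corpus$tokens)

#' Extract one context from a corpus
#' @param corpus a `packed_corpus`.
#' @param i context index.
#' @return List with `token_ids`, `contig_index`, `positions`, `loss_mask`,
#'   `weights`, `read_ids` (all per-slot except `read_ids`).
#' @export
get_context <- function(corpus, i) {
  list(token_ids = corpus$tokens[i, ], contig_index = corpus$contig[i, ],
       positions = corpus$pos[i, ], loss_mask = corpus$loss_mask[i, ],
       weights = corpus$weights[i, ], read_ids = corpus$read_ids[[i]])
}

# Core packer. items: list of lists with fields ids (int token ids, 0-based),
# contig (single contig name), pos (int vector, NA allowed), read_id.
# break_after: indices after which the current context must be flushed.
pack_items <- function(items, vocab, config, break_after = integer(0)) {
  L <- config$context_length
  PAD <- vocab$symbol_to_id[["PAD"]]; BOS <- vocab$symbol_to_id[["BOS"]]
  SEP <- vocab$symbol_to_id[["SEP"]]
  contig_names <- unique(vapply(items, `[[`, character(1), "contig"))
  rows_tok <- list(); rows_ct <- list(); rows_pos <- list(); rows_lm <- list()
  rows_id <- list()
  tok <- rep(PAD, L); ct <- rep(NA_integer_, L); po <- rep(NA_integer_, L)
  lm <- rep(FALSE, L); ids_here <- character(0)
  used <- 0L
  open_context <- function() {
    tok <<- rep(PAD, L); ct <<- rep(NA_integer_, L); po <<- rep(NA_integer_, L)
    lm <<- rep(FALSE, L); ids_here <<- character(0)
    tok[1] <<- BOS; used <<- 1L
  }
  flush_context <- function() {
    if (used > 1L) {
      rows_tok[[length(rows_tok) + 1L]] <<- tok
      rows_ct[[length(rows_ct) + 1L]] <<- ct
      rows_pos[[length(rows_pos) + 1L]] <<- po
      rows_lm[[length(rows_lm) + 1L]] <<- lm
      rows_id[[length(rows_id) + 1L]] <<- ids_here
    }
    used <<- 0L
  }
  for (j in seq_along(items)) {
    it <- items[[j]]
    len <- length(it$ids)
    if (len > L - 2L)
      fail("item of %d tokens exceeds context capacity L-2 = %d", len, L - 2L)
    if (used == 0L) open_context()
    if (used + len + 1L > L) { flush_context(); open_context() }
    slots <- used + seq_len(len)
    tok[slots] <- it$ids
    ct[slots] <- match(it$contig, contig_names)
    po[slots] <- it$pos
    lm[slots] <- TRUE
    tok[used + len + 1L] <- SEP
    lm[used + len + 1L] <- TRUE
    if (!is.null(it$read_id)) ids_here <- c(ids_here, it$read_id)
    used <- used + len + 1L
    if (j %in% break_after) flush_context()
  }
  flush_context()
  n <- length(rows_tok)
  tokens <- matrix(if (n) unlist(rows_tok) else integer(0), nrow = n, byrow = TRUE, ncol = L)
  contig <- matrix(if (n) unlist(rows_ct) else integer(0), nrow = n, byrow = TRUE, ncol = L)
  pos <- matrix(if (n) unlist(rows_pos) else integer(0), nrow = n, byrow = TRUE, ncol = L)
  loss_mask <- matrix(if (n) unlist(rows_lm) else logical(0), nrow = n, byrow = TRUE, ncol = L)
  weights <- matrix(0, nrow = n, ncol = L); weights[loss_mask] <- 1
  new_corpus(tokens, contig, pos, loss_mask, weights, rows_id, contig_names, vocab, config)
}

reads_to_items <- function(reads, vocab) {
  lapply(seq_len(nrow(reads)), function(i) {
    ids <- encode_tokens(reads$bases[i], vocab)
    list(ids = ids, contig = reads$contig[i],
         pos = reads$start[i] + seq_along(ids) - 1L, read_id = reads$read_id[i])
  })
}

contig_breaks <- function(contigs) {
  if (!length(contigs)) return(integer(0))
  which(contigs != c(contigs[-1], NA))
}

#' Pack reads in ascending genomic order
#'
#' Reads appear within each context sorted by (contig, start); each read's
#' tokens are contiguous and followed by one SEP; contexts never mix
#' contigs.
#'
#' @param reads an `aligned_reads` data frame.
#' @param vocab a [build_vocab()] vocabulary.
#' @param config a [packing_config()].
#' @return A `packed_corpus`.
#' @export
pack_consecutive <- function(reads, vocab, config = packing_config("consecutive")) {
  ord <- order(reads$contig, reads$start, reads$read_id)
  r <- reads[ord, , drop = FALSE]
  pack_items(reads_to_items(r, vocab), vocab, config,
             break_after = contig_breaks(r$contig))
}

#' Pack reads in seeded random order
#'
#' A seeded uniform shuffle of each contig's read set, then the same fill
#' rule as [pack_consecutive()].
#' @inheritParams pack_consecutive
#' @export
pack_random <- function(reads, vocab, config = packing_config("random")) {
  ord <- order(reads$contig, reads$start, reads$read_id)
  r <- reads[ord, , drop = FALSE]
  pieces <- split(seq_len(nrow(r)), r$contig)
  with_seed(derive_seed(config$seed, 606L), {
    shuffled <- unlist(lapply(pieces[order(names(pieces))],
                              function(ix) ix[sample.int(length(ix))]),
                       use.names = FALSE)
  })
  r2 <- r[shuffled, , drop = FALSE]
  pack_items(reads_to_items(r2, vocab), vocab, config,
             break_after = contig_breaks(r2$contig))
}

#' Pack non-overlapping reads together
#'
#' Greedy left-to-right passes over coordinate-sorted reads: a read joins
#' the current pass only if its interval does not overlap the previously
#' selected read's interval; skipped reads carry to later passes until all
#' are packed. Intervals within any single context are pairwise disjoint.
#' @inheritParams pack_consecutive
#' @export
pack_spaced <- function(reads, vocab, config = packing_config("spaced")) {
  ord <- order(reads$contig, reads$start, reads$read_id)
  r <- reads[ord, , drop = FALSE]
  items <- list(); breaks <- integer(0)
  for (nm in sort(unique(r$contig))) {
    ix <- which(r$contig == nm)
    remaining <- ix
    while (length(remaining)) {
      last_end <- -1L; sel <- integer(0); rest <- integer(0)
      for (i in remaining) {
        s <- r$start[i]; e <- s + nchar(r$bases[i])
        if (s >= last_end) { sel <- c(sel, i); last_end <- e } else rest <- c(rest, i)
      }
      items <- c(items, reads_to_items(r[sel, , drop = FALSE], vocab))
      breaks <- c(breaks, length(items))  # each pass starts fresh contexts
      remaining <- rest
    }
  }
  pack_items(items, vocab, config, break_after = breaks)
}

# Majority-vote consensus over a chain of overlapping reads; ties resolved
# by the reference base.
merge_chain <- function(reads, ix, ref_int, chain_start, chain_end) {
  span <- chain_end - chain_start
  counts <- matrix(0L, nrow = 5L, ncol = span)
  for (i in ix) {
    b <- seq_to_int(reads$bases[i])
    off <- reads$start[i] - chain_start
    idx <- cbind(b, off + seq_along(b))
    counts[idx] <- counts[idx] + 1L
  }
  best <- max.col(t(counts), ties.method = "first")
  refslice <- ref_int[(chain_start + 1L):chain_end]
  top <- counts[cbind(best, seq_len(span))]
  tie <- counts[cbind(refslice, seq_len(span))] == top
  best[tie] <- refslice[tie]
  best
}

#' Merge overlapping reads into contiguous sequences and pack them
#'
#' Maximal chains of interval-overlapping (or abutting) reads are merged
#' into one contiguous consensus sequence (per-position majority over
#' covering reads, ties broken by the reference base), then packed
#' consecutively; merged segments longer than L-2 split at L-2 boundaries.
#'
#' @inheritParams pack_consecutive
#' @param ref a `reference_genome` (tie-break source).
#' @export
pack_overlapping <- function(reads, ref, vocab, config = packing_config("overlapping")) {
  L <- config$context_length
  ord <- order(reads$contig, reads$start, reads$read_id)
  r <- reads[ord, , drop = FALSE]
  items <- list(); breaks <- integer(0)
  for (nm in sort(unique(r$contig))) {
    ix <- which(r$contig == nm)
    ref_int <- seq_to_int(contig_seq(ref, nm))
    ends <- r$start[ix] + nchar(r$bases[ix])
    chain <- list(ix[1]); chain_end <- ends[1]; chain_start <- r$start[ix[1]]
    chains <- list()
    for (j in seq_along(ix)[-1]) {
      i <- ix[j]
      if (r$start[i] <= chain_end) {
        chain[[length(chain) + 1L]] <- i
        chain_end <- max(chain_end, ends[j])
      } else {
        chains[[length(chains) + 1L]] <- list(ix = unlist(chain), s = chain_start, e = chain_end)
        chain <- list(i); chain_start <- r$start[i]; chain_end <- ends[j]
      }
    }
    chains[[length(chains) + 1L]] <- list(ix = unlist(chain), s = chain_start, e = chain_end)
    for (ch in chains) {
      cons <- merge_chain(r, ch$ix, ref_int, ch$s, ch$e)
      ids_all <- encode_tokens(int_to_seq(cons), vocab)
      pos_all <- ch$s + seq_along(ids_all) - 1L
      rid <- r$read_id[ch$ix]
      piece_starts <- seq(1L, length(ids_all), by = L - 2L)
      for (pj in seq_along(piece_starts)) {
        a <- piece_starts[pj]; b <- min(a + L - 3L, length(ids_all))
        items[[length(items) + 1L]] <- list(
          ids = ids_all[a:b], contig = nm, pos = pos_all[a:b],
          read_id = if (pj == 1L) rid else NULL)
      }
    }
    breaks <- c(breaks, length(items))
  }
  pack_items(items, vocab, config, break_after = breaks)
}

#' Pack a reference genome into contexts
#'
#' Each contig is chunked into (L-2)-token windows; each window becomes one
#' context: BOS-prefixed, SEP-terminated, PAD-completed.
#'
#' @param ref a `reference_genome`.
#' @inheritParams pack_consecutive
#' @export
pack_reference <- function(ref, vocab, config = packing_config("reference")) {
  L <- config$context_length
  items <- list(); breaks <- integer(0)
  for (nm in names(ref$contigs)) {
    ids_all <- encode_tokens(ref$contigs[[nm]], vocab)
    piece_starts <- seq(1L, length(ids_all), by = L - 2L)
    for (a in piece_starts) {
      b <- min(a + L - 3L, length(ids_all))
      items[[length(items) + 1L]] <- list(ids = ids_all[a:b], contig = nm,
                                          pos = (a:b) - 1L, read_id = NULL)
      breaks <- c(breaks, length(items))  # one window per context
    }
  }
  pack_items(items, vocab, config, break_after = breaks)
}

#' Pack a cohort subject by subject
#'
#' Packs each subject's reads separately (contexts never mix subjects, so
#' within-context overlap reflects one donor genome) and concatenates the
#' resulting corpora.
#'
#' @param cohort a `read_cohort`.
#' @param vocab a [build_vocab()] vocabulary.
#' @param config a [packing_config()].
#' @param ref a `reference_genome` (needed by some strategies).
#' @return A `packed_corpus`.
#' @export
pack_cohort <- function(cohort, vocab, config, ref = NULL) {
  parts <- lapply(cohort, function(s) pack_reads(s$reads, vocab, config, ref = ref))
  combine_corpora(parts)
}

#' Concatenate packed corpora
#' @param corpora list of `packed_corpus` objects sharing a vocabulary and
#'   context length.
#' @return A single `packed_corpus`.
#' @export
combine_corpora <- function(corpora) {
  corpora <- corpora[vapply(corpora, n_contexts, integer(1)) > 0L]
  if (!length(corpora)) fail("no non-empty corpora to combine")
  L <- ncol(corpora[[1]]$tokens)
  stopifnot(all(vapply(corpora, function(cc) ncol(cc$tokens), integer(1)) == L))
  all_names <- unique(unlist(lapply(corpora, `[[`, "contig_names")))
  remap <- function(cc) {
    m <- match(cc$contig_names, all_names)
    ct <- cc$contig
    ct[] <- m[cc$contig]
    ct
  }
  new_corpus(do.call(rbind, lapply(corpora, `[[`, "tokens")),
             do.call(rbind, lapply(corpora, remap)),
             do.call(rbind, lapply(corpora, `[[`, "pos")),
             do.call(rbind, lapply(corpora, `[[`, "loss_mask")),
             do.call(rbind, lapply(corpora, `[[`, "weights")),
             do.call(c, lapply(corpora, `[[`, "read_ids")),
             all_names, corpora[[1]]$vocab, corpora[[1]]$config)
}

#' Pack reads (or a reference) under a named strategy
#'
#' Dispatch wrapper over the five packing strategies.
#'
#' @param reads an `aligned_reads` data frame (ignored for `reference`).
#' @param vocab a [build_vocab()] vocabulary.
#' @param config a [packing_config()]; `config$strategy` selects the packer.
#' @param ref a `reference_genome` (required for `overlapping` and
#'   `reference`).
#' @return A `packed_corpus`.
#' @export
pack_reads <- function(reads, vocab, config, ref = NULL) {
  switch(config$strategy,
         consecutive = pack_consecutive(reads, vocab, config),
         random = pack_random(reads, vocab, config),
         spaced = pack_spaced(reads, vocab, config),
         overlapping = {
           if (is.null(ref)) fail("overlapping packing requires 'ref'")
           pack_overlapping(reads, ref, vocab, config)
         },
         reference = {
           if (is.null(ref)) fail("reference packing requires 'ref'")
           pack_reference(ref, vocab, config)
         })
}
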
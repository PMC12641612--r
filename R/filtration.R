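# Quality-aware k-fold read filtration.
#
# Reads are ranked globally by (carries-a-variant desc, mean base quality
# desc, read_id asc) and the top ceil(n/k) are retained; an explicit repair
# pass then guarantees that every (position, allele) supported by any input
# read is still supported by the retained set, by swapping variant-carrying
# reads in for the lowest-ranked retained non-variant reads.

#' Filtration configuration
#' @param reduction_factor fold-reduction `k` (default 8, the headline
#'   setting: an 8-fold cut of the training read set).
#' @param preserve_variants repair pass on/off.
#' @return A `filtration_config`.
#' @export
filtration_config <- function(reduction_factor = 8L, preserve_variants = TRUE) {
  check_scalar(reduction_factor, "reduction_factor", lower = 1, integer = TRUE)
  structure(list(reduction_factor = as.integer(reduction_factor),
                 preserve_variants = isTRUE(preserve_variants)),
            class = "filtration_config")
}

#' Score reads for filtration
#'
#' For each read: `variant_flag` is `TRUE` iff at least one base differs
#' from the reference over the read's interval, and `quality_score` is the
#' arithmetic mean of the per-base Phred qualities.
#'
#' @param reads an `aligned_reads` data frame (one or more rows).
#' @param ref a `reference_genome`.
#' @return A data frame with columns `read_id`, `variant_flag`,
#'   `quality_score`.
#' @export
score_read <- function(reads, ref) {
  stopifnot(inherits(ref, "reference_genome"))
  n <- nrow(reads)
  vf <- logical(n); qs <- numeric(n)
  for (nm in unique(reads$contig)) {
    idx <- which(reads$contig == nm)
    cs <- contig_seq(ref, nm)
    lens <- nchar(reads$bases[idx])
    if (any(reads$start[idx] < 0L | reads$start[idx] + lens > nchar(cs)))
      fail("read overhangs contig '%s'", nm)
    refsub <- substring(cs, reads$start[idx] + 1L, reads$start[idx] + lens)
    vf[idx] <- reads$bases[idx] != refsub
  }
  qs <- vapply(reads$qual, function(q) mean(chr_to_phred(q)), numeric(1), USE.NAMES = FALSE)
  data.frame(read_id = reads$read_id, variant_flag = vf, quality_score = qs,
             stringsAsFactors = FALSE)
}

# (position, allele) support sets as "contig:pos:allele" keys, one entry per
# read listing the non-reference alleles it carries. Whole-string comparison
# first so the per-base diff only touches mismatching reads.
read_alt_keys <- function(reads, ref) {
  keys <- vector("list", nrow(reads))
  for (nm in unique(reads$contig)) {
    idx <- which(reads$contig == nm)
    cs <- contig_seq(ref, nm)
    lens <- nchar(reads$bases[idx])
    refsub <- substring(cs, reads$start[idx] + 1L, reads$start[idx] + lens)
    mism <- idx[reads$bases[idx] != refsub]
    for (i in mism) {
      b <- strsplit(reads$bases[i], "", fixed = TRUE)[[1]]
      r <- strsplit(substring(cs, reads$start[i] + 1L, reads$start[i] + length(b)),
                    "", fixed = TRUE)[[1]]
      d <- which(b != r)
      keys[[i]] <- sprintf("%s:%d:%s", nm, reads$start[i] + d - 1L, b[d])
    }
  }
  keys
}

#' Filter reads k-fold, preserving variant evidence
#'
#' Retains exactly `ceil(n / k)` reads: the top slice of the global ranking
#' by `(variant_flag desc, quality_score desc, read_id asc)`. With
#' `preserve_variants`, any (position, allele) supported by an input read
#' but absent from the slice is repaired by swapping its best-ranked carrier
#' in for the lowest-ranked retained non-variant read (best effort: when no
#' retained non-variant read remains, the cardinality contract wins). Output
#' is coordinate-sorted.
#'
#' @param reads an `aligned_reads` data frame.
#' @param ref a `reference_genome`.
#' @param config a [filtration_config()].
#' @return Retained `aligned_reads`, with a `report` attribute
#'   (`n_in`, `n_out`, `fold`, `n_variant_positions_preserved`).
#' @export
filter_reads <- function(reads, ref, config = filtration_config()) {
  stopifnot(inherits(config, "filtration_config"))
  k <- config$reduction_factor
  n <- nrow(reads)
  if (n == 0L) {
    out <- reads
    attr(out, "report") <- data.frame(n_in = 0L, n_out = 0L, fold = NA_real_,
                                      n_variant_positions_preserved = 0L)
    return(out)
  }
  sc <- score_read(reads, ref)
  rnk <- order(-sc$variant_flag, -sc$quality_score, sc$read_id)
  n_keep <- as.integer(ceiling(n / k))
  keep <- rnk[seq_len(n_keep)]
  n_pres <- 0L
  if (config$preserve_variants && k > 1L) {
    alt <- read_alt_keys(reads, ref)
    nk <- lengths(alt)
    all_keys <- unique(unlist(alt))
    if (length(all_keys)) {
      kept <- logical(n); kept[keep] <- TRUE
      rank_of <- integer(n); rank_of[rnk] <- seq_len(n)
      # key -> carrier read indices, carriers best-rank first
      pair_read <- rep.int(seq_len(n), nk)
      pair_key <- unlist(alt)
      ord <- order(rank_of[pair_read])
      carriers_by_key <- split(pair_read[ord], pair_key[ord])
      supported <- new.env(parent = emptyenv())
      for (key in unique(unlist(alt[keep]))) assign(key, TRUE, envir = supported)
      missing <- all_keys[!vapply(all_keys, exists, logical(1), envir = supported)]
      # retained non-variant reads, worst-ranked first, available to sacrifice
      sacrificial <- keep[!sc$variant_flag[keep]]
      sacrificial <- sacrificial[order(-rank_of[sacrificial])]
      si <- 1L
      for (key in missing) {
        if (si > length(sacrificial)) break
        if (exists(key, envir = supported)) next  # covered by an earlier swap
        cand <- carriers_by_key[[key]]
        cand <- cand[!kept[cand]]
        if (!length(cand)) next
        best <- cand[1]
        kept[sacrificial[si]] <- FALSE; si <- si + 1L
        kept[best] <- TRUE
        for (kk in alt[[best]]) assign(kk, TRUE, envir = supported)
      }
      keep <- which(kept)
      n_pres <- sum(vapply(all_keys, exists, logical(1), envir = supported))
    }
  }
  out <- reads[sort(keep), , drop = FALSE]
  out <- out[order(out$contig, out$start, out$read_id), , drop = FALSE]
  out <- new_reads(out)
  attr(out, "report") <- data.frame(n_in = n, n_out = length(keep),
                                    fold = n / length(keep),
                                    n_variant_positions_preserved = n_pres)
  out
}

#' Write a filtration report as TSV
#' @param filtered result of [filter_reads()].
#' @param path output path.
#' @export
write_filtration_report <- function(filtered, path) {
  utils::write.table(attr(filtered, "report"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
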
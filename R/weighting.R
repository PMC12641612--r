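# Dynamic importance weighting: per-token loss weights inversely related to
# the empirical allele frequency at the token's genomic position, so rare
# (variant) bases carry more of the training signal than redundant
# reference bases.

#' Weighting configuration
#' @param mode `uniform` or `dynamic`.
#' @param alpha inverse-frequency exponent (>= 0; 0 reduces to uniform).
#' @param clip_max raw weights are clipped to `[1/clip_max, clip_max]`.
#' @param epsilon smoothing constant added to the allele frequency.
#' @return A `weighting_config`.
#' @export
weighting_config <- function(mode = "uniform", alpha = 1, clip_max = 100, epsilon = 1e-6) {
  mode <- match.arg(mode, c("uniform", "dynamic"))
  check_scalar(alpha, "alpha", lower = 0)
  check_scalar(clip_max, "clip_max", lower = 1)
  check_scalar(epsilon, "epsilon", lower = .Machine$double.xmin)
  structure(list(mode = mode, alpha = alpha, clip_max = clip_max, epsilon = epsilon),
            class = "weighting_config")
}

#' Build a per-position allele-count pileup
#'
#' `counts[a, p+1]` is the number of reads covering 0-based position `p`
#' with base `a` (rows A, C, G, T, N); depth is the column sum.
#'
#' @param reads an `aligned_reads` data frame.
#' @param ref a `reference_genome` (supplies contig names and lengths).
#' @return A `pileup_table`: per contig, a 5 x contig-length integer count
#'   matrix.
#' @export
build_pileup <- function(reads, ref) {
  out <- lapply(names(ref$contigs), function(nm) {
    clen <- nchar(ref$contigs[[nm]])
    ix <- which(reads$contig == nm)
    if (!length(ix)) return(matrix(0L, nrow = 5L, ncol = clen,
                                   dimnames = list(BASES_N, NULL)))
    lens <- nchar(reads$bases[ix])
    alleles <- unlist(lapply(ix, function(i) seq_to_int(reads$bases[i])),
                      use.names = FALSE)
    pos0 <- rep(reads$start[ix], lens) + sequence(lens) - 1L
    if (any(pos0 < 0L | pos0 >= clen)) fail("read overhangs contig '%s'", nm)
    flat <- (pos0) * 5L + alleles  # 1-based within column-major 5 x clen
    m <- matrix(tabulate(flat, nbins = 5L * clen), nrow = 5L,
                dimnames = list(BASES_N, NULL))
    m
  })
  names(out) <- names(ref$contigs)
  structure(out, class = "pileup_table")
}

#' Per-position depth from a pileup
#' @param pileup a `pileup_table`.
#' @param contig contig name.
#' @return Integer vector of depths (length = contig length).
#' @export
pileup_depth <- function(pileup, contig) colSums(pileup[[contig]])

#' Fill per-slot loss weights in a packed corpus
#'
#' Uniform mode sets every loss-masked slot to weight 1. Dynamic mode gives
#' each nucleotide slot the inverse relative allele frequency of its token,
#' `(c(p,a)/d(p) + epsilon)^(-alpha)`, clipped to `[1/clip_max, clip_max]`,
#' then rescales nucleotide weights to mean 1; loss-masked structural slots
#' (SEP) keep weight exactly 1, so the corpus mean over all loss-masked
#' slots is exactly 1. PAD/BOS slots keep weight 0.
#'
#' @param corpus a `packed_corpus`.
#' @param pileup a [build_pileup()] table covering every nucleotide slot.
#' @param config a [weighting_config()].
#' @return The corpus with its `weights` matrix filled.
#' @export
compute_weights <- function(corpus, pileup, config = weighting_config()) {
  stopifnot(inherits(corpus, "packed_corpus"), inherits(config, "weighting_config"))
  W <- matrix(0, nrow = nrow(corpus$tokens), ncol = ncol(corpus$tokens))
  W[corpus$loss_mask] <- 1
  if (config$mode == "dynamic") {
    nuc_lo <- corpus$vocab$symbol_to_id[["A"]]
    is_nuc <- corpus$loss_mask & corpus$tokens >= nuc_lo & !is.na(corpus$pos)
    idx <- which(is_nuc)
    if (length(idx)) {
      allele <- corpus$tokens[idx] - nuc_lo + 1L  # 1..5 over A,C,G,T,N
      ctg <- corpus$contig[idx]; p <- corpus$pos[idx]
      u <- numeric(length(idx))
      for (ci in unique(ctg)) {
        nm <- corpus$contig_names[ci]
        m <- pileup[[nm]]
        if (is.null(m)) fail("pileup lacks contig '%s'", nm)
        sel <- which(ctg == ci)
        if (any(p[sel] >= ncol(m)))
          fail("slot position %d absent from pileup for contig '%s'",
               max(p[sel]), nm)
        d <- colSums(m)[p[sel] + 1L]
        cc <- m[cbind(allele[sel], p[sel] + 1L)]
        if (any(d == 0))
          fail("slot position %d absent from pileup for contig '%s'",
               p[sel][which(d == 0)[1]], nm)
        f <- cc / d
        u[sel] <- (f + config$epsilon)^(-config$alpha)
      }
      u <- pmin(pmax(u, 1 / config$clip_max), config$clip_max)
      W[idx] <- u / mean(u)
    }
  }
  corpus$weights <- W
  corpus$weighting <- config
  corpus
}
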
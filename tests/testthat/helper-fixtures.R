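# Shared fixtures, built in code.

# A reference genome from explicit sequences.
toy_ref <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- sprintf("contig%02d", seq_along(seqs))
  readlm:::new_reference(seqs)
}

# An aligned_reads data frame from parallel vectors; qualities default to a
# constant Phred 30.
toy_reads <- function(bases, start, contig = "contig01", qual = NULL,
                      subject_id = "S1", read_id = NULL) {
  n <- length(bases)
  if (is.null(qual))
    qual <- vapply(nchar(bases), function(k) readlm:::phred_to_chr(rep(30L, k)), "")
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  readlm:::new_reads(data.frame(
    read_id = read_id, contig = rep_len(contig, n), start = as.integer(start),
    bases = bases, qual = qual, mapq = 60L,
    subject_id = rep_len(subject_id, n), stringsAsFactors = FALSE))
}

# Random nucleotide string.
rand_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small model for structural tests.
tiny_model <- function(...) {
  build_model(model_config(n_layers = 1L, d_model = 16L, n_heads = 2L,
                           context_length = 64L, seed = 7L, ...))
}

# Independent per-position depth oracle (event counting, no pileup code).
depth_oracle <- function(reads, contig, clen) {
  ix <- which(reads$contig == contig)
  ev <- integer(clen + 1L)
  for (i in ix) {
    s <- reads$start[i]; e <- s + nchar(reads$bases[i])
    ev[s + 1L] <- ev[s + 1L] + 1L
    ev[e + 1L] <- ev[e + 1L] - 1L
  }
  cumsum(ev)[seq_len(clen)]
}
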
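# Nucleotide tokenizer: a fixed 9-symbol vocabulary well under the 16-entry
# budget the model's embedding table is designed around. Structural symbols
# first (PAD is id 0 by convention), then the nucleotides on contiguous ids.

VOCAB_SYMBOLS <- c("PAD", "BOS", "SEP", "MASK", "A", "C", "G", "T", "N")

#' Build the token vocabulary
#'
#' Fixed, versioned map between symbols and integer ids: `PAD=0`, `BOS=1`,
#' `SEP=2`, `MASK=3`, then `A`,`C`,`G`,`T`,`N` on contiguous ids 4-8. Contig
#' identity is carried in packed-context metadata, not in dedicated tokens,
#' which keeps the vocabulary at 9 symbols (the embedding budget allows up
#' to 16).
#'
#' @return A `token_vocab`: list with `symbol_to_id`, `id_to_symbol`,
#'   `nucleotide_ids`, `size`, `version`.
#' @export
build_vocab <- function() {
  ids <- seq_along(VOCAB_SYMBOLS) - 1L
  names(ids) <- VOCAB_SYMBOLS
  structure(list(
    symbol_to_id = ids,
    id_to_symbol = stats::setNames(VOCAB_SYMBOLS, ids),
    nucleotide_ids = unname(ids[BASES_N]),
    size = length(ids),
    version = "1"), class = "token_vocab")
}

#' @export
print.token_vocab <- function(x, ...) {
  cat(sprintf("<token_vocab v%s> %d symbols: %s\n", x$version, x$size,
              paste(sprintf("%s=%d", names(x$symbol_to_id), x$symbol_to_id), collapse = " ")))
  invisible(x)
}

#' Encode a nucleotide sequence as token ids
#'
#' Length-preserving; characters outside A/C/G/T/N raise an error naming the
#' first offending index.
#'
#' @param sequence a character string over A/C/G/T/N.
#' @param vocab a [build_vocab()] vocabulary.
#' @return Integer vector of token ids.
#' @export
encode_tokens <- function(sequence, vocab) {
  stopifnot(inherits(vocab, "token_vocab"))
  if (!nzchar(sequence)) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ids <- vocab$symbol_to_id[chars]
  bad <- which(is.na(ids) | !(chars %in% BASES_N))
  if (length(bad))
    fail("encode_tokens: invalid character '%s' at index %d", chars[bad[1]], bad[1])
  unname(ids)
}

#' Decode token ids back to text
#'
#' Inverse of [encode_tokens()] on nucleotides; structural tokens render as
#' bracketed markers (`[PAD]`, `[BOS]`, `[SEP]`, `[MASK]`).
#'
#' @param ids integer token ids.
#' @param vocab a [build_vocab()] vocabulary.
#' @return A character string.
#' @export
decode_tokens <- function(ids, vocab) {
  stopifnot(inherits(vocab, "token_vocab"))
  if (!length(ids)) return("")
  if (any(is.na(ids)) || any(ids < 0L) || any(ids >= vocab$size))
    fail("decode_tokens: token id out of range [0, %d]", vocab$size - 1L)
  sym <- vocab$id_to_symbol[as.character(ids)]
  structural <- !(sym %in% BASES_N)
  sym[structural] <- paste0("[", sym[structural], "]")
  paste(sym, collapse = "")
}

#' Serialize a vocabulary as a two-column text table
#' @param vocab a `token_vocab`.
#' @param path output path.
#' @export
write_vocab <- function(vocab, path) {
  utils::write.table(data.frame(symbol = names(vocab$symbol_to_id),
                                id = unname(vocab$symbol_to_id)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
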
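# Plain-text FASTA / SAM / VCF input and output.
#
# Coordinates are 0-based half-open everywhere in memory and 1-based only at
# the format boundary (SAM POS, VCF POS). Readers enforce the narrow
# contracts this toolkit trains on: single-match-run CIGARs, single-base
# REF/ALT, A/C/G/T[/N] alphabets. Out-of-scope records (unmapped, secondary,
# indels, multi-allelics) are skipped with a counted warning, not errors.

#' Read a FASTA file
#'
#' Sequences are uppercased, `U` is normalised to `T`, and any character
#' outside A/C/G/T/N raises a parse error naming the offending line. `N` is
#' rejected when `allow_n = FALSE` (reference genomes are clean by
#' convention).
#'
#' @param path file path.
#' @param allow_n allow `N` in sequences.
#' @return A `reference_genome`.
#' @export
read_fasta <- function(path, allow_n = FALSE) {
  if (!file.exists(path)) fail("file not found: %s", path)
  lines <- readLines(path)
  seqs <- list(); cur <- NULL; buf <- character()
  flush <- function() {
    if (!is.null(cur)) seqs[[cur]] <<- paste(buf, collapse = "")
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      cur <- sub("\\s.*$", "", substring(ln, 2))
      if (!nzchar(cur)) fail("FASTA parse error at line %d: empty header", i)
      if (cur %in% names(seqs)) fail("FASTA parse error at line %d: duplicate contig '%s'", i, cur)
      buf <- character()
    } else {
      if (is.null(cur)) fail("FASTA parse error at line %d: sequence before header", i)
      s <- chartr("u", "t", toupper(ln))
      s <- chartr("U", "T", s)
      ok <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
      if (!grepl(ok, s)) fail("FASTA parse error at line %d: invalid character in sequence", i)
      buf <- c(buf, s)
    }
  }
  flush()
  if (!length(seqs)) fail("FASTA parse error: no sequences in %s", path)
  new_reference(unlist(seqs))
}

#' Write a genome as FASTA
#' @param ref a `reference_genome`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(ref$contigs)) {
    writeLines(paste0(">", nm), con)
    s <- ref$contigs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write aligned reads as SAM
#'
#' Coordinate-sorted single-end SAM: mandatory `@SQ` lines, one `@RG` per
#' subject, 1-based POS, CIGAR `<len>M`, populated SEQ/QUAL, `RG:Z:` tag.
#'
#' @param reads an `aligned_reads` data frame.
#' @param ref a `reference_genome` supplying `@SQ` headers.
#' @param path output path.
#' @export
write_sam <- function(reads, ref, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(ref$contigs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(ref$contigs[[nm]])), con)
  for (sid in unique(reads$subject_id))
    writeLines(sprintf("@RG\tID:%s\tSM:%s", sid, sid), con)
  ord <- order(reads$contig, reads$start, reads$read_id)
  r <- reads[ord, ]
  if (nrow(r))
    writeLines(sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                       r$read_id, r$contig, r$start + 1L, r$mapq,
                       nchar(r$bases), r$bases, r$qual, r$subject_id), con)
  invisible(path)
}

#' Read aligned reads from SAM
#'
#' POS is converted to a 0-based start. Unmapped, secondary and
#' supplementary records are skipped; so are records whose CIGAR is not a
#' single match run (insertions, deletions, soft clips are out of scope).
#' Skip counts are attached as the `"skipped"` attribute and reported in one
#' consolidated warning.
#'
#' @param path SAM file path.
#' @return An `aligned_reads` data frame with a `skipped` attribute
#'   (named integer: `unmapped`, `secondary`, `cigar`).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  skipped <- c(unmapped = 0L, secondary = 0L, cigar = 0L)
  rows <- list()
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    for (i in seq_along(f)) {
      x <- f[[i]]
      if (length(x) < 11L) fail("SAM parse error: record %d has fewer than 11 fields", i)
      flag <- as.integer(x[2])
      if (bitwAnd(flag, 4L) != 0L) { skipped["unmapped"] <- skipped["unmapped"] + 1L; next }
      if (bitwAnd(flag, 256L) != 0L || bitwAnd(flag, 2048L) != 0L) {
        skipped["secondary"] <- skipped["secondary"] + 1L; next
      }
      if (!grepl("^[0-9]+M$", x[6])) { skipped["cigar"] <- skipped["cigar"] + 1L; next }
      rg <- grep("^RG:Z:", x[-(1:11)], value = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = x[1], contig = x[3], start = as.integer(x[4]) - 1L,
        bases = x[10], qual = x[11], mapq = as.integer(x[5]),
        subject_id = if (length(rg)) sub("^RG:Z:", "", rg[1]) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (any(skipped > 0L))
    warning(sprintf("read_alignments: skipped %d unmapped, %d secondary/supplementary, %d non-matching-CIGAR record(s)",
                    skipped["unmapped"], skipped["secondary"], skipped["cigar"]), call. = FALSE)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), contig = character(), start = integer(),
               bases = character(), qual = character(), mapq = integer(),
               subject_id = character())
  out <- new_reads(df)
  attr(out, "skipped") <- skipped
  out
}

#' Write a variant table as VCF v4.2
#'
#' 1-based POS, single-base REF/ALT, record label carried in `INFO` as
#' `LABEL=`.
#'
#' @param variants a `variant_table`.
#' @param ref a `reference_genome` supplying `##contig` headers.
#' @param path output path.
#' @export
write_variants <- function(variants, ref, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines('##INFO=<ID=LABEL,Number=1,Type=String,Description="Record label">', con)
  for (nm in names(ref$contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", nm, nchar(ref$contigs[[nm]])), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tLABEL=%s",
                       variants$contig, variants$position + 1L,
                       variants$ref_allele, variants$alt_allele, variants$label), con)
  invisible(path)
}

#' Read a VCF v4.2 variant table
#'
#' POS converts to a 0-based position; labels round-trip through
#' `INFO/LABEL`. Multi-allelic and indel records are skipped with a counted
#' warning (attached as the `"skipped"` attribute).
#'
#' @param path VCF file path.
#' @return A `variant_table` with a `skipped` attribute.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  skipped <- 0L
  rows <- list()
  for (ln in body) {
    x <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(x) < 8L) fail("VCF parse error: record with fewer than 8 fields")
    ref_a <- x[4]; alt_a <- x[5]
    if (nchar(ref_a) != 1L || nchar(alt_a) != 1L || grepl(",", alt_a, fixed = TRUE)) {
      skipped <- skipped + 1L; next
    }
    lab <- regmatches(x[8], regexpr("LABEL=[^;]*", x[8]))
    rows[[length(rows) + 1L]] <- data.frame(
      contig = x[1], position = as.integer(x[2]) - 1L,
      ref_allele = ref_a, alt_allele = alt_a,
      label = if (length(lab)) sub("^LABEL=", "", lab) else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(sprintf("read_variants: skipped %d multi-allelic/indel record(s)", skipped),
            call. = FALSE)
  out <- new_variant_table(if (length(rows)) do.call(rbind, rows) else NULL)
  attr(out, "skipped") <- skipped
  out
}
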
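# Seeded simulator for exome-style aligned short reads.
#
# The simulator is the study-condition generator for the whole toolkit: it
# emulates 151-bp aligned reads, per-position coverage bounded in
# [coverage_min, coverage_max], rare non-reference bases per read, Phred
# qualities, multi-subject cohorts and a diverged second genome that stands
# in for multispecies data.

#' Simulation configuration
#'
#' Bundles every knob of the read simulator. Defaults encode the study
#' conditions the toolkit targets: 151-bp reads, coverage depth between 1 and
#' 180 reads per position, roughly one substitution per kilobase in donor
#' genomes and one sequencing error per kilobase of read sequence (so a
#' typical read carries ~1-2 non-reference bases), and a 15% diverged second
#' genome.
#'
#' @param n_contigs number of contigs in the simulated reference.
#' @param contig_length length of each contig in bp.
#' @param read_length read length in bp (default 151).
#' @param coverage_min,coverage_max bounds on per-position read depth.
#' @param variant_rate substitution rate per bp for donor genomes.
#' @param base_error_rate per-base sequencing error probability.
#' @param quality_mean,quality_sd Phred quality model (clipped normal).
#' @param quality_clip length-2 integer clip range for qualities.
#' @param divergence substitution rate per bp for the diverged genome.
#' @param n_subjects number of cohort subjects.
#' @param seed master integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 1L, contig_length = 100000L, read_length = 151L,
                       coverage_min = 1L, coverage_max = 180L,
                       variant_rate = 1e-3, base_error_rate = 1e-3,
                       quality_mean = 30, quality_sd = 5, quality_clip = c(2L, 40L),
                       divergence = 0.15, n_subjects = 1L, seed = 1L) {
  check_scalar(n_contigs, "n_contigs", lower = 1, integer = TRUE)
  check_scalar(contig_length, "contig_length", lower = 1, integer = TRUE)
  check_scalar(read_length, "read_length", lower = 1, integer = TRUE)
  check_scalar(coverage_min, "coverage_min", lower = 1, integer = TRUE)
  check_scalar(coverage_max, "coverage_max", lower = coverage_min, integer = TRUE)
  check_scalar(variant_rate, "variant_rate", lower = 0, upper = 1)
  check_scalar(base_error_rate, "base_error_rate", lower = 0, upper = 1)
  check_scalar(divergence, "divergence", lower = 0, upper = 1)
  check_scalar(quality_sd, "quality_sd", lower = 0)
  check_scalar(n_subjects, "n_subjects", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(
    n_contigs = as.integer(n_contigs), contig_length = as.integer(contig_length),
    read_length = as.integer(read_length),
    coverage_min = as.integer(coverage_min), coverage_max = as.integer(coverage_max),
    variant_rate = variant_rate, base_error_rate = base_error_rate,
    quality_mean = quality_mean, quality_sd = quality_sd,
    quality_clip = as.integer(quality_clip),
    divergence = divergence, n_subjects = as.integer(n_subjects),
    seed = as.integer(seed)), class = "sim_config")
}

new_reference <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    fail("contig names must be present and unique")
  if (any(nchar(sequences) == 0L)) fail("contig sequences must be non-empty")
  structure(list(contigs = sequences), class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %d contig(s), %s bp total\n",
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ",")))
  for (nm in names(x$contigs))
    cat(sprintf("  %s: %d bp\n", nm, nchar(x$contigs[[nm]])))
  invisible(x)
}

contig_seq <- function(ref, contig) {
  s <- ref$contigs[[contig]]
  if (is.null(s)) fail("unknown contig '%s'", contig)
  s
}

#' Simulate a reference genome
#'
#' Draws `n_contigs` uniform-random nucleotide sequences of `contig_length`
#' bp. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return A `reference_genome`: a named list of A/C/G/T character sequences.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 101L), {
    seqs <- vapply(seq_len(config$n_contigs), function(i) {
      paste(sample(BASES, config$contig_length, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("contig%02d", seq_len(config$n_contigs))
  new_reference(seqs)
}

new_variant_table <- function(df) {
  need <- c("contig", "position", "ref_allele", "alt_allele", "label")
  if (is.null(df)) df <- data.frame(contig = character(), position = integer(),
                                    ref_allele = character(), alt_allele = character(),
                                    label = character())
  stopifnot(all(need %in% names(df)))
  df <- df[order(df$contig, df$position), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Inject substitution variants into a genome
#'
#' Each base mutates independently with probability `rate` to a uniformly
#' chosen different base, producing a donor genome plus the table of applied
#' substitutions (0-based positions).
#'
#' @param ref a `reference_genome`.
#' @param rate substitution probability per bp.
#' @param seed integer seed.
#' @param label label stored with each variant record.
#' @return list with elements `donor` (a `reference_genome`) and `variants`
#'   (a `variant_table` data frame).
#' @export
apply_variants <- function(ref, rate, seed, label = "simulated") {
  check_scalar(rate, "rate", lower = 0, upper = 1)
  recs <- list()
  donor <- ref$contigs
  with_seed(derive_seed(seed, 202L), {
    for (nm in names(donor)) {
      v <- seq_to_int(donor[[nm]])
      n <- length(v)
      hit <- which(stats::runif(n) < rate)
      if (length(hit)) {
        old <- v[hit]
        # uniform over the 3 alternate bases
        shift <- sample.int(3L, length(hit), replace = TRUE)
        new <- ((old - 1L + shift) %% 4L) + 1L
        v[hit] <- new
        donor[[nm]] <- int_to_seq(v)
        recs[[nm]] <- data.frame(contig = nm, position = hit - 1L,
                                 ref_allele = BASES[old], alt_allele = BASES[new],
                                 label = label, stringsAsFactors = FALSE)
      }
    }
  })
  tab <- if (length(recs)) do.call(rbind, recs) else NULL
  list(donor = new_reference(donor), variants = new_variant_table(tab))
}

#' Simulate a diverged genome
#'
#' Substitution-only divergence at the given rate, preserving contig
#' structure; a stand-in for a second-species genome.
#'
#' @inheritParams apply_variants
#' @param divergence substitution probability per bp.
#' @return A `reference_genome`.
#' @export
simulate_diverged_genome <- function(ref, divergence, seed) {
  check_scalar(divergence, "divergence", lower = 0, upper = 1)
  apply_variants(ref, divergence, derive_seed(seed, 303L), label = "diverged")$donor
}

new_reads <- function(df) {
  need <- c("read_id", "contig", "start", "bases", "qual", "mapq", "subject_id")
  stopifnot(all(need %in% names(df)))
  df <- df[, need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("<aligned_reads> %d reads, %d contig(s), %d subject(s)\n",
              nrow(x), length(unique(x$contig)), length(unique(x$subject_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# Layered coverage model. Tile length is 7 * read_length (~1 kb for 151-bp
# reads); each tile draws a target depth uniformly on
# [coverage_min, coverage_max]; depth level l covers the union of tiles whose
# target is >= l with abutting, non-overlapping reads. Because tile length is
# an exact multiple of read length, per-position depth equals the tile target
# exactly at every position covered by whole reads, which keeps the depth
# inside the configured bounds at every interior position.
tile_depth_targets <- function(contig_length, config) {
  tile_len <- 7L * config$read_length
  n_tiles <- max(1L, contig_length %/% tile_len)
  sample.int(config$coverage_max - config$coverage_min + 1L, n_tiles,
             replace = TRUE) + config$coverage_min - 1L
}

read_starts_for_contig <- function(contig_length, targets, read_length) {
  tile_len <- 7L * read_length
  n_tiles <- length(targets)
  starts <- integer(0)
  for (lev in seq_len(max(targets))) {
    active <- targets >= lev
    r <- rle(active)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run_start <- (begs[j] - 1L) * tile_len
      run_end <- if (ends[j] == n_tiles) contig_length else ends[j] * tile_len
      if (run_end - run_start >= read_length) {
        k <- (run_end - run_start) %/% read_length
        starts <- c(starts, run_start + (seq_len(k) - 1L) * read_length)
      }
    }
  }
  sort(starts)
}

#' Simulate aligned reads from a donor genome
#'
#' Emits `read_length`-bp reads whose bases copy the donor sequence with
#' independent per-base errors at `base_error_rate`, whose qualities follow a
#' clipped-normal Phred model, and whose coordinates are aligned to the
#' reference. Per-position depth lies within
#' `[coverage_min, coverage_max]` at every position covered by whole reads.
#'
#' @param donor donor `reference_genome` (bases that reads copy).
#' @param ref reference `reference_genome` (coordinate system; must share
#'   contig names and lengths with `donor`).
#' @param config a [sim_config()].
#' @param subject_id subject identifier stored in each read.
#' @param seed optional seed override (defaults to `config$seed`).
#' @return An `aligned_reads` data frame, coordinate-sorted.
#' @export
simulate_reads <- function(donor, ref, config, subject_id = "S1", seed = config$seed) {
  stopifnot(inherits(donor, "reference_genome"), inherits(ref, "reference_genome"))
  if (!identical(names(donor$contigs), names(ref$contigs)) ||
      !identical(nchar(donor$contigs), nchar(ref$contigs)))
    fail("donor and ref must share contig names and lengths")
  rl <- config$read_length
  out <- list()
  with_seed(derive_seed(seed, 404L), {
    for (nm in names(donor$contigs)) {
      clen <- nchar(donor$contigs[[nm]])
      if (clen < rl) fail("contig '%s' (%d bp) is shorter than read_length %d", nm, clen, rl)
      targets <- tile_depth_targets(clen, config)
      starts <- read_starts_for_contig(clen, targets, rl)
      n <- length(starts)
      if (!n) next
      dseq <- seq_to_int(donor$contigs[[nm]])
      base_mat <- matrix(dseq[rep(starts, each = rl) + seq_len(rl)], nrow = rl)
      # sequencing errors: substitute a uniformly chosen different base
      err <- which(matrix(stats::runif(rl * n) < config$base_error_rate, nrow = rl))
      if (length(err)) {
        old <- base_mat[err]
        base_mat[err] <- ((old - 1L + sample.int(3L, length(err), replace = TRUE)) %% 4L) + 1L
      }
      q <- round(stats::rnorm(rl * n, config$quality_mean, config$quality_sd))
      q <- pmin(pmax(q, config$quality_clip[1]), config$quality_clip[2])
      qmat <- matrix(as.integer(q), nrow = rl)
      bases <- apply(base_mat, 2, int_to_seq)
      quals <- apply(qmat, 2, phred_to_chr)
      out[[nm]] <- data.frame(
        read_id = sprintf("%s:%s:%09d:%06d", subject_id, nm, starts, seq_len(n)),
        contig = nm, start = starts, bases = bases, qual = quals,
        mapq = 60L, subject_id = subject_id, stringsAsFactors = FALSE)
    }
  })
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), contig = character(), start = integer(),
               bases = character(), qual = character(), mapq = integer(),
               subject_id = character())
  df <- df[order(df$contig, df$start, df$read_id), ]
  new_reads(df)
}

#' Simulate a multi-subject cohort
#'
#' Each subject receives an independent donor genome ([apply_variants()]) and
#' read set ([simulate_reads()]) under sub-seeds derived by hashing the
#' master seed with the subject index, so per-subject draws are independent
#' yet reproducible.
#'
#' @param ref a `reference_genome`.
#' @param config a [sim_config()]; `n_subjects` sets cohort size.
#' @return A list (class `read_cohort`) with one entry per subject:
#'   `subject_id`, `reads`, `variants`, `donor`.
#' @export
simulate_cohort <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  res <- lapply(seq_len(config$n_subjects), function(i) {
    sid <- sprintf("S%03d", i)
    sub_seed <- derive_seed(config$seed, 505L, i)
    av <- apply_variants(ref, config$variant_rate, sub_seed)
    reads <- simulate_reads(av$donor, ref, config, subject_id = sid,
                            seed = derive_seed(sub_seed, 1L))
    list(subject_id = sid, reads = reads, variants = av$variants, donor = av$donor)
  })
  names(res) <- vapply(res, `[[`, character(1), "subject_id")
  structure(res, class = "read_cohort")
}

#' Pool the reads of a cohort into one coordinate-sorted read set
#' @param cohort a `read_cohort`.
#' @return An `aligned_reads` data frame.
#' @export
cohort_reads <- function(cohort) {
  df <- do.call(rbind, lapply(cohort, function(s) as.data.frame(s$reads)))
  df <- df[order(df$contig, df$start, df$read_id), ]
  new_reads(df)
}
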
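#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
BASES_N <- c("A", "C", "G", "T", "N")

fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    fail("'%s' must be a single non-missing number", name)
  if (integer && x != round(x))
    fail("'%s' must be an integer (got %s)", name, format(x))
  if (x < lower || x > upper)
    fail("'%s' must be in [%s, %s] (got %s)", name, format(lower), format(upper), format(x))
  invisible(x)
}

# Derive a bounded sub-seed from a master seed and stream labels. Plain
# integer hashing (no RNG draw) so derivation itself is state-free.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Phred conversions (SAM Phred+33 encoding).
phred_to_chr <- function(q) intToUtf8(as.integer(q) + 33L, multiple = FALSE)
chr_to_phred <- function(s) utf8ToInt(s) - 33L

seq_to_int <- function(s) {
  # A=1 C=2 G=3 T=4 N=5; input assumed validated upstream
  m <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES_N)
  if (anyNA(m)) fail("sequence contains a character outside {A,C,G,T,N}")
  m
}

int_to_seq <- function(v) paste(BASES_N[v], collapse = "")
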
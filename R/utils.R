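#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
CALLS <- c("AA", "BB", "AB", "NN")

#' Reverse-complement a nucleotide string
#'
#' @param seq character vector of 5'->3' nucleotide strings (ACGT).
#' @return character vector of reverse complements, 5'->3'.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "",
                       fixed = TRUE)[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Validate a single-base argument.
check_base <- function(x, what = "base") {
  if (!(is.character(x) && length(x) == 1L && x %in% BASES)) {
    stop(sprintf("%s must be one of A, C, G, T (got '%s')", what,
                 paste(x, collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

check_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop(sprintf("%s must be a non-empty string", what), call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop(sprintf("%s contains a base outside A/C/G/T", what), call. = FALSE)
  }
  invisible(seq)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# 96-well coordinates in row-major order: A1..A12, B1..B12, ..., H12.
well_ids <- function(n = 96L) {
  stopifnot(n >= 1L, n <= 96L)
  all <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
  all[seq_len(n)]
}

is_valid_well <- function(w) grepl("^[A-H](1[0-2]|[1-9])$", w)
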
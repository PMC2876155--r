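# Artificial-mismatch specificity matrix and the third-base-from-3'-end
# replacement rule.
#
# The matrix records, for each (matching base -> replacement base)
# substitution introduced at the third nucleotide from a primer's 3' end,
# the fraction of tested primers that showed single-band allele-specific
# amplification.  It drives both which substitutions are permitted and
# which replacement is chosen for a given template base.

#' Load an artificial-mismatch specificity matrix
#'
#' Reads a mismatch specificity table: one row per (original, replacement)
#' base pair with empirical success counts.  The bundled default matrix
#' encodes the published screen of 10 allele-specific primers per
#' substitution; users may substitute their own empirical matrix with the
#' same columns.
#'
#' @param path TSV file with columns `original`, `replacement`,
#'   `successes`, `trials`.  Default: the matrix bundled with the package.
#' @return An object of class `mismatch_matrix`: a list with `fraction`
#'   (4x4 numeric matrix, rows = original base, columns = replacement base,
#'   entries in \[0,1\]), `successes` and `trials` (integer matrices of the
#'   same shape).
#' @export
mismatch_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mismatch_matrix.tsv", package = "asppcr",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("original", "replacement", "successes", "trials")
  if (!all(need %in% names(tab))) {
    stop("mismatch matrix file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  frac <- succ <- tri <- matrix(NA_real_, 4L, 4L, dimnames = list(BASES, BASES))
  for (i in seq_len(nrow(tab))) {
    o <- tab$original[i]; r <- tab$replacement[i]
    check_base(o, "original"); check_base(r, "replacement")
    succ[o, r] <- tab$successes[i]
    tri[o, r] <- tab$trials[i]
    frac[o, r] <- tab$successes[i] / tab$trials[i]
  }
  if (anyNA(frac)) stop("mismatch matrix is missing cells", call. = FALSE)
  if (any(diag(frac) != 0)) {
    stop("diagonal (no-mismatch) cells must be 0: primers without a ",
         "mismatch have no allele specificity", call. = FALSE)
  }
  structure(list(fraction = frac, successes = succ, trials = tri),
            class = "mismatch_matrix")
}

#' @export
print.mismatch_matrix <- function(x, ...) {
  cat("Artificial-mismatch specificity matrix (% single-band specific)\n")
  print(round(100 * x$fraction))
  invisible(x)
}

#' Specificity of an artificial base substitution
#'
#' @param original the matching (template-complementary) primer base being
#'   replaced, one of A/C/G/T.
#' @param replacement the base written in its place.
#' @param matrix a [mismatch_matrix()] object.
#' @return specificity as a percentage in \[0, 100\].
#' @export
specificity <- function(original, replacement, matrix = mismatch_matrix()) {
  check_base(original, "original"); check_base(replacement, "replacement")
  100 * matrix$fraction[original, replacement]
}

#' Base pairs permitted as artificial mismatches
#'
#' The permitted substitutions are the unordered pairs whose both directed
#' matrix cells reach 50% specificity: the A-G transition and the A-T,
#' A-C and G-T transversions.
#'
#' @param matrix a [mismatch_matrix()] object.
#' @param threshold minimum specificity fraction both directions must
#'   reach (default 0.5).
#' @return data.frame with columns `base1`, `base2` (base1 < base2
#'   alphabetically), one row per allowed unordered pair.
#' @export
allowed_pairs <- function(matrix = mismatch_matrix(), threshold = 0.5) {
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    b1 <- BASES[i]; b2 <- BASES[j]
    if (matrix$fraction[b1, b2] >= threshold &&
        matrix$fraction[b2, b1] >= threshold) {
      out[[length(out) + 1L]] <- data.frame(base1 = min(b1, b2),
                                            base2 = max(b1, b2),
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Choose the artificial-mismatch replacement for a primer base
#'
#' Given the primer base at the third position from the 3' end, selects
#' the replacement base among its allowed partners with maximal
#' specificity.  Ties are broken by the requested Tm bias (`raise`
#' prefers a G/C replacement, `lower` an A/T replacement), then
#' alphabetically; the choice is a pure function of its inputs.
#'
#' @param original primer base at the third position from the 3' end.
#' @param tm_bias one of `"neutral"`, `"raise"`, `"lower"`.
#' @param matrix a [mismatch_matrix()] object.
#' @return list of class `mismatch_choice`: `position_from_3prime` (always
#'   3), `original`, `replacement`, `score` (specificity fraction).
#' @export
choose_replacement <- function(original,
                               tm_bias = c("neutral", "raise", "lower"),
                               matrix = mismatch_matrix()) {
  check_base(original, "original")
  tm_bias <- match.arg(tm_bias)
  ap <- allowed_pairs(matrix)
  partners <- c(ap$base2[ap$base1 == original], ap$base1[ap$base2 == original])
  partners <- sort(partners)
  stopifnot(length(partners) >= 1L)
  score <- matrix$fraction[original, partners]
  cand <- partners[score == max(score)]
  if (length(cand) > 1L && tm_bias != "neutral") {
    pref <- if (tm_bias == "raise") c("C", "G") else c("A", "T")
    hit <- cand[cand %in% pref]
    if (length(hit) > 0L) cand <- hit
  }
  repl <- sort(cand)[1L]  # residual ties alphabetical
  structure(list(position_from_3prime = 3L, original = original,
                 replacement = repl,
                 score = matrix$fraction[original, repl]),
            class = "mismatch_choice")
}

#' Apply an artificial mismatch to a primer sequence
#'
#' Substitutes the chosen replacement base at the third position from the
#' primer's 3' end; the output differs from the input at exactly that one
#' position.
#'
#' @param primer 5'->3' nucleotide string, length >= 3.
#' @param choice a `mismatch_choice` from [choose_replacement()].
#' @return the modified primer sequence.
#' @export
apply_mismatch <- function(primer, choice) {
  check_seq(primer, "primer")
  stopifnot(inherits(choice, "mismatch_choice"))
  n <- nchar(primer)
  if (n < 3L) stop("primer must be at least 3 bases long", call. = FALSE)
  pos <- n - 2L
  have <- substr(primer, pos, pos)
  if (have != choice$original) {
    stop(sprintf(paste0("inconsistent mismatch choice: primer base at the ",
                        "third position from the 3' end is %s, choice ",
                        "expects %s"), have, choice$original), call. = FALSE)
  }
  substr(primer, pos, pos) <- choice$replacement
  primer
}
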
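# Assembly of complete ASP assays: two allele-specific forward primers
# (3' terminus on the SNP, artificial mismatch at the third base from the
# 3' end) plus one shared, non-allele-specific reverse primer, all tuned
# to a common annealing protocol.

#' Design parameter set for ASP assays
#'
#' @param len_min,len_max primer length bounds, bases.
#' @param product_min,product_max PCR product size bounds, bp.
#' @param annealing annealing temperature recorded on each assay, degC
#'   (the standardized protocol anneals at 58 degC).
#' @param tm_bias tie-break preference passed to [choose_replacement()]
#'   when two replacement bases are equally specific.
#' @param max_self_comp longest tolerated self-reverse-complementary run
#'   within a primer (a simple dimer/hairpin screen).
#' @param strand `"+"` designs the allele-specific primers on the forward
#'   strand; `"-"` on the reverse strand (3' terminus then carries the
#'   allele complement).
#' @return list of class `design_params`.
#' @export
design_params <- function(len_min = 18L, len_max = 30L,
                          product_min = 100L, product_max = 500L,
                          annealing = 58,
                          tm_bias = c("neutral", "raise", "lower"),
                          max_self_comp = 6L,
                          strand = c("+", "-")) {
  stopifnot(len_min >= 8L, len_max >= len_min,
            product_min >= 1L, product_max >= product_min)
  structure(list(len_min = as.integer(len_min), len_max = as.integer(len_max),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 annealing = annealing, tm_bias = match.arg(tm_bias),
                 max_self_comp = as.integer(max_self_comp),
                 strand = match.arg(strand)),
            class = "design_params")
}

as_locus <- function(locus) {
  if (is.data.frame(locus)) {
    stopifnot(nrow(locus) == 1L)
    locus <- as.list(locus)
  }
  stopifnot(all(c("name", "chrom", "pos", "allele_a", "allele_b") %in%
                  names(locus)))
  locus$pos <- as.integer(locus$pos)
  locus
}

#' Extract the SNP-flanking template from a reference
#'
#' Slices `+/- window` bases around the SNP, checks the reference base
#' against the two declared alleles, and materializes both allele
#' variants of the slice.
#'
#' @param genome named character vector (id -> sequence).
#' @param locus one marker: a single-row `snp_table` or a list with
#'   `name, chrom, pos, allele_a, allele_b`.
#' @param window flank width, bp.
#' @return list of class `asp_template`: `chrom`, `start` (reference
#'   coordinate of slice base 1), `seq` (reference slice), `offset`
#'   (1-based SNP index within the slice), `ref_base`, `seq_a`/`seq_b`
#'   (the slice carrying allele A / allele B), `truncated` flag, `locus`.
#' @export
extract_template <- function(genome, locus, window = 600L) {
  locus <- as_locus(locus)
  if (!locus$chrom %in% names(genome)) {
    stop("chromosome not in reference: ", locus$chrom, call. = FALSE)
  }
  chrom_seq <- genome[[locus$chrom]]
  n <- nchar(chrom_seq)
  if (locus$pos < 1L || locus$pos > n) {
    stop("SNP position outside sequence bounds: ", locus$pos, call. = FALSE)
  }
  start <- max(1L, locus$pos - window)
  end <- min(n, locus$pos + window)
  truncated <- (locus$pos - window < 1L) || (locus$pos + window > n)
  if (truncated) {
    warning("template truncated: SNP ", locus$name, " is closer than ",
            window, " bp to a contig end", call. = FALSE)
  }
  seq <- substr(chrom_seq, start, end)
  offset <- locus$pos - start + 1L
  ref_base <- substr(seq, offset, offset)
  if (!ref_base %in% c(locus$allele_a, locus$allele_b)) {
    stop(sprintf("reference mismatch at %s:%d: reference base %s matches neither allele %s/%s",
                 locus$chrom, locus$pos, ref_base, locus$allele_a,
                 locus$allele_b), call. = FALSE)
  }
  seq_a <- seq; substr(seq_a, offset, offset) <- locus$allele_a
  seq_b <- seq; substr(seq_b, offset, offset) <- locus$allele_b
  structure(list(chrom = locus$chrom, start = start, seq = seq,
                 offset = offset, ref_base = ref_base,
                 seq_a = seq_a, seq_b = seq_b, truncated = truncated,
                 locus = locus),
            class = "asp_template")
}

# Orient a template for minus-strand design: reverse-complement the slice
# and swap the alleles to their complements.  Coordinates stay anchored
# via `start` + `plus_length`; `rc` records the flip.
orient_template <- function(tmpl, strand) {
  if (strand == "+") { tmpl$rc <- FALSE; return(tmpl) }
  W <- nchar(tmpl$seq)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  out <- tmpl
  out$seq <- revcomp(tmpl$seq)
  out$seq_a <- revcomp(tmpl$seq_a)
  out$seq_b <- revcomp(tmpl$seq_b)
  out$offset <- W - tmpl$offset + 1L
  out$ref_base <- comp(tmpl$ref_base)
  out$locus$allele_a <- comp(tmpl$locus$allele_a)
  out$locus$allele_b <- comp(tmpl$locus$allele_b)
  out$rc <- TRUE
  out$plus_length <- W
  out
}

# Map a template-space interval [i, j] back to reference coordinates.
template_to_ref <- function(tmpl, i, j) {
  if (isTRUE(tmpl$rc)) {
    c(tmpl$start + tmpl$plus_length - j, tmpl$start + tmpl$plus_length - i)
  } else {
    c(tmpl$start + i - 1L, tmpl$start + j - 1L)
  }
}

new_primer <- function(seq, strand, start, end, tm, mismatch = NULL,
                       allele = "none", in_window = TRUE) {
  structure(list(seq = seq, strand = strand, start = start, end = end,
                 tm = tm, gc = gc_content(seq), mismatch = mismatch,
                 allele = allele, in_window = in_window),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("primer [%s%s] 5'-%s-3'  %dnt  Tm %.1f  GC %.2f\n",
              x$allele, x$strand, x$seq, nchar(x$seq), x$tm, x$gc))
  invisible(x)
}

# Build the allele-specific forward primer of length L (template space):
# slice ending on the SNP, 3' terminus forced to the allele base,
# artificial mismatch applied at the third base from the 3' end.
forward_candidate <- function(tmpl, allele_base, L, choice) {
  s <- substr(tmpl$seq, tmpl$offset - L + 1L, tmpl$offset)
  substr(s, L, L) <- allele_base
  apply_mismatch(s, choice)
}

#' Design one allele-specific forward primer
#'
#' The primer's 3'-terminal base sits on the SNP and equals the chosen
#' allele; an artificial mismatch replaces the template base at the third
#' position from the 3' end (replacement chosen from the specificity
#' matrix); the length is tuned so the Tm (mismatch position treated as
#' non-contributing) falls in the target window.
#'
#' @param template an [extract_template()] result (already oriented).
#' @param locus the marker (used for allele lookup).
#' @param allele `"A"` or `"B"`.
#' @param thermo a [thermo_params()] object.
#' @param design a [design_params()] object.
#' @param mm a [mismatch_matrix()] object.
#' @return a `primer` object (allele set, mismatch recorded).
#' @export
design_allele_forward <- function(template, locus, allele = c("A", "B"),
                                  thermo = thermo_params(),
                                  design = design_params(),
                                  mm = mismatch_matrix()) {
  allele <- match.arg(allele)
  locus <- as_locus(locus)
  allele_base <- if (allele == "A") template$locus$allele_a else
    template$locus$allele_b
  choice <- forward_mismatch_choice(template, design, mm)
  scan <- scan_forward_lengths(template, allele_base, choice, thermo, design)
  primer_from_scan(template, scan, allele, choice)
}

forward_mismatch_choice <- function(template, design, mm) {
  if (template$offset < design$len_min) {
    stop("design infeasible: SNP too close to template 5' end",
         call. = FALSE)
  }
  orig <- substr(template$seq, template$offset - 2L, template$offset - 2L)
  choose_replacement(orig, design$tm_bias, mm)
}

# Scan candidate lengths; returns the smallest length whose Tm (for every
# allele variant supplied) is inside the window, else the best
# out-of-window length.
scan_forward_lengths <- function(template, allele_bases, choice, thermo,
                                 design) {
  len_hi <- min(design$len_max, template$offset)
  best <- NULL
  for (L in design$len_min:len_hi) {
    seqs <- vapply(allele_bases, forward_candidate, "", tmpl = template,
                   L = L, choice = choice)
    tms <- vapply(seqs, melting_temperature, 0, params = thermo,
                  mismatch_pos = L - 2L)
    dev <- max(abs(tms - thermo$target_tm))
    if (dev <= thermo$tm_window) {
      return(list(L = L, seqs = seqs, tms = tms, in_window = TRUE))
    }
    if (is.null(best) || dev < best$dev) {
      best <- list(L = L, seqs = seqs, tms = tms, dev = dev)
    }
  }
  c(best[c("L", "seqs", "tms")], list(in_window = FALSE))
}

primer_from_scan <- function(template, scan, allele, choice, which = 1L) {
  L <- scan$L
  ref <- template_to_ref(template, template$offset - L + 1L, template$offset)
  strand <- if (isTRUE(template$rc)) "-" else "+"
  # `start` is the reference coordinate of the 5' end on the primer's strand
  start5 <- if (strand == "+") ref[1L] else ref[2L]
  new_primer(scan$seqs[[which]], strand, start5, ref[2L - (strand == "-")],
             scan$tms[[which]], mismatch = choice, allele = allele,
             in_window = scan$in_window)
}

# Longest substring whose reverse complement also occurs in the primer.
max_self_comp_run <- function(seq) {
  n <- nchar(seq)
  for (k in n:1) {
    subs <- unique(substring(seq, 1:(n - k + 1L), k:n))
    if (any(vapply(revcomp(subs), grepl, NA, x = seq, fixed = TRUE))) {
      return(k)
    }
  }
  0L
}

#' Design the shared (non-allele-specific) reverse primer
#'
#' The reverse primer anneals to the opposite strand with its 3' end
#' oriented toward the SNP, placed so the product size falls inside the
#' configured bounds and the Tm inside the target window; its footprint
#' excludes the SNP so one reverse primer serves both allele reactions.
#' Candidate placements are scanned from the smallest admissible product
#' size outward; the nearest acceptable placement wins.
#'
#' @param template an oriented [extract_template()] result.
#' @param forward the designed forward `primer` (fixes the product 5' end).
#' @param thermo a [thermo_params()] object.
#' @param design a [design_params()] object.
#' @return list: `primer` (a `primer` object, allele `"none"`) and
#'   `product_size` (bp).
#' @export
design_common_reverse <- function(template, forward,
                                  thermo = thermo_params(),
                                  design = design_params()) {
  W <- nchar(template$seq)
  f5 <- template$offset - nchar(forward$seq) + 1L  # template-space 5' index
  for (P in design$product_min:design$product_max) {
    r5 <- f5 + P - 1L                    # template-space reverse 5' index
    if (r5 > W) break
    for (L in design$len_min:design$len_max) {
      lo <- r5 - L + 1L
      if (lo <= template$offset) next    # footprint must exclude the SNP
      s <- revcomp(substr(template$seq, lo, r5))
      tm <- melting_temperature(s, thermo)
      if (abs(tm - thermo$target_tm) > thermo$tm_window) next
      if (max_self_comp_run(s) > design$max_self_comp) next
      ref <- template_to_ref(template, lo, r5)
      strand <- if (isTRUE(template$rc)) "+" else "-"
      start5 <- if (strand == "-") ref[2L] else ref[1L]
      return(list(primer = new_primer(s, strand, start5, ref[1L], tm),
                  product_size = P))
    }
  }
  stop("design infeasible: no reverse-primer placement satisfies both the ",
       "product-size bounds [", design$product_min, ", ",
       design$product_max, "] and the Tm window ", thermo$target_tm,
       " +/- ", thermo$tm_window, call. = FALSE)
}

#' Design a complete ASP assay for one SNP
#'
#' Builds the two allele-specific forward primers (identical except at
#' the 3'-terminal SNP base, sharing one artificial mismatch and one
#' length so both Tm values sit in the window) and the shared reverse
#' primer.
#'
#' @param genome named character vector (id -> sequence).
#' @param locus one marker (single-row `snp_table` or list).
#' @param thermo a [thermo_params()] object.
#' @param design a [design_params()] object.
#' @param mm a [mismatch_matrix()] object.
#' @param strand_fallback if `TRUE` and forward-strand design is
#'   infeasible, design is retried on the reverse strand.
#' @return object of class `asp_assay`: `locus`, `fwd_a`, `fwd_b`,
#'   `reverse`, `product_size`, `annealing_temp`, `in_window`.
#' @export
design_assay <- function(genome, locus, thermo = thermo_params(),
                         design = design_params(), mm = mismatch_matrix(),
                         strand_fallback = FALSE) {
  locus <- as_locus(locus)
  window <- design$len_max + design$product_max
  tmpl0 <- extract_template(genome, locus, window)
  try_strand <- function(strand) {
    tmpl <- orient_template(tmpl0, strand)
    choice <- forward_mismatch_choice(tmpl, design, mm)
    ab <- c(tmpl$locus$allele_a, tmpl$locus$allele_b)
    scan <- scan_forward_lengths(tmpl, ab, choice, thermo, design)
    fwd_a <- primer_from_scan(tmpl, scan, "A", choice, which = 1L)
    fwd_b <- primer_from_scan(tmpl, scan, "B", choice, which = 2L)
    rev <- design_common_reverse(tmpl, fwd_a, thermo, design)
    structure(list(locus = locus, fwd_a = fwd_a, fwd_b = fwd_b,
                   reverse = rev$primer, product_size = rev$product_size,
                   annealing_temp = design$annealing,
                   in_window = scan$in_window),
              class = "asp_assay")
  }
  res <- tryCatch(try_strand(design$strand), error = function(e) e)
  if (inherits(res, "error") && strand_fallback) {
    other <- if (design$strand == "+") "-" else "+"
    res2 <- tryCatch(try_strand(other), error = function(e) e)
    if (!inherits(res2, "error")) return(res2)
  }
  if (inherits(res, "error")) {
    stop("assay design failed for marker ", locus$name, ": ",
         conditionMessage(res), call. = FALSE)
  }
  res
}

#' @export
print.asp_assay <- function(x, ...) {
  cat(sprintf("ASP assay for %s (%s:%d %s/%s)\n", x$locus$name,
              x$locus$chrom, x$locus$pos, x$locus$allele_a, x$locus$allele_b))
  cat("  fwd A:  "); print(x$fwd_a)
  cat("  fwd B:  "); print(x$fwd_b)
  cat("  shared: "); print(x$reverse)
  cat(sprintf("  product %d bp, annealing %.0f degC, mismatch %s->%s\n",
              x$product_size, x$annealing_temp, x$fwd_a$mismatch$original,
              x$fwd_a$mismatch$replacement))
  invisible(x)
}

# Mismatch count between a primer and the template region under its
# footprint (both given 5'->3' in the same orientation).
footprint_mismatches <- function(primer_seq, region_seq) {
  a <- seq_chars(primer_seq); b <- seq_chars(region_seq)
  stopifnot(length(a) == length(b))
  which(a != b)
}

#' Check the allele-discrimination pattern of an assay
#'
#' Each allele-specific primer should differ from its own allele template
#' at exactly one position (the artificial mismatch) and from the other
#' allele template at exactly two (3' terminus + artificial mismatch);
#' the shared reverse primer should match both templates perfectly.
#'
#' @param assay an `asp_assay`.
#' @param genome the reference it was designed against.
#' @return data.frame: `primer`, `vs_allele`, `n_mismatch`, `expected`,
#'   `ok`, plus `positions` (from the 3' end, comma-separated); attribute
#'   `ok` is TRUE when every row matches its expectation.
#' @export
check_allele_discrimination <- function(assay, genome) {
  window <- nchar(assay$fwd_a$seq) + assay$product_size + 50L
  tmpl <- extract_template(genome, assay$locus, window)
  tmpl <- orient_template(tmpl, assay$fwd_a$strand)
  off <- tmpl$offset
  rows <- list()
  add <- function(primer_name, primer_seq, region_a, region_b, expected) {
    for (al in c("A", "B")) {
      region <- if (al == "A") region_a else region_b
      mm <- footprint_mismatches(primer_seq, region)
      exp_n <- expected[[al]]
      rows[[length(rows) + 1L]] <<- data.frame(
        primer = primer_name, vs_allele = al, n_mismatch = length(mm),
        expected = exp_n, ok = length(mm) == exp_n,
        positions = paste(nchar(primer_seq) - mm + 1L, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  for (p in c("fwd_a", "fwd_b")) {
    primer <- assay[[p]]
    L <- nchar(primer$seq)
    reg_a <- substr(tmpl$seq_a, off - L + 1L, off)
    reg_b <- substr(tmpl$seq_b, off - L + 1L, off)
    expected <- if (p == "fwd_a") list(A = 1L, B = 2L) else
      list(A = 2L, B = 1L)
    add(p, primer$seq, reg_a, reg_b, expected)
  }
  # reverse primer footprint (template space), identical in both alleles
  Lr <- nchar(assay$reverse$seq)
  f5 <- off - nchar(assay$fwd_a$seq) + 1L
  r5 <- f5 + assay$product_size - 1L
  reg <- substr(tmpl$seq, r5 - Lr + 1L, r5)
  add("reverse", assay$reverse$seq, revcomp(reg), revcomp(reg),
      list(A = 0L, B = 0L))
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$ok)
  out
}

# All start positions where `pattern_regex` matches `seq` (overlapping).
regex_sites <- function(seq, pattern_regex) {
  m <- gregexpr(paste0("(?=", pattern_regex, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# 3'-terminal 12-mer of a primer as a regex, with the artificial-mismatch
# position (if any) as a wildcard.
anchor_regex <- function(primer, rc = FALSE) {
  L <- nchar(primer$seq)
  k <- min(12L, L)
  a <- substr(primer$seq, L - k + 1L, L)
  chars <- seq_chars(a)
  if (!is.null(primer$mismatch)) {
    wp <- k - 2L  # third base from the 3' end within the anchor
    if (wp >= 1L) chars[wp] <- "."
  }
  if (rc) {
    comp <- chartr("ACGT.", "TGCA.", chars)
    chars <- rev(comp)
  }
  paste(chars, collapse = "")
}

#' Predict PCR products of an assay across a genome
#'
#' A product is predicted wherever a forward primer's 3'-terminal 12-mer
#' (artificial-mismatch position treated as a wildcard) occurs on one
#' strand and the reverse primer's 3'-terminal 12-mer occurs on the
#' other, in amplifiable orientation, within `max_product`.  Supports the
#' single-band-specificity requirement: a well-behaved assay yields one
#' product, at its own locus.
#'
#' @param genome named character vector.
#' @param assay an `asp_assay`.
#' @param max_product largest product size considered, bp.
#' @return data.frame ordered by coordinate: `chrom`, `start`, `end`,
#'   `size`, `fwd_primer` (`"fwd_a"`/`"fwd_b"`), `orientation`.
#' @export
in_silico_amplification <- function(genome, assay, max_product = 2000L) {
  out <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    for (p in c("fwd_a", "fwd_b")) {
      fwd <- assay[[p]]
      k_f <- min(12L, nchar(fwd$seq))
      k_r <- min(12L, nchar(assay$reverse$seq))
      ext_f <- nchar(fwd$seq) - k_f           # fwd 5' overhang beyond anchor
      ext_r <- nchar(assay$reverse$seq) - k_r
      # orientation 1: fwd on + strand, reverse anneals downstream
      fs <- regex_sites(seq, anchor_regex(fwd))
      rs <- regex_sites(seq, anchor_regex(assay$reverse, rc = TRUE))
      for (i in fs) for (j in rs) {
        if (j > i + k_f - 1L && (j + k_r - 1L) - i + 1L <= max_product) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = i - ext_f, end = j + k_r - 1L + ext_r,
            size = j + k_r - i + ext_f + ext_r, fwd_primer = p,
            orientation = "+", stringsAsFactors = FALSE)
        }
      }
      # orientation 2: fwd on - strand, reverse on + strand upstream
      fs2 <- regex_sites(seq, anchor_regex(fwd, rc = TRUE))
      rs2 <- regex_sites(seq, anchor_regex(assay$reverse))
      for (j in rs2) for (i in fs2) {
        if (i > j + k_r - 1L && (i + k_f - 1L) - j + 1L <= max_product) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = j - ext_r, end = i + k_f - 1L + ext_f,
            size = i + k_f - j + ext_f + ext_r, fwd_primer = p,
            orientation = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      fwd_primer = character(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$chrom, res$start, res$end, res$fwd_primer), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
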
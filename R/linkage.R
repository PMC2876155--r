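# Multi-sample application: recombination events in an F2 population,
# interval narrowing from recombinant genotypes plus homozygous-progeny
# phenotypes, marker-spacing summaries and graphical genotypes.

#' Crossovers implied by a pair of adjacent F2 genotype calls
#'
#' Convention: identical calls imply no detectable crossover (an AB/AB
#' pair can hide a double crossover in repulsion, which is undetectable
#' without phase and counted 0); homozygote vs heterozygote implies one;
#' opposite homozygotes imply two.
#'
#' @param g1,g2 calls at two markers adjacent in map order, in
#'   `{AA, BB, AB}`.
#' @return integer 0, 1 or 2; `NA` (with both excluded from counts) if
#'   either call is `NN`.
#' @export
crossover_count <- function(g1, g2) {
  if (g1 == "NN" || g2 == "NN") return(NA_integer_)
  stopifnot(g1 %in% CALLS, g2 %in% CALLS)
  if (g1 == g2) return(0L)
  if (g1 != "AB" && g2 != "AB") return(2L)  # AA vs BB
  1L
}

#' Find recombinant individuals between two markers
#'
#' @param matrix character genotype matrix (samples x markers).
#' @param marker_i,marker_j distinct marker column names.
#' @return data.frame of class `recombination_events`: `sample`,
#'   `left_marker`, `right_marker`, `crossovers` (1 or 2), one row per
#'   recombinant; attribute `excluded` lists samples with `NN` at either
#'   marker.
#' @export
find_recombinants <- function(matrix, marker_i, marker_j) {
  if (identical(marker_i, marker_j)) {
    stop("marker_i and marker_j must differ", call. = FALSE)
  }
  stopifnot(marker_i %in% colnames(matrix), marker_j %in% colnames(matrix))
  xo <- vapply(rownames(matrix), function(s) {
    crossover_count(matrix[s, marker_i], matrix[s, marker_j])
  }, integer(1))
  excluded <- names(xo)[is.na(xo)]
  rec <- names(xo)[!is.na(xo) & xo >= 1L]
  out <- data.frame(sample = rec,
                    left_marker = rep(marker_i, length(rec)),
                    right_marker = rep(marker_j, length(rec)),
                    crossovers = unname(xo[rec]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("recombination_events", "data.frame"),
            excluded = excluded)
}

#' Narrow a locus interval from recombinants and progeny phenotypes
#'
#' For each phenotyped recombinant (phenotype `"A"` or `"B"`, established
#' on homozygous progeny), the causal locus is constrained to the markers
#' where that individual's genotype is the phenotype-matching homozygote.
#' The admissible region is the intersection of these constraints across
#' individuals; the returned bounds are the markers immediately flanking
#' the admissible run (or the map ends).
#'
#' @param calls genotype matrix restricted to the recombinant samples;
#'   columns must be the markers in `marker_order`.
#' @param phenotype named character vector: sample -> `"A"` or `"B"`.
#' @param marker_order markers ordered along the map.
#' @param positions_cm optional named numeric vector of cM positions.
#' @return list of class `interval_result`: `left_bound`, `right_bound`,
#'   `admissible` (marker names), `width_cm` (NA without positions),
#'   `supporting` (per adjacent interval, informative-recombinant count).
#' @export
narrow_interval <- function(calls, phenotype, marker_order,
                            positions_cm = NULL) {
  stopifnot(all(marker_order %in% colnames(calls)),
            all(names(phenotype) %in% rownames(calls)),
            all(phenotype %in% c("A", "B")))
  calls <- calls[, marker_order, drop = FALSE]
  admissible <- rep(TRUE, length(marker_order))
  names(admissible) <- marker_order
  per_sample <- list()
  for (s in names(phenotype)) {
    want <- if (phenotype[[s]] == "A") "AA" else "BB"
    ok <- calls[s, ] == want
    per_sample[[s]] <- ok
    admissible <- admissible & ok
  }
  if (!any(admissible)) {
    # identify samples whose constraints conflict with the rest
    counts <- Reduce(`+`, lapply(per_sample, as.integer))
    worst <- names(per_sample)[vapply(per_sample, function(ok) {
      !any(ok & counts == max(counts))
    }, NA)]
    stop("inconsistent phenotypes/genotypes: admissible region is empty ",
         "(conflicting sample(s): ", paste(worst, collapse = ", "), ")",
         call. = FALSE)
  }
  idx <- which(admissible)
  lo <- min(idx); hi <- max(idx)
  left_bound <- marker_order[max(1L, lo - 1L)]
  right_bound <- marker_order[min(length(marker_order), hi + 1L)]
  width_cm <- if (!is.null(positions_cm)) {
    unname(positions_cm[right_bound] - positions_cm[left_bound])
  } else NA_real_
  # informative recombinants per adjacent marker interval
  supporting <- integer(length(marker_order) - 1L)
  names(supporting) <- paste(marker_order[-length(marker_order)],
                             marker_order[-1L], sep = "..")
  for (s in rownames(calls)) {
    for (k in seq_len(length(marker_order) - 1L)) {
      xo <- crossover_count(calls[s, k], calls[s, k + 1L])
      if (!is.na(xo) && xo >= 1L) supporting[k] <- supporting[k] + 1L
    }
  }
  structure(list(left_bound = left_bound, right_bound = right_bound,
                 admissible = marker_order[idx], width_cm = width_cm,
                 supporting = supporting),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("locus interval: %s .. %s", x$left_bound, x$right_bound))
  if (!is.na(x$width_cm)) cat(sprintf(" (%.1f cM)", x$width_cm))
  cat("\nadmissible markers:", paste(x$admissible, collapse = ", "), "\n")
  invisible(x)
}

#' Marker spacing summary
#'
#' @param snps a `snp_table` with physical positions in the `mbp` column.
#' @return list: `per_chrom` (data.frame `chrom, n_markers, mean_gap_mbp`;
#'   single-marker chromosomes get NA and are noted), `genome_mean_mbp`
#'   (total spanned length / number of adjacent intervals).
#' @export
map_spacing <- function(snps) {
  stopifnot("mbp" %in% names(snps), !anyNA(snps$mbp))
  snps <- snps[order(snps$chrom, snps$mbp), ]
  by_chrom <- split(snps$mbp, snps$chrom)
  per <- do.call(rbind, lapply(names(by_chrom), function(ch) {
    pos <- by_chrom[[ch]]
    data.frame(chrom = ch, n_markers = length(pos),
               mean_gap_mbp = if (length(pos) >= 2L) mean(diff(pos)) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  spans <- vapply(by_chrom, function(p) diff(range(p)), 0)
  n_int <- vapply(by_chrom, function(p) length(p) - 1L, 0L)
  usable <- n_int > 0L
  if (!any(usable)) stop("need >= 2 markers on >= 1 chromosome",
                         call. = FALSE)
  list(per_chrom = per,
       genome_mean_mbp = sum(spans[usable]) / sum(n_int[usable]))
}

CALL_COLORS <- c(AA = "#d62728", BB = "#1f77b4", AB = "#e8c832",
                 NN = "#000000")

#' Render graphical genotypes
#'
#' One horizontal track per sample per chromosome, one colored segment
#' per marker: allele-A homozygote red, allele-B homozygote blue,
#' heterozygote yellow, undetermined black.  Writes an SVG (hand-emitted,
#' byte-deterministic for fixed input) and a TSV track table as a
#' plain-text fallback.  Markers lacking a position are drawn in an
#' `unplaced` lane with a warning.
#'
#' @param matrix genotype matrix (samples x markers).
#' @param snps a `snp_table` giving `chrom` and `mbp` per marker.
#' @param out output path prefix; writes `<out>.svg` and `<out>.tsv`.
#' @return invisible list of the two file paths.
#' @export
graphical_genotypes <- function(matrix, snps, out) {
  markers <- colnames(matrix)
  info <- snps[match(markers, snps$name), ]
  unplaced <- markers[is.na(info$mbp) | is.na(info$chrom)]
  if (length(unplaced) > 0L) {
    warning("marker(s) without position drawn in an unplaced lane: ",
            paste(unplaced, collapse = ", "), call. = FALSE)
  }
  chrom <- ifelse(markers %in% unplaced, "unplaced",
                  as.character(info$chrom))
  pos <- ifelse(markers %in% unplaced,
                stats::ave(seq_along(markers), chrom, FUN = seq_along),
                info$mbp)
  track <- do.call(rbind, lapply(rownames(matrix), function(s) {
    data.frame(sample = s, marker = markers, chrom = chrom, pos_mbp = pos,
               call = unname(matrix[s, ]),
               color = unname(CALL_COLORS[matrix[s, ]]),
               stringsAsFactors = FALSE)
  }))
  track <- track[order(track$sample, track$chrom, track$pos_mbp), ]
  tsv <- paste0(out, ".tsv"); svg <- paste0(out, ".svg")
  utils::write.table(track, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(render_track_svg(track), svg)
  invisible(list(svg = svg, tsv = tsv))
}

# Minimal deterministic SVG: a row of lanes per (sample, chromosome),
# one rect per marker.
render_track_svg <- function(track) {
  lane_key <- paste(track$sample, track$chrom, sep = " / ")
  lanes <- unique(lane_key)
  lane_h <- 18L; pad <- 4L; label_w <- 180L; plot_w <- 600L
  xmax <- max(track$pos_mbp)
  xmin <- min(track$pos_mbp)
  span <- max(xmax - xmin, 1e-9)
  height <- length(lanes) * (lane_h + pad) + pad
  lines <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'width="%d" height="%d">'),
                     label_w + plot_w + 20L, height))
  for (li in seq_along(lanes)) {
    y <- pad + (li - 1L) * (lane_h + pad)
    lines <- c(lines,
               sprintf(paste0('<text x="4" y="%d" font-size="11" ',
                              'font-family="monospace">%s</text>'),
                       y + 13L, lanes[li]))
    sub <- track[lane_key == lanes[li], , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      x <- label_w + round((sub$pos_mbp[i] - xmin) / span * (plot_w - 10L))
      lines <- c(lines,
                 sprintf(paste0('<rect x="%d" y="%d" width="10" ',
                                'height="%d" fill="%s"><title>%s %s',
                                '</title></rect>'),
                         x, y, lane_h, sub$color[i], sub$marker[i],
                         sub$call[i]))
    }
  }
  c(lines, "</svg>")
}
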
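# Endpoint-fluorescence genotype calling: 96-well plate layouts for the
# multi-sample (48 samples x 1 marker) and multi-locus (1 sample x 48
# markers) schemes, per-channel thresholds, and the codominant quadrant
# rule AA / BB / AB / NN.

#' Build 96-well plate layouts
#'
#' Each genotyped (sample, marker) unit occupies two adjacent wells: the
#' allele-A reaction then the allele-B reaction, filled row-major
#' (A1, A2, ...).  A 96-well plate therefore holds 48 units: 48 samples
#' of one marker (`multi_sample`) or 48 markers of one sample
#' (`multi_locus`); plates are added as needed (`ceil(n/48)`).
#'
#' A plate set serves one marker across samples (`multi_sample`) or one
#' sample across markers (`multi_locus`); passing several markers (or
#' samples) produces one plate set each, concatenated.
#'
#' @param mode `"multi_sample"` or `"multi_locus"`.
#' @param samples sample identifiers.
#' @param markers marker identifiers.
#' @param plate_prefix prefix for generated plate identifiers.
#' @return data.frame of class `plate_layout`: `plate`, `well`, `sample`,
#'   `marker`, `channel`; attribute `mode`, `n_plates`.
#' @export
make_layout <- function(mode = c("multi_sample", "multi_locus"),
                        samples, markers, plate_prefix = "P") {
  mode <- match.arg(mode)
  if (length(samples) == 0L || length(markers) == 0L) {
    stop("samples and markers must be non-empty", call. = FALSE)
  }
  one_set <- function(units, set_id, n_sets) {
    n <- length(units)
    rows <- vector("list", n)
    for (u in seq_len(n)) {
      plate <- if (n_sets == 1L) {
        paste0(plate_prefix, (u - 1L) %/% 48L + 1L)
      } else {
        paste0(plate_prefix, set_id, "_", (u - 1L) %/% 48L + 1L)
      }
      slot <- (u - 1L) %% 48L  # unit slot within its plate
      wells <- well_ids(96L)[c(2L * slot + 1L, 2L * slot + 2L)]
      s <- if (mode == "multi_sample") units[u] else set_id
      m <- if (mode == "multi_sample") set_id else units[u]
      rows[[u]] <- data.frame(plate = plate, well = wells, sample = s,
                              marker = m, channel = c("A", "B"),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  sets <- if (mode == "multi_sample") markers else samples
  units <- if (mode == "multi_sample") samples else markers
  out <- do.call(rbind, lapply(sets, function(sid)
    one_set(units, sid, length(sets))))
  rownames(out) <- NULL
  key <- paste(out$sample, out$marker, out$channel)
  stopifnot(!anyDuplicated(key))
  structure(out, class = c("plate_layout", "data.frame"), mode = mode,
            n_plates = length(unique(out$plate)))
}

#' Per-channel fluorescence calling thresholds
#'
#' `two_cluster` splits each channel's intensities with deterministic
#' 1-D two-means (centers initialized at the minimum and maximum) and
#' sets the threshold at the midpoint of the two cluster centers.  The
#' split is accepted only when the high/low center ratio reaches
#' `min_separation`; otherwise the method falls back to `fixed` —
#' `fixed_frac` of the channel maximum — and the fallback is flagged.
#'
#' @param intensities named list with numeric vectors `A` and `B` (one
#'   intensity per well of that channel).
#' @param method `"two_cluster"` or `"fixed"`.
#' @param min_separation minimum high/low cluster-center ratio for a
#'   valid two-cluster split.
#' @param fixed_frac threshold as a fraction of the channel maximum for
#'   the fixed method.
#' @return list of class `call_thresholds`: `threshold_a`, `threshold_b`,
#'   `method`, `fallback` (per channel, logical).
#' @export
estimate_thresholds <- function(intensities,
                                method = c("two_cluster", "fixed"),
                                min_separation = 3, fixed_frac = 0.3) {
  method <- match.arg(method)
  stopifnot(is.list(intensities), all(c("A", "B") %in% names(intensities)))
  one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) stop("no intensities in channel", call. = FALSE)
    if (max(x) == min(x)) {
      stop("degenerate signal: all intensities in a channel are equal",
           call. = FALSE)
    }
    if (method == "fixed") {
      return(list(threshold = fixed_frac * max(x), fallback = FALSE))
    }
    if (length(x) < 4L) {
      stop("two_cluster thresholding needs at least 4 wells per channel",
           call. = FALSE)
    }
    centers <- two_means_1d(x)
    if (centers[2L] / max(centers[1L], .Machine$double.eps) <
        min_separation) {
      list(threshold = fixed_frac * max(x), fallback = TRUE)
    } else {
      list(threshold = mean(centers), fallback = FALSE)
    }
  }
  a <- one(intensities$A); b <- one(intensities$B)
  structure(list(threshold_a = a$threshold, threshold_b = b$threshold,
                 method = method,
                 fallback = c(A = a$fallback, B = b$fallback)),
            class = "call_thresholds")
}

# Exact 1-D two-means: the optimal 2-partition of points on a line is an
# interval split, so enumerate the n-1 split points of the sorted data
# and keep the one minimizing the within-cluster sum of squares (ties:
# smallest split index).  Returns sorted cluster centers c(low, high).
two_means_1d <- function(x) {
  x <- sort(x)
  n <- length(x)
  best_ss <- Inf; best_k <- 1L
  for (k in 1:(n - 1L)) {
    lo <- x[1:k]; hi <- x[(k + 1L):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best_k <- k }
  }
  c(mean(x[1:best_k]), mean(x[(best_k + 1L):n]))
}

#' Classify one two-channel well pair
#'
#' Quadrant rule on the two allele reactions: only channel A above its
#' threshold is `AA`, only channel B is `BB`, both are `AB`
#' (heterozygote), neither is `NN` (no amplification, e.g. failed
#' template).
#'
#' @param intensity_a,intensity_b endpoint intensities (arbitrary units,
#'   >= 0); NA counts as below threshold.
#' @param thresholds a [estimate_thresholds()] result.
#' @return one of `"AA"`, `"BB"`, `"AB"`, `"NN"`.
#' @export
classify_well_pair <- function(intensity_a, intensity_b, thresholds) {
  a_pos <- !is.na(intensity_a) && intensity_a > thresholds$threshold_a
  b_pos <- !is.na(intensity_b) && intensity_b > thresholds$threshold_b
  if (a_pos && b_pos) "AB" else if (a_pos) "AA" else if (b_pos) "BB" else "NN"
}

#' Call genotypes from joined plate data
#'
#' @param plate_data output of [read_plate_csv()] (or the equivalent
#'   data.frame with columns `plate, well, sample, marker, channel,
#'   intensity`).
#' @param thresholds either a `call_thresholds` object applied to all
#'   plates, or a method name (`"two_cluster"`/`"fixed"`) to estimate
#'   thresholds per plate and channel.
#' @param ... passed to [estimate_thresholds()] when estimating.
#' @return character genotype matrix (samples x markers) with calls in
#'   `{AA, BB, AB, NN}`; missing channels call as if below threshold.
#' @export
call_plates <- function(plate_data, thresholds = "two_cluster", ...) {
  need <- c("plate", "well", "sample", "marker", "channel", "intensity")
  stopifnot(all(need %in% names(plate_data)))
  key <- paste(plate_data$sample, plate_data$marker, plate_data$channel)
  if (anyDuplicated(key)) {
    stop("ambiguous plate data: duplicated (sample, marker, channel): ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  # resolve thresholds per plate
  thr_for_plate <- function(p) {
    if (inherits(thresholds, "call_thresholds")) return(thresholds)
    sub <- plate_data[plate_data$plate == p, ]
    estimate_thresholds(list(A = sub$intensity[sub$channel == "A"],
                             B = sub$intensity[sub$channel == "B"]),
                        method = thresholds, ...)
  }
  plates <- sort(unique(plate_data$plate))
  thr <- stats::setNames(lapply(plates, thr_for_plate), plates)
  samples <- unique(plate_data$sample)
  markers <- unique(plate_data$marker)
  calls <- matrix("NN", length(samples), length(markers),
                  dimnames = list(samples, markers))
  units <- unique(plate_data[c("plate", "sample", "marker")])
  ukey <- paste(units$sample, units$marker)
  ch_a <- plate_data[plate_data$channel == "A", ]
  ch_b <- plate_data[plate_data$channel == "B", ]
  ia <- ch_a$intensity[match(ukey, paste(ch_a$sample, ch_a$marker))]
  ib <- ch_b$intensity[match(ukey, paste(ch_b$sample, ch_b$marker))]
  ta <- vapply(units$plate, function(p) thr[[p]]$threshold_a, 0)
  tb <- vapply(units$plate, function(p) thr[[p]]$threshold_b, 0)
  a_pos <- !is.na(ia) & ia > ta
  b_pos <- !is.na(ib) & ib > tb
  call <- ifelse(a_pos & b_pos, "AB",
                 ifelse(a_pos, "AA", ifelse(b_pos, "BB", "NN")))
  calls[cbind(match(units$sample, samples),
              match(units$marker, markers))] <- call
  calls
}

#' Genotype call rate
#'
#' Fraction of determined (non-`NN`) calls.
#'
#' @param matrix character genotype matrix (samples x markers).
#' @param by `"overall"` for one number, `"sample"`/`"marker"` for the
#'   per-margin rates (returned with a `mean` attribute).
#' @return numeric fraction(s) in \[0, 1\].
#' @export
call_rate <- function(matrix, by = c("overall", "sample", "marker")) {
  by <- match.arg(by)
  stopifnot(length(matrix) > 0L)
  det <- matrix != "NN"
  if (by == "overall") return(mean(det))
  margin <- if (by == "sample") 1L else 2L
  rates <- apply(det, margin, mean)
  attr(rates, "mean") <- mean(rates)
  rates
}
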
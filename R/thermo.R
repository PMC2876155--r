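# Melting-temperature machinery used to standardize every assay to one
# annealing protocol (58 degC annealing, endpoint read at 75 degC).

# Unified nearest-neighbor dinucleotide parameters for DNA/DNA duplexes:
# enthalpy kcal/mol, entropy cal/(mol K), 5'->3' top-strand steps.
NN_DH <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
           TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
           CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
           GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
           TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
           CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
           GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)
# Duplex initiation with a terminal G.C vs terminal A.T pair.
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
GAS_CONSTANT <- 1.987  # cal/(mol K)

#' Thermodynamic parameter set for primer Tm calculations
#'
#' @param method `"nearest_neighbor"` (unified dinucleotide parameter set
#'   with salt correction; the standard for PCR primers) or `"wallace"`
#'   (the 2(A+T)+4(G+C) rule, a fast approximation).
#' @param monovalent_salt monovalent cation concentration, mol/L.
#' @param primer_conc primer strand concentration, mol/L.
#' @param target_tm Tm all primers are tuned towards, degC.  Default 60
#'   degC, pairing with the standardized 58 degC annealing protocol.
#' @param tm_window half-width of the acceptable Tm band, degC.
#' @return list of class `thermo_params`.
#' @export
thermo_params <- function(method = c("nearest_neighbor", "wallace"),
                          monovalent_salt = 0.05,
                          primer_conc = 250e-9,
                          target_tm = 60,
                          tm_window = 2) {
  method <- match.arg(method)
  stopifnot(monovalent_salt > 0, primer_conc > 0, tm_window > 0)
  structure(list(method = method, monovalent_salt = monovalent_salt,
                 primer_conc = primer_conc, target_tm = target_tm,
                 tm_window = tm_window),
            class = "thermo_params")
}

#' GC content of a sequence
#'
#' @param seq non-empty ACGT string.
#' @return fraction of G+C bases, in \[0, 1\].
#' @export
gc_content <- function(seq) {
  check_seq(seq)
  ch <- seq_chars(seq)
  sum(ch %in% c("G", "C")) / length(ch)
}

# Per-step (dH, dS) contributions of a duplex, including initiation terms.
# Returns list(dh, ds) where element i (i in 1..n-1) is the stack between
# bases i and i+1; init holds the two terminal initiation contributions.
nn_steps <- function(ch) {
  steps <- paste0(ch[-length(ch)], ch[-1L])
  init_key <- ifelse(ch[c(1L, length(ch))] %in% c("G", "C"), "GC", "AT")
  list(dh = unname(NN_DH[steps]), ds = unname(NN_DS[steps]),
       init_dh = sum(NN_INIT_DH[init_key]),
       init_ds = sum(NN_INIT_DS[init_key]))
}

nn_tm_from_sums <- function(dh, ds, params, n_bases) {
  # salt-corrected entropy; primer in excess over template => CT/4
  ds_salt <- ds + 0.368 * (n_bases - 1L) * log(params$monovalent_salt)
  1000 * dh / (ds_salt + GAS_CONSTANT * log(params$primer_conc / 4)) - 273.15
}

#' Melting temperature of a primer
#'
#' Nearest-neighbor Tm sums dinucleotide enthalpies/entropies over all
#' adjacent base steps plus duplex-initiation terms, applies a monovalent
#' salt entropy correction, and converts to degC at the configured primer
#' concentration.  Wallace Tm is `2(A+T) + 4(G+C)`.
#'
#' An artificial mismatch can be marked with `mismatch_pos` (1-based from
#' the 5' end): the two base stacks involving that position are treated as
#' non-contributing and each replaced by the mean of the two stacks
#' immediately flanking the mismatched base, approximating the duplex as
#' perfectly matched minus one pair.  Mismatch-specific thermodynamic
#' penalty tables are out of scope.
#'
#' @param seq primer sequence, 5'->3', length >= 8.
#' @param params a [thermo_params()] object.
#' @param mismatch_pos optional 1-based position of a non-pairing base.
#' @return Tm in degC.
#' @export
melting_temperature <- function(seq, params = thermo_params(),
                                mismatch_pos = NULL) {
  check_seq(seq)
  n <- nchar(seq)
  if (n < 8L) stop("sequence must be at least 8 bases long", call. = FALSE)
  ch <- seq_chars(seq)
  if (params$method == "wallace") {
    at <- sum(ch %in% c("A", "T")); gc <- sum(ch %in% c("G", "C"))
    return(2 * at + 4 * gc)
  }
  st <- nn_steps(ch)
  if (!is.null(mismatch_pos)) {
    stopifnot(mismatch_pos >= 1L, mismatch_pos <= n)
    m <- as.integer(mismatch_pos)
    involved <- intersect(c(m - 1L, m), seq_len(n - 1L))
    flank <- intersect(c(m - 2L, m + 1L), seq_len(n - 1L))
    flank <- setdiff(flank, involved)
    if (length(flank) == 0L) {
      stop("mismatch too close to both primer ends to average flanking stacks",
           call. = FALSE)
    }
    st$dh[involved] <- mean(st$dh[flank])
    st$ds[involved] <- mean(st$ds[flank])
  }
  nn_tm_from_sums(sum(st$dh) + st$init_dh, sum(st$ds) + st$init_ds, params, n)
}

#' Fit a primer length to the target Tm
#'
#' With the 3' end pinned at `three_prime_index` on the template, extends
#' the primer 5'-wards and returns the smallest length in
#' `[len_min, len_max]` whose Tm falls inside `target_tm +/- tm_window`.
#' If no length lands in the window the length minimizing the absolute
#' deviation is returned, flagged out-of-window.
#'
#' @param template template sequence (the strand the primer copies).
#' @param three_prime_index 1-based template position of the primer 3' end.
#' @param params a [thermo_params()] object.
#' @param len_min,len_max candidate primer length bounds.
#' @return list: `length`, `tm`, `seq`, `in_window` (logical).
#' @export
fit_length_to_tm <- function(template, three_prime_index,
                             params = thermo_params(),
                             len_min = 18L, len_max = 30L) {
  check_seq(template, "template")
  stopifnot(len_min >= 8L, len_max >= len_min)
  if (three_prime_index < len_min) {
    stop("design infeasible: template exhausted before the minimum ",
         "primer length", call. = FALSE)
  }
  len_hi <- min(len_max, three_prime_index)
  best <- NULL
  for (L in len_min:len_hi) {
    s <- substr(template, three_prime_index - L + 1L, three_prime_index)
    tm <- melting_temperature(s, params)
    dev <- abs(tm - params$target_tm)
    if (dev <= params$tm_window) {
      return(list(length = L, tm = tm, seq = s, in_window = TRUE))
    }
    if (is.null(best) || dev < best$dev) {
      best <- list(length = L, tm = tm, seq = s, dev = dev)
    }
  }
  list(length = best$length, tm = best$tm, seq = best$seq, in_window = FALSE)
}
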
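# Synthetic-data generators with known truth: random genomes with
# biallelic SNPs, F2 populations segregating under the Haldane map
# function, diversity panels, and two-channel endpoint-fluorescence
# plates.  Every generator is deterministic for a fixed seed.

#' Simulation configuration
#'
#' Defaults emulate the assay regime the toolkit targets: a positive to
#' negative endpoint-signal ratio of 10 (the specific product is read
#' against background at a signal/noise ratio well above 6), Gaussian
#' well noise at half the background level, and whole-sample dropout at
#' 8/96 (the germination-failure rate observed in a 96-plant F2 screen).
#'
#' @param seed integer RNG seed.
#' @param n_chrom,chrom_len_bp chromosome count and length.
#' @param n_snps number of SNPs, distributed round-robin over chromosomes.
#' @param gc genome GC fraction.
#' @param mu_pos,mu_neg,sigma endpoint-intensity distribution parameters
#'   (arbitrary fluorescence units).
#' @param dropout probability a sample yields no amplification anywhere.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_len_bp = 20000L,
                       n_snps = 16L, gc = 0.43,
                       mu_pos = 1000, mu_neg = 100, sigma = 50,
                       dropout = 8 / 96) {
  stopifnot(mu_pos > mu_neg, mu_neg >= 0, sigma > 0,
            dropout >= 0, dropout < 1, gc > 0, gc < 1)
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_len_bp = as.integer(chrom_len_bp),
                 n_snps = as.integer(n_snps), gc = gc,
                 mu_pos = mu_pos, mu_neg = mu_neg, sigma = sigma,
                 dropout = dropout),
            class = "sim_config")
}

#' Simulate a reference genome with biallelic SNPs
#'
#' Chromosome sequences are i.i.d. draws at the configured base
#' composition.  SNPs are assigned round-robin to chromosomes and placed
#' at uniform-random positions at least `min_spacing` bp from each other
#' and from the contig ends (room for a full assay).  Allele A is the
#' reference base; allele B is drawn uniformly from the other three.
#'
#' @param config a [sim_config()].
#' @param min_spacing minimum distance between SNPs and from contig ends.
#' @return list: `genome` (named character vector) and `snps`
#'   (a `snp_table`).
#' @export
simulate_reference <- function(config = sim_config(), min_spacing = 600L) {
  with_seed(config$seed, {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    genome <- vapply(seq_len(config$n_chrom), function(i) {
      paste(sample(names(p), config$chrom_len_bp, replace = TRUE, prob = p),
            collapse = "")
    }, "")
    names(genome) <- paste0("chr", seq_len(config$n_chrom))
    chrom_of <- rep(seq_len(config$n_chrom),
                    length.out = config$n_snps)  # round-robin
    snps <- vector("list", config$n_snps)
    placed <- vector("list", config$n_chrom)
    for (i in seq_len(config$n_snps)) {
      ci <- chrom_of[i]
      lo <- min_spacing + 1L
      hi <- config$chrom_len_bp - min_spacing
      if (hi < lo) stop("placement error: chromosome too short for the ",
                        "requested SNP spacing", call. = FALSE)
      pos <- NA_integer_
      for (try in 1:1000) {
        cand <- sample(lo:hi, 1L)
        if (all(abs(cand - placed[[ci]]) >= min_spacing)) {
          pos <- cand; break
        }
      }
      if (is.na(pos)) stop("placement error: SNP density infeasible at ",
                           "spacing ", min_spacing, call. = FALSE)
      placed[[ci]] <- c(placed[[ci]], pos)
      ref <- substr(genome[[ci]], pos, pos)
      alt <- sample(setdiff(BASES, ref), 1L)
      snps[[i]] <- data.frame(name = sprintf("S%04d", i),
                              chrom = names(genome)[ci], pos = pos,
                              allele_a = ref, allele_b = alt,
                              cm = NA_real_, mbp = pos / 1e6,
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, snps)
    list(genome = genome, snps = new_snp_table(validate_snp_table(df)))
  })
}

#' Haldane map function
#'
#' Converts genetic map distance to recombination fraction assuming no
#' crossover interference: `r = (1 - exp(-2 d / 100)) / 2` for `d` in
#' centimorgans.
#'
#' @param d_cm map distance, cM (>= 0).
#' @return recombination fraction in \[0, 0.5).
#' @export
haldane_r <- function(d_cm) {
  if (any(d_cm < 0)) stop("map distance must be non-negative", call. = FALSE)
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Simulate an F2 population
#'
#' Each F2 plant is the union of two independent gametes from the F1.
#' A gamete is generated marker-to-marker along the map: the parental
#' phase at the first marker is a fair coin, then switches between
#' adjacent markers with probability `haldane_r(delta cM)` (Haldane, no
#' interference).  Genotype = sum of the two gametes.
#'
#' @param map_positions named numeric vector: marker -> cM position,
#'   non-decreasing.
#' @param n_plants number of F2 individuals.
#' @param seed RNG seed.
#' @return character genotype matrix (plants x markers) with values
#'   `AA`/`AB`/`BB` — the true genotypes.
#' @export
simulate_f2 <- function(map_positions, n_plants, seed = 1L) {
  if (is.unsorted(map_positions)) {
    stop("map positions must be ordered (non-decreasing cM)", call. = FALSE)
  }
  n_mark <- length(map_positions)
  r <- haldane_r(diff(map_positions))
  with_seed(seed, {
    # one gamete pool per parent: phase at marker 1 is a fair coin, then
    # cumulative switches (XOR) along the map
    gametes <- function() {
      first <- sample(0:1, n_plants, replace = TRUE)
      if (n_mark == 1L) return(matrix(first, ncol = 1L))
      sw <- matrix(stats::runif(n_plants * (n_mark - 1L)) <
                     rep(r, each = n_plants), n_plants)
      cum <- sw
      if (n_mark > 2L) for (k in 2:(n_mark - 1L)) {
        cum[, k] <- cum[, k - 1L] + cum[, k]
      }
      (cbind(0L, cum) + first) %% 2L
    }
    dose <- gametes() + gametes()  # copies of allele B
    calls <- matrix(c("AA", "AB", "BB")[dose + 1L], n_plants, n_mark,
                    dimnames = list(paste0("F2_", seq_len(n_plants)),
                                    names(map_positions)))
    calls
  })
}

#' Simulate endpoint-fluorescence plates for a genotype matrix
#'
#' Channel intensity is drawn from `Normal(mu_pos, sigma)` when the
#' channel's allele is present in the genotype and `Normal(mu_neg,
#' sigma)` otherwise, truncated at 0.  Dropout samples (probability
#' `config$dropout`, e.g. germination failure) read background in both
#' channels at every marker.
#'
#' @param matrix true genotype matrix (samples x markers), calls in
#'   `{AA, AB, BB}`.
#' @param layout a [make_layout()] layout covering the matrix cells.
#' @param config a [sim_config()] (intensity and dropout parameters).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list: `plate_data` (data.frame `plate, well, sample, marker,
#'   channel, intensity`), `truth` (the input matrix), `dropped`
#'   (character vector of dropout samples).
#' @export
simulate_plates <- function(matrix, layout, config = sim_config(),
                            seed = config$seed) {
  stopifnot(inherits(layout, "plate_layout"))
  with_seed(seed, {
    samples <- unique(layout$sample)
    dropped <- samples[stats::runif(length(samples)) < config$dropout]
    geno <- matrix[cbind(layout$sample, layout$marker)]
    present <- ifelse(layout$channel == "A",
                      geno %in% c("AA", "AB"), geno %in% c("BB", "AB"))
    present[layout$sample %in% dropped] <- FALSE
    mu <- ifelse(present, config$mu_pos, config$mu_neg)
    intensity <- pmax(0, stats::rnorm(nrow(layout), mu, config$sigma))
    pd <- data.frame(plate = layout$plate, well = layout$well,
                     sample = layout$sample, marker = layout$marker,
                     channel = layout$channel, intensity = intensity,
                     stringsAsFactors = FALSE)
    list(plate_data = pd, truth = matrix, dropped = dropped)
  })
}

#' Simulate a multi-locus diversity panel
#'
#' Generates genotypes for a set of inbred lines falling into a few
#' deeply diverged clades: each clade has a founder genotype (homozygous
#' at every marker), lines copy their clade founder with independent
#' per-marker flip probability `within_div`, and each call is missed
#' (`NN`) with probability `no_call`.  The default `no_call` mirrors the
#' multi-locus array regime where roughly 94% of genotypes are
#' determined.
#'
#' @param n_lines,n_markers panel dimensions.
#' @param n_clades number of diverged groups.
#' @param within_div per-marker probability a line differs from its
#'   clade founder.
#' @param no_call per-call missingness probability.
#' @param seed RNG seed.
#' @return list: `calls` (lines x markers character matrix), `clade`
#'   (named integer vector: line -> clade).
#' @export
simulate_panel <- function(n_lines = 11L, n_markers = 96L, n_clades = 3L,
                           within_div = 0.05, no_call = 0.064, seed = 1L) {
  stopifnot(n_lines >= n_clades, n_clades >= 2L)
  with_seed(seed, {
    founders <- matrix(sample(c("AA", "BB"), n_clades * n_markers,
                              replace = TRUE),
                       n_clades, n_markers)
    clade <- rep(seq_len(n_clades), length.out = n_lines)
    calls <- matrix("", n_lines, n_markers,
                    dimnames = list(paste0("line", seq_len(n_lines)),
                                    sprintf("M%03d", seq_len(n_markers))))
    flip <- c(AA = "BB", BB = "AA")
    for (i in seq_len(n_lines)) {
      g <- founders[clade[i], ]
      do_flip <- stats::runif(n_markers) < within_div
      g[do_flip] <- flip[g[do_flip]]
      g[stats::runif(n_markers) < no_call] <- "NN"
      calls[i, ] <- g
    }
    list(calls = calls, clade = stats::setNames(clade, rownames(calls)))
  })
}
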
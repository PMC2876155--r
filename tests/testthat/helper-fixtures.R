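# Shared fixtures: tiny genomes and loci built in code.

# A random single-chromosome genome with one SNP far enough from both
# ends for a full assay.
random_locus_instance <- function(seed, chrom_len = 1500L, gc = 0.43) {
  ref <- simulate_reference(sim_config(seed = seed, n_chrom = 1L,
                                       chrom_len_bp = chrom_len,
                                       n_snps = 1L, gc = gc))
  list(genome = ref$genome, locus = ref$snps[1L, ])
}

# Deterministic toy genome from an explicit sequence.
toy_genome <- function(seq, name = "chr1") {
  stats::setNames(toupper(seq), name)
}

# Evenly spaced map over a span.
toy_map <- function(n_markers, span_cm) {
  stats::setNames(seq(0, span_cm, length.out = n_markers),
                  sprintf("M%02d", seq_len(n_markers)))
}

# Simulate plates for a genotype matrix across all its markers and call
# them back; returns the called matrix aligned to the truth.
simulate_and_call <- function(truth, config, seed,
                              thresholds = "two_cluster") {
  lay <- make_layout("multi_sample", rownames(truth), colnames(truth))
  sim <- simulate_plates(truth, lay, config, seed = seed)
  calls <- call_plates(sim$plate_data, thresholds = thresholds)
  list(calls = calls[rownames(truth), colnames(truth), drop = FALSE],
       dropped = sim$dropped)
}
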
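# Recombination detection, interval narrowing and map utilities.

test_that("crossover counting follows the F2 convention", {
  expect_equal(crossover_count("AA", "AA"), 0L)
  expect_equal(crossover_count("AB", "AB"), 0L)  # repulsion invisible
  expect_equal(crossover_count("AA", "AB"), 1L)
  expect_equal(crossover_count("BB", "AB"), 1L)
  expect_equal(crossover_count("AA", "BB"), 2L)
  expect_true(is.na(crossover_count("NN", "AA")))
})

test_that("find_recombinants equals the brute-force definition", {
  withr::with_seed(51, {
    for (rep in 1:10) {
      n <- sample(5:30, 1)
      m <- matrix(sample(c("AA", "AB", "BB", "NN"), 2 * n, replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)),
                  n, 2, dimnames = list(paste0("s", 1:n), c("m1", "m2")))
      ev <- find_recombinants(m, "m1", "m2")
      # brute force over samples
      brute <- character(0)
      excluded <- character(0)
      for (s in rownames(m)) {
        if (m[s, 1] == "NN" || m[s, 2] == "NN") {
          excluded <- c(excluded, s)
        } else if (m[s, 1] != m[s, 2]) {
          brute <- c(brute, s)
        }
      }
      expect_equal(ev$sample, brute)
      expect_equal(attr(ev, "excluded"), excluded)
    }
  })
  m <- matrix("AA", 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_equal(nrow(find_recombinants(m, "a", "b")), 0L)
  expect_error(find_recombinants(m, "a", "a"), "must differ")
})

test_that("a single recombinant constrains one interval side", {
  markers <- paste0("m", 1:5)
  calls <- matrix("AA", 1, 5, dimnames = list("r1", markers))
  calls[1, 3:5] <- "AB"  # crossover between m2 and m3
  # A-type phenotype matches the left homozygous block
  res <- narrow_interval(calls, c(r1 = "A"), markers,
                         stats::setNames(seq(0, 40, 10), markers))
  expect_equal(res$admissible, c("m1", "m2"))
  expect_equal(res$right_bound, "m3")
  expect_equal(res$left_bound, "m1")
  expect_equal(res$width_cm, 20)
})

test_that("opposing recombinants narrow the interval from both sides", {
  markers <- paste0("m", 1:5)
  calls <- rbind(
    r1 = c("AA", "AA", "AA", "AB", "AB"),  # A-type: locus left of m4
    r2 = c("AB", "AB", "AA", "AA", "AA"))  # A-type: locus right of m2
  colnames(calls) <- markers
  res <- narrow_interval(calls, c(r1 = "A", r2 = "A"), markers)
  expect_equal(res$admissible, "m3")
  expect_equal(res$left_bound, "m2")
  expect_equal(res$right_bound, "m4")
})

test_that("contradictory phenotypes raise an inconsistency error", {
  markers <- paste0("m", 1:3)
  calls <- rbind(r1 = c("AA", "AA", "BB"),
                 r2 = c("AA", "AA", "BB"))
  colnames(calls) <- markers
  # r1 says locus is in the AA block, r2 (B-type) says the BB block,
  # but their blocks are disjoint
  expect_error(
    narrow_interval(calls, c(r1 = "A", r2 = "B"), markers),
    "inconsistent")
})

test_that("interval narrowing recovers a simulated causal locus", {
  map <- toy_map(5, 30)
  causal <- names(map)[3]
  hits <- 0L
  for (k in 1:20) {
    truth <- simulate_f2(map, 96, seed = 600 + k)
    ev <- find_recombinants(truth, names(map)[1], names(map)[5])
    hom <- ev$sample[truth[ev$sample, causal] %in% c("AA", "BB")]
    if (length(hom) == 0) next
    phenotype <- stats::setNames(
      ifelse(truth[hom, causal] == "AA", "A", "B"), hom)
    res <- narrow_interval(truth[hom, , drop = FALSE], phenotype,
                           names(map), map)
    if (causal %in% res$admissible) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("marker spacing averages adjacent physical gaps", {
  snps <- data.frame(name = paste0("S", 1:3), chrom = "chr1",
                     pos = 1:3, allele_a = "A", allele_b = "G",
                     cm = NA, mbp = c(0, 10, 30))
  sp <- map_spacing(snps)
  expect_equal(sp$genome_mean_mbp, 15)
  expect_equal(sp$per_chrom$mean_gap_mbp, 15)
  # two chromosomes each spanning 10 in one interval
  snps2 <- data.frame(name = paste0("S", 1:4),
                      chrom = rep(c("c1", "c2"), each = 2),
                      pos = 1:4, allele_a = "A", allele_b = "G",
                      cm = NA, mbp = c(0, 10, 0, 10))
  expect_equal(map_spacing(snps2)$genome_mean_mbp, 10)
  # brute-force agreement on random inputs
  withr::with_seed(52, {
    for (rep in 1:5) {
      n <- sample(4:20, 1)
      snpsr <- data.frame(name = paste0("S", 1:n),
                          chrom = sample(c("c1", "c2"), n, replace = TRUE),
                          pos = 1:n, allele_a = "A", allele_b = "G",
                          cm = NA, mbp = runif(n, 0, 40))
      if (min(table(snpsr$chrom)) < 2) next
      sp <- map_spacing(snpsr)
      gaps <- unlist(lapply(split(snpsr$mbp, snpsr$chrom),
                            function(p) diff(sort(p))))
      expect_equal(sp$genome_mean_mbp, sum(gaps) / length(gaps))
    }
  })
})

test_that("graphical genotypes render deterministically with all 4 colors", {
  m <- matrix(c("AA", "BB", "AB", "NN", "AA", "BB", "AB", "NN"), 2, 4,
              dimnames = list(c("s1", "s2"), paste0("S", 1:4)))
  snps <- data.frame(name = paste0("S", 1:4), chrom = c("c1", "c1", "c2",
                                                        "c2"),
                     pos = 1:4, allele_a = "A", allele_b = "G",
                     cm = NA, mbp = c(0, 5, 0, 5))
  out1 <- tempfile(); out2 <- tempfile()
  files1 <- graphical_genotypes(m, snps, out1)
  files2 <- graphical_genotypes(m, snps, out2)
  expect_identical(readLines(files1$svg), readLines(files2$svg))
  track <- utils::read.delim(files1$tsv)
  expect_equal(nrow(track), 8L)  # 2 samples x 4 markers
  expect_equal(sort(unique(track$call)), c("AA", "AB", "BB", "NN"))
  expect_equal(length(unique(paste(track$sample, track$chrom))), 4L)
  # all-NN sample renders black
  expect_true(all(track$color[track$call == "NN"] == "#000000"))
  # a marker without position goes to the unplaced lane with a warning
  snps_np <- snps; snps_np$mbp[4] <- NA
  expect_warning(files3 <- graphical_genotypes(m, snps_np, tempfile()),
                 "unplaced")
  track3 <- utils::read.delim(files3$tsv)
  expect_true("unplaced" %in% track3$chrom)
})
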
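# ASP assay assembly: template extraction, allele-specific forwards,
# shared reverse, discrimination pattern, in-silico amplification.

# Brute-force base-by-base mismatch count between equal-length strings.
oracle_mismatch_count <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

test_that("extract_template slices, marks the SNP and checks the reference", {
  seq <- strrep("ACGT", 250)  # 1000 bp
  genome <- toy_genome(seq)
  locus <- list(name = "S1", chrom = "chr1", pos = 500L,
                allele_a = substr(seq, 500, 500), allele_b = "A")
  tmpl <- extract_template(genome, locus, window = 100L)
  expect_equal(nchar(tmpl$seq), 201L)
  expect_equal(tmpl$offset, 101L)
  expect_equal(substr(tmpl$seq, tmpl$offset, tmpl$offset), locus$allele_a)
  # reference carries allele A -> allele-A template equals the slice
  expect_equal(tmpl$seq_a, tmpl$seq)
  expect_equal(oracle_mismatch_count(tmpl$seq_a, tmpl$seq_b), 1L)
  # reference base matching neither allele is an error
  bad <- locus; bad$allele_a <- "G"; bad$allele_b <- "C"
  if (substr(seq, 500, 500) %in% c("G", "C")) bad$allele_a <- "T"
  expect_error(extract_template(genome, bad, 100L), "reference mismatch")
  # truncation warning near a contig end
  near_end <- list(name = "S2", chrom = "chr1", pos = 30L,
                   allele_a = substr(seq, 30, 30), allele_b = "A")
  expect_warning(extract_template(genome, near_end, 100L), "truncated")
})

test_that("forward primers discriminate alleles by construction", {
  inst <- random_locus_instance(401)
  tmpl <- extract_template(inst$genome, inst$locus, 600L)
  tmpl <- asppcr:::orient_template(tmpl, "+")
  fwd <- design_allele_forward(tmpl, inst$locus, "A")
  L <- nchar(fwd$seq)
  off <- tmpl$offset
  # 3'-terminal base equals allele A
  expect_equal(substr(fwd$seq, L, L), inst$locus$allele_a)
  # exactly 1 difference vs the allele-A template footprint (the
  # artificial mismatch), exactly 2 vs the allele-B footprint
  reg_a <- substr(tmpl$seq_a, off - L + 1, off)
  reg_b <- substr(tmpl$seq_b, off - L + 1, off)
  expect_equal(oracle_mismatch_count(fwd$seq, reg_a), 1L)
  expect_equal(oracle_mismatch_count(fwd$seq, reg_b), 2L)
  # the single difference sits at the third base from the 3' end
  diffs <- which(strsplit(fwd$seq, "")[[1]] != strsplit(reg_a, "")[[1]])
  expect_equal(diffs, L - 2L)
  # determinism
  fwd2 <- design_allele_forward(tmpl, inst$locus, "A")
  expect_identical(fwd, fwd2)
})

test_that("the shared reverse primer satisfies placement and Tm windows", {
  inst <- random_locus_instance(402)
  assay <- design_assay(inst$genome, inst$locus)
  dp <- design_params(); tp <- thermo_params()
  expect_gte(assay$product_size, dp$product_min)
  expect_lte(assay$product_size, dp$product_max)
  expect_lte(abs(assay$reverse$tm - tp$target_tm), tp$tm_window)
  # the reverse primer's reverse complement occurs exactly once in the
  # template forward strand (string-search oracle)
  hits <- gregexpr(revcomp(assay$reverse$seq), inst$genome[[1]],
                   fixed = TRUE)[[1]]
  expect_equal(length(hits[hits > 0]), 1L)
  # footprint excludes the SNP
  expect_false(inst$locus$pos >= hits && inst$locus$pos <=
                 hits + nchar(assay$reverse$seq) - 1L)
  # exhaustive placement oracle: no admissible placement with a smaller
  # product size (nearest-acceptable-wins)
  tmpl <- asppcr:::orient_template(
    extract_template(inst$genome, inst$locus, dp$len_max + dp$product_max),
    "+")
  f5 <- tmpl$offset - nchar(assay$fwd_a$seq) + 1L
  smaller <- 0L
  for (P in seq_len(assay$product_size - dp$product_min) +
       dp$product_min - 1L) {
    for (L in dp$len_min:dp$len_max) {
      r5 <- f5 + P - 1L
      lo <- r5 - L + 1L
      if (lo <= tmpl$offset || r5 > nchar(tmpl$seq)) next
      s <- revcomp(substr(tmpl$seq, lo, r5))
      if (abs(melting_temperature(s, tp) - tp$target_tm) <= tp$tm_window &&
          asppcr:::max_self_comp_run(s) <= dp$max_self_comp) {
        smaller <- smaller + 1L
      }
    }
  }
  expect_equal(smaller, 0L)
})

test_that("pinned product bounds give that product or infeasibility", {
  inst <- random_locus_instance(403)
  dp150 <- design_params(product_min = 150L, product_max = 150L)
  res <- tryCatch(design_assay(inst$genome, inst$locus, design = dp150),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "infeasible")
  } else {
    expect_equal(res$product_size, 150L)
  }
})

test_that("complete assays satisfy every structural invariant", {
  for (seed in 411:420) {
    inst <- random_locus_instance(seed)
    assay <- design_assay(inst$genome, inst$locus)
    fa <- assay$fwd_a$seq; fb <- assay$fwd_b$seq
    expect_equal(nchar(fa), nchar(fb))
    # identical except at the 3'-terminal base
    expect_equal(oracle_mismatch_count(fa, fb), 1L)
    expect_equal(substr(fa, nchar(fa), nchar(fa)), inst$locus$allele_a)
    expect_equal(substr(fb, nchar(fb), nchar(fb)), inst$locus$allele_b)
    # same artificial mismatch in both
    expect_identical(assay$fwd_a$mismatch, assay$fwd_b$mismatch)
    L <- nchar(fa)
    expect_equal(substr(fa, L - 2L, L - 2L),
                 assay$fwd_a$mismatch$replacement)
    # mismatch drawn from the allowed pairs
    ap <- allowed_pairs()
    mc <- assay$fwd_a$mismatch
    pair <- sort(c(mc$original, mc$replacement))
    expect_true(any(ap$base1 == pair[1] & ap$base2 == pair[2]))
    # shared reverse, not allele specific
    expect_equal(assay$reverse$allele, "none")
    expect_equal(assay$annealing_temp, 58)
  }
})

test_that("discrimination report counts equal a brute-force comparison", {
  inst <- random_locus_instance(404)
  assay <- design_assay(inst$genome, inst$locus)
  rep <- check_allele_discrimination(assay, inst$genome)
  expect_true(attr(rep, "ok"))
  expect_equal(rep$n_mismatch[rep$primer == "fwd_a"], c(1L, 2L))
  expect_equal(rep$n_mismatch[rep$primer == "fwd_b"], c(2L, 1L))
  expect_equal(rep$n_mismatch[rep$primer == "reverse"], c(0L, 0L))
  # oracle recomputation for fwd_a vs both allele templates
  tmpl <- asppcr:::orient_template(
    extract_template(inst$genome, inst$locus, 600L), "+")
  L <- nchar(assay$fwd_a$seq); off <- tmpl$offset
  expect_equal(rep$n_mismatch[rep$primer == "fwd_a" & rep$vs_allele == "A"],
               oracle_mismatch_count(assay$fwd_a$seq,
                                     substr(tmpl$seq_a, off - L + 1, off)))
  expect_equal(rep$n_mismatch[rep$primer == "fwd_a" & rep$vs_allele == "B"],
               oracle_mismatch_count(assay$fwd_a$seq,
                                     substr(tmpl$seq_b, off - L + 1, off)))
})

test_that("minus-strand design puts the allele complement at the 3' end", {
  inst <- random_locus_instance(405)
  dp <- design_params(strand = "-")
  assay <- design_assay(inst$genome, inst$locus, design = dp)
  fa <- assay$fwd_a$seq
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(substr(fa, nchar(fa), nchar(fa)),
               unname(comp[inst$locus$allele_a]))
  expect_equal(assay$fwd_a$strand, "-")
  expect_equal(assay$reverse$strand, "+")
  rep <- check_allele_discrimination(assay, inst$genome)
  expect_true(attr(rep, "ok"))
})

test_that("in-silico amplification finds the assay's own product once", {
  inst <- random_locus_instance(406)
  assay <- design_assay(inst$genome, inst$locus)
  prods <- in_silico_amplification(inst$genome, assay)
  expect_gte(nrow(prods), 1L)
  # the designed amplicon covers the SNP
  covering <- prods$start <= inst$locus$pos & prods$end >= inst$locus$pos
  expect_true(any(covering))
  # allele B's terminal base mismatches the reference, so only the
  # allele-A forward matches the reference genome at the locus
  expect_true(all(prods$fwd_primer[covering] == "fwd_a"))
})

test_that("a duplicated amplicon is reported twice, matching a naive scan", {
  inst <- random_locus_instance(407)
  assay <- design_assay(inst$genome, inst$locus)
  # duplicate the amplicon verbatim on a second contig
  prods1 <- in_silico_amplification(inst$genome, assay)
  amp <- substr(inst$genome[[1]], prods1$start[1], prods1$end[1])
  genome2 <- c(inst$genome,
               chrX = paste0(strrep("T", 300), amp, strrep("T", 300)))
  prods2 <- in_silico_amplification(genome2, assay)
  expect_equal(nrow(prods2), nrow(prods1) + sum(prods1$start == prods1$start[1]))
  expect_true("chrX" %in% prods2$chrom)
  # naive quadratic oracle on the small duplicated contig
  fwd12 <- substr(assay$fwd_a$seq, nchar(assay$fwd_a$seq) - 11,
                  nchar(assay$fwd_a$seq))
  rev12 <- substr(assay$reverse$seq, nchar(assay$reverse$seq) - 11,
                  nchar(assay$reverse$seq))
  g <- genome2[["chrX"]]
  match_wild <- function(site, pat, wild_at) {
    all(vapply(seq_len(nchar(pat)), function(k) {
      k == wild_at || substr(site, k, k) == substr(pat, k, k)
    }, NA))
  }
  naive <- 0L
  for (i in 1:(nchar(g) - 11)) {
    if (!match_wild(substr(g, i, i + 11), fwd12, 10L)) next
    for (j in (i + 12):(nchar(g) - 11)) {
      if (substr(g, j, j + 11) == revcomp(rev12) &&
          j + 11 - i + 1 <= 2000) naive <- naive + 1L
    }
  }
  expect_equal(sum(prods2$chrom == "chrX" & prods2$fwd_primer == "fwd_a" &
                     prods2$orientation == "+"), naive)
})

test_that("self-complementarity screen measures the longest palindromic run", {
  expect_equal(asppcr:::max_self_comp_run("AAAAAA"), 0L)
  # GAATTC: EcoRI site, self-reverse-complementary over all 6 bases
  expect_equal(asppcr:::max_self_comp_run("GAATTC"), 6L)
  expect_gte(asppcr:::max_self_comp_run("ACGT"), 4L)
})
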
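# Multi-locus application: genotype distances between lines,
# neighbor-joining with bootstrap support, Newick export, and the
# shared-chromosome report.

#' Distance between two codominant call vectors
#'
#' Per locus where both calls are determined: opposite homozygotes score
#' 1, identical calls 0, homozygote vs heterozygote 0.5 (a documented
#' convention: the heterozygote shares one allele with either
#' homozygote).  The distance is the mean over shared determined loci.
#'
#' @param x,y character call vectors over the same markers.
#' @param min_shared minimum number of mutually determined loci.
#' @return fraction in \[0, 1\].
#' @export
genotype_distance <- function(x, y, min_shared = 10L) {
  stopifnot(length(x) == length(y))
  keep <- x != "NN" & y != "NN"
  if (sum(keep) < min_shared) {
    stop("lines share only ", sum(keep), " determined loci (need >= ",
         min_shared, ")", call. = FALSE)
  }
  x <- x[keep]; y <- y[keep]
  d <- ifelse(x == y, 0, ifelse(x == "AB" | y == "AB", 0.5, 1))
  mean(d)
}

#' Pairwise genotype distance matrix
#'
#' @param matrix genotype matrix (lines x markers).
#' @inheritParams genotype_distance
#' @return symmetric numeric matrix with line labels.
#' @export
genotype_dist_matrix <- function(matrix, min_shared = 10L) {
  n <- nrow(matrix)
  labs <- rownames(matrix)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <-
      genotype_distance(matrix[i, ], matrix[j, ], min_shared)
  }
  d
}

#' Neighbor-joining tree
#'
#' The standard rate-corrected agglomeration: repeatedly join the pair
#' minimizing `Q(i,j) = (r - 2) d(i,j) - R(i) - R(j)`, with branch
#' lengths from the usual formulas; ties are broken by the smallest
#' (i, j) pair in the current label order, making the output
#' deterministic.  Negative branch-length estimates are clamped to zero
#' with a warning.
#'
#' @param d symmetric distance matrix with row/column labels (n >= 3).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with a zero diagonal",
         call. = FALSE)
  }
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  fmt <- function(lab, len) sprintf("%s:%.10g", lab, clamp(len))
  # each active cluster is a growing Newick fragment
  labs <- rownames(d)
  repeat {
    r <- nrow(d)
    if (r == 3L) break
    R <- rowSums(d)
    q_best <- Inf; bi <- bj <- NA_integer_
    for (i in 1:(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * d[i, j] - R[i] - R[j]
      if (q < q_best - 1e-12) { q_best <- q; bi <- i; bj <- j }
    }
    li <- d[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (r - 2))
    lj <- d[bi, bj] - li
    new_lab <- sprintf("(%s,%s)", fmt(labs[bi], li), fmt(labs[bj], lj))
    dn <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(r), c(bi, bj))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    labs <- c(labs[keep], new_lab)
    dimnames(d2) <- list(labs, labs)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s,%s,%s);", fmt(labs[1], la), fmt(labs[2], lb),
                 fmt(labs[3], lc))
  if (clamped) {
    warning("negative neighbor-joining branch length(s) clamped to 0",
            call. = FALSE)
  }
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data tree, then resamples marker columns with
#' replacement `n_reps` times (columns are taken in sorted marker-name
#' order, so support is invariant to input column order), rebuilds the
#' tree per replicate, and counts for each internal edge of the
#' full-data tree the replicates containing the same bipartition.
#' Support counts are stored as internal node labels.
#'
#' @param matrix genotype matrix (lines x markers), >= 3 lines and >= 2
#'   markers.
#' @param n_reps bootstrap replicate count (0 returns the full-data tree
#'   with no support labels).
#' @param seed RNG seed for the resampling.
#' @inheritParams genotype_distance
#' @return an `ape::phylo` tree; `node.label` holds bootstrap counts.
#' @export
bootstrap_tree <- function(matrix, n_reps = 1000L, seed = 1L,
                           min_shared = 10L) {
  stopifnot(nrow(matrix) >= 3L, ncol(matrix) >= 2L)
  matrix <- matrix[, order(colnames(matrix)), drop = FALSE]
  full <- neighbor_joining(genotype_dist_matrix(matrix, min_shared))
  if (n_reps == 0L) return(full)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(k) {
      cols <- sample.int(ncol(matrix), replace = TRUE)
      suppressWarnings(
        neighbor_joining(genotype_dist_matrix(matrix[, cols, drop = FALSE],
                                              min_shared)))
    })
  })
  support <- ape::prop.clades(full, reps, rooted = FALSE)
  support[is.na(support)] <- 0L
  full$node.label <- as.character(support)
  # the root of the unrooted representation carries no bipartition
  full$node.label[1L] <- ""
  full
}

#' Write a tree to a Newick file
#'
#' Bootstrap supports (node labels) are written as internal node labels;
#' taxon labels containing whitespace or Newick metacharacters are
#' single-quoted.
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  needs_quote <- which(grepl("[][(),:;' \t]", tree$tip.label))
  orig <- tree$tip.label[needs_quote]
  tokens <- sprintf("xQUOTEDx%dx", seq_along(needs_quote))
  tree$tip.label[needs_quote] <- tokens
  txt <- ape::write.tree(tree)
  for (k in seq_along(tokens)) {
    quoted <- paste0("'", gsub("'", "''", orig[k]), "'")
    txt <- sub(tokens[k], quoted, txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Report chromosomes with identical SNP patterns across lines
#'
#' For each chromosome, groups lines whose genotype vectors over that
#' chromosome's markers are exactly equal (undetermined calls must match
#' too); only groups of two or more lines are reported.
#'
#' @param matrix genotype matrix (lines x markers).
#' @param snps a `snp_table` assigning markers to chromosomes.
#' @return data.frame: `chrom`, `lines` (comma-separated), `n_lines`.
#' @export
shared_chromosomes <- function(matrix, snps) {
  out <- list()
  for (ch in unique(snps$chrom)) {
    mk <- intersect(snps$name[snps$chrom == ch], colnames(matrix))
    if (length(mk) == 0L) next
    sig <- apply(matrix[, mk, drop = FALSE], 1L, paste, collapse = "")
    for (grp in split(names(sig), sig)) {
      if (length(grp) >= 2L) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, lines = paste(sort(grp), collapse = ","),
          n_lines = length(grp), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), lines = character(0),
                      n_lines = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
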
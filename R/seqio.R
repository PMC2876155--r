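# File IO for the formats the toolkit touches: FASTA references, SNP
# tables (VCF or TSV), assay tables, fluorescence plate CSVs and genotype
# matrices.  Coordinates are 1-based, inclusive, forward strand (VCF
# convention).

#' Read a FASTA reference
#'
#' @param path FASTA file.
#' @return named character vector: sequence id (up to first whitespace) ->
#'   uppercase nucleotide string, multi-line records concatenated.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (line 1): expected a '>' header, got: ",
         substr(first, 1L, 40L), call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

new_snp_table <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("snp_table", "data.frame"))
}

validate_snp_table <- function(df) {
  for (col in c("allele_a", "allele_b")) {
    bad <- !df[[col]] %in% BASES
    if (any(bad)) {
      stop("non-ACGT allele for marker(s): ",
           paste(df$name[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (any(df$allele_a == df$allele_b)) {
    stop("allele_a equals allele_b for marker(s): ",
         paste(df$name[df$allele_a == df$allele_b], collapse = ", "),
         call. = FALSE)
  }
  if (any(df$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    stop("duplicate marker position(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Read a SNP marker table
#'
#' Accepts either a TSV with header columns
#' `name, chrom, pos, allele_a, allele_b` (optional `cm`, `mbp`) or a VCF
#' 4.x file restricted to biallelic SNP records.  Positions are 1-based.
#' Output is sorted by (chrom, pos) regardless of input order; duplicate
#' (chrom, pos) rows are rejected.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`; default guessed from the extension.
#' @param skip_invalid if `TRUE`, non-SNP VCF records (indels,
#'   multiallelic sites) are dropped with a warning instead of an error.
#' @return data.frame of class `snp_table` with columns `name`, `chrom`,
#'   `pos`, `allele_a`, `allele_b`, `cm`, `mbp` (the last two may be NA).
#' @export
read_snp_table <- function(path, dialect = NULL, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "vcf"))
  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
    ok <- ref %in% BASES & alt %in% BASES
    if (any(!ok)) {
      msg <- paste0("unsupported variant record(s) (indel or multiallelic): ",
                    paste(sprintf("%s:%s", fix$CHROM[!ok], fix$POS[!ok]),
                          collapse = ", "))
      if (skip_invalid) warning(msg, call. = FALSE) else
        stop(msg, call. = FALSE)
    }
    fix <- fix[ok, , drop = FALSE]
    nm <- fix$ID
    nm[is.na(nm) | nm == "."] <-
      sprintf("%s_%s", fix$CHROM, fix$POS)[is.na(nm) | nm == "."]
    df <- data.frame(name = nm, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     allele_a = toupper(fix$REF),
                     allele_b = toupper(fix$ALT),
                     cm = NA_real_, mbp = NA_real_, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    need <- c("name", "chrom", "pos", "allele_a", "allele_b")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("SNP TSV is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (!"cm" %in% names(df)) df$cm <- NA_real_
    if (!"mbp" %in% names(df)) df$mbp <- NA_real_
    df <- df[c(need, "cm", "mbp")]
    df$pos <- as.integer(df$pos)
    df$chrom <- as.character(df$chrom)
    df$allele_a <- toupper(df$allele_a)
    df$allele_b <- toupper(df$allele_b)
  }
  new_snp_table(validate_snp_table(df))
}

#' Write a SNP marker table (TSV dialect)
#'
#' @param snps a `snp_table` data.frame.
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read endpoint-fluorescence plate data
#'
#' Joins a plate CSV to a plate layout.  Two CSV dialects are
#' auto-detected from the header: long format
#' (`plate, well, channel, intensity`) and the two-column format
#' (`plate, well, intensity`) where the channel is implied by the layout.
#' Every layout well must appear at most once; layout wells absent from
#' the CSV are returned with NA intensity and flagged missing.
#'
#' @param path CSV file.
#' @param layout a [make_layout()] layout.
#' @return data.frame: `plate, well, sample, marker, channel, intensity,
#'   missing`; attribute `n_missing`.
#' @export
read_plate_csv <- function(path, layout) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  need <- c("plate", "well", "intensity")
  miss <- setdiff(need, names(dat))
  if (length(miss) > 0L) {
    stop("plate CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_well <- !is_valid_well(dat$well)
  if (any(bad_well)) {
    stop("invalid well coordinate(s): ",
         paste(unique(dat$well[bad_well]), collapse = ", "), call. = FALSE)
  }
  if (any(dat$intensity < 0, na.rm = TRUE)) {
    stop("negative fluorescence intensity in ", path, call. = FALSE)
  }
  key_dat <- paste(dat$plate, dat$well)
  key_lay <- paste(layout$plate, layout$well)
  unknown <- !key_dat %in% key_lay
  if (any(unknown)) {
    stop("well(s) not in layout: ",
         paste(unique(key_dat[unknown]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(key_dat)) {
    stop("duplicated well row(s): ",
         paste(unique(key_dat[duplicated(key_dat)]), collapse = ", "),
         call. = FALSE)
  }
  if ("channel" %in% names(dat)) {
    mism <- dat$channel != layout$channel[match(key_dat, key_lay)]
    if (any(mism)) {
      stop("channel column disagrees with layout for well(s): ",
           paste(key_dat[mism], collapse = ", "), call. = FALSE)
    }
  }
  out <- layout
  out$intensity <- dat$intensity[match(key_lay, key_dat)]
  out$missing <- is.na(out$intensity)
  attr(out, "n_missing") <- sum(out$missing)
  out
}

#' Write designed ASP assays to a TSV file
#'
#' One row per assay: marker identity, both allele-specific forward
#' primers, the shared reverse primer, their Tm values, product size,
#' annealing temperature and the artificial mismatch applied.  The format
#' round-trips losslessly through [read_assays()].
#'
#' @param assays list of `asp_assay` objects from [design_assay()].
#' @param path output path.
#' @export
write_assays <- function(assays, path) {
  cols <- c("marker", "chrom", "pos", "allele_a", "allele_b",
            "fwd_a_seq", "fwd_a_tm", "fwd_b_seq", "fwd_b_tm",
            "reverse_seq", "reverse_tm", "product_size", "annealing_temp",
            "mismatch_original", "mismatch_replacement", "strand")
  rows <- lapply(assays, function(a) {
    data.frame(marker = a$locus$name, chrom = a$locus$chrom,
               pos = a$locus$pos, allele_a = a$locus$allele_a,
               allele_b = a$locus$allele_b,
               fwd_a_seq = a$fwd_a$seq, fwd_a_tm = a$fwd_a$tm,
               fwd_b_seq = a$fwd_b$seq, fwd_b_tm = a$fwd_b$tm,
               reverse_seq = a$reverse$seq, reverse_tm = a$reverse$tm,
               product_size = a$product_size,
               annealing_temp = a$annealing_temp,
               mismatch_original = a$fwd_a$mismatch$original,
               mismatch_replacement = a$fwd_a$mismatch$replacement,
               strand = a$fwd_a$strand, stringsAsFactors = FALSE)
  })
  df <- if (length(rows) == 0L) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assay TSV written by [write_assays()]
#'
#' @param path assay TSV.
#' @return data.frame, one row per assay.
#' @export
read_assays <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = c(chrom = "character",
                                   allele_a = "character",
                                   allele_b = "character",
                                   mismatch_original = "character",
                                   mismatch_replacement = "character",
                                   strand = "character"))
}

#' Read/write a genotype matrix TSV
#'
#' Rows are samples, columns are markers, cells in `{AA, BB, AB, NN}`
#' (`NN` = no call).
#'
#' @param path TSV file; first column `sample`, remaining columns markers.
#' @return character matrix with sample rownames and marker colnames.
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  if (names(df)[1L] != "sample") {
    stop("genotype matrix TSV must start with a 'sample' column",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample
  bad <- !m %in% CALLS
  if (any(bad)) {
    stop("invalid genotype call value(s): ",
         paste(unique(m[bad]), collapse = ", "), call. = FALSE)
  }
  m
}

#' @rdname read_genotype_matrix
#' @param matrix character genotype matrix (samples x markers).
#' @export
write_genotype_matrix <- function(matrix, path) {
  df <- data.frame(sample = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
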
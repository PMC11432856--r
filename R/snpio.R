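#' Write the SNP matrix as a concatenated-SNP multi-FASTA
#'
#' One record per accession; the sequence is the concatenation of the called
#' bases at the retained polymorphic sites, in reference-position order.
#' Positions are recorded in the header line of the first record's description
#' only via the side file written by [write_snp_positions()]; the FASTA itself
#' carries plain accession ids so it can feed external alignment/tree tools.
#'
#' @param sm A [snp_matrix()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_snp_fasta <- function(sm, path) {
  stopifnot(inherits(sm, "snp_matrix"))
  seqs <- apply(sm$calls, 1L, paste, collapse = "")
  if (ncol(sm$calls) == 0L) seqs <- setNames(rep("", nrow(sm$calls)), sm$accessions)
  x <- Biostrings::BStringSet(seqs)
  names(x) <- sm$accessions
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a concatenated-SNP multi-FASTA
#'
#' @param path FASTA path.
#' @param positions Optional 1-based reference positions for the columns;
#'   defaults to 1..n.
#' @return A [snp_matrix()].
#' @export
read_snp_fasta <- function(path, positions = NULL) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  lens <- unique(nchar(seqs))
  if (length(lens) > 1) stop("unequal sequence lengths in ", path)
  n_sites <- if (length(lens)) lens else 0L
  calls <- matrix(NA_character_, length(seqs), n_sites,
                  dimnames = list(names(x), NULL))
  if (n_sites > 0) {
    for (i in seq_along(seqs)) calls[i, ] <- strsplit(seqs[[i]], "")[[1]]
  }
  if (is.null(positions)) positions <- seq_len(n_sites)
  snp_matrix(calls = calls, positions = positions)
}

#' Write SNP-site reference positions
#' @param sm A [snp_matrix()].
#' @param path Output TSV path.
#' @export
write_snp_positions <- function(sm, path) {
  data.table::fwrite(data.table::data.table(pos = sm$positions), path, sep = "\t")
  invisible(path)
}

#' Write the SNP matrix as VCF v4.2
#'
#' One record per retained site with the original reference coordinate, the
#' reference base as REF and every other observed base as ALT, and one
#' haploid GT sample column per accession (0 = REF, 1.. = ALT index).
#'
#' @param sm A [snp_matrix()].
#' @param reference Character vector of reference bases covering the genome
#'   (indexed by `sm$positions`), or a vector of per-site reference bases of
#'   length `ncol(sm$calls)`.
#' @param path Output VCF path.
#' @param chrom CHROM field value (reference sequence id).
#' @param reference_length Genome length for the `##contig` header; inferred
#'   from `reference` when it covers the genome.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(sm, reference, path, chrom = "mito_ref",
                          reference_length = NULL) {
  stopifnot(inherits(sm, "snp_matrix"))
  n_sites <- ncol(sm$calls)
  ref_bases <- if (length(reference) == n_sites) reference else reference[sm$positions]
  if (anyNA(ref_bases)) stop("reference does not cover all SNP positions")
  if (is.null(reference_length)) {
    reference_length <- if (length(reference) > n_sites) length(reference) else
      max(sm$positions, 1L)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mitovar",
    sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(reference_length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sm$accessions), collapse = "\t")
  )
  lines <- character(n_sites)
  for (j in seq_len(n_sites)) {
    ref <- ref_bases[j]
    col <- sm$calls[, j]
    alts <- sort(setdiff(unique(col), ref))
    if (length(alts) == 0L) alts <- "."
    alleles <- c(ref, alts)
    gt <- match(col, alleles) - 1L
    lines[j] <- paste(c(chrom, sm$positions[j], ".", ref,
                        paste(alts, collapse = ","), ".", "PASS", ".", "GT",
                        as.character(gt)), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF written by [write_snp_vcf()] back into a SNP matrix
#'
#' @param path VCF path.
#' @return A [snp_matrix()] (plus attribute `ref_bases` with the REF column).
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  head_line <- body[1]
  if (!startsWith(head_line, "#CHROM")) stop("missing #CHROM header in ", path)
  cols <- strsplit(sub("^#", "", head_line), "\t")[[1]]
  samples <- cols[-(1:9)]
  recs <- body[-1]
  n <- length(recs)
  calls <- matrix(NA_character_, length(samples), n,
                  dimnames = list(samples, NULL))
  positions <- integer(n)
  ref_bases <- character(n)
  for (j in seq_len(n)) {
    f <- strsplit(recs[j], "\t")[[1]]
    positions[j] <- as.integer(f[2])
    ref_bases[j] <- f[4]
    alts <- if (f[5] == ".") character(0) else strsplit(f[5], ",")[[1]]
    alleles <- c(f[4], alts)
    gt <- as.integer(f[-(1:9)])
    calls[, j] <- alleles[gt + 1L]
  }
  sm <- snp_matrix(calls = calls, positions = positions)
  attr(sm, "ref_bases") <- ref_bases
  sm
}

#' Write / read a reference sequence as FASTA
#' @param sequence Character vector of bases or character scalar.
#' @param path FASTA path.
#' @param name Sequence id.
#' @return `write_reference_fasta` returns `path`; `read_reference_fasta`
#'   returns a character vector of single bases.
#' @export
write_reference_fasta <- function(sequence, path, name = "mito_ref") {
  if (length(sequence) > 1) sequence <- paste(sequence, collapse = "")
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  strsplit(as.character(x[[1]]), "")[[1]]
}
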
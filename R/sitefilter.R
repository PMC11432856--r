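#' Filtering configuration for consensus calling
#'
#' Defaults encode the contamination-aware retention rule for plant
#' mitochondrial pileups: read depths at or below `min_depth_exclusive` are
#' NUMT-class artifacts, depths at or above `max_depth_exclusive` are
#' plastid-class artifacts, and consensus frequencies at or below
#' `min_consensus_freq_exclusive` indicate mixed mapping; all three are
#' treated as missing data. Both boundaries are exclusive: depth 20 and depth
#' 900 are dropped, a consensus frequency of exactly 0.80 is dropped.
#'
#' @param min_depth_exclusive Retain only depths strictly above this value.
#' @param max_depth_exclusive Retain only depths strictly below this value.
#' @param min_consensus_freq_exclusive Retain only consensus frequencies
#'   strictly above this value.
#' @param window_size Window size in bp for [window_snp_density()].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth_exclusive = 20,
                          max_depth_exclusive = 900,
                          min_consensus_freq_exclusive = 0.80,
                          window_size = 1000L) {
  stopifnot(min_depth_exclusive >= 0,
            min_depth_exclusive < max_depth_exclusive,
            min_consensus_freq_exclusive > 0.5,
            min_consensus_freq_exclusive < 1,
            window_size >= 1)
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 max_depth_exclusive = max_depth_exclusive,
                 min_consensus_freq_exclusive = min_consensus_freq_exclusive,
                 window_size = as.integer(window_size)),
            class = "filter_config")
}

#' Classify a site's read depth
#'
#' @param depth Non-negative read depth (vectorised).
#' @param cfg A [filter_config()].
#' @return Character vector in `{"retain", "drop_low", "drop_high"}`;
#'   `retain` iff `min_depth_exclusive < depth < max_depth_exclusive`.
#' @export
classify_site_depth <- function(depth, cfg = filter_config()) {
  if (any(depth < 0)) stop("depth must be non-negative")
  out <- rep("retain", length(depth))
  out[depth <= cfg$min_depth_exclusive] <- "drop_low"
  out[depth >= cfg$max_depth_exclusive] <- "drop_high"
  out
}

#' Call the consensus base at one site
#'
#' The consensus is the most frequent base; its frequency is the consensus
#' count over total depth (base counts plus indel reads). The call is missing
#' when indel-supporting reads are the plurality (`indel_majority`) or when
#' the consensus frequency is at or below the threshold (`low_consensus`).
#' Indel reads count toward depth but never toward consensus identity.
#'
#' @param base_counts Numeric vector of counts named A, C, G, T.
#' @param indel_count Count of indel-supporting reads.
#' @param cfg A [filter_config()].
#' @return List with `base` (A/C/G/T or NA), `freq` (consensus frequency) and
#'   `flag` (`"retained"`, `"low_consensus"` or `"indel_majority"`).
#' @export
call_consensus <- function(base_counts, indel_count = 0, cfg = filter_config()) {
  total <- sum(base_counts) + indel_count
  if (total <= 0) stop("all-zero counts: depth-filter sites before calling")
  top <- which.max(base_counts)  # first maximum; ties can never be retained
  freq <- base_counts[[top]] / total
  if (indel_count > max(base_counts)) {
    return(list(base = NA_character_, freq = freq, flag = "indel_majority"))
  }
  if (freq <= cfg$min_consensus_freq_exclusive) {
    return(list(base = NA_character_, freq = freq, flag = "low_consensus"))
  }
  list(base = names(base_counts)[top], freq = freq, flag = "retained")
}

# Vectorised consensus over a site_table; returns list(base, freq, flag)
# with flag in retained/depth_low/depth_high/low_consensus/indel_majority.
consensus_calls <- function(st, cfg) {
  counts <- st$base_counts
  depth <- st$depth
  n <- length(depth)
  top_idx <- max.col(counts, ties.method = "first")
  top_count <- counts[cbind(seq_len(n), top_idx)]
  freq <- ifelse(depth > 0, top_count / depth, 0)
  base <- DNA_BASES[top_idx]
  flag <- rep("retained", n)
  flag[freq <= cfg$min_consensus_freq_exclusive] <- "low_consensus"
  flag[st$indel_count > top_count] <- "indel_majority"
  dc <- classify_site_depth(depth, cfg)
  flag[dc == "drop_low"] <- "depth_low"
  flag[dc == "drop_high"] <- "depth_high"
  base[flag != "retained"] <- NA_character_
  list(base = base, freq = freq, flag = flag)
}

#' Refine a reference sequence from a deep pileup
#'
#' At sites whose depth and consensus pass the retention rule, the reference
#' base is replaced by the consensus base; at all other sites (including
#' plastid-depth and NUMT-depth artifacts) the original base is kept, so
#' high-depth cpDNA alleles never enter the refined reference.
#'
#' @param st A [site_table()] covering the full reference.
#' @param reference Character vector of reference bases (length = n sites).
#' @param cfg A [filter_config()]. For reference refinement a looser plastid
#'   bound (e.g. `max_depth_exclusive = 10000`) can be supplied.
#' @return List with `sequence` (corrected character vector) and `changes`
#'   (data.frame pos/old/new).
#' @export
refine_reference <- function(st, reference, cfg = filter_config()) {
  if (length(reference) != length(st$pos)) {
    stop("site table and reference have different lengths")
  }
  calls <- consensus_calls(st, cfg)
  corrected <- reference
  ok <- calls$flag == "retained" & calls$base != reference
  corrected[ok] <- calls$base[ok]
  changes <- data.frame(pos = st$pos[ok], old = reference[ok],
                        new = calls$base[ok])
  list(sequence = corrected, changes = changes)
}

#' Build the accession x position consensus matrix
#'
#' Applies depth classification then consensus calling to every accession and
#' site. Missing calls carry a provenance flag: `depth_low`, `depth_high`,
#' `low_consensus` or `indel_majority`.
#'
#' @param site_tables Named list of [site_table()] objects on a shared
#'   reference coordinate system.
#' @param cfg A [filter_config()].
#' @return An object of class `consensus_matrix`: list with `calls`
#'   (character matrix, NA = missing), `flags` (character matrix) and
#'   `positions`.
#' @export
build_consensus_matrix <- function(site_tables, cfg = filter_config()) {
  ids <- vapply(site_tables, function(s) s$accession_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate accession ids")
  pos <- site_tables[[1]]$pos
  for (s in site_tables) {
    if (!identical(s$pos, pos)) stop("site tables disagree on reference positions")
  }
  n <- length(ids)
  calls <- matrix(NA_character_, n, length(pos), dimnames = list(ids, NULL))
  flags <- matrix("retained", n, length(pos), dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    cc <- consensus_calls(site_tables[[i]], cfg)
    calls[i, ] <- cc$base
    flags[i, ] <- cc$flag
  }
  structure(list(calls = calls, flags = flags, positions = pos),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("consensus_matrix:", nrow(x$calls), "accessions x", ncol(x$calls),
      "sites;", sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' Extract polymorphic sites shared by all accessions
#'
#' A column is retained iff no accession is missing there and at least two
#' distinct bases occur; missing data is evaluated before polymorphism, so a
#' site that is variant only through a missing accession is dropped as
#' missing, never counted as a SNP. Columns are ordered by reference
#' position.
#'
#' @param cm A `consensus_matrix`.
#' @return An object of class `snp_matrix`: list with `calls` (character
#'   matrix accessions x retained sites), `positions` (1-based reference
#'   positions) and `accessions`.
#' @export
extract_snp_sites <- function(cm) {
  stopifnot(inherits(cm, "consensus_matrix"))
  complete <- colSums(is.na(cm$calls)) == 0L
  n_alleles <- apply(cm$calls, 2L, function(col) length(unique(col[!is.na(col)])))
  keep <- complete & n_alleles >= 2L
  snp_matrix(calls = cm$calls[, keep, drop = FALSE],
             positions = cm$positions[keep])
}

#' SNP matrix container
#'
#' @param calls Character matrix (accessions x sites) of A/C/G/T with row
#'   names = accession ids; no missing entries allowed.
#' @param positions Integer vector of 1-based reference positions, strictly
#'   increasing, one per column.
#' @return Object of class `snp_matrix`.
#' @export
snp_matrix <- function(calls, positions) {
  positions <- as.integer(positions)
  stopifnot(is.matrix(calls), length(positions) == ncol(calls),
            !is.null(rownames(calls)))
  if (anyNA(calls)) stop("snp_matrix cannot contain missing calls")
  if (ncol(calls) > 1 && any(diff(positions) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  structure(list(calls = calls, positions = positions,
                 accessions = rownames(calls)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix:", nrow(x$calls), "accessions x", ncol(x$calls), "SNP sites\n")
  invisible(x)
}

#' Count SNPs in non-overlapping windows along the reference
#'
#' Windows are anchored at position 1 and 1-based inclusive: 1-1000,
#' 1001-2000, ... for the default 1000-bp size; the last window may be short.
#'
#' @param positions 1-based SNP positions.
#' @param reference_length Reference length in bp.
#' @param window_size Window width in bp.
#' @return data.frame with `start`, `end` and `n_snps`; counts sum to
#'   `length(positions)`.
#' @export
window_snp_density <- function(positions, reference_length, window_size = 1000L) {
  if (length(positions) && (min(positions) < 1 || max(positions) > reference_length)) {
    stop("SNP positions out of range [1, reference_length]")
  }
  reference_length <- as.integer(reference_length)
  window_size <- as.integer(window_size)
  n_win <- as.integer(ceiling(reference_length / window_size))
  start <- (seq_len(n_win) - 1L) * window_size + 1L
  end <- pmin(start + window_size - 1L, reference_length)
  idx <- (as.integer(positions) - 1L) %/% window_size + 1L
  counts <- tabulate(idx, nbins = n_win)
  data.frame(start = start, end = end, n_snps = counts)
}
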
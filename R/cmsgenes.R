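#' CMS-gene query
#'
#' A query sequence for presence/absence screening, e.g. the 1161-bp
#' NH2-extension of atp6 (preSatp6) diagnostic for Owen-type cytoplasmic male
#' sterility, orf129 (E-type) or the cox1 NH2-extension (G-type).
#'
#' @param name Query name.
#' @param sequence DNA string (A/C/G/T only; ambiguity codes rejected).
#' @return Object of class `gene_query` with `full_length = nchar(sequence)`.
#' @export
gene_query <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("query must contain only A/C/G/T")
  structure(list(name = name, sequence = sequence,
                 full_length = nchar(sequence)),
            class = "gene_query")
}

#' Classification thresholds for gene hits
#'
#' The printed decision rule: a hit at the query's full alignment length with
#' at most `max_mismatches_present` mismatches means the gene is present; a
#' shorter alignment with at least `min_mismatches_like` mismatches is a
#' diverged homologue ("-like"). Everything in between is ambiguous.
#'
#' @param max_mismatches_present Mismatch ceiling for "present" (default 3).
#' @param min_mismatches_like Mismatch floor for "like" (default 8).
#' @param min_identity_report Minimum identity for reporting any hit.
#' @return Object of class `classify_config`.
#' @export
classify_config <- function(max_mismatches_present = 3L,
                            min_mismatches_like = 8L,
                            min_identity_report = 0.7) {
  stopifnot(max_mismatches_present < min_mismatches_like)
  structure(list(max_mismatches_present = as.integer(max_mismatches_present),
                 min_mismatches_like = as.integer(min_mismatches_like),
                 min_identity_report = min_identity_report),
            class = "classify_config")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Search contigs for the best local alignment of a gene query
#'
#' Seed-and-extend local alignment on both strands: exact k-mer seeds locate
#' candidate diagonals, ungapped X-drop extension scores each diagonal
#' (match +1, mismatch -2), and the maximal-scoring segment on the best
#' diagonals is refined by banded dynamic programming with affine gaps
#' (open -5, extend -2). The best hit maximises alignment length (the aligned
#' query span), then minimises mismatches; gap columns are excluded from the
#' mismatch count. No hit is returned when identity falls below
#' `min_identity_report`.
#'
#' @param contigs Named character vector of contig sequences.
#' @param query A [gene_query()].
#' @param k Seed length.
#' @param cfg A [classify_config()] (for the reporting threshold).
#' @param band Half-width of the DP band around the seeded diagonal.
#' @return A `gene_hit` list (query, contig, start, end, strand,
#'   alignment_length, mismatches, identity) or `NULL` when nothing aligns.
#' @export
search_gene <- function(contigs, query, k = 15L, cfg = classify_config(),
                        band = 16L) {
  stopifnot(inherits(query, "gene_query"), length(contigs) > 0)
  if (is.null(names(contigs))) names(contigs) <- paste0("contig", seq_along(contigs))
  best <- NULL
  for (cid in names(contigs)) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") contigs[[cid]] else revcomp(contigs[[cid]])
      hit <- align_query(query$sequence, subject, k = k, band = band)
      if (is.null(hit)) next
      hit$contig <- cid
      hit$strand <- strand
      if (strand == "-") {
        clen <- nchar(subject)
        s <- clen - hit$end + 1L
        e <- clen - hit$start + 1L
        hit$start <- s; hit$end <- e
      }
      if (is.null(best) ||
          hit$alignment_length > best$alignment_length ||
          (hit$alignment_length == best$alignment_length &&
           hit$mismatches < best$mismatches)) {
        best <- hit
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (best$identity < cfg$min_identity_report) return(NULL)
  best$query <- query$name
  class(best) <- "gene_hit"
  best
}

# Seed-and-extend on one strand. Returns the single best local hit or NULL.
align_query <- function(qseq, sseq, k = 15L, band = 16L, xdrop = 20L) {
  q <- strsplit(qseq, "")[[1]]
  s <- strsplit(sseq, "")[[1]]
  qlen <- length(q); slen <- length(s)
  if (slen < k || qlen < k) return(NULL)

  # hash subject k-mers
  n_kmers <- slen - k + 1L
  skmers <- substring(sseq, seq_len(n_kmers), seq_len(n_kmers) + k - 1L)
  kmer_index <- split(seq_len(n_kmers), skmers)

  # collect candidate diagonals (subject_pos - query_pos) from seed matches
  diags <- integer(0)
  qstarts <- seq(1L, qlen - k + 1L, by = max(1L, k %/% 2L))
  for (qs in qstarts) {
    kmer <- substr(qseq, qs, qs + k - 1L)
    hitpos <- kmer_index[[kmer]]
    if (!is.null(hitpos)) diags <- c(diags, hitpos - qs)
  }
  if (!length(diags)) return(NULL)
  diag_tab <- sort(table(diags), decreasing = TRUE)
  cand <- as.integer(names(diag_tab))[seq_len(min(3L, length(diag_tab)))]

  best <- NULL
  for (dg in cand) {
    # ungapped scoring along the diagonal: find the maximal scoring segment
    q_from <- max(1L, 1L - dg)
    q_to <- min(qlen, slen - dg)
    if (q_to - q_from + 1L < k) next
    qs <- q[q_from:q_to]
    ss <- s[(q_from + dg):(q_to + dg)]
    score <- ifelse(qs == ss, 1, -2)
    seg <- max_scoring_segment(score)
    if (is.null(seg)) next
    mism <- sum(qs[seg$from:seg$to] != ss[seg$from:seg$to])
    aln_len <- seg$to - seg$from + 1L
    hit <- list(
      q_start = q_from + seg$from - 1L,
      q_end = q_from + seg$to - 1L,
      start = q_from + seg$from - 1L + dg,
      end = q_from + seg$to - 1L + dg,
      alignment_length = aln_len,
      mismatches = mism,
      identity = 1 - mism / aln_len,
      score = seg$score
    )
    if (is.null(best) || hit$score > best$score) best <- hit
  }
  if (is.null(best)) return(NULL)
  # banded gapped refinement around the best diagonal hit; on substitution-only
  # inserts the ungapped segment is already optimal (every gap pair costs more
  # than the mismatches it could save), so refinement is only attempted when
  # the ungapped alignment leaves room for an indel to pay off
  if (best$identity < 0.98 || best$alignment_length < length(q) %/% 2L) {
    refined <- banded_local_dp(q, s, best, band = band)
    if (!is.null(refined) && refined$score > best$score) best <- refined
  }
  best[c("start", "end", "alignment_length", "mismatches", "identity",
         "q_start", "q_end", "score")]
}

# Kadane's algorithm: maximal-sum contiguous segment; NULL if all negative.
max_scoring_segment <- function(score) {
  best_sum <- -Inf; best_from <- 1L; best_to <- 0L
  cur <- 0; cur_from <- 1L
  for (i in seq_along(score)) {
    if (cur <= 0) { cur <- 0; cur_from <- i }
    cur <- cur + score[i]
    if (cur > best_sum) { best_sum <- cur; best_from <- cur_from; best_to <- i }
  }
  if (best_sum <= 0) return(NULL)
  list(from = best_from, to = best_to, score = best_sum)
}

# Banded Smith-Waterman (affine gaps) restricted to a band around the seeded
# diagonal. Traceback reports aligned query span, mismatches (gap columns
# excluded) and subject interval.
banded_local_dp <- function(q, s, seed_hit, band = 16L,
                            match = 1, mismatch = -2, gap_open = -5,
                            gap_extend = -2) {
  dg <- seed_hit$start - seed_hit$q_start
  qlen <- length(q); slen <- length(s)
  s_lo <- max(1L, 1L + dg - band)
  s_hi <- min(slen, qlen + dg + band)
  sw <- s[s_lo:s_hi]
  m <- length(sw); n <- qlen
  NEG <- -1e9
  # full DP over query x windowed subject with band constraint
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in query (subject consumed)
  Fm <- matrix(NEG, n + 1L, m + 1L) # gap in subject (query consumed)
  ptr <- matrix(0L, n + 1L, m + 1L) # 1 diag, 2 up(E? naming below), 3 left
  best_score <- 0; best_cell <- c(1L, 1L)
  for (i in seq_len(n)) {
    j_center <- i + dg - s_lo + 1L
    j_from <- max(1L, j_center - band)
    j_to <- min(m, j_center + band)
    for (j in j_from:j_to) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] + gap_open, E[i + 1L, j] + gap_extend)
      Fm[i + 1L, j + 1L] <- max(H[i, j + 1L] + gap_open, Fm[i, j + 1L] + gap_extend)
      sub <- H[i, j] + if (q[i] == sw[j]) match else mismatch
      h <- max(0, sub, E[i + 1L, j + 1L], Fm[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      ptr[i + 1L, j + 1L] <- if (h == 0) 0L else if (h == sub) 1L else
        if (h == E[i + 1L, j + 1L]) 3L else 2L
      if (h > best_score) { best_score <- h; best_cell <- c(i + 1L, j + 1L) }
    }
  }
  if (best_score <= 0) return(NULL)
  # traceback
  i <- best_cell[1]; j <- best_cell[2]
  q_end <- i - 1L; s_end <- j - 1L
  mism <- 0L
  while (i > 1L && j > 1L && H[i, j] > 0) {
    p <- ptr[i, j]
    if (p == 1L) {
      if (q[i - 1L] != sw[j - 1L]) mism <- mism + 1L
      i <- i - 1L; j <- j - 1L
    } else if (p == 3L) {
      j <- j - 1L
    } else if (p == 2L) {
      i <- i - 1L
    } else break
  }
  q_start <- i; s_start <- j
  aln_len <- q_end - q_start + 1L
  list(q_start = q_start, q_end = q_end,
       start = s_lo + s_start - 1L, end = s_lo + s_end - 1L,
       alignment_length = aln_len, mismatches = mism,
       identity = 1 - mism / max(1L, aln_len), score = best_score)
}

#' Classify a gene hit by the alignment-length / mismatch rule
#'
#' @param hit A `gene_hit` from [search_gene()] or `NULL`.
#' @param query The [gene_query()] searched for.
#' @param cfg A [classify_config()].
#' @return One of `"present"` (full-length alignment, mismatches <=
#'   `max_mismatches_present`), `"like"` (shorter alignment with mismatches >=
#'   `min_mismatches_like`), `"absent"` (no hit) or `"ambiguous"` (falls
#'   outside both printed regimes).
#' @export
classify_hit <- function(hit, query, cfg = classify_config()) {
  if (is.null(hit)) return("absent")
  stopifnot(hit$alignment_length <= query$full_length,
            hit$mismatches <= hit$alignment_length)
  if (hit$alignment_length == query$full_length &&
      hit$mismatches <= cfg$max_mismatches_present) return("present")
  if (hit$alignment_length < query$full_length &&
      hit$mismatches >= cfg$min_mismatches_like) return("like")
  "ambiguous"
}

#' Screen a cohort of contig sets for CMS-associated genes
#'
#' @param contig_sets Named list (accession -> named character vector of
#'   contigs); an accession with `NULL`/empty contigs is recorded as
#'   `no_contigs` and excluded from per-gene denominators.
#' @param queries List of [gene_query()] objects.
#' @param cfg A [classify_config()].
#' @param metadata Optional data.frame with columns `accession` and any of
#'   `clade`, `coast` for cross-tabulation.
#' @return List with `hits` (data.frame: accession, gene, contig, start, end,
#'   strand, aln_len, mismatches, label), `counts` (per gene x label),
#'   `denominator` (accessions with contigs) and, when metadata is given,
#'   `crosstab` (gene x label x clade/coast counts).
#' @export
screen_cohort <- function(contig_sets, queries, cfg = classify_config(),
                          metadata = NULL) {
  rows <- list()
  for (acc in names(contig_sets)) {
    contigs <- contig_sets[[acc]]
    if (is.null(contigs) || length(contigs) == 0) {
      for (q in queries) {
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, gene = q$name, contig = NA, start = NA, end = NA,
          strand = NA, aln_len = NA, mismatches = NA, label = "no_contigs")
      }
      next
    }
    for (q in queries) {
      hit <- search_gene(contigs, q, cfg = cfg)
      label <- classify_hit(hit, q, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, gene = q$name,
        contig = if (is.null(hit)) NA else hit$contig,
        start = if (is.null(hit)) NA else hit$start,
        end = if (is.null(hit)) NA else hit$end,
        strand = if (is.null(hit)) NA else hit$strand,
        aln_len = if (is.null(hit)) NA else hit$alignment_length,
        mismatches = if (is.null(hit)) NA else hit$mismatches,
        label = label)
    }
  }
  hits <- do.call(rbind, rows)
  scored <- hits[hits$label != "no_contigs", , drop = FALSE]
  counts <- as.data.frame.matrix(table(scored$gene, scored$label))
  denominator <- length(unique(scored$accession))
  out <- list(hits = hits, counts = counts, denominator = denominator)
  if (!is.null(metadata)) {
    merged <- merge(scored, metadata, by = "accession")
    dims <- intersect(c("clade", "coast"), names(metadata))
    out$crosstab <- lapply(setNames(dims, dims), function(d) {
      as.data.frame(table(gene = merged$gene, label = merged$label,
                          group = merged[[d]]))
    })
  }
  out
}
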
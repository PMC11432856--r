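#' Configuration for a synthetic mitochondrial cohort
#'
#' Builds and validates the configuration used by [simulate_clades()] and
#' [make_site_tables()]. The simulated cohort mimics plant mitochondrial
#' resequencing in which reads of three different origins map onto the
#' mitochondrial reference at three characteristic depths: plastid-homologous
#' regions attract the abundant cpDNA reads (mean depth ~3000), genuine
#' mitochondrial sequence sits near ~100, and nuclear copies of mtDNA (NUMTs)
#' whose mitochondrial counterpart is absent from the accession appear at ~5.
#'
#' @param genome_length Reference length in bp.
#' @param n_accessions Number of accessions in the cohort.
#' @param n_clades Number of clades (maternal lineages).
#' @param snps_per_clade Number of diagnostic substitutions shared by all
#'   members of a clade.
#' @param private_snp_rate Expected number of accession-private substitutions
#'   (Poisson mean per accession).
#' @param depth_mito Mean read depth at genuine mitochondrial sites.
#' @param depth_plastid Mean depth inside plastid-homologous regions.
#' @param depth_numt Mean depth inside NUMT-only regions.
#' @param plastid_regions,numt_regions Lists of 0-based half-open intervals
#'   `c(start, end)` on the reference; must lie within the genome and be
#'   mutually disjoint.
#' @param heteroplasmy_rate Fraction of retained-depth sites given a minor
#'   allele in addition to the haplotype base.
#' @param heteroplasmy_minor_freq Minor-allele read fraction at heteroplasmic
#'   sites; must be in (0, 0.5).
#' @param rng_seed Integer seed; all generation is a pure function of it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000L,
                       n_accessions = 40L,
                       n_clades = 4L,
                       snps_per_clade = 50L,
                       private_snp_rate = 0,
                       depth_mito = 100,
                       depth_plastid = 3000,
                       depth_numt = 5,
                       plastid_regions = list(c(2000L, 3000L)),
                       numt_regions = list(c(10000L, 10500L)),
                       heteroplasmy_rate = 0.01,
                       heteroplasmy_minor_freq = 0.25,
                       rng_seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_accessions = as.integer(n_accessions),
    n_clades = as.integer(n_clades),
    snps_per_clade = as.integer(snps_per_clade),
    private_snp_rate = private_snp_rate,
    depth_mito = depth_mito,
    depth_plastid = depth_plastid,
    depth_numt = depth_numt,
    plastid_regions = lapply(plastid_regions, as.integer),
    numt_regions = lapply(numt_regions, as.integer),
    heteroplasmy_rate = heteroplasmy_rate,
    heteroplasmy_minor_freq = heteroplasmy_minor_freq,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length > 0, cfg$n_accessions > 0, cfg$n_clades > 0,
            cfg$snps_per_clade >= 0, cfg$private_snp_rate >= 0)
  if (!(cfg$depth_numt < 20 && 20 < cfg$depth_mito && cfg$depth_mito < 900 &&
        900 < cfg$depth_plastid)) {
    stop("depth classes must satisfy depth_numt < 20 < depth_mito < 900 < depth_plastid")
  }
  if (!(cfg$heteroplasmy_minor_freq > 0 && cfg$heteroplasmy_minor_freq < 0.5)) {
    stop("heteroplasmy_minor_freq must be in (0, 0.5)")
  }
  regions <- c(cfg$plastid_regions, cfg$numt_regions)
  for (r in regions) {
    if (length(r) != 2L || r[1] < 0L || r[2] > cfg$genome_length || r[1] >= r[2]) {
      stop("region intervals must be half-open [start, end) within [0, genome_length)")
    }
  }
  if (length(regions) > 1L) {
    ends <- do.call(rbind, regions)
    o <- order(ends[, 1])
    ends <- ends[o, , drop = FALSE]
    if (any(ends[-1, 1] < ends[-nrow(ends), 2])) {
      stop("plastid/NUMT regions must be mutually disjoint")
    }
  }
  invisible(cfg)
}

DNA_BASES <- c("A", "C", "G", "T")

#' 0-based half-open region list to a logical site mask (1-based positions)
#' @noRd
region_mask <- function(regions, genome_length) {
  mask <- logical(genome_length)
  for (r in regions) mask[(r[1] + 1L):r[2]] <- TRUE
  mask
}

#' Simulate a clade-structured haplotype cohort
#'
#' Draws a random reference sequence, assigns accessions to clades round-robin,
#' and plants clade-diagnostic and accession-private substitutions under an
#' infinite-sites model (no position reused, uniform random alternative base).
#' True SNP positions avoid the configured plastid/NUMT regions so that the
#' simulated polymorphism is recoverable after contamination filtering.
#'
#' @param cfg A [sim_config()].
#' @return A list with `reference` (character vector of bases), `haplotypes`
#'   (character matrix, accessions x positions), and `truth` — a list holding
#'   `clade_of` (named vector), `true_snp_positions` (sorted, 1-based),
#'   `snp_alleles` (data.frame of pos/ref/alt per diagnostic or private SNP),
#'   and `cms_carriers` (empty list; filled by contig simulation).
#' @export
simulate_clades <- function(cfg) {
  validate_sim_config(cfg)
  withr_seed <- set_local_seed(cfg$rng_seed)
  on.exit(withr_seed(), add = TRUE)

  L <- cfg$genome_length
  reference <- sample(DNA_BASES, L, replace = TRUE)

  contaminated <- region_mask(c(cfg$plastid_regions, cfg$numt_regions), L)
  clean_pos <- which(!contaminated)

  acc_ids <- sprintf("acc%03d", seq_len(cfg$n_accessions))
  clades <- sprintf("clade%d", ((seq_len(cfg$n_accessions) - 1L) %% cfg$n_clades) + 1L)
  names(clades) <- acc_ids

  n_private <- if (cfg$private_snp_rate > 0) {
    stats::rpois(cfg$n_accessions, cfg$private_snp_rate)
  } else {
    integer(cfg$n_accessions)
  }
  n_needed <- cfg$n_clades * cfg$snps_per_clade + sum(n_private)
  if (n_needed > length(clean_pos)) {
    stop("infeasible config: ", n_needed, " SNP positions requested but only ",
         length(clean_pos), " uncontaminated sites available")
  }

  snp_pos <- if (n_needed > 0) sort(sample(clean_pos, n_needed)) else integer(0)
  # deal positions out: first the clade blocks, then private ones
  pool <- sample(snp_pos)  # random assignment of positions to roles
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }

  haplotypes <- matrix(rep(reference, each = cfg$n_accessions),
                       nrow = cfg$n_accessions, ncol = L,
                       dimnames = list(acc_ids, NULL))

  alleles <- list()
  alt_base <- function(ref) sample(setdiff(DNA_BASES, ref), 1L)
  for (cl in unique(clades)) {
    pos <- take(cfg$snps_per_clade)
    members <- names(clades)[clades == cl]
    for (p in pos) {
      alt <- alt_base(reference[p])
      haplotypes[members, p] <- alt
      alleles[[length(alleles) + 1L]] <-
        data.frame(pos = p, ref = reference[p], alt = alt, scope = cl)
    }
  }
  for (i in seq_len(cfg$n_accessions)) {
    pos <- take(n_private[i])
    for (p in pos) {
      alt <- alt_base(reference[p])
      haplotypes[acc_ids[i], p] <- alt
      alleles[[length(alleles) + 1L]] <-
        data.frame(pos = p, ref = reference[p], alt = alt, scope = acc_ids[i])
    }
  }
  snp_alleles <- if (length(alleles)) {
    a <- do.call(rbind, alleles)
    a[order(a$pos), , drop = FALSE]
  } else {
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               scope = character(0))
  }

  truth <- list(
    clade_of = clades,
    true_snp_positions = sort(snp_pos),
    snp_alleles = snp_alleles,
    cms_carriers = list()
  )
  list(reference = reference, haplotypes = haplotypes, truth = truth)
}

# Scoped RNG: restores the caller's seed state on exit so simulation calls
# behave as pure functions of their own seed.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate per-accession site tables with contamination depth classes
#'
#' For each accession and reference position, draws a Poisson read depth around
#' the class mean: `depth_mito` at ordinary sites, `depth_plastid` inside
#' plastid-homologous regions (where base counts reflect a fixed divergent
#' plastid allele rather than the accession's haplotype) and `depth_numt`
#' inside NUMT-only regions. At heteroplasmic sites (sampled at
#' `heteroplasmy_rate` among ordinary sites) reads split between the haplotype
#' base (`1 - heteroplasmy_minor_freq`) and a minor allele.
#'
#' @param sim Result of [simulate_clades()].
#' @param cfg The same [sim_config()] used to generate `sim`.
#' @return A named list of `site_table` objects (see [site_table()]), one per
#'   accession.
#' @export
make_site_tables <- function(sim, cfg) {
  validate_sim_config(cfg)
  restore <- set_local_seed(cfg$rng_seed + 1L)
  on.exit(restore(), add = TRUE)

  L <- cfg$genome_length
  plastid <- region_mask(cfg$plastid_regions, L)
  numt <- region_mask(cfg$numt_regions, L)
  ordinary <- !(plastid | numt)

  # fixed divergent plastid allele per plastid site, shared by all accessions
  plastid_allele <- character(L)
  idx <- which(plastid)
  ref <- sim$reference
  plastid_allele[idx] <- vapply(idx, function(p) {
    sample(setdiff(DNA_BASES, ref[p]), 1L)
  }, character(1))

  acc_ids <- rownames(sim$haplotypes)
  out <- vector("list", length(acc_ids))
  names(out) <- acc_ids
  for (a in acc_ids) {
    hap <- sim$haplotypes[a, ]
    depth <- integer(L)
    depth[ordinary] <- stats::rpois(sum(ordinary), cfg$depth_mito)
    depth[plastid] <- stats::rpois(sum(plastid), cfg$depth_plastid)
    depth[numt] <- stats::rpois(sum(numt), cfg$depth_numt)

    major <- hap
    major[plastid] <- plastid_allele[plastid]

    counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
    het <- ordinary & (stats::runif(L) < cfg$heteroplasmy_rate) & depth > 0L
    minor_n <- integer(L)
    minor_n[het] <- as.integer(round(depth[het] * cfg$heteroplasmy_minor_freq))
    minor_base <- character(L)
    minor_base[het] <- vapply(which(het), function(p) {
      sample(setdiff(DNA_BASES, major[p]), 1L)
    }, character(1))

    maj_idx <- cbind(seq_len(L), match(major, DNA_BASES))
    counts[maj_idx] <- depth - minor_n
    if (any(het)) {
      min_idx <- cbind(which(het), match(minor_base[het], DNA_BASES))
      counts[min_idx] <- counts[min_idx] + minor_n[het]
    }

    out[[a]] <- site_table(
      accession_id = a,
      pos = seq_len(L),
      depth = depth,
      base_counts = counts,
      indel_count = integer(L)
    )
  }
  out
}

#' Per-site nucleotide composition table for one accession
#'
#' The container corresponding to a per-site pileup dump: position, total read
#' depth and counts of A/C/G/T plus indel-supporting reads over the shared
#' mitochondrial reference.
#'
#' @param accession_id Accession identifier.
#' @param pos Integer vector of 1-based reference positions, strictly
#'   increasing, each position present exactly once.
#' @param depth Total read depth per site; must equal
#'   `rowSums(base_counts) + indel_count`.
#' @param base_counts Integer matrix with columns A, C, G, T.
#' @param indel_count Reads supporting an insertion/deletion at the site.
#' @return An object of class `site_table`.
#' @export
site_table <- function(accession_id, pos, depth, base_counts, indel_count) {
  pos <- as.integer(pos)
  depth <- as.integer(depth)
  indel_count <- as.integer(indel_count)
  storage.mode(base_counts) <- "integer"
  if (is.null(colnames(base_counts))) colnames(base_counts) <- DNA_BASES
  stopifnot(identical(colnames(base_counts), DNA_BASES))
  n <- length(pos)
  if (length(depth) != n || nrow(base_counts) != n || length(indel_count) != n) {
    stop("site_table fields must have equal length")
  }
  if (n > 1 && any(diff(pos) <= 0L)) stop("positions must be strictly increasing")
  if (any(depth != rowSums(base_counts) + indel_count)) {
    stop("depth must equal sum of base counts plus indel count at every site")
  }
  structure(list(accession_id = accession_id, pos = pos, depth = depth,
                 base_counts = base_counts, indel_count = indel_count),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat("site_table:", x$accession_id, "-", length(x$pos), "sites, mean depth",
      round(mean(x$depth), 1), "\n")
  invisible(x)
}

#' Write / read a site table as TSV
#'
#' Schema: `pos depth A C G T ins del` with 1-based positions. Insertion and
#' deletion support are written separately but pooled into `indel_count` on
#' read.
#'
#' @param st A `site_table`.
#' @param path Output file.
#' @return `write_site_table` returns `path` invisibly; `read_site_table`
#'   returns a `site_table`.
#' @export
write_site_table <- function(st, path) {
  df <- data.table::data.table(
    pos = st$pos, depth = st$depth,
    A = st$base_counts[, "A"], C = st$base_counts[, "C"],
    G = st$base_counts[, "G"], T = st$base_counts[, "T"],
    ins = st$indel_count, del = 0L
  )
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_site_table
#' @param accession_id Accession id to attach; defaults to the file stem.
#' @export
read_site_table <- function(path, accession_id = NULL) {
  if (is.null(accession_id)) {
    accession_id <- sub("\\.(tsv|txt)$", "", basename(path))
  }
  df <- data.table::fread(path, sep = "\t")
  need <- c("pos", "depth", "A", "C", "G", "T", "ins", "del")
  if (!all(need %in% names(df))) {
    stop("site table ", path, " lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  site_table(accession_id = accession_id, pos = df$pos, depth = df$depth,
             base_counts = as.matrix(df[, c("A", "C", "G", "T")]),
             indel_count = df$ins + df$del)
}

#' Embed a gene query into a contig with a controlled number of mismatches
#'
#' Used to construct positives and negatives for the alignment-length /
#' mismatch classification of CMS-associated genes: the (optionally truncated)
#' query is copied into the contig at a recorded offset with exactly
#' `n_mismatches` substitutions. Mismatch positions keep a margin from the
#' insert ends and from each other so that a local aligner retains them inside
#' the optimal alignment rather than trimming them off.
#'
#' @param contig Character scalar (DNA) to embed into.
#' @param query Character scalar, the gene query sequence.
#' @param n_mismatches Number of substitutions to introduce into the insert.
#' @param truncate_to Length to truncate the query to before embedding
#'   (`NULL` for full length).
#' @param offset 1-based position in `contig` at which the insert replaces
#'   contig sequence; defaults to the middle.
#' @param seed Integer seed controlling mismatch placement.
#' @return A list with `contig` (modified sequence), `offset`, `insert_length`
#'   and `mismatch_positions` (relative to the insert, 1-based).
#' @export
embed_gene <- function(contig, query, n_mismatches, truncate_to = NULL,
                       offset = NULL, seed = 1L) {
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  qlen <- nchar(query)
  if (!is.null(truncate_to)) {
    if (truncate_to > qlen) stop("truncate_to exceeds query length")
    query <- substr(query, 1L, truncate_to)
    qlen <- truncate_to
  }
  if (n_mismatches > qlen) stop("n_mismatches exceeds insert length")
  margin <- 10L
  spacing <- 10L
  candidates <- seq(margin + 1L, qlen - margin)
  if (n_mismatches > 0) {
    pos <- integer(0)
    pool <- candidates
    for (i in seq_len(n_mismatches)) {
      if (!length(pool)) stop("cannot place ", n_mismatches,
                              " spaced mismatches in insert of length ", qlen)
      p <- if (length(pool) == 1L) pool else sample(pool, 1L)
      pos <- c(pos, p)
      pool <- pool[abs(pool - p) >= spacing]
    }
    pos <- sort(pos)
  } else {
    pos <- integer(0)
  }
  insert <- strsplit(query, "")[[1]]
  for (p in pos) insert[p] <- sample(setdiff(DNA_BASES, insert[p]), 1L)
  insert <- paste(insert, collapse = "")

  clen <- nchar(contig)
  if (is.null(offset)) offset <- max(1L, (clen - qlen) %/% 2L)
  if (offset + qlen - 1L > clen) stop("insert does not fit in contig at offset")
  contig_out <- paste0(substr(contig, 1L, offset - 1L), insert,
                       substr(contig, offset + qlen, clen))
  list(contig = contig_out, offset = as.integer(offset),
       insert_length = qlen, mismatch_positions = pos)
}

#' Random DNA string
#' @param n Length in bp.
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
random_dna <- function(n, seed = 1L) {
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate per-accession contigs with embedded CMS-gene variants
#'
#' Builds one background contig per accession and, for the designated
#' carriers, embeds the gene query with the requested truncation/mismatch
#' profile. The returned truth records the intended alignment length and
#' mismatch count per (accession, gene).
#'
#' @param acc_ids Character vector of accession ids.
#' @param queries Named character vector of query sequences.
#' @param carriers A data.frame with columns `accession`, `gene`,
#'   `n_mismatches`, `truncate_to` (NA for full length).
#' @param contig_length Background contig length in bp.
#' @param seed Integer seed.
#' @return List with `contigs` (named list of named character vectors,
#'   contig id -> sequence per accession) and `truth` (data.frame of intended
#'   hits: accession, gene, length, mismatches).
#' @export
simulate_cms_cohort <- function(acc_ids, queries, carriers,
                                contig_length = 5000L, seed = 1L) {
  stopifnot(all(carriers$gene %in% names(queries)),
            all(carriers$accession %in% acc_ids))
  contigs <- list()
  truth <- list()
  for (i in seq_along(acc_ids)) {
    a <- acc_ids[i]
    bg <- random_dna(contig_length, seed = seed + 1000L + i)
    rows <- carriers[carriers$accession == a, , drop = FALSE]
    acc_contigs <- character(0)
    if (nrow(rows) == 0) {
      acc_contigs <- c(contig1 = bg)
    } else {
      for (j in seq_len(nrow(rows))) {
        g <- rows$gene[j]
        trunc <- rows$truncate_to[j]
        emb <- embed_gene(bg, queries[[g]], rows$n_mismatches[j],
                          truncate_to = if (is.na(trunc)) NULL else trunc,
                          seed = seed + 2000L * j + i)
        acc_contigs[paste0("contig", j)] <- emb$contig
        truth[[length(truth) + 1L]] <- data.frame(
          accession = a, gene = g,
          length = emb$insert_length,
          mismatches = length(emb$mismatch_positions)
        )
      }
    }
    contigs[[a]] <- acc_contigs
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(accession = character(0), gene = character(0),
               length = integer(0), mismatches = integer(0))
  list(contigs = contigs, truth = truth)
}

#' Simulate collection-coast metadata biased by mitochondrial group
#'
#' Assigns each accession an Atlantic or Mediterranean coast with a
#' group-dependent bias, emulating the geographic structure of wild beet
#' mitotypes.
#'
#' @param clade_of Named vector accession -> clade label.
#' @param group_map Named vector clade -> group (see [default_group_map()]);
#'   by default odd-numbered clades map to "GroupA".
#' @param p_mediterranean_a Probability a GroupA accession is Mediterranean.
#' @param p_mediterranean_b Probability a GroupB accession is Mediterranean.
#' @param seed Integer seed.
#' @return data.frame with columns accession, clade, group, coast.
#' @export
simulate_coast_metadata <- function(clade_of, group_map = NULL,
                                    p_mediterranean_a = 0.85,
                                    p_mediterranean_b = 0.3,
                                    seed = 1L) {
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  clades <- unique(clade_of)
  if (is.null(group_map)) {
    num <- as.integer(sub("\\D+", "", clades))
    group_map <- ifelse(num %% 2L == 1L, "GroupA", "GroupB")
    names(group_map) <- clades
  }
  group <- unname(group_map[clade_of])
  p <- ifelse(group == "GroupA", p_mediterranean_a, p_mediterranean_b)
  coast <- ifelse(stats::runif(length(clade_of)) < p,
                  "Mediterranean", "Atlantic")
  data.frame(accession = names(clade_of), clade = unname(clade_of),
              group = group, coast = coast, row.names = NULL)
}

#' Write a truth set as JSON
#' @param truth Truth list from [simulate_clades()].
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(clade_of = as.list(truth$clade_of),
         true_snp_positions = truth$true_snp_positions,
         snp_alleles = truth$snp_alleles,
         cms_carriers = truth$cms_carriers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
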
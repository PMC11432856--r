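# Shared fixtures and independent oracles for the test suite.

# Small clade-structured cohort used across modules (memoised per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 5000L, n_accessions = 12L,
                        n_clades = 3L, snps_per_clade = 20L,
                        plastid_regions = list(c(500L, 800L)),
                        numt_regions = list(c(2000L, 2200L)),
                        heteroplasmy_rate = 0, rng_seed = 7L)
      sim <- simulate_clades(cfg)
      tables <- make_site_tables(sim, cfg)
      cm <- build_consensus_matrix(tables)
      sm <- extract_snp_sites(cm)
      cache <<- list(cfg = cfg, sim = sim, tables = tables, cm = cm, sm = sm)
    }
    cache
  }
})

# Smith-Waterman oracle (Biostrings) with the same scoring scheme as
# search_gene: match +1, mismatch -2, gap open -5, gap extend -2.
sw_oracle <- function(query, contig) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(contig),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  list(alignment_length = Biostrings::width(Biostrings::pattern(pa)),
       mismatches = Biostrings::nmismatch(pa),
       score = Biostrings::score(pa))
}

# Exact rational-arithmetic two-sided Fisher oracle via Python fractions,
# applying the same 1e-7 relative tie rule as fisher_exact() but on exact
# fractions. Takes a list of length-4 count vectors, returns numeric p-values.
fisher_rational_oracle <- function(tables) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from fractions import Fraction",
    "from math import comb",
    "def p2(a, b, c, d):",
    "    n = a + b + c + d",
    "    r1, c1 = a + b, a + c",
    "    denom = comb(n, c1)",
    "    lo = max(0, c1 - (n - r1)); hi = min(r1, c1)",
    "    probs = [Fraction(comb(r1, k) * comb(n - r1, c1 - k), denom) for k in range(lo, hi + 1)]",
    "    pobs = probs[a - lo]",
    "    thresh = pobs * (1 + Fraction(1, 10**7))",
    "    return sum(p for p in probs if p <= thresh)",
    "tables = json.load(sys.stdin)",
    "json.dump([float(p2(*t)) for t in tables], sys.stdout)"
  ), script)
  out <- system2("python", script, input = as.character(jsonlite::toJSON(tables)),
                 stdout = TRUE)
  unlink(script)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# Naive UPGMA oracle: full O(n^3) re-scan; inter-cluster distance recomputed
# from the ORIGINAL distance matrix as the unweighted mean over member pairs.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    heights[step] <- best_d / 2
    merges[[step]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# member leaf sets per merge step of an upgma_tree, sorted
upgma_merge_sets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1)
  expand <- function(code) {
    if (code < 0) return(-code)
    sets[[code]]
  }
  for (s in seq_len(n - 1)) {
    sets[[s]] <- sort(c(expand(tree$merge[s, 1]), expand(tree$merge[s, 2])))
  }
  sets
}

# Naive neighbor-joining oracle: direct transcription of the Saitou-Nei
# update rules with explicit loops, independent of neighbor_joining()'s
# bookkeeping. Returns the tree topology as a set of canonical splits.
nj_oracle_splits <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  groups <- as.list(labels)
  splits <- list()
  all_tips <- sort(labels)
  while (nrow(d) > 3) {
    m <- nrow(d)
    best <- NULL; best_q <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        qij <- (m - 2) * d[i, j] - sum(d[i, ]) - sum(d[j, ])
        if (qij < best_q) { best_q <- qij; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merged <- sort(c(groups[[i]], groups[[j]]))
    if (length(merged) > 1 && length(merged) < length(all_tips) - 1) {
      side <- if (all_tips[1] %in% merged) setdiff(all_tips, merged) else merged
      splits[[length(splits) + 1L]] <- paste(sort(side), collapse = "|")
    }
    new_d <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    groups <- c(groups[keep], list(merged))
  }
  unique(unlist(splits))
}

# random unrooted topology + branch lengths -> additive distance matrix
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sort(tr$tip.label)
  list(tree = tr, d = stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
}

random_snp_calls <- function(n_acc, n_sites, seed, bases = c("A", "C", "G", "T")) {
  set.seed(seed)
  matrix(sample(bases, n_acc * n_sites, replace = TRUE), n_acc, n_sites,
         dimnames = list(sprintf("acc%02d", seq_len(n_acc)), NULL))
}
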
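#' Run the full mitotype pipeline from a configuration
#'
#' Orchestrates simulation (or input loading), consensus/SNP calling,
#' clustering, PCA, tree building, CMS-gene screening and the geographic
#' association test, writing every intermediate to `out_dir` together with a
#' JSON run manifest.
#'
#' The configuration is a list (or path to a JSON file) with entries:
#' \describe{
#'   \item{out_dir}{Output directory (created if needed).}
#'   \item{seed}{Master seed; per-stage seeds are derived from it.}
#'   \item{simulate}{If `TRUE`, a synthetic cohort is generated from the
#'     `sim` sub-list (arguments of [sim_config()]); otherwise `reference`
#'     (FASTA path) and `tables_dir` (site-table TSVs) must be given.}
#'   \item{k_clusters}{Flat clusters to cut from the dendrogram (default 4).}
#'   \item{pca_components}{Number of PCA components (default 5).}
#'   \item{bootstrap_reps}{Bootstrap replicates for the tree (default 100).}
#'   \item{cms}{Optional sub-list: `n_present`, `n_like`, `query_length`
#'     controlling the synthetic CMS cohort, or `contigs_dir`/`queries`
#'     paths for real contigs.}
#'   \item{geo}{If `TRUE`, run the coast association test (synthetic
#'     metadata when simulating, else a `meta` TSV path).}
#' }
#'
#' @param config List or path to a JSON config file.
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config_hash = config_hash(cfg),
    version = as.character(utils::packageVersion("mitovar")),
    seed = cfg$seed,
    stages = list(),
    counts = list()
  )
  path <- function(f) file.path(cfg$out_dir, f)

  # --- stage: simulate or load ---------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim_args <- cfg$sim
    sim_args$rng_seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_clades(scfg)
    tables <- make_site_tables(sim, scfg)
    write_reference_fasta(sim$reference, path("reference.fa"))
    write_truth_json(sim$truth, path("truth.json"))
    reference <- sim$reference
    truth <- sim$truth
    manifest$stages$simulate <- list(reference = path("reference.fa"),
                                     truth = path("truth.json"))
  } else {
    reference <- read_reference_fasta(cfg$reference)
    files <- list.files(cfg$tables_dir, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no site-table TSVs found in ", cfg$tables_dir)
    tables <- lapply(files, read_site_table)
    names(tables) <- vapply(tables, function(t) t$accession_id, character(1))
    truth <- NULL
    manifest$stages$load <- list(reference = cfg$reference, n_tables = length(tables))
  }
  manifest$counts$n_accessions <- length(tables)
  manifest$counts$reference_length <- length(reference)

  # --- stage: call ----------------------------------------------------------
  fcfg <- filter_config()
  cm <- build_consensus_matrix(tables, fcfg)
  sm <- extract_snp_sites(cm)
  write_snp_fasta(sm, path("snps.fa"))
  write_snp_positions(sm, path("snp_positions.tsv"))
  write_snp_vcf(sm, reference, path("snps.vcf"))
  dens <- window_snp_density(sm$positions, length(reference), fcfg$window_size)
  data.table::fwrite(dens, path("snp_density.tsv"), sep = "\t")
  manifest$stages$call <- list(snp_fasta = path("snps.fa"),
                               vcf = path("snps.vcf"),
                               density = path("snp_density.tsv"))
  manifest$counts$n_snps <- ncol(sm$calls)

  # --- stage: cluster -------------------------------------------------------
  em <- encode_alleles(sm, reference)
  d <- bray_curtis_matrix(em)
  write_distance_tsv(d, path("bray_curtis.tsv"))
  tree_u <- upgma(d)
  labels <- cut_clusters(tree_u, cfg$k_clusters)
  data.table::fwrite(data.table::data.table(accession = names(labels),
                                            cluster = labels),
                     path("clusters.tsv"), sep = "\t")
  write_newick(as_phylo_upgma(tree_u), path("dendrogram.nwk"))
  manifest$stages$cluster <- list(distances = path("bray_curtis.tsv"),
                                  dendrogram = path("dendrogram.nwk"),
                                  clusters = path("clusters.tsv"))
  manifest$counts$k_clusters <- length(unique(labels))

  # --- stage: pca -----------------------------------------------------------
  pca <- snp_pca(em, cfg$pca_components)
  sc <- data.table::data.table(accession = rownames(pca$scores))
  for (j in seq_len(ncol(pca$scores))) sc[[paste0("PC", j)]] <- pca$scores[, j]
  data.table::fwrite(sc, path("pca_scores.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(component = seq_along(pca$explained),
                                            explained = pca$explained),
                     path("pca_explained.tsv"), sep = "\t")
  manifest$stages$pca <- list(scores = path("pca_scores.tsv"),
                              explained = path("pca_explained.tsv"))

  # --- stage: tree ----------------------------------------------------------
  bs <- bootstrap_nj(sm, n_reps = cfg$bootstrap_reps, seed = cfg$seed + 101L)
  write_newick(bs$tree, path("tree.nwk"))
  manifest$stages$tree <- list(newick = path("tree.nwk"),
                               bootstrap_reps = bs$n_reps)
  manifest$counts$min_support <- if (length(bs$support)) min(bs$support) else NA

  # --- stage: cms -----------------------------------------------------------
  if (!is.null(cfg$cms)) {
    ccfg <- classify_config()
    if (isTRUE(cfg$simulate)) {
      cms <- simulate_cms_inputs(names(tables), cfg$cms, seed = cfg$seed + 202L)
      res <- screen_cohort(cms$contigs, cms$queries, ccfg)
      data.table::fwrite(cms$truth, path("cms_truth.tsv"), sep = "\t")
    } else {
      queries <- load_queries_fasta(cfg$cms$queries)
      contigs <- load_contig_dir(cfg$cms$contigs_dir)
      res <- screen_cohort(contigs, queries, ccfg)
    }
    data.table::fwrite(res$hits, path("cms_hits.tsv"), sep = "\t")
    manifest$stages$cms <- list(hits = path("cms_hits.tsv"))
    manifest$counts$cms_present <- sum(res$hits$label == "present")
    manifest$counts$cms_like <- sum(res$hits$label == "like")
  }

  # --- stage: geo -----------------------------------------------------------
  if (isTRUE(cfg$geo)) {
    if (isTRUE(cfg$simulate)) {
      meta <- simulate_coast_metadata(truth$clade_of, seed = cfg$seed + 303L)
      gm <- stats::setNames(meta$group[!duplicated(meta$clade)],
                            meta$clade[!duplicated(meta$clade)])
    } else {
      meta <- utils::read.delim(cfg$meta)
      gm <- default_group_map()
    }
    geo <- geo_association(meta, gm)
    data.table::fwrite(as.data.frame(geo$table), path("contingency.tsv"), sep = "\t")
    jsonlite::write_json(list(table = geo$table, p_value = geo$p_value,
                              excluded_n = geo$excluded_n),
                         path("geo.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$geo <- list(report = path("geo.json"))
    manifest$counts$p_value <- geo$p_value
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

validate_pipeline_config <- function(cfg) {
  defaults <- list(seed = 1L, simulate = FALSE, sim = list(), k_clusters = 4L,
                   pca_components = 5L, bootstrap_reps = 100L, cms = NULL,
                   geo = FALSE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  cfg$seed <- as.integer(cfg$seed)
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$reference)) stop("config must set 'reference' when simulate is false")
    if (is.null(cfg$tables_dir)) stop("config must set 'tables_dir' when simulate is false")
    if (!file.exists(cfg$reference)) stop("reference not found: ", cfg$reference)
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

# Synthetic CMS inputs for the simulated pipeline: one query, the first
# n_present accessions carry near-exact inserts, the next n_like carry
# truncated diverged inserts.
simulate_cms_inputs <- function(acc_ids, cms_cfg, seed = 1L) {
  n_present <- if (is.null(cms_cfg$n_present)) 5L else as.integer(cms_cfg$n_present)
  n_like <- if (is.null(cms_cfg$n_like)) 3L else as.integer(cms_cfg$n_like)
  qlen <- if (is.null(cms_cfg$query_length)) 1161L else as.integer(cms_cfg$query_length)
  if (n_present + n_like > length(acc_ids)) stop("more CMS carriers than accessions")
  qseq <- random_dna(qlen, seed = seed)
  queries <- list(gene_query("preSatp6_synthetic", qseq))
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  carriers <- data.frame(
    accession = acc_ids[seq_len(n_present + n_like)],
    gene = "preSatp6_synthetic",
    n_mismatches = c(sample(0:3, n_present, replace = TRUE),
                     sample(8:15, n_like, replace = TRUE)),
    truncate_to = c(rep(NA_integer_, n_present),
                    sample(seq(qlen %/% 2L, qlen - 100L), n_like, replace = TRUE))
  )
  sim <- simulate_cms_cohort(acc_ids, stats::setNames(
    lapply(queries, function(q) q$sequence),
    vapply(queries, function(q) q$name, character(1))), carriers, seed = seed)
  list(contigs = sim$contigs, queries = queries, truth = sim$truth,
       carriers = carriers)
}

#' Load query sequences from FASTA as gene_query objects
#' @param path FASTA path.
#' @return List of [gene_query()] objects named by record id.
#' @export
load_queries_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  qs <- lapply(seq_along(x), function(i) gene_query(names(x)[i], as.character(x[[i]])))
  stats::setNames(qs, names(x))
}

#' Load per-accession contig FASTAs from a directory (`<accession>.fa`)
#' @param dir Directory of FASTA files.
#' @return Named list accession -> named character vector of contigs.
#' @export
load_contig_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  out <- lapply(files, function(f) {
    x <- Biostrings::readDNAStringSet(f)
    stats::setNames(as.character(x), names(x))
  })
  stats::setNames(out, sub("\\.(fa|fasta)$", "", basename(files)))
}
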
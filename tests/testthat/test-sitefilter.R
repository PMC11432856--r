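test_that("depth boundaries are exclusive on both sides", {
  cfg <- filter_config()
  expect_identical(classify_site_depth(c(0, 20, 21, 899, 900, 5000), cfg),
                   c("drop_low", "drop_low", "retain", "retain",
                     "drop_high", "drop_high"))
  expect_error(classify_site_depth(-1, cfg), "non-negative")
})

test_that("consensus calling enforces the strict 80% rule", {
  cfg <- filter_config()
  r <- call_consensus(c(A = 81, C = 19, G = 0, T = 0), 0, cfg)
  expect_identical(r$base, "A")
  expect_equal(r$freq, 0.81)
  expect_identical(r$flag, "retained")

  r <- call_consensus(c(A = 80, C = 20, G = 0, T = 0), 0, cfg)
  expect_identical(r$flag, "low_consensus")
  expect_true(is.na(r$base))

  # ties can never clear a threshold above 0.5
  r <- call_consensus(c(A = 50, C = 50, G = 0, T = 0), 0, cfg)
  expect_identical(r$flag, "low_consensus")

  # indel plurality masks the site even when one base dominates the rest
  r <- call_consensus(c(A = 30, C = 0, G = 0, T = 0), 60, cfg)
  expect_identical(r$flag, "indel_majority")

  expect_error(call_consensus(c(A = 0, C = 0, G = 0, T = 0), 0, cfg), "all-zero")
})

test_that("reference refinement corrects retained sites only", {
  cfg <- filter_config()
  ref <- c("A", "A", "A", "A")
  counts <- rbind(c(95, 5, 0, 0),    # consensus A, matches reference
                  c(5, 95, 0, 0),    # consensus C at depth 100 -> corrected
                  c(100, 2900, 0, 0),# plastid-class depth -> untouched
                  c(1, 9, 0, 0))     # NUMT-class depth -> untouched
  colnames(counts) <- c("A", "C", "G", "T")
  st <- site_table("acc", 1:4, rowSums(counts), counts, rep(0L, 4))
  out <- refine_reference(st, ref, cfg)
  expect_identical(out$sequence, c("A", "C", "A", "A"))
  expect_equal(out$changes$pos, 2L)
  expect_identical(out$changes$old, "A")
  expect_identical(out$changes$new, "C")

  # consensus equal to reference everywhere -> zero changes
  st2 <- site_table("acc", 1:4,
                    rowSums(counts[c(1, 1, 1, 1), ]),
                    counts[c(1, 1, 1, 1), ], rep(0L, 4))
  expect_identical(nrow(refine_reference(st2, ref, cfg)$changes), 0L)

  expect_error(refine_reference(st, ref[1:3], cfg), "length")
})

test_that("consensus matrix flags missing data by provenance", {
  co <- small_cohort()
  cm <- co$cm
  # all NUMT-region columns are missing with depth_low for every accession
  numt_cols <- 2001:2200
  expect_true(all(cm$flags[, numt_cols] == "depth_low"))
  expect_true(all(is.na(cm$calls[, numt_cols])))
  # plastid-region columns are depth_high
  expect_true(all(cm$flags[, 501:800] == "depth_high"))
  # uncontaminated sites are all retained (heteroplasmy_rate = 0)
  clean <- setdiff(seq_along(cm$positions), c(501:800, 2001:2200))
  expect_true(all(cm$flags[, clean] == "retained"))
  # conservation: retained + missing = reference length per accession
  expect_true(all(rowSums(cm$flags == "retained") + rowSums(cm$flags != "retained")
                  == length(cm$positions)))

  expect_error(build_consensus_matrix(co$tables[c(1, 1)]), "duplicate")
})

test_that("a 75/25 heteroplasmic site is filtered as low consensus", {
  cfg <- sim_config(genome_length = 500L, n_accessions = 2L, n_clades = 1L,
                    snps_per_clade = 0L, plastid_regions = list(),
                    numt_regions = list(), heteroplasmy_rate = 1,
                    heteroplasmy_minor_freq = 0.25, rng_seed = 9L)
  sim <- simulate_clades(cfg)
  tabs <- make_site_tables(sim, cfg)
  cm <- build_consensus_matrix(tabs)
  # 0.75 <= 0.80, so essentially every site should be masked as low_consensus
  expect_gt(mean(cm$flags == "low_consensus"), 0.99)
})

test_that("SNP extraction drops missing, indel and invariant sites", {
  calls <- rbind(acc1 = c("A", "A", "A", "A", "C"),
                 acc2 = c("A", "G", "A", "G", "C"),
                 acc3 = c("A", NA, "A", "G", "T"))
  flags <- matrix("retained", 3, 5, dimnames = dimnames(calls))
  flags[3, 2] <- "depth_low"
  flags[is.na(calls)] <- "depth_low"
  # site 3: make one accession indel-majority
  calls[2, 3] <- NA
  flags[2, 3] <- "indel_majority"
  cm <- structure(list(calls = calls, flags = flags, positions = 1:5),
                  class = "consensus_matrix")
  sm <- extract_snp_sites(cm)
  expect_identical(sm$positions, c(4L, 5L))
  expect_identical(sm$calls[, 1], c(acc1 = "A", acc2 = "G", acc3 = "G"))

  # all-identical cohort: no SNP columns
  cm0 <- structure(list(calls = matrix("A", 3, 5, dimnames = dimnames(calls)),
                        flags = matrix("retained", 3, 5), positions = 1:5),
                   class = "consensus_matrix")
  expect_identical(ncol(extract_snp_sites(cm0)$calls), 0L)
})

test_that("synthetic cohort SNP recovery matches the truth set exactly", {
  co <- small_cohort()
  expect_identical(co$sm$positions, co$sim$truth$true_snp_positions)
  # called bases equal the haplotype bases at the retained sites
  expect_identical(unname(co$sm$calls),
                   unname(co$sim$haplotypes[, co$sm$positions]))
})

test_that("lowering thresholds never shrinks the retained call set", {
  co <- small_cohort()
  strict <- build_consensus_matrix(co$tables, filter_config())
  loose_depth <- build_consensus_matrix(
    co$tables, filter_config(min_depth_exclusive = 5))
  loose_freq <- build_consensus_matrix(
    co$tables, filter_config(min_consensus_freq_exclusive = 0.6))
  s <- strict$flags == "retained"
  expect_true(all(loose_depth$flags[s] == "retained"))
  expect_true(all(loose_freq$flags[s] == "retained"))
})

test_that("SNP extraction agrees with a naive triple-loop oracle", {
  set.seed(31)
  for (trial in 1:3) {
    n_acc <- 10; n_sites <- 400
    calls <- random_snp_calls(n_acc, n_sites, seed = 100 + trial,
                              bases = c("A", "A", "A", "A", "G", "T"))
    calls[sample(length(calls), 60)] <- NA
    flags <- ifelse(is.na(calls), "depth_low", "retained")
    cm <- structure(list(calls = calls, flags = flags,
                         positions = seq_len(n_sites)),
                    class = "consensus_matrix")
    keep <- logical(n_sites)
    for (j in seq_len(n_sites)) {
      col <- calls[, j]
      ok <- TRUE
      for (i in seq_len(n_acc)) if (is.na(col[i])) ok <- FALSE
      keep[j] <- ok && length(unique(col)) >= 2
    }
    sm <- extract_snp_sites(cm)
    expect_identical(sm$positions, which(keep))
  }
})

test_that("window counts follow the 1-anchored inclusive convention", {
  expect_identical(window_snp_density(integer(0), 3500)$n_snps, rep(0L, 4))
  d <- window_snp_density(c(1L, 1000L, 1001L), 2000)
  expect_identical(d$n_snps, c(2L, 1L))
  expect_identical(d$start, c(1L, 1001L))
  expect_identical(d$end, c(1000L, 2000L))
  expect_error(window_snp_density(2001L, 2000), "out of range")

  set.seed(17)
  pos <- sample(1:54321, 500)
  d <- window_snp_density(pos, 54321)
  # brute-force per-window recount
  brute <- vapply(seq_len(nrow(d)), function(w) {
    sum(pos >= d$start[w] & pos <= d$end[w])
  }, integer(1))
  expect_identical(d$n_snps, brute)
  expect_identical(sum(d$n_snps), 500L)
})

test_that("SNP multi-FASTA and VCF round-trip", {
  co <- small_cohort()
  sm <- co$sm
  fa <- withr::local_tempfile(fileext = ".fa")
  pos <- withr::local_tempfile(fileext = ".tsv")
  write_snp_fasta(sm, fa)
  write_snp_positions(sm, pos)
  back <- read_snp_fasta(fa, positions = data.table::fread(pos)$pos)
  expect_identical(back$calls, sm$calls)
  expect_identical(back$positions, sm$positions)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(sm, co$sim$reference, vcf)
  vback <- read_snp_vcf(vcf)
  expect_identical(vback$calls, sm$calls)
  expect_identical(vback$positions, sm$positions)
  expect_identical(attr(vback, "ref_bases"), co$sim$reference[sm$positions])

  # independent reader cross-check
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_identical(as.integer(v@fix[, "POS"]), sm$positions)
  expect_identical(unname(v@fix[, "REF"]), co$sim$reference[sm$positions])

  # random matrices round-trip too
  for (trial in 1:3) {
    calls <- random_snp_calls(5, 20, seed = 200 + trial)
    rsm <- snp_matrix(calls, sort(sample(1:1000, 20)))
    write_snp_fasta(rsm, fa)
    rback <- read_snp_fasta(fa, positions = rsm$positions)
    expect_identical(rback$calls, rsm$calls)
    ref <- strsplit(random_dna(1000, seed = trial), "")[[1]]
    write_snp_vcf(rsm, ref, vcf)
    expect_identical(read_snp_vcf(vcf)$calls, rsm$calls)
  }
})
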
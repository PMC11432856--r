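test_that("p-distance and JC69 follow their closed forms", {
  calls <- rbind(s1 = c("A", "A", "A", "A"), s2 = c("A", "A", "A", "G"))
  sm <- snp_matrix(calls, 1:4)
  expect_equal(snp_distance(sm, "p")["s1", "s2"], 0.25)
  expect_equal(snp_distance(sm, "JC69")["s1", "s2"],
               -0.75 * log(1 - 1 / 3), tolerance = 1e-12)
  same <- snp_matrix(rbind(a = c("A", "C"), b = c("A", "C")), 1:2)
  expect_equal(snp_distance(same, "p")["a", "b"], 0)
  expect_equal(snp_distance(same, "JC69")["a", "b"], 0)

  # convexity: correction never below the raw distance; saturation clamps
  for (i in 1:10) {
    calls <- random_snp_calls(2, 40, seed = 500 + i, bases = c("A", "G"))
    sm <- snp_matrix(calls, 1:40)
    p <- snp_distance(sm, "p")[1, 2]
    jc <- suppressWarnings(snp_distance(sm, "JC69")[1, 2])
    expect_gte(jc, p)
  }
  sat <- snp_matrix(rbind(a = rep("A", 4), b = rep("G", 4)), 1:4)
  expect_warning(dj <- snp_distance(sat, "JC69"), "saturated")
  expect_equal(dj[1, 2], 5.0)
  expect_error(snp_distance(snp_matrix(
    matrix(character(0), 2, 0, dimnames = list(c("a", "b"), NULL)),
    integer(0))), "zero-length")
})

test_that("NJ recovers a four-taxon additive tree exactly", {
  # tree: ((A:1,B:2):1,(C:3,D:4)) with internal edge 1
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_identical(tree_bipartitions(tr), "C|D")
  # branch lengths: recomputed cophenetic distances reproduce the input
  expect_equal(stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-10)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("star-shaped distances produce zero internal branch lengths", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  dimnames(d) <- list(letters[1:5], letters[1:5])
  tr <- neighbor_joining(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

test_that("NJ recovers random additive topologies and matches the naive oracle", {
  for (trial in 1:20) {
    ad <- random_additive_matrix(8, seed = 600 + trial)
    tr <- neighbor_joining(ad$d)
    expect_equal(phangorn::RF.dist(tr, ape::unroot(ad$tree)), 0)
    # independent naive Saitou-Nei transcription gives the same splits
    expect_setequal(tree_bipartitions(tr), nj_oracle_splits(ad$d))
    # the established implementation agrees on additive input
    expect_equal(phangorn::RF.dist(tr, ape::nj(stats::as.dist(ad$d))), 0)
  }
})

test_that("NJ topology on five taxa matches exhaustive search over all topologies", {
  # on an additive matrix exactly one unrooted topology admits a perfect
  # least-squares fit; enumerate all of them and compare
  for (trial in 1:5) {
    ad <- random_additive_matrix(5, seed = 700 + trial)
    tips <- rownames(ad$d)
    all_tr <- phangorn::allTrees(5, rooted = FALSE, tip.label = tips)
    fits <- vapply(all_tr, function(tt) {
      tt$edge.length <- rep(1, nrow(tt$edge))
      # design matrix: path indicator per pair x edge
      n <- length(tips)
      pairs <- t(combn(n, 2))
      X <- matrix(0, nrow(pairs), nrow(tt$edge))
      for (r in seq_len(nrow(pairs))) {
        pth <- ape::nodepath(tt, pairs[r, 1], pairs[r, 2])
        for (s in seq_len(length(pth) - 1)) {
          e <- which((tt$edge[, 1] == pth[s] & tt$edge[, 2] == pth[s + 1]) |
                     (tt$edge[, 2] == pth[s] & tt$edge[, 1] == pth[s + 1]))
          X[r, e] <- 1
        }
      }
      y <- ad$d[pairs]
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    best <- all_tr[[which.min(fits)]]
    expect_lt(min(fits), 1e-16)
    expect_equal(phangorn::RF.dist(neighbor_joining(ad$d), best), 0)
  }
})

test_that("bootstrap supports behave on degenerate and reproducible cases", {
  # every column splits the taxa identically -> that bipartition gets 100%
  calls <- rbind(a = rep("A", 10), b = rep("A", 10),
                 c = rep("G", 10), d = rep("G", 10))
  sm <- snp_matrix(calls, 1:10)
  bs <- bootstrap_nj(sm, n_reps = 50, seed = 4)
  expect_identical(names(bs$support), "c|d")
  expect_equal(unname(bs$support), 100)

  bs2 <- bootstrap_nj(sm, n_reps = 50, seed = 4)
  expect_identical(bs$support, bs2$support)
  bs3 <- bootstrap_nj(sm, n_reps = 50, seed = 5)
  expect_identical(names(bs3$support), names(bs$support))
})

test_that("strong clade signal earns high bootstrap support", {
  co <- small_cohort()
  # p-distance here: with only 60 columns a resampled between-clade JC69
  # distance can hit the saturation clamp and blur the deeper splits
  bs <- bootstrap_nj(co$sm, n_reps = 100, seed = 12, model = "p")
  clade_splits <- vapply(split(names(co$sim$truth$clade_of),
                               co$sim$truth$clade_of), function(members) {
    tips <- sort(co$sm$accessions)
    side <- if (tips[1] %in% members) setdiff(tips, members) else members
    paste(sort(side), collapse = "|")
  }, character(1))
  present <- clade_splits[clade_splits %in% names(bs$support)]
  # with 12 taxa in 3 clades, one clade split is the complement of the other
  # two combined; at least two of the three appear as internal splits
  expect_gte(length(present), 2)
  expect_true(all(bs$support[present] >= 95))
})

test_that("outgroup rooting separates a divergent taxon", {
  co <- small_cohort()
  calls <- co$sm$calls
  og <- calls[1, , drop = FALSE]
  set.seed(9)
  flip <- sample(ncol(calls), ceiling(ncol(calls) * 0.6))
  og[1, flip] <- vapply(og[1, flip], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  rownames(og) <- "outgroup"
  sm <- snp_matrix(rbind(calls, og), co$sm$positions)
  tr <- neighbor_joining(suppressWarnings(snp_distance(sm, "JC69")))
  rooted <- root_with_outgroup(tr, "outgroup")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  tip_sides <- lapply(kids, function(k) {
    if (k <= length(rooted$tip.label)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label
  })
  expect_true(any(vapply(tip_sides, function(s) identical(s, "outgroup"),
                         logical(1))))
  expect_error(root_with_outgroup(tr, "nope"), "not present")
})

test_that("clade membership expands exemplars to monophyletic groups", {
  co <- small_cohort()
  # divergent outgroup built from the ancestral (reference) alleles, so it
  # attaches centrally and every simulated clade stays monophyletic
  calls <- co$sm$calls
  og <- matrix(co$sim$reference[co$sm$positions], 1,
               dimnames = list("outgroup", NULL))
  set.seed(19)
  flip <- sample(ncol(calls), ceiling(ncol(calls) * 0.4))
  og[1, flip] <- vapply(og[1, flip], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  sm <- snp_matrix(rbind(calls, og), co$sm$positions)
  tr <- neighbor_joining(suppressWarnings(snp_distance(sm, "JC69")))
  rooted <- root_with_outgroup(tr, "outgroup")
  truth <- co$sim$truth$clade_of
  exemplars <- lapply(split(names(truth), truth), function(m) m[1:2])
  cmres <- clade_membership(rooted, exemplars)
  got <- cmres$membership[names(truth)]
  # membership matches the simulated clades wherever assigned
  assigned <- !is.na(got)
  expect_true(all(got[assigned] == truth[assigned]))
  expect_length(cmres$non_monophyletic, 0)

  # an exemplar set spanning two clades is flagged
  bad <- exemplars
  bad[[1]] <- c(bad[[1]][1], bad[[2]][1])
  flagged <- clade_membership(rooted, bad)
  expect_true(names(bad)[1] %in% flagged$non_monophyletic)
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  for (trial in 1:5) {
    ad <- random_additive_matrix(7, seed = 800 + trial)
    tr <- neighbor_joining(ad$d)
    tr$node.label <- as.character(seq_len(tr$Nnode) * 10)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    back <- read_newick(path)
    expect_equal(phangorn::RF.dist(tr, back), 0)
    ord <- match(back$tip.label, tr$tip.label)
    coph_a <- stats::cophenetic(tr)[tr$tip.label, tr$tip.label]
    coph_b <- stats::cophenetic(back)[tr$tip.label, tr$tip.label]
    expect_equal(coph_a, coph_b, tolerance = 1e-10)
    expect_setequal(back$node.label, tr$node.label)
  }
})
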
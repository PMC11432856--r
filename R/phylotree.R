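#' Pairwise distances from a concatenated-SNP alignment
#'
#' @param sm A [snp_matrix()] (or character matrix of equal-length sequences
#'   with row names).
#' @param model `"p"` for the raw proportion of mismatching sites or
#'   `"JC69"` for the Jukes-Cantor correction `-(3/4) log(1 - 4p/3)`.
#'   Saturated pairs (`p >= 0.75`) are clamped to `max_distance` with a
#'   warning.
#' @param max_distance Clamp value for saturated JC69 pairs.
#' @return A `distance_matrix`.
#' @export
snp_distance <- function(sm, model = c("p", "JC69"), max_distance = 5.0) {
  model <- match.arg(model)
  calls <- if (inherits(sm, "snp_matrix")) sm$calls else sm
  if (ncol(calls) == 0) stop("zero-length alignment")
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- mean(calls[i, ] != calls[j, ])
      v <- if (model == "p") {
        p
      } else if (p >= 0.75) {
        saturated <- TRUE
        max_distance
      } else {
        -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  if (saturated) warning("saturated pair(s) clamped to ", max_distance)
  structure(d, class = c("distance_matrix", "matrix"))
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion `Q(i,j) = (m - 2) d(i,j) - r(i) - r(j)` is joined, with exact
#' ties broken by the smallest pair index in the current scan order. Negative
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' edge (preserving the path length between the joined nodes).
#'
#' @param d Square symmetric distance matrix with at least 3 taxa.
#' @return An unrooted `phylo` object (ape).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # ape phylo bookkeeping: tips 1..n, internal nodes appended from n+1
  next_node <- n + 1L
  node_id <- seq_len(n)           # phylo node id of each active cluster
  edges <- matrix(0L, 0, 2)
  lengths <- numeric(0)
  cur <- d

  while (nrow(cur) > 3) {
    m <- nrow(cur)
    r <- rowSums(cur)
    q <- (m - 2) * cur - outer(r, r, "+")
    diag(q) <- Inf
    best <- c(1L, 2L); best_q <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (q[i, j] < best_q) { best_q <- q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- cur[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- cur[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    lengths <- c(lengths, bi, bj)
    new_d <- (cur[i, ] + cur[j, ] - cur[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_d[keep]),
                 c(new_d[keep], 0))
    node_id <- c(node_id[keep], u)
  }
  # final 3-star
  b1 <- (cur[1, 2] + cur[1, 3] - cur[2, 3]) / 2
  b2 <- (cur[1, 2] + cur[2, 3] - cur[1, 3]) / 2
  b3 <- (cur[1, 3] + cur[2, 3] - cur[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  u <- next_node
  edges <- rbind(edges, c(u, node_id[1]), c(u, node_id[2]), c(u, node_id[3]))
  lengths <- c(lengths, b)

  # renumber internal nodes to ape's convention (root = n+1, preorder) and
  # order edges cladewise
  n_internal <- u - n
  children <- split(seq_len(nrow(edges)), edges[, 1])
  new_id <- integer(u)
  new_id[seq_len(n)] <- seq_len(n)
  edge_order <- preorder_edges(edges, children, u, n)
  visited_internal <- unique(edges[edge_order, 1])
  new_id[visited_internal] <- n + seq_along(visited_internal)
  edges2 <- edges[edge_order, , drop = FALSE]
  edges2[] <- new_id[edges2]
  tree <- list(edge = edges2, edge.length = lengths[edge_order],
               tip.label = labels, Nnode = n_internal)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

# depth-first (preorder) edge ordering: each edge precedes its subtree's edges
preorder_edges <- function(edges, children, root, n) {
  out <- integer(0)
  walk <- function(node) {
    for (e in children[[as.character(node)]]) {
      out <<- c(out, e)
      child <- edges[e, 2]
      if (child > n) walk(child)
    }
  }
  walk(root)
  out
}

#' Unrooted bipartitions of a tree
#'
#' Each internal edge splits the taxa in two; a split is represented
#' canonically as the sorted side that does not contain the first tip label
#' (alphabetically), encoded as a single string.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split encodings (internal edges with
#'   a non-trivial split only).
#' @export
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  n <- length(tree$tip.label)
  splits <- character(0)
  desc <- descendant_tips(tree)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    side <- tree$tip.label[desc[[child]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1 || length(side) >= n - 1) next
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

# tip indices below each node
descendant_tips <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  desc <- vector("list", total)
  for (i in seq_len(n)) desc[[i]] <- i
  # postorder: children before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

#' Bootstrap a neighbor-joining tree from a SNP alignment
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times; the support of each
#' internal bipartition of the point tree is the percentage of replicate
#' trees containing it (classic Felsenstein-style supports on the
#' point-estimate topology).
#'
#' @param sm A [snp_matrix()] or character matrix.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed; replicates draw their column indices from a
#'   stream deterministically derived from it.
#' @param model Distance model passed to [snp_distance()].
#' @return List with `tree` (point-estimate `phylo` with `node.label`
#'   supports), `support` (named vector, canonical split -> percentage) and
#'   `n_reps`.
#' @export
bootstrap_nj <- function(sm, n_reps = 1000L, seed = 1L, model = "JC69") {
  calls <- if (inherits(sm, "snp_matrix")) sm$calls else sm
  if (ncol(calls) < 1) stop("alignment must have at least one column")
  point <- neighbor_joining(suppressWarnings(snp_distance(calls, model = model)))
  splits <- tree_bipartitions(point)
  hits <- setNames(numeric(length(splits)), splits)
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(ncol(calls), replace = TRUE)
    boot <- calls[, idx, drop = FALSE]
    bt <- neighbor_joining(suppressWarnings(snp_distance(boot, model = model)))
    bsplits <- tree_bipartitions(bt)
    hits[splits %in% bsplits] <- hits[splits %in% bsplits] + 1
  }
  support <- 100 * hits / n_reps
  point$node.label <- node_support_labels(point, support)
  list(tree = point, support = support, n_reps = n_reps)
}

# map split supports onto internal-node labels (root and trivial nodes blank)
node_support_labels <- function(tree, support) {
  n <- length(tree$tip.label)
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  desc <- descendant_tips(tree)
  labs <- rep("", tree$Nnode)
  for (node in (n + 1):(n + tree$Nnode)) {
    side <- tree$tip.label[desc[[node]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1 || length(side) >= n - 1) next
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labs[node - n] <- format(round(support[[key]], 1), trim = TRUE)
    }
  }
  labs
}

#' Root a tree on an outgroup
#'
#' @param tree A `phylo` object.
#' @param outgroup Tip label of the outgroup taxon.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' not present in the tree")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Assign accessions to named clades by exemplar sets
#'
#' Each clade is defined by a set of exemplar accessions; its members are all
#' tips of the smallest monophyletic group (MRCA clade on the rooted tree)
#' containing the exemplars. If the exemplar set is not monophyletic the
#' nearest containing clade is still reported and the clade is flagged. Tips
#' covered by several clade definitions take the smallest containing group.
#'
#' @param tree Rooted `phylo`.
#' @param clade_defs Named list of character vectors of exemplar tip labels.
#' @return List with `membership` (named vector tip -> clade label or NA) and
#'   `non_monophyletic` (character vector of flagged clade names).
#' @export
clade_membership <- function(tree, clade_defs) {
  stopifnot(!is.null(names(clade_defs)))
  n <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  membership <- setNames(rep(NA_character_, n), tree$tip.label)
  group_size <- setNames(rep(Inf, n), tree$tip.label)
  flagged <- character(0)
  for (nm in names(clade_defs)) {
    ex <- clade_defs[[nm]]
    missing <- setdiff(ex, tree$tip.label)
    if (length(missing)) stop("exemplars not in tree: ", paste(missing, collapse = ", "))
    node <- if (length(ex) == 1) match(ex, tree$tip.label) else
      ape::getMRCA(tree, ex)
    tips <- tree$tip.label[desc[[node]]]
    other_ex <- unlist(clade_defs[setdiff(names(clade_defs), nm)])
    if (length(intersect(tips, other_ex))) {
      # containing group swallows exemplars of other clades: the exemplar set
      # is not monophyletic with respect to the competing definitions
      flagged <- c(flagged, nm)
    }
    take <- length(tips) < group_size[tips]
    membership[tips[take]] <- nm
    group_size[tips[take]] <- length(tips)
  }
  list(membership = membership, non_monophyletic = unique(flagged))
}

#' Write / read Newick
#'
#' Thin wrappers over ape that keep node-label supports intact.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick` returns `path`; `read_newick` returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
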
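#' Encode a SNP matrix as binary non-reference-allele indicators
#'
#' Each retained site contributes one column per non-reference allele observed
#' there; an accession scores 1 in the column of the allele it carries and 0
#' elsewhere (all zeros across a site's columns = carries the reference
#' allele). Columns are ordered by reference position, then allele
#' alphabetically; all-zero columns are dropped.
#'
#' @param sm A [snp_matrix()].
#' @param ref_bases Character vector of reference bases, one per retained site
#'   (length `ncol(sm$calls)`), or a genome-length vector indexed by
#'   `sm$positions`.
#' @return List of class `encoded_matrix` with `x` (numeric 0/1 matrix),
#'   `site` (reference position per column) and `allele` (base per column).
#' @export
encode_alleles <- function(sm, ref_bases) {
  stopifnot(inherits(sm, "snp_matrix"))
  n_sites <- ncol(sm$calls)
  if (length(ref_bases) != n_sites) ref_bases <- ref_bases[sm$positions]
  if (anyNA(ref_bases)) stop("reference base missing for a retained site")
  cols <- list()
  site <- integer(0)
  allele <- character(0)
  for (j in seq_len(n_sites)) {
    obs <- sm$calls[, j]
    alts <- sort(setdiff(unique(obs), ref_bases[j]))
    for (a in alts) {
      cols[[length(cols) + 1L]] <- as.numeric(obs == a)
      site <- c(site, sm$positions[j])
      allele <- c(allele, a)
    }
  }
  x <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(sm$calls), 0)
  rownames(x) <- sm$accessions
  keep <- colSums(x) > 0
  structure(list(x = x[, keep, drop = FALSE], site = site[keep],
                 allele = allele[keep]),
            class = "encoded_matrix")
}

#' Bray-Curtis dissimilarity between two non-negative vectors
#'
#' `sum(|u - v|) / sum(u + v)`; a pair of all-zero vectors (both identical to
#' the reference at every encoded allele) is defined as 0 with a warning.
#'
#' @param u,v Equal-length non-negative numeric vectors.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop("vectors must be non-negative")
  denom <- sum(u + v)
  if (denom == 0) {
    warning("both vectors all-zero (reference-identical pair); distance set to 0")
    return(0)
  }
  sum(abs(u - v)) / denom
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param em An [encode_alleles()] result or a plain numeric matrix with row
#'   names.
#' @return Object of class `distance_matrix`: symmetric matrix with zero
#'   diagonal and accession ids as dimnames.
#' @export
bray_curtis_matrix <- function(em) {
  x <- if (inherits(em, "encoded_matrix")) em$x else em
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- suppressWarnings(bray_curtis(x[i, ], x[j, ]))
    }
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Classic UPGMA: the distance between clusters is the size-weighted
#' arithmetic mean of member-pair distances. Ties in the minimum inter-cluster
#' distance are broken by the smallest leaf index of the candidate pair, so
#' the merge order is fully deterministic. Dendrogram node heights follow the
#' ultrametric convention (half the merge distance); the raw merge distances
#' are retained alongside.
#'
#' @param d Square symmetric distance matrix (or `distance_matrix`).
#' @return Object of class `upgma_tree` with `merge` (hclust-style merge
#'   matrix), `height` (half merge distance), `merge_distance` (full),
#'   `labels` and `order`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)                # current cluster ids; leaves are 1..n
  members <- as.list(seq_len(n))      # leaf indices per active cluster
  node_of <- -seq_len(n)              # hclust code: negative = leaf
  cur <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        dij <- cur[i, j]
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
        # exact ties: prefer the pair whose smallest leaf index is smallest,
        # then the smaller partner; row-major scan already realises this
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(node_of[i], node_of[j]))
    if (node_of[i] < 0 && node_of[j] < 0) {
      merge[step, ] <- rev(sort(c(node_of[i], node_of[j])))  # smaller leaf first
    }
    height[step] <- best_d / 2
    ni <- length(members[[i]]); nj <- length(members[[j]])
    new_members <- c(members[[i]], members[[j]])
    # weighted average linkage update (Lance-Williams for UPGMA)
    new_row <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    members <- c(members[keep], list(new_members))
    node_of <- c(node_of[keep], step)
    active <- seq_len(m - 1)
  }
  hc <- structure(list(merge = merge, height = height * 2, labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "bray-curtis"),
                  class = "hclust")
  hc$order <- order_dendrogram(merge, n)
  structure(list(merge = merge, height = height, merge_distance = height * 2,
                 labels = labels, order = hc$order, hclust = hc),
            class = "upgma_tree")
}

# leaf order by depth-first traversal of the merge matrix
order_dendrogram <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("upgma_tree:", length(x$labels), "leaves, root height",
      signif(max(x$height), 4), "\n")
  invisible(x)
}

#' @export
as.hclust.upgma_tree <- function(x, ...) x$hclust

#' Convert a UPGMA tree to an ape phylo object (ultrametric, half-heights)
#' @param x An `upgma_tree`.
#' @param ... Unused.
#' @return An object of class `phylo` with ultrametric branch lengths.
#' @export
as_phylo_upgma <- function(x, ...) {
  hc <- x$hclust
  hc$height <- x$height  # half merge distance = ultrametric node heights
  ape::as.phylo(hc)
}

#' Cut a UPGMA dendrogram into k flat clusters
#'
#' Cuts the k-1 highest merges; cluster labels are renumbered so that cluster
#' 1 contains the smallest leaf index, cluster 2 the smallest leaf index not
#' in cluster 1, and so on.
#'
#' @param tree An [upgma()] result.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  raw <- stats::cutree(tree$hclust, k = k)
  first_seen <- unique(raw)  # cutree already orders by first occurrence...
  relabel <- match(raw, first_seen)
  names(relabel) <- tree$labels
  relabel
}

#' Principal component analysis of the encoded SNP matrix
#'
#' Columns are mean-centred (not scaled); components come from the singular
#' value decomposition of the centred matrix (equivalently the
#' eigendecomposition of the covariance). The sign of each component is fixed
#' so that its largest-magnitude loading is positive.
#'
#' @param em An [encode_alleles()] result or numeric matrix.
#' @param n_components Number of components to return.
#' @return List with `scores` (accessions x components), `loadings`,
#'   `explained` (per-component proportion of variance) and `sdev`.
#' @export
snp_pca <- function(em, n_components = 10L) {
  x <- if (inherits(em, "encoded_matrix")) em$x else em
  if (nrow(x) < 2 || ncol(x) < 1) stop("need >= 2 accessions and >= 1 column")
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var == 0) stop("zero-variance input: explained proportions undefined")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, length(p$sdev), sum(p$sdev > 1e-12))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings,
       explained = explained[seq_len(k)], sdev = p$sdev[seq_len(k)])
}

#' Write a distance matrix as square TSV with id header row/column
#' @param d A `distance_matrix` (or square matrix with dimnames).
#' @param path Output TSV path.
#' @export
write_distance_tsv <- function(d, path) {
  d <- as.matrix(d)
  df <- data.table::data.table(id = rownames(d))
  for (j in seq_len(ncol(d))) df[[colnames(d)[j]]] <- d[, j]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
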
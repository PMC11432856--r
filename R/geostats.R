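#' Default clade-to-group mapping for wild beet mitotypes
#'
#' Wild Beta vulgaris mitochondrial clades fall into two large groups whose
#' geographic distributions differ: GroupA = clades 1, 2, 4A, 4B, 4C, 4D
#' (Mediterranean-overrepresented) and GroupB = clades 3, 4E, 4F, 4G, 4H
#' (Atlantic-overrepresented).
#'
#' @return Named character vector clade -> group.
#' @export
default_group_map <- function() {
  c("1" = "GroupA", "2" = "GroupA", "4A" = "GroupA", "4B" = "GroupA",
    "4C" = "GroupA", "4D" = "GroupA",
    "3" = "GroupB", "4E" = "GroupB", "4F" = "GroupB", "4G" = "GroupB",
    "4H" = "GroupB")
}

#' Map a clade label to its large mitochondrial group
#'
#' @param clade Clade label(s).
#' @param gm Named vector clade -> group; defaults to [default_group_map()].
#' @return Group label(s).
#' @export
assign_group <- function(clade, gm = default_group_map()) {
  out <- gm[as.character(clade)]
  if (anyNA(out)) {
    stop("unmapped clade label(s): ",
         paste(unique(clade[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Build the coast x mitochondrial-group contingency table
#'
#' Accessions whose coast is not Atlantic or Mediterranean, or whose clade is
#' unmapped, are excluded and counted in `excluded_n`.
#'
#' @param meta data.frame with columns `coast` and `clade` (one row per
#'   accession).
#' @param gm Clade-to-group map.
#' @return Object of class `contingency2x2`: list with `table` (2x2 integer
#'   matrix, rows Atlantic/Mediterranean, columns GroupA/GroupB), `margins`
#'   and `excluded_n`.
#' @export
build_contingency <- function(meta, gm = default_group_map()) {
  coasts <- c("Atlantic", "Mediterranean")
  ok_coast <- meta$coast %in% coasts
  ok_clade <- as.character(meta$clade) %in% names(gm)
  keep <- ok_coast & ok_clade
  excluded <- sum(!keep)
  m <- meta[keep, , drop = FALSE]
  group <- assign_group(m$clade, gm)
  groups <- sort(unique(unname(gm)))
  tab <- matrix(0L, 2, length(groups), dimnames = list(coasts, groups))
  t0 <- table(factor(m$coast, levels = coasts),
              factor(group, levels = groups))
  tab[] <- as.integer(t0)
  contingency2x2(tab, excluded_n = excluded)
}

#' @rdname build_contingency
#' @param counts data.frame of per-clade counts with columns `clade`,
#'   `Atlantic`, `Mediterranean` (one row per clade), e.g. as returned by
#'   [wild_beet_clade_counts()].
#' @export
contingency_from_counts <- function(counts, gm = default_group_map()) {
  group <- assign_group(counts$clade, gm)
  groups <- sort(unique(unname(gm)))
  tab <- matrix(0L, 2, length(groups),
                dimnames = list(c("Atlantic", "Mediterranean"), groups))
  for (g in groups) {
    rows <- group == g
    tab["Atlantic", g] <- sum(counts$Atlantic[rows])
    tab["Mediterranean", g] <- sum(counts$Mediterranean[rows])
  }
  contingency2x2(tab, excluded_n = 0L)
}

contingency2x2 <- function(tab, excluded_n = 0L) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  storage.mode(tab) <- "integer"
  row_m <- rowSums(tab); col_m <- colSums(tab)
  storage.mode(row_m) <- storage.mode(col_m) <- "integer"
  structure(list(table = tab,
                 margins = list(row = row_m, col = col_m,
                                total = as.integer(sum(tab))),
                 excluded_n = as.integer(excluded_n)),
            class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  print(x$table)
  cat("total:", x$margins$total)
  if (x$excluded_n > 0) cat(" (", x$excluded_n, " excluded)", sep = "")
  cat("\n")
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table (log-space)
#'
#' Exact p-value by summing, over all tables with the observed margins, the
#' hypergeometric probabilities that do not exceed the observed table's
#' probability (the minimum-likelihood rule used by mainstream statistics
#' tools). Probabilities are computed in log space via `lgamma` for numerical
#' stability; float ties are resolved with a relative tolerance of 1e-7 when
#' comparing table probabilities.
#'
#' @param x A `contingency2x2`, or a 2x2 matrix of non-negative counts.
#' @param tie_tol Relative tolerance for probability ties.
#' @return The two-sided p-value in (0, 1]. A zero row or column margin
#'   returns p = 1 with a warning.
#' @export
fisher_exact <- function(x, tie_tol = 1e-7) {
  tab <- if (inherits(x, "contingency2x2")) x$table else as.matrix(x)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("zero margin: p = 1 by convention")
    return(1)
  }
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  ks <- lo:hi
  # log P(A = k) for hypergeometric with margins (r1, n - r1; c1, n - c1)
  logp <- lgamma(r1 + 1) - lgamma(ks + 1) - lgamma(r1 - ks + 1) +
    lgamma(n - r1 + 1) - lgamma(c1 - ks + 1) - lgamma(n - r1 - c1 + ks + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  log_obs <- logp[ks == a]
  include <- logp <= log_obs + log1p(tie_tol)
  # log-sum-exp over the included tables
  mx <- max(logp[include])
  p <- exp(mx + log(sum(exp(logp[include] - mx))))
  min(p, 1)
}

#' Bundled survey counts of wild beet accessions by coast and clade
#'
#' Per-clade counts of wild Beta vulgaris (ssp. maritima and ssp. adanensis)
#' accessions collected on the Atlantic and Mediterranean coasts, across the
#' eleven mitochondrial clades (1, 2, 3, 4A-4H). Summing within the two large
#' mitochondrial groups yields the 2x2 table used for the geographic
#' association test.
#'
#' @return data.frame with columns `clade`, `Atlantic`, `Mediterranean`.
#' @export
wild_beet_clade_counts <- function() {
  path <- system.file("extdata", "wild_beet_clade_counts.tsv",
                      package = "mitovar")
  df <- utils::read.delim(path, colClasses = c("character", "integer", "integer"))
  df
}

#' Geographic association report
#'
#' Builds the 2x2 coast x group table from accession metadata and computes
#' the two-sided Fisher exact p-value.
#'
#' @param meta Accession metadata (see [build_contingency()]).
#' @param gm Clade-to-group map.
#' @return List with `table`, `margins`, `p_value`, `excluded_n`.
#' @export
geo_association <- function(meta, gm = default_group_map()) {
  ct <- build_contingency(meta, gm)
  list(table = ct$table, margins = ct$margins,
       p_value = fisher_exact(ct), excluded_n = ct$excluded_n)
}
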
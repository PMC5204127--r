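#' Build binary phylogenetic profiles of features across gene copies
#'
#' Entry `(copy, feature)` is 1 iff the copy carries at least `min_hits`
#' accepted hits of that feature. All-zero (or all-one) feature columns are
#' retained in the matrix but flagged as `constant`, since Pearson
#' correlation is undefined for them.
#'
#' @param hits accepted feature hit table.
#' @param gene_copies data frame with columns `id`, `paralogue_label`,
#'   `clade_label` — the gene copies forming the rows (typically the
#'   duplicated copies only).
#' @param features character vector of feature ids forming the columns.
#' @param min_hits minimum hit count for presence (default 1).
#' @return An object of class `confeax_profiles`: list with `matrix`
#'   (copies x features, 0/1), `copies`, `constant`.
#' @export
build_profiles <- function(hits, gene_copies, features, min_hits = 1L) {
  hits <- validate_hits(hits)
  if (anyDuplicated(gene_copies$id)) stop("duplicate copy ids", call. = FALSE)
  if (anyDuplicated(features)) stop("duplicate feature ids", call. = FALSE)
  keep <- hits$seq_id %in% gene_copies$id
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) && any(!hits$feature_id %in% features))
    stop("hit references unknown feature id", call. = FALSE)
  m <- matrix(0L, nrow(gene_copies), length(features),
              dimnames = list(gene_copies$id, features))
  if (nrow(hits)) {
    tab <- table(factor(hits$seq_id, levels = gene_copies$id),
                 factor(hits$feature_id, levels = features))
    m[] <- as.integer(tab >= min_hits)
  }
  structure(list(matrix = m, copies = gene_copies,
                 constant = features[apply(m, 2, function(x) length(unique(x)) == 1)]),
            class = "confeax_profiles")
}

#' @export
print.confeax_profiles <- function(x, ...) {
  cat(sprintf("Feature profile matrix: %d gene copies x %d features (%d constant)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$constant)))
  invisible(x)
}

#' Pairwise Pearson correlation of feature profiles
#'
#' Standard Pearson r between binary feature columns across gene copies.
#' Constant columns have undefined r: their rows/columns are `NA` and they
#' are flagged for exclusion from clustering.
#'
#' @param profiles a `confeax_profiles` or a numeric matrix (copies x
#'   features).
#' @return Symmetric feature x feature correlation matrix with unit
#'   diagonal where defined.
#' @export
pearson_matrix <- function(profiles) {
  m <- if (inherits(profiles, "confeax_profiles")) profiles$matrix else profiles
  if (nrow(m) < 2) stop("need at least 2 gene copies", call. = FALSE)
  suppressWarnings(r <- cor(m))
  diag(r)[!is.nan(diag(r))] <- 1
  r[is.nan(r)] <- NA_real_
  const <- apply(m, 2, function(x) var(x) == 0)
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r)[!const] <- 1
  r
}

#' Pearson distance d = 1 - r
#'
#' @param r correlation matrix (entries in `[-1, 1]`).
#' @return Distance matrix in `[0, 2]` with zero diagonal.
#' @export
pearson_distance <- function(r) {
  d <- 1 - r
  if (!is.null(dim(d))) diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Repeatedly merges the pair of clusters with the smallest average
#' inter-cluster distance; the merge height is that average divided by 2
#' (ultrametric convention). Ties are broken by the lexicographically
#' smallest pair of cluster representatives (each cluster represented by its
#' smallest member label). Features with `NA` distances (constant profiles)
#' are excluded with a warning before clustering.
#'
#' @param d symmetric distance matrix with labelled rows/columns.
#' @return An object of class `confeax_dendrogram`: list with `merge` and
#'   `height` (hclust conventions), `labels`, `newick`, `hclust`, and
#'   `excluded` (features dropped for undefined distances).
#' @export
average_linkage_cluster <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  # drop the smallest set of items that removes all undefined distances
  # (greedily: the item with the most NAs first)
  excluded <- character(0)
  while (anyNA(d)) {
    worst <- which.max(rowSums(is.na(d)))
    excluded <- c(excluded, rownames(d)[worst])
    d <- d[-worst, -worst, drop = FALSE]
  }
  if (length(excluded)) {
    warning("excluding items with undefined distances: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    labels <- rownames(d)
  }
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items to cluster", call. = FALSE)

  size <- rep(1L, n)
  rep_lab <- labels                  # lexicographic representative
  idx <- -seq_len(n)                 # hclust coding: negative = singleton
  active <- rep(TRUE, n)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    best <- NULL
    act <- which(active)
    for (ai in seq_along(act)) for (aj in seq_along(act)) {
      if (aj <= ai) next
      i <- act[ai]; j <- act[aj]
      dist_ij <- D[i, j]
      pair <- sort(c(rep_lab[i], rep_lab[j]))
      if (is.null(best) || dist_ij < best$d ||
          (dist_ij == best$d &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(i = i, j = j, d = dist_ij, pair = pair)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(idx[i], idx[j]))
    height[step] <- best$d / 2
    # UPGMA update: size-weighted average distance to the new cluster
    for (k in act) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- (size[i] * D[i, k] + size[j] * D[j, k]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    idx[i] <- step
  }

  hc <- structure(list(merge = merge, height = height,
                       order = dendrogram_order(merge, n),
                       labels = labels, method = "average",
                       call = match.call(), dist.method = "pearson"),
                  class = "hclust")
  structure(list(merge = merge, height = height, labels = labels,
                 newick = merges_to_newick(merge, height, labels),
                 hclust = hc, excluded = excluded),
            class = "confeax_dendrogram")
}

# leaf order with no branch crossings (hclust convention)
dendrogram_order <- function(merge, n) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(n - 1)
}

# newick string with branch lengths = height differences (leaves at 0)
merges_to_newick <- function(merge, height, labels) {
  node <- function(i) {
    if (i < 0) return(list(txt = labels[-i], h = 0))
    a <- node(merge[i, 1]); b <- node(merge[i, 2])
    h <- height[i]
    list(txt = sprintf("(%s:%.10g,%s:%.10g)", a$txt, h - a$h, b$txt, h - b$h),
         h = h)
  }
  paste0(node(nrow(merge))$txt, ";")
}

#' @export
print.confeax_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram of %d items (heights %.3g .. %.3g)\n",
              length(x$labels), min(x$height), max(x$height)))
  if (length(x$excluded))
    cat("  excluded (undefined distances):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Full coevolution analysis of a profile matrix
#'
#' Computes the Pearson correlation matrix, the distance `d = 1 - r`, the
#' UPGMA dendrogram, and the co-segregation report at the `k`-cluster cut.
#'
#' @param profiles a `confeax_profiles`.
#' @param k number of clusters for the headline report (default 2, the
#'   expected subfunctionalized split).
#' @return An object of class `confeax_coevolution` with elements `r`, `d`,
#'   `dendrogram`, `clusters`, `report`, `constant`.
#' @export
coevolution_analysis <- function(profiles, k = 2) {
  r <- pearson_matrix(profiles)
  d <- pearson_distance(r)
  dend <- average_linkage_cluster(d)
  rep <- cosegregation_report(dend, profiles, k = k)
  structure(list(r = r, d = d, dendrogram = dend,
                 clusters = rep$clusters, report = rep,
                 constant = profiles$constant),
            class = "confeax_coevolution")
}

#' Co-segregating feature sets at a dendrogram cut
#'
#' Cuts the feature dendrogram into `k` clusters and reports, per cluster,
#' the mean feature presence within each paralogue label — the red/blue
#' co-presence/absence signature of subfunctionalization.
#'
#' @param dend a `confeax_dendrogram` over features.
#' @param profiles the `confeax_profiles` the distances came from.
#' @param k number of clusters (at most the number of clustered features).
#' @return List with `clusters` (named membership vector) and `enrichment`
#'   (cluster x paralogue mean-presence matrix).
#' @export
cosegregation_report <- function(dend, profiles, k = 2) {
  if (k > length(dend$labels))
    stop("k exceeds the number of clustered features", call. = FALSE)
  cl <- stats::cutree(dend$hclust, k = k)
  m <- profiles$matrix
  par <- profiles$copies$paralogue_label
  pls <- sort(unique(par))
  enr <- matrix(NA_real_, k, length(pls),
                dimnames = list(paste0("cluster", seq_len(k)), pls))
  for (ci in seq_len(k)) {
    feats <- names(cl)[cl == ci]
    for (p in pls)
      enr[ci, p] <- mean(m[par == p, feats, drop = FALSE])
  }
  list(clusters = cl, enrichment = enr, k = k)
}

#' @export
print.confeax_coevolution <- function(x, ...) {
  cat(sprintf("Coevolution analysis: %d features", ncol(x$r)))
  if (length(x$constant))
    cat(sprintf(" (%d constant, excluded from clustering)", length(x$constant)))
  cat("\n")
  k <- x$report$k
  for (ci in seq_len(k)) {
    feats <- names(x$clusters)[x$clusters == ci]
    cat(sprintf("  cluster %d: %s\n", ci, paste(feats, collapse = ", ")))
  }
  cat("  mean presence by paralogue:\n")
  print(round(x$report$enrichment, 3))
  invisible(x)
}
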
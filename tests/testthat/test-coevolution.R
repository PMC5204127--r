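copies_df <- function(ids, par = NULL) {
  data.frame(id = ids,
             paralogue_label = par %||% rep(c("MAD", "BUB"), length.out = length(ids)),
             clade_label = NA_character_, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("profile matrix: presence thresholds, dimensions, constant flags", {
  hits <- data.frame(feature_id = c("ABBA", "ABBA", "KEN"),
                     seq_id = c("c1", "c1", "c2"),
                     start = c(0L, 20L, 5L), end = c(6L, 26L, 13L),
                     score_bits = 1, evalue = 0.001, iteration = 1L,
                     stringsAsFactors = FALSE)
  copies <- copies_df(c("c1", "c2", "c3"))
  p <- build_profiles(hits, copies, c("ABBA", "KEN", "DBOX"))
  expect_equal(dim(p$matrix), c(3L, 3L))
  expect_equal(p$matrix["c1", "ABBA"], 1L)   # 2 hits, min_hits 1
  expect_equal(p$matrix["c3", "ABBA"], 0L)   # no hits
  expect_true("DBOX" %in% p$constant)        # all-zero column retained, flagged

  p2 <- build_profiles(hits, copies, c("ABBA", "KEN", "DBOX"), min_hits = 2)
  expect_equal(p2$matrix["c1", "ABBA"], 1L)
  expect_equal(p2$matrix["c2", "KEN"], 0L)

  expect_error(build_profiles(hits, copies, "ABBA"), "unknown feature")
})

test_that("Pearson matrix: identity, anti-correlation, hand-computed zero", {
  m <- cbind(f1 = c(1, 1, 0, 0), f2 = c(1, 1, 0, 0), f3 = c(0, 0, 1, 1),
             f4 = c(1, 0, 1, 0))
  r <- pearson_matrix(m)
  expect_equal(r["f1", "f2"], 1)
  expect_equal(r["f1", "f3"], -1)
  expect_equal(r["f4", "f1"], 0)   # covariance cancels
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))

  # constant columns are NA and flagged
  m2 <- cbind(m, f5 = c(1, 1, 1, 1))
  r2 <- pearson_matrix(m2)
  expect_true(all(is.na(r2["f5", ])))

  # permutation of rows leaves r unchanged; feature order permutes r
  perm <- c(3, 1, 4, 2)
  expect_equal(pearson_matrix(m[perm, ]), r)
  expect_equal(pearson_matrix(m[, c(2, 1, 3, 4)]),
               r[c(2, 1, 3, 4), c(2, 1, 3, 4)])
})

test_that("Pearson distance is 1 - r with the right range and diagonal", {
  r <- matrix(c(1, -1, 0, -1, 1, 0.5, 0, 0.5, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  d <- pearson_distance(r)
  expect_equal(d["a", "b"], 2)   # r = -1
  expect_equal(d["a", "c"], 1)   # r = 0
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("UPGMA: hand-checked 3-item agglomeration", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.5
  d["B", "C"] <- d["C", "B"] <- 0.5
  cl <- average_linkage_cluster(d)
  expect_equal(cl$height, c(0.05, 0.25))
  expect_equal(cl$merge[1, ], c(-2L, -1L))
  expect_equal(cl$merge[2, ], c(-3L, 1L))
})

test_that("UPGMA equals the brute-force reference on random matrices", {
  set.seed(61)
  for (rep in 1:40) {
    n <- 8
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    dimnames(d) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
    cl <- average_linkage_cluster(d)
    ref <- upgma_reference(d)
    expect_equal(cl$merge, ref$merge)
    expect_equal(cl$height, ref$height, tolerance = 1e-12)
    # heights are non-decreasing (no inversions for average linkage)
    expect_true(all(diff(cl$height) >= -1e-12))
  }
})

test_that("identical items merge first at height 0; newick is well-formed", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0
  cl <- average_linkage_cluster(d)
  expect_equal(cl$height[1], 0)
  expect_equal(sort(cl$merge[1, ]), c(-2L, -1L))
  skip_if_not_installed("ape")
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, letters[1:4])
  # ultrametric: all tips equidistant from the root
  depths <- ape::node.depth.edgelength(tree)[seq_len(4)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
})

test_that("NA rows from constant features are excluded with a warning", {
  m <- cbind(f1 = c(1, 1, 0, 0), f2 = c(0, 0, 1, 1), f3 = c(1, 0, 1, 0),
             f4 = c(1, 1, 1, 1))
  d <- pearson_distance(pearson_matrix(m))
  expect_warning(cl <- average_linkage_cluster(d), "f4")
  expect_setequal(cl$labels, c("f1", "f2", "f3"))
  expect_equal(cl$excluded, "f4")
})

test_that("noiseless subfunctionalized features split exactly at k = 2", {
  copies <- copies_df(sprintf("c%02d", 1:8),
                      par = rep(c("MAD", "BUB"), each = 4))
  m <- cbind(A = rep(c(1, 0), each = 4), B = rep(c(1, 0), each = 4),
             C = rep(c(1, 0), each = 4), D = rep(c(0, 1), each = 4),
             E = rep(c(0, 1), each = 4))
  rownames(m) <- copies$id
  profiles <- structure(list(matrix = m, copies = copies,
                             constant = character(0)),
                        class = "confeax_profiles")
  co <- coevolution_analysis(profiles, k = 2)
  cl <- co$clusters
  expect_equal(length(unique(cl[c("A", "B", "C")])), 1L)
  expect_equal(length(unique(cl[c("D", "E")])), 1L)
  expect_false(cl[["A"]] == cl[["D"]])
  # enrichment mirrors the red/blue blocks: MAD cluster present in MAD only
  enr <- co$report$enrichment
  madcl <- cl[["A"]]
  expect_equal(unname(enr[madcl, "MAD"]), 1)
  expect_equal(unname(enr[madcl, "BUB"]), 0)

  # k = n features -> singletons
  co_n <- cosegregation_report(co$dendrogram, profiles, k = 5)
  expect_equal(sort(unname(co_n$clusters)), 1:5)
  expect_error(cosegregation_report(co$dendrogram, profiles, k = 6), "exceeds")
})

test_that("anti-correlated sets separate whenever within < between distances", {
  set.seed(71)
  for (rep in 1:10) {
    n_each <- sample(2:4, 2, replace = TRUE)
    labs <- c(paste0("m", seq_len(n_each[1])), paste0("b", seq_len(n_each[2])))
    n <- length(labs)
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    within <- runif(1, 0, 0.4)
    between <- within + runif(1, 0.1, 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      same <- substr(labs[i], 1, 1) == substr(labs[j], 1, 1)
      d[i, j] <- d[j, i] <- if (same) within * runif(1) else
        between + runif(1, 0, 0.2)
    }
    cl <- average_linkage_cluster(d)
    hc <- stats::cutree(cl$hclust, k = 2)
    expect_equal(length(unique(hc[grep("^m", labs)])), 1L)
    expect_equal(length(unique(hc[grep("^b", labs)])), 1L)
    expect_false(hc[[grep("^m", labs)[1]]] == hc[[grep("^b", labs)[1]]])
  }
})
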
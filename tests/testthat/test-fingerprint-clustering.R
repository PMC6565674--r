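test_that("z-normalization matches hand arithmetic and is idempotent", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, -1))
  Z <- normalize_matrix(X)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(Z[, "b"]), c(0, 0, 0))
  expect_equal(max(abs(colMeans(Z))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(Z[, c("a", "c")], 2, sd)), c(1, 1))
  expect_lt(max(abs(normalize_matrix(Z) - Z)), 1e-12)
  expect_error(normalize_matrix(X[1, , drop = FALSE]), ">= 2")
  # missing entries are mean-imputed before scaling
  Xm <- X; Xm[2, 1] <- NA
  expect_message(Zm <- normalize_matrix(Xm), "imputing")
  expect_false(anyNA(Zm))
})

test_that("hierarchical clustering recovers planted groups exactly", {
  set.seed(1)
  d <- 10
  g1 <- t(replicate(4, rnorm(d, 0, 0.1)))
  g2 <- t(replicate(4, c(5, rep(0, d - 1)) + rnorm(d, 0, 0.1)))
  M <- rbind(g1, g2)
  rownames(M) <- c(paste0("WT-0h-", 1:4), paste0("Mut-0h-", 1:4))
  attr(M, "normalized") <- TRUE
  tree <- cluster_fingerprints(M)
  cl <- tree$assignment
  # adjusted Rand index 1 <=> identical partitions up to relabeling
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])
  expect_equal(tree$reference_cluster, unname(cl[1]))
  # duplicated rows merge at height zero
  Md <- rbind(M, M[1, , drop = FALSE])
  rownames(Md)[9] <- "WT-0h-copy"
  attr(Md, "normalized") <- TRUE
  t2 <- suppressWarnings(cluster_fingerprints(Md))
  expect_equal(min(t2$hclust$height), 0)
  # single row: one cluster, no merges
  M1 <- M[1, , drop = FALSE]; attr(M1, "normalized") <- TRUE
  t1 <- cluster_fingerprints(M1)
  expect_null(t1$hclust)
  expect_equal(unname(t1$assignment), 1L)
})

test_that("distance to the reference centroid is Euclidean and translation invariant", {
  set.seed(2)
  M <- rbind("WT-0h-1" = rep(1, 6), "WT-0h-2" = rep(3, 6),
             "Mut-4h-x" = rep(10, 6))
  attr(M, "normalized") <- TRUE
  tree <- cluster_fingerprints(M)
  expect_equal(distance_to_reference(rep(2, 6), tree), 0)
  expect_equal(distance_to_reference(rep(2, 6) + c(3, 4, 0, 0, 0, 0), tree), 5)
  shift <- rnorm(6)
  Ms <- sweep(M, 2, -shift); attr(Ms, "normalized") <- TRUE
  tr2 <- cluster_fingerprints(Ms)
  expect_equal(distance_to_reference(rep(2, 6) + shift, tr2),
               distance_to_reference(rep(2, 6), tree))
})

test_that("BCD and WCD behave as centroid distance and within-group scatter", {
  d <- 40
  wt0 <- matrix(7, 2, d)
  mut0 <- matrix(7, 3, d)
  M0 <- rbind(wt0, mut0)
  q0 <- cluster_quality(M0, 1:2, 3:5)
  expect_equal(unname(q0), c(0, 0))
  set.seed(3)
  dst <- 6; s <- 0.5
  wt <- t(replicate(40, rnorm(d, 0, s)))
  mut <- t(replicate(40, c(dst, rep(0, d - 1)) + rnorm(d, 0, s)))
  q <- cluster_quality(rbind(wt, mut), 1:40, 41:80)
  expect_lt(abs(q["BCD"] - dst), 0.8)
  expect_lt(abs(q["WCD"] - s * sqrt(d)), 0.3)
  expect_error(cluster_quality(M0, 1, 2:3), ">= 2")
  # shrinking within-group noise increases the BCD/WCD ratio monotonically
  ratios <- vapply(c(1, 0.5, 0.25, 0.1), function(sg) {
    wtg <- t(replicate(30, rnorm(d, 0, sg)))
    mtg <- t(replicate(30, c(dst, rep(0, d - 1)) + rnorm(d, 0, sg)))
    q <- cluster_quality(rbind(wtg, mtg), 1:30, 31:60)
    unname(q["BCD"] / q["WCD"])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

# independent oracle for the elimination procedure on planted instances:
# uses the true cluster memberships and plain distance arithmetic, no
# hclust involved
brute_force_selection <- function(M, truth_labels, n_rounds) {
  ref <- colMeans(M[grep("^WT-0h", rownames(M)), , drop = FALSE])
  remaining <- unique(truth_labels[grepl("^Mut-4h", names(truth_labels))])
  hits <- character(0)
  for (r in seq_len(n_rounds)) {
    cd <- vapply(remaining, function(cl) {
      rows <- names(truth_labels)[truth_labels == cl]
      sqrt(sum((colMeans(M[rows, , drop = FALSE]) - ref)^2))
    }, numeric(1))
    best_cl <- remaining[which.min(cd)]
    rows <- names(truth_labels)[truth_labels == best_cl]
    rd <- vapply(rows, function(rr) sqrt(sum((M[rr, ] - ref)^2)), numeric(1))
    hits <- c(hits, rows[which.min(rd)])
    remaining <- setdiff(remaining, best_cl)
  }
  hits
}

test_that("iterative cluster elimination matches brute force on planted screens", {
  ps <- planted_screen_matrix(cluster_dists = c(1, 2, 3), seed = 4)
  truth_labels <- sub("[0-9]+$", "", rownames(ps$M))
  names(truth_labels) <- rownames(ps$M)
  oracle <- brute_force_selection(ps$M, truth_labels, 3)
  sel <- select_polytherapy(ps$M, n_rounds = 3)
  expect_identical(sel$hits, oracle)
  # reference rows are never selectable
  expect_false(any(grepl("^WT-0h", sel$hits)))
  # row order does not change the selection
  perm <- sample(nrow(ps$M))
  Mp <- ps$M[perm, , drop = FALSE]; attr(Mp, "normalized") <- TRUE
  expect_identical(select_polytherapy(Mp, n_rounds = 3)$hits, sel$hits)
  # determinism
  expect_identical(select_polytherapy(ps$M, n_rounds = 3)$hits, sel$hits)
})

test_that("single-cluster screens stop after their only round", {
  ps <- planted_screen_matrix(cluster_dists = 2, seed = 5)
  sel <- select_polytherapy(ps$M, n_rounds = 1)
  expect_length(sel$hits, 1)
  expect_match(sel$hits, "^Mut-4h-a")
  expect_warning(select_polytherapy(ps$M, n_rounds = 3), "exhausted|selectable")
})

test_that("planted complementary triples are recovered across seeds", {
  ok <- vapply(1:20, function(s) {
    ps <- planted_screen_matrix(cluster_dists = c(1, 2, 3), seed = s)
    truth_labels <- sub("[0-9]+$", "", rownames(ps$M))
    names(truth_labels) <- rownames(ps$M)
    identical(select_polytherapy(ps$M, n_rounds = 3)$hits,
              brute_force_selection(ps$M, truth_labels, 3))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
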
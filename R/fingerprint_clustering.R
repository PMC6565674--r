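# Fingerprint matrix normalization, hierarchical clustering, cluster-quality
# metrics, and the iterative cluster-elimination polytherapy selection.

#' Build a fingerprint matrix from per-condition fingerprints
#'
#' @param fps named list of `fc_fingerprint`s (names become row labels,
#'   e.g. `"WT-0h"`, `"Mut-0h"`, `"Mut-4h-drugA"`).
#' @return numeric matrix, rows = conditions, columns = metric ids.
#' @export
fingerprint_matrix <- function(fps) {
  stopifnot(length(fps) >= 1, !is.null(names(fps)))
  ids <- metric_ids(fps[[1]])
  X <- t(vapply(fps, function(f) f$value, numeric(length(ids))))
  dimnames(X) <- list(names(fps), ids)
  X
}

#' Z-normalize a fingerprint matrix across conditions
#'
#' Column-wise `(x - mean) / sd` over all condition rows; missing entries are
#' mean-imputed per metric first (with a message), and constant columns map
#' to zeros. Idempotent up to floating point.
#'
#' @param X numeric matrix (conditions x metrics), >= 2 rows.
#' @return normalized matrix with attribute `normalized = TRUE`.
#' @export
normalize_matrix <- function(X) {
  if (nrow(X) < 2L) stop_fc("normalization needs >= 2 condition rows")
  n_missing <- sum(is.na(X))
  if (n_missing) {
    message(sprintf("mean-imputing %d missing fingerprint entries", n_missing))
    for (c in which(colSums(is.na(X)) > 0)) {
      mu <- mean(X[, c], na.rm = TRUE)
      X[is.na(X[, c]), c] <- if (is.finite(mu)) mu else 0
    }
  }
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  Z <- sweep(X, 2L, mu)
  nz <- sd > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, sd[nz], `/`)
  Z[, !nz] <- 0
  attr(Z, "normalized") <- TRUE
  Z
}

# flat cut by the largest relative merge-height gap, with a minimum cluster
# count. The ratio form is scale-free: it finds the boundary between
# between-group and within-group merge heights instead of always preferring
# the single most separated split at the top of the tree.
cut_by_gap <- function(hc, min_k = 2, max_k = NULL) {
  n <- length(hc$height) + 1L
  max_k <- max_k %||% max(min_k, n - 1L)
  ks <- seq(max(2L, min_k), min(max_k, n))
  if (n <= min_k) return(stats::cutree(hc, k = min(n, min_k)))
  h <- sort(hc$height, decreasing = TRUE)   # h[k-1] closes the k-cluster cut
  eps <- 1e-12 + 1e-9 * max(h)
  gaps <- vapply(ks, function(k) {
    upper <- if (k == 1L) Inf else h[k - 1L]
    lower <- if (k > length(h)) 0 else h[k]
    (upper + eps) / (lower + eps)
  }, numeric(1))
  k <- ks[which.max(gaps)]   # first maximum: fewest clusters on ties
  stats::cutree(hc, k = k)
}

#' Hierarchically cluster fingerprint rows
#'
#' Agglomerative clustering of normalized fingerprints on Euclidean
#' distances with Ward linkage; the flat cut maximizes the merge-height gap
#' subject to a minimum cluster count. The reference cluster is the one
#' holding the untreated wild-type rows (majority vote with a warning if
#' they split).
#'
#' @param M normalized fingerprint matrix (see [normalize_matrix()]).
#' @param method linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @param min_k,max_k bounds for the flat cut.
#' @param reference_pattern regular expression identifying untreated
#'   wild-type rows (default `"^WT-0h"`).
#' @return object of class `fc_tree`: list with `hclust`, `assignment`
#'   (named integer vector), `reference_cluster`, and the matrix `M`.
#' @export
cluster_fingerprints <- function(M, method = "ward.D2", min_k = 2,
                                 max_k = NULL, reference_pattern = "^WT-0h") {
  if (is.null(attr(M, "normalized")))
    warning("matrix does not look normalized; call normalize_matrix() first")
  if (nrow(M) == 1L) {
    return(structure(list(hclust = NULL,
                          assignment = stats::setNames(1L, rownames(M)),
                          reference_cluster = if (grepl(reference_pattern,
                                                        rownames(M))) 1L else NA,
                          M = M),
                     class = "fc_tree"))
  }
  hc <- stats::hclust(stats::dist(M), method = method)
  cl <- cut_by_gap(hc, min_k = min_k, max_k = max_k)
  names(cl) <- rownames(M)
  ref_rows <- grep(reference_pattern, rownames(M))
  ref <- NA_integer_
  if (length(ref_rows)) {
    tab <- table(cl[ref_rows])
    ref <- as.integer(names(tab)[which.max(tab)])
    if (length(tab) > 1L)
      warning("untreated wild-type rows split across clusters; using the majority cluster")
  }
  structure(list(hclust = hc, assignment = cl, reference_cluster = ref, M = M),
            class = "fc_tree")
}

#' @export
print.fc_tree <- function(x, ...) {
  cat(sprintf("<fc_tree> %d rows, %d clusters (reference cluster %s)\n",
              length(x$assignment), length(unique(x$assignment)),
              x$reference_cluster))
  invisible(x)
}

reference_centroid <- function(tree) {
  rows <- names(tree$assignment)[tree$assignment == tree$reference_cluster]
  if (!length(rows)) stop_fc("reference cluster is empty")
  colMeans(tree$M[rows, , drop = FALSE])
}

#' Euclidean distance from a condition row to the reference centroid
#'
#' @param row numeric metric vector, or a row label present in the tree.
#' @param tree an `fc_tree`.
#' @return nonnegative scalar.
#' @export
distance_to_reference <- function(row, tree) {
  if (is.character(row)) row <- tree$M[row, ]
  sqrt(sum((row - reference_centroid(tree))^2))
}

#' Cluster-quality metrics: BCD and WCD
#'
#' Between-cluster distance: Euclidean distance between the wild-type and
#' mutant centroids (larger is better). Within-cluster distance: mean
#' distance of wild-type rows to their centroid (smaller is better).
#'
#' @param M fingerprint matrix.
#' @param wt_rows,mut_rows row labels or indices for the two groups.
#' @return named numeric `c(BCD, WCD)`.
#' @export
cluster_quality <- function(M, wt_rows, mut_rows) {
  W <- M[wt_rows, , drop = FALSE]; U <- M[mut_rows, , drop = FALSE]
  if (nrow(W) < 2L)
    stop_fc("WCD needs >= 2 wild-type rows, got %d", nrow(W))
  if (nrow(U) < 1L) stop_fc("no mutant rows")
  cw <- colMeans(W); cu <- colMeans(U)
  bcd <- sqrt(sum((cw - cu)^2))
  wcd <- mean(sqrt(rowSums(sweep(W, 2L, cw)^2)))
  c(BCD = bcd, WCD = wcd)
}

#' Iterative cluster-elimination polytherapy selection
#'
#' Each round: re-cluster the remaining compound rows together with the
#' fixed reference (and context) rows; find the non-reference cluster whose
#' centroid is nearest the reference centroid among clusters holding at
#' least one selectable compound; within it select the compound row closest
#' to the reference centroid; then eliminate that entire cluster's compounds
#' and repeat. Ties are broken lexicographically by row label, so the
#' result is deterministic and invariant to row order.
#'
#' @param M normalized fingerprint matrix; rows must include reference rows
#'   (matching `reference_pattern`) and compound rows
#'   (matching `compound_pattern`).
#' @param n_rounds number of complementary hits to select (default 3).
#' @param reference_pattern regexp for untreated wild-type rows.
#' @param compound_pattern regexp for selectable compound rows
#'   (default `"^Mut-4h-"`).
#' @param min_k,max_k,method clustering controls, see
#'   [cluster_fingerprints()].
#' @return object of class `selection_result`: list with `hits` (ordered
#'   labels), `rounds` (per-round data.frames of cluster members and
#'   distances) and `eliminated`.
#' @export
select_polytherapy <- function(M, n_rounds = 3, reference_pattern = "^WT-0h",
                               compound_pattern = "^Mut-4h-",
                               min_k = 2, max_k = NULL, method = "ward.D2") {
  all_rows <- rownames(M)[order(rownames(M))]   # row-order invariance
  M <- M[all_rows, , drop = FALSE]
  attr(M, "normalized") <- TRUE
  compounds <- grep(compound_pattern, all_rows, value = TRUE)
  context <- setdiff(all_rows, compounds)
  if (!any(grepl(reference_pattern, context)))
    stop_fc("no reference rows match '%s'", reference_pattern)

  remaining <- compounds
  hits <- character(0); rounds <- list(); eliminated <- character(0)
  for (r in seq_len(n_rounds)) {
    if (!length(remaining)) {
      warning(sprintf("clusters exhausted after %d of %d rounds", r - 1L, n_rounds))
      break
    }
    rows <- c(context, remaining)
    Msub <- M[rows, , drop = FALSE]
    attr(Msub, "normalized") <- TRUE
    tree <- cluster_fingerprints(Msub, method = method,
                                 min_k = min_k, max_k = max_k,
                                 reference_pattern = reference_pattern)
    refc <- reference_centroid(tree)
    cl <- tree$assignment
    cand <- setdiff(unique(cl), tree$reference_cluster)
    cand <- cand[vapply(cand, function(c)
      any(names(cl)[cl == c] %in% remaining), logical(1))]
    if (!length(cand)) {
      warning(sprintf("no selectable cluster left in round %d", r))
      break
    }
    cdist <- vapply(cand, function(c) {
      sqrt(sum((colMeans(tree$M[names(cl)[cl == c], , drop = FALSE]) - refc)^2))
    }, numeric(1))
    best_cluster <- cand[order(cdist, cand)][1]   # tie: lowest cluster id
    members <- intersect(names(cl)[cl == best_cluster], remaining)
    ddist <- vapply(members, function(m)
      sqrt(sum((tree$M[m, ] - refc)^2)), numeric(1))
    pick <- members[order(ddist, members)][1]     # tie: lexicographic label
    hits <- c(hits, pick)
    rounds[[r]] <- data.frame(
      round = r, row = names(cl)[cl == best_cluster],
      selected = names(cl)[cl == best_cluster] == pick,
      cluster_distance = cdist[match(best_cluster, cand)],
      row_distance = vapply(names(cl)[cl == best_cluster], function(m)
        sqrt(sum((tree$M[m, ] - refc)^2)), numeric(1)),
      row.names = NULL)
    eliminated <- c(eliminated, members)
    remaining <- setdiff(remaining, members)
  }
  structure(list(hits = hits, rounds = rounds, eliminated = eliminated),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d rounds\n", length(x$hits)))
  for (r in seq_along(x$hits))
    cat(sprintf("  round %d: %s (cluster of %d)\n", r, x$hits[r],
                sum(x$rounds[[r]]$round == r)))
  invisible(x)
}
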
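# Fixture builders shared across the suite. Everything is generated in code;
# no stored data.

# A supervoxel_set built directly from per-region dF/F traces, bypassing the
# imaging pipeline. `traces_by_region` is a list (one element per region) of
# frames x supervoxels matrices.
make_sv <- function(traces_by_region, rate = 20, pre_duration = NULL) {
  dff <- do.call(cbind, traces_by_region)
  region <- rep(seq_along(traces_by_region),
                vapply(traces_by_region, ncol, integer(1)))
  n <- ncol(dff)
  members <- lapply(seq_len(n), function(i) cbind(z = 1, y = i, x = 1))
  structure(list(members = members, region = region,
                 traces = 100 * (1 + dff), dff = dff,
                 active = rep(TRUE, n), frame_rate = rate,
                 voxel_size = c(40, 10, 10), diameter_um = rep(10, n),
                 schedule = list(pre_duration = pre_duration %||%
                                   (nrow(dff) / rate))),
            class = "supervoxel_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# correlated Gaussian trace pairs via one shared latent factor
latent_traces <- function(T, n_per_group, rho, n_groups = 2, seed = 1) {
  set.seed(seed)
  L <- rnorm(T)
  lapply(seq_len(n_groups), function(g)
    vapply(seq_len(n_per_group), function(i)
      sqrt(rho) * L + sqrt(1 - rho) * rnorm(T), numeric(T)))
}

# a tiny atlas shared by synthetic-data tests
tiny_atlas <- function(n_regions = 4, shape = c(4, 14, 14), seed = 1) {
  generate_atlas(shape, n_regions = n_regions, seed = seed)
}

# planted-cluster fingerprint matrix for selection tests: reference rows at
# the origin, mutant rows far away, and compound clusters at controlled
# distances from the reference with known best members.
planted_screen_matrix <- function(cluster_dists = c(1, 2, 3),
                                  n_per_cluster = 3, dim = 12, noise = 0.06,
                                  seed = 1) {
  set.seed(seed)
  rows <- list(); labels <- character(0); truth <- list()
  add <- function(center, n, label) {
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- center + rnorm(dim, 0, noise)
      labels[length(labels) + 1L] <<- if (n > 1) paste0(label, i) else label
    }
  }
  add(rep(0, dim), 3, "WT-0h-")
  add(rep(2.5, dim), 2, "Mut-0h-")
  for (k in seq_along(cluster_dists)) {
    center <- rep(0, dim)
    center[k] <- cluster_dists[k]
    lab <- paste0("Mut-4h-", letters[k])
    add(center, n_per_cluster, lab)
    truth[[lab]] <- cluster_dists[k]
  }
  M <- do.call(rbind, rows)
  rownames(M) <- labels
  attr(M, "normalized") <- TRUE
  list(M = M, cluster_dists = cluster_dists)
}
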
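# Synthetic labeled brain atlas: connected anatomical regions tiling an
# ellipsoidal brain-shaped mask, standing in for a manually segmented
# larval-zebrafish reference atlas.

#' Canonical larval-zebrafish region names
#'
#' The eleven bilaterally resolved brain areas used for inter-area
#' connectivity: cerebellum (Ce), left/right hindbrain (HBl, HBr),
#' left/right olfactory bulb (OBl, OBr), left/right optic tectum (OTl, OTr),
#' pallium (Pa), subpallium (SPa), habenula (Ha) and thalamus (Th).
#'
#' @return character vector of length 11.
#' @export
zf_region_names <- function() {
  c("Ce", "HBl", "HBr", "OBl", "OBr", "OTl", "OTr", "Pa", "SPa", "Ha", "Th")
}

#' Generate a labeled synthetic brain atlas
#'
#' Places region seed points inside an ellipsoidal brain mask by
#' farthest-point sampling and assigns every mask voxel to its nearest seed
#' (anisotropy-aware Voronoi). Voronoi cells of a convex mask are convex,
#' so every region is spatially connected and non-empty.
#'
#' @param shape integer vector `(z, y, x)` grid dimensions.
#' @param n_regions number of regions (>= 2); 11 by default.
#' @param region_names names for the regions; defaults to
#'   [zf_region_names()] when `n_regions == 11`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param seed integer seed; the atlas is deterministic given `shape`,
#'   `n_regions` and `seed`.
#' @return an object of class `atlas_labels`: list with `labels` (3D integer
#'   array, 0 = background), `region_names`, `voxel_size`.
#' @examples
#' atl <- generate_atlas(c(4, 16, 16), n_regions = 4, seed = 1)
#' table(atl$labels[atl$labels > 0])
#' @export
generate_atlas <- function(shape = c(8, 64, 64), n_regions = 11,
                           region_names = NULL,
                           voxel_size = c(40, 10, 10), seed = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_regions >= 2)
  if (is.null(region_names)) {
    region_names <- if (n_regions == 11) zf_region_names() else
      sprintf("R%02d", seq_len(n_regions))
  }
  if (length(region_names) != n_regions)
    stop_fc("region_names has length %d but n_regions = %d",
            length(region_names), n_regions)

  # ellipsoidal brain mask centred in the grid
  gz <- seq_len(shape[1]); gy <- seq_len(shape[2]); gx <- seq_len(shape[3])
  cz <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2; cx <- (shape[3] + 1) / 2
  rz <- max(shape[1] / 2, 0.6); ry <- max(shape[2] / 2.1, 0.6)
  rx <- max(shape[3] / 2.4, 0.6)
  ez <- ((gz - cz) / rz)^2
  ey <- ((gy - cy) / ry)^2
  ex <- ((gx - cx) / rx)^2
  mask <- outer(outer(ez, ey, `+`), ex, `+`) <= 1
  vox <- which(mask, arr.ind = TRUE)          # columns z, y, x
  if (nrow(vox) < n_regions)
    stop_fc("shape %s too small: brain mask holds %d voxels for %d regions",
            paste(shape, collapse = "x"), nrow(vox), n_regions)

  # physical coordinates for anisotropy-aware distances
  phys <- sweep(vox, 2L, voxel_size, `*`)
  set.seed(substream_seed(seed, "atlas"))
  seeds <- integer(n_regions)
  seeds[1] <- sample.int(nrow(vox), 1L)
  d2 <- rowSums(sweep(phys, 2L, phys[seeds[1], ], `-`)^2)
  if (n_regions > 1) for (k in 2:n_regions) {
    seeds[k] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(phys, 2L, phys[seeds[k], ], `-`)^2))
  }

  # nearest-seed assignment
  dmat <- vapply(seeds, function(s)
    rowSums(sweep(phys, 2L, phys[s, ], `-`)^2), numeric(nrow(phys)))
  lab <- max.col(-dmat, ties.method = "first")

  labels <- array(0L, dim = shape)
  labels[vox] <- lab
  structure(list(labels = labels, region_names = region_names,
                 voxel_size = voxel_size),
            class = "atlas_labels")
}

#' @export
print.atlas_labels <- function(x, ...) {
  cnt <- tabulate(x$labels[x$labels > 0], nbins = length(x$region_names))
  cat(sprintf("<atlas_labels> %s grid, %d regions, %d brain voxels\n",
              paste(dim(x$labels), collapse = "x"),
              length(x$region_names), sum(cnt)))
  cat(paste(sprintf("%s:%d", x$region_names, cnt), collapse = " "), "\n")
  invisible(x)
}

#' Stimulus schedule for photosensitive-seizure imaging
#'
#' The imaging protocol: a resting (pre-stimulus) period followed by
#' seizure-inducing light stimuli, each consisting of two 500-ms pulses
#' separated by a 1-s gap, presented every two minutes.
#'
#' @param pre_duration seconds of resting recording before the first stimulus.
#' @param stimulus_times onset times (s) of each stimulus; strictly
#'   increasing, all at or after `pre_duration`.
#' @param pulse_len,gap,n_pulses pulse pattern within one stimulus.
#' @return object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(pre_duration = 600,
                              stimulus_times = 600 + 120 * 0:3,
                              pulse_len = 0.5, gap = 1, n_pulses = 2) {
  stimulus_times <- as.numeric(stimulus_times)
  if (length(stimulus_times) > 1 && any(diff(stimulus_times) <= 0))
    stop_fc("stimulus_times must be strictly increasing")
  if (length(stimulus_times) && any(stimulus_times < pre_duration))
    stop_fc("all stimulus_times must be >= pre_duration (%g s)", pre_duration)
  structure(list(pre_duration = pre_duration, stimulus_times = stimulus_times,
                 pulse_pattern = list(pulse_len = pulse_len, gap = gap,
                                      n_pulses = n_pulses)),
            class = "stimulus_schedule")
}
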
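# Writers for the pipeline's plain-text outputs: tidy/wide fingerprint CSVs,
# Newick dendrograms, selection JSON, supervoxel summaries.

#' Write fingerprints as tidy and wide CSV
#'
#' @param fps named list of `fc_fingerprint`s.
#' @param tidy_path,wide_path output CSV paths (either may be NULL).
#' @return invisibly, the tidy data.frame.
#' @export
write_fingerprint_csv <- function(fps, tidy_path = NULL, wide_path = NULL) {
  nm <- attr(fps[[1]], "region_names")
  tidy <- do.call(rbind, lapply(names(fps), function(g) {
    f <- fps[[g]]
    data.frame(group = g, area_i = nm[f$i], area_j = nm[f$j],
               state = as.character(f$state), value = f$value,
               n_larvae = f$n_larvae)
  }))
  if (!is.null(tidy_path))
    utils::write.csv(tidy, tidy_path, row.names = FALSE)
  if (!is.null(wide_path)) {
    X <- fingerprint_matrix(fps)
    utils::write.csv(data.frame(group = rownames(X), X, check.names = FALSE),
                     wide_path, row.names = FALSE)
  }
  invisible(tidy)
}

#' Convert an hclust tree to Newick text
#'
#' @param hc an `hclust` object (or `fc_tree`).
#' @return single Newick string with merge heights as branch lengths.
#' @export
tree_to_newick <- function(hc) {
  if (inherits(hc, "fc_tree")) hc <- hc$hclust
  if (is.null(hc)) return("();")
  lab <- gsub("[,();: ]", "_", hc$labels)
  node_str <- function(k, parent_h) {
    if (k < 0) {          # leaf
      sprintf("%s:%.6g", lab[-k], parent_h)
    } else {
      h <- hc$height[k]
      sprintf("(%s,%s):%.6g", node_str(hc$merge[k, 1], h),
              node_str(hc$merge[k, 2], h), parent_h - h)
    }
  }
  n <- length(hc$height)
  h <- hc$height[n]
  paste0("(", node_str(hc$merge[n, 1], h), ",",
         node_str(hc$merge[n, 2], h), ");")
}

#' Write a selection result as JSON
#' @param sel a `selection_result`.
#' @param path output path.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(list(hits = sel$hits,
                            rounds = sel$rounds,
                            eliminated = sel$eliminated),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Supervoxel summary CSV (id, region, n_voxels, diameter, active)
#' @param sv a `supervoxel_set`.
#' @param atlas optional `atlas_labels` for region names.
#' @param path output path or NULL.
#' @return the summary data.frame, invisibly when writing.
#' @export
supervoxel_summary <- function(sv, atlas = NULL, path = NULL) {
  nm <- if (!is.null(atlas)) atlas$region_names[sv$region] else sv$region
  out <- data.frame(id = seq_along(sv$members), region = nm,
                    n_voxels = vapply(sv$members, nrow, integer(1)),
                    diameter_um = sv$diameter_um, active = sv$active)
  if (!is.null(path)) { utils::write.csv(out, path, row.names = FALSE); return(invisible(out)) }
  out
}

#' Write a volume series as per-slice multi-page TIFF stacks
#'
#' Optional export for external viewers; requires the `tiff` package.
#'
#' @param volume a `volume_series`.
#' @param dir output directory (one TIFF per z-slice).
#' @export
write_volume_tiff <- function(volume, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_fc("the 'tiff' package is required for TIFF export")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$data)
  mx <- max(volume$data)
  for (z in seq_len(d[2])) {
    pages <- lapply(seq_len(d[1]), function(t)
      volume$data[t, z, , ] / mx)
    tiff::writeTIFF(pages, file.path(dir, sprintf("slice%02d.tif", z)),
                    bits.per.sample = 16)
  }
  invisible(dir)
}
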
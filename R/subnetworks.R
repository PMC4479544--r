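# Functional-subnetwork derivation from volumetric statistical maps and
# induced-subgraph analysis. Volumes must already be voxel-aligned to the
# atlas label volume; registration is upstream of this package.

#' Region-label volume
#'
#' 3-D integer array where 0 is background and positive values are region
#' identities, paired with a map from identity to region name. Region id
#' `r` corresponds to node index `r` of the connectivity matrices.
#'
#' @param voxels 3-D integer array.
#' @param region_labels Character vector of region names; element `r` names
#'   region id `r`.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(voxels, region_labels) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) stop("`voxels` must be 3-D", call. = FALSE)
  ids <- sort(unique(as.vector(voxels)))
  ids <- ids[ids > 0]
  if (length(ids) && max(ids) > length(region_labels)) {
    stop("voxel values exceed the number of region labels", call. = FALSE)
  }
  structure(list(voxels = voxels, region_labels = as.character(region_labels)),
            class = "label_volume")
}

#' Statistical-map volume
#'
#' 3-D real array of z-scores, shape-matched to its [label_volume()].
#'
#' @param voxels 3-D numeric array.
#' @return Object of class `stat_map_volume`.
#' @export
stat_map_volume <- function(voxels) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) stop("`voxels` must be 3-D", call. = FALSE)
  structure(list(voxels = voxels), class = "stat_map_volume")
}

#' Read a volume from a NIfTI file
#'
#' @param path NIfTI file path.
#' @param type `"labels"` for an integer region-label volume (supply
#'   `region_labels`), `"map"` for a statistical map.
#' @param region_labels Region names for `type = "labels"`.
#' @return A [label_volume()] or [stat_map_volume()].
#' @export
read_volume <- function(path, type = c("map", "labels"), region_labels = NULL) {
  type <- match.arg(type)
  arr <- as.array(RNifti::readNifti(path))
  if (type == "labels") {
    label_volume(round(arr), region_labels)
  } else {
    stat_map_volume(arr)
  }
}

#' Write a volume to a NIfTI file
#'
#' @param vol A [label_volume()] or [stat_map_volume()].
#' @param path Output path.
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol$voxels), path)
  invisible(path)
}

#' Named node subset defining a subnetwork
#'
#' @param name Subnetwork name.
#' @param nodes Integer region indices (at least 3 for topology analysis,
#'   enforced at analysis time, not construction).
#' @param region_labels Optional full region-label vector for display.
#' @return Object of class `subnetwork_definition`.
#' @export
subnetwork_definition <- function(name, nodes, region_labels = NULL) {
  nodes <- sort(unique(as.integer(nodes)))
  if (any(nodes < 1)) stop("node indices must be positive", call. = FALSE)
  structure(list(name = as.character(name), nodes = nodes,
                 region_labels = region_labels),
            class = "subnetwork_definition")
}

#' @export
print.subnetwork_definition <- function(x, ...) {
  cat(sprintf("<subnetwork_definition> %s: %d node(s)\n", x$name,
              length(x$nodes)))
  invisible(x)
}

#' Derive a subnetwork by proportional overlap with a thresholded map
#'
#' A region is included when the fraction of its voxels whose map value
#' exceeds `z_thresh` is at least `min_frac` (inclusive, "50% or more").
#'
#' @param labels A [label_volume()].
#' @param map A [stat_map_volume()] of the same shape.
#' @param z_thresh Map threshold (default `z > 4`).
#' @param min_frac Minimum proportional overlap (default 0.5).
#' @param name Name for the resulting definition.
#' @return A [subnetwork_definition()]. Regions present in the label map's
#'   label list but with zero voxels are excluded with a warning.
#' @export
overlap_mask <- function(labels, map, z_thresh = 4, min_frac = 0.5,
                         name = "subnetwork") {
  stopifnot(inherits(labels, "label_volume"),
            inherits(map, "stat_map_volume"))
  if (!identical(dim(labels$voxels), dim(map$voxels))) {
    stop("label and map volumes must have identical shape", call. = FALSE)
  }
  if (!is.finite(z_thresh)) stop("`z_thresh` must be finite", call. = FALSE)
  n_regions <- length(labels$region_labels)
  lab <- as.vector(labels$voxels)
  supra <- as.vector(map$voxels) > z_thresh
  in_region <- lab > 0
  vox_per <- tabulate(lab[in_region], nbins = n_regions)
  supra_per <- tabulate(lab[in_region & supra], nbins = n_regions)
  empty <- which(vox_per == 0)
  if (length(empty)) {
    warning("region(s) with zero voxels excluded: ",
            paste(labels$region_labels[empty], collapse = ", "),
            call. = FALSE)
  }
  frac <- ifelse(vox_per > 0, supra_per / pmax(vox_per, 1), 0)
  nodes <- which(vox_per > 0 & frac >= min_frac)
  subnetwork_definition(name, nodes, labels$region_labels)
}

#' Derive the default mode network from a set of functional-mode maps
#'
#' Each map is weighted by its mean value over the posterior cingulate
#' region, the weighted maps are summed, and the combined map is masked
#' with [overlap_mask()].
#'
#' @param tfm_maps List of [stat_map_volume()] objects.
#' @param labels A [label_volume()].
#' @param pcc_region Region id of the posterior cingulate cortex.
#' @param z_thresh,min_frac Passed to [overlap_mask()].
#' @param name Name for the resulting definition (default `"DMN"`).
#' @return A [subnetwork_definition()].
#' @export
derive_dmn <- function(tfm_maps, labels, pcc_region, z_thresh = 4,
                       min_frac = 0.5, name = "DMN") {
  stopifnot(inherits(labels, "label_volume"), length(tfm_maps) >= 1)
  pcc_vox <- labels$voxels == pcc_region
  if (!any(pcc_vox)) stop("PCC region has no voxels", call. = FALSE)
  combined <- 0
  for (m in tfm_maps) {
    stopifnot(inherits(m, "stat_map_volume"))
    w <- mean(m$voxels[pcc_vox])
    combined <- combined + w * m$voxels
  }
  overlap_mask(labels, stat_map_volume(combined), z_thresh, min_frac, name)
}

#' Induce the subnetwork's submatrix of a count matrix
#'
#' @param m A [stream_matrix()].
#' @param def A [subnetwork_definition()] with at least 2 nodes.
#' @return A [stream_matrix()] restricted to the definition's nodes,
#'   preserving counts and label order.
#' @export
induced_subgraph_matrix <- function(m, def) {
  stopifnot(inherits(m, "stream_matrix"),
            inherits(def, "subnetwork_definition"))
  if (length(def$nodes) < 2) {
    stop("subnetwork needs at least 2 nodes", call. = FALSE)
  }
  if (max(def$nodes) > nrow(m$counts)) {
    stop("node index out of range for this matrix", call. = FALSE)
  }
  stream_matrix(m$counts[def$nodes, def$nodes, drop = FALSE],
                region_labels = m$region_labels[def$nodes],
                subject_id = m$subject_id)
}

#' Read a node-set file
#'
#' Plain text, one region label per line; `#` starts a comment.
#'
#' @param path File path.
#' @param region_labels Full region-label vector used to resolve labels to
#'   node indices.
#' @param name Definition name; defaults to the file name without extension.
#' @return A [subnetwork_definition()].
#' @export
read_node_set <- function(path, region_labels, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  idx <- match(lines, region_labels)
  if (anyNA(idx)) {
    stop("unknown region label(s): ", paste(lines[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  subnetwork_definition(name, idx, region_labels)
}

#' Write a node-set file
#'
#' @param def A [subnetwork_definition()] carrying `region_labels`.
#' @param path Output path.
#' @export
write_node_set <- function(def, path) {
  stopifnot(inherits(def, "subnetwork_definition"))
  if (is.null(def$region_labels)) {
    stop("definition carries no region labels to write", call. = FALSE)
  }
  writeLines(def$region_labels[def$nodes], path)
  invisible(path)
}

#' Network-level MTPC analysis of subnetworks
#'
#' For each definition: induce the subnetwork's submatrix for every
#' subject, compute network-level metric curves across the threshold sweep,
#' and run [mtpc()] per metric.
#'
#' @param cohort A [cohort_data()].
#' @param defs List of [subnetwork_definition()] objects (each with at
#'   least 3 nodes).
#' @param design A [design_spec()].
#' @param thresholds Streamline-threshold sweep (default 0:20).
#' @param metrics Network-level metrics to test (default density, global
#'   efficiency, mean clustering, mean betweenness).
#' @return Named list (one element per definition) of named lists of
#'   `mtpc_result` objects (one per metric), plus a `summary` attribute
#'   data frame.
#' @export
subnetwork_analysis <- function(cohort, defs, design, thresholds = 0:20,
                                metrics = c("density", "global_efficiency",
                                            "mean_clustering",
                                            "mean_betweenness")) {
  stopifnot(inherits(cohort, "cohort_data"), length(defs) >= 1)
  if (inherits(defs, "subnetwork_definition")) defs <- list(defs)
  out <- list()
  for (def in defs) {
    stopifnot(inherits(def, "subnetwork_definition"))
    if (length(def$nodes) < 3) {
      stop("subnetwork '", def$name, "' has fewer than 3 nodes", call. = FALSE)
    }
    sub_mats <- lapply(cohort$matrices, induced_subgraph_matrix, def = def)
    sub_cohort <- cohort_data(cohort$subjects, sub_mats)
    curves <- metric_curves(sub_cohort, thresholds, mode = "streamline",
                            level = "global", metrics = metrics)
    out[[def$name]] <- lapply(curves, mtpc, design = design)
  }
  summ <- do.call(rbind, lapply(names(out), function(nm) {
    df <- do.call(rbind, lapply(out[[nm]], mtpc_summary))
    df$subnetwork <- nm
    df
  }))
  attr(out, "summary") <- summ
  out
}
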
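# Connectivity-matrix and cohort input/output, thresholding, binarization.

#' Streamline-count connectivity matrix
#'
#' A symmetric nonnegative-integer region-by-region matrix of streamline
#' counts, the raw unit of input for connectome group analysis.
#'
#' @param counts Square numeric matrix of nonnegative integers; must be
#'   symmetric with a zero diagonal.
#' @param region_labels Character vector of region names, one per row.
#'   Defaults to the matrix dimnames or `"region_1"`, ... .
#' @param subject_id Identifier for the subject the matrix belongs to.
#' @return An object of class `stream_matrix` with elements `counts`,
#'   `region_labels` and `subject_id`.
#' @examples
#' m <- stream_matrix(matrix(c(0, 3, 3, 0), 2, 2), c("A", "B"), "s1")
#' @export
stream_matrix <- function(counts, region_labels = NULL, subject_id = NA_character_) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 2L || ncol(counts) != n) {
    stop("`counts` must be a square matrix with n >= 2", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("streamline counts must be nonnegative and non-missing", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("streamline counts must be integers", call. = FALSE)
  }
  if (max(abs(counts - t(counts))) > 0) {
    stop("streamline count matrix must be exactly symmetric ",
         "(counts between unordered region pairs)", call. = FALSE)
  }
  diag(counts) <- 0
  counts <- round(counts)
  if (is.null(region_labels)) {
    region_labels <- rownames(counts)
    if (is.null(region_labels)) region_labels <- paste0("region_", seq_len(n))
  }
  if (length(region_labels) != n) {
    stop("`region_labels` must have one entry per region", call. = FALSE)
  }
  dimnames(counts) <- list(region_labels, region_labels)
  structure(
    list(counts = counts, region_labels = as.character(region_labels),
         subject_id = as.character(subject_id)),
    class = "stream_matrix"
  )
}

#' @export
print.stream_matrix <- function(x, ...) {
  cat("<stream_matrix> subject", x$subject_id, "-", nrow(x$counts),
      "regions,", sum(x$counts[upper.tri(x$counts)] > 0),
      "nonzero connections\n")
  invisible(x)
}

#' Binarized network at a threshold
#'
#' @param adjacency Square 0/1 matrix, symmetric, zero diagonal.
#' @param tau The streamline-count threshold that produced the network, or
#'   the target density for density-matched networks.
#' @param mode `"streamline"` or `"density"`.
#' @param region_labels Region names.
#' @return Object of class `binary_network`.
#' @export
binary_network <- function(adjacency, tau, mode = c("streamline", "density"),
                           region_labels = NULL) {
  mode <- match.arg(mode)
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 2L || ncol(adjacency) != n) {
    stop("`adjacency` must be square with n >= 2", call. = FALSE)
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop("`adjacency` must be binary", call. = FALSE)
  }
  if (max(abs(adjacency - t(adjacency))) > 0) {
    stop("`adjacency` must be symmetric", call. = FALSE)
  }
  diag(adjacency) <- 0
  if (is.null(region_labels)) {
    region_labels <- rownames(adjacency)
    if (is.null(region_labels)) region_labels <- paste0("region_", seq_len(n))
  }
  dimnames(adjacency) <- list(region_labels, region_labels)
  structure(
    list(adjacency = adjacency, tau = tau, mode = mode,
         region_labels = as.character(region_labels)),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  e <- sum(x$adjacency[upper.tri(x$adjacency)])
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.4f), %s tau = %s\n",
              n, e, 2 * e / (n * (n - 1)), x$mode, format(x$tau)))
  invisible(x)
}

#' Aggregate streamline endpoint pairs into a count matrix
#'
#' Tallies unordered region pairs hit by individual streamlines into a
#' symmetric streamline-count matrix. Self-connections (both endpoints in
#' the same region) are discarded.
#'
#' @param endpoint_pairs Two-column matrix (or data.frame) of 1-based region
#'   indices, one row per streamline.
#' @param n_regions Number of atlas regions.
#' @param region_labels Optional region names.
#' @param subject_id Subject identifier.
#' @return A [stream_matrix()].
#' @examples
#' aggregate_streamlines(rbind(c(1, 2), c(2, 1), c(2, 3)), n_regions = 3)
#' @export
aggregate_streamlines <- function(endpoint_pairs, n_regions,
                                  region_labels = NULL,
                                  subject_id = NA_character_) {
  counts <- matrix(0, n_regions, n_regions)
  if (length(endpoint_pairs)) {
    ep <- as.matrix(endpoint_pairs)
    if (ncol(ep) != 2L) stop("`endpoint_pairs` must have two columns", call. = FALSE)
    if (anyNA(ep) || any(ep < 1) || any(ep > n_regions) ||
        any(ep != round(ep))) {
      stop("region indices must be integers in [1, n_regions]", call. = FALSE)
    }
    keep <- ep[, 1] != ep[, 2]
    ep <- ep[keep, , drop = FALSE]
    if (nrow(ep)) {
      i <- pmin(ep[, 1], ep[, 2])
      j <- pmax(ep[, 1], ep[, 2])
      tab <- table(factor(i + n_regions * (j - 1),
                          levels = seq_len(n_regions * n_regions)))
      counts[] <- as.numeric(tab)
      counts <- counts + t(counts)
    }
  }
  stream_matrix(counts, region_labels, subject_id)
}

#' Binarize a count matrix at a streamline threshold
#'
#' An edge is retained when its streamline count exceeds `tau` (strict, so
#' `tau = 0` keeps any connection supported by at least one streamline).
#' Set `inclusive = TRUE` for a `count >= tau` rule.
#'
#' @param m A [stream_matrix()].
#' @param tau Nonnegative integer streamline threshold. Values above 20 are
#'   allowed but warned about: sparse tails of the count distribution make
#'   higher thresholds unreliable.
#' @param inclusive Use `>=` instead of the default strict `>`.
#' @return A [binary_network()].
#' @export
threshold_binarize <- function(m, tau, inclusive = FALSE) {
  stopifnot(inherits(m, "stream_matrix"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("`tau` must be a single nonnegative number", call. = FALSE)
  }
  if (tau > 20) {
    warning("tau = ", tau, " is outside the usual 0-20 streamline range",
            call. = FALSE)
  }
  adj <- if (inclusive) (m$counts >= tau) else (m$counts > tau)
  adj <- adj * 1
  diag(adj) <- 0
  binary_network(adj, tau = tau, mode = "streamline",
                 region_labels = m$region_labels)
}

#' Binarize a count matrix at a matched density
#'
#' Keeps the `k` highest-count connections, where
#' `k = round(target_density * n * (n - 1) / 2)`, so that every subject's
#' binarized network has exactly the same density. Ties in count are broken
#' deterministically by ascending (row, column) region index.
#'
#' @param m A [stream_matrix()].
#' @param target_density Fraction of possible connections to keep, in (0, 1].
#' @return A [binary_network()] with `mode = "density"` and `tau` set to the
#'   target density. If fewer than `k` nonzero connections exist, all are
#'   kept and a warning reports the achieved density.
#' @export
density_match_threshold <- function(m, target_density) {
  stopifnot(inherits(m, "stream_matrix"))
  if (!is.numeric(target_density) || length(target_density) != 1L ||
      is.na(target_density) || target_density <= 0 || target_density > 1) {
    stop("`target_density` must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(m$counts)
  npairs <- n * (n - 1) / 2
  k <- round(target_density * npairs)
  ut <- which(upper.tri(m$counts), arr.ind = TRUE)
  cnt <- m$counts[upper.tri(m$counts)]
  nz <- cnt > 0
  if (k > sum(nz)) {
    warning(sprintf(
      "only %d nonzero connections available for target %d; achieved density %.4f",
      sum(nz), k, sum(nz) / npairs), call. = FALSE)
    k <- sum(nz)
  }
  adj <- matrix(0, n, n)
  if (k > 0) {
    ord <- order(-cnt, ut[, 1], ut[, 2])
    keep <- ord[seq_len(k)]
    adj[cbind(ut[keep, 1], ut[keep, 2])] <- 1
    adj <- adj + t(adj)
  }
  binary_network(adj, tau = target_density, mode = "density",
                 region_labels = m$region_labels)
}

# ---- cohort -----------------------------------------------------------------

.GROUP_LEVELS <- c("control", "PE")
.GENDER_LEVELS <- c("male", "female")
.HANDEDNESS_LEVELS <- c("right", "left", "none")

#' Cohort of subjects with aligned connectivity matrices
#'
#' @param subjects Data frame with columns `subject_id`, `group`
#'   (control/PE), `age`, `gender` (male/female), `handedness`
#'   (right/left/none).
#' @param matrices List of [stream_matrix()], one per subject row, all
#'   sharing the same regions.
#' @return Object of class `cohort_data`.
#' @export
cohort_data <- function(subjects, matrices) {
  subjects <- as.data.frame(subjects)
  req <- c("subject_id", "group", "age", "gender", "handedness")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) {
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(matrices) != nrow(subjects)) {
    stop("one matrix per subject row required", call. = FALSE)
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  for (col in c("group", "gender", "handedness")) {
    lv <- switch(col, group = .GROUP_LEVELS, gender = .GENDER_LEVELS,
                 handedness = .HANDEDNESS_LEVELS)
    v <- as.character(subjects[[col]])
    bad <- setdiff(unique(v), lv)
    if (length(bad)) {
      stop(sprintf("unknown %s level(s): %s (expected %s)", col,
                   paste(bad, collapse = ", "), paste(lv, collapse = "/")),
           call. = FALSE)
    }
    subjects[[col]] <- factor(v, levels = lv)
  }
  subjects$age <- as.numeric(subjects$age)
  if (anyNA(subjects$age)) stop("missing age values", call. = FALSE)
  if (!all(vapply(matrices, inherits, TRUE, "stream_matrix"))) {
    stop("all matrices must be stream_matrix objects", call. = FALSE)
  }
  labs <- matrices[[1]]$region_labels
  same <- vapply(matrices, function(m) identical(m$region_labels, labs), TRUE)
  if (!all(same)) {
    stop("all matrices must share the same regions in the same order",
         call. = FALSE)
  }
  for (i in seq_along(matrices)) {
    matrices[[i]]$subject_id <- subjects$subject_id[i]
  }
  structure(list(subjects = subjects, matrices = matrices,
                 region_labels = labs),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data>", nrow(x$subjects), "subjects (",
      paste(sprintf("%s: %d", levels(x$subjects$group),
                    tabulate(x$subjects$group, 2)), collapse = ", "),
      "),", length(x$region_labels), "regions\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A `cohort_data` object.
#' @export
n_subjects <- function(x) nrow(x$subjects)

#' Write a connectivity matrix as TSV
#'
#' Tab-separated, one header row of region labels, then the n x n integer
#' count matrix.
#'
#' @param m A [stream_matrix()].
#' @param path Output file path.
#' @export
write_connectivity_matrix <- function(m, path) {
  stopifnot(inherits(m, "stream_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(m$region_labels, collapse = "\t"), con)
  write.table(format(m$counts, trim = TRUE, scientific = FALSE), con,
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix from TSV
#'
#' @param path File path: a header row of region labels followed by the
#'   square integer count matrix.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A [stream_matrix()].
#' @export
read_connectivity_matrix <- function(path, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square", call. = FALSE)
  }
  stream_matrix(m, region_labels = colnames(df), subject_id = subject_id)
}

#' Read a cohort from matrix files and a covariate table
#'
#' Matrices are matched to covariate rows by subject id (file name without
#' extension). Subjects lacking a matrix, or matrices lacking a covariate
#' row, are an error naming the unmatched ids.
#'
#' @param matrix_paths Character vector of TSV connectivity-matrix paths.
#' @param covariate_path CSV with columns `subject_id`, `group`, `age`,
#'   `gender`, `handedness`.
#' @return A [cohort_data()] ordered as the covariate table.
#' @export
read_cohort <- function(matrix_paths, covariate_path) {
  subjects <- read.csv(covariate_path, stringsAsFactors = FALSE)
  mats <- lapply(matrix_paths, read_connectivity_matrix)
  ids <- vapply(mats, function(m) m$subject_id, "")
  missing_mat <- setdiff(subjects$subject_id, ids)
  extra_mat <- setdiff(ids, subjects$subject_id)
  if (length(missing_mat) || length(extra_mat)) {
    stop("unmatched subject id(s): ",
         paste(c(missing_mat, extra_mat), collapse = ", "), call. = FALSE)
  }
  mats <- mats[match(subjects$subject_id, ids)]
  cohort_data(subjects, mats)
}

#' Write a cohort as a directory of matrix TSVs plus a covariate CSV
#'
#' @param cohort A [cohort_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written `matrix_paths` and
#'   `covariate_path`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subjects$subject_id, ".tsv"))
  for (i in seq_along(paths)) {
    write_connectivity_matrix(cohort$matrices[[i]], paths[i])
  }
  cov_path <- file.path(dir, "covariates.csv")
  df <- cohort$subjects
  df[] <- lapply(df, as.character)
  write.csv(df, cov_path, row.names = FALSE, quote = FALSE)
  invisible(list(matrix_paths = paths, covariate_path = cov_path))
}
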
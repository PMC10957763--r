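#' Connectivity matrices
#'
#' A connectivity matrix holds the edge strengths of one subject's brain
#' network for one modality: structural (e.g. fiber counts normalised by ROI
#' surface areas) or functional (Pearson correlations of regional time
#' series, negatives zeroed).  The matrix is symmetric, nonnegative, with a
#' zero diagonal; functional entries additionally lie in \[0, 1\].
#'
#' @param weights numeric n x n matrix of edge strengths.
#' @param modality `"structural"` or `"functional"`.
#' @param region_labels optional character vector of n region (ROI) names.
#' @param refined set to TRUE for beta-mapped matrices, whose functional
#'   weights may legitimately exceed 1 (up to `alpha`).
#' @return An object of class `connectivity_matrix`: a list with elements
#'   `weights`, `modality` and `region_labels`.
#' @export
connectivity_matrix <- function(weights, modality = c("structural", "functional"),
                                region_labels = NULL, refined = FALSE) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("non-square connectivity matrix: ", nrow(weights), " x ", ncol(weights))
  if (anyNA(weights))
    stop("connectivity matrix contains NA/NaN entries")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-8)
    stop("asymmetric beyond tolerance (max |w_ij - w_ji| = ",
         format(asym), " > 1e-8)")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(weights < 0))
    stop("negative ", modality, " weights are not allowed")
  if (modality == "functional" && !refined && any(weights > 1 + 1e-9))
    stop("functional weights must lie in [0, 1]")
  n <- nrow(weights)
  if (is.null(region_labels)) {
    region_labels <- if (!is.null(rownames(weights))) rownames(weights)
                     else paste0("R", seq_len(n))
  }
  if (length(region_labels) != n)
    stop("region_labels length (", length(region_labels),
         ") does not match matrix size (", n, ")")
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, modality = modality,
                 region_labels = region_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x$weights)
  ut <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<connectivity_matrix> %s, %d regions, %d positive edges, density %.3f\n",
              x$modality, n, sum(ut > 0), mean(ut > 0)))
  invisible(x)
}

n_regions <- function(cm) nrow(cm$weights)

guess_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a connectivity matrix from a delimited text file
#'
#' Reads a square numeric matrix from TSV (default) or CSV, optionally with a
#' header row of region labels.  The matrix is validated, symmetrised by
#' averaging when the asymmetry is at most 1e-8 (larger asymmetry is an
#' error), and its diagonal is forced to zero.
#'
#' @param path file path.
#' @param modality `"structural"` or `"functional"`.
#' @param sep field separator; by default sniffed from the first line.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path, modality = c("structural", "functional"),
                                     sep = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- guess_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(utils::read.table(path, sep = sep, header = has_header,
                                   check.names = FALSE))
  labels <- if (has_header) colnames(m) else NULL
  storage.mode(m) <- "double"
  connectivity_matrix(m, modality, region_labels = labels)
}

#' Write a connectivity matrix as TSV
#'
#' The inverse of [read_connectivity_matrix()]: region labels on the header
#' row, tab-separated numeric rows.
#'
#' @param cm a [connectivity_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(cm, path) {
  utils::write.table(cm$weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = cm$region_labels)
  invisible(path)
}

#' Functional connectivity from regional time series
#'
#' Pearson correlations between all pairs of regional time series; negative
#' correlations are set to zero (they lack a clear biological reading) and so
#' is the diagonal.  A region with a constant series has no defined
#' correlation: its row and column are set to zero with a warning rather
#' than aborting a cohort run.
#'
#' @param ts numeric matrix, regions x timepoints (T >= 3), or a list with
#'   elements `values` and `region_labels` as returned by [read_timeseries()].
#' @return A functional [connectivity_matrix()] with entries in \[0, 1\].
#' @export
fc_from_timeseries <- function(ts) {
  labels <- NULL
  if (is.list(ts) && !is.null(ts$values)) {
    labels <- ts$region_labels
    ts <- ts$values
  }
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 timepoints, got ", ncol(ts))
  if (anyNA(ts)) stop("time series contain missing values")
  sds <- apply(ts, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(ts)))
  if (any(sds == 0)) {
    warning("constant time series in region(s) ",
            paste(which(sds == 0), collapse = ", "),
            "; their correlations are set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  r[r < 0] <- 0
  diag(r) <- 0
  connectivity_matrix(r, "functional", region_labels = labels)
}

#' Structural connectivity from fiber counts and ROI surface areas
#'
#' Each edge strength is the streamline (fiber) count between two regions
#' divided by the sum of their surface areas:
#' `w_ij = fibers_ij / (area_i + area_j)`.
#'
#' @param fiber_counts symmetric nonnegative n x n matrix of fiber counts.
#' @param surface_areas positive numeric vector of n ROI surface areas.
#' @param region_labels optional region names.
#' @return A structural [connectivity_matrix()].
#' @export
sc_from_fibers <- function(fiber_counts, surface_areas, region_labels = NULL) {
  fiber_counts <- as.matrix(fiber_counts)
  if (any(surface_areas <= 0)) stop("all surface areas must be positive")
  if (length(surface_areas) != nrow(fiber_counts))
    stop("surface_areas length does not match fiber matrix size")
  denom <- outer(surface_areas, surface_areas, `+`)
  w <- fiber_counts / denom
  diag(w) <- 0
  connectivity_matrix(w, "structural", region_labels = region_labels)
}

#' Read a regions x timepoints time-series table
#'
#' @param path TSV/CSV file, one row per region, optional header of timepoint
#'   names, optional first column of region labels (detected when the first
#'   field is non-numeric).
#' @param sep field separator; sniffed by default.
#' @return list with `values` (regions x T matrix) and `region_labels`.
#' @export
read_timeseries <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- guess_sep(path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.numeric(tab[[1]])) {
    labels <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  values <- as.matrix(tab)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("time series contain non-numeric or missing values")
  rownames(values) <- labels
  list(values = values, region_labels = labels)
}

#' Read a cohort manifest
#'
#' The manifest is a delimited table with columns `subject_id`, `group`,
#' `sc_path` and `fc_path`.  Relative paths are resolved against the
#' manifest's directory.  Duplicate subject ids and dangling paths are
#' errors.
#'
#' @param path manifest file path.
#' @param sep field separator; sniffed by default.
#' @return A data frame (one row per subject, in file order) with resolved
#'   paths, of class `cohort_manifest`.
#' @export
read_cohort_manifest <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (is.null(sep)) sep <- guess_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "sc_path", "fc_path")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("manifest lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  tab$sc_path <- resolve(tab$sc_path)
  tab$fc_path <- resolve(tab$fc_path)
  for (p in c(tab$sc_path, tab$fc_path))
    if (!file.exists(p)) stop("manifest references missing file: ", p)
  class(tab) <- c("cohort_manifest", "data.frame")
  tab
}

#' Load all subjects referenced by a manifest
#'
#' Reads every subject's structural and functional matrix and checks that all
#' subjects share the same region count and label order (region order is
#' positional; a mismatch is an error, never a silent reindex).
#'
#' @param manifest a `cohort_manifest` (or path to one).
#' @return list of subjects, each a list with `id`, `group`, `sc`, `fc`.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    list(id = manifest$subject_id[i],
         group = manifest$group[i],
         sc = read_connectivity_matrix(manifest$sc_path[i], "structural"),
         fc = read_connectivity_matrix(manifest$fc_path[i], "functional"))
  })
  ref <- subjects[[1]]$sc$region_labels
  for (s in subjects) {
    for (cm in list(s$sc, s$fc)) {
      if (n_regions(cm) != length(ref))
        stop("subject ", s$id, ": region count mismatch")
      if (!identical(cm$region_labels, ref))
        stop("subject ", s$id, ": region label order differs from cohort")
    }
  }
  subjects
}
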
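#' Sub-network partition of ROIs
#'
#' A named, ordered, disjoint grouping of ROI indices covering every ROI.
#' Indices are 1-based positions into the ROI name vector of the time series
#' the partition is applied to.
#'
#' @param networks Named list of integer vectors (1-based ROI indices).
#' @param roi_names Optional character vector of ROI names the indices refer
#'   to; stored for provenance and validation against time series.
#'
#' @return A `subnet_partition` object: named list of integer index vectors
#'   with attributes `U` (group count) and `roi_names`.
#' @export
#' @examples
#' subnet_partition(list(A = 1:2, B = 3:4), paste0("r", 1:4))
subnet_partition <- function(networks, roi_names = NULL) {
  if (is.null(names(networks)) || any(!nzchar(names(networks))) ||
      anyDuplicated(names(networks))) {
    abort("sub-networks must have unique non-empty names", class = "hierfcn_validation")
  }
  networks <- lapply(networks, function(v) as.integer(v))
  all_idx <- unlist(networks, use.names = FALSE)
  n_roi <- if (is.null(roi_names)) max(all_idx) else length(roi_names)
  sizes <- lengths(networks)
  if (any(sizes < 2L)) {
    abort(paste0("each sub-network needs >= 2 ROIs; too small: ",
                 paste(names(networks)[sizes < 2L], collapse = ", ")),
          class = "hierfcn_validation")
  }
  if (anyDuplicated(all_idx)) {
    abort(paste0("overlapping sub-networks: ROI index ",
                 all_idx[duplicated(all_idx)][1], " appears twice"),
          class = "hierfcn_validation")
  }
  missing_idx <- setdiff(seq_len(n_roi), all_idx)
  if (length(missing_idx) > 0) {
    abort(paste0("uncovered ROI index(es): ",
                 paste(head(missing_idx, 5), collapse = ", ")),
          class = "hierfcn_validation")
  }
  if (any(all_idx < 1L) || any(all_idx > n_roi)) {
    abort("ROI index out of range", class = "hierfcn_validation")
  }
  structure(networks, U = length(networks), roi_names = roi_names,
            class = "subnet_partition")
}

#' @export
print.subnet_partition <- function(x, ...) {
  cat(sprintf("<subnet_partition> %d sub-networks over %d ROIs\n",
              attr(x, "U"), length(unlist(x))))
  for (nm in names(x)) cat(sprintf("  %-8s %d ROIs\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Number of sub-networks in a partition
#' @param partition A [subnet_partition].
#' @return Integer count `U`.
#' @export
n_subnetworks <- function(partition) attr(partition, "U")

#' Load a sub-network partition from JSON
#'
#' The JSON object maps sub-network names to arrays of ROI names (resolved
#' case-sensitively against `roi_names`) or of 1-based ROI indices.  Keys
#' starting with `"_"` are treated as comments and skipped.
#'
#' @param path Path to the JSON file.
#' @param roi_names Character vector of ROI names to resolve against.
#' @return A [subnet_partition].
#' @export
load_partition <- function(path, roi_names) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "hierfcn_validation")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")]
  networks <- lapply(raw, function(members) {
    if (is.character(members)) {
      idx <- match(members, roi_names)
      if (anyNA(idx)) {
        abort(paste0("unknown ROI name(s): ",
                     paste(members[is.na(idx)], collapse = ", ")),
              class = "hierfcn_validation")
      }
      idx
    } else {
      as.integer(members)
    }
  })
  subnet_partition(networks, roi_names = roi_names)
}

#' Write a partition as JSON (ROI-name form)
#' @param partition A [subnet_partition] whose `roi_names` attribute is set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  rn <- attr(partition, "roi_names")
  obj <- if (is.null(rn)) unclass(partition) else lapply(partition, function(i) rn[i])
  jsonlite::write_json(obj, path, pretty = TRUE, auto_unbox = FALSE)
  invisible(path)
}

#' Canonical six-network division of the AAL-116 atlas
#'
#' Returns the bundled division of the 116 AAL regions into six functional
#' sub-networks: sensorimotor (SMN, 18 ROIs), visual (14), execution and
#' attention (EAN, 17), default mode (DMN, 22), subcortical nuclei (SBC, 19)
#' and cerebellum (Cerebel, 26).  The region-to-network assignment bundled
#' here is a synthetic reconstruction from standard AAL region names that
#' matches those published network sizes; it is not the original
#' BrainNet-Viewer node file.
#'
#' @return A [subnet_partition] over the 116 AAL ROI names.
#' @export
#' @examples
#' p <- aal_subnetworks()
#' lengths(p)
aal_subnetworks <- function() {
  path <- system.file("extdata", "aal116_subnetworks_synthetic.json",
                      package = "hierfcn", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")]
  roi_names <- unname(unlist(raw))
  # canonical ROI order: as listed network by network in the asset
  load_partition(path, roi_names = roi_names)
}

#' Data-driven sub-network partition by k-means on ROI time series
#'
#' Clusters ROIs by the similarity of their time series: each subject's
#' series are z-scored per ROI, averaged across subjects, and the resulting
#' per-ROI profile vectors are clustered with k-means (k-means++ seeding,
#' Euclidean distance).  Deterministic given `seed`.
#'
#' @param subjects List of [roi_ts] objects sharing the same `roi_names`.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param max_retries Re-seeding attempts if a cluster comes back with fewer
#'   than 2 ROIs (the partition invariant requires group sizes >= 2).
#' @return A [subnet_partition] with groups named `C1..Ck`.
#' @export
partition_by_kmeans <- function(subjects, k, seed, max_retries = 5L) {
  if (k < 2L) abort("k must be >= 2", class = "hierfcn_validation")
  rn <- subjects[[1]]$roi_names
  if (!all(vapply(subjects, function(s) identical(s$roi_names, rn), logical(1)))) {
    abort("all subjects must share roi_names", class = "hierfcn_validation")
  }
  # per-ROI profile: z-scored series averaged across subjects (ROI x time)
  prof <- Reduce(`+`, lapply(subjects, function(s) {
    t(scale(s$values))
  })) / length(subjects)
  prof[!is.finite(prof)] <- 0  # zero-variance ROI series z-score to NaN
  for (attempt in 0:max_retries) {
    centers <- kmeanspp_centers(prof, k, seed + attempt)
    km <- tryCatch(kmeans(prof, centers = centers, iter.max = 100L),
                   error = function(e) NULL)  # e.g. duplicate seeded centers
    if (is.null(km)) next
    sizes <- tabulate(km$cluster, nbins = k)
    if (all(sizes >= 2L)) {
      groups <- split(seq_along(rn), km$cluster)
      names(groups) <- paste0("C", seq_len(k))
      return(subnet_partition(groups, roi_names = rn))
    }
  }
  abort(sprintf(
    "k-means produced a cluster with < 2 ROIs in all %d attempts (k = %d, %d ROIs)",
    max_retries + 1L, k, length(rn)), class = "hierfcn_validation")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(x, k, seed) {
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = probs)
    d2j <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  x[centers, , drop = FALSE]
}
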
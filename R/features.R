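#' Sub-network mean time series
#'
#' Averages the ROI time series within each sub-network, giving one series
#' per sub-network.  These mean series carry the connectivity between
#' sub-networks that is lost when fitting is restricted to within-network
#' ROI sets.
#'
#' @param ts A [roi_ts] object.
#' @param partition A [subnet_partition] valid for `ts`.
#' @return A [roi_ts] with `U` columns named after the sub-networks.
#' @export
mean_series <- function(ts, partition) {
  stopifnot(inherits(ts, "roi_ts"), inherits(partition, "subnet_partition"))
  validate_partition_for(partition, ts)
  out <- vapply(partition, function(idx) rowMeans(ts$values[, idx, drop = FALSE]),
                numeric(nrow(ts$values)))
  roi_ts(out, roi_names = names(partition), subject_id = ts$subject_id)
}

validate_partition_for <- function(partition, ts) {
  n <- length(unlist(partition))
  if (n != ncol(ts$values)) {
    abort(sprintf("partition covers %d ROIs but time series has %d", n, ncol(ts$values)),
          class = "hierfcn_validation")
  }
  rn <- attr(partition, "roi_names")
  if (!is.null(rn) && !identical(rn, ts$roi_names)) {
    abort("partition roi_names do not match the time series", class = "hierfcn_validation")
  }
  invisible(TRUE)
}

# Internal constructor for a tagged feature block: a tibble with provenance
# columns plus the feature value.  `feature` is a stable column identifier.
feature_block <- function(tag, network, network_2, roi_i, roi_j, role, value) {
  tibble(
    feature = paste(tag, network, roi_i, roi_j, sep = "|"),
    tag = tag, network = network, network_2 = network_2,
    roi_i = roi_i, roi_j = roi_j, role = role, value = value
  )
}

#' Intra-sub-network connectivity features for one subject
#'
#' Per sub-network: build the sliding-window correlation sequence, fit the
#' matrix-normal model, and vectorise the fitted mean (low-order, strict
#' lower triangle in row-major `i > j` order) and factor covariance
#' (high-order, lower triangle including the diagonal, whose entries carry
#' variance information).
#'
#' @param ts A [roi_ts].
#' @param partition A [subnet_partition].
#' @param spec A [window_spec].
#' @param tol,max_iter,ridge Passed to [fit_factor()].
#' @return A list with tibbles `intra_low` and `intra_high` (columns
#'   `feature`, `tag`, `network`, `roi_i`, `roi_j`, `role`, `value`).
#' @export
extract_intra <- function(ts, partition, spec = window_spec(60, 4),
                          tol = 1e-6, max_iter = 100L, ridge = 1e-6) {
  validate_partition_for(partition, ts)
  lows <- list(); highs <- list()
  for (nm in names(partition)) {
    sq <- fcn_sequence(ts, partition[[nm]], spec)
    fit <- fit_factor(sq, tol = tol, max_iter = max_iter, ridge = ridge)
    lm <- lower_tri_tbl(fit$M_hat, diag = FALSE, roi_names = sq$roi_names)
    lc <- lower_tri_tbl(fit$C_hat, diag = TRUE, roi_names = sq$roi_names)
    lows[[nm]] <- feature_block("intra_low", nm, NA_character_,
                                lm$roi_i, lm$roi_j, "mean", lm$value)
    highs[[nm]] <- feature_block("intra_high", nm, NA_character_,
                                 lc$roi_i, lc$roi_j, "factor", lc$value)
  }
  list(intra_low = dplyr::bind_rows(lows), intra_high = dplyr::bind_rows(highs))
}

#' Inter-sub-network connectivity features for one subject
#'
#' The sub-network mean series ([mean_series()]) are treated as `U` nodes;
#' their sliding-window correlation sequence is fitted with the same
#' matrix-normal model.  The fitted mean gives `U(U-1)/2` low-order and the
#' factor `U(U+1)/2` high-order features over network pairs.
#'
#' @inheritParams extract_intra
#' @return A list with tibbles `inter_low` and `inter_high`.
#' @export
extract_inter <- function(ts, partition, spec = window_spec(60, 4),
                          tol = 1e-6, max_iter = 100L, ridge = 1e-6) {
  ms <- mean_series(ts, partition)
  sq <- fcn_sequence(ms, spec = spec)
  fit <- fit_factor(sq, tol = tol, max_iter = max_iter, ridge = ridge)
  lm <- lower_tri_tbl(fit$M_hat, diag = FALSE, roi_names = sq$roi_names)
  lc <- lower_tri_tbl(fit$C_hat, diag = TRUE, roi_names = sq$roi_names)
  list(
    inter_low = feature_block("inter_low", lm$roi_i, lm$roi_j,
                              lm$roi_i, lm$roi_j, "mean", lm$value),
    inter_high = feature_block("inter_high", lc$roi_i, lc$roi_j,
                               lc$roi_i, lc$roi_j, "factor", lc$value)
  )
}

#' Min-max normalise a feature block
#'
#' Rescales the block's values to `[0, 1]` by the block's own minimum and
#' maximum.  A constant block maps to all zeros with a warning.
#'
#' @param block A feature-block tibble (with a `value` column) or a bare
#'   numeric vector.
#' @return Same type as the input, rescaled.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))
minmax_normalize <- function(block) {
  v <- if (is.data.frame(block)) block$value else block
  if (length(v) == 0) abort("empty block", class = "hierfcn_validation")
  rng <- range(v)
  if (diff(rng) == 0) {
    warn("constant feature block; normalised to all zeros")
    out <- rep(0, length(v))
  } else {
    out <- (v - rng[1]) / (rng[2] - rng[1])
  }
  if (is.data.frame(block)) { block$value <- out; block } else out
}

# canonical fusion order of the four hierarchy blocks
block_tag_order <- c("intra_high", "intra_low", "inter_high", "inter_low",
                     "static_baseline", "dynamic_baseline")

#' Fuse feature blocks into one subject-level feature vector
#'
#' Concatenates blocks in the fixed tag order intra_high, intra_low,
#' inter_high, inter_low (baseline blocks, when present, follow), keeping
#' per-feature provenance.
#'
#' @param blocks List of feature-block tibbles.
#' @return One tibble, rows ordered by block tag.
#' @export
fuse_blocks <- function(blocks) {
  if (length(blocks) == 0) abort("no blocks to fuse", class = "hierfcn_validation")
  block_tags <- vapply(blocks, function(b) b$tag[1], character(1))
  if (anyDuplicated(block_tags)) {
    abort("duplicated block tag", class = "hierfcn_validation")
  }
  fused <- dplyr::bind_rows(blocks)
  tags <- unique(fused$tag)
  if (!all(tags %in% block_tag_order)) {
    abort(paste0("unknown block tag: ", setdiff(tags, block_tag_order)[1]),
          class = "hierfcn_validation")
  }
  fused$tag <- factor(fused$tag, levels = block_tag_order)
  fused <- dplyr::arrange(fused, .data$tag)
  fused$tag <- as.character(fused$tag)
  fused
}

#' Static full-series correlation baseline features
#'
#' The conventional static connectivity estimate: strict lower triangle of
#' the Pearson correlation matrix of the full (unwindowed) series over the
#' selected ROIs.
#'
#' @param ts A [roi_ts].
#' @param roi_subset Integer ROI indices; `NULL` for all.
#' @return A feature-block tibble with tag `static_baseline`.
#' @export
baseline_static <- function(ts, roi_subset = NULL) {
  sq <- fcn_sequence(ts, roi_subset, window_spec(nrow(ts$values), 1L))
  m <- sq$matrices[, , 1]
  lt <- lower_tri_tbl(m, diag = FALSE, roi_names = sq$roi_names)
  feature_block("static_baseline", "full", NA_character_,
                lt$roi_i, lt$roi_j, "mean", lt$value)
}

#' Dynamic windowed-correlation baseline features
#'
#' The low-order dynamic connectivity estimate: the elementwise mean of the
#' sliding-window correlation sequence (equal to [fit_mean()] of that
#' sequence), vectorised as a strict lower triangle.  With a single window
#' covering the whole series this reduces exactly to [baseline_static()].
#'
#' @param ts A [roi_ts].
#' @param roi_subset Integer ROI indices; `NULL` for all.
#' @param spec A [window_spec].
#' @return A feature-block tibble with tag `dynamic_baseline`.
#' @export
baseline_dynamic <- function(ts, roi_subset = NULL, spec = window_spec(60, 4)) {
  sq <- fcn_sequence(ts, roi_subset, spec)
  m <- fit_mean(sq)
  lt <- lower_tri_tbl(m, diag = FALSE, roi_names = sq$roi_names)
  feature_block("dynamic_baseline", "full", NA_character_,
                lt$roi_i, lt$roi_j, "mean", lt$value)
}

#' Dimension diagnostics of the sub-network division
#'
#' For each sub-network, the dimension of one windowed connectivity matrix
#' treated as a single multivariate sample (`N_u^2`), its ratio to the
#' number of time points, and its percentage of the full-network dimension
#' (`N_u^2 / N^2 * 100`).  The last row reports the undivided full network.
#' These quantify how far the division relieves the
#' high-dimension/small-sample problem of the matrix-normal fit.
#'
#' @param partition A [subnet_partition].
#' @param M_time Number of time points.
#' @return Tibble with columns `network`, `n_roi`, `dim` (`N_u^2`),
#'   `ratio_to_time`, `pct_of_full`.
#' @export
#' @examples
#' dimension_report(aal_subnetworks(), 170)
dimension_report <- function(partition, M_time) {
  sizes <- as.numeric(lengths(partition))
  total <- sum(sizes)
  per <- tibble(
    network = names(partition),
    n_roi = as.integer(sizes),
    dim = sizes^2,
    ratio_to_time = sizes^2 / M_time,
    pct_of_full = sizes^2 / total^2 * 100
  )
  full <- tibble(network = "full", n_roi = as.integer(total),
                 dim = total^2,
                 ratio_to_time = total^2 / M_time, pct_of_full = 100)
  dplyr::bind_rows(per, full)
}

#' Extract the fused feature table for a cohort
#'
#' Runs the whole feature hierarchy for every subject — intra-network
#' matrix-normal fits, the inter-network fit on mean series, optional
#' static/dynamic baselines — and returns one wide tibble (subjects x
#' features, unnormalised; normalisation happens per cross-validation fold
#' in [nested_cv()], or explicitly via [minmax_normalize()]).
#'
#' @param subjects List of [roi_ts] objects.
#' @param partition A [subnet_partition].
#' @param spec A [window_spec].
#' @param baselines Also compute `static_baseline` and `dynamic_baseline`
#'   blocks over all ROIs?
#' @param tol,max_iter,ridge Passed to [fit_factor()].
#' @return A tibble with `subject_id` plus one column per feature, carrying
#'   a `provenance` attribute (tibble with `feature`, `tag`, `network`,
#'   `network_2`, `roi_i`, `roi_j`, `role`).
#' @export
extract_features <- function(subjects, partition, spec = window_spec(60, 4),
                             baselines = FALSE,
                             tol = 1e-6, max_iter = 100L, ridge = 1e-6) {
  rows <- purrr::map(subjects, function(ts) {
    intra <- extract_intra(ts, partition, spec, tol, max_iter, ridge)
    inter <- extract_inter(ts, partition, spec, tol, max_iter, ridge)
    blocks <- list(intra$intra_high, intra$intra_low,
                   inter$inter_high, inter$inter_low)
    if (baselines) {
      blocks <- c(blocks, list(baseline_static(ts),
                               baseline_dynamic(ts, spec = spec)))
    }
    fused <- fuse_blocks(blocks)
    fused$subject_id <- ts$subject_id
    fused
  })
  long <- dplyr::bind_rows(rows)
  prov <- dplyr::distinct(long[long$subject_id == long$subject_id[1],
                               c("feature", "tag", "network", "network_2",
                                 "roi_i", "roi_j", "role")])
  wide <- tidyr::pivot_wider(long[, c("subject_id", "feature", "value")],
                             names_from = "feature", values_from = "value")
  wide <- wide[, c("subject_id", prov$feature)]
  attr(wide, "provenance") <- prov
  wide
}

#' Feature provenance of a feature table
#' @param features A feature table from [extract_features()].
#' @return The provenance tibble (one row per feature column).
#' @export
feature_provenance <- function(features) {
  p <- attr(features, "provenance")
  if (is.null(p)) abort("feature table has no provenance attribute",
                        class = "hierfcn_validation")
  p
}
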
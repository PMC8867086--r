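#' Sliding-window specification
#'
#' @param width Window width `l_w` in time points (>= 2).
#' @param step Step size `l_s` in time points (>= 1).
#' @return A `window_spec` object.
#' @export
#' @examples
#' window_spec(60, 4)
window_spec <- function(width, step) {
  width <- as.integer(width); step <- as.integer(step)
  if (is.na(width) || width < 2L) abort("window width must be >= 2", class = "hierfcn_validation")
  if (is.na(step) || step < 1L) abort("step size must be >= 1", class = "hierfcn_validation")
  structure(list(width = width, step = step), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> width %d, step %d\n", x$width, x$step))
  invisible(x)
}

#' Number of sliding windows
#'
#' `K = floor((M_time - l_w) / l_s) + 1`: the number of full windows of
#' width `l_w` stepped by `l_s` that fit in `M_time` time points; trailing
#' partial windows are discarded.
#'
#' @param M_time Number of time points.
#' @param spec A [window_spec].
#' @return Integer `K >= 1`.
#' @export
#' @examples
#' num_windows(170, window_spec(60, 4))  # 28
num_windows <- function(M_time, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (spec$width > M_time) {
    abort(sprintf("window width %d exceeds series length %d", spec$width, M_time),
          class = "hierfcn_validation")
  }
  as.integer((M_time - spec$width) %/% spec$step + 1L)
}

#' Pearson correlation with a zero-variance convention
#'
#' Standard product-moment correlation; if either vector has zero variance
#' the correlation is defined as 0 (with a warning) rather than NaN, which
#' keeps downstream matrix-normal fitting well-posed.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("length mismatch", class = "hierfcn_validation")
  if (length(x) < 2L) abort("need >= 2 observations", class = "hierfcn_validation")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance input; correlation defined as 0")
    return(0)
  }
  cor(x, y)
}

#' Sliding-window correlation-network sequence
#'
#' Builds the sequence of `K` symmetric Pearson-correlation matrices over a
#' ROI subset.  Window `k` (1-based) covers rows
#' `(k-1) * l_s + 1` to `(k-1) * l_s + l_w`.  Zero-variance columns within a
#' window get zero correlations (unit diagonal kept) with a warning.
#'
#' @param ts A [roi_ts] object (or plain numeric matrix, time x ROI).
#' @param roi_subset Integer vector of 1-based ROI column indices; `NULL`
#'   selects all ROIs.
#' @param spec A [window_spec].
#' @return An `fcn_seq` object: list with `matrices` (array
#'   `N_u x N_u x K`), `window_starts` (1-based), `roi_subset`, `roi_names`.
#' @export
fcn_sequence <- function(ts, roi_subset = NULL, spec = window_spec(60, 4)) {
  vals <- if (inherits(ts, "roi_ts")) ts$values else as.matrix(ts)
  if (is.null(roi_subset)) roi_subset <- seq_len(ncol(vals))
  roi_subset <- as.integer(roi_subset)
  if (length(roi_subset) == 0 || any(roi_subset < 1L) || any(roi_subset > ncol(vals))) {
    abort("roi_subset empty or out of range", class = "hierfcn_validation")
  }
  M <- nrow(vals)
  K <- num_windows(M, spec)
  sub <- vals[, roi_subset, drop = FALSE]
  n_u <- ncol(sub)
  mats <- array(NA_real_, dim = c(n_u, n_u, K))
  starts <- (seq_len(K) - 1L) * spec$step + 1L
  degenerate <- FALSE
  for (k in seq_len(K)) {
    win <- sub[starts[k]:(starts[k] + spec$width - 1L), , drop = FALSE]
    sds <- apply(win, 2, sd)
    if (any(sds == 0)) {
      degenerate <- TRUE
      cc <- suppressWarnings(cor(win))
      cc[!is.finite(cc)] <- 0
    } else {
      cc <- cor(win)
    }
    cc <- (cc + t(cc)) / 2
    diag(cc) <- 1
    mats[, , k] <- cc
  }
  if (degenerate) warn("zero-variance ROI within a window; its correlations set to 0")
  rn <- if (inherits(ts, "roi_ts")) ts$roi_names[roi_subset] else colnames(sub)
  if (!is.null(rn)) dimnames(mats) <- list(rn, rn, NULL)
  structure(list(matrices = mats, window_starts = starts,
                 roi_subset = roi_subset, roi_names = rn),
            class = "fcn_seq")
}

#' @export
print.fcn_seq <- function(x, ...) {
  d <- dim(x$matrices)
  cat(sprintf("<fcn_seq> %d windows of %d x %d correlation matrices\n", d[3], d[1], d[2]))
  invisible(x)
}

#' @export
length.fcn_seq <- function(x) dim(x$matrices)[3]

# Coerce fcn_seq / list of matrices / 3-d array to an N x N x K array.
as_matrix_array <- function(x) {
  if (inherits(x, "fcn_seq")) return(x$matrices)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    mats <- lapply(x, as.matrix)
    n <- nrow(mats[[1]])
    return(array(unlist(mats), dim = c(n, ncol(mats[[1]]), length(mats))))
  }
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  abort("cannot interpret input as a sequence of matrices", class = "hierfcn_validation")
}
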
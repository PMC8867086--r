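#' ROI time-series container
#'
#' Holds one subject's region-of-interest (ROI) signal matrix in time-by-ROI
#' orientation, i.e. row `m` is one imaging volume and column `i` is the
#' average signal of the `i`-th ROI.
#'
#' @param values Numeric matrix, `M_time x N_roi`, no missing values.
#' @param roi_names Character vector of unique ROI names; defaults to the
#'   column names of `values`.
#' @param subject_id Single string identifying the subject.
#'
#' @return An object of class `roi_ts`: a list with elements `subject_id`,
#'   `values` (matrix with ROI column names) and `roi_names`.
#' @export
#' @examples
#' ts <- roi_ts(matrix(rnorm(20), 10, 2), c("r1", "r2"), "s1")
#' dim(ts$values)
roi_ts <- function(values, roi_names = colnames(values), subject_id = "subject") {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("`values` must be numeric", class = "hierfcn_validation")
  if (anyNA(values) || any(!is.finite(values))) {
    abort("time series contains missing or non-finite values", class = "hierfcn_validation")
  }
  if (nrow(values) < 2L) abort("need at least 2 time points", class = "hierfcn_validation")
  if (ncol(values) < 2L) abort("need at least 2 ROIs", class = "hierfcn_validation")
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(ncol(values)))
  roi_names <- as.character(roi_names)
  if (length(roi_names) != ncol(values) || anyDuplicated(roi_names)) {
    abort("`roi_names` must be unique and match the number of columns",
          class = "hierfcn_validation")
  }
  colnames(values) <- roi_names
  rownames(values) <- NULL
  structure(list(subject_id = as.character(subject_id)[1],
                 values = values, roi_names = roi_names),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d time points x %d ROIs\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$values)

#' Read a subject's ROI time series from a delimited file
#'
#' The file must be a rectangular numeric table with a header row of ROI
#' names and one row per time point.  Constant (zero-variance) columns are
#' permitted but flagged with a warning; downstream correlation code treats
#' them as zero-correlation ROIs.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#'
#' @return A [roi_ts] object.
#' @export
read_timeseries <- function(path, dialect = c("tsv", "csv"), subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "hierfcn_validation")
  delim <- if (dialect == "tsv") "\t" else ","
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort("file has no data rows", class = "hierfcn_format")
  cells <- strsplit(lines, delim, fixed = TRUE)
  nfield <- lengths(cells)
  if (any(nfield != nfield[1])) {
    bad <- which(nfield != nfield[1])[1]
    abort(sprintf("ragged table: row %d has %d fields, expected %d",
                  bad, nfield[bad], nfield[1]),
          class = "hierfcn_format")
  }
  header <- cells[[1]]
  body <- cells[-1]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(length(header))))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(header))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at data row %d, column %d ('%s')",
                  idx[1], idx[2], body[[idx[1]]][idx[2]]),
          class = "hierfcn_parse")
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  out <- roi_ts(vals, roi_names = header, subject_id = subject_id)
  sds <- apply(out$values, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("constant (zero-variance) ROI column(s): ",
                paste(out$roi_names[sds == 0], collapse = ", ")))
  }
  out
}

#' Write a subject's ROI time series
#'
#' Values are serialised with `%.17g` so a TSV round trip through
#' [read_timeseries()] reproduces the doubles bit-identically.
#'
#' @param ts A [roi_ts] object.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ts, "roi_ts"))
  delim <- if (dialect == "tsv") "\t" else ","
  rows <- apply(ts$values, 1, function(r) paste(sprintf("%.17g", r), collapse = delim))
  writeLines(c(paste(ts$roi_names, collapse = delim), rows), path)
  invisible(path)
}

#' Read a subject label table
#'
#' Expects a TSV with columns `subject_id` and `label`, the latter coded
#' `ASD`/`NC` (or already `1`/`-1`).  ASD (patients) map to +1, normal
#' controls to -1; the classifier treats +1 as the positive class.
#'
#' @param path Path to the label TSV.
#' @return A tibble with columns `subject_id` (character) and `label`
#'   (integer, +1 or -1).
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("subject_id", "label") %in% names(df))) {
    abort("label table must have columns 'subject_id' and 'label'", class = "hierfcn_format")
  }
  lab <- dplyr::case_when(
    df$label %in% c("ASD", "1", "+1") ~ 1L,
    df$label %in% c("NC", "-1") ~ -1L,
    TRUE ~ NA_integer_
  )
  if (anyNA(lab)) {
    abort(paste0("unrecognised label(s): ",
                 paste(unique(df$label[is.na(lab)]), collapse = ", ")),
          class = "hierfcn_format")
  }
  if (anyDuplicated(df$subject_id)) abort("duplicated subject_id", class = "hierfcn_validation")
  tibble(subject_id = df$subject_id, label = lab)
}

#' Write a subject label table
#'
#' @param labels Tibble with `subject_id` and `label` (+1/-1) columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- tibble(subject_id = labels$subject_id,
                label = ifelse(labels$label > 0, "ASD", "NC"))
  readr::write_tsv(out, path)
  invisible(path)
}
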
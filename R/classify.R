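#' Selection and cross-validation configuration
#'
#' Default hyperparameter grids follow the evaluation protocol: t-test
#' threshold `p` in 0.01..0.10 (step 0.01), LASSO `lambda` in 0.1..0.9
#' (step 0.1), and linear-SVM soft-margin cost in `2^-4 .. 2^4`, searched by
#' nested fivefold cross-validation.
#'
#' @param p_grid Numeric grid of t-test p-value thresholds.
#' @param lambda_grid Numeric grid of LASSO penalties (on the
#'   sum-of-squares scale of the selection objective).
#' @param cost_grid Numeric grid of SVM soft-margin costs.
#' @param outer_folds,inner_folds Fold counts (>= 2).
#' @param repeats Number of repeated runs with reshuffled folds.
#' @param seed Integer seed controlling all fold shuffling.
#' @param normalization `"fold"` (block min-max from training subjects only,
#'   applied to test subjects) or `"global"` (pooled over all subjects).
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_grid = seq(0.01, 0.10, by = 0.01),
                             lambda_grid = seq(0.1, 0.9, by = 0.1),
                             cost_grid = 2^(-4:4),
                             outer_folds = 5L, inner_folds = 5L,
                             repeats = 1L, seed = 1L,
                             normalization = c("fold", "global")) {
  normalization <- match.arg(normalization)
  if (length(p_grid) == 0 || length(lambda_grid) == 0 || length(cost_grid) == 0) {
    abort("hyperparameter grids must be non-empty", class = "hierfcn_validation")
  }
  if (outer_folds < 2L || inner_folds < 2L) {
    abort("fold counts must be >= 2", class = "hierfcn_validation")
  }
  structure(list(p_grid = p_grid, lambda_grid = lambda_grid,
                 cost_grid = cost_grid,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 normalization = normalization),
            class = "selection_config")
}

# Feature table (tibble with subject_id) or matrix -> numeric matrix with
# feature column names.
as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  df <- as.data.frame(features)
  if ("subject_id" %in% names(df)) {
    rn <- df$subject_id
    df$subject_id <- NULL
    m <- as.matrix(df)
    rownames(m) <- rn
  } else {
    m <- as.matrix(df)
  }
  m
}

align_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    if (is.data.frame(features) && "subject_id" %in% names(features)) {
      idx <- match(features$subject_id, labels$subject_id)
      if (anyNA(idx)) {
        abort(paste0("subjects without labels: ",
                     paste(features$subject_id[is.na(idx)], collapse = ", ")),
              class = "hierfcn_validation")
      }
      return(as.integer(labels$label[idx]))
    }
    return(as.integer(labels$label))
  }
  as.integer(labels)
}

# Vectorised pooled-variance two-sample t-test p-values per column.
# Columns with zero variance in both groups and equal means get NA
# (undefined test); zero variance with distinct means gets p = 0.
two_sample_t_pvals <- function(X, y) {
  g1 <- y > 0; g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) abort("need >= 2 subjects in each class", class = "hierfcn_validation")
  m1 <- colMeans(X[g1, , drop = FALSE]); m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- colSums((X[g1, , drop = FALSE] - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((X[g2, , drop = FALSE] - rep(m2, each = n2))^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  zero <- se == 0
  p[zero & (m1 == m2)] <- NA_real_
  p[zero & (m1 != m2)] <- 0
  p
}

#' t-test feature filter
#'
#' Keeps features whose two-sample (pooled-variance) t-test between the two
#' groups has `p < p_threshold`.  Features with zero variance in both groups
#' (undefined test) are always dropped.
#'
#' @param features Feature table or matrix (rows = subjects).
#' @param labels Label tibble (`subject_id`, `label`) or a +1/-1 vector.
#' @param p_threshold Threshold; `1` keeps every testable feature.
#' @return Integer vector of selected column indices (ascending).
#' @export
ttest_filter <- function(features, labels, p_threshold) {
  X <- as_feature_matrix(features)
  y <- align_labels(features, labels)
  p <- two_sample_t_pvals(X, y)
  unname(which(!is.na(p) & p < p_threshold))
}

#' LASSO feature selection
#'
#' Solves the L1-penalised least squares `min_w 1/2 sum_l (I_l - f_l' w)^2 +
#' lambda ||w||_1` (labels regressed on features, no intercept) and returns
#' the nonzero-coefficient support.  Solved with glmnet (its penalty scale
#' is the objective's divided by the number of subjects); the
#' single-predictor case uses the closed-form soft threshold and
#' `lambda = 0` with more subjects than features the exact least-squares
#' solve.
#'
#' @param features Feature table or matrix (already filtered).
#' @param labels Labels as in [ttest_filter()].
#' @param lambda Penalty `>= 0`.
#' @return List with `weights` (named numeric) and `selected` (integer
#'   column indices with nonzero weight).
#' @export
lasso_select <- function(features, labels, lambda) {
  X <- as_feature_matrix(features)
  y <- as.numeric(align_labels(features, labels))
  if (lambda < 0) abort("lambda must be >= 0", class = "hierfcn_validation")
  p <- ncol(X)
  if (p == 0) return(list(weights = numeric(0), selected = integer(0)))
  if (p == 1) {
    xy <- sum(X[, 1] * y); xx <- sum(X[, 1]^2)
    w <- if (xx == 0) 0 else sign(xy) * max(abs(xy) - lambda, 0) / xx
    weights <- setNames(w, colnames(X))
  } else if (lambda == 0 && nrow(X) > p) {
    weights <- setNames(drop(qr.solve(X, y)), colnames(X))
  } else {
    n <- nrow(X)
    lam <- lambda / n
    lam_path <- if (lam > 0) lam * c(16, 8, 4, 2, 1) else
      c(max(abs(crossprod(X, y))) / n * c(0.5, 0.1, 0.02, 0.004), 0)
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = lam_path,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    co <- stats::coef(fit, s = lam, exact = FALSE)
    weights <- setNames(as.numeric(co)[-1], colnames(X))  # drop intercept row
  }
  list(weights = weights, selected = unname(which(abs(weights) > 1e-10)))
}

#' Train a linear soft-margin SVM
#'
#' Maximum-margin linear classifier on the selected features.  When no
#' feature survived selection the classifier degrades (with a warning) to
#' predicting the training majority class, so cross-validation never
#' crashes on an empty selection.
#'
#' @param features Feature table or matrix (training rows).
#' @param labels Labels as in [ttest_filter()].
#' @param cost Soft-margin cost parameter.
#' @return A `hier_svm` classifier.
#' @export
train_svm <- function(features, labels, cost = 1) {
  X <- as_feature_matrix(features)
  y <- align_labels(features, labels)
  if (ncol(X) == 0) {
    warn("no features selected; falling back to majority-class prediction")
    maj <- if (sum(y > 0) > sum(y < 0)) 1L else -1L
    return(structure(list(type = "majority", label = maj), class = "hier_svm"))
  }
  if (length(unique(y)) < 2) abort("both classes required for training",
                                   class = "hierfcn_validation")
  model <- e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
                      cost = cost, scale = FALSE)
  structure(list(type = "svm", model = model, features = colnames(X)),
            class = "hier_svm")
}

#' @export
predict.hier_svm <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (object$type == "majority") return(rep(object$label, nrow(X)))
  as.integer(as.character(predict(object$model, X[, object$features, drop = FALSE])))
}

#' Classification metrics from a binary confusion matrix
#'
#' The +1 (patient) class is treated as positive.  Ratios with zero
#' denominator are reported as `NA` with the `undefined` field naming them.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return One-row tibble with `acc`, `tpr`, `tnr`, `ppv`, `npv`,
#'   `undefined` (comma-separated names of undefined metrics, or `""`).
#' @export
#' @examples
#' classification_metrics(8, 1, 9, 2)
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) abort("negative counts", class = "hierfcn_validation")
  if (sum(counts) == 0) abort("empty confusion matrix", class = "hierfcn_validation")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble(
    acc = (tp + tn) / sum(counts),
    tpr = ratio(tp, tp + fn), tnr = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn)
  )
  und <- names(out)[vapply(out, is.na, logical(1))]
  out$undefined <- paste(und, collapse = ",")
  out
}

# Deterministic stratified fold assignment: within each class, shuffle and
# deal subjects round-robin over folds.
stratified_folds <- function(y, k, seed) {
  set.seed(seed %% .Machine$integer.max)
  fold <- integer(length(y))
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      abort(sprintf("class %d has %d subjects, fewer than %d folds",
                    cls, length(idx), k), class = "hierfcn_validation")
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Per-block min-max statistics pooled over the entries of `rows`
# (Eq.-7-style block normalisation), and their application.
block_norm_stats <- function(X, block_cols, rows) {
  lapply(block_cols, function(cols) {
    v <- X[rows, cols, drop = FALSE]
    r <- range(v)
    list(min = r[1], span = if (diff(r) == 0) 1 else diff(r))
  })
}

apply_block_norm <- function(X, block_cols, stats) {
  out <- X
  for (tag in names(block_cols)) {
    s <- stats[[tag]]
    out[, block_cols[[tag]]] <- (X[, block_cols[[tag]], drop = FALSE] - s$min) / s$span
  }
  out
}

#' Nested cross-validated feature selection and classification
#'
#' Outer loop: stratified k-fold split estimating generalisation.  Inner
#' loop (on the outer-training subjects only): stratified k-fold grid search
#' over `(p_threshold, lambda, cost)` by mean inner accuracy, ties broken
#' toward the simpler model (larger `p`, larger `lambda`, smaller cost).
#' The winning configuration is refitted on the full outer-training set and
#' scored on the held-out fold.  Block min-max normalisation, the t-test
#' filter and the LASSO are always refitted on training rows only (unless
#' `normalization = "global"`), so no test information leaks into selection.
#' The whole procedure is repeated `repeats` times with reshuffled folds.
#'
#' @param features Feature table from [extract_features()] (or any tibble
#'   with `subject_id` + numeric columns; a `provenance` attribute enables
#'   block-wise normalisation and contribution tracing).
#' @param labels Label tibble or +1/-1 vector aligned with `features`.
#' @param cfg A [selection_config()].
#' @return A `cv_result`: list with `folds` (per-repeat, per-fold metrics
#'   and chosen hyperparameters), `selected` (per-fold selected features),
#'   `summary` (mean and sd per metric, over folds and over repeat means),
#'   `config`, `provenance`.
#' @export
nested_cv <- function(features, labels, cfg = selection_config()) {
  X <- as_feature_matrix(features)
  y <- align_labels(features, labels)
  prov <- attr(features, "provenance")
  block_cols <- if (!is.null(prov)) {
    split(match(prov$feature, colnames(X)), prov$tag)
  } else {
    list(all = seq_len(ncol(X)))
  }
  grid <- expand.grid(p = cfg$p_grid, lambda = cfg$lambda_grid,
                      cost = cfg$cost_grid, KEEP.OUT.ATTRS = FALSE)

  global_stats <- if (cfg$normalization == "global") {
    block_norm_stats(X, block_cols, seq_len(nrow(X)))
  } else NULL

  fold_rows <- list(); sel_rows <- list()
  for (r in seq_len(cfg$repeats)) {
    outer_seed <- (cfg$seed + 7919L * r) %% .Machine$integer.max
    folds <- stratified_folds(y, cfg$outer_folds, outer_seed)
    for (f in seq_len(cfg$outer_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      inner_seed <- (outer_seed + 104729L * f) %% .Machine$integer.max
      infold <- stratified_folds(y[tr], cfg$inner_folds, inner_seed)

      # inner grid search: precompute per-inner-fold normalisation + p-values
      inner_correct <- matrix(0, nrow(grid), cfg$inner_folds)
      inner_n <- integer(cfg$inner_folds)
      for (g in seq_len(cfg$inner_folds)) {
        itr <- tr[infold != g]; ival <- tr[infold == g]
        inner_n[g] <- length(ival)
        st <- if (is.null(global_stats)) block_norm_stats(X, block_cols, itr) else global_stats
        Xn <- apply_block_norm(X, block_cols, st)
        pv <- two_sample_t_pvals(Xn[itr, , drop = FALSE], y[itr])
        for (gi in seq_len(nrow(grid))) {
          keep <- which(!is.na(pv) & pv < grid$p[gi])
          sel <- if (length(keep)) {
            keep[lasso_select(Xn[itr, keep, drop = FALSE], y[itr],
                              grid$lambda[gi])$selected]
          } else integer(0)
          clf <- suppressWarnings(
            train_svm(Xn[itr, sel, drop = FALSE], y[itr], grid$cost[gi]))
          pred <- predict(clf, Xn[ival, sel, drop = FALSE])
          inner_correct[gi, g] <- sum(pred == y[ival])
        }
      }
      acc <- rowSums(inner_correct) / sum(inner_n)
      ord <- order(-acc, -grid$p, -grid$lambda, grid$cost)
      best <- grid[ord[1], ]

      # refit the winner on the full outer-training set
      st <- if (is.null(global_stats)) block_norm_stats(X, block_cols, tr) else global_stats
      Xn <- apply_block_norm(X, block_cols, st)
      pv <- two_sample_t_pvals(Xn[tr, , drop = FALSE], y[tr])
      keep <- which(!is.na(pv) & pv < best$p)
      sel <- if (length(keep)) {
        keep[lasso_select(Xn[tr, keep, drop = FALSE], y[tr], best$lambda)$selected]
      } else integer(0)
      clf <- suppressWarnings(train_svm(Xn[tr, sel, drop = FALSE], y[tr], best$cost))
      pred <- predict(clf, Xn[te, sel, drop = FALSE])
      met <- classification_metrics(tp = sum(pred == 1 & y[te] == 1),
                                    fp = sum(pred == 1 & y[te] == -1),
                                    tn = sum(pred == -1 & y[te] == -1),
                                    fn = sum(pred == -1 & y[te] == 1))
      fold_rows[[length(fold_rows) + 1L]] <- dplyr::bind_cols(
        tibble(rep = r, fold = f, p = best$p, lambda = best$lambda,
               cost = best$cost, n_selected = length(sel),
               inner_acc = acc[ord[1]]), met)
      if (length(sel)) {
        sel_rows[[length(sel_rows) + 1L]] <-
          tibble(rep = r, fold = f, feature = colnames(X)[sel])
      }
    }
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  sel_tbl <- if (length(sel_rows)) dplyr::bind_rows(sel_rows) else
    tibble(rep = integer(0), fold = integer(0), feature = character(0))

  metric_cols <- c("acc", "tpr", "tnr", "ppv", "npv")
  over_folds <- tidyr::pivot_longer(folds_tbl[, c("rep", "fold", metric_cols)],
                                    dplyr::all_of(metric_cols),
                                    names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(over = "folds")
  over_reps <- tidyr::pivot_longer(folds_tbl[, c("rep", "fold", metric_cols)],
                                   dplyr::all_of(metric_cols),
                                   names_to = "metric") |>
    dplyr::group_by(.data$rep, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop") |>
    dplyr::mutate(over = "repeats")

  structure(list(folds = folds_tbl, selected = sel_tbl,
                 summary = dplyr::bind_rows(over_folds, over_reps),
                 config = cfg, provenance = prov),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary[x$summary$over == "folds", ]
  cat(sprintf("<cv_result> %d repeats x %d outer folds\n",
              x$config$repeats, x$config$outer_folds))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Per-fold metrics of a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold tibble (metrics + chosen hyperparameters).
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row-per-metric summary of a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Summary tibble with mean and sd per metric, computed both over
#'   all folds and over per-repeat means.
#' @export
glance.cv_result <- function(x, ...) x$summary

#' Sub-network contribution rates of the selected features
#'
#' Traces every selected feature occurrence (across repeats and folds) back
#' to its sub-network: intra-network features credit their network with
#' weight 1; inter-network features credit each endpoint network with
#' weight 1/2.  Rates are normalised to sum to one.
#'
#' @param result A `cv_result` from [nested_cv()].
#' @param provenance Provenance tibble; defaults to the one stored in
#'   `result`.
#' @return Tibble with `network`, `credit`, `rate`, sorted by rate.
#' @export
contribution_trace <- function(result, provenance = result$provenance) {
  if (is.null(provenance)) abort("provenance required", class = "hierfcn_validation")
  sel <- dplyr::left_join(result$selected, provenance, by = "feature")
  networks <- unique(c(provenance$network[provenance$tag %in% c("intra_low", "intra_high")],
                       provenance$network[provenance$tag %in% c("inter_low", "inter_high")],
                       provenance$network_2[provenance$tag %in% c("inter_low", "inter_high")]))
  networks <- setdiff(networks[!is.na(networks)], "full")
  credit <- setNames(rep(0, length(networks)), networks)
  intra <- sel[sel$tag %in% c("intra_low", "intra_high"), ]
  if (nrow(intra)) {
    tab <- table(intra$network)
    credit[names(tab)] <- credit[names(tab)] + as.numeric(tab)
  }
  inter <- sel[sel$tag %in% c("inter_low", "inter_high"), ]
  if (nrow(inter)) {
    for (col in c("network", "network_2")) {
      tab <- table(inter[[col]])
      credit[names(tab)] <- credit[names(tab)] + as.numeric(tab) / 2
    }
  }
  total <- sum(credit)
  tibble(network = names(credit), credit = as.numeric(credit),
         rate = if (total > 0) as.numeric(credit) / total else rep(0, length(credit))) |>
    dplyr::arrange(dplyr::desc(.data$rate), .data$network)
}

#' Most frequently selected low-order connections
#'
#' Ranks ROI-pair (low-order) features by how often they were selected
#' across repeats and folds.  Ties are broken lexicographically by ROI pair
#' for determinism.
#'
#' @param result A `cv_result`.
#' @param provenance Provenance tibble; defaults to the stored one.
#' @param n Number of edges to return (top 10 by default); if fewer are
#'   available all are returned with a warning.
#' @return Tibble with `roi_i`, `roi_j`, `network`, `freq`.
#' @export
top_edges <- function(result, provenance = result$provenance, n = 10L) {
  if (is.null(provenance)) abort("provenance required", class = "hierfcn_validation")
  sel <- dplyr::left_join(result$selected, provenance, by = "feature")
  low <- sel[sel$role == "mean" & !is.na(sel$roi_i) &
               sel$tag %in% c("intra_low", "static_baseline", "dynamic_baseline"), ]
  ranked <- low |>
    dplyr::count(.data$roi_i, .data$roi_j, .data$network, name = "freq") |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$roi_i, .data$roi_j)
  if (nrow(ranked) < n) {
    warn(sprintf("only %d distinct selected edges available (requested %d)",
                 nrow(ranked), n))
    return(ranked)
  }
  ranked[seq_len(n), ]
}
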
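make_xy <- function(n = 24, p = 10, seed = 1, informative = integer(0), shift = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c(1L, -1L), each = n / 2)
  for (j in informative) X[, j] <- X[, j] + shift * y
  list(X = X, y = y)
}

test_that("the t-test filter keeps signal and drops untestable features", {
  d <- make_xy(n = 30, p = 6, seed = 2, informative = 3, shift = 2)
  d$X[, 5] <- 7  # constant in both groups: undefined test
  sel <- ttest_filter(d$X, d$y, 0.05)
  expect_true(3 %in% sel)
  expect_false(5 %in% sel)
  # p = 1 keeps every testable feature
  expect_identical(ttest_filter(d$X, d$y, 1), setdiff(1:6, 5L))
})

test_that("the filter is monotone in the threshold and matches t.test", {
  d <- make_xy(n = 20, p = 25, seed = 3, informative = 1:3, shift = 0.8)
  sels <- lapply(c(0.01, 0.05, 0.2, 1), function(p) ttest_filter(d$X, d$y, p))
  for (i in 1:3) expect_true(all(sels[[i]] %in% sels[[i + 1]]))
  # oracle: stats::t.test with pooled variance
  pv <- hierfcn:::two_sample_t_pvals(d$X, d$y)
  for (j in c(1, 7, 25)) {
    ref <- t.test(d$X[d$y > 0, j], d$X[d$y < 0, j], var.equal = TRUE)$p.value
    expect_equal(unname(pv[j]), ref, tolerance = 1e-12)
  }
})

test_that("LASSO selection follows the penalised least-squares objective", {
  d <- make_xy(n = 40, p = 5, seed = 4, informative = 2, shift = 1.5)
  # full shrinkage
  expect_length(lasso_select(d$X, d$y, lambda = 1e6)$selected, 0)
  # lambda = 0 with n > p: exact least squares
  w0 <- lasso_select(d$X, d$y, lambda = 0)$weights
  ref <- qr.solve(d$X, d$y)
  expect_equal(unname(w0), unname(ref), tolerance = 1e-8)
  # single predictor: closed-form soft threshold
  x1 <- d$X[, 2, drop = FALSE]
  lam <- 5
  got <- lasso_select(x1, d$y, lam)$weights
  xy <- sum(x1 * d$y)
  expect_equal(unname(got), sign(xy) * max(abs(xy) - lam, 0) / sum(x1^2))
  expect_identical(lasso_select(x1, d$y, lam)$selected, 1L)
})

test_that("LASSO support is non-increasing in lambda", {
  d <- make_xy(n = 30, p = 12, seed = 5, informative = 1:4, shift = 1)
  sizes <- vapply(seq(0.1, 0.9, by = 0.1) * 30, function(l) {
    length(lasso_select(d$X, d$y, l)$selected)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("glmnet-based LASSO agrees with coordinate-descent on a small case", {
  # independent oracle: plain cyclic coordinate descent on the objective
  d <- make_xy(n = 26, p = 4, seed = 6, informative = 1, shift = 1.2)
  lam <- 8
  w <- rep(0, 4)
  for (it in 1:500) {
    for (j in 1:4) {
      r <- d$y - d$X[, -j, drop = FALSE] %*% w[-j]
      rho <- sum(d$X[, j] * r)
      w[j] <- sign(rho) * max(abs(rho) - lam, 0) / sum(d$X[, j]^2)
    }
  }
  got <- lasso_select(d$X, d$y, lam)$weights
  expect_equal(unname(got), w, tolerance = 1e-4)
})

test_that("the linear SVM separates separable data and respects symmetry", {
  X <- matrix(c(1, 1, 2, 2, -1, -1, -2, -2), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  y <- c(1L, 1L, -1L, -1L)
  clf <- train_svm(X, y, cost = 10)
  expect_identical(predict(clf, X), y)
  clf2 <- train_svm(X, -y, cost = 10)
  expect_identical(predict(clf2, X), -y)
})

test_that("an empty feature set falls back to majority-class prediction", {
  X <- matrix(numeric(0), nrow = 5, ncol = 0)
  y <- c(1L, 1L, 1L, -1L, -1L)
  expect_warning(clf <- train_svm(X, y), "majority")
  expect_identical(predict(clf, matrix(numeric(0), 3, 0)), rep(1L, 3))
})

test_that("confusion-matrix metrics follow their definitions", {
  m <- classification_metrics(tp = 8, fp = 1, tn = 9, fn = 2)
  expect_equal(m$acc, 0.85)
  expect_equal(m$tpr, 0.8)
  expect_equal(m$tnr, 0.9)
  all1 <- classification_metrics(10, 0, 10, 0)
  expect_true(all(unlist(all1[c("acc", "tpr", "tnr", "ppv", "npv")]) == 1))
  und <- classification_metrics(0, 0, 5, 5)
  expect_true(is.na(und$ppv))
  expect_match(und$undefined, "ppv")
  expect_error(classification_metrics(-1, 0, 0, 1), class = "hierfcn_validation")
})

test_that("stratified folds keep both classes in every fold deterministically", {
  y <- rep(c(1L, -1L), c(13, 17))
  f1 <- hierfcn:::stratified_folds(y, 5, seed = 3)
  f2 <- hierfcn:::stratified_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_gte(sum(y[f1 == k] == 1), 2)
    expect_gte(sum(y[f1 == k] == -1), 3)
  }
  expect_error(hierfcn:::stratified_folds(rep(c(1L, -1L), c(3, 20)), 5, 1),
               class = "hierfcn_validation")
})

small_cfg <- function(seed = 1, repeats = 1L) {
  selection_config(p_grid = c(0.05, 0.2), lambda_grid = c(0.5, 2),
                   cost_grid = c(0.5, 2), outer_folds = 4L, inner_folds = 3L,
                   repeats = repeats, seed = seed)
}

test_that("nested CV is deterministic and detects a leaked label column", {
  d <- make_xy(n = 24, p = 8, seed = 9)
  X <- cbind(d$X, leak = 10 * as.numeric(d$y))
  r1 <- nested_cv(X, d$y, small_cfg(seed = 5))
  r2 <- nested_cv(X, d$y, small_cfg(seed = 5))
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$selected, r2$selected)
  expect_equal(mean(r1$folds$acc), 1)
})

test_that("outer-fold selection is untouched by test-row perturbations", {
  d <- make_xy(n = 24, p = 10, seed = 11, informative = 1:2, shift = 1)
  cfg <- small_cfg(seed = 13)
  base <- nested_cv(d$X, d$y, cfg)
  folds <- hierfcn:::stratified_folds(d$y, cfg$outer_folds,
                                      (cfg$seed + 7919L) %% .Machine$integer.max)
  # corrupt the held-out rows of fold 1 only: everything fitted on the
  # training side of fold 1 (normalisation, filter, LASSO, SVM choice)
  # must be unchanged
  X2 <- d$X
  X2[folds == 1, ] <- X2[folds == 1, ] + 100
  pert <- nested_cv(X2, d$y, cfg)
  f1 <- base$folds[base$folds$fold == 1, ]
  f2 <- pert$folds[pert$folds$fold == 1, ]
  expect_identical(f1[, c("p", "lambda", "cost", "n_selected")],
                   f2[, c("p", "lambda", "cost", "n_selected")])
  expect_identical(base$selected$feature[base$selected$fold == 1],
                   pert$selected$feature[pert$selected$fold == 1])
})

test_that("contribution tracing credits networks by the 1 / half rule", {
  prov <- tibble::tibble(
    feature = c("a", "b", "c"),
    tag = c("intra_low", "intra_low", "inter_low"),
    network = c("DMN", "SMN", "DMN"), network_2 = c(NA, NA, "EAN"),
    roi_i = c("r1", "r3", "DMN"), roi_j = c("r2", "r4", "EAN"),
    role = "mean")
  fake <- structure(list(
    selected = tibble::tibble(rep = 1L, fold = 1L, feature = c("a", "b")),
    provenance = prov), class = "cv_result")
  ct <- contribution_trace(fake)
  expect_equal(ct$rate[ct$network == "DMN"], 0.5)
  expect_equal(ct$rate[ct$network == "SMN"], 0.5)
  expect_equal(ct$rate[ct$network == "EAN"], 0)

  fake$selected <- tibble::tibble(rep = 1L, fold = 1L, feature = "c")
  ct2 <- contribution_trace(fake)
  expect_equal(ct2$rate[ct2$network == "DMN"], 0.5)
  expect_equal(ct2$rate[ct2$network == "EAN"], 0.5)

  fake$selected <- tibble::tibble(rep = 1L, fold = 1L, feature = "a")
  ct3 <- contribution_trace(fake)
  expect_equal(ct3$rate[ct3$network == "DMN"], 1)
})

test_that("top edges rank by frequency with lexicographic tie-break", {
  prov <- tibble::tibble(
    feature = c("e1", "e2", "e3"),
    tag = "intra_low", network = "DMN", network_2 = NA_character_,
    roi_i = c("r2", "r1", "r3"), roi_j = c("r1", "r3", "r1"),
    role = "mean")
  fake <- structure(list(
    selected = tibble::tibble(rep = c(1L, 1L, 2L, 2L, 2L),
                              fold = 1L,
                              feature = c("e1", "e2", "e1", "e2", "e3")),
    provenance = prov), class = "cv_result")
  expect_warning(ranked <- top_edges(fake, n = 10), "only 3")
  expect_identical(nrow(ranked), 3L)
  expect_equal(ranked$freq[1:2], c(2, 2))
  # tie between e1 (r2,r1) and e2 (r1,r3): lexicographic roi_i wins
  expect_identical(ranked$roi_i[1], "r1")
  ranked3 <- top_edges(fake, n = 2)
  expect_identical(nrow(ranked3), 2L)
})
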
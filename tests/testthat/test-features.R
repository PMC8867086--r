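test_that("mean_series averages ROI series within each sub-network", {
  vals <- cbind(c(1, 2, 3), c(3, 4, 5), c(10, 10, 10), c(20, 30, 40))
  ts <- roi_ts(vals, paste0("r", 1:4))
  p <- subnet_partition(list(A = 1:2, B = 3:4), paste0("r", 1:4))
  ms <- mean_series(ts, p)
  expect_equal(unname(ms$values[, "A"]), c(2, 3, 4))
  expect_equal(unname(ms$values[, "B"]), c(15, 20, 25))

  # identical ROIs: the mean equals each member series
  ts2 <- roi_ts(cbind(vals[, 1], vals[, 1], vals[, 2], vals[, 2]), paste0("r", 1:4))
  ms2 <- mean_series(ts2, p)
  expect_equal(unname(ms2$values[, "A"]), vals[, 1])
})

test_that("mean_series matches a brute-force per-group average at full scale", {
  p <- aal_subnetworks()
  set.seed(12)
  ts <- roi_ts(matrix(rnorm(170 * 116), 170, 116), attr(p, "roi_names"))
  ms <- mean_series(ts, p)
  expect_identical(dim(ms$values), c(170L, 6L))
  for (nm in names(p)) {
    brute <- apply(ts$values[, p[[nm]], drop = FALSE], 1, mean)
    expect_equal(unname(ms$values[, nm]), brute)
  }
})

test_that("intra feature block sizes follow the triangle counts", {
  ts <- toy_ts(M = 60, N = 6, seed = 31)
  p <- toy_partition(N = 6, groups = 3)
  intra <- extract_intra(ts, p, window_spec(20, 10))
  expect_identical(nrow(intra$intra_low), 3L)   # 3 networks x 1 pair
  expect_identical(nrow(intra$intra_high), 9L)  # 3 networks x 3 entries

  # a 2-ROI network contributes 1 low-order and 3 high-order entries
  p2 <- subnet_partition(list(A = 1:2, B = 3:6), paste0("r", 1:6))
  intra2 <- extract_intra(ts, p2, window_spec(20, 10))
  expect_identical(sum(intra2$intra_low$network == "A"), 1L)
  expect_identical(sum(intra2$intra_high$network == "A"), 3L)
})

test_that("constant-correlation input yields constant low-order features", {
  # two states of an AR-free generator with a single planted correlation
  part <- subnet_partition(list(A = 1:3), paste0("r", 1:3))
  spec <- cohort_spec(n_per_group = 1, M_time = 4000, partition = part,
                      rho_within = 0.6, rho_between = 0, n_states = 1,
                      noise_sd = 0, seed = 5)
  ts <- generate_cohort(spec)$timeseries[[1]]
  intra <- extract_intra(ts, part, window_spec(2000, 1000))
  vals <- intra$intra_low$value
  expect_lt(max(vals) - min(vals), 0.06)
  expect_equal(mean(vals), 0.6, tolerance = 0.05)
})

test_that("inter features cover the network-pair triangles", {
  p <- aal_subnetworks()
  set.seed(3)
  ts <- roi_ts(matrix(rnorm(170 * 116), 170, 116), attr(p, "roi_names"))
  inter <- extract_inter(ts, p, window_spec(60, 4))
  expect_identical(nrow(inter$inter_low), 15L)   # 6*5/2
  expect_identical(nrow(inter$inter_high), 21L)  # 6*7/2

  p2 <- toy_partition(N = 6, groups = 2)
  ts2 <- toy_ts(M = 50, N = 6, seed = 9)
  inter2 <- extract_inter(ts2, p2, window_spec(20, 10))
  expect_identical(nrow(inter2$inter_low), 1L)
})

test_that("extract_inter equals composing mean_series, fcn_sequence and the fit", {
  ts <- toy_ts(M = 60, N = 6, seed = 77)
  p <- toy_partition(N = 6, groups = 3)
  spec <- window_spec(25, 5)
  inter <- extract_inter(ts, p, spec)
  ms <- mean_series(ts, p)
  sq <- fcn_sequence(ms, NULL, spec)
  fit <- fit_factor(sq)
  manual_low <- fit$M_hat[cbind(c(2, 3, 3), c(1, 1, 2))]
  expect_equal(inter$inter_low$value, unname(manual_low))
})

test_that("min-max normalisation maps blocks onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_equal(minmax_normalize(c(0, 0.25, 1)), c(0, 0.25, 1))
})

test_that("fusion concatenates blocks in the canonical tag order", {
  ts <- toy_ts(M = 60, N = 6, seed = 31)
  p <- toy_partition(N = 6, groups = 3)
  intra <- extract_intra(ts, p, window_spec(20, 10))
  inter <- extract_inter(ts, p, window_spec(20, 10))
  fused <- fuse_blocks(list(inter$inter_low, intra$intra_high,
                            intra$intra_low, inter$inter_high))
  expect_identical(unique(fused$tag),
                   c("intra_high", "intra_low", "inter_high", "inter_low"))
  expect_identical(nrow(fused), 9L + 3L + 6L + 3L)
  expect_identical(fuse_blocks(list(intra$intra_low)), intra$intra_low)
  expect_error(fuse_blocks(list()), class = "hierfcn_validation")
  expect_error(fuse_blocks(list(intra$intra_low, intra$intra_low)),
               "duplicated", class = "hierfcn_validation")
})

test_that("baseline features match their static/dynamic definitions", {
  set.seed(44)
  ts <- roi_ts(matrix(rnorm(90 * 10), 90, 10), paste0("r", 1:10))
  st <- baseline_static(ts)
  expect_identical(nrow(st), 45L)  # 10*9/2
  expect_equal(sort(st$value), sort(cor(ts$values)[lower.tri(diag(10))]))

  # single full-length window: dynamic == static
  dyn1 <- baseline_dynamic(ts, spec = window_spec(90, 7))
  expect_equal(dyn1$value, st$value)

  # dynamic mean equals fit_mean of the same sequence
  spec <- window_spec(30, 15)
  dyn <- baseline_dynamic(ts, spec = spec)
  m <- fit_mean(fcn_sequence(ts, NULL, spec))
  expect_equal(dyn$value, unname(m[cbind(dyn$roi_i, dyn$roi_j)]))
})

test_that("dimension diagnostics reproduce the sub-network ratio arithmetic", {
  dr <- dimension_report(aal_subnetworks(), 170)
  expect_equal(dr$ratio_to_time[dr$network == "Cerebel"], 26^2 / 170)
  expect_equal(dr$ratio_to_time[dr$network == "full"], 116^2 / 170)
  expect_equal(dr$pct_of_full[dr$network == "DMN"], 22^2 / 116^2 * 100)
  expect_equal(dr$dim[dr$network == "full"], 13456)
})

test_that("the fused feature table has stable width and provenance cover", {
  p <- cohort_partition()
  cohort <- generate_cohort(cohort_spec(n_per_group = 3, M_time = 60,
                                        partition = p, seed = 21,
                                        state_dwell = 30))
  feats <- extract_features(cohort$timeseries, p, window_spec(20, 10))
  prov <- feature_provenance(feats)
  # 3 networks of 4 ROIs: intra_high 3*10, intra_low 3*6, inter_high 6, inter_low 3
  expect_identical(ncol(feats) - 1L, 30L + 18L + 6L + 3L)
  expect_identical(prov$feature, setdiff(colnames(feats), "subject_id"))
  expect_identical(anyDuplicated(prov$feature), 0L)
  expect_identical(nrow(feats), 6L)
})

test_that("low-order vectorisation round-trips through the unit diagonal", {
  a <- random_fcn_array(5, 12, seed = 55)
  fit <- fit_factor(a)
  lt <- hierfcn:::lower_tri_tbl(fit$M_hat, diag = FALSE)
  back <- hierfcn:::unvec_lower_tri(lt$value, 5, diag = FALSE)
  expect_equal(unname(back), unname(fit$M_hat))
})

test_that("permuting ROIs inside a network permutes provenance, not values", {
  ts <- toy_ts(M = 60, N = 6, seed = 91)
  p1 <- subnet_partition(list(A = c(1, 2, 3), B = 4:6), paste0("r", 1:6))
  p2 <- subnet_partition(list(A = c(3, 1, 2), B = 4:6), paste0("r", 1:6))
  i1 <- extract_intra(ts, p1, window_spec(20, 10))
  i2 <- extract_intra(ts, p2, window_spec(20, 10))
  expect_equal(sort(i1$intra_low$value), sort(i2$intra_low$value))
  expect_false(identical(i1$intra_low$roi_i, i2$intra_low$roi_i))
})
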
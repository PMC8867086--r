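# Shared fixtures: everything is generated in code at test time.

# deterministic small time series
toy_ts <- function(M = 40, N = 6, seed = 1, subject_id = "toy") {
  set.seed(seed)
  roi_ts(matrix(rnorm(M * N), M, N), paste0("r", seq_len(N)), subject_id)
}

toy_partition <- function(N = 6, groups = 3) {
  idx <- split(seq_len(N), rep(seq_len(groups), each = N / groups))
  names(idx) <- paste0("net", seq_len(groups))
  subnet_partition(idx, roi_names = paste0("r", seq_len(N)))
}

# random symmetric unit-diagonal "connectivity" matrices
random_fcn_array <- function(n, K, seed, scale = 0.3) {
  set.seed(seed)
  a <- array(0, dim = c(n, n, K))
  for (k in seq_len(K)) {
    m <- matrix(rnorm(n * n, sd = scale), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    a[, , k] <- m
  }
  a
}

# a random symmetric positive-definite matrix
random_spd <- function(n, seed, jitter = 0.5) {
  set.seed(seed)
  B <- matrix(rnorm(n * n), n, n)
  crossprod(B) / n + diag(jitter, n)
}

# small three-network partition used by the cohort-level tests
cohort_partition <- function(n_per_net = 4, networks = c("SMN", "DMN", "Visual")) {
  n <- n_per_net * length(networks)
  idx <- split(seq_len(n), rep(seq_along(networks), each = n_per_net))
  names(idx) <- networks
  subnet_partition(idx, roi_names = paste0("r", seq_len(n)))
}

write_toy_tsv <- function(lines, name = "ts.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
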
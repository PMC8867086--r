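#' Maximum-likelihood mean of a correlation-network sequence
#'
#' The matrix-normal MLE of the population mean is the elementwise average
#' of the `K` sampled matrices; for correlation matrices the unit diagonal
#' is preserved exactly.  This average is the low-order connectivity
#' estimate.
#'
#' @param x An [fcn_sequence()] result, a list of matrices, or an
#'   `N x N x K` array.
#' @return A symmetric `N x N` matrix.
#' @export
fit_mean <- function(x) {
  a <- as_matrix_array(x)
  if (dim(a)[3] < 1L) abort("empty sequence", class = "hierfcn_validation")
  m <- rowMeans(a, dims = 2L)
  dimnames(m) <- dimnames(a[, , 1, drop = FALSE])[1:2]
  m
}

#' Flip-flop MLE of the shared Kronecker covariance factor
#'
#' Fits the matrix-variate normal model `W_k ~ MN(M, C, C)` whose vectorised
#' covariance is the Kronecker product `C %x% C` (the row and column factors
#' coincide because the sampled connectivity matrices are symmetric).  The
#' factor is estimated by the fixed-point iteration
#' `C <- (1/(K * N)) * sum_k (W_k - M) C^{-1} (W_k - M)^T`
#' started from the identity, symmetrising each iterate.  Because both
#' Kronecker factors are constrained equal, the raw substitution alternates
#' the overall scale between the two factors (for 1x1 data it is exactly the
#' 2-periodic map `c -> s/c`), so each iterate is followed by the
#' likelihood-optimal rescaling `alpha^2 = q / (K * n^2)` (`q` being the
#' quadratic form at the new iterate) — the exact maximiser of the
#' log-likelihood along the scale direction — which restores convergence to
#' the balanced fixed point.  The estimated `C` is the high-order
#' connectivity: the covariance structure of whole connectivity matrices
#' across windows.
#'
#' A scaled ridge (`ridge * mean(diag(C))`) is added before inversion only
#' when `C` is numerically singular or ill-conditioned, which is expected
#' whenever the number of windows `K` is below the matrix dimension.  The
#' matrix-normal log-likelihood is recorded at every iterate.
#'
#' @param x Sequence of matrices (as in [fit_mean()]).
#' @param M_hat Mean matrix; defaults to [fit_mean()] of `x`.
#' @param tol Relative Frobenius-change convergence threshold.
#' @param max_iter Maximum number of flip-flop iterations.
#' @param ridge Relative ridge used when inversion needs stabilising; set to
#'   0 to forbid regularisation (degenerate inputs then error).
#' @return An object of class `mvnd_fit` with elements `M_hat`, `C_hat`,
#'   `loglik_trace`, `n_iter`, `converged`, `ridge_used`.
#' @export
#' @examples
#' w <- lapply(1:20, function(k) {m <- diag(3); m[lower.tri(m)] <- rnorm(3, 0, .2)
#'   m[upper.tri(m)] <- t(m)[upper.tri(m)]; m})
#' fit <- fit_factor(w)
#' fit$converged
fit_factor <- function(x, M_hat = NULL, tol = 1e-6, max_iter = 100L, ridge = 1e-6) {
  a <- as_matrix_array(x)
  n <- dim(a)[1]
  K <- dim(a)[3]
  if (dim(a)[2] != n) abort("matrices must be square", class = "hierfcn_validation")
  if (is.null(M_hat)) M_hat <- fit_mean(a)
  if (!isTRUE(all.equal(dim(M_hat), c(n, n)))) {
    abort("M_hat shape incompatible with the sequence", class = "hierfcn_validation")
  }
  resid <- array(a - as.vector(M_hat), dim = dim(a))
  if (max(abs(resid)) < 1e-14 && ridge <= 0) {
    abort("all residuals are zero: degenerate covariance (set ridge > 0)",
          class = "hierfcn_numeric")
  }

  C <- diag(n)
  loglik <- numeric(0)
  ridge_used <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    inv <- stabilised_inverse(C, ridge)
    ridge_used <- max(ridge_used, inv$eps)
    Cnew <- matrix(0, n, n)
    for (k in seq_len(K)) {
      R <- resid[, , k]
      Cnew <- Cnew + R %*% inv$inv %*% t(R)
    }
    Cnew <- Cnew / (K * n)
    Cnew <- (Cnew + t(Cnew)) / 2
    if (any(!is.finite(Cnew))) {
      abort(sprintf("non-finite flip-flop iterate at iteration %d", iter),
            class = "hierfcn_numeric")
    }
    # closed-form scale balancing: maximise the likelihood over alpha in
    # C = alpha * Cnew (alpha^2 = q / (K n^2), q = quadratic form at Cnew)
    inv2 <- stabilised_inverse(Cnew, ridge)
    ridge_used <- max(ridge_used, inv2$eps)
    q <- 0
    for (k in seq_len(K)) {
      R <- resid[, , k]
      q <- q + sum(diag(inv2$inv %*% t(R) %*% inv2$inv %*% R))
    }
    alpha <- sqrt(q / (K * n^2))
    Cnew <- alpha * Cnew
    ll <- matnorm_loglik(a, M_hat, Cnew, ridge = ridge)
    # ascent safeguard: in degenerate regimes (very few samples relative to
    # the matrix dimension) the likelihood is unbounded and the iteration can
    # oscillate; never accept an iterate that lowers the log-likelihood
    if (length(loglik) > 0 && ll < loglik[length(loglik)] - 1e-8) {
      iter <- iter - 1L
      break
    }
    loglik <- c(loglik, ll)
    delta <- norm(Cnew - C, "F") / max(norm(C, "F"), .Machine$double.eps)
    C <- Cnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (sum(diag(C)) < 0) C <- -C  # sign convention: trace(C) > 0
  dimnames(C) <- dimnames(M_hat)
  structure(list(M_hat = M_hat, C_hat = C, loglik_trace = loglik,
                 n_iter = iter, converged = converged, ridge_used = ridge_used,
                 n = n, K = K),
            class = "mvnd_fit")
}

#' Fit the full matrix-normal model to a window sequence
#'
#' Convenience wrapper: [fit_mean()] then [fit_factor()].
#'
#' @inheritParams fit_factor
#' @return An `mvnd_fit` object.
#' @export
fit_mvnd <- function(x, tol = 1e-6, max_iter = 100L, ridge = 1e-6) {
  fit_factor(x, M_hat = NULL, tol = tol, max_iter = max_iter, ridge = ridge)
}

# Inverse of a symmetric PSD matrix; adds eps = ridge * mean(diag) * I only
# when the plain Cholesky fails or the condition number is extreme.
stabilised_inverse <- function(C, ridge) {
  n <- nrow(C)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(ch)) {
    d <- diag(ch)^2
    if (max(d) / max(min(d), .Machine$double.xmin) < 1e12) {
      return(list(inv = chol2inv(ch), eps = 0))
    }
  }
  if (ridge <= 0) {
    abort("singular covariance factor and ridge disabled", class = "hierfcn_numeric")
  }
  scale <- mean(diag(C))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  eps <- ridge * scale
  ch <- tryCatch(chol(C + diag(eps, n)), error = function(e) NULL)
  while (is.null(ch)) {
    eps <- eps * 10
    if (eps > 1e6 * scale) abort("covariance factor irrecoverably singular",
                                 class = "hierfcn_numeric")
    ch <- tryCatch(chol(C + diag(eps, n)), error = function(e) NULL)
  }
  list(inv = chol2inv(ch), eps = eps)
}

#' Matrix-normal log-likelihood with equal row/column factors
#'
#' Sum over the sequence of the log-density of `W_k ~ MN(M, C, C)`, i.e. the
#' multivariate normal density of `vec(W_k)` under covariance `C %x% C`:
#' `-(n^2/2) log(2*pi) - n log|C| - (1/2) tr(C^{-1} (W-M)^T C^{-1} (W-M))`
#' per sample.
#'
#' @param x Sequence of matrices (as in [fit_mean()]).
#' @param M_hat Mean matrix.
#' @param C Covariance factor (positive definite, possibly after ridge).
#' @param ridge Relative ridge applied if `C` is singular; 0 to error
#'   instead.
#' @return A finite scalar log-likelihood.
#' @export
matnorm_loglik <- function(x, M_hat, C, ridge = 0) {
  a <- as_matrix_array(x)
  n <- dim(a)[1]
  inv <- stabilised_inverse(C, ridge)
  Cr <- if (inv$eps > 0) C + diag(inv$eps, n) else C
  ld <- as.numeric(determinant(Cr, logarithm = TRUE)$modulus)
  K <- dim(a)[3]
  quad <- 0
  for (k in seq_len(K)) {
    R <- a[, , k] - M_hat
    quad <- quad + sum(diag(inv$inv %*% t(R) %*% inv$inv %*% R))
  }
  -K * (n^2 / 2) * log(2 * pi) - K * n * ld - quad / 2
}

#' @export
print.mvnd_fit <- function(x, ...) {
  cat(sprintf("<mvnd_fit> %d x %d, K = %d samples; %d iterations (%s), ridge %.2e\n",
              x$n, x$n, x$K, x$n_iter,
              if (x$converged) "converged" else "max_iter reached", x$ridge_used))
  invisible(x)
}

#' Tidy a matrix-normal fit into an edge-level tibble
#'
#' One row per matrix entry of the lower triangle: the mean (low-order
#' connectivity, strict lower triangle) and factor-covariance (high-order,
#' including the diagonal) values with their ROI pair.
#'
#' @param x An `mvnd_fit`.
#' @param ... Unused.
#' @return Tibble with columns `role` (`"mean"`/`"factor"`), `roi_i`,
#'   `roi_j`, `value`.
#' @export
tidy.mvnd_fit <- function(x, ...) {
  rn <- rownames(x$M_hat)
  if (is.null(rn)) rn <- paste0("roi", seq_len(x$n))
  lowm <- lower_tri_tbl(x$M_hat, diag = FALSE, roi_names = rn)
  lowc <- lower_tri_tbl(x$C_hat, diag = TRUE, roi_names = rn)
  dplyr::bind_rows(
    dplyr::mutate(lowm, role = "mean", .before = 1),
    dplyr::mutate(lowc, role = "factor", .before = 1)
  )
}

#' One-row summary of a matrix-normal fit
#' @param x An `mvnd_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `K`, `n_iter`, `converged`, `ridge_used`,
#'   `loglik`.
#' @export
glance.mvnd_fit <- function(x, ...) {
  tibble(n = x$n, K = x$K, n_iter = x$n_iter, converged = x$converged,
         ridge_used = x$ridge_used,
         loglik = if (length(x$loglik_trace)) x$loglik_trace[length(x$loglik_trace)] else NA_real_)
}

# Lower-triangle vectorisation in fixed row-major order over (i > j) pairs:
# i ascending, then j < i (with j <= i when diag = TRUE).  Feature indices
# are stable under this traversal.
lower_tri_tbl <- function(m, diag = FALSE, roi_names = NULL) {
  n <- nrow(m)
  if (is.null(roi_names)) roi_names <- rownames(m)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n))
  ii <- jj <- integer(0)
  for (i in seq_len(n)) {
    j_max <- if (diag) i else i - 1L
    if (j_max >= 1L) {
      ii <- c(ii, rep.int(i, j_max))
      jj <- c(jj, seq_len(j_max))
    }
  }
  tibble(roi_i = roi_names[ii], roi_j = roi_names[jj],
         i = ii, j = jj, value = m[cbind(ii, jj)])
}

# Inverse of the strict-lower-triangle vectorisation with unit diagonal.
unvec_lower_tri <- function(values, n, diag = FALSE) {
  m <- diag(1, n)
  pos <- 1L
  for (i in seq_len(n)) {
    j_max <- if (diag) i else i - 1L
    if (j_max >= 1L) {
      m[i, seq_len(j_max)] <- values[pos:(pos + j_max - 1L)]
      pos <- pos + j_max
    }
  }
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}
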